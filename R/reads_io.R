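#' @useDynLib ssurecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor.test rnorm runif setNames coef simulate
#' @importFrom utils write.table head
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the session RNG as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Convert Phred quality scores to error probabilities
#'
#' @param q integer vector of Phred scores.
#' @return numeric vector, `10^(-q/10)`.
#' @export
phred_to_error_prob <- function(q) 10^(-q / 10)

#' Construct a set of sequencing reads
#'
#' A `read_set` stores read identifiers, called bases and per-base Phred
#' quality scores.  Error probabilities are derived as `10^(-Q/10)`; `N`
#' calls are treated as maximally uninformative (error probability 3/4)
#' wherever probabilities are consumed.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base calls over `A,C,G,T,N`.
#' @param qual list of integer vectors of Phred scores, one per read, each
#'   the same length as the corresponding sequence.
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  seq <- unname(toupper(seq))
  id <- unname(id)
  qual <- unname(qual)
  nc <- nchar(seq)
  ql <- lengths(qual)
  if (any(nc != ql)) {
    bad <- which(nc != ql)[1L]
    stop("read ", id[bad], ": sequence length ", nc[bad],
         " != quality length ", ql[bad])
  }
  structure(list(id = as.character(id), seq = seq,
                 qual = lapply(qual, as.integer)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  if (length(x) > 0) {
    n <- min(3L, length(x))
    for (i in seq_len(n))
      cat(sprintf("  %s  %s%s\n", x$id[i],
                  substr(x$seq[i], 1, 40),
                  if (nchar(x$seq[i]) > 40) "..." else ""))
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Per-base error probabilities of a read set
#'
#' @param reads a [read_set].
#' @return list of numeric vectors; `N` bases get probability 3/4.
#' @export
error_probs <- function(reads) {
  p <- lapply(reads$qual, phred_to_error_prob)
  for (i in which(grepl("N", reads$seq, fixed = TRUE))) {
    b <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]] == "N"
    p[[i]][b] <- 0.75
  }
  p
}

.QUAL_OFFSET <- 33L
.QUAL_MAX <- 45L   # accept Q in [0, 45]; higher suggests a Phred+64 file

#' Read a FASTQ file
#'
#' Parses strict 4-line-record FASTQ with Sanger/Illumina-1.8 Phred+33
#' qualities.  Malformed records raise errors naming the offending line;
#' quality characters outside the Phred+33 range (for example from
#' Phred+64 encoded files) are rejected rather than silently rescaled.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [read_set].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("FASTQ parse error at line ", n,
         ": file does not contain complete 4-line records")
  if (n == 0L) return(read_set(character(), character(), list()))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]

  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1L] - 1L) * 4L + 1L,
         ": record header does not start with '@'")
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1L] - 1L) * 4L + 3L,
         ": separator line does not start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1L] - 1L) * 4L + 4L,
         ": sequence and quality lengths differ")

  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  quals <- lapply(qual, function(qs) {
    q <- utf8ToInt(qs) - .QUAL_OFFSET
    if (length(q) && (min(q) < 0L || max(q) > .QUAL_MAX))
      stop("quality characters outside the Phred+33 range [0, ", .QUAL_MAX,
           "]; Phred+64 encoded input is not supported")
    q
  })
  read_set(ids, toupper(seq), quals)
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads a [read_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qs <- vapply(reads$qual, function(q) intToUtf8(q + .QUAL_OFFSET), "")
  out <- character(4L * length(reads))
  out[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = length(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads))] <- qs
  writeLines(out, path)
  invisible(path)
}

#' Trim low-quality 3' read ends
#'
#' Removes the maximal contiguous run of trailing bases whose Phred
#' quality is at or below `q_threshold`.  Interior low-quality bases are
#' retained; a fully low-quality read becomes empty.
#'
#' @param reads a [read_set].
#' @param q_threshold quality cutoff (default 2).
#' @return the trimmed [read_set].
#' @export
trim_reads <- function(reads, q_threshold = 2) {
  keep <- vapply(reads$qual, function(q) {
    n <- length(q)
    while (n > 0L && q[n] <= q_threshold) n <- n - 1L
    n
  }, 0L)
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- mapply(function(q, k) q[seq_len(k)], reads$qual, keep,
                       SIMPLIFY = FALSE)
  reads
}

#' Filter read pairs on a minimum mate length
#'
#' A pair is kept only if both mates are at least `min_len` bases long
#' (applied after trimming).  Order is preserved.
#'
#' @param reads1,reads2 [read_set]s of the two mates, index-aligned.
#' @param min_len minimum mate length in bp (default 60).
#' @return list with elements `reads1`, `reads2`, `kept` (logical index).
#' @export
filter_pairs <- function(reads1, reads2, min_len = 60) {
  stopifnot(length(reads1) == length(reads2))
  keep <- nchar(reads1$seq) >= min_len & nchar(reads2$seq) >= min_len
  list(reads1 = reads1[keep], reads2 = reads2[keep], kept = keep)
}
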