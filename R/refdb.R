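#' Read a FASTA file of reference sequences
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Pairwise sequence identity from a global alignment
#'
#' Aligns two sequences globally with free end gaps and returns the
#' fraction of matching columns.  With `exclude = "ends"` the denominator
#' is all alignment columns except terminal gap columns (internal gaps
#' count against identity); with `exclude = "all"` only columns where both
#' sequences have a base are counted, the convention used when deciding
#' whether two evolving candidate sequences have become the same.
#'
#' @param a,b sequences (character scalars).
#' @param exclude which gap columns to drop from the denominator.
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b, exclude = c("ends", "all")) {
  exclude <- match.arg(exclude)
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | pb == "-"
  ng <- which(!gap)
  if (length(ng) == 0) return(0)
  idx <- if (exclude == "all") ng else seq(min(ng), max(ng))
  sum(pa[idx] == pb[idx] & pa[idx] != "-") / length(idx)
}

# kmer prescreen wrapper: TRUE if pair could plausibly reach `ident`
.kmer_prescreen <- function(a, b, ident, k = 8L) {
  if (nchar(a) < 4L * k || nchar(b) < 4L * k) return(TRUE)
  # at identity `ident`, expected shared-kmer fraction ~ ident^k; use a
  # generous safety factor so the screen never rejects a true positive
  cpp_shared_kmer_frac(a, b, k) >= 0.25 * ident^k
}

# Normalize database sequences: uppercase, U->T, other IUPAC ambiguity
# codes replaced by a random concrete base compatible with the code.
.AMBIG <- list(R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

normalize_db <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  has_amb <- grepl("[^ACGT]", seqs)
  for (i in which(has_amb)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T"))
    for (j in bad) {
      opts <- .AMBIG[[ch[j]]]
      if (is.null(opts)) opts <- c("A", "C", "G", "T")
      ch[j] <- opts[sample.int(length(opts), 1L)]
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Prepare a candidate reference database
#'
#' Drops sequences outside the accepted length range, normalizes the
#' alphabet (`U` to `T`, uppercase, ambiguity codes replaced by a random
#' compatible base) and collapses near-identical entries by greedy
#' length-sorted centroid clustering: sequences are visited longest first,
#' joining the first existing centroid they match at `cluster_id` global
#' identity or better, otherwise founding a new centroid.
#'
#' @param seqs named character vector of reference sequences.
#' @param min_len,max_len accepted sequence length range in bp.
#' @param cluster_id identity threshold for clustering (fraction).
#' @param seed optional RNG seed (used for ambiguity-code replacement).
#' @return named character vector of cluster centroids, with a
#'   `clusters` attribute mapping every surviving input id to its
#'   centroid id.
#' @export
prepare_db <- function(seqs, min_len = 1200, max_len = 1900,
                       cluster_id = 0.97, seed = NULL) {
  with_seed(seed, {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("reference sequences must have unique names")
    seqs <- normalize_db(seqs)
    len <- nchar(seqs)
    seqs <- seqs[len >= min_len & len <= max_len]
    if (length(seqs) == 0) {
      warning("no sequences survive the length filter")
      return(structure(character(),
                       clusters = setNames(character(), character())))
    }
    ord <- order(-nchar(seqs))  # longest first; ties keep input order
    seqs <- seqs[ord]
    centroid_idx <- integer()
    assign_to <- character(length(seqs))
    for (i in seq_along(seqs)) {
      placed <- FALSE
      for (ci in centroid_idx) {
        if (!.kmer_prescreen(seqs[[ci]], seqs[[i]], cluster_id)) next
        if (seq_identity(seqs[[ci]], seqs[[i]], exclude = "ends") >=
            cluster_id) {
          assign_to[i] <- names(seqs)[ci]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        centroid_idx <- c(centroid_idx, i)
        assign_to[i] <- names(seqs)[i]
      }
    }
    structure(seqs[centroid_idx],
              clusters = setNames(assign_to, names(seqs)))
  })
}

#' Randomly mutate a reference database
#'
#' For each sequence, exactly `round(fraction * length)` distinct
#' positions are chosen uniformly at random and each is replaced by one of
#' the three other bases, chosen uniformly.  Used to test robustness of
#' downstream reconstruction to reference databases that do not contain
#' the true sequences.
#'
#' @param seqs named character vector.
#' @param fraction fraction of positions to mutate per sequence.
#' @param seed optional RNG seed.
#' @return list with `db` (mutated named character vector) and `log`
#'   (data.frame: `seq_id`, `position` (0-based), `ref_base`, `new_base`).
#' @export
mutate_db <- function(seqs, fraction = 0.10, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    logs <- vector("list", length(seqs))
    out <- seqs
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      L <- length(ch)
      k <- round(fraction * L)
      if (k == 0) { logs[[i]] <- NULL; next }
      pos <- sort(sample.int(L, k))
      old <- ch[pos]
      new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "",
                    USE.NAMES = FALSE)
      ch[pos] <- new
      out[[i]] <- paste(ch, collapse = "")
      logs[[i]] <- data.frame(seq_id = names(seqs)[i], position = pos - 1L,
                              ref_base = old, new_base = new,
                              stringsAsFactors = FALSE)
    }
    log <- do.call(rbind, logs)
    if (is.null(log))
      log <- data.frame(seq_id = character(), position = integer(),
                        ref_base = character(), new_base = character(),
                        stringsAsFactors = FALSE)
    rownames(log) <- NULL
    list(db = out, log = log)
  })
}
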