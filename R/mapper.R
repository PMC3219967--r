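#' Read-mapping policy
#'
#' Describes the acceptance rules of the built-in ungapped paired-end
#' mapper, mirroring the mapping policy used for SSU reconstruction: an
#' alignment is valid when it has at most `max_seed_mismatches`
#' mismatches within the first `seed_len` bases of each mate, the Phred
#' qualities of all mismatched bases in a mate sum to at most
#' `max_qual_sum_mismatch`, and (for pairs) the mates are in
#' forward-reverse orientation with an insert length within
#' `insert_median +/- insert_tolerance_sds * insert_sd`.
#'
#' @param seed_len seed length in bp.
#' @param max_seed_mismatches maximum mismatches inside the seed.
#' @param max_qual_sum_mismatch maximum summed Phred quality over
#'   mismatched positions, per mate.
#' @param insert_median,insert_sd expected insert size median and
#'   standard deviation in bp.
#' @param insert_tolerance_sds allowed deviation in standard deviations.
#' @param report_mode `"all_top_stratum"` reports every valid placement
#'   with the minimal total mismatch count; `"best_single_random_tie"`
#'   reports one of them, chosen uniformly at random.
#' @return an object of class `mapping_policy`.
#' @export
mapping_policy <- function(seed_len = 20, max_seed_mismatches = 3,
                           max_qual_sum_mismatch = 300,
                           insert_median = 200, insert_sd = 25,
                           insert_tolerance_sds = 3,
                           report_mode = c("all_top_stratum",
                                           "best_single_random_tie")) {
  report_mode <- match.arg(report_mode)
  stopifnot(seed_len >= 1, max_seed_mismatches >= 0,
            max_qual_sum_mismatch >= 0, insert_median >= 0,
            insert_sd >= 0, insert_tolerance_sds >= 0)
  structure(list(seed_len = as.integer(seed_len),
                 max_seed_mismatches = as.integer(max_seed_mismatches),
                 max_qual_sum_mismatch = as.integer(max_qual_sum_mismatch),
                 insert_median = insert_median, insert_sd = insert_sd,
                 insert_tolerance_sds = insert_tolerance_sds,
                 report_mode = report_mode),
            class = "mapping_policy")
}

#' @export
print.mapping_policy <- function(x, ...) {
  cat("mapping policy:\n")
  cat(sprintf("  seed: <= %d mismatches in first %d bp\n",
              x$max_seed_mismatches, x$seed_len))
  cat(sprintf("  mismatch quality sum: <= %d per mate\n",
              x$max_qual_sum_mismatch))
  cat(sprintf("  insert: %g +/- %g x %g bp, FR orientation\n",
              x$insert_median, x$insert_tolerance_sds, x$insert_sd))
  cat("  report:", x$report_mode, "\n")
  invisible(x)
}

insert_bounds <- function(policy) {
  tol <- policy$insert_tolerance_sds * policy$insert_sd
  c(as.integer(floor(policy$insert_median - tol)),
    as.integer(ceiling(policy$insert_median + tol)))
}

#' Map reads or read pairs to reference sequences
#'
#' Deterministic ungapped mapping of single reads or read pairs against a
#' set of reference sequences under a [mapping_policy()].  Both strands
#' are searched.  Per read (or pair) and reference, the best placement is
#' kept (fewest mismatches; ties resolved to the plus strand, then the
#' smallest offsets); across references only the top stratum (minimal
#' mismatch count) is reported, either in full or as a single random
#' draw depending on the policy's `report_mode`.
#'
#' @param reads1 a [read_set] (first mates, or single-end reads).
#' @param reads2 optional [read_set] of second mates (as sequenced, i.e.
#'   reverse-complement orientation relative to the fragment).
#' @param refs named character vector of reference sequences.
#' @param policy a [mapping_policy()].
#' @param mode optional override of the policy's report mode.
#' @param seed optional RNG seed for random tie-breaking.
#' @return data.frame with columns `read` (index into `reads1`), `ref`
#'   (reference name), `start1` (0-based leftmost offset of mate 1),
#'   `strand1` (`+`/`-`), `start2`, `strand2` (NA for single-end) and
#'   `mismatches` (total).  Reads with no valid placement are absent.
#' @export
map_reads <- function(reads1, reads2 = NULL, refs, policy = mapping_policy(),
                      mode = NULL, seed = NULL) {
  stopifnot(inherits(reads1, "read_set"), length(refs) > 0,
            !is.null(names(refs)))
  if (!is.null(reads2)) stopifnot(length(reads1) == length(reads2))
  mode <- if (is.null(mode)) policy$report_mode else
    match.arg(mode, c("all_top_stratum", "best_single_random_tie"))
  ib <- insert_bounds(policy)
  res <- with_seed(seed, cpp_map_reads(
    unname(refs), reads1$seq, reads1$qual,
    if (is.null(reads2)) NULL else reads2$seq,
    if (is.null(reads2)) NULL else reads2$qual,
    policy$seed_len, policy$max_seed_mismatches,
    policy$max_qual_sum_mismatch, ib[1], ib[2],
    mode == "best_single_random_tie"))
  data.frame(read = res$read, ref = names(refs)[res$ref],
             start1 = res$start1,
             strand1 = ifelse(res$strand1 > 0, "+", "-"),
             start2 = res$start2,
             strand2 = ifelse(is.na(res$strand2), NA,
                              ifelse(res$strand2 > 0, "+", "-")),
             mismatches = res$mismatches, stringsAsFactors = FALSE)
}

#' Import read placements from a SAM or BAM file
#'
#' Converts primary and secondary ungapped alignments produced by an
#' external mapper into the placement table used by the reconstruction
#' engine.  Alignments whose CIGAR contains indels or clipping are
#' skipped (the engine is ungapped by construction) and counted in the
#' `skipped` attribute; unmapped records are ignored.  Mates of a proper
#' pair aligned to the same reference are combined into one paired
#' placement; remaining alignments are emitted as single-end placements.
#'
#' @param path path to a SAM (text) or BAM file.
#' @param refs named character vector of reference sequences; alignment
#'   reference names must be a subset of `names(refs)`.
#' @return placement data.frame as for [map_reads()], with `read` holding
#'   query names rather than indices, plus a `skipped` attribute.
#' @export
read_sam <- function(path, refs) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  rn <- as.character(b$rname)
  unknown <- setdiff(unique(rn[mapped]), names(refs))
  if (length(unknown))
    stop("alignment reference not in candidate set: ",
         paste(unknown, collapse = ", "))
  ungapped <- grepl("^[0-9]+M$", b$cigar)
  skipped <- sum(mapped & !ungapped)
  if (skipped > 0)
    warning(skipped, " alignment(s) with indel/clip CIGAR skipped")
  use <- which(mapped & ungapped)

  qname <- b$qname[use]
  flag <- b$flag[use]
  rname <- rn[use]
  start <- b$pos[use] - 1L                      # SAM POS is 1-based
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  mate1 <- bitwAnd(flag, 64L) > 0L
  mate2 <- bitwAnd(flag, 128L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L

  out <- list()
  used <- rep(FALSE, length(use))
  # pair up primary proper-pair mates on the same reference
  key <- paste(qname, rname)
  cand1 <- which(mate1 & proper & !secondary)
  idx2 <- split(which(mate2 & proper & !secondary),
                key[mate2 & proper & !secondary])
  for (i in cand1) {
    js <- idx2[[key[i]]]
    js <- js[!used[js] & strand[js] != strand[i]]
    if (length(js) == 0) next
    j <- js[1]
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      read = qname[i], ref = rname[i], start1 = start[i],
      strand1 = strand[i], start2 = start[j], strand2 = strand[j],
      mismatches = NA_integer_, stringsAsFactors = FALSE)
  }
  rest <- which(!used)
  if (length(rest))
    out[[length(out) + 1L]] <- data.frame(
      read = qname[rest], ref = rname[rest], start1 = start[rest],
      strand1 = strand[rest], start2 = NA_integer_,
      strand2 = NA_character_, mismatches = NA_integer_,
      stringsAsFactors = FALSE)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read = character(), ref = character(), start1 = integer(),
               strand1 = character(), start2 = integer(),
               strand2 = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
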