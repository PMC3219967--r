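.BASES <- c("A", "C", "G", "T")

base_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES)  # NA for N etc.
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Build candidate sequences from reference sequences
#'
#' Each candidate holds a per-position base probability matrix (rows sum
#' to one), its consensus (per-position argmax) and a prior probability
#' (its current abundance estimate).  Reference bases start as point
#' masses; positions with ambiguous input get a uniform row.
#'
#' @param refs named character vector of reference sequences.
#' @param priors optional named prior vector (default uniform).
#' @return list of candidates, class `ssu_candidates`.
#' @export
new_candidates <- function(refs, priors = NULL) {
  stopifnot(!is.null(names(refs)), !anyDuplicated(names(refs)))
  if (is.null(priors))
    priors <- setNames(rep(1 / length(refs), length(refs)), names(refs))
  out <- lapply(names(refs), function(id) {
    cs <- toupper(refs[[id]])
    code <- base_codes(cs)
    L <- length(code)
    m <- matrix(0, L, 4, dimnames = list(NULL, .BASES))
    known <- !is.na(code)
    m[cbind(which(known), code[known])] <- 1
    if (any(!known)) {
      m[!known, ] <- 0.25
      cs <- paste(ifelse(known, strsplit(cs, "")[[1]], "A"), collapse = "")
    }
    list(id = id, probs = m, consensus = cs,
         prior = unname(priors[[id]]), coverage = integer(L))
  })
  names(out) <- names(refs)
  class(out) <- "ssu_candidates"
  out
}

#' @export
`[.ssu_candidates` <- function(x, i) {
  structure(unclass(x)[i], class = "ssu_candidates")
}

#' Current priors of a candidate set
#' @param candidates an `ssu_candidates` list.
#' @return named numeric vector.
#' @export
candidate_priors <- function(candidates)
  vapply(candidates, function(c) c$prior, 0)

#' Current consensus sequences of a candidate set
#' @param candidates an `ssu_candidates` list.
#' @return named character vector.
#' @export
candidate_consensus <- function(candidates)
  vapply(candidates, function(c) c$consensus, "")

# per-row argmax with tolerance-aware tie-breaking: previous consensus
# base wins ties, then alphabetical order
consensus_from_probs <- function(probs, prev = NULL, tol = 1e-12) {
  L <- nrow(probs)
  mx <- do.call(pmax, lapply(1:4, function(j) probs[, j]))
  pick <- max.col(probs, ties.method = "first")  # first = alphabetical
  if (!is.null(prev)) {
    pc <- base_codes(prev)
    tied <- !is.na(pc) & probs[cbind(seq_len(L), pc)] >= mx - tol
    pick[tied] <- pc[tied]
  }
  paste(.BASES[pick], collapse = "")
}

#' Probability of observing a read base given a reference base distribution
#'
#' Marginalizes the per-base sequencing error model over the reference
#' base distribution: a matching base is observed with probability
#' `1 - p` and each of the three mismatching bases with probability
#' `p / 3`, where `p` is the base's error probability.
#'
#' @param read_base single character in `A,C,G,T,N`.
#' @param error_prob the base's error probability in `(0, 1]`.
#' @param ref_base_dist numeric vector of length 4 (probabilities of
#'   `A,C,G,T` at the reference position), summing to one.
#' @return the emission probability.
#' @export
base_emission_prob <- function(read_base, error_prob, ref_base_dist) {
  stopifnot(length(ref_base_dist) == 4,
            abs(sum(ref_base_dist) - 1) < 1e-6)
  b <- match(toupper(read_base), .BASES)
  if (is.na(b)) return(error_prob / 3)  # uninformative call
  (1 - error_prob) * ref_base_dist[[b]] +
    (error_prob / 3) * (1 - ref_base_dist[[b]])
}

#' Log-likelihood of a read (or pair) given a candidate sequence
#'
#' Product over all mapped positions of the emission probabilities
#' ([base_emission_prob()]); the two mates of a pair are treated as one
#' longer read.  Minus-strand mates are compared reverse-complemented.
#'
#' @param candidate one candidate (element of [new_candidates()]).
#' @param seq1,ep1 mate-1 bases and error probabilities (as sequenced).
#' @param start1,strand1 0-based leftmost offset and strand (`"+"`/`"-"`).
#' @param seq2,ep2,start2,strand2 optional mate 2.
#' @return log-likelihood (natural log).
#' @export
read_likelihood <- function(candidate, seq1, ep1, start1, strand1,
                            seq2 = NULL, ep2 = NULL, start2 = NULL,
                            strand2 = NULL) {
  one <- function(seq, ep, start, strand) {
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    if (strand == "-") {
      ch <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
      ep <- rev(ep)
    }
    ll <- 0
    for (i in seq_along(ch))
      ll <- ll + log(base_emission_prob(ch[i], ep[i],
                                        candidate$probs[start + i, ]))
    ll
  }
  ll <- one(seq1, ep1, start1, strand1)
  if (!is.null(seq2)) ll <- ll + one(seq2, ep2, start2, strand2)
  ll
}

strand_int <- function(s) ifelse(is.na(s), NA_integer_,
                                 ifelse(s == "+", 1L, -1L))

#' Expectation step: posterior read-to-candidate assignment
#'
#' For every mapped read (or pair), computes the posterior probability
#' that each mapped candidate generated it: likelihood times the
#' candidate's prior, normalized over the read's mapped candidates
#' (log-sum-exp).  Candidates without a reported mapping for a read have
#' posterior exactly zero.  A read whose total probability underflows
#' falls back to a uniform posterior over its mapped candidates (counted
#' in the `n_fallback` attribute).
#'
#' @param records placement data.frame from [map_reads()].
#' @param reads1,reads2 the [read_set]s that were mapped.
#' @param candidates an `ssu_candidates` list.
#' @param ep1,ep2 optional precomputed [error_probs()].
#' @return `records` sorted by read, with `loglik` and `posterior`
#'   columns appended (class `posterior_table`); attributes
#'   `total_loglik` (sum over reads of log marginal probability),
#'   `n_reads`, `n_fallback`.
#' @export
e_step <- function(records, reads1, reads2 = NULL, candidates,
                   ep1 = NULL, ep2 = NULL) {
  ids <- names(candidates)
  cand <- match(records$ref, ids)
  if (anyNA(cand)) stop("placement references unknown candidate")
  ord <- order(records$read)
  records <- records[ord, , drop = FALSE]
  cand <- cand[ord]
  if (is.null(ep1)) ep1 <- error_probs(reads1)
  if (!is.null(reads2) && is.null(ep2)) ep2 <- error_probs(reads2)
  pri <- candidate_priors(candidates)
  res <- cpp_estep(records$read, cand,
                   records$start1, strand_int(records$strand1),
                   if (is.null(reads2)) rep(NA_integer_, nrow(records))
                   else records$start2,
                   strand_int(records$strand2),
                   reads1$seq, ep1,
                   if (is.null(reads2)) NULL else reads2$seq,
                   if (is.null(reads2)) NULL else ep2,
                   lapply(candidates, function(c) c$probs),
                   log(pri))
  records$loglik <- res$loglik
  records$posterior <- res$posterior
  rownames(records) <- NULL
  structure(records, class = c("posterior_table", "data.frame"),
            total_loglik = sum(res$read_lognorm),
            n_reads = length(res$read_id), n_fallback = res$n_fallback)
}

#' Maximization step: update candidate priors (abundances)
#'
#' The new prior of each candidate is the mean of its posterior
#' assignment probabilities over all reads with mappings.
#'
#' @param post a `posterior_table` from [e_step()].
#' @return named numeric vector summing to one over candidates with
#'   nonzero posterior mass.
#' @export
m_step_priors <- function(post) {
  J <- length(unique(post$read))
  if (J == 0) stop("no reads mapped")
  mass <- rowsum(post$posterior, post$ref)
  setNames(as.vector(mass) / J, rownames(mass))
}

#' Maximization step: correct candidate sequences
#'
#' Recomputes every candidate's per-position base probabilities as the
#' posterior-weighted, quality-adjusted sum of evidence from aligned read
#' bases, then renormalizes each row and recomputes the consensus
#' (argmax; ties broken by the previous consensus base, then
#' alphabetically).  Positions covered by no read retain their previous
#' row.
#'
#' @param post a `posterior_table` from [e_step()].
#' @param reads1,reads2 the mapped [read_set]s.
#' @param candidates an `ssu_candidates` list.
#' @param ep1,ep2 optional precomputed [error_probs()].
#' @return the updated `ssu_candidates` list.
#' @export
m_step_consensus <- function(post, reads1, reads2 = NULL, candidates,
                             ep1 = NULL, ep2 = NULL) {
  ids <- names(candidates)
  cand <- match(post$ref, ids)
  if (is.null(ep1)) ep1 <- error_probs(reads1)
  if (!is.null(reads2) && is.null(ep2)) ep2 <- error_probs(reads2)
  lens <- vapply(candidates, function(c) nrow(c$probs), 0L)
  res <- cpp_mstep_acc(post$read, cand,
                       post$start1, strand_int(post$strand1),
                       if (is.null(reads2)) rep(NA_integer_, nrow(post))
                       else post$start2,
                       strand_int(post$strand2),
                       post$posterior,
                       reads1$seq, ep1,
                       if (is.null(reads2)) NULL else reads2$seq,
                       if (is.null(reads2)) NULL else ep2,
                       unname(lens))
  for (i in seq_along(candidates)) {
    acc <- res$acc[[i]]
    cov <- res$coverage[[i]]
    upd <- cov > 0L
    if (!any(upd)) { candidates[[i]]$coverage <- cov; next }
    pos <- which(upd & rowSums(acc) > 0)
    probs <- candidates[[i]]$probs
    probs[pos, ] <- acc[pos, , drop = FALSE] /
      rowSums(acc[pos, , drop = FALSE])
    colnames(probs) <- .BASES
    candidates[[i]]$probs <- probs
    candidates[[i]]$consensus <-
      consensus_from_probs(probs, prev = candidates[[i]]$consensus)
    candidates[[i]]$coverage <- cov
  }
  candidates
}

#' Merge candidates that have converged onto the same sequence
#'
#' Any pair of candidate consensus sequences whose global-alignment
#' identity over non-gapped positions exceeds `merge_id` is collapsed:
#' the lower-prior candidate is absorbed into the higher-prior one, which
#' keeps its base probabilities and gains the absorbed prior.  Pairs are
#' examined highest-prior-first and the scan restarts after every merge
#' so transitive chains collapse fully.
#'
#' @param candidates an `ssu_candidates` list.
#' @param merge_id identity threshold (strict: merge only above it).
#' @return list with `candidates` and `n_merged`.
#' @export
merge_pass <- function(candidates, merge_id = 0.97) {
  n_merged <- 0L
  repeat {
    if (length(candidates) < 2) break
    pri <- candidate_priors(candidates)
    ord <- order(-pri)
    merged <- FALSE
    for (a in seq_along(ord)[-length(ord)]) {
      i <- ord[a]
      for (b in seq((a + 1), length(ord))) {
        j <- ord[b]
        ci <- candidates[[i]]$consensus
        cj <- candidates[[j]]$consensus
        if (ci != cj && !.kmer_prescreen(ci, cj, merge_id)) next
        if (ci == cj || seq_identity(ci, cj, exclude = "all") > merge_id) {
          candidates[[i]]$prior <- candidates[[i]]$prior +
            candidates[[j]]$prior
          candidates[[j]] <- NULL
          n_merged <- n_merged + 1L
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(candidates = candidates, n_merged = n_merged)
}

#' Split candidates showing evidence of multiple strains
#'
#' A candidate is duplicated when the second most probable base exceeds
#' `minor_prob` at strictly more than `site_frac` of its positions.  The
#' twin takes the second most probable base at every such variant
#' position (sharp rows, `1 - 0.01` on the chosen base) and the parent's
#' rows elsewhere; the parent's prior is divided between the two in
#' proportion to the mean major and minor base probabilities over the
#' variant positions.
#'
#' @param candidates an `ssu_candidates` list.
#' @param minor_prob minor-base probability threshold.
#' @param site_frac fraction-of-positions threshold (strict).
#' @return list with `candidates`, `n_split` and `n_variant_positions`
#'   (total variant positions written into twins).
#' @export
split_pass <- function(candidates, minor_prob = 0.10, site_frac = 0.04) {
  eps <- 0.01
  n_split <- 0L
  n_var <- 0L
  new <- list()
  existing <- names(candidates)
  for (cd in candidates) {
    m <- cd$probs
    L <- nrow(m)
    i1 <- max.col(m, ties.method = "first")
    mx <- m[cbind(seq_len(L), i1)]
    m2 <- m
    m2[cbind(seq_len(L), i1)] <- -Inf
    i2 <- max.col(m2, ties.method = "first")
    second <- m2[cbind(seq_len(L), i2)]
    variant <- second > minor_prob
    if (sum(variant) / L > site_frac) {
      k <- 1L
      repeat {
        nid <- paste0(cd$id, "_v", k)
        if (!nid %in% c(existing, names(new))) break
        k <- k + 1L
      }
      tp <- cd$probs
      vpos <- which(variant)
      tp[vpos, ] <- eps / 3
      tp[cbind(vpos, i2[vpos])] <- 1 - eps
      tch <- strsplit(cd$consensus, "", fixed = TRUE)[[1]]
      tch[vpos] <- .BASES[i2[vpos]]
      wmaj <- mean(mx[vpos])
      wmin <- mean(second[vpos])
      twin <- list(id = nid, probs = tp,
                   consensus = paste(tch, collapse = ""),
                   prior = cd$prior * wmin / (wmaj + wmin),
                   coverage = cd$coverage)
      cd$prior <- cd$prior * wmaj / (wmaj + wmin)
      new[[nid]] <- twin
      n_split <- n_split + 1L
      n_var <- n_var + length(vpos)
    }
    new[[cd$id]] <- cd
  }
  # keep original ordering: parents first in input order, twins after
  ordered <- c(names(candidates), setdiff(names(new), names(candidates)))
  out <- new[ordered]
  class(out) <- "ssu_candidates"
  list(candidates = out, n_split = n_split, n_variant_positions = n_var)
}

#' Initialize the reconstruction state by hard assignment
#'
#' Maps every read (pair) in best-single mode (random tie-breaking among
#' equally good references), assigns each read wholly to its chosen
#' reference, drops references with no assigned reads, sets priors to the
#' assigned read fractions and runs one maximization step to correct the
#' starting sequences.
#'
#' @param reads1,reads2 [read_set]s (mate 2 optional).
#' @param db named character vector of candidate reference sequences.
#' @param policy a [mapping_policy()].
#' @param seed optional RNG seed for tie-breaking.
#' @param ep1,ep2 optional precomputed [error_probs()].
#' @return list (class `em_state`) with `candidates`, `J` (mapped reads)
#'   and `iteration = 0`.
#' @export
em_initialize <- function(reads1, reads2 = NULL, db,
                          policy = mapping_policy(), seed = NULL,
                          ep1 = NULL, ep2 = NULL) {
  rec <- map_reads(reads1, reads2, db, policy,
                   mode = "best_single_random_tie", seed = seed)
  if (nrow(rec) == 0) stop("no reads mapped to the starting database")
  rec$posterior <- 1
  rec$loglik <- NA_real_
  J <- nrow(rec)
  counts <- table(rec$ref)
  keep <- names(counts)
  pri <- setNames(as.vector(counts) / J, keep)
  candidates <- new_candidates(db[keep], priors = pri)
  candidates <- m_step_consensus(rec, reads1, reads2, candidates,
                                 ep1 = ep1, ep2 = ep2)
  structure(list(candidates = candidates, J = J, iteration = 0L),
            class = "em_state")
}
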