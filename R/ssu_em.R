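#' Reconstruct full-length SSU rRNA genes from short reads
#'
#' Fits a probabilistic mixture of candidate SSU gene sequences to short
#' shotgun reads by expectation maximization.  Starting from a candidate
#' reference database, reads are mapped (ungapped, both strands, pairs in
#' forward-reverse orientation), multi-mapping reads are assigned
#' probabilistically (E-step), and each candidate's abundance prior and
#' per-position base probabilities are re-estimated from the weighted
#' read evidence (M-step).  Candidates that converge onto each other are
#' merged; candidates showing minor-allele evidence of multiple strains
#' are split.  Iteration stops when no consensus base changes and the
#' priors have stabilized, or after `max_iter` iterations.
#'
#' @param reads1 first mates: a [read_set] or a FASTQ path.
#' @param reads2 optional second mates (as sequenced).
#' @param db candidate reference sequences: named character vector or a
#'   FASTA path.  Typically prepared with [prepare_db()].
#' @param policy a [mapping_policy()]; set `insert_median`/`insert_sd` to
#'   the library's values.
#' @param max_iter maximum EM iterations.
#' @param merge_id consensus identity above which candidates merge.
#' @param split_minor_prob,split_site_frac thresholds of the strain
#'   splitting rule (see [split_pass()]).
#' @param report_threshold candidates below this final prior are dropped
#'   from summaries and FASTA output only; the fit itself keeps them.
#' @param prior_tol priors are considered stable when no prior moves by
#'   more than this over each of the last three iterations.
#' @param trim apply 3'-end quality trimming ([trim_reads()]) and the
#'   minimum-length pair filter before fitting.  Disable for read sets
#'   shorter than `min_read_len`.
#' @param min_read_len minimum post-trim mate length.
#' @param q_trim trimming quality cutoff.
#' @param mapper `"internal"` remaps reads against the current consensus
#'   sequences every iteration; a path to a SAM/BAM file freezes the
#'   mapping to the supplied external alignments (read names must match
#'   the FASTQ ids up to a `/1` / `/2` mate suffix).
#' @param seed optional integer seed controlling every random draw of
#'   the run (mapping tie-breaks).
#' @param verbose print per-iteration progress.
#' @return an object of class `ssu_em`; see [coef.ssu_em()],
#'   [summary.ssu_em()], [plot.ssu_em()], [write_ssu_fasta()],
#'   [probability_track()].
#' @export
ssu_em <- function(reads1, reads2 = NULL, db, policy = mapping_policy(),
                   max_iter = 40, merge_id = 0.97,
                   split_minor_prob = 0.10, split_site_frac = 0.04,
                   report_threshold = 0, prior_tol = 1e-4,
                   trim = TRUE, min_read_len = 60, q_trim = 2,
                   mapper = "internal", seed = NULL, verbose = FALSE) {
  cl <- match.call()
  t0 <- proc.time()[["elapsed"]]
  if (is.character(reads1) && length(reads1) == 1) reads1 <- read_fastq(reads1)
  if (is.character(reads2) && length(reads2) == 1) reads2 <- read_fastq(reads2)
  if (is.character(db) && length(db) == 1 && file.exists(db))
    db <- read_fasta(db)
  stopifnot(inherits(reads1, "read_set"), is.character(db),
            !is.null(names(db)))
  paired <- !is.null(reads2)

  if (trim) {
    reads1 <- trim_reads(reads1, q_trim)
    if (paired) {
      reads2 <- trim_reads(reads2, q_trim)
      fp <- filter_pairs(reads1, reads2, min_read_len)
      reads1 <- fp$reads1
      reads2 <- fp$reads2
    } else {
      reads1 <- reads1[nchar(reads1$seq) >= min_read_len]
    }
  }
  n_input <- length(reads1)
  if (n_input == 0) stop("no reads left after trimming/filtering")
  ep1 <- error_probs(reads1)
  ep2 <- if (paired) error_probs(reads2) else NULL

  frozen <- NULL
  if (!identical(mapper, "internal")) {
    sam <- read_sam(mapper, db)
    strip <- function(x) sub("/[12]$", "", x)
    idx <- match(strip(sam$read), strip(reads1$id))
    if (anyNA(idx))
      stop("SAM read names not found in the FASTQ input: ",
           paste(head(unique(sam$read[is.na(idx)]), 3), collapse = ", "))
    sam$read <- idx
    frozen <- sam
  }

  with_seed(seed, {
    state <- if (is.null(frozen)) {
      em_initialize(reads1, reads2, db, policy, ep1 = ep1, ep2 = ep2)
    } else {
      init_from_frozen(frozen, reads1, reads2, db, ep1, ep2)
    }
    cands <- state$candidates
    prev_consensus <- candidate_consensus(cands)
    prev_priors <- candidate_priors(cands)

    nt_changes <- integer(0)
    prior_hist <- list(candidate_priors(cands))
    loglik_hist <- numeric(0)
    J_hist <- integer(0)
    inv_dev <- numeric(0)
    n_fallback <- 0L
    converged <- FALSE
    iter <- 0L
    stable_priors <- 0L

    while (iter < max_iter) {
      iter <- iter + 1L
      rec <- if (is.null(frozen)) {
        map_reads(reads1, reads2, candidate_consensus(cands), policy,
                  mode = "all_top_stratum")
      } else {
        frozen[frozen$ref %in% names(cands), , drop = FALSE]
      }
      if (nrow(rec) == 0) stop("no reads mapped at iteration ", iter)

      post <- e_step(rec, reads1, reads2, cands, ep1 = ep1, ep2 = ep2)
      n_fallback <- n_fallback + attr(post, "n_fallback")
      J <- attr(post, "n_reads")
      pri <- m_step_priors(post)

      # prune candidates whose posterior mass fell to exactly zero
      pri <- pri[pri > 0]
      keep <- names(cands)[names(cands) %in% names(pri)]
      cands <- cands[keep]
      for (id in keep) cands[[id]]$prior <- unname(pri[[id]])
      post <- post[post$ref %in% keep, , drop = FALSE]

      cands <- m_step_consensus(post, reads1, reads2, cands,
                                ep1 = ep1, ep2 = ep2)
      mp <- merge_pass(cands, merge_id)
      sp <- split_pass(mp$candidates, split_minor_prob, split_site_frac)
      cands <- sp$candidates

      # invariant checks (posterior rows, priors, base-probability rows)
      dev_post <- max(abs(rowsum(post$posterior, post$read) - 1))
      dev_pri <- abs(sum(candidate_priors(cands)) - 1)
      dev_rows <- max(vapply(cands, function(c)
        max(abs(rowSums(c$probs) - 1)), 0))
      inv_dev[iter] <- max(dev_post, dev_pri, dev_rows)

      # consensus changes relative to the previous iteration
      cur_consensus <- candidate_consensus(cands)
      shared <- intersect(names(cur_consensus), names(prev_consensus))
      nt <- sum(vapply(shared, function(id)
        hamming(cur_consensus[[id]], prev_consensus[[id]]), 0)) +
        sp$n_variant_positions
      nt_changes[iter] <- nt

      cur_priors <- candidate_priors(cands)
      all_ids <- union(names(cur_priors), names(prev_priors))
      dprior <- max(abs(
        ifelse(all_ids %in% names(cur_priors), cur_priors[all_ids], 0) -
        ifelse(all_ids %in% names(prev_priors), prev_priors[all_ids], 0)))
      stable_priors <- if (dprior < prior_tol) stable_priors + 1L else 0L

      prior_hist[[iter + 1L]] <- cur_priors
      loglik_hist[iter] <- attr(post, "total_loglik")
      J_hist[iter] <- J
      if (verbose)
        message(sprintf(
          "iter %2d: %d candidates, J=%d, nt changes=%d, max dPrior=%.2e",
          iter, length(cands), J, nt, dprior))

      prev_consensus <- cur_consensus
      prev_priors <- cur_priors
      if (nt == 0 && stable_priors >= 3L) { converged <- TRUE; break }
    }

    ord <- order(-candidate_priors(cands))
    cands <- cands[ord]
    structure(list(
      candidates = cands,
      prior = candidate_priors(cands),
      consensus = candidate_consensus(cands),
      n_reads_input = n_input,
      n_reads_mapped = if (length(J_hist)) J_hist[length(J_hist)] else NA,
      iterations = iter, converged = converged,
      nt_changes = nt_changes, prior_history = prior_hist,
      loglik = loglik_hist, J_history = J_hist,
      invariant_deviation = inv_dev, n_underflow_fallback = n_fallback,
      report_threshold = report_threshold, policy = policy,
      paired = paired, seed = seed, call = cl,
      elapsed = proc.time()[["elapsed"]] - t0),
      class = "ssu_em")
  })
}

# hard-assignment initialization from a frozen external mapping
init_from_frozen <- function(frozen, reads1, reads2, db, ep1, ep2) {
  rec <- frozen
  # keep one best placement per read at random among its references
  picks <- vapply(split(seq_len(nrow(rec)), rec$read), function(ix)
    ix[sample.int(length(ix), 1L)], 0L)
  rec <- rec[picks, , drop = FALSE]
  rec$posterior <- 1
  J <- nrow(rec)
  counts <- table(rec$ref)
  pri <- setNames(as.vector(counts) / J, names(counts))
  candidates <- new_candidates(db[names(counts)], priors = pri)
  candidates <- m_step_consensus(rec, reads1, reads2, candidates,
                                 ep1 = ep1, ep2 = ep2)
  structure(list(candidates = candidates, J = J, iteration = 0L),
            class = "em_state")
}

#' @export
print.ssu_em <- function(x, ...) {
  cat("SSU gene reconstruction by expectation maximization\n")
  cat(sprintf("  %d reads in, %s mapped at the final iteration\n",
              x$n_reads_input, format(x$n_reads_mapped)))
  cat(sprintf("  %d candidate sequence(s) after %d iteration(s) (%s)\n",
              length(x$candidates), x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  top <- head(x$prior, 5)
  for (i in seq_along(top))
    cat(sprintf("  %-20s prior %.4f  length %d\n", names(top)[i], top[i],
                nchar(x$consensus[[i]])))
  if (length(x$prior) > 5) cat("  ...\n")
  invisible(x)
}

#' Final abundance estimates (priors) of a reconstruction
#' @param object an `ssu_em` fit.
#' @param ... unused.
#' @return named numeric vector, sorted decreasing.
#' @export
coef.ssu_em <- function(object, ...) object$prior

#' @export
summary.ssu_em <- function(object, ...) {
  keep <- object$prior >= object$report_threshold
  amb <- vapply(object$candidates, function(c) {
    m <- c$probs
    i1 <- max.col(m, ties.method = "first")
    m[cbind(seq_len(nrow(m)), i1)] <- -Inf
    sum(apply(m, 1, max) > 0.10)
  }, 0L)
  tab <- data.frame(id = names(object$prior), prior = unname(object$prior),
                    length = nchar(unname(object$consensus)),
                    ambiguous_positions = unname(amb),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, iterations = object$iterations,
                 converged = object$converged,
                 n_reads_mapped = object$n_reads_mapped,
                 report_threshold = object$report_threshold),
            class = "summary.ssu_em")
}

#' @export
print.summary.ssu_em <- function(x, ...) {
  cat(sprintf(
    "Reconstructed SSU sequences (prior >= %g), %d iterations, %s:\n",
    x$report_threshold, x$iterations,
    if (x$converged) "converged" else "not converged"))
  print(x$table, digits = 4)
  invisible(x)
}

#' Convergence diagnostics plot
#'
#' Two panels: consensus base changes per iteration, and each
#' candidate's prior probability trajectory (candidates below
#' `threshold` at the end are drawn grey).
#'
#' @param x an `ssu_em` fit.
#' @param threshold highlight threshold for the prior panel.
#' @param ... unused.
#' @export
plot.ssu_em <- function(x, threshold = 0.01, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$nt_changes), x$nt_changes, type = "b",
                 xlab = "iteration", ylab = "consensus base changes",
                 main = "sequence convergence", pch = 16)
  ids <- unique(unlist(lapply(x$prior_history, names)))
  iters <- seq_along(x$prior_history) - 1L
  traj <- sapply(ids, function(id) vapply(x$prior_history, function(p)
    if (id %in% names(p)) p[[id]] else 0, 0))
  graphics::matplot(iters, traj, type = "l", lty = 1,
                    col = ifelse(ids %in% names(x$prior)[x$prior >= threshold],
                                 grDevices::rainbow(length(ids)), "grey70"),
                    xlab = "iteration", ylab = "prior probability",
                    main = "abundance convergence")
  invisible(x)
}

#' Write reconstructed sequences to FASTA
#'
#' Headers carry the rank, final prior and length:
#' `>ssu_<k> prior=<p> length=<L>`.
#'
#' @param fit an `ssu_em` fit.
#' @param path output path.
#' @param threshold minimum prior to report (defaults to the fit's
#'   `report_threshold`).
#' @return `path`, invisibly.
#' @export
write_ssu_fasta <- function(fit, path, threshold = NULL) {
  if (is.null(threshold)) threshold <- fit$report_threshold
  keep <- which(fit$prior >= threshold)
  seqs <- fit$consensus[keep]
  names(seqs) <- sprintf("ssu_%d prior=%.6f length=%d", seq_along(keep),
                         fit$prior[keep], nchar(seqs))
  write_fasta(seqs, path)
}

#' Per-position base probability track of one candidate
#'
#' @param fit an `ssu_em` fit.
#' @param id candidate id (default: the most abundant).
#' @param path optional TSV output path (columns A, C, G, T).
#' @return the L x 4 probability matrix, invisibly if written.
#' @export
probability_track <- function(fit, id = NULL, path = NULL) {
  if (is.null(id)) id <- names(fit$prior)[1]
  m <- fit$candidates[[id]]$probs
  if (!is.null(path)) {
    write.table(round(m, 6), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(m))
  }
  m
}

#' Simulate reads from a fitted reconstruction
#'
#' Draws read pairs from the fitted community (consensus sequences at
#' their estimated abundances) with the supplied error model; useful for
#' posterior predictive checking.
#'
#' @param object an `ssu_em` fit.
#' @param nsim number of read pairs.
#' @param seed optional RNG seed.
#' @param ... passed to [simulate_reads()].
#' @return see [simulate_reads()].
#' @export
simulate.ssu_em <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_reads(object$consensus, profile = object$prior, n_pairs = nsim,
                 insert_mean = object$policy$insert_median,
                 insert_sd = object$policy$insert_sd, seed = seed, ...)
}
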