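# Independent brute-force oracles used to validate the package's fast
# implementations.  These are deliberately written as plain, direct
# transcriptions of the definitions (exhaustive scans, naive loops) and
# share no code with the package internals.

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")

# all valid ungapped placements of one mate on every reference/strand
oracle_mate_hits <- function(seq, qual, refs, policy) {
  L <- nchar(seq)
  out <- list()
  if (L == 0) return(out)
  eff <- min(policy$seed_len, L)
  for (ri in seq_along(refs)) {
    refch <- strsplit(refs[[ri]], "", fixed = TRUE)[[1]]
    RL <- length(refch)
    if (RL < L) next
    for (strand in c(1L, -1L)) {
      aln <- if (strand > 0) seq else oracle_revcomp(seq)
      a <- strsplit(aln, "", fixed = TRUE)[[1]]
      q_aln <- if (strand > 0) qual else rev(qual)
      seed_idx <- if (strand > 0) seq_len(eff) else seq(L - eff + 1, L)
      for (s in 0:(RL - L)) {
        r <- refch[s + seq_len(L)]
        mis <- which(a != r | a == "N" | r == "N")
        if (sum(q_aln[mis]) > policy$max_qual_sum_mismatch) next
        if (sum(mis %in% seed_idx) > policy$max_seed_mismatches) next
        out[[length(out) + 1L]] <-
          list(ref = ri, pos = s, strand = strand, mm = length(mis))
      }
    }
  }
  out
}

# exhaustive paired-end mapping under the policy, all_top_stratum mode
oracle_map_pairs <- function(reads1, reads2, refs, policy) {
  tol <- policy$insert_tolerance_sds * policy$insert_sd
  min_ins <- floor(policy$insert_median - tol)
  max_ins <- ceiling(policy$insert_median + tol)
  rows <- list()
  for (i in seq_along(reads1$id)) {
    h1 <- oracle_mate_hits(reads1$seq[i], reads1$qual[[i]], refs, policy)
    h2 <- oracle_mate_hits(reads2$seq[i], reads2$qual[[i]], refs, policy)
    L1 <- nchar(reads1$seq[i]); L2 <- nchar(reads2$seq[i])
    best <- list()  # per ref
    for (a in h1) for (b in h2) {
      if (a$ref != b$ref || b$strand != -a$strand) next
      ins <- if (a$strand > 0) (b$pos + L2) - a$pos else (a$pos + L1) - b$pos
      if (ins < min_ins || ins > max_ins || ins < max(L1, L2)) next
      cand <- list(ref = a$ref, s1 = a$pos, st1 = a$strand,
                   s2 = b$pos, st2 = b$strand, mm = a$mm + b$mm)
      key <- as.character(a$ref)
      old <- best[[key]]
      replace <- is.null(old) ||
        cand$mm < old$mm ||
        (cand$mm == old$mm && (cand$st1 > old$st1 ||
          (cand$st1 == old$st1 && (cand$s1 < old$s1 ||
            (cand$s1 == old$s1 && cand$s2 < old$s2)))))
      if (replace) best[[key]] <- cand
    }
    if (length(best) == 0) next
    mmin <- min(vapply(best, function(x) x$mm, 0))
    for (key in as.character(sort(as.integer(names(best))))) {
      x <- best[[key]]
      if (x$mm > mmin) next
      rows[[length(rows) + 1L]] <- data.frame(
        read = i, ref = names(refs)[x$ref], start1 = x$s1,
        strand1 = if (x$st1 > 0) "+" else "-", start2 = x$s2,
        strand2 = if (x$st2 > 0) "+" else "-", mismatches = x$mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(read = integer(), ref = character(),
                      start1 = integer(), strand1 = character(),
                      start2 = integer(), strand2 = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# naive emission probability: sum over reference bases of
# Pr(observed | ref base) * Pr(ref base)
oracle_emission <- function(b, p, row) {
  bases <- c("A", "C", "G", "T")
  tot <- 0
  for (n in 1:4) {
    pr_b_given_n <- if (!b %in% bases) p / 3
      else if (b == bases[n]) 1 - p else p / 3
    tot <- tot + pr_b_given_n * row[n]
  }
  tot
}

# direct per-mate likelihood (linear domain, fine at tiny scale)
oracle_mate_lik <- function(seq, ep, start, strand, probs) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (strand == "-") {
    ch <- strsplit(oracle_revcomp(seq), "", fixed = TRUE)[[1]]
    ep <- rev(ep)
  }
  lik <- 1
  for (i in seq_along(ch))
    lik <- lik * oracle_emission(ch[i], ep[i], probs[start + i, ])
  lik
}

# one full E+M iteration from the printed formulas, all loops explicit
oracle_em_iteration <- function(rec, reads1, reads2, cands) {
  ids <- names(cands)
  ep1 <- ssurecon::error_probs(reads1)
  ep2 <- if (!is.null(reads2)) ssurecon::error_probs(reads2)

  lik <- numeric(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    ci <- match(rec$ref[k], ids)
    i <- rec$read[k]
    lik[k] <- oracle_mate_lik(reads1$seq[i], ep1[[i]], rec$start1[k],
                              rec$strand1[k], cands[[ci]]$probs)
    if (!is.null(reads2) && !is.na(rec$start2[k]))
      lik[k] <- lik[k] * oracle_mate_lik(reads2$seq[i], ep2[[i]],
                                         rec$start2[k], rec$strand2[k],
                                         cands[[ci]]$probs)
  }
  post <- numeric(nrow(rec))
  for (i in unique(rec$read)) {
    ix <- which(rec$read == i)
    pri <- vapply(ix, function(k) cands[[rec$ref[k]]]$prior, 0)
    post[ix] <- lik[ix] * pri / sum(lik[ix] * pri)
  }

  J <- length(unique(rec$read))
  priors <- setNames(numeric(length(ids)), ids)
  for (k in seq_len(nrow(rec)))
    priors[rec$ref[k]] <- priors[rec$ref[k]] + post[k]
  priors <- priors / J

  bases <- c("A", "C", "G", "T")
  new_probs <- lapply(cands, function(cd) cd$probs)
  for (id in ids) {
    cd <- cands[[id]]
    L <- nrow(cd$probs)
    acc <- matrix(0, L, 4, dimnames = list(NULL, bases))
    cov <- integer(L)
    ks <- which(rec$ref == id)
    for (k in ks) {
      i <- rec$read[k]
      add_mate <- function(seq, ep, start, strand) {
        ch <- strsplit(seq, "", fixed = TRUE)[[1]]
        if (strand == "-") {
          ch <- strsplit(oracle_revcomp(seq), "", fixed = TRUE)[[1]]
          ep <- rev(ep)
        }
        for (j in seq_along(ch)) {
          pos <- start + j
          for (n in 1:4) {
            I <- as.numeric(ch[j] == bases[n])
            acc[pos, n] <<- acc[pos, n] +
              post[k] * (I * (1 - ep[j]) + (1 - I) * ep[j] / 3)
          }
          cov[pos] <<- cov[pos] + 1L
        }
      }
      add_mate(reads1$seq[i], ep1[[i]], rec$start1[k], rec$strand1[k])
      if (!is.null(reads2) && !is.na(rec$start2[k]))
        add_mate(reads2$seq[i], ep2[[i]], rec$start2[k], rec$strand2[k])
    }
    m <- cd$probs
    for (pos in which(cov > 0)) m[pos, ] <- acc[pos, ] / sum(acc[pos, ])
    new_probs[[id]] <- m
  }
  list(posterior = post, likelihood = lik, priors = priors,
       probs = new_probs)
}

oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= half) best <- L
  }
  best
}

# -- small fixture builders -------------------------------------------------

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a read_set of perfect-copy pairs drawn from given references
perfect_pairs <- function(refs, n, read_len = 20, insert = 50, q = 30,
                          seed = NULL) {
  draw <- function() {
    ref <- sample(names(refs), 1)
    L <- nchar(refs[[ref]])
    s <- sample.int(L - insert + 1, 1)
    frag <- substr(refs[[ref]], s, s + insert - 1)
    list(m1 = substr(frag, 1, read_len),
         m2 = oracle_revcomp(substr(frag, insert - read_len + 1, insert)))
  }
  ssurecon_with_seed <- function(expr) if (is.null(seed)) expr else {
    set.seed(seed); expr
  }
  ssurecon_with_seed({
    ps <- replicate(n, draw(), simplify = FALSE)
    list(reads1 = read_set(sprintf("p%03d/1", 1:n),
                           vapply(ps, `[[`, "", "m1"),
                           replicate(n, rep(q, read_len), simplify = FALSE)),
         reads2 = read_set(sprintf("p%03d/2", 1:n),
                           vapply(ps, `[[`, "", "m2"),
                           replicate(n, rep(q, read_len), simplify = FALSE)))
  })
}

# inject k substitutions at given (or random) positions of a sequence
substitute_at <- function(seq, pos, seed = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!is.null(seed)) set.seed(seed)
  for (p in pos)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
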