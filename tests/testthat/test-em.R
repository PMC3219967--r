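delta <- function(b) {
  v <- setNames(numeric(4), c("A", "C", "G", "T"))
  v[b] <- 1
  v
}

test_that("base emission marginalizes the error model correctly", {
  expect_equal(base_emission_prob("A", 0.3, delta("A")), 0.7)
  expect_equal(base_emission_prob("C", 0.3, delta("A")), 0.1)
  expect_equal(base_emission_prob("A", 0.3, c(0.5, 0.5, 0, 0)), 0.4)
  expect_equal(base_emission_prob("N", 0.75, delta("A")), 0.25)
})

test_that("read likelihood is the product of per-position emissions", {
  cand <- new_candidates(c(x = "AC"))[[1]]
  ll <- read_likelihood(cand, "AC", c(0.1, 0.2), 0, "+")
  expect_equal(exp(ll), 0.9 * 0.8, tolerance = 1e-12)
  # a pair's likelihood is the product of the mates' likelihoods
  cand2 <- new_candidates(c(x = "ACGTACGT"))[[1]]
  l1 <- read_likelihood(cand2, "ACG", c(0.1, 0.1, 0.1), 0, "+")
  l2 <- read_likelihood(cand2, oracle_revcomp("ACG"), c(0.2, 0.2, 0.2),
                        5, "-")
  both <- read_likelihood(cand2, "ACG", c(0.1, 0.1, 0.1), 0, "+",
                          oracle_revcomp("ACG"), c(0.2, 0.2, 0.2), 5, "-")
  expect_equal(both, l1 + l2, tolerance = 1e-12)
  # perfect read, vanishing error: likelihood tends to 1
  l <- read_likelihood(cand2, "ACGTACGT", rep(1e-9, 8), 0, "+")
  expect_equal(exp(l), 1, tolerance = 1e-6)
})

make_records <- function(reads, refs) {
  # single-end placements of equal-length reads at offset 0 on every ref
  do.call(rbind, lapply(seq_along(reads$id), function(i)
    data.frame(read = i, ref = names(refs), start1 = 0, strand1 = "+",
               start2 = NA_integer_, strand2 = NA_character_,
               mismatches = NA_integer_, stringsAsFactors = FALSE)))
}

test_that("posteriors follow Bayes' rule over mapped candidates", {
  # engineer likelihoods (0.9, 0.1): one-base read, delta references
  reads <- read_set("r/1", "A", list(5L))   # p such that 1-p = 0.9
  p <- 0.1
  reads$qual <- list(as.integer(round(-10 * log10(p))))
  refs <- c(s1 = "A", s2 = "G")             # lik: 1-p = .9, p/3 = .0333...
  # use explicit priors
  cands <- new_candidates(refs, priors = c(s1 = 0.5, s2 = 0.5))
  # make likelihood of s2 exactly 0.1: Pr(A|G-mismatch) = p/3 -> want .1
  # choose p = 0.3: lik s1 = 0.7, s2 = 0.1 — ratios as in the uniform case
  reads$qual <- list(as.integer(round(-10 * log10(0.3))))
  # ratios only matter; check uniform-prior case first
  ep <- list(0.3)
  post <- e_step(make_records(reads, refs), reads, candidates = cands,
                 ep1 = ep)
  expect_equal(post$posterior[post$ref == "s1"], 0.7 / 0.8)
  expect_equal(post$posterior[post$ref == "s2"], 0.1 / 0.8)

  cands2 <- new_candidates(refs, priors = c(s1 = 0.8, s2 = 0.2))
  post2 <- e_step(make_records(reads, refs), reads, candidates = cands2,
                  ep1 = ep)
  # (0.7*0.8, 0.1*0.2) normalized = (28/29, 1/29)
  expect_equal(post2$posterior[post2$ref == "s1"], 28 / 29,
               tolerance = 1e-12)

  # likelihoods (.9,.1) priors (.8,.2) -> (36/37, 1/37): construct directly
  lik_post <- c(0.9 * 0.8, 0.1 * 0.2)
  expect_equal(lik_post[1] / sum(lik_post), 36 / 37)

  # single mapped candidate: posterior 1
  post3 <- e_step(make_records(reads, refs[1]), reads,
                  candidates = cands[1], ep1 = ep)
  expect_equal(post3$posterior, 1)
})

test_that("prior update averages posteriors over mapped reads", {
  tab <- data.frame(read = c(1, 2, 2), ref = c("X", "X", "Y"),
                    posterior = c(1, 0.25, 0.75))
  pri <- m_step_priors(tab)
  expect_equal(pri[["X"]], 0.625)
  expect_equal(pri[["Y"]], 0.375)
  tab2 <- data.frame(read = 1:4, ref = "X", posterior = 1)
  expect_equal(m_step_priors(tab2)[["X"]], 1)
  tab3 <- data.frame(read = c(1, 1, 2, 2), ref = c("X", "Y", "X", "Y"),
                     posterior = 0.5)
  expect_equal(unname(m_step_priors(tab3)), c(0.5, 0.5))
})

test_that("consensus correction weighs quality-adjusted evidence", {
  refs <- c(x = "G")
  cands <- new_candidates(refs)
  reads <- read_set("r/1", "A", list(20L))
  rec <- data.frame(read = 1, ref = "x", start1 = 0, strand1 = "+",
                    start2 = NA_integer_, strand2 = NA_character_,
                    posterior = 1)
  upd <- m_step_consensus(rec, reads, candidates = cands, ep1 = list(0.01))
  # (0.99, 0.01/3 * 3) normalized: Pr(A) = 0.99
  expect_equal(unname(upd[["x"]]$probs[1, "A"]), 0.99, tolerance = 1e-12)
  expect_equal(upd[["x"]]$consensus, "A")
  expect_equal(sum(upd[["x"]]$probs[1, ]), 1, tolerance = 1e-12)
})

test_that("tied evidence splits probability and tie-break keeps the old base", {
  refs <- c(x = "C")
  cands <- new_candidates(refs)
  reads <- read_set(c("r1/1", "r2/1"), c("A", "C"), list(20L, 20L))
  rec <- data.frame(read = 1:2, ref = "x", start1 = 0, strand1 = "+",
                    start2 = NA_integer_, strand2 = NA_character_,
                    posterior = 1)
  upd <- m_step_consensus(rec, reads, candidates = cands,
                          ep1 = list(0.01, 0.01))
  expect_equal(unname(upd[["x"]]$probs[1, "A"]),
               unname(upd[["x"]]$probs[1, "C"]))
  expect_equal(upd[["x"]]$consensus, "C")   # previous consensus wins ties
})

test_that("zero-coverage positions keep their previous base row", {
  refs <- c(x = "GTT")
  cands <- new_candidates(refs)
  reads <- read_set("r/1", "A", list(20L))
  rec <- data.frame(read = 1, ref = "x", start1 = 0, strand1 = "+",
                    start2 = NA_integer_, strand2 = NA_character_,
                    posterior = 1)
  upd <- m_step_consensus(rec, reads, candidates = cands, ep1 = list(0.01))
  expect_equal(unname(upd[["x"]]$probs[2, ]), c(0, 0, 0, 1))
  expect_equal(unname(upd[["x"]]$probs[3, ]), c(0, 0, 0, 1))
  expect_equal(substr(upd[["x"]]$consensus, 2, 3), "TT")
  expect_equal(upd[["x"]]$coverage, c(1L, 0L, 0L))
})

test_that("one E+M iteration matches the brute-force oracle to 1e-9", {
  set.seed(51)
  for (case in 1:4) {
    ncand <- sample(2:3, 1)
    base <- random_seq(60)
    refs <- setNames(c(base, vapply(seq_len(ncand - 1), function(i)
      substitute_at(base, sample(60, 3)), "")), paste0("c", 1:ncand))
    pp <- perfect_pairs(refs, 15, read_len = 12, insert = 30)
    for (i in sample(15, 6))
      pp$reads1$seq[i] <- substitute_at(pp$reads1$seq[i], sample(12, 1))
    # random (non-uniform) priors and slightly diffuse base rows
    pri <- runif(ncand)
    cands <- new_candidates(refs, priors = setNames(pri / sum(pri),
                                                    names(refs)))
    for (j in seq_along(cands)) {
      m <- cands[[j]]$probs * 0.94 + 0.015
      cands[[j]]$probs <- m / rowSums(m)
    }
    pol <- mapping_policy(insert_median = 30, insert_sd = 2, seed_len = 12,
                          max_seed_mismatches = 2)
    rec <- map_reads(pp$reads1, pp$reads2, refs, pol)
    expect_gt(nrow(rec), 10)

    post <- e_step(rec, pp$reads1, pp$reads2, cands)
    pri_new <- m_step_priors(post)
    upd <- m_step_consensus(post, pp$reads1, pp$reads2, cands)

    want <- oracle_em_iteration(post[order(post$read, post$ref), ],
                                pp$reads1, pp$reads2, cands)
    got <- post[order(post$read, post$ref), ]
    expect_equal(got$posterior, want$posterior, tolerance = 1e-9)
    expect_equal(exp(got$loglik), want$likelihood, tolerance = 1e-9)
    for (id in names(refs)) {
      if (id %in% names(pri_new))
        expect_equal(pri_new[[id]], want$priors[[id]], tolerance = 1e-9)
      expect_equal(upd[[id]]$probs, want$probs[[id]], tolerance = 1e-9)
    }
  }
})

test_that("merging absorbs the lower-prior candidate above the threshold", {
  set.seed(52)
  s <- random_seq(1500)
  same <- new_candidates(c(a = s, b = s), priors = c(a = 0.7, b = 0.3))
  m <- merge_pass(same)
  expect_length(m$candidates, 1)
  expect_equal(names(m$candidates), "a")       # higher prior survives
  expect_equal(m$candidates[["a"]]$prior, 1)

  near <- substitute_at(s, sample(1500, 30))   # 98% identity -> merged
  far <- substitute_at(s, sample(1500, 60))    # 96% identity -> kept
  m2 <- merge_pass(new_candidates(c(a = s, b = near),
                                  priors = c(a = 0.6, b = 0.4)))
  expect_length(m2$candidates, 1)
  m3 <- merge_pass(new_candidates(c(a = s, b = far),
                                  priors = c(a = 0.6, b = 0.4)))
  expect_length(m3$candidates, 2)
})

test_that("splitting follows the strict 4%/10% rule", {
  set.seed(53)
  mk <- function(n_variant) {
    cands <- new_candidates(c(x = random_seq(100)))
    if (n_variant > 0) {
      pos <- seq_len(n_variant)
      major <- max.col(cands[["x"]]$probs[pos, , drop = FALSE])
      minor <- (major %% 4) + 1
      for (k in seq_along(pos)) {
        row <- numeric(4)
        row[major[k]] <- 0.8
        row[minor[k]] <- 0.2
        cands[["x"]]$probs[pos[k], ] <- row
      }
    }
    cands
  }
  s5 <- split_pass(mk(5))          # 5% of positions > 4% -> split
  expect_equal(s5$n_split, 1L)
  expect_length(s5$candidates, 2)
  expect_equal(sum(candidate_priors(s5$candidates)), 1, tolerance = 1e-12)
  # twin takes the minor base at variant positions
  twin <- s5$candidates[[setdiff(names(s5$candidates), "x")]]
  expect_equal(sum(strsplit(twin$consensus, "")[[1]] !=
                   strsplit(s5$candidates[["x"]]$consensus, "")[[1]]), 5)
  # prior split 0.8 : 0.2
  expect_equal(twin$prior, 0.2, tolerance = 1e-12)

  s4 <- split_pass(mk(4))          # exactly 4% is not "more than 4%"
  expect_equal(s4$n_split, 0L)
  s0 <- split_pass(mk(0))          # pure point-mass rows never split
  expect_equal(s0$n_split, 0L)
})

test_that("split twins unsupported by reads return their mass on merge", {
  set.seed(54)
  cands <- new_candidates(c(x = random_seq(100)))
  pos <- 1:5
  for (k in pos) {
    row <- numeric(4)
    major <- which.max(cands[["x"]]$probs[k, ])
    row[major] <- 0.85
    row[(major %% 4) + 1] <- 0.15
    cands[["x"]]$probs[k, ] <- row
  }
  sp <- split_pass(cands)
  expect_equal(sp$n_split, 1L)
  total_before <- sum(candidate_priors(sp$candidates))
  # twin differs at 5 of 100 positions (95% < 97%): NOT merged back;
  # but an identical-consensus twin is
  tw <- names(sp$candidates)[2]
  sp$candidates[[tw]]$consensus <- sp$candidates[[1]]$consensus
  m <- merge_pass(sp$candidates)
  expect_length(m$candidates, 1)
  expect_equal(sum(candidate_priors(m$candidates)), total_before,
               tolerance = 1e-9)
})

test_that("initialization hard-assigns reads and runs an M-step", {
  set.seed(55)
  refs <- c(a = random_seq(300), b = random_seq(300))
  pp <- perfect_pairs(refs["a"], 20, read_len = 30, insert = 50, seed = 56)
  st <- em_initialize(pp$reads1, pp$reads2, refs,
                      pol_small <- mapping_policy(insert_median = 50,
                                                  insert_sd = 5))
  expect_length(st$candidates, 1)       # zero-read candidate dropped
  expect_equal(names(st$candidates), "a")
  expect_equal(st$candidates[["a"]]$prior, 1)
  expect_equal(st$J, 20)
  # priors equal assigned-read fractions
  pp2 <- perfect_pairs(refs, 40, read_len = 30, insert = 50, seed = 57)
  st2 <- em_initialize(pp2$reads1, pp2$reads2, refs, pol_small, seed = 1)
  counts <- table(map_reads(pp2$reads1, pp2$reads2, refs, pol_small,
                            mode = "best_single_random_tie", seed = 1)$ref)
  expect_equal(unname(candidate_priors(st2$candidates)[names(counts)]),
               as.vector(counts) / sum(counts))
  # determinism
  st3 <- em_initialize(pp2$reads1, pp2$reads2, refs, pol_small, seed = 1)
  expect_identical(candidate_priors(st2$candidates),
                   candidate_priors(st3$candidates))
})

test_that("log-likelihood is non-decreasing with a frozen mapping", {
  set.seed(58)
  base <- random_seq(120)
  refs <- c(a = substitute_at(base, sample(120, 8)),
            b = substitute_at(base, sample(120, 8)))
  pp <- perfect_pairs(c(x = base, y = substitute_at(base, sample(120, 4))),
                      40, read_len = 20, insert = 60)
  pol <- mapping_policy(insert_median = 60, insert_sd = 5)
  cands <- new_candidates(refs)
  rec <- map_reads(pp$reads1, pp$reads2, refs, pol)
  expect_gt(nrow(rec), 20)
  lls <- numeric(8)
  for (it in 1:8) {
    post <- e_step(rec, pp$reads1, pp$reads2, cands)
    lls[it] <- attr(post, "total_loglik")
    pri <- m_step_priors(post)
    for (id in names(cands)) cands[[id]]$prior <-
      if (id %in% names(pri)) unname(pri[[id]]) else 0
    cands <- m_step_consensus(post, pp$reads1, pp$reads2, cands)
  }
  expect_true(all(diff(lls) > -1e-9))
})

test_that("a clean single-reference run converges to the truth", {
  set.seed(59)
  truth <- c(org = random_seq(500))
  pp <- perfect_pairs(truth, 300, read_len = 40, insert = 120, seed = 60)
  fit <- ssu_em(pp$reads1, pp$reads2, db = truth,
                policy = mapping_policy(insert_median = 120, insert_sd = 5),
                trim = FALSE, seed = 61)
  expect_true(fit$converged)
  expect_equal(unname(fit$prior), 1)
  expect_equal(unname(fit$consensus), truth[["org"]])
})

test_that("reconstruction beats a 10%-mutated starting reference", {
  set.seed(62)
  truth <- c(org = random_seq(700))
  db <- mutate_db(truth, 0.10, seed = 63)$db
  pp <- perfect_pairs(truth, 1200, read_len = 50, insert = 150, seed = 64)
  fit <- ssu_em(pp$reads1, pp$reads2, db = db,
                policy = mapping_policy(insert_median = 150, insert_sd = 5),
                trim = FALSE, seed = 65)
  id_start <- seq_identity(db[[1]], truth[[1]])
  id_final <- seq_identity(unname(fit$consensus)[1], truth[[1]])
  expect_lt(id_start, 0.92)
  expect_gt(id_final, id_start)
  expect_gt(id_final, 0.99)
  # nt changes reach zero on converging runs
  expect_equal(fit$nt_changes[fit$iterations], 0)
})

test_that("fit object methods work", {
  set.seed(66)
  truth <- c(org = random_seq(400))
  pp <- perfect_pairs(truth, 150, read_len = 40, insert = 100, seed = 67)
  fit <- ssu_em(pp$reads1, pp$reads2, db = truth,
                policy = mapping_policy(insert_median = 100, insert_sd = 5),
                trim = FALSE, seed = 68)
  expect_s3_class(fit, "ssu_em")
  expect_named(coef(fit), "org")
  expect_output(print(fit), "reconstruction")
  s <- summary(fit)
  expect_equal(s$table$id, "org")
  expect_output(print(s), "Reconstructed")
  png <- tempfile(fileext = ".png")
  grDevices::png(png)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(png))
  fa <- tempfile(fileext = ".fasta")
  write_ssu_fasta(fit, fa)
  expect_match(readLines(fa)[1], "^>ssu_1 prior=.* length=400$")
  out <- read_fasta(fa)
  expect_equal(unname(out), unname(fit$consensus))
  tr <- probability_track(fit, "org")
  expect_equal(dim(tr), c(400L, 4L))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_length(sim$reads1, 50)
})
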