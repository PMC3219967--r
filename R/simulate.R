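#' Expected SSU gene abundances of a defined community
#'
#' The expected relative abundance of each member's SSU gene is its SSU
#' copy number times its genome abundance, normalized over the
#' community; for an evenly mixed community this reduces to copy number
#' over total copies.
#'
#' @param copies named integer vector of SSU copy numbers (>= 1).
#' @param genome_abundance optional named vector of relative genome
#'   abundances (default even); normalized internally.
#' @return named numeric vector summing to one.
#' @export
expected_ssu_abundance <- function(copies, genome_abundance = NULL) {
  stopifnot(all(copies >= 1))
  if (is.null(genome_abundance))
    genome_abundance <- rep(1, length(copies))
  stopifnot(length(genome_abundance) == length(copies))
  w <- copies * genome_abundance
  setNames(as.vector(w) / sum(w), names(copies))
}

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

# substitute each position independently with probability p (to a random
# other base), the per-branch step of the Jukes-Cantor-style generator
jc_mutate <- function(seq, p) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < p)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(.BASES, b), 1L),
                      "", USE.NAMES = FALSE)
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Generate a ground-truthed synthetic SSU community
#'
#' Evolves one random ancestral gene along a random (or supplied) rooted
#' tree under a Jukes-Cantor substitution model, yielding one
#' full-length SSU gene per community member together with SSU copy
#' numbers, the expected abundance profile and the generating tree
#' (usable directly for phylogenetic evaluation, e.g. weighted UniFrac).
#' Branch lengths are rescaled so that the minimum pairwise patristic
#' distance is `min_divergence`, guaranteeing distinct, species-level
#' separated members.
#'
#' The default copy numbers (23, 15, 12, 10, 8, 7, 6, 5, 2 over nine
#' members, evenly mixed genomes) give expected SSU abundances spanning
#' 2.3% to 26.1%.
#'
#' @param n_members number of community members.
#' @param copies SSU copy numbers per member.
#' @param gene_length gene length in bp.
#' @param min_divergence minimum pairwise substitution distance between
#'   members (substitutions per site).
#' @param tree optional rooted `phylo` tree with `n_members` tips.
#' @param seed optional RNG seed.
#' @return list (class `ssu_community`) with `genes` (named character),
#'   `copies`, `profile` (expected abundances), `tree` (tip labels =
#'   member names) and `params`.
#' @export
sim_community <- function(n_members = 9,
                          copies = c(23, 15, 12, 10, 8, 7, 6, 5, 2),
                          gene_length = 1500, min_divergence = 0.10,
                          tree = NULL, seed = NULL) {
  stopifnot(length(copies) == n_members)
  with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rtree(n_members)
      d <- ape::cophenetic.phylo(tree)
      mind <- min(d[upper.tri(d)])
      tree$edge.length <- tree$edge.length * (min_divergence / mind)
    }
    stopifnot(ape::is.rooted(tree), length(tree$tip.label) == n_members)
    nm <- sprintf("member_%02d", seq_len(n_members))
    tree$tip.label <- nm  # deterministic relabeling in tip order
    names(copies) <- nm

    # evolve sequences root -> tips
    ntip <- n_members
    root <- ntip + 1L
    seqs <- character(ntip + tree$Nnode)
    seqs[root] <- random_dna(gene_length)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]
      chi <- ord$edge[e, 2]
      b <- ord$edge.length[e]
      p_sub <- 0.75 * (1 - exp(-4 * b / 3))
      seqs[chi] <- jc_mutate(seqs[par], p_sub)
    }
    genes <- setNames(seqs[seq_len(ntip)], tree$tip.label)

    structure(list(genes = genes, copies = copies,
                   profile = expected_ssu_abundance(copies),
                   tree = tree,
                   params = list(gene_length = gene_length,
                                 min_divergence = min_divergence)),
              class = "ssu_community")
  })
}

#' @export
print.ssu_community <- function(x, ...) {
  cat("synthetic SSU community:", length(x$genes), "members,",
      x$params$gene_length, "bp genes\n")
  print(round(x$profile, 4))
  invisible(x)
}

#' Pad sequences with random flanking bases
#'
#' Prepends and appends `pad_len` uniform-random bases to every
#' sequence, emulating the genomic context around an SSU gene so that
#' simulated shotgun fragments can straddle the gene boundaries.
#'
#' @param genes named character vector.
#' @param pad_len pad length per side in bp.
#' @param seed optional RNG seed.
#' @return named character vector of padded sequences.
#' @export
pad_sequences <- function(genes, pad_len = 1000, seed = NULL) {
  if (pad_len == 0) return(genes)
  with_seed(seed, {
    vapply(genes, function(g)
      paste0(random_dna(pad_len), g, random_dna(pad_len)), "")
  })
}

#' Parametric per-base quality model
#'
#' Describes read quality vectors with a linearly decaying mean Phred
#' score plus Gaussian noise, clamped to `[q_min, q_max]` — the typical
#' shape of short-read quality profiles.  Alternatively, pass a FASTQ
#' file of real reads to [simulate_reads()]'s `quality` argument to
#' sample observed quality vectors instead.
#'
#' @param q_start,q_end mean Phred score at the first/last read position.
#' @param sd per-base Gaussian noise (Phred units).
#' @param q_min,q_max clamp range.
#' @return list of class `quality_profile`.
#' @export
quality_profile <- function(q_start = 38, q_end = 22, sd = 4,
                            q_min = 2, q_max = 40) {
  structure(list(q_start = q_start, q_end = q_end, sd = sd,
                 q_min = q_min, q_max = q_max), class = "quality_profile")
}

# n x len integer matrix of Phred scores
draw_qualities <- function(quality, n, len) {
  if (inherits(quality, "quality_profile")) {
    mu <- seq(quality$q_start, quality$q_end, length.out = len)
    q <- matrix(round(rnorm(n * len, mean = rep(mu, each = n),
                            sd = quality$sd)), nrow = n)
    q[q < quality$q_min] <- quality$q_min
    q[q > quality$q_max] <- quality$q_max
    storage.mode(q) <- "integer"
    q
  } else if (is.character(quality) && length(quality) == 1) {
    src <- read_fastq(quality)
    ok <- which(lengths(src$qual) >= len)
    if (length(ok) == 0) stop("no quality vectors of length >= ", len,
                              " in ", quality)
    idx <- ok[sample.int(length(ok), n, replace = TRUE)]
    t(vapply(src$qual[idx], function(q) q[seq_len(len)], integer(len)))
  } else stop("quality must be a quality_profile or a FASTQ path")
}

#' Simulate paired-end shotgun reads from a community
#'
#' Draws read pairs wgsim-style: a source sequence is chosen per pair
#' according to `profile`, a fragment start is uniform and the fragment
#' length Normal(`insert_mean`, `insert_sd`) (rounded, clamped to at
#' least `read_len`); the mates are the two fragment ends, mate 2
#' reverse-complemented.  Each read is assigned a quality vector and
#' substitution errors are injected per base with probability
#' `10^(-Q/10)` (to a uniformly random other base), so the realized
#' error process matches the reported qualities.
#'
#' @param genes named character vector of source sequences (e.g. padded
#'   SSU genes).
#' @param profile named sampling weights over `names(genes)` (default
#'   uniform).
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment (insert) length distribution.
#' @param quality a [quality_profile()] or a FASTQ path to sample real
#'   quality vectors from.
#' @param error_free skip error injection (qualities still assigned).
#' @param seed optional RNG seed.
#' @return list with `reads1`, `reads2` ([read_set]s) and `truth`
#'   (data.frame: `read` index, `member`, `start`, `insert`).
#' @export
simulate_reads <- function(genes, profile = NULL, n_pairs,
                           read_len = 76, insert_mean = 200,
                           insert_sd = 25, quality = quality_profile(),
                           error_free = FALSE, seed = NULL) {
  stopifnot(insert_mean >= read_len, !is.null(names(genes)))
  if (is.null(profile))
    profile <- setNames(rep(1 / length(genes), length(genes)), names(genes))
  stopifnot(all(names(profile) %in% names(genes)))
  glen <- nchar(genes)
  if (any(glen[names(profile)] < read_len))
    stop("source sequences shorter than the read length")

  with_seed(seed, {
    member <- sample(names(profile), n_pairs, replace = TRUE,
                     prob = profile)
    L <- unname(glen[member])
    frag <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
    for (tries in 1:100) {
      bad <- which(frag > L)
      if (length(bad) == 0) break
      frag[bad] <- pmax(read_len,
                        round(rnorm(length(bad), insert_mean, insert_sd)))
      if (tries == 100)
        stop("could not draw fragments within the source sequences; ",
             "some members are shorter than the insert size")
    }
    frag <- pmin(frag, L)
    start <- 1L + floor(runif(n_pairs) * (L - frag + 1))

    m1 <- substring(genes[member], start, start + read_len - 1L)
    m2end <- start + frag - 1L
    m2 <- substring(genes[member], m2end - read_len + 1L, m2end)
    m2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(m2)))

    q1 <- draw_qualities(quality, n_pairs, read_len)
    q2 <- draw_qualities(quality, n_pairs, read_len)
    if (!error_free) {
      m1 <- inject_errors(m1, q1)
      m2 <- inject_errors(m2, q2)
    }
    ids <- sprintf("simread_%06d", seq_len(n_pairs))
    reads1 <- read_set(paste0(ids, "/1"), m1, asplit(q1, 1))
    reads2 <- read_set(paste0(ids, "/2"), m2, asplit(q2, 1))
    truth <- data.frame(read = seq_len(n_pairs), member = member,
                        start = start, insert = frag,
                        stringsAsFactors = FALSE)
    list(reads1 = reads1, reads2 = reads2, truth = truth)
  })
}

# quality-driven substitution errors; seqs: equal-length reads,
# q: matching integer quality matrix (reads x positions)
inject_errors <- function(seqs, q) {
  n <- length(seqs)
  len <- ncol(q)
  p <- 10^(-q / 10)
  hit <- which(matrix(runif(n * len), n) < p, arr.ind = TRUE)
  if (nrow(hit) == 0) return(seqs)
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  hit <- hit[ch[hit] %in% .BASES, , drop = FALSE]  # leave N calls alone
  if (nrow(hit) == 0) return(seqs)
  old <- ch[hit]
  # uniformly one of the three other bases: shift by 1..3 in base order
  shift <- sample.int(3L, nrow(hit), replace = TRUE)
  ch[hit] <- .BASES[((match(old, .BASES) - 1L + shift) %% 4L) + 1L]
  do.call(paste0, lapply(seq_len(len), function(j) ch[, j]))
}
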