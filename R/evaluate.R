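#' Match reconstructions to truth and correlate abundances
#'
#' Greedily matches reconstructed sequences (most abundant first) to
#' their best-identity truth sequence by global alignment (identity over
#' non-end-gap columns), subject to a minimum identity floor of
#' `min_identity` — reconstructions below the floor against every
#' remaining truth sequence are reported as novel.  Each truth member is
#' matched to at most one reconstruction and vice versa; unmatched truth
#' members receive estimated abundance zero.  Pearson correlation is
#' computed over all truth members.
#'
#' @param truth_profile named numeric vector of expected abundances.
#' @param truth_seqs named character vector of true sequences (names as
#'   in `truth_profile`).
#' @param recon_seqs named character vector of reconstructed sequences.
#' @param priors named numeric vector of estimated abundances
#'   (`names(recon_seqs)`).
#' @param min_identity identity floor for a valid match (default the
#'   OTU-level 0.97).
#' @param top_n optionally restrict to the `top_n` most abundant
#'   reconstructions before matching.
#' @return list with `pairs` (data.frame: `truth`, `recon`, `identity`,
#'   `truth_abundance`, `estimated_prior`), `novel` (unmatched
#'   reconstruction ids), `r`, `p.value`.
#' @export
match_and_correlate <- function(truth_profile, truth_seqs, recon_seqs,
                                priors, min_identity = 0.97,
                                top_n = NULL) {
  stopifnot(length(truth_profile) >= 3,
            all(names(truth_profile) %in% names(truth_seqs)))
  ord <- order(-priors)
  if (!is.null(top_n)) ord <- head(ord, top_n)
  recon_ids <- names(recon_seqs)[ord]

  assigned <- setNames(rep(NA_character_, length(truth_profile)),
                       names(truth_profile))
  ident <- setNames(rep(NA_real_, length(truth_profile)),
                    names(truth_profile))
  novel <- character()
  for (rid in recon_ids) {
    open <- names(assigned)[is.na(assigned)]
    if (length(open) == 0) { novel <- c(novel, rid); next }
    ids <- vapply(open, function(tn)
      seq_identity(recon_seqs[[rid]], truth_seqs[[tn]], exclude = "ends"),
      0)
    best <- which.max(ids)
    if (ids[best] >= min_identity) {
      assigned[open[best]] <- rid
      ident[open[best]] <- ids[best]
    } else novel <- c(novel, rid)
  }

  est <- ifelse(is.na(assigned), 0, priors[assigned])
  pairs <- data.frame(truth = names(truth_profile), recon = assigned,
                      identity = unname(ident),
                      truth_abundance = unname(truth_profile),
                      estimated_prior = unname(est),
                      stringsAsFactors = FALSE)
  if (stats::sd(pairs$estimated_prior) == 0 ||
      stats::sd(pairs$truth_abundance) == 0)
    stop("degenerate abundances: correlation undefined (zero variance)")
  ct <- cor.test(pairs$truth_abundance, pairs$estimated_prior)
  list(pairs = pairs, novel = novel, r = unname(ct$estimate),
       p.value = ct$p.value)
}

#' N50 length statistic
#'
#' The largest length `L` such that sequences of length at least `L`
#' together contain at least half of the total sequence length.
#'
#' @param lengths positive integer vector.
#' @return the N50, an integer.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Weighted UniFrac distance between two communities on a tree
#'
#' Raw weighted UniFrac is the branch-length-weighted difference of
#' relative abundance mass between two communities across a shared
#' rooted tree: `sum_b len_b * |A_b - B_b|`, where `A_b` is the fraction
#' of community A's mass on leaves below branch `b`.  The normalized
#' variant divides by the abundance-weighted maximum attainable value,
#' `sum_i (A_i + B_i) * d_i` with `d_i` the root-to-leaf distance, so it
#' lies in `[0, 1]`.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param profile_a,profile_b named abundance vectors on (a subset of)
#'   the tree's tip labels; normalized to sum to one internally.
#' @param normalized return the normalized distance (default) or raw.
#' @param n_perm if positive, also compute a permutation p-value by
#'   shuffling leaf labels (`n_perm` permutations).
#' @param seed optional RNG seed for the permutation test.
#' @return the distance, with attributes `raw`, `normalized` and (if
#'   requested) `p.value`.
#' @export
weighted_unifrac <- function(tree, profile_a, profile_b,
                             normalized = TRUE, n_perm = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing_a <- setdiff(names(profile_a), tree$tip.label)
  missing_b <- setdiff(names(profile_b), tree$tip.label)
  if (length(c(missing_a, missing_b)))
    stop("leaf not present in tree: ",
         paste(unique(c(missing_a, missing_b)), collapse = ", "))
  a <- tip_masses(tree, profile_a)
  b <- tip_masses(tree, profile_b)

  dist_for <- function(a, b) {
    am <- clade_masses(tree, a)
    bm <- clade_masses(tree, b)
    raw <- sum(tree$edge.length * abs(am - bm))
    depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    norm <- raw / sum((a + b) * depth)
    c(raw = raw, normalized = norm)
  }
  d <- dist_for(a, b)
  out <- unname(if (normalized) d[["normalized"]] else d[["raw"]])
  attr(out, "raw") <- d[["raw"]]
  attr(out, "normalized") <- d[["normalized"]]
  if (n_perm > 0) {
    key <- if (normalized) "normalized" else "raw"
    obs <- d[[key]]
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        perm <- sample.int(length(a))
        dist_for(a[perm], b[perm])[[key]] >= obs
      }, NA)) })
    attr(out, "p.value") <- (hits + 1) / (n_perm + 1)
  }
  out
}

# normalized abundance vector aligned to tip order
tip_masses <- function(tree, profile) {
  if (abs(sum(profile)) == 0) stop("profile has zero total mass")
  m <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  m[names(profile)] <- profile / sum(profile)
  unname(m)
}

# for each edge, the fraction of mass on tips below its child node
clade_masses <- function(tree, tipmass) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  mass <- c(tipmass, numeric(nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    mass[po$edge[e, 1]] <- mass[po$edge[e, 1]] + mass[po$edge[e, 2]]
  mass[tree$edge[, 2]]
}
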