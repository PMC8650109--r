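#' Abundance-weighted betaMNTD for one pair of communities
#'
#' The between-community mean nearest taxon distance: for each taxon present
#' in one community, the patristic distance to its closest relative in the
#' other community, averaged with relative-abundance weights and symmetrized,
#'
#'   betaMNTD = 1/2 \[ sum_i f_i min_j d(i,j) + sum_j f_j min_i d(j,i) \]
#'
#' where f are relative abundances among taxa present (> 0) in each
#' community. A taxon shared by both communities has nearest-relative
#' distance zero (itself), so identical communities score 0.
#'
#' @param abund_a,abund_b Named abundance vectors (any non-negative scale;
#'   re-normalized internally over present taxa).
#' @param dm Taxon patristic distance matrix covering all present taxa.
#' @return Non-negative scalar, in branch-length units.
#' @examples
#' dm <- patristic_distances(read_phylo("((A:1,B:1):1,(C:1,D:1):1);"))
#' beta_mntd(c(A = 1), c(C = 1), dm)          # 4: the full path A..C
#' beta_mntd(c(A = .5, B = .5), c(B = 1), dm) # 0.5
#' @export
beta_mntd <- function(abund_a, abund_b, dm) {
  f_a <- present_freqs(abund_a, "first community")
  f_b <- present_freqs(abund_b, "second community")
  miss <- setdiff(c(names(f_a), names(f_b)), rownames(dm))
  if (length(miss))
    stop("taxa missing from distance matrix: ", paste(miss, collapse = ", "))
  sub <- dm[names(f_a), names(f_b), drop = FALSE]
  0.5 * (sum(f_a * apply(sub, 1, min)) + sum(f_b * apply(sub, 2, min)))
}

present_freqs <- function(x, what) {
  if (is.null(names(x))) stop(what, " abundances must be named by taxon")
  x <- x[x > 0]
  if (!length(x)) stop(what, " is empty (no taxa with positive abundance)")
  x / sum(x)
}

#' Pairwise betaMNTD matrix for an abundance table
#'
#' Computes abundance-weighted betaMNTD between every pair of samples,
#' optionally under a permutation of taxon identities (the null
#' randomization). The heavy loop runs in compiled code.
#'
#' @param counts Samples x taxa abundance matrix (counts or relative
#'   abundances; rows are re-normalized over present taxa).
#' @param dm Taxon distance matrix containing every table taxon.
#' @param perm Optional integer permutation of `ncol(counts)` taxon
#'   identities; default identity (observed statistic).
#' @return Symmetric samples x samples matrix.
#' @export
bmntd <- function(counts, dm, perm = NULL) {
  validate_counts(counts)
  miss <- setdiff(colnames(counts), rownames(dm))
  if (length(miss))
    stop("taxa missing from distance matrix: ", paste(head(miss, 5), collapse = ", "))
  dmx <- dm[colnames(counts), colnames(counts), drop = FALSE]
  relab <- relative_abundance(counts)
  if (is.null(perm)) perm <- seq_len(ncol(counts))
  out <- bmntd_pairwise_cpp(dmx, relab, as.integer(perm) - 1L)
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

#' Null distribution of betaMNTD by taxon shuffling
#'
#' Generates `n_reps` null replicates of the full pairwise betaMNTD matrix by
#' shuffling taxon identities across the phylogeny and recomputing; one
#' shuffle per replicate is shared by all sample pairs. Returns running
#' moments (mean, sample SD) per pair, and optionally the full replicate
#' array for small problems.
#'
#' @param counts Samples x taxa abundance matrix.
#' @param dm Taxon distance matrix.
#' @param n_reps Number of null replicates (default 999).
#' @param keep Keep all replicate matrices (memory ~ n^2 * n_reps).
#' @return List with `mean`, `sd` (samples x samples matrices) and, when
#'   `keep = TRUE`, `reps` (array n x n x n_reps).
#' @export
bmntd_null <- function(counts, dm, n_reps = 999, keep = FALSE) {
  if (n_reps < 2) stop("n_reps must be at least 2 (SD undefined otherwise)")
  validate_counts(counts)
  S <- ncol(counts)
  n <- nrow(counts)
  acc <- matrix(0, n, n)
  acc2 <- matrix(0, n, n)
  reps <- if (keep) array(NA_real_, c(n, n, n_reps)) else NULL
  for (r in seq_len(n_reps)) {
    b <- bmntd(counts, dm, perm = sample.int(S))
    acc <- acc + b
    acc2 <- acc2 + b * b
    if (keep) reps[, , r] <- b
  }
  m <- acc / n_reps
  v <- (acc2 - n_reps * m * m) / (n_reps - 1)
  v[v < 0] <- 0
  out <- list(mean = m, sd = sqrt(v))
  dimnames(out$mean) <- dimnames(out$sd) <- list(rownames(counts), rownames(counts))
  if (keep) out$reps <- reps
  out
}

#' Beta nearest taxon index
#'
#' Standardized effect size of observed betaMNTD against its null
#' distribution, in units of null standard deviations:
#' `(obs - mean(null)) / sd(null)` with the sample SD. Values below -2 or
#' above +2 indicate a significant deviation (selection).
#'
#' @param obs Observed betaMNTD (scalar or matrix).
#' @param null_mean,null_sd Null moments, same shape as `obs`; alternatively
#'   pass a numeric vector of null replicates as `null_mean` and omit
#'   `null_sd`.
#' @return betaNTI, same shape as `obs`.
#' @export
beta_nti <- function(obs, null_mean, null_sd = NULL) {
  if (is.null(null_sd)) {
    null <- null_mean
    if (length(null) < 2) stop("null distribution needs at least 2 values")
    null_mean <- mean(null)
    null_sd <- sd(null)
  }
  if (any(null_sd <= 0))
    stop("null SD is zero: betaNTI undefined (degenerate null distribution)")
  (obs - null_mean) / null_sd
}

pair_seed <- function(seed, i, j) {
  ((seed %% 100000L) * 20011L + i * 1009L + j * 7L) %% 2147483629L
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' Compares the observed Bray-Curtis dissimilarity of one sample pair against
#' a null distribution from `n_reps` simulations of stochastic community
#' assembly. Each null replicate re-assembles both samples from the
#' metacommunity described by the whole table: a sample's observed richness
#' worth of taxa is drawn without replacement with probability proportional
#' to occupancy (the fraction of samples each taxon occurs in), each drawn
#' taxon receives one read, and the remaining reads are distributed
#' multinomially with probability proportional to each taxon's total relative
#' abundance. The result is rescaled to `[-1, 1]`:
#'
#'   RC = 2 * ( \[ #(null < obs) + 0.5 #(null = obs) \] / n_reps - 0.5 )
#'
#' RC < -0.95 flags pairs more similar than the stochastic expectation,
#' RC > +0.95 more dissimilar.
#'
#' @param counts Integer count matrix (samples x taxa), the metacommunity
#'   frame of reference.
#' @param pair Length-2 vector of sample ids or row indices.
#' @param n_reps Number of null assemblies (default 999).
#' @return Scalar in `[-1, 1]`.
#' @export
rc_bray <- function(counts, pair, n_reps = 999) {
  validate_counts(counts, integer_counts = TRUE)
  if (length(pair) != 2) stop("pair must have exactly two samples")
  idx <- if (is.character(pair)) match(pair, rownames(counts)) else as.integer(pair)
  if (anyNA(idx)) stop("pair samples not found in table")
  occupancy <- colMeans(counts > 0)
  p_abund <- colSums(counts) / sum(counts)
  x <- counts[idx[1], ]
  y <- counts[idx[2], ]
  if (sum(x) == 0 || sum(y) == 0) stop("RC-bray undefined for empty samples")
  obs <- bc_pair(x, y)
  nulls <- vapply(seq_len(n_reps), function(r) {
    bc_pair(assemble_null_sample(sum(x > 0), sum(x), occupancy, p_abund),
            assemble_null_sample(sum(y > 0), sum(y), occupancy, p_abund))
  }, numeric(1))
  rc_raw <- (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_reps
  2 * (rc_raw - 0.5)
}

bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

assemble_null_sample <- function(richness, n_reads, occupancy, p_abund) {
  S <- length(occupancy)
  if (richness > S)
    stop("sample richness exceeds metacommunity taxon count")
  drawn <- sample.int(S, richness, replace = FALSE, prob = occupancy)
  out <- numeric(S)
  out[drawn] <- 1
  extra <- n_reads - richness
  if (extra > 0) {
    p <- p_abund[drawn]
    if (sum(p) == 0) p <- rep(1, length(drawn))
    out[drawn] <- out[drawn] + rmultinom(1, extra, p)[, 1]
  }
  out
}

#' RC-bray for many pairs with per-pair reproducible streams
#'
#' Computes [rc_bray()] for each requested pair, seeding each pair's random
#' stream deterministically from `(seed, i, j)` so results are independent of
#' evaluation order and of which subset of pairs is requested.
#'
#' @param counts Integer count matrix.
#' @param pairs Two-column matrix of sample indices (rows of `counts`).
#' @param n_reps Null replicates per pair.
#' @param seed Base seed for the per-pair streams.
#' @return Numeric vector, one RC value per row of `pairs`.
#' @export
rc_bray_pairs <- function(counts, pairs, n_reps = 999, seed = 1) {
  pairs <- as.matrix(pairs)
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    withr_seed <- pair_seed(seed, min(i, j), max(i, j))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(withr_seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    rc_bray(counts, c(i, j), n_reps = n_reps)
  }, numeric(1))
}
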