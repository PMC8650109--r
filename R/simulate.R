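REGIMES <- c("homogeneous_selection", "variable_selection",
             "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic community generator. The default
#' design is a nested soil survey: 3 hillslopes x 6 locations x 5 depth
#' classes x 2 time points (180 samples), 200 taxa, 2,000 reads per sample —
#' a desk-scale stand-in for a depth-resolved amplicon data set.
#'
#' @param regime Generating assembly regime, one of
#'   `"homogeneous_selection"`, `"variable_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`.
#' @param n_taxa Number of taxa (tree tips).
#' @param slopes,locations,depths,times Factor levels of the nested design
#'   (slopes up to 3 named East/Central/West, depths up to 5 named D1..D5,
#'   times up to 2 named pre/post).
#' @param per_cell Samples per design cell.
#' @param reads Sequencing depth per sample (multinomial total).
#' @param bm_rate Brownian-motion rate of the niche trait (variance per unit
#'   branch length).
#' @param niche_dim Number of independent Brownian niche dimensions. A single
#'   dimension carries weak phylogenetic signal at the nearest-taxon level on
#'   desk-scale trees; several jointly conserved dimensions make niche-near
#'   taxa reliably clade-mates (default 8).
#' @param sigma_sel Niche breadth of the Gaussian environmental filter,
#'   expressed adaptively: the breadth is set to the `sigma_sel` quantile of
#'   the taxa's niche distances to the optimum, so roughly that fraction of
#'   the metacommunity sits within one breadth of the optimum (selection
#'   regimes only; default 0.1). Smaller is stronger selection.
#' @param migration Selection regimes: founder-pool size as a fraction of
#'   `reads` (small pools mean different samples fix different members of
#'   the favored set). `homogenizing_dispersal`: the fraction of each
#'   sample's reads fixed to the shared pool composition (large =
#'   well-mixed). Unused by the other neutral regimes.
#' @param drift_sd Lognormal SD of independent per-sample, per-taxon
#'   abundance drift around the metacommunity (neutral regimes): strong
#'   drift (`dispersal_limitation`, default 2.5) reshuffles local dominance
#'   entirely; mild drift (`drift`, default 0.2) produces fluctuations
#'   comparable to the stochastic-assembly expectation.
#' @param meta_shape Lognormal SD of metacommunity relative abundances.
#' @param seed Default seed used by [simulate_dataset()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(regime = "drift", n_taxa = 200,
                       slopes = 3, locations = 6, depths = 5, times = 2,
                       per_cell = 1, reads = 2000,
                       bm_rate = 1, niche_dim = 8, sigma_sel = 0.1,
                       migration = NULL, drift_sd = NULL,
                       meta_shape = 1, seed = 1) {
  regime <- match.arg(regime, REGIMES)
  if (is.null(migration))
    migration <- switch(regime, homogenizing_dispersal = 0.8, 0.02)
  if (is.null(drift_sd))
    drift_sd <- switch(regime, dispersal_limitation = 2.5, drift = 0.2, 0)
  stopifnot(n_taxa >= 2, reads >= 1, bm_rate >= 0, niche_dim >= 1,
            sigma_sel > 0, sigma_sel <= 1,
            migration >= 0, migration <= 1, drift_sd >= 0,
            slopes >= 1, slopes <= 3, locations >= 1,
            depths >= 1, depths <= 5, times >= 1, times <= 2)
  structure(list(regime = regime, n_taxa = n_taxa, slopes = slopes,
                 locations = locations, depths = depths, times = times,
                 per_cell = per_cell, reads = reads, bm_rate = bm_rate,
                 niche_dim = niche_dim,
                 sigma_sel = sigma_sel, migration = migration,
                 drift_sd = drift_sd, meta_shape = meta_shape, seed = seed),
            class = "sim_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (birth-only) tree with branch lengths rescaled to unit mean, the
#' substrate for Brownian niche traits.
#'
#' @param n_taxa Number of tips.
#' @return A `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa) {
  stopifnot(n_taxa >= 2)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / mean(tree$edge.length)
  tree
}

#' Simulate a Brownian niche trait on a tree
#'
#' One continuous trait evolving by Brownian motion along the branches:
#' increments are Normal(0, rate * branch length), so closely related tips
#' carry similar niches — the phylogenetic signal that betaNTI inference
#' presumes.
#'
#' @param tree A `phylo` object.
#' @param bm_rate Variance accrued per unit branch length.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, bm_rate = 1) {
  stopifnot(bm_rate >= 0)
  if (bm_rate == 0)
    return(setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_rate))
}

#' Simulate a multidimensional conserved niche
#'
#' `dim` independent Brownian traits evolved on an early-burst rescaling of
#' the tree (rate decaying toward the present, decay strength
#' `conservatism`), returned as a tips x dim matrix. The early burst places
#' most niche divergence on deep branches, so clades occupy distinct regions
#' of niche space and niche-near taxa are reliably clade-mates — the strong
#' niche conservatism that phylogenetic turnover inference presumes. With
#' `conservatism = 0` the traits are plain Brownian.
#'
#' @param tree A `phylo` object.
#' @param bm_rate Per-dimension Brownian rate (at the root, for the
#'   early-burst model).
#' @param dim Number of niche dimensions.
#' @param conservatism Early-burst decay strength (0 = plain Brownian).
#' @return Numeric matrix, rownames = tip labels.
#' @export
simulate_niche <- function(tree, bm_rate = 1, dim = 8, conservatism = 8) {
  tr <- if (conservatism > 0) early_burst_tree(tree, conservatism) else tree
  out <- sapply(seq_len(dim), function(k) simulate_traits(tr, bm_rate))
  rownames(out) <- tree$tip.label
  out
}

# rescale edge lengths so a Brownian rate decaying as exp(-a * t / T) is
# equivalent to constant-rate Brownian motion on the rescaled tree
early_burst_tree <- function(tree, a) {
  nd <- ape::node.depth.edgelength(tree)
  Tm <- max(nd)
  t2 <- tree
  t2$edge.length <- (Tm / a) * (exp(-a * nd[tree$edge[, 1]] / Tm) -
                                  exp(-a * nd[tree$edge[, 2]] / Tm))
  t2
}

# mean per-dimension squared distance from each taxon niche to a point
niche_dist2 <- function(niche, point) {
  rowMeans((niche - matrix(point, nrow(niche), ncol(niche), byrow = TRUE))^2)
}

design_metadata <- function(config) {
  slopes <- c("East", "Central", "West")[seq_len(config$slopes)]
  depths <- paste0("D", seq_len(config$depths))
  times <- c("pre", "post")[seq_len(config$times)]
  md <- expand.grid(rep = seq_len(config$per_cell), time = times,
                    depth = depths, location = seq_len(config$locations),
                    slope = slopes, stringsAsFactors = FALSE)
  md$sample <- sprintf("%s.L%d.%s.%s%s", substr(md$slope, 1, 1), md$location,
                       md$depth, md$time,
                       ifelse(config$per_cell > 1, paste0(".r", md$rep), ""))
  md$rep <- NULL
  md[c("sample", "slope", "location", "depth", "time")]
}

env_covariates <- function(md, optima = NULL) {
  n <- nrow(md)
  d <- as.integer(sub("D", "", md$depth))
  post <- as.numeric(md$time == "post")
  drive <- if (is.null(optima)) rep(0, n) else as.numeric(scale(optima))
  md$pH <- 7.5 - 0.15 * d + 0.3 * drive + rnorm(n, 0, 0.1)
  md$EC <- 0.4 + 0.05 * d + 0.1 * post + rnorm(n, 0, 0.05)
  md$TC <- 2.0 + 0.5 * drive - 0.1 * d + rnorm(n, 0, 0.2)
  md$OC <- 1.2 + 0.4 * drive - 0.08 * d + rnorm(n, 0, 0.15)
  md$IC <- pmax(0, md$TC - md$OC + rnorm(n, 0, 0.05))
  md$TN <- 0.2 + 0.05 * drive + rnorm(n, 0, 0.02)
  md$SWC_mean_Annual <- 0.10 + 0.02 * d + 0.05 * post + rnorm(n, 0, 0.01)
  md$SWC_fractimedry_Annual <- pmin(1, pmax(0, 0.6 - 0.05 * d - 0.2 * post +
                                              rnorm(n, 0, 0.05)))
  md$Temperature_Instantaneous <- 22 - 0.4 * d - 1.5 * post + rnorm(n, 0, 0.5)
  md$DNA_conc <- pmax(0.1, 8 - 1.2 * d + rnorm(n, 0, 0.8))
  md
}

#' Simulate communities under a known assembly regime
#'
#' Builds a sample x taxon count table plus nested metadata from a tree and
#' a Brownian niche trait, under one of five generating regimes:
#'
#' * `homogeneous_selection` — every sample filters the metacommunity through
#'   the same Gaussian niche (optimum = the niche-space medoid taxon, breadth
#'   `sigma_sel` in per-dimension SD units), so compositions converge on one
#'   clade neighborhood.
#' * `variable_selection` — each sample anchors its optimum at the niche of a
#'   uniformly drawn taxon, so compositions diverge along the phylogeny.
#' * `dispersal_limitation` — no selection; each sample's abundances drift
#'   independently and strongly around the metacommunity (lognormal
#'   perturbation, SD `drift_sd`), so samples disagree even on the relative
#'   abundances of shared taxa far beyond the stochastic expectation.
#' * `homogenizing_dispersal` — no selection; all samples assemble from one
#'   shared realized pool, with a fraction `migration` of reads fixed to the
#'   pool composition (mass effects), so compositions converge.
#' * `drift` — the same lognormal abundance drift at moderate strength:
#'   fluctuations comparable to the stochastic-assembly baseline.
#'
#' Metacommunity relative abundances follow a lognormal rank-abundance
#' curve. Environmental covariates in the metadata follow depth/time
#' gradients and, for selection regimes, track the sample optima.
#'
#' @param config A [sim_config()].
#' @param tree Optional tree (simulated if omitted).
#' @param traits Optional niche matrix from [simulate_niche()] (or a single
#'   named trait vector; simulated if omitted).
#' @return List: `counts` (samples x taxa, integer), `metadata` (with env
#'   covariates), `tree`, `traits` (niche matrix), `optima` (per-sample
#'   scalar niche driver, NA for neutral regimes), `config`.
#' @export
simulate_communities <- function(config, tree = NULL, traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- simulate_tree(config$n_taxa)
  if (is.null(traits))
    traits <- simulate_niche(tree, config$bm_rate, config$niche_dim)
  if (is.null(dim(traits))) traits <- cbind(traits)
  traits <- traits[tree$tip.label, , drop = FALSE]
  S <- length(tree$tip.label)
  md <- design_metadata(config)
  n <- nrow(md)
  p_meta <- exp(rnorm(S, 0, config$meta_shape))
  p_meta <- p_meta / sum(p_meta)

  counts <- matrix(0L, n, S, dimnames = list(md$sample, tree$tip.label))
  optima <- rep(NA_real_, n)

  draw <- function(p) as.integer(rmultinom(1, config$reads, p)[, 1])

  pool_size <- max(5L, as.integer(round(config$migration * config$reads)))

  if (config$regime %in% c("homogeneous_selection", "variable_selection")) {
    # Gaussian niche filter on the metacommunity, then a finite founder pool:
    # different samples fix different members of the favored clade, which is
    # what makes phylogenetic turnover (not just composition) informative.
    # Optima are anchored at taxon niche positions so the favored set is
    # never empty and is a clade neighborhood (anchoring at the niche-space
    # centroid would pick weakly-drifted taxa from many clades instead).
    # Environments favor populated niche regions: the homogeneous optimum
    # sits in the densest neighborhood, and variable optima are drawn with
    # probability proportional to neighborhood density.
    radius <- vapply(seq_len(S), function(i)
      quantile(sqrt(niche_dist2(traits, traits[i, ])[-i]), config$sigma_sel),
      numeric(1))
    anchor <- if (config$regime == "homogeneous_selection")
      rep(which.min(radius), n)
    else sample.int(S, n, replace = TRUE, prob = 1 / radius)
    pc1 <- prcomp(traits, scale. = FALSE)$x[, 1]
    optima <- pc1[anchor]
    for (s in seq_len(n)) {
      d2 <- niche_dist2(traits, traits[anchor[s], ])
      sigma <- max(quantile(sqrt(d2[-anchor[s]]), config$sigma_sel), 1e-12)
      w <- p_meta * exp(-d2 / (2 * sigma^2))
      if (sum(w) == 0) w <- p_meta
      pool <- rmultinom(1, pool_size, w / sum(w))[, 1]
      counts[s, ] <- draw(pool / sum(pool))
    }
  } else if (config$regime %in% c("dispersal_limitation", "drift")) {
    # independent lognormal abundance drift around the metacommunity:
    # samples keep broadly overlapping membership but disagree on relative
    # abundances, strongly (isolation) or moderately (drift)
    for (s in seq_len(n)) {
      w <- p_meta * exp(rnorm(S, 0, config$drift_sd))
      counts[s, ] <- draw(w / sum(w))
    }
  } else if (config$regime == "homogenizing_dispersal") {
    pool <- rmultinom(1, config$reads, p_meta)[, 1]
    c_pool <- pool / sum(pool)
    core <- floor(config$migration * config$reads * c_pool)
    for (s in seq_len(n)) {
      extra <- config$reads - sum(core)
      counts[s, ] <- as.integer(core + rmultinom(1, extra, c_pool)[, 1])
    }
  }

  # all-zero taxa are kept: the table's taxon set is the full metacommunity
  # tree, so the taxon-shuffling null retains its metacommunity context even
  # when selection restricts the observed taxa to a clade neighborhood
  md <- env_covariates(md, if (all(is.na(optima))) NULL else optima)
  list(counts = counts, metadata = md, tree = tree,
       traits = traits, optima = optima, config = config)
}

#' One-call synthetic data set
#'
#' Seeds the generator and runs tree, trait and community simulation.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return See [simulate_communities()].
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  set.seed(seed)
  simulate_communities(config)
}

#' Restrict a community to a guild (marker-gene sub-population)
#'
#' Subsets the table to the guild's taxa and prunes the tree to match —
#' the synthetic analogue of a marker-gene variant table paired with its
#' gene tree. Counts are not renormalized. Samples left with zero guild
#' reads are dropped with a warning.
#'
#' @param counts Samples x taxa matrix.
#' @param tree Tree over (at least) the table taxa.
#' @param taxa Guild member taxon ids.
#' @return List: `counts`, `tree`.
#' @export
extract_guild_table <- function(counts, tree, taxa) {
  miss <- setdiff(taxa, colnames(counts))
  if (length(miss)) stop("guild taxa absent from table: ",
                         paste(head(miss, 5), collapse = ", "))
  sub <- counts[, taxa, drop = FALSE]
  empty <- rowSums(sub) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " sample(s) with no guild reads")
    sub <- sub[!empty, , drop = FALSE]
  }
  if (length(taxa) < 2) stop("guild needs at least two taxa")
  list(counts = sub, tree = ape::keep.tip(tree, taxa))
}

#' Simulate guild sub-populations with shared or independent drivers
#'
#' Generates one community in which two (or more) disjoint guilds experience
#' environmental selection of sample-varying *strength*: each guild has a
#' fixed niche optimum (its densest niche neighborhood), and a latent
#' per-sample driver in `[0, 1]` scales how strongly that guild is filtered
#' toward it. Samples under weak filtering assemble the guild neutrally
#' (betaNTI near 0 against other samples); samples under strong filtering
#' collapse the guild onto the optimum's clade neighborhood (increasingly
#' negative betaNTI), so a guild's per-sample mean betaNTI tracks its
#' driver. With `shared_driver = TRUE` all guilds respond to the same latent
#' trajectory (coordinated assembly); otherwise each guild's trajectory is
#' independent. Taxa outside every guild assemble neutrally. This is the
#' test bed for cross-gene betaNTI coordination.
#'
#' @param config A [sim_config()] (regime field ignored; selection applies to
#'   guild members only).
#' @param n_guilds Number of guilds.
#' @param guild_frac Fraction of taxa per guild.
#' @param shared_driver Share one latent trajectory across guilds.
#' @param seed Seed.
#' @return List: `counts`, `metadata`, `tree`, `guilds` (named list of taxon
#'   id vectors, `g1`, `g2`, ...), `driver` (n_samples x n_guilds matrix of
#'   latent selection-strength values). The metadata environmental
#'   covariates track the first guild's driver.
#' @export
simulate_guild_dataset <- function(config, n_guilds = 2, guild_frac = 0.3,
                                   shared_driver = TRUE, seed = config$seed) {
  set.seed(seed)
  tree <- simulate_tree(config$n_taxa)
  niche <- simulate_niche(tree, config$bm_rate, config$niche_dim)
  S <- config$n_taxa
  md <- design_metadata(config)
  n <- nrow(md)
  gsize <- max(2L, floor(guild_frac * S))
  perm <- sample.int(S)
  guilds <- lapply(seq_len(n_guilds), function(g)
    tree$tip.label[perm[((g - 1) * gsize + 1):(g * gsize)]])
  names(guilds) <- paste0("g", seq_len(n_guilds))

  # bimodal selection strength (episodic environment: most samples either
  # weakly or strongly filtered) gives the driver high variance in [0, 1]
  u <- matrix(rbeta(n * n_guilds, 0.4, 0.4), n, n_guilds)
  if (shared_driver) u <- matrix(u[, 1], n, n_guilds)

  p_meta <- exp(rnorm(S, 0, config$meta_shape))
  p_meta <- p_meta / sum(p_meta)
  counts <- matrix(0L, n, S, dimnames = list(md$sample, tree$tip.label))
  # fixed optimum per guild: the guild member with the densest niche
  # neighborhood among its fellow members
  guild_idx <- lapply(guilds, match, table = tree$tip.label)
  guild_geom <- lapply(guild_idx, function(gi) {
    sub <- niche[gi, , drop = FALSE]
    radius <- vapply(seq_along(gi), function(k)
      quantile(sqrt(niche_dist2(sub, sub[k, ])[-k]), config$sigma_sel),
      numeric(1))
    a <- which.min(radius)
    list(d2 = niche_dist2(sub, sub[a, ]), sigma = max(radius[a], 1e-12))
  })
  pool_size <- max(5L, as.integer(round(config$migration * config$reads)))
  for (s in seq_len(n)) {
    w <- p_meta
    for (g in seq_len(n_guilds)) {
      geom <- guild_geom[[g]]
      w[guild_idx[[g]]] <- w[guild_idx[[g]]] *
        exp(-u[s, g] * geom$d2 / (2 * geom$sigma^2))
    }
    pool <- rmultinom(1, pool_size, w / sum(w))[, 1]
    counts[s, ] <- as.integer(rmultinom(1, config$reads, pool / sum(pool))[, 1])
  }
  md <- env_covariates(md, u[, 1])
  list(counts = counts, metadata = md, tree = tree, guilds = guilds,
       driver = u)
}
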