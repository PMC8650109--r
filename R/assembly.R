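#' Infer community assembly processes from a table and a phylogeny
#'
#' The main entry point. For every pair of samples it computes the observed
#' abundance-weighted betaMNTD, a taxon-shuffling null distribution
#' (`n_reps` replicates, one shuffle shared by all pairs per replicate), the
#' standardized effect size betaNTI, and — for pairs where selection is not
#' implicated (|betaNTI| <= 2) — the Raup-Crick metric on Bray-Curtis
#' dissimilarity against a stochastic assembly null. Each pair is then
#' classified into one of five processes: variable selection, homogeneous
#' selection, homogenizing dispersal, dispersal limitation, or undominated.
#'
#' Workflow details mirror common amplicon practice: samples under
#' `min_depth` total reads are dropped first; remaining samples are rarefied
#' without replacement to `rarefy_to` reads (skip by leaving it `NULL`, e.g.
#' for relative-abundance marker-gene tables); betaMNTD weights are relative
#' abundances of the analyzed table. RC-bray requires integer counts and is
#' computed on the rarefied table.
#'
#' @param counts Samples x taxa abundance matrix. Integer counts unless
#'   `rc_policy = "none"` and no rarefaction is requested.
#' @param tree Rooted phylogeny (`phylo`) containing every table taxon.
#' @param metadata Optional data.frame with a `sample` column plus grouping
#'   factors and environmental covariates.
#' @param n_reps betaMNTD null replicates (default 999).
#' @param rc_reps RC-bray null replicates per pair (default 999).
#' @param min_depth Drop samples with fewer total reads (default 0: keep all).
#' @param rarefy_to Rarefaction depth, or `NULL` to skip.
#' @param rc_policy `"nonsignificant"` (default: RC only where
#'   |betaNTI| <= 2), `"all"`, or `"none"` (selection calls only; other pairs
#'   left unclassified).
#' @param within Optional character vector of metadata columns; only pairs
#'   whose samples share every named factor level (e.g. the same time point)
#'   enter the pair table. betaNTI matrices are still computed for all pairs.
#' @param seed Integer seed governing rarefaction, the null shuffles and the
#'   per-pair RC streams.
#' @return An object of class `"assembly"`: a list with `pairs` (long-format
#'   data.frame: sample_a, sample_b, bmntd_obs, null_mean, null_sd, bnti,
#'   rc_bray, process), `bnti` (full symmetric matrix), `counts` (the
#'   analyzed table), `metadata`, and `params`.
#' @seealso [summary.assembly()], [plot.assembly()], [bnti_matrix()],
#'   [summarize_processes()]
#' @examples
#' sim <- simulate_dataset(sim_config(regime = "homogeneous_selection",
#'                                    n_taxa = 40, locations = 2, depths = 2,
#'                                    reads = 500), seed = 1)
#' fit <- assembly_analysis(sim$counts, sim$tree, sim$metadata,
#'                          n_reps = 99, rc_reps = 99, seed = 1)
#' summary(fit)
#' @export
assembly_analysis <- function(counts, tree, metadata = NULL,
                              n_reps = 999, rc_reps = 999,
                              min_depth = 0, rarefy_to = NULL,
                              rc_policy = c("nonsignificant", "all", "none"),
                              within = NULL, seed = 1) {
  rc_policy <- match.arg(rc_policy)
  cl <- match.call()
  validate_inputs(counts, tree, metadata)
  set.seed(seed)

  removed <- character()
  if (min_depth > 0) {
    counts <- filter_min_depth(counts, min_depth)
    removed <- attr(counts, "removed_samples")
  }
  if (!is.null(rarefy_to)) counts <- rarefy_counts(counts, rarefy_to)
  if (nrow(counts) < 2) stop("need at least two samples after filtering")

  dm <- patristic_distances(ape::keep.tip(tree, colnames(counts)))
  obs <- bmntd(counts, dm)
  null <- bmntd_null(counts, dm, n_reps = n_reps)

  bnti <- matrix(NA_real_, nrow(counts), nrow(counts),
                 dimnames = dimnames(obs))
  ok <- null$sd > 0
  bnti[ok] <- (obs[ok] - null$mean[ok]) / null$sd[ok]
  diag(bnti) <- NA_real_
  if (any(!ok & upper.tri(ok)))
    warning("degenerate null (SD = 0) for ",
            sum(!ok & upper.tri(ok)), " pair(s); betaNTI set to NA")

  ut <- which(upper.tri(obs), arr.ind = TRUE)
  pairs <- data.frame(
    sample_a = rownames(counts)[ut[, 1]],
    sample_b = rownames(counts)[ut[, 2]],
    bmntd_obs = obs[ut],
    null_mean = null$mean[ut],
    null_sd = null$sd[ut],
    bnti = bnti[ut],
    stringsAsFactors = FALSE
  )
  idx <- ut

  if (!is.null(within)) {
    if (is.null(metadata)) stop("`within` requires metadata")
    key <- do.call(paste, c(metadata[match(rownames(counts), metadata$sample),
                                     within, drop = FALSE], sep = "/"))
    keep <- key[idx[, 1]] == key[idx[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
    idx <- idx[keep, , drop = FALSE]
  }

  pairs$rc_bray <- NA_real_
  if (rc_policy != "none" && nrow(pairs)) {
    need <- if (rc_policy == "all") rep(TRUE, nrow(pairs)) else
      !is.na(pairs$bnti) & abs(pairs$bnti) <= 2
    if (any(need)) {
      validate_counts(counts, integer_counts = TRUE)
      pairs$rc_bray[need] <- rc_bray_pairs(counts, idx[need, , drop = FALSE],
                                           n_reps = rc_reps, seed = seed)
    }
  }

  pairs$process <- NA_character_
  classifiable <- !is.na(pairs$bnti) &
    (abs(pairs$bnti) > 2 | !is.na(pairs$rc_bray))
  if (any(classifiable))
    pairs$process[classifiable] <- classify_pair(pairs$bnti[classifiable],
                                                 pairs$rc_bray[classifiable])
  rownames(pairs) <- NULL

  structure(list(
    pairs = pairs,
    bnti = bnti,
    counts = counts,
    metadata = metadata,
    params = list(n_reps = n_reps, rc_reps = rc_reps, min_depth = min_depth,
                  rarefy_to = rarefy_to, rc_policy = rc_policy,
                  within = within, seed = seed,
                  removed_samples = removed),
    call = cl
  ), class = "assembly")
}

#' Extract the full betaNTI matrix from a fit
#'
#' @param fit An `"assembly"` object.
#' @return Symmetric samples x samples matrix of betaNTI (NA diagonal).
#' @export
bnti_matrix <- function(fit) {
  stopifnot(inherits(fit, "assembly"))
  fit$bnti
}

#' @export
print.assembly <- function(x, ...) {
  cat("Community assembly null-model fit\n")
  cat(sprintf("  samples: %d   taxa: %d   pairs classified: %d\n",
              nrow(x$counts), ncol(x$counts),
              sum(!is.na(x$pairs$process))))
  cat(sprintf("  betaMNTD null reps: %d   RC-bray reps: %d (policy: %s)\n",
              x$params$n_reps, x$params$rc_reps, x$params$rc_policy))
  if (!is.null(x$params$rarefy_to))
    cat(sprintf("  rarefied to %d reads per sample\n", x$params$rarefy_to))
  bn <- x$pairs$bnti
  cat(sprintf("  betaNTI: median %.2f   %%|betaNTI|>2: %.1f\n",
              median(bn, na.rm = TRUE),
              100 * mean(abs(bn) > 2, na.rm = TRUE)))
  invisible(x)
}

#' Summarize an assembly fit
#'
#' Process fractions over all classified pairs, optionally within metadata
#' groups (a pair counts toward a group only when both samples share the
#' group's level of every factor).
#'
#' @param object An `"assembly"` fit.
#' @param by Optional character vector of metadata columns to group by.
#' @param ... Unused.
#' @return A `"summary.assembly"` object wrapping the process-fraction table.
#' @export
summary.assembly <- function(object, by = NULL, ...) {
  done <- object$pairs[!is.na(object$pairs$process), , drop = FALSE]
  tab <- summarize_processes(done, metadata = object$metadata, group_by = by)
  structure(list(processes = tab, n_pairs_total = nrow(object$pairs),
                 bnti_median = median(object$pairs$bnti, na.rm = TRUE),
                 by = by),
            class = "summary.assembly")
}

#' @export
print.summary.assembly <- function(x, ...) {
  cat("Relative influence of assembly processes\n")
  cat(sprintf("  pairs: %d   median betaNTI: %.2f\n\n",
              x$n_pairs_total, x$bnti_median))
  tab <- x$processes
  tab[PROCESS_LEVELS] <- lapply(tab[PROCESS_LEVELS], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Histogram of betaNTI values
#'
#' Plots the betaNTI distribution of classified pairs with the significance
#' boundaries at +-2 marked; with `by`, one panel per metadata group.
#'
#' @param x An `"assembly"` fit.
#' @param by Optional metadata column to facet by (pairs with mixed levels
#'   dropped).
#' @param width Bin width (default 0.5).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.assembly <- function(x, by = NULL, width = 0.5, ...) {
  p <- x$pairs[!is.na(x$pairs$bnti), , drop = FALSE]
  panel <- function(v, main) {
    hist(v, breaks = seq(floor(min(v, -6)), ceiling(max(v, 6)), by = width),
         main = main, xlab = expression(beta * "NTI"), col = "grey80", ...)
    abline(v = c(-2, 2), lty = 2, col = "red3")
  }
  if (is.null(by)) {
    panel(p$bnti, "betaNTI distribution")
  } else {
    md <- x$metadata
    ka <- md[[by]][match(p$sample_a, md$sample)]
    kb <- md[[by]][match(p$sample_b, md$sample)]
    p <- p[ka == kb, , drop = FALSE]
    grp <- ka[ka == kb]
    lv <- unique(grp)
    op <- par(mfrow = c(1, length(lv)))
    on.exit(par(op))
    for (g in lv) panel(p$bnti[grp == g], paste0(by, ": ", g))
  }
  invisible(x)
}

#' @export
as.data.frame.assembly <- function(x, ...) x$pairs

#' Write the long-format pair table of a fit to TSV
#'
#' @param fit An `"assembly"` fit.
#' @param path Output path.
#' @export
write_pairs <- function(fit, path) {
  stopifnot(inherits(fit, "assembly"))
  write.table(fit$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
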