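#' Per-sample mean betaNTI, optionally controlling for a grouping factor
#'
#' Averages each sample's betaNTI values against its eligible partners. With
#' `control = NULL` every other sample is a partner; with e.g.
#' `control = "depth"` only samples from the same depth class are averaged —
#' a sample from Depth1 is compared only to other Depth1 samples. Samples
#' with no eligible partner are excluded with a warning.
#'
#' @param bnti Symmetric samples x samples betaNTI matrix (e.g.
#'   [bnti_matrix()] of a fit).
#' @param metadata Data.frame with a `sample` column; required when `control`
#'   is given.
#' @param control Metadata column name (e.g. `"depth"`, `"time"`), or `NULL`.
#' @return Named numeric vector of per-sample means.
#' @export
within_group_mean_bnti <- function(bnti, metadata = NULL, control = NULL) {
  check_bnti_matrix(bnti)
  ids <- rownames(bnti)
  if (is.null(control)) {
    grp <- rep("all", length(ids))
  } else {
    if (is.null(metadata)) stop("`control` requires metadata")
    grp <- metadata[[control]][match(ids, metadata$sample)]
    if (anyNA(grp)) stop("samples missing from metadata or control column")
    grp <- as.character(grp)
  }
  out <- vapply(seq_along(ids), function(i) {
    partners <- which(grp == grp[i])
    partners <- setdiff(partners, i)
    vals <- bnti[i, partners]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }, numeric(1))
  names(out) <- ids
  if (anyNA(out)) {
    warning("excluding samples with no eligible partner: ",
            paste(ids[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

check_bnti_matrix <- function(bnti) {
  if (!is.matrix(bnti) || nrow(bnti) != ncol(bnti))
    stop("betaNTI matrix must be square")
  if (is.null(rownames(bnti)) || !identical(rownames(bnti), colnames(bnti)))
    stop("betaNTI matrix must be labelled by sample on both margins")
  invisible(bnti)
}

#' Correlate per-sample mean betaNTI across marker genes
#'
#' For every pair of marker-gene (guild) data sets, correlates the
#' per-sample mean betaNTI vectors on the samples common to both. Pairs with
#' fewer than 3 common samples are reported as not computable (`NA`).
#'
#' @param means Named list of per-sample mean betaNTI vectors, one per gene
#'   (e.g. narG, nifH, rbcL, rps3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` by default to keep the per-pair tests directly comparable.
#' @return List of gene x gene matrices `r`, `p`, `n` (common-sample count).
#' @export
cross_gene_correlation <- function(means, method = c("pearson", "spearman"),
                                   p_adjust = "none") {
  method <- match.arg(method)
  g <- names(means)
  if (is.null(g) || length(g) < 2) stop("need a named list of >= 2 genes")
  k <- length(g)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(g, g))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    common <- intersect(names(means[[i]]), names(means[[j]]))
    n[i, j] <- n[j, i] <- length(common)
    if (length(common) >= 3) {
      ct <- cor.test(means[[i]][common], means[[j]][common], method = method,
                     exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (p_adjust != "none") {
    ut <- upper.tri(p)
    p[ut] <- p.adjust(p[ut], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(r = r, p = p, n = n)
}

#' Correlate per-gene mean betaNTI with environmental variables
#'
#' For each gene and each named environmental variable, correlates the
#' per-sample mean betaNTI (computed upstream under the desired depth/time
#' control) with the sample's value of the variable. Constant variables are
#' flagged as not computable.
#'
#' @param means Named list of per-sample mean betaNTI vectors, one per gene.
#' @param metadata Data.frame with `sample` plus the environmental columns.
#' @param variables Character vector of metadata column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data.frame: gene, variable, n, r, p (NA where not computable).
#' @export
env_correlation <- function(means, metadata, variables,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  miss <- setdiff(variables, names(metadata))
  if (length(miss)) stop("variables absent from metadata: ",
                         paste(miss, collapse = ", "))
  rows <- list()
  for (g in names(means)) {
    m <- means[[g]]
    env <- metadata[match(names(m), metadata$sample), , drop = FALSE]
    for (v in variables) {
      x <- env[[v]]
      ok <- !is.na(x) & !is.na(m)
      res <- data.frame(gene = g, variable = v, n = sum(ok),
                        r = NA_real_, p = NA_real_)
      if (sum(ok) >= 3 && sd(x[ok]) > 0) {
        ct <- cor.test(m[ok], x[ok], method = method, exact = FALSE)
        res$r <- unname(ct$estimate)
        res$p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sub-population (marker-gene) assembly analysis
#'
#' Runs the full betaNTI workflow independently for each marker gene's
#' (tree, abundance table) pair, then computes per-sample mean betaNTI under
#' the requested control, the gene x gene correlation matrix, and (when
#' environmental variables are named) gene x environment correlations.
#' Marker-gene read totals differ across metagenomes, so tables are analyzed
#' on relative abundances with no rarefaction and selection calls only
#' (betaNTI is used quantitatively here; RC-bray is skipped by default).
#'
#' @param genes Named list; each element a list with `counts` (samples x
#'   variants) and `tree` (`phylo` over the variants).
#' @param metadata Shared sample metadata.
#' @param control `NULL`, `"depth"`, `"time"`, ... — factor controlling the
#'   per-sample averaging.
#' @param variables Optional environmental columns for [env_correlation()].
#' @param n_reps betaMNTD null replicates per gene.
#' @param method Correlation method.
#' @param seed Seed (one per gene, derived deterministically).
#' @return List of class `"subpop_assembly"`: `fits`, `means`,
#'   `cross_gene` (r/p/n matrices), `env` (data.frame or NULL), `control`.
#' @export
subpop_assembly <- function(genes, metadata, control = NULL,
                            variables = NULL, n_reps = 999,
                            method = "pearson", seed = 1) {
  if (is.null(names(genes))) stop("`genes` must be a named list")
  fits <- lapply(seq_along(genes), function(k) {
    g <- genes[[k]]
    assembly_analysis(g$counts, g$tree, metadata = metadata,
                      n_reps = n_reps, rc_policy = "none",
                      seed = pair_seed(seed, k, 1L))
  })
  names(fits) <- names(genes)
  means <- lapply(fits, function(f)
    within_group_mean_bnti(bnti_matrix(f), metadata, control))
  cross <- cross_gene_correlation(means, method = method)
  env <- if (!is.null(variables))
    env_correlation(means, metadata, variables, method = method) else NULL
  structure(list(fits = fits, means = means, cross_gene = cross, env = env,
                 control = control),
            class = "subpop_assembly")
}

#' @export
print.subpop_assembly <- function(x, ...) {
  cat("Sub-population (marker-gene) assembly analysis\n")
  cat("  genes:", paste(names(x$means), collapse = ", "), "\n")
  cat("  control:", if (is.null(x$control)) "none" else x$control, "\n")
  cat("  gene x gene correlations (r):\n")
  print(round(x$cross_gene$r, 3))
  invisible(x)
}
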