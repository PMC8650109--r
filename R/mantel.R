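#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized upper triangles, with significance
#' from joint row/column permutations of the predictor matrix. The p-value
#' uses the +1 correction, `p = (1 + #[r_perm >= r_obs]) / (1 + n_perm)`,
#' one-tailed for a positive association by default (`"two.sided"` counts
#' `|r_perm| >= |r_obs|`).
#'
#' @param dm_response,dm_predictor Square labelled distance matrices over the
#'   same samples (order may differ; matched by label).
#' @param n_perm Number of permutations (default 999).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `r`, `p`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(dm_response, dm_predictor, n_perm = 999,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_square_symmetric(dm_response)
  check_square_symmetric(dm_predictor)
  if (!setequal(rownames(dm_response), rownames(dm_predictor)))
    stop("distance matrices must cover the same samples")
  dm_predictor <- dm_predictor[rownames(dm_response), rownames(dm_response)]
  n <- nrow(dm_response)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  ut <- upper.tri(dm_response)
  x <- dm_response[ut]
  if (sd(x) == 0 || sd(dm_predictor[ut]) == 0)
    stop("constant distance matrix: Mantel correlation not computable")
  r_obs <- cor(x, dm_predictor[ut])
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm <- cor(x, dm_predictor[p, p][ut])
    hit <- if (alternative == "greater") r_perm >= r_obs
           else abs(r_perm) >= abs(r_obs)
    exceed <- exceed + hit
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, alternative = alternative)
}

# betaNTI "distance" structures may carry negative values, so Mantel inputs
# are only required to be square, labelled and symmetric.
check_square_symmetric <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("matrix must be square")
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm)))
    stop("matrix must have identical row and column labels")
  if (anyNA(dm[upper.tri(dm)] - t(dm)[upper.tri(dm)]) ||
      max(abs(dm - t(dm)), na.rm = TRUE) > 1e-8)
    stop("matrix must be symmetric without missing off-diagonal values")
  invisible(dm)
}

#' Distance matrix from a scalar environmental variable
#'
#' The standard construction for Mantel tests against a scalar covariate:
#' entry (a, b) is `|v_a - v_b|`.
#'
#' @param values Named numeric vector (names = sample ids).
#' @return Square labelled distance matrix.
#' @export
env_distance <- function(values) {
  if (is.null(names(values))) stop("values must be named by sample")
  if (anyNA(values)) stop("values contain NA")
  out <- abs(outer(values, values, "-"))
  dimnames(out) <- list(names(values), names(values))
  out
}

#' betaNTI-environment Mantel screen
#'
#' Runs [mantel_test()] of a betaNTI distance structure against the absolute
#' difference matrix of each named environmental variable, and flags strong
#' relationships at the conventional `r >= 0.30`, `p <= 0.05` cut.
#'
#' @param bnti Symmetric betaNTI matrix (NAs not allowed off-diagonal; subset
#'   samples first if needed).
#' @param metadata Data.frame with `sample` and the environmental columns.
#' @param variables Character vector of variable names.
#' @param n_perm Permutations per test.
#' @param r_min,p_max Thresholds for the `strong` flag.
#' @return Data.frame: variable, r, p, strong.
#' @export
mantel_env_screen <- function(bnti, metadata, variables, n_perm = 999,
                              r_min = 0.30, p_max = 0.05) {
  check_bnti_matrix(bnti)
  d <- bnti
  diag(d) <- 0
  rows <- lapply(variables, function(v) {
    vals <- metadata[[v]][match(rownames(bnti), metadata$sample)]
    names(vals) <- rownames(bnti)
    res <- tryCatch(mantel_test(d, env_distance(vals), n_perm = n_perm),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, r = NA_real_, p = NA_real_, strong = NA))
    data.frame(variable = v, r = res$r, p = res$p,
               strong = res$r >= r_min & res$p <= p_max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
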