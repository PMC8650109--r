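PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "homogenizing_dispersal", "dispersal_limitation",
                    "undominated")

#' Classify a sample pair into an ecological assembly process
#'
#' The two-tier decision rule: betaNTI > 2 indicates variable selection,
#' betaNTI < -2 homogeneous selection. When |betaNTI| < 2 selection is not
#' implicated and RC-bray decides: RC < -0.95 homogenizing dispersal,
#' RC > +0.95 dispersal limitation, |RC| <= 0.95 undominated. Exact boundary
#' hits (|betaNTI| = 2) fall through to the dispersal tier, and |RC| = 0.95
#' to undominated — both measure-zero conventions, fixed and documented here.
#'
#' @param bnti betaNTI value(s).
#' @param rc RC-bray value(s); may be `NA` only where `|bnti| >= 2`.
#' @return Character vector of process labels.
#' @examples
#' classify_pair(-3.1, NA)     # homogeneous_selection
#' classify_pair(1.0, 0.97)    # dispersal_limitation
#' @export
classify_pair <- function(bnti, rc = NA_real_) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  need_rc <- abs(bnti) <= 2
  if (any(need_rc & is.na(rc)))
    stop("RC-bray required (and absent) for pairs with |betaNTI| <= 2")
  out <- character(n)
  out[bnti > 2] <- "variable_selection"
  out[bnti < -2] <- "homogeneous_selection"
  out[need_rc & rc < -0.95] <- "homogenizing_dispersal"
  out[need_rc & rc > 0.95] <- "dispersal_limitation"
  out[need_rc & abs(rc) <= 0.95] <- "undominated"
  out
}

#' Relative influence of assembly processes, by group
#'
#' Tallies classified sample pairs into the five process fractions, overall
#' or within groups defined by sample metadata factors. A pair belongs to a
#' group only when both of its samples carry the same level of every grouping
#' factor; mixed pairs are dropped. Groups with zero pairs are excluded with
#' a warning.
#'
#' @param pairs Data.frame with columns `sample_a`, `sample_b`, `process`
#'   (e.g. the `$pairs` of an [assembly_analysis()] fit).
#' @param metadata Data.frame with a `sample` column; required when
#'   `group_by` is given.
#' @param group_by Character vector of metadata column names.
#' @return Data.frame: one row per group, columns `n_pairs` and the five
#'   process fractions (summing to 1).
#' @export
summarize_processes <- function(pairs, metadata = NULL, group_by = NULL) {
  stopifnot(all(c("sample_a", "sample_b", "process") %in% names(pairs)))
  if (is.null(group_by)) {
    grp <- rep("all", nrow(pairs))
  } else {
    if (is.null(metadata)) stop("metadata required when group_by is given")
    key <- function(samples) {
      idx <- match(samples, metadata$sample)
      if (anyNA(idx)) stop("pair samples missing from metadata")
      do.call(paste, c(metadata[idx, group_by, drop = FALSE], sep = " / "))
    }
    ka <- key(pairs$sample_a)
    kb <- key(pairs$sample_b)
    same <- ka == kb
    pairs <- pairs[same, , drop = FALSE]
    grp <- ka[same]
  }
  if (!nrow(pairs)) {
    warning("no within-group pairs to summarize")
    return(data.frame(group = character(), n_pairs = integer()))
  }
  split_p <- split(pairs$process, grp)
  rows <- lapply(names(split_p), function(g) {
    p <- split_p[[g]]
    frac <- as.numeric(table(factor(p, levels = PROCESS_LEVELS))) / length(p)
    df <- data.frame(group = g, n_pairs = length(p))
    df[PROCESS_LEVELS] <- as.list(frac)
    df
  })
  do.call(rbind, rows)
}

#' betaNTI histogram bin counts
#'
#' Fixed-width bins for plotting the per-group distribution of betaNTI
#' (default width 0.5 over `[-6, 6]`; values outside the range are clamped
#' into the end bins so no pair is dropped).
#'
#' @param bnti Numeric vector of betaNTI values.
#' @param width Bin width.
#' @param range Two-element range covered by the bins.
#' @return Data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
bnti_histogram <- function(bnti, width = 0.5, range = c(-6, 6)) {
  breaks <- seq(range[1], range[2], by = width)
  x <- pmin(pmax(bnti, range[1] + width / 2), range[2] - width / 2)
  h <- hist(x, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = h$counts)
}
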