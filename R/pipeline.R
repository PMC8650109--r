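#' Run the full assembly workflow from a config
#'
#' End-to-end driver: reads tree/table/metadata, validates, runs
#' [assembly_analysis()], writes the long-format pair table, process
#' summaries (overall and per slope x time), betaNTI histogram bins, the
#' per-sample mean betaNTI table, an optional Mantel screen against
#' environmental variables, and a run log recording every decision value.
#' Deterministic given the inputs and the config seed.
#'
#' @param config Path to a YAML file or an equivalent named list. Recognized
#'   fields: `tree` (Newick path), `table` (TSV path),
#'   `table_orientation` (`taxa_rows`/`samples_rows`), `metadata` (CSV path),
#'   `seed`, `n_reps`, `rc_reps`, `min_depth`, `rarefy_to`, `rc_policy`,
#'   `within` (metadata columns restricting the pair universe),
#'   `group_by` (summary grouping columns), `mantel_variables`,
#'   `mantel_permutations`, `mean_bnti_control`.
#' @param output_dir Results directory (created if absent).
#' @return Invisibly, a list with the fit and the written file paths.
#' @export
run_assembly_pipeline <- function(config, output_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- function(field) {
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
    cfg[[field]]
  }
  get <- function(field, default) if (is.null(cfg[[field]])) default else cfg[[field]]

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(output_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)

  tree <- read_phylo(file = req("tree"))
  counts <- read_abundance_table(req("table"),
                                 orientation = get("table_orientation", "taxa_rows"))
  metadata <- if (!is.null(cfg$metadata)) read_sample_metadata(cfg$metadata) else NULL

  rep_v <- validate_inputs(counts, tree, metadata, raise = TRUE)
  for (w in rep_v$warnings) {
    message("validation: ", w)
    log_line("warning: %s", w)
  }

  seed <- get("seed", 1)
  n_reps <- get("n_reps", 999)
  rc_reps <- get("rc_reps", 999)
  min_depth <- get("min_depth", 0)
  rarefy_to <- cfg$rarefy_to
  rc_policy <- get("rc_policy", "nonsignificant")
  within <- cfg$within
  log_line("assemblyflux version: %s", as.character(packageVersion("assemblyflux")))
  log_line("seed: %d | n_reps: %d | rc_reps: %d", seed, n_reps, rc_reps)
  log_line("min_depth: %s | rarefy_to: %s | rc_policy: %s",
           min_depth, if (is.null(rarefy_to)) "none" else rarefy_to, rc_policy)
  log_line("within: %s", if (is.null(within)) "none" else paste(within, collapse = ","))
  log_line("bnti thresholds: +-2 | rc thresholds: +-0.95")

  fit <- assembly_analysis(counts, tree, metadata,
                           n_reps = n_reps, rc_reps = rc_reps,
                           min_depth = min_depth, rarefy_to = rarefy_to,
                           rc_policy = rc_policy, within = within, seed = seed)
  if (length(fit$params$removed_samples))
    log_line("samples removed by min_depth: %s",
             paste(fit$params$removed_samples, collapse = ","))

  files <- character()
  out <- function(name) {
    p <- file.path(output_dir, name)
    files <<- c(files, p)
    p
  }

  write_pairs(fit, out("pairwise_results.tsv"))

  done <- fit$pairs[!is.na(fit$pairs$process), , drop = FALSE]
  sum_all <- summarize_processes(done)
  write.table(sum_all, out("process_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  group_by <- get("group_by",
                  if (!is.null(metadata) &&
                      all(c("slope", "time") %in% names(metadata)))
                    c("slope", "time") else NULL)
  if (!is.null(group_by) && nrow(done)) {
    sum_grp <- summarize_processes(done, metadata, group_by)
    write.table(sum_grp, out("process_summary_by_group.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  hist_tab <- bnti_histogram(fit$pairs$bnti[!is.na(fit$pairs$bnti)])
  write.table(hist_tab, out("bnti_histogram.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  control <- cfg$mean_bnti_control
  mb <- within_group_mean_bnti(bnti_matrix(fit), metadata, control)
  write.table(data.frame(sample = names(mb), mean_bnti = mb),
              out("mean_bnti.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(cfg$mantel_variables)) {
    scr <- mantel_env_screen(bnti_matrix(fit), metadata, cfg$mantel_variables,
                             n_perm = get("mantel_permutations", 999))
    write.table(scr, out("mantel_env.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log_line("outputs: %s", paste(basename(files), collapse = ", "))
  invisible(list(fit = fit, files = files, log = logf))
}

#' Write a simulated data set in the formats the pipeline consumes
#'
#' @param sim Output of [simulate_dataset()] or [simulate_communities()].
#' @param dir Target directory.
#' @return Named paths (tree, table, metadata), invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(sim$tree, tree_path)
  table_path <- file.path(dir, "table.tsv")
  write_abundance_table(sim$counts, table_path)
  md_path <- file.path(dir, "metadata.csv")
  write.table(sim$metadata, md_path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(tree = tree_path, table = table_path, metadata = md_path))
}
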