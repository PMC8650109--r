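#' Validate a sample-by-taxon abundance matrix
#'
#' Abundance tables are plain numeric matrices with samples as rows and taxa
#' as columns, both uniquely named. Raw count tables must be non-negative
#' integers; relative-abundance tables are non-negative reals.
#'
#' @param counts Matrix to validate.
#' @param integer_counts Require integer entries (raw counts).
#' @return The matrix, invisibly.
#' @export
validate_counts <- function(counts, integer_counts = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("abundance table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("sample ids (rownames) must be present and unique")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("taxon ids (colnames) must be present and unique")
  if (anyNA(counts) || any(counts < 0))
    stop("abundance table has missing or negative entries")
  if (integer_counts && any(abs(counts - round(counts)) > 1e-8))
    stop("abundance table must contain integer counts")
  invisible(counts)
}

#' Drop samples below a minimum sequencing depth
#'
#' Removes every sample whose total read count is below `min_reads` (samples
#' at exactly `min_reads` are retained), then drops taxa whose total count
#' becomes zero. The removed sample ids are attached as attribute
#' `"removed_samples"` so attrition is always reportable.
#'
#' @param counts Integer count matrix, samples x taxa.
#' @param min_reads Minimum total reads per sample.
#' @return Filtered matrix with attribute `removed_samples`.
#' @examples
#' m <- rbind(a = c(x = 4999L, y = 0L), b = c(x = 5000L, y = 0L))
#' filter_min_depth(m, 5000)
#' @export
filter_min_depth <- function(counts, min_reads) {
  validate_counts(counts, integer_counts = TRUE)
  if (min_reads < 0) stop("min_reads must be non-negative")
  keep <- rowSums(counts) >= min_reads
  removed <- rownames(counts)[!keep]
  if (!any(keep))
    stop("all samples fall below min_reads = ", min_reads)
  out <- counts[keep, , drop = FALSE]
  out <- out[, colSums(out) > 0, drop = FALSE]
  attr(out, "removed_samples") <- removed
  out
}

#' Rarefy each sample to a fixed depth
#'
#' Classic rarefaction: each sample's reads are subsampled without
#' replacement to exactly `depth`. One draw per analysis, reproducible under
#' [set.seed()].
#'
#' @param counts Integer count matrix, samples x taxa.
#' @param depth Target reads per sample; every sample must have at least this
#'   many.
#' @return Integer matrix with all row sums equal to `depth`.
#' @export
rarefy_counts <- function(counts, depth) {
  validate_counts(counts, integer_counts = TRUE)
  if (depth < 1) stop("depth must be a positive integer")
  short <- rownames(counts)[rowSums(counts) < depth]
  if (length(short))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(short, collapse = ", "))
  out <- counts
  storage.mode(out) <- "integer"
  for (s in seq_len(nrow(counts))) {
    tot <- sum(counts[s, ])
    if (tot == depth) next
    reads <- rep.int(seq_len(ncol(counts)), counts[s, ])
    pick <- sample(reads, depth, replace = FALSE)
    out[s, ] <- tabulate(pick, nbins = ncol(counts))
  }
  out
}

#' Convert counts to relative abundances
#'
#' @param counts Non-negative matrix with no all-zero rows.
#' @return Matrix whose rows each sum to one.
#' @export
relative_abundance <- function(counts) {
  validate_counts(counts)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("all-zero samples: ", paste(rownames(counts)[rs == 0], collapse = ", "))
  counts / rs
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed with
#' [vegan::vegdist()]. Values lie in `[0, 1]` for non-negative data.
#'
#' @param counts Abundance matrix, samples x taxa (counts or relative
#'   abundances).
#' @return Symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  validate_counts(counts)
  if (nrow(counts) < 2) stop("need at least two samples")
  if (any(rowSums(counts) == 0))
    stop("Bray-Curtis undefined for all-zero samples")
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Read and write abundance tables as TSV
#'
#' The on-disk orientation follows the QIIME classic convention (taxa as
#' rows, samples as columns) by default; `orientation = "samples_rows"` reads
#' or writes the transpose. In memory, tables are always samples x taxa.
#'
#' @param path File path.
#' @param counts Samples x taxa matrix.
#' @param orientation `"taxa_rows"` (classic) or `"samples_rows"`.
#' @return `read_abundance_table` returns a samples x taxa matrix.
#' @export
read_abundance_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  x <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE, comment.char = ""))
  if (orientation == "taxa_rows") x <- t(x)
  validate_counts(x)
  x
}

#' @rdname read_abundance_table
#' @export
write_abundance_table <- function(counts, path,
                                  orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  validate_counts(counts)
  x <- if (orientation == "taxa_rows") t(counts) else counts
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  names(df)[1] <- if (orientation == "taxa_rows") "taxon" else "sample"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' One row per sample; must contain a `sample` column. Grouping factors
#' (`time`, `slope`, `depth`, `location`) are kept as character; remaining
#' columns are environmental covariates.
#'
#' @param path CSV file path.
#' @return A data.frame with rownames set to sample ids.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample" %in% names(md)) stop("metadata must contain a `sample` column")
  if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
  rownames(md) <- md$sample
  md
}

#' Check that tree, table and metadata agree
#'
#' Errors on taxa present in the table but missing from the tree (use
#' [prune_to_shared()] first if pruning is intended) and on samples without a
#' metadata row; warns on tree tips or metadata rows that are unused.
#'
#' @param tree `phylo` object or NULL.
#' @param counts Samples x taxa matrix.
#' @param metadata Data.frame with a `sample` column, or NULL.
#' @return A list with `errors` and `warnings` character vectors; errors are
#'   raised unless `raise = FALSE`.
#' @param raise Raise an error when validation fails.
#' @export
validate_inputs <- function(counts, tree = NULL, metadata = NULL, raise = TRUE) {
  errs <- character()
  warns <- character()
  validate_counts(counts)
  if (!is.null(tree)) {
    missing_tips <- setdiff(colnames(counts), tree$tip.label)
    if (length(missing_tips))
      errs <- c(errs, paste0(length(missing_tips),
                             " taxa in table absent from tree (e.g. ",
                             paste(head(missing_tips, 3), collapse = ", "), ")"))
    unused <- setdiff(tree$tip.label, colnames(counts))
    if (length(unused))
      warns <- c(warns, paste0(length(unused), " tree tips unused by table"))
  }
  if (!is.null(metadata)) {
    missing_md <- setdiff(rownames(counts), metadata$sample)
    if (length(missing_md))
      errs <- c(errs, paste0("samples without metadata: ",
                             paste(head(missing_md, 3), collapse = ", ")))
    unused_md <- setdiff(metadata$sample, rownames(counts))
    if (length(unused_md))
      warns <- c(warns, paste0(length(unused_md), " metadata rows unused"))
  }
  if (raise && length(errs))
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "))
  list(errors = errs, warnings = warns)
}
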