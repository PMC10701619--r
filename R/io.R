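#' Construct a cohort expression matrix
#'
#' Wraps a genes x samples numeric matrix together with a cohort identifier
#' and the measurement scale. `scale = "log"` means values are already
#' log-transformed (the usual case for normalized microarray series and
#' log-scale RNA-seq summaries); `scale = "linear"` means non-negative
#' intensities/counts that will be log2-ratioed during fold computation.
#'
#' @param values Numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @param cohort_id Cohort label carried through all downstream results.
#' @param scale Either `"log"` or `"linear"`.
#' @return An object of class `expression_matrix` (a numeric matrix with
#'   attributes `cohort_id` and `scale`).
#' @export
expression_matrix <- function(values, cohort_id, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value at (gene '", rownames(values)[idx[[1L]]],
         "', sample '", colnames(values)[idx[[2L]]], "')")
  }
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be non-negative")
  structure(values, cohort_id = as.character(cohort_id)[1L], scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix '", attr(x, "cohort_id"), "': ",
      nrow(x), " genes x ", ncol(x), " samples (", attr(x, "scale"),
      " scale)\n", sep = "")
  invisible(x)
}

#' Read a genes x samples expression TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers
#' and whose first column holds gene identifiers. Every cell must be
#' numeric; blank or non-numeric cells, and duplicate gene or sample
#' identifiers, are errors (no silent collapsing or imputation: the
#' downstream per-sample profile statistics are undefined with holes).
#'
#' @inheritParams expression_matrix
#' @param path Path to the TSV file.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, cohort_id, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or missing cell at (gene '", genes[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "')")
  }
  dimnames(num) <- list(genes, samples)
  expression_matrix(num, cohort_id = cohort_id, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param expr An [expression_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' Expects a TSV with columns `sample_id`, `time` (non-negative, study time
#' units) and `event` (1 = event observed, 0 = right-censored).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `sample_id` (character), `time`
#'   (numeric) and `event` (integer in \{0, 1\}).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival TSV must have columns: ", paste(need, collapse = ", "))
  survival_records(data.frame(sample_id = as.character(df$sample_id),
                              time = as.numeric(df$time),
                              event = df$event,
                              stringsAsFactors = FALSE))
}

#' Validate a survival record table
#'
#' @param df A data frame with columns `sample_id`, `time`, `event`.
#' @return The validated data frame (event coerced to integer).
#' @export
survival_records <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("sample_id", "time", "event") %in% colnames(df)))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in survival records: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df$time) || any(df$time < 0)) {
    bad <- df$sample_id[is.na(df$time) | df$time < 0]
    stop("negative or missing survival time for: ",
         paste(bad, collapse = ", "))
  }
  if (!all(df$event %in% c(0, 1))) {
    bad <- df$sample_id[!(df$event %in% c(0, 1))]
    stop("event must be 0 or 1; offending sample(s): ",
         paste(bad, collapse = ", "))
  }
  df$event <- as.integer(df$event)
  df
}

#' Write a survival table as TSV
#'
#' @param records Survival data frame (see [read_survival]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survival <- function(records, path) {
  records <- survival_records(records)
  utils::write.table(records[, c("sample_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a data.frame (or lines) atomically: temp file in the same directory,
# then rename, so a failing stage never leaves a partial result file.
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
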