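#' Per-gene log2 fold expression relative to the cohort median
#'
#' For every gene, the fold value of a sample is its log2 expression minus
#' the gene's median log2 expression across all samples of the cohort. Log-
#' scale input is centred directly; linear-scale input is log2-ratioed
#' against the per-gene median (which must then be strictly positive).
#' Even sample counts use the standard midpoint-of-order-statistics median.
#'
#' @param expr An [expression_matrix] with >= 2 samples.
#' @return A `fold_matrix`: numeric matrix of the same shape and dimnames,
#'   with the `cohort_id` attribute carried over.
#' @export
fold_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr) < 2L) stop("fold computation needs >= 2 samples")
  vals <- unclass(expr)
  med <- apply(vals, 1L, stats::median)
  if (attr(expr, "scale") == "linear") {
    if (any(vals <= 0)) {
      g <- rownames(vals)[which(rowSums(vals <= 0) > 0)[1L]]
      stop("linear-scale values must be strictly positive for fold ",
           "computation; offending gene: '", g, "'")
    }
    if (any(med == 0))
      stop("gene(s) with zero median expression: ",
           paste(rownames(vals)[med == 0], collapse = ", "))
    f <- log2(vals / med)
  } else {
    f <- vals - med
  }
  structure(f, cohort_id = attr(expr, "cohort_id"),
            class = c("fold_matrix", "matrix", "array"))
}

#' @export
print.fold_matrix <- function(x, ...) {
  cat("fold_matrix '", attr(x, "cohort_id"), "': ", nrow(x), " genes x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

# Per-sample profile statistics shared by all sets scored on one cohort.
profile_stats <- function(folds) {
  mu <- colMeans(folds)
  sdv <- apply(folds, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero fold-profile standard deviation in sample(s): ",
         paste(colnames(folds)[sdv == 0], collapse = ", "))
  list(mean = mu, sd = sdv)
}

score_one_set <- function(folds, members, prof) {
  matched <- intersect(members, rownames(folds))
  m <- length(matched)
  if (m == 0L) return(list(score = NULL, matched = 0L))
  set_mean <- colMeans(folds[matched, , drop = FALSE])
  list(score = sqrt(m) * (set_mean - prof$mean) / prof$sd, matched = m)
}

#' Per-sample gene-set activation z-score
#'
#' The activity score of a gene set in a sample is the difference between
#' the set's mean fold expression and the sample's whole-profile mean fold
#' expression, divided by the whole-profile fold standard deviation (n-1
#' denominator), multiplied by the square root of the number of set genes
#' matched in the matrix. The sqrt(n) factor uses the matched count, not
#' the nominal set size.
#'
#' @param folds A [fold_matrix].
#' @param set A [gene_set].
#' @param min_genes Minimum matched genes required (default 2).
#' @return Named numeric vector of scores, one per sample.
#' @export
activation_score <- function(folds, set, min_genes = 2L) {
  stopifnot(inherits(folds, "fold_matrix"), inherits(set, "gene_set"))
  prof <- profile_stats(folds)
  res <- score_one_set(folds, set$members, prof)
  if (res$matched < min_genes)
    stop("gene set '", set$name, "': ", res$matched,
         " member(s) matched; need >= ", min_genes)
  res$score
}

#' Activation z-scores for a whole gene-set collection
#'
#' Scores every set of the collection against one cohort's fold matrix.
#' Sets matching fewer than `min_genes` genes are skipped with a warning
#' (never silently); if every set is skipped, that is an error. Row order
#' follows the collection.
#'
#' @inheritParams activation_score
#' @param collection A [gene_set_collection].
#' @return An `activity_table`: sets x samples numeric matrix with a
#'   `matched_genes` attribute (named integer vector) and the cohort id.
#' @export
activity_table <- function(folds, collection, min_genes = 2L) {
  stopifnot(inherits(folds, "fold_matrix"),
            inherits(collection, "gene_set_collection"))
  if (!length(collection)) stop("empty gene-set collection")
  prof <- profile_stats(folds)
  scores <- vector("list", length(collection))
  matched <- integer(length(collection))
  for (i in seq_along(collection)) {
    res <- score_one_set(folds, collection[[i]]$members, prof)
    matched[i] <- res$matched
    if (res$matched >= min_genes) scores[[i]] <- res$score
  }
  keep <- !vapply(scores, is.null, logical(1L))
  if (any(!keep))
    warning("skipped ", sum(!keep), " gene set(s) with < ", min_genes,
            " matched genes: ",
            paste(names(collection)[!keep], collapse = ", "))
  if (!any(keep)) stop("no gene set matched >= ", min_genes, " genes")
  tab <- do.call(rbind, scores[keep])
  rownames(tab) <- names(collection)[keep]
  structure(tab,
            matched_genes = stats::setNames(matched[keep],
                                            names(collection)[keep]),
            cohort_id = attr(folds, "cohort_id"),
            class = c("activity_table", "matrix", "array"))
}

#' @export
print.activity_table <- function(x, ...) {
  cat("activity_table '", attr(x, "cohort_id"), "': ", nrow(x),
      " gene sets x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Composite up-minus-down signature score
#'
#' Per-sample difference between the activation scores of an up-regulated
#' and a down-regulated gene set — the signature score used to stratify
#' patients (e.g. a treatment's induced minus repressed genes).
#'
#' @inheritParams activation_score
#' @param up,down [gene_set] objects for the up- and down-regulated arms.
#' @return Named numeric vector: `activation_score(up) -
#'   activation_score(down)` per sample.
#' @export
signature_score <- function(folds, up, down, min_genes = 2L) {
  activation_score(folds, up, min_genes) -
    activation_score(folds, down, min_genes)
}

#' Write an activity table as TSV with a JSON sidecar
#'
#' The TSV holds sets x samples scores; the sidecar records the matched
#' gene count per set and the scoring parameters.
#'
#' @param tab An `activity_table`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param params Optional named list of parameters to record.
#' @return Invisibly, `path`.
#' @export
write_activity_table <- function(tab, path, params = list()) {
  stopifnot(inherits(tab, "activity_table"))
  df <- data.frame(set_name = rownames(tab), tab, check.names = FALSE)
  write_tsv_atomic(df, path)
  write_json_atomic(list(cohort_id = attr(tab, "cohort_id"),
                         matched_genes = as.list(attr(tab, "matched_genes")),
                         parameters = params),
                    paste0(path, ".json"))
  invisible(path)
}
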