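#' Pearson correlation of two per-sample score vectors within a cohort
#'
#' @param x,y Numeric vectors of equal length >= 4 with nonzero variance.
#' @param cohort_id Cohort label.
#' @param set_name Name of the gene set whose activity `y` holds.
#' @return One-row `data.frame` with columns `cohort_id`, `set_name`, `r`
#'   and `n`.
#' @export
cohort_correlation <- function(x, y, cohort_id, set_name) {
  if (length(x) != length(y))
    stop("score vectors differ in length (", length(x), " vs ", length(y),
         ")")
  n <- length(x)
  if (n < 4L) stop("need >= 4 samples for a cohort correlation; got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a score vector (cohort '", cohort_id, "', set '",
         set_name, "')")
  data.frame(cohort_id = as.character(cohort_id),
             set_name = as.character(set_name),
             r = stats::cor(x, y), n = n, stringsAsFactors = FALSE)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, the variance-stabilizing transform under which
#' per-cohort correlations are pooled; the inverse is `tanh`. Out-of-range
#' input is an error, never clamped.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' DerSimonian-Laird random-effects pooling of correlations
#'
#' Pools per-cohort Pearson correlations on the Fisher-z scale with
#' DerSimonian-Laird random-effects weights. With `z_i = atanh(r_i)` and
#' `v_i = 1 / (n_i - 3)`: fixed weights `w_i = 1 / v_i` give the fixed
#' pooled `z_F` and Cochran's `Q = sum(w_i (z_i - z_F)^2)`;
#' `tau^2 = max(0, (Q - (k - 1)) / C)` with `C = sum(w) - sum(w^2)/sum(w)`
#' (and `tau^2 = 0` for a single cohort); random weights
#' `w*_i = 1 / (v_i + tau^2)` give the pooled estimate, its standard error
#' `1 / sqrt(sum(w*))`, a two-sided normal p-value, and
#' `meta_r = tanh(pooled_z)`.
#'
#' @param correlations `data.frame` with columns `r`, `n` and `cohort_id`
#'   (one row per cohort, all for the same set; see [cohort_correlation]).
#' @param set_name Optional set name recorded in the result; defaults to
#'   the (single) `set_name` of the input if present.
#' @return A list of class `meta_result`: `set_name`, `k`, `meta_r`,
#'   `pooled_z`, `se`, `p_value`, `tau2`, `Q`.
#' @export
meta_dsl <- function(correlations, set_name = NULL) {
  stopifnot(is.data.frame(correlations),
            all(c("r", "n") %in% colnames(correlations)))
  k <- nrow(correlations)
  if (k == 0L) stop("no cohort correlations to pool")
  if ("set_name" %in% colnames(correlations)) {
    sn <- unique(correlations$set_name)
    if (length(sn) > 1L)
      stop("meta_dsl pools one set at a time; got: ",
           paste(sn, collapse = ", "))
    if (is.null(set_name)) set_name <- sn
  }
  if ("cohort_id" %in% colnames(correlations) &&
      anyDuplicated(correlations$cohort_id))
    stop("duplicate cohort_id in meta-analysis input")
  if (any(correlations$n < 4L))
    stop("every cohort needs n >= 4 (Fisher-z variance 1/(n-3))")
  z <- fisher_z(correlations$r)
  v <- 1 / (correlations$n - 3)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  Q <- sum(w * (z - z_fixed)^2)
  if (k == 1L) {
    tau2 <- 0
  } else {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  w_star <- 1 / (v + tau2)
  pooled_z <- sum(w_star * z) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  p <- 2 * stats::pnorm(-abs(pooled_z / se))
  structure(list(set_name = set_name %||% NA_character_, k = k,
                 meta_r = tanh(pooled_z), pooled_z = pooled_z, se = se,
                 p_value = p, tau2 = tau2, Q = Q),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result%s: k = %d, meta_r = %.4f, p = %.3g, tau2 = %.4g\n",
              if (is.na(x$set_name)) "" else paste0(" '", x$set_name, "'"),
              x$k, x$meta_r, x$p_value, x$tau2))
  invisible(x)
}

#' Classify a pooled association against the screen thresholds
#'
#' A set is `"positive"` if `meta_r > r_threshold` with
#' `p < p_threshold`, `"negative"` if `meta_r < -r_threshold` with
#' `p < p_threshold`, otherwise `"not_significant"`. Inequalities are
#' strict at both thresholds.
#'
#' @param meta_r Pooled correlation (or a `meta_result`).
#' @param p_value Pooled p-value (ignored if `meta_r` is a `meta_result`).
#' @param r_threshold Effect-size threshold (default 0.3).
#' @param p_threshold Significance threshold (default 0.05).
#' @return `"positive"`, `"negative"` or `"not_significant"`.
#' @export
classify_association <- function(meta_r, p_value = NULL, r_threshold = 0.3,
                                 p_threshold = 0.05) {
  if (inherits(meta_r, "meta_result")) {
    p_value <- meta_r$p_value
    meta_r <- meta_r$meta_r
  }
  if (is.null(p_value)) stop("p_value required")
  if (p_value < p_threshold && meta_r > r_threshold) return("positive")
  if (p_value < p_threshold && meta_r < -r_threshold) return("negative")
  "not_significant"
}

#' Cross-cohort meta-correlation screen of gene-set activity against EMT
#'
#' For every gene set scored in at least one cohort, correlates its
#' activation scores with the EMT set's activation scores within each
#' cohort (Pearson), pools the per-cohort correlations by
#' DerSimonian-Laird random effects ([meta_dsl]) over the cohorts where the
#' set was scored, and classifies the pooled association
#' ([classify_association]). Benjamini-Hochberg q-values across the
#' screened sets are added informationally; the screen's filter is the
#' `meta_r` effect-size gate, not a multiplicity-adjusted p.
#'
#' @param tables Named list of `activity_table`s, one per cohort, each
#'   containing the EMT set's row.
#' @param emt_set_name Row name of the EMT signature in every table.
#' @param r_threshold,p_threshold Classification thresholds.
#' @return `data.frame` sorted by decreasing `meta_r` with columns
#'   `set_name`, `k`, `meta_r`, `pooled_z`, `se`, `p_value`, `tau2`, `Q`,
#'   `q_value`, `classification`.
#' @export
meta_screen <- function(tables, emt_set_name, r_threshold = 0.3,
                        p_threshold = 0.05) {
  if (!length(tables)) stop("no cohort activity tables supplied")
  stopifnot(all(vapply(tables, inherits, logical(1L), "activity_table")))
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, attr, character(1L), "cohort_id")
  for (cid in names(tables)) {
    if (!(emt_set_name %in% rownames(tables[[cid]])))
      stop("EMT set '", emt_set_name, "' missing from cohort '", cid, "'")
  }
  all_sets <- unique(unlist(lapply(tables, rownames)))
  all_sets <- setdiff(all_sets, emt_set_name)
  if (!length(all_sets)) stop("no metabolic sets to screen")

  rows <- vector("list", length(all_sets))
  for (i in seq_along(all_sets)) {
    sn <- all_sets[[i]]
    cors <- list()
    for (cid in names(tables)) {
      tab <- tables[[cid]]
      if (!(sn %in% rownames(tab))) next
      cors[[length(cors) + 1L]] <-
        cohort_correlation(tab[emt_set_name, ], tab[sn, ], cid, sn)
    }
    m <- meta_dsl(do.call(rbind, cors))
    rows[[i]] <- data.frame(set_name = sn, k = m$k, meta_r = m$meta_r,
                            pooled_z = m$pooled_z, se = m$se,
                            p_value = m$p_value, tau2 = m$tau2, Q = m$Q,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$classification <- vapply(seq_len(nrow(out)), function(i) {
    classify_association(out$meta_r[i], out$p_value[i], r_threshold,
                         p_threshold)
  }, character(1L))
  out <- out[order(-out$meta_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signed edge list of classified screen hits
#'
#' One edge per set classified positive or negative, from the EMT node to
#' the set, weighted by `meta_r` — the format network viewers ingest.
#'
#' @param screen_result Output of [meta_screen].
#' @param emt_set_name Source node label.
#' @return `data.frame` with columns `source`, `target`, `weight`,
#'   `classification`.
#' @export
screen_edge_list <- function(screen_result, emt_set_name = "EMT") {
  hits <- screen_result[screen_result$classification != "not_significant", ,
                        drop = FALSE]
  data.frame(source = rep(emt_set_name, nrow(hits)),
             target = hits$set_name, weight = hits$meta_r,
             classification = hits$classification,
             stringsAsFactors = FALSE)
}
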