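#' Read a run configuration
#'
#' Accepts a YAML or JSON file (by extension) or an already-built list.
#' A configuration names either real inputs (`cohorts`: list of
#' `{cohort_id, expression, scale}` entries, plus `gmt` and optionally
#' `survival` paths) or a `simulate` block (currently `design: planted`
#' with optional overrides passed to [planted_screen_design]) — exactly one
#' of the two. Common fields: `emt_set`, `r_threshold`, `p_threshold`,
#' `min_genes`, `seed`, `out_dir`, and for survival runs `up_set` /
#' `down_set`.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_real <- !is.null(config$cohorts)
  has_sim <- !is.null(config$simulate)
  if (has_real == has_sim)
    stop("config must provide exactly one of 'cohorts' (real inputs) or ",
         "'simulate'")
  config$r_threshold <- config$r_threshold %||% 0.3
  config$p_threshold <- config$p_threshold %||% 0.05
  config$min_genes <- as.integer(config$min_genes %||% 2L)
  config$seed <- as.integer(config$seed %||% 1L)
  if (config$r_threshold <= 0 || config$p_threshold <= 0)
    stop("thresholds must be positive")
  config
}

# Resolve config into cohorts: list of (expression, survival or NULL) plus
# the gene-set catalogue.
load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!identical(sim$design %||% "planted", "planted"))
      stop("unknown simulation design: ", sim$design)
    args <- sim[setdiff(names(sim), "design")]
    args$seed <- config$seed
    design <- do.call(planted_screen_design, args)
    cohorts <- generate_multi_cohort(design$specs)
    list(cohorts = cohorts, catalogue = design$catalogue,
         emt_set = config$emt_set %||% design$emt_set_name,
         design = design)
  } else {
    catalogue <- read_gmt(config$gmt %||% stop("config needs 'gmt'"))
    emt_set <- config$emt_set %||% stop("config needs 'emt_set'")
    cohorts <- lapply(config$cohorts, function(co) {
      expr <- read_expression(co$expression, cohort_id = co$cohort_id,
                              scale = co$scale %||% "log")
      surv <- if (!is.null(co$survival)) read_survival(co$survival)
      list(expression = expr, survival = surv, truth = NULL)
    })
    names(cohorts) <- vapply(config$cohorts, `[[`, character(1L),
                             "cohort_id")
    list(cohorts = cohorts, catalogue = catalogue, emt_set = emt_set,
         design = NULL)
  }
}

stage <- function(name, cohort_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(cohort_id)) name else
      paste0(name, " [cohort ", cohort_id, "]")
    stop("stage '", where, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

run_manifest <- function(config, out_dir, stage_name) {
  list(stage = stage_name,
       package_version = as.character(utils::packageVersion("emtscreen")),
       r_version = as.character(getRversion()),
       seed = config$seed,
       parameters = list(emt_set = config$emt_set,
                         r_threshold = config$r_threshold,
                         p_threshold = config$p_threshold,
                         min_genes = config$min_genes),
       inputs = if (!is.null(config$cohorts))
         lapply(config$cohorts, function(co)
           list(cohort_id = co$cohort_id,
                expression = co$expression,
                md5 = unname(tools::md5sum(co$expression))))
       else list(simulate = config$simulate %||% list(design = "planted")))
}

#' Write simulated cohorts to disk
#'
#' Materializes a simulated multi-cohort design as expression TSVs,
#' survival TSVs (when simulated) and the gene-set catalogue as GMT, so a
#' simulated run can be re-fed through the real-input path.
#'
#' @param config Run configuration (list or path; must contain `simulate`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
run_simulate <- function(config, out_dir = config$out_dir) {
  config <- read_run_config(config)
  if (is.null(config$simulate)) stop("run_simulate needs a 'simulate' block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- stage("simulate", NULL, load_inputs(config))
  files <- character(0)
  for (cid in names(inputs$cohorts)) {
    co <- inputs$cohorts[[cid]]
    f <- file.path(out_dir, paste0(cid, "_expression.tsv"))
    write_expression(co$expression, f)
    files <- c(files, f)
    if (!is.null(co$survival)) {
      f <- file.path(out_dir, paste0(cid, "_survival.tsv"))
      write_survival(co$survival, f)
      files <- c(files, f)
    }
  }
  f <- file.path(out_dir, "catalogue.gmt")
  write_gmt(inputs$catalogue, f)
  files <- c(files, f)
  write_json_atomic(run_manifest(config, out_dir, "simulate"),
                    file.path(out_dir, "manifest.json"))
  invisible(c(files, file.path(out_dir, "manifest.json")))
}

#' Score every cohort's gene-set activity
#'
#' Fold matrix then activation z-scores per cohort, written as TSVs with
#' JSON sidecars.
#'
#' @param config Run configuration (list or path).
#' @param out_dir Output directory.
#' @return Invisibly, the named list of `activity_table`s.
#' @export
run_score <- function(config, out_dir = config$out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- stage("load", NULL, load_inputs(config))
  tables <- lapply(names(inputs$cohorts), function(cid) {
    stage("score", cid, {
      folds <- fold_matrix(inputs$cohorts[[cid]]$expression)
      tab <- activity_table(folds, inputs$catalogue,
                            min_genes = config$min_genes)
      write_activity_table(tab, file.path(out_dir,
                                          paste0(cid, "_activity.tsv")),
                           params = list(min_genes = config$min_genes))
      tab
    })
  })
  names(tables) <- names(inputs$cohorts)
  write_json_atomic(run_manifest(config, out_dir, "score"),
                    file.path(out_dir, "manifest.json"))
  invisible(tables)
}

#' Run the cross-cohort EMT meta-correlation screen
#'
#' Per cohort: fold matrix and gene-set activation scores; then
#' per-cohort Pearson correlations of each set's activity with the EMT
#' set's activity, pooled by DerSimonian-Laird random effects and
#' classified against the `meta_r` / p thresholds. Results, the edge list
#' of classified hits, and a machine-readable run manifest are written
#' atomically.
#'
#' @param config Run configuration (list or path); the EMT set must be
#'   present in the catalogue.
#' @param out_dir Output directory.
#' @return Invisibly, the screen result `data.frame` (see [meta_screen]).
#' @export
run_screen <- function(config, out_dir = config$out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- stage("load", NULL, load_inputs(config))
  if (!(inputs$emt_set %in% names(inputs$catalogue)))
    stop("EMT set '", inputs$emt_set, "' not in the gene-set catalogue")
  tables <- list()
  for (cid in names(inputs$cohorts)) {
    tables[[cid]] <- stage("score", cid, {
      folds <- fold_matrix(inputs$cohorts[[cid]]$expression)
      activity_table(folds, inputs$catalogue, min_genes = config$min_genes)
    })
  }
  res <- stage("meta_correlation", NULL,
               meta_screen(tables, inputs$emt_set,
                           r_threshold = config$r_threshold,
                           p_threshold = config$p_threshold))
  write_tsv_atomic(res, file.path(out_dir, "screen_results.tsv"))
  write_tsv_atomic(screen_edge_list(res, inputs$emt_set),
                   file.path(out_dir, "screen_edges.tsv"))
  write_json_atomic(run_manifest(config, out_dir, "screen"),
                    file.path(out_dir, "manifest.json"))
  invisible(res)
}

#' Run a median-split survival stratification
#'
#' Computes the composite signature score (`up_set` minus `down_set`
#' activation; or the single `emt_set`/`score_set` activation when no pair
#' is given) per sample of one cohort, splits at the median, and writes
#' the stratification, Kaplan-Meier curves and the log-rank/Cox comparison.
#'
#' @param config Run configuration (list or path). Uses `cohort_id` to
#'   pick the cohort (default: first), and `up_set`/`down_set` or
#'   `score_set` to define the score. Survival records must cover every
#'   scored sample.
#' @param out_dir Output directory.
#' @return Invisibly, the [compare_survival] result.
#' @export
run_survival <- function(config, out_dir = config$out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- stage("load", NULL, load_inputs(config))
  cid <- config$cohort_id %||% names(inputs$cohorts)[[1L]]
  if (!(cid %in% names(inputs$cohorts)))
    stop("cohort '", cid, "' not among inputs")
  co <- inputs$cohorts[[cid]]
  if (is.null(co$survival))
    stop("no survival records for cohort '", cid, "'")
  scores <- stage("signature_score", cid, {
    folds <- fold_matrix(co$expression)
    if (!is.null(config$up_set) && !is.null(config$down_set)) {
      signature_score(folds, inputs$catalogue[[config$up_set]],
                      inputs$catalogue[[config$down_set]],
                      min_genes = config$min_genes)
    } else {
      sn <- config$score_set %||% inputs$emt_set
      activation_score(folds, inputs$catalogue[[sn]],
                       min_genes = config$min_genes)
    }
  })
  missing <- setdiff(names(scores), co$survival$sample_id)
  if (length(missing))
    stop("stage 'survival [cohort ", cid, "]' failed: no survival record ",
         "for sample(s): ", paste(missing, collapse = ", "))
  cmp <- stage("survival", cid, compare_survival(co$survival, scores))
  strat <- cmp$stratification
  write_tsv_atomic(strat, file.path(out_dir, "stratification.tsv"))
  write_tsv_atomic(cmp$km_curves, file.path(out_dir, "km_curves.tsv"))
  write_json_atomic(list(logrank_statistic = cmp$logrank_statistic,
                         logrank_p = cmp$logrank_p,
                         hazard_ratio = cmp$hazard_ratio,
                         hr_ci_low = cmp$hr_ci_low,
                         hr_ci_high = cmp$hr_ci_high,
                         split_value = attr(strat, "split_value"),
                         n_low = sum(strat$group == "low"),
                         n_high = sum(strat$group == "high")),
                    file.path(out_dir, "survival_comparison.json"))
  write_json_atomic(run_manifest(config, out_dir, "survival"),
                    file.path(out_dir, "manifest.json"))
  invisible(cmp)
}
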