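#' Specify a latent gene module for simulation
#'
#' Each module carries one latent activity per sample, correlated with the
#' cohort's latent EMT axis at `target_rho`. Genes in the module load on the
#' latent with magnitude `loading`; a `sign_split` fraction load positively
#' and the rest negatively (for bidirectional signatures such as a
#' mesenchymal/epithelial pair). `target_rho = 1` pins the module latent to
#' the EMT axis itself, which is how the EMT signature module is declared.
#'
#' @param name Module name; also the prefix of its simulated gene ids.
#' @param n_genes Number of genes (>= 2).
#' @param target_rho Planted correlation with the EMT latent, in `[-1, 1]`.
#' @param loading Per-gene loading magnitude (> 0).
#' @param sign_split Fraction of genes with positive loading, in `(0, 1]`.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(name, n_genes, target_rho, loading = 1,
                        sign_split = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_genes <- as.integer(n_genes)
  if (n_genes < 2L) stop("module '", name, "': n_genes must be >= 2")
  if (!is.finite(target_rho) || abs(target_rho) > 1)
    stop("module '", name, "': target_rho must lie in [-1, 1]")
  if (!is.finite(loading) || loading <= 0)
    stop("module '", name, "': loading must be positive")
  if (sign_split <= 0 || sign_split > 1)
    stop("module '", name, "': sign_split must be in (0, 1]")
  structure(list(name = name, n_genes = n_genes, target_rho = target_rho,
                 loading = loading, sign_split = sign_split),
            class = "module_spec")
}

#' Specify a simulated cohort
#'
#' Defines one cohort of the latent-factor generative model: per-sample EMT
#' latent `e ~ N(0,1)`; per-module latent
#' `a = rho * e + sqrt(1 - rho^2) * eta`, `eta ~ N(0,1)`; gene values
#' `x = lambda * a + noise_sd * eps` with `lambda = +/- loading`;
#' background genes are pure `N(0, noise_sd^2)` noise. The matrix is emitted
#' on log scale. Optionally, exponential survival times are generated whose
#' log-hazard depends on the standardized EMT latent (see `survival`),
#' censored by an independent Uniform(0, `censor_time_max`) time.
#'
#' @param cohort_id Cohort label.
#' @param n_samples Number of samples (>= 4, so that the Fisher-z variance
#'   1/(n-3) of downstream correlations exists).
#' @param modules List of [module_spec] objects (unique names).
#' @param n_background_genes Number of pure-noise genes (>= 0).
#' @param noise_sd Gene-level noise standard deviation (> 0).
#' @param survival `NULL`, or a list with `baseline_rate` (> 0), `beta`
#'   (log-hazard per SD of the EMT latent, or per group under
#'   `link = "median"`), `censor_time_max` (> 0) and optionally `link`
#'   (`"linear"`, the default: hazard multiplier `exp(beta * z)` with `z`
#'   the standardized EMT latent; or `"median"`: `exp(beta)` applied to
#'   samples with `z` above its median, so the planted group hazard ratio
#'   is exactly `exp(beta)`).
#' @param seed Integer RNG seed; identical seed + spec gives bit-identical
#'   output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, n_samples, modules,
                        n_background_genes = 0, noise_sd = 0.5,
                        survival = NULL, seed = 1L) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L,
            nzchar(cohort_id))
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) stop("cohort '", cohort_id, "': n_samples must be >= 4")
  if (!is.list(modules) || !length(modules) ||
      !all(vapply(modules, inherits, logical(1L), "module_spec")))
    stop("'modules' must be a non-empty list of module_spec objects")
  nms <- vapply(modules, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate module name(s): ", paste(nms[duplicated(nms)],
                                             collapse = ", "))
  names(modules) <- nms
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive")
  n_background_genes <- as.integer(n_background_genes)
  if (n_background_genes < 0L) stop("n_background_genes must be >= 0")
  if (!is.null(survival)) {
    stopifnot(is.list(survival),
              all(c("baseline_rate", "beta", "censor_time_max") %in%
                    names(survival)))
    if (survival$baseline_rate <= 0) stop("baseline_rate must be positive")
    if (survival$censor_time_max <= 0) stop("censor_time_max must be positive")
    survival$link <- match.arg(survival$link %||% "linear",
                               c("linear", "median"))
  }
  structure(list(cohort_id = cohort_id, n_samples = n_samples,
                 modules = modules, n_background_genes = n_background_genes,
                 noise_sd = noise_sd, survival = survival,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic cohort
#'
#' Draws the latent-factor model defined by a [cohort_spec] and returns the
#' expression matrix (log scale), the survival table (if requested) and the
#' ground truth used by recovery tests.
#'
#' @param spec A [cohort_spec].
#' @return A list with elements:
#'   \describe{
#'     \item{expression}{[expression_matrix], genes x samples, log scale.}
#'     \item{survival}{survival `data.frame` or `NULL`.}
#'     \item{truth}{list with `emt_latent` (per-sample), `module_latent`
#'       (modules x samples matrix), `loadings` (named per-gene loadings),
#'       `hazard_multiplier` and, under `link = "median"`, `survival_group`
#'       (`"low"`/`"high"` by the true EMT latent).}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  sample_ids <- sprintf("%s_S%03d", spec$cohort_id, seq_len(n))
  set.seed(spec$seed)

  e <- stats::rnorm(n)
  mods <- spec$modules
  a <- matrix(0, nrow = length(mods), ncol = n,
              dimnames = list(names(mods), sample_ids))
  blocks <- vector("list", length(mods) + 1L)
  loadings <- numeric(0)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    rho <- m$target_rho
    a[i, ] <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n)
    n_pos <- max(1L, round(m$sign_split * m$n_genes))
    lam <- c(rep(m$loading, n_pos), rep(-m$loading, m$n_genes - n_pos))
    names(lam) <- sprintf("%s_g%03d", m$name, seq_len(m$n_genes))
    x <- tcrossprod(lam, a[i, ]) +
      spec$noise_sd * matrix(stats::rnorm(m$n_genes * n), nrow = m$n_genes)
    rownames(x) <- names(lam)
    blocks[[i]] <- x
    loadings <- c(loadings, lam)
  }
  if (spec$n_background_genes > 0L) {
    bg <- spec$noise_sd *
      matrix(stats::rnorm(spec$n_background_genes * n),
             nrow = spec$n_background_genes)
    rownames(bg) <- sprintf("BG_g%04d", seq_len(spec$n_background_genes))
    blocks[[length(mods) + 1L]] <- bg
    loadings <- c(loadings, stats::setNames(rep(0, spec$n_background_genes),
                                            rownames(bg)))
  }
  vals <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1L))])
  colnames(vals) <- sample_ids
  expr <- expression_matrix(vals, cohort_id = spec$cohort_id, scale = "log")

  truth <- list(emt_latent = stats::setNames(e, sample_ids),
                module_latent = a, loadings = loadings,
                hazard_multiplier = NULL, survival_group = NULL)
  surv <- NULL
  if (!is.null(spec$survival)) {
    sv <- spec$survival
    z <- (e - mean(e)) / stats::sd(e)
    if (sv$link == "median") {
      grp <- ifelse(z > stats::median(z), "high", "low")
      eta <- sv$beta * (grp == "high")
      truth$survival_group <- stats::setNames(grp, sample_ids)
    } else {
      eta <- sv$beta * z
    }
    mult <- exp(eta)
    rate <- sv$baseline_rate * mult
    t_event <- stats::rexp(n, rate = rate)
    t_cens <- stats::runif(n, 0, sv$censor_time_max)
    surv <- data.frame(sample_id = sample_ids,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       stringsAsFactors = FALSE)
    truth$hazard_multiplier <- stats::setNames(mult, sample_ids)
  }
  list(expression = expr, survival = surv, truth = truth)
}

#' Generate several cohorts with independent RNG streams
#'
#' Each cohort's seed is taken from its spec unless `master_seed` is given,
#' in which case cohort `i` uses `master_seed + i` so a whole multi-cohort
#' run is reproducible from one integer.
#'
#' @param specs List of [cohort_spec] objects with unique `cohort_id`s.
#' @param master_seed Optional integer overriding per-cohort seeds.
#' @return Named list (by cohort id) of [generate_cohort] results.
#' @export
generate_multi_cohort <- function(specs, master_seed = NULL) {
  if (!length(specs)) return(list())
  stopifnot(all(vapply(specs, inherits, logical(1L), "cohort_spec")))
  ids <- vapply(specs, `[[`, character(1L), "cohort_id")
  if (anyDuplicated(ids))
    stop("duplicate cohort_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!is.null(master_seed)) sp$seed <- as.integer(master_seed) + i
    out[[i]] <- generate_cohort(sp)
  }
  names(out) <- ids
  out
}

#' Gene-set catalogue implied by a cohort's module structure
#'
#' Returns one gene set per module (all of that module's genes). With
#' `directional = TRUE`, modules with a mixed `sign_split` are additionally
#' split into `<name>_UP` (positive loadings) and `<name>_DN` (negative
#' loadings) sets, as needed for bidirectional signatures.
#'
#' @param spec A [cohort_spec].
#' @param directional Also emit sign-split subsets for mixed modules.
#' @return A [gene_set_collection].
#' @export
module_gene_sets <- function(spec, directional = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  sets <- list()
  for (m in spec$modules) {
    ids <- sprintf("%s_g%03d", m$name, seq_len(m$n_genes))
    sets[[length(sets) + 1L]] <- gene_set(m$name, ids, "simulated module")
    if (directional && m$sign_split < 1) {
      n_pos <- max(1L, round(m$sign_split * m$n_genes))
      sets[[length(sets) + 1L]] <-
        gene_set(paste0(m$name, "_UP"), ids[seq_len(n_pos)],
                 "positive-loading genes")
      sets[[length(sets) + 1L]] <-
        gene_set(paste0(m$name, "_DN"), ids[-seq_len(n_pos)],
                 "negative-loading genes")
    }
  }
  gene_set_collection(sets)
}

#' Six-cohort screen design with planted metabolic associations
#'
#' The default multi-cohort study design used throughout the package's
#' validation: six lung-cancer-sized cohorts (442, 293, 510, 85, 78 and 68
#' samples; 1,476 in total), an EMT signature module pinned to the EMT axis,
#' and a catalogue of 335 metabolic gene-set modules of which two are
#' planted negative (propionate- and butanoate-like, rho = -0.46), two
#' planted positive (chondroitin- and heparan-sulfate-like, rho = +0.45)
#' and the rest null (rho = 0).
#'
#' @param seed Master seed; cohort `i` draws from `seed + i`.
#' @param n_null Number of null metabolic modules (default 331, for a
#'   335-set catalogue).
#' @param genes_per_set Genes per metabolic module.
#' @param emt_genes Genes in the EMT signature module.
#' @param n_background_genes Pure-noise genes per cohort.
#' @param noise_sd Gene-level noise SD.
#' @param survival Optional survival spec applied to every cohort (see
#'   [cohort_spec]).
#' @return List with `specs` (list of [cohort_spec]), `emt_set_name`,
#'   `planted` (data frame of planted set names and rhos) and `catalogue`
#'   (the 335-set [gene_set_collection] plus the EMT set).
#' @export
planted_screen_design <- function(seed = 1L, n_null = 331L,
                                  genes_per_set = 10L, emt_genes = 25L,
                                  n_background_genes = 300L, noise_sd = 0.5,
                                  survival = NULL) {
  planted <- data.frame(
    set_name = c("PROPIONATE_METABOLISM", "BUTANOATE_METABOLISM",
                 "CHONDROITIN_SULFATE_BIOSYNTHESIS",
                 "HEPARAN_SULFATE_BIOSYNTHESIS"),
    target_rho = c(-0.46, -0.46, 0.45, 0.45),
    stringsAsFactors = FALSE)
  mods <- list(module_spec("EMT_SIGNATURE", emt_genes, target_rho = 1))
  for (i in seq_len(nrow(planted)))
    mods[[length(mods) + 1L]] <- module_spec(planted$set_name[i],
                                             genes_per_set,
                                             planted$target_rho[i])
  for (i in seq_len(n_null))
    mods[[length(mods) + 1L]] <- module_spec(sprintf("METABOLIC_SET_%03d", i),
                                             genes_per_set, target_rho = 0)
  sizes <- c(442L, 293L, 510L, 85L, 78L, 68L)
  specs <- lapply(seq_along(sizes), function(i) {
    cohort_spec(sprintf("COHORT%d", i), sizes[i], mods,
                n_background_genes = n_background_genes,
                noise_sd = noise_sd, survival = survival,
                seed = as.integer(seed) + i)
  })
  catalogue <- module_gene_sets(specs[[1L]])
  list(specs = specs, emt_set_name = "EMT_SIGNATURE", planted = planted,
       catalogue = catalogue)
}
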