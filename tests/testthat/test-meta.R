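test_that("cohort correlations reproduce exact and textbook cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohort_correlation(x, 2 * x + 3, "C", "S")$r, 1)
  expect_equal(cohort_correlation(x, -x, "C", "S")$r, -1)

  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  # covariance over product of SDs, written out
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cohort_correlation(a, b, "C", "S")$r, r_hand,
               tolerance = 1e-12)

  expect_error(cohort_correlation(1:3, 1:3, "C", "S"), ">= 4")
  expect_error(cohort_correlation(1:5, rep(1, 5), "C", "S"), "zero variance")
  expect_error(cohort_correlation(1:5, 1:4, "C", "S"), "length")
})

test_that("fisher_z is atanh with strict domain and exact inverse", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
  set.seed(5)
  r <- runif(100, -0.99, 0.99)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("homogeneous studies collapse to the common correlation", {
  d <- data.frame(cohort_id = c("A", "B", "C"), set_name = "S",
                  r = 0.4, n = 50)
  m <- meta_dsl(d)
  expect_equal(m$Q, 0, tolerance = 1e-12)
  expect_identical(m$tau2, 0)
  expect_equal(m$meta_r, 0.4, tolerance = 1e-12)
})

test_that("a single study passes through with se = 1/sqrt(n-3)", {
  m <- meta_dsl(data.frame(cohort_id = "A", set_name = "S",
                           r = -0.46, n = 442))
  expect_equal(m$meta_r, -0.46, tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(439), tolerance = 1e-12)
  expect_identical(m$tau2, 0)
  expect_identical(m$k, 1L)
})

test_that("two-study pooling matches step-by-step DerSimonian-Laird arithmetic", {
  d <- data.frame(cohort_id = c("A", "B"), set_name = "S",
                  r = c(0.2, 0.6), n = c(103, 103))
  z <- atanh(c(0.2, 0.6))
  v <- c(1 / 100, 1 / 100)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  Q <- sum(w * (z - z_fixed)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - 1) / C)
  w_star <- 1 / (v + tau2)
  pooled_z <- sum(w_star * z) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  m <- meta_dsl(d)
  expect_equal(m$Q, Q, tolerance = 1e-10)
  expect_equal(m$tau2, tau2, tolerance = 1e-10)
  expect_equal(m$pooled_z, pooled_z, tolerance = 1e-10)
  expect_equal(m$se, se, tolerance = 1e-10)
  expect_equal(m$meta_r, tanh(pooled_z), tolerance = 1e-10)
  expect_equal(m$p_value, 2 * pnorm(-abs(pooled_z / se)), tolerance = 1e-10)
})

test_that("heterogeneous pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  d <- data.frame(cohort_id = c("A", "B", "C"), set_name = "S",
                  r = c(0.1, 0.45, -0.2), n = c(120, 60, 250))
  m <- meta_dsl(d)
  fit <- metafor::rma(yi = atanh(d$r), vi = 1 / (d$n - 3), method = "DL")
  expect_equal(m$pooled_z, as.numeric(fit$b), tolerance = 1e-10)
  expect_equal(m$tau2, fit$tau2, tolerance = 1e-10)
  expect_equal(m$Q, fit$QE, tolerance = 1e-10)
  expect_equal(m$se, fit$se, tolerance = 1e-10)
})

test_that("pooling is order-invariant and bounded by the extreme study", {
  d <- data.frame(cohort_id = c("A", "B", "C"), set_name = "S",
                  r = c(0.15, 0.4, 0.3), n = c(80, 200, 45))
  m1 <- meta_dsl(d)
  m2 <- meta_dsl(d[c(3, 1, 2), ])
  expect_equal(m1[c("meta_r", "se", "tau2", "Q")],
               m2[c("meta_r", "se", "tau2", "Q")], tolerance = 1e-12)
  expect_lte(abs(m1$meta_r), max(abs(d$r)))
  expect_error(meta_dsl(d[0, ]), "no cohort")
  expect_error(meta_dsl(d[c(1, 1), ]), "duplicate cohort_id")
})

test_that("association classification applies strict effect and p gates", {
  expect_identical(classify_association(-0.46, 1e-6), "negative")
  expect_identical(classify_association(0.46, 1e-6), "positive")
  expect_identical(classify_association(0.31, 0.2), "not_significant")
  expect_identical(classify_association(0.3, 0.001), "not_significant")
  expect_identical(classify_association(-0.3, 0.001), "not_significant")
  m <- meta_dsl(data.frame(cohort_id = "A", r = -0.46, n = 442))
  expect_identical(classify_association(m), "negative")
})

test_that("the screen pools per set, classifies, and exports edges", {
  design <- planted_screen_design(seed = 21, n_null = 10,
                                  n_background_genes = 50)
  cohorts <- generate_multi_cohort(design$specs[1:3])
  tabs <- lapply(cohorts, function(co)
    activity_table(fold_matrix(co$expression), design$catalogue))
  res <- meta_screen(tabs, "EMT_SIGNATURE")
  expect_identical(nrow(res), length(design$catalogue) - 1L)
  expect_true(all(res$k == 3L))
  expect_false(is.unsorted(rev(res$meta_r)))
  edges <- screen_edge_list(res, "EMT_SIGNATURE")
  expect_identical(edges$target,
                   res$set_name[res$classification != "not_significant"])

  # self-correlation control: the EMT set screened as a candidate
  res2 <- meta_screen(tabs, "METABOLIC_SET_001")
  emt_row <- res2[res2$set_name == "EMT_SIGNATURE", ]
  expect_identical(nrow(emt_row), 1L)

  expect_error(meta_screen(tabs, "NOT_A_SET"), "missing from cohort")
  expect_error(meta_screen(list(), "EMT_SIGNATURE"), "no cohort")
})

test_that("a one-cohort screen reports k = 1 and zero heterogeneity", {
  design <- planted_screen_design(seed = 31, n_null = 5,
                                  n_background_genes = 30)
  co <- generate_cohort(design$specs[[4]])
  tab <- activity_table(fold_matrix(co$expression), design$catalogue)
  res <- meta_screen(list(COHORT4 = tab), "EMT_SIGNATURE")
  expect_true(all(res$k == 1L))
  expect_true(all(res$tau2 == 0))
})

test_that("screening a set against itself gives a maximal positive hit", {
  design <- planted_screen_design(seed = 41, n_null = 5,
                                  n_background_genes = 30)
  cohorts <- generate_multi_cohort(design$specs[4:6])
  # near-duplicate of the EMT set under a metabolic alias (a verbatim copy
  # would correlate exactly 1, outside the Fisher-z domain)
  alias <- gene_set("EMT_ALIAS",
                    design$catalogue[["EMT_SIGNATURE"]]$members[-1])
  coll <- gene_set_collection(c(unclass(design$catalogue), list(alias)))
  tabs <- lapply(cohorts, function(co)
    activity_table(fold_matrix(co$expression), coll))
  res <- meta_screen(tabs, "EMT_SIGNATURE")
  row <- res[res$set_name == "EMT_ALIAS", ]
  expect_identical(row$classification, "positive")
  expect_identical(res$set_name[[1]], "EMT_ALIAS")
  expect_gt(row$meta_r, 0.99)
})
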