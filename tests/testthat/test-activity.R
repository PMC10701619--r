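test_that("fold computation handles log and linear scales", {
  m <- matrix(c(1, 2, 4), 1, 3,
              dimnames = list("G1", c("S1", "S2", "S3")))
  lin <- expression_matrix(m, "C", scale = "linear")
  expect_equal(unname(unclass(fold_matrix(lin))[1, ]), c(-1, 0, 1))

  m2 <- matrix(5, 1, 3, dimnames = list("G1", c("S1", "S2", "S3")))
  logm <- expression_matrix(m2, "C", scale = "log")
  expect_equal(unname(unclass(fold_matrix(logm))[1, ]), c(0, 0, 0))

  m3 <- rbind(G1 = c(1, 2, 4), G2 = c(0, 1, 2))
  colnames(m3) <- c("S1", "S2", "S3")
  lin0 <- expression_matrix(m3, "C", scale = "linear")
  expect_error(fold_matrix(lin0), "G2")
})

test_that("fold matrix matches the two-pass oracle on a random linear matrix", {
  ex <- random_expression(20, 7, seed = 42, scale = "linear")
  expect_equal(unclass(fold_matrix(ex)), naive_fold(ex),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("per-gene fold medians are zero for odd sample counts", {
  ex <- random_expression(30, 9, seed = 7)
  f <- fold_matrix(ex)
  expect_equal(unname(apply(unclass(f), 1, median)), rep(0, 30),
               tolerance = 1e-12)
})

test_that("activation score evaluates the z-score formula exactly", {
  # 5-gene, 1-sample fixture worked by hand: profile mean 0,
  # profile SD sqrt(2.5) (n-1 denominator), set mean 1.5
  f <- structure(matrix(c(1, -1, 0, 2, -2), 5, 2,
                        dimnames = list(paste0("G", 1:5), c("S1", "S2"))),
                 cohort_id = "C", class = c("fold_matrix", "matrix", "array"))
  sc <- activation_score(f, gene_set("TOP", c("G1", "G4")))
  expect_equal(unname(sc[["S1"]]), sqrt(2) * 1.5 / sqrt(2.5),
               tolerance = 1e-12)
})

test_that("the all-genes set scores exactly zero in every sample", {
  ex <- random_expression(40, 6, seed = 11)
  f <- fold_matrix(ex)
  sc <- activation_score(f, gene_set("ALL", rownames(ex)))
  expect_equal(unname(sc), rep(0, 6), tolerance = 1e-12)
})

test_that("activation score matches the brute-force oracle on random fixtures", {
  for (i in 1:10) {
    ex <- random_expression(25 + i, 5 + (i %% 4), seed = 100 + i,
                            scale = if (i %% 2) "log" else "linear")
    set <- random_gene_set(ex, 4 + (i %% 6), seed = 200 + i)
    sc <- activation_score(fold_matrix(ex), set)
    expect_equal(sc, naive_activation(ex, set$members), tolerance = 1e-12)
  }
})

test_that("duplicating all genes rescales the score as direct recomputation predicts", {
  ex <- random_expression(15, 4, seed = 31)
  set <- random_gene_set(ex, 5, seed = 32)
  f1 <- unclass(fold_matrix(ex))
  dup <- rbind(f1, `rownames<-`(f1, paste0(rownames(f1), "_dup")))
  f2 <- structure(dup, cohort_id = "C",
                  class = c("fold_matrix", "matrix", "array"))
  set2 <- gene_set("SETDUP", c(set$members, paste0(set$members, "_dup")))
  sc2 <- activation_score(f2, set2)
  # matched count doubles (sqrt(2) factor); the n-1 profile SD also shifts
  sd1 <- apply(f1, 2, sd)
  sd2 <- apply(dup, 2, sd)
  sc1 <- activation_score(structure(f1, cohort_id = "C",
                                    class = c("fold_matrix", "matrix",
                                              "array")), set)
  expect_equal(unname(sc2), unname(sc1 * sqrt(2) * sd1 / sd2),
               tolerance = 1e-12)
})

test_that("adding a global constant leaves folds and scores unchanged", {
  ex <- random_expression(30, 8, seed = 55)
  set <- random_gene_set(ex, 6, seed = 56)
  shifted <- expression_matrix(unclass(ex) + 3.7, "C", scale = "log")
  expect_equal(unclass(fold_matrix(shifted)), unclass(fold_matrix(ex)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(activation_score(fold_matrix(shifted), set),
               activation_score(fold_matrix(ex), set), tolerance = 1e-12)
})

test_that("rescaling one sample's folds leaves its activation score unchanged", {
  ex <- random_expression(30, 5, seed = 66)
  set <- random_gene_set(ex, 7, seed = 67)
  f <- unclass(fold_matrix(ex))
  f2 <- f
  f2[, 3] <- f2[, 3] * 4.2  # numerator and profile SD both scale by k
  mk <- function(x) structure(x, cohort_id = "C",
                              class = c("fold_matrix", "matrix", "array"))
  expect_equal(activation_score(mk(f2), set)[[3]],
               activation_score(mk(f), set)[[3]], tolerance = 1e-12)
})

test_that("activity tables skip under-matched sets loudly and keep order", {
  ex <- random_expression(20, 5, seed = 77)
  f <- fold_matrix(ex)
  coll <- gene_set_collection(list(
    gene_set("A", rownames(ex)[1:4]),
    gene_set("ONE", c(rownames(ex)[5], "ABSENT")),
    gene_set("B", rownames(ex)[6:10])))
  expect_warning(tab <- activity_table(f, coll), "ONE")
  expect_identical(rownames(tab), c("A", "B"))
  expect_identical(attr(tab, "matched_genes"), c(A = 4L, B = 5L))
  expect_error(activity_table(f, gene_set_collection(list())), "empty")
  bad <- gene_set_collection(list(gene_set("X", c("NOPE", "NADA"))))
  expect_warning(expect_error(activity_table(f, bad), "no gene set matched"))
})

test_that("zero profile SD is reported with the sample name", {
  f <- structure(matrix(0, 3, 2, dimnames = list(paste0("G", 1:3),
                                                 c("S1", "S2"))),
                 cohort_id = "C", class = c("fold_matrix", "matrix", "array"))
  expect_error(activation_score(f, gene_set("S", c("G1", "G2"))), "S1")
})

test_that("signature scores are exact differences of activation rows", {
  ex <- random_expression(40, 7, seed = 88)
  f <- fold_matrix(ex)
  up <- gene_set("UP", rownames(ex)[1:8])
  down <- gene_set("DN", rownames(ex)[21:28])
  expect_identical(signature_score(f, up, down),
                   activation_score(f, up) - activation_score(f, down))
  expect_equal(unname(signature_score(f, up, up)), rep(0, 7))
  all_set <- gene_set("ALL", rownames(ex))
  expect_equal(signature_score(f, all_set, down),
               -activation_score(f, down), tolerance = 1e-12)
})
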