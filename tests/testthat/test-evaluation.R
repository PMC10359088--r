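test_that("oracle assignment takes the row minimum with low-index ties", {
  Y <- sensitivity_matrix(matrix(c(0.5, -1.2, 0.3), 1, 3,
                                 dimnames = list("p1", c("d1", "d2", "d3"))))
  o <- oracle_assign(Y)
  expect_identical(o$drug, "d2")
  expect_identical(o$value, -1.2)
  Yt <- sensitivity_matrix(matrix(c(1, 1, 2), 1, 3,
                                  dimnames = list("p1", c("a", "b", "c"))))
  expect_identical(oracle_assign(Yt)$drug, "a")
  # achieved values equal independently recomputed row minima
  withr::with_seed(19, v <- matrix(rnorm(400), 50, 8))
  v[sample(400, 60)] <- NA
  v[rowSums(!is.na(v)) == 0, 1] <- 0
  Y50 <- sensitivity_matrix(v)
  expect_equal(oracle_assign(Y50)$value,
               apply(v, 1L, min, na.rm = TRUE), ignore_attr = TRUE)
  v[1, ] <- NA
  expect_error(oracle_assign(sensitivity_matrix(v)), "no observed")
})

test_that("regret is achieved minus best, never negative, NA if unmeasured", {
  Y <- sensitivity_matrix(matrix(c(1, 3), 1, 2,
                                 dimnames = list("p1", c("a", "b"))))
  a <- predict(decision_tree("b"),
               biomarker_matrix(matrix(0, 1, 1,
                                       dimnames = list("p1", "g"))))
  expect_identical(delta_ic50(a, Y), c(p1 = 2))
  expect_identical(delta_ic50(oracle_assign(Y), Y), c(p1 = 0))
  Yna <- sensitivity_matrix(matrix(c(NA, 3), 1, 2,
                                   dimnames = list("p1", c("a", "b"))))
  aa <- structure(data.frame(patient_id = "p1", drug = "a", value = NA),
                  class = c("drug_assignment", "data.frame"))
  expect_true(is.na(delta_ic50(aa, Yna)))
  # dominance over random assignments
  withr::with_seed(29, {
    v <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("d", 1:10)))
    Y20 <- sensitivity_matrix(v)
    ids <- rownames(v)
    for (i in 1:10) {
      a <- structure(data.frame(patient_id = ids,
                                drug = sample(colnames(v), 20, TRUE),
                                value = NA),
                     class = c("drug_assignment", "data.frame"))
      expect_true(all(delta_ic50(a, Y20) >= 0))
    }
  })
})

test_that("folds are balanced, seeded, disjoint and order-stable", {
  plan <- make_folds(paste0("P", 1:10), k = 5, seed = 7)
  expect_identical(as.integer(table(plan$fold)), rep(2L, 5))
  expect_identical(plan$fold, make_folds(paste0("P", 1:10), 5, 7)$fold)
  # permuting input order never changes a patient's fold
  ids <- paste0("S", 1:23)
  f1 <- make_folds(ids, 4, 11)$fold
  f2 <- make_folds(rev(ids), 4, 11)$fold
  expect_identical(f1[ids], f2[ids])
  for (s in 1:25) {
    withr::with_seed(s, {
      P <- sample(6:60, 1); k <- sample(2:min(6, P), 1)
    })
    ids <- paste0("x", seq_len(P))
    f <- make_folds(ids, k, seed = s)$fold
    expect_setequal(names(f), ids)
    expect_lte(diff(range(table(f))), 1L)
    expect_identical(sort(unique(f)), seq_len(k))
  }
  expect_error(make_folds(paste0("P", 1:5), k = 1, seed = 1), ">= 2")
  expect_error(make_folds(paste0("P", 1:3), k = 4, seed = 1), "exceeds")
})

test_that("cross-validation evaluates held-out measured responses", {
  sim <- simulate_planted_tree_cohort(n_patients = 100, n_markers = 10,
                                      seed = 31)
  Ys <- compute_ic50_star(sim$Y)
  # the cheating oracle baseline achieves zero regret
  rep_o <- cross_validate(Ys, sim$X, oracle_method(), k = 5, seed = 2)
  expect_true(all(rep_o$per_patient$delta == 0))
  # a constant method's achieved values are that drug's held-out column
  rep_c <- cross_validate(Ys, sim$X, best_single_drug_method(), k = 5,
                          seed = 2)
  pp <- rep_c$per_patient
  expect_equal(pp$achieved,
               unclass(Ys)[cbind(match(pp$patient_id, rownames(Ys)),
                                 match(pp$drug, colnames(Ys)))])
  # every patient appears exactly once
  expect_setequal(pp$patient_id, rownames(Ys))
  # ODT beats the no-biomarker baseline on planted data
  rep_t <- cross_validate(Ys, sim$X, odt_method(), k = 5, seed = 2)
  expect_lt(median(rep_t$per_patient$delta), median(pp$delta))
})

test_that("the harness never leaks test patients into training", {
  sim <- simulate_planted_tree_cohort(n_patients = 60, n_markers = 6,
                                      seed = 37)
  Ys <- compute_ic50_star(sim$Y)
  seen <- list()
  probe <- method_spec(
    "probe",
    fit = function(Y, X) {
      seen[[length(seen) + 1L]] <<- rownames(Y)
      colnames(Y)[1L]
    },
    predict = function(model, X, Y = NULL)
      structure(data.frame(patient_id = rownames(X), drug = model,
                           value = NA),
                class = c("drug_assignment", "data.frame")))
  plan <- make_folds(rownames(Ys), 5, seed = 13)
  rep_p <- cross_validate(Ys, sim$X, probe, plan = plan)
  for (f in 1:5) {
    test_ids <- names(plan$fold)[plan$fold == f]
    expect_length(intersect(seen[[f]], test_ids), 0L)
    expect_setequal(c(seen[[f]], test_ids), rownames(Ys))
  }
})

test_that("per-fold failures are recorded and flag the report partial", {
  sim <- simulate_planted_tree_cohort(n_patients = 40, n_markers = 5,
                                      seed = 41)
  Ys <- compute_ic50_star(sim$Y)
  flaky <- method_spec(
    "flaky",
    fit = function(Y, X) if (rownames(Y)[1] == "P001")
      stop("boom") else colnames(Y)[1L],
    predict = function(model, X, Y = NULL)
      structure(data.frame(patient_id = rownames(X), drug = model,
                           value = NA),
                class = c("drug_assignment", "data.frame")))
  rep_f <- cross_validate(Ys, sim$X, flaky, k = 4, seed = 3)
  expect_true(rep_f$partial)
  expect_gte(length(rep_f$errors), 1L)
})

test_that("rank-sum validation matches exhaustive enumeration exactly", {
  r <- intragroup_test_raw <- function(g1, g2) {
    # direct wrapper: compare through the package by building a cohort
    n <- length(g1) + length(g2)
    ids <- paste0("p", seq_len(n))
    v <- cbind(dX = c(g1, g2) + 10, other = rep(100, n))
    rownames(v) <- ids
    a <- structure(
      data.frame(patient_id = ids,
                 drug = rep(c("dX", "other"), c(length(g1), length(g2))),
                 value = NA),
      class = c("drug_assignment", "data.frame"))
    intragroup_test(a, sensitivity_matrix(v), "dX", measure = "value")
  }
  res <- r(c(1, 2, 3), c(4, 5, 6, 7))
  expect_identical(res$statistic, 0)
  expect_equal(res$p_value, enumerate_ranksum(c(1, 2, 3), c(4, 5, 6, 7)),
               tolerance = 1e-12)
  expect_true(res$exact)
  for (s in 1:30) {
    withr::with_seed(s, {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      g1 <- rnorm(n1); g2 <- rnorm(n2)
    })
    got <- r(g1, g2)
    expect_equal(got$p_value, enumerate_ranksum(g1, g2), tolerance = 1e-12)
  }
  # identical multisets in both groups: perfect symmetry, p = 1
  sym <- r(c(1, 2, 3), c(1, 2, 3))
  expect_false(sym$exact)   # ties force the corrected normal approximation
  expect_equal(sym$p_value, 1)
})

test_that("degenerate intragroup groups are skipped with a reason", {
  co <- toy_cohort()
  a <- predict(decision_tree("dA"), co$X, Y = co$Y)
  res <- intragroup_test(a, co$Y, "dA")
  expect_true(res$skipped)
  expect_match(res$reason, "empty")
})

test_that("comparison table recomputes summaries from stored values", {
  sim <- simulate_planted_tree_cohort(n_patients = 80, n_markers = 8,
                                      seed = 43)
  Ys <- compute_ic50_star(sim$Y)
  r1 <- cross_validate(Ys, sim$X, odt_method(), k = 4, seed = 5)
  r2 <- cross_validate(Ys, sim$X, best_single_drug_method(), k = 4,
                       seed = 5)
  tab <- compare_methods(list(r1, r2))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$median[1], median(r1$per_patient$achieved, na.rm = TRUE))
  expect_equal(tab$mean_delta[2], mean(r2$per_patient$delta, na.rm = TRUE))
  tab2 <- compare_methods(list(r1, r1))
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
  r3 <- cross_validate(Ys[1:40, ], sim$X[1:40, ], odt_method(), k = 4,
                       seed = 5)
  expect_error(compare_methods(list(r1, r3)), "cohort")
})
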