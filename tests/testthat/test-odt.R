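test_that("score_split computes A + B by direct summation", {
  Yv <- matrix(c(3, 1, 2, 2, 0, 4, 1, 3), 4, 2, byrow = TRUE,
               dimnames = list(paste0("P", 1:4), c("d0", "d1")))
  Y <- sensitivity_matrix(Yv, scale = "benefit")
  expect_equal(score_split(Y, c(TRUE, TRUE, FALSE, FALSE), "d0", "d1"), 12)
  # all-true mask: objective is the column sum of drug_true
  expect_equal(score_split(Y, rep(TRUE, 4), "d0", "d1"), sum(Yv[, "d0"]))
  expect_error(score_split(Y, rep(TRUE, 4), "nope", "d1"), "unknown drug")
  expect_error(score_split(Y, TRUE, "d0", "d1"), "mask")
  # random instances against a naive double loop
  for (s in 1:50) {
    inst <- random_split_instance(s, P = 10L, M = 1L, D = 3L)
    mask <- withr::with_seed(s + 1000L, sample(c(TRUE, FALSE), 10L, TRUE))
    d <- withr::with_seed(s + 2000L, sample(colnames(inst$Y), 2L))
    naive <- 0
    for (p in 1:10) {
      naive <- naive +
        if (mask[p]) unclass(inst$Y)[p, d[1]] else unclass(inst$Y)[p, d[2]]
    }
    expect_equal(score_split(inst$Y, mask, d[1], d[2]), naive)
  }
})

test_that("find_best_split matches brute-force enumeration (binary markers)", {
  for (s in 1:60) {
    inst <- random_split_instance(s)
    got <- find_best_split(inst$Y, inst$X)
    want <- brute_force_split(inst$Y, inst$X)
    expect_identical(got$objective, want$objective)
    expect_identical(got[c("marker", "drug_true", "drug_false")],
                     want[c("marker", "drug_true", "drug_false")])
  }
})

test_that("find_best_split matches brute force with continuous thresholds", {
  for (s in 1:40) {
    inst <- random_split_instance(s, M = 6L, n_continuous = 3L)
    ctl <- odt_control(transform = if (s %% 2) "identity" else "signed_sqrt")
    got <- find_best_split(inst$Y, inst$X, control = ctl)
    want <- brute_force_split(inst$Y, inst$X, control = ctl)
    expect_identical(got$objective, want$objective)
    expect_identical(got[c("marker", "threshold", "drug_true", "drug_false")],
                     want[c("marker", "threshold", "drug_true",
                            "drug_false")])
  }
})

test_that("constructed optimum and degenerate markers behave as designed", {
  Yv <- matrix(c(10, 0, 10, 0, 0, 10, 0, 10), 4, 2, byrow = TRUE,
               dimnames = list(paste0("P", 1:4), c("A", "B")))
  Xv <- cbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 1, 1))
  rownames(Xv) <- rownames(Yv)
  s <- find_best_split(sensitivity_matrix(Yv, scale = "benefit"),
                       biomarker_matrix(Xv))
  expect_identical(s[c("marker", "drug_true", "drug_false")],
                   list(marker = "g1", drug_true = "A", drug_false = "B"))
  expect_equal(s$objective, 40)
  # a constant marker cannot split; alone it yields no decision
  s2 <- find_best_split(sensitivity_matrix(Yv, scale = "benefit"),
                        biomarker_matrix(Xv[, "g2", drop = FALSE]))
  expect_null(s2)
})

test_that("splitting never scores below the best single drug", {
  for (s in 1:25) {
    inst <- random_split_instance(s, P = 20L)
    got <- find_best_split(inst$Y, inst$X)
    single_best <- max(colSums(unclass(inst$Y)))
    expect_gte(got$objective, single_best)
  }
})

test_that("patient permutation leaves the fitted tree invariant", {
  sim <- simulate_planted_tree_cohort(n_patients = 80, n_markers = 10,
                                      seed = 21)
  Ys <- compute_ic50_star(sim$Y)
  t1 <- fit_odt(Ys, sim$X)
  perm <- withr::with_seed(5, sample(nrow(Ys)))
  t2 <- fit_odt(Ys[perm, ], sim$X[perm, ])
  expect_true(same_tree_structure(t1, t2))
  expect_equal(t1$root$objective, t2$root$objective)
})

test_that("stopping rules produce leaves as specified", {
  co <- toy_cohort()
  Ys <- compute_ic50_star(co$Y)
  # (a) min_group_size > P: single leaf at the best overall drug
  t <- fit_odt(Ys, co$X, odt_control(min_group_size = 10L))
  expect_s3_class(t$root, "tree_leaf")
  best <- colnames(Ys)[which.max(colSums(-unclass(Ys)))]
  expect_identical(t$root$drug, best)
  # (b) one dominant drug for everyone: best split ties both branches
  Yd <- sensitivity_matrix(
    matrix(c(0, 5, 0, 5, 0, 5, 0, 5), 4, 2,
           dimnames = list(paste0("P", 1:4), c("win", "lose"))))
  t2 <- fit_odt(Yd, co$X, odt_control(min_group_size = 2L))
  expect_s3_class(t2$root, "tree_leaf")
  expect_identical(t2$root$drug, "win")
  # (d) max_depth caps the recursion
  sim <- simulate_planted_tree_cohort(n_patients = 100, n_markers = 10,
                                      seed = 2)
  t3 <- fit_odt(compute_ic50_star(sim$Y), sim$X,
                odt_control(min_group_size = 2L, max_depth = 1))
  expect_s3_class(t3$root, "tree_split")
  expect_s3_class(t3$root$if_true, "tree_leaf")
  expect_s3_class(t3$root$if_false, "tree_leaf")
})

test_that("missing responses error by default and are averaged on request", {
  co <- toy_cohort()
  Yna <- co$Y
  Yna[1, 1] <- NA
  expect_error(fit_odt(Yna, co$X), "missing")
  t <- fit_odt(Yna, co$X, odt_control(min_group_size = 2L,
                                      na_action = "mean"))
  expect_s3_class(t, "decision_tree")
})

test_that("prediction routes by the node rules and matches fit bookkeeping", {
  t <- decision_tree(tree_split("g1", if_true = "A", if_false = "B"))
  X <- biomarker_matrix(matrix(c(1, 0), 2, 1,
                               dimnames = list(c("p1", "p2"), "g1")))
  expect_identical(predict(t, X)$drug, c("A", "B"))
  tc <- decision_tree(tree_split("e1", threshold = 0.5,
                                 if_true = "A", if_false = "B"))
  Xc <- biomarker_matrix(matrix(c(0.5, 0.49), 2, 1,
                                dimnames = list(c("p1", "p2"), "e1")))
  expect_identical(predict(tc, Xc)$drug, c("A", "B"))  # boundary goes true
  expect_error(predict(t, Xc), "lacks marker")
  # training patients reach exactly the leaves recorded during fitting
  sim <- simulate_planted_tree_cohort(n_patients = 150, n_markers = 12,
                                      seed = 9)
  Ys <- compute_ic50_star(sim$Y)
  tree <- fit_odt(Ys, sim$X)
  refit <- predict(tree, sim$X)
  expect_identical(refit$drug, attr(tree, "training_assignment")$drug)
})

test_that("signed-sqrt leaf objectives re-score identically after fitting", {
  sim <- simulate_planted_tree_cohort(n_patients = 120, n_markers = 10,
                                      seed = 4)
  Ys <- compute_ic50_star(sim$Y)
  ctl <- odt_control(transform = "signed_sqrt")
  tree <- fit_odt(Ys, sim$X, ctl)
  B <- to_benefit(Ys)
  check_node <- function(node, subset) {
    if (inherits(node, "tree_leaf")) return(invisible(NULL))
    x <- unclass(sim$X)[subset, node$marker]
    m <- if (is.null(node$threshold)) x == 1 else x >= node$threshold
    d1 <- if (inherits(node$if_true, "tree_leaf")) node$if_true$drug
          else NULL
    rescored <- score_split(B[subset, ], m,
                            drug_true = .leaf_best(node$if_true),
                            drug_false = .leaf_best(node$if_false),
                            transform = "signed_sqrt")
    expect_equal(rescored, node$objective, tolerance = 1e-9)
    check_node(node$if_true, subset[m])
    check_node(node$if_false, subset[!m])
  }
  # the drug credited to a branch at split time: its best single drug
  .leaf_best <- function(node) {
    if (inherits(node, "tree_leaf")) node$drug
    else stop("rescoring only checks split nodes whose branches are leaves")
  }
  # restrict the check to depth-1 (both children leaves) nodes
  walk <- function(node, subset) {
    if (inherits(node, "tree_leaf")) return(invisible(NULL))
    if (inherits(node$if_true, "tree_leaf") &&
        inherits(node$if_false, "tree_leaf")) {
      check_node(node, subset)
    } else {
      x <- unclass(sim$X)[subset, node$marker]
      m <- if (is.null(node$threshold)) x == 1 else x >= node$threshold
      walk(node$if_true, subset[m])
      walk(node$if_false, subset[!m])
    }
  }
  walk(tree$root, seq_len(nrow(Ys)))
})

test_that("planted depth-2 structure is recovered under moderate noise", {
  hits <- vapply(1:8, function(s) {
    sim <- simulate_planted_tree_cohort(seed = s)
    tree <- fit_odt(compute_ic50_star(sim$Y), sim$X)
    same_tree_structure(tree, sim$truth$tree)
  }, logical(1L))
  expect_gte(mean(hits), 7 / 8)
})
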