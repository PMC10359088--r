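# fixture builders and independent oracles shared across the suite

# small random instance for split-search oracle tests
random_split_instance <- function(seed, P = 15L, M = 6L, D = 4L,
                                  n_continuous = 0L) {
  withr::with_seed(seed, {
    kinds <- c(rep("continuous", n_continuous),
               rep("binary", M - n_continuous))
    Xv <- sapply(seq_len(M), function(j)
      if (kinds[j] == "binary") rbinom(P, 1L, 0.5) else rnorm(P))
    dimnames(Xv) <- list(sprintf("P%02d", 1:P), sprintf("m%d", 1:M))
    Yv <- matrix(rnorm(P * D), P, D,
                 dimnames = list(rownames(Xv), sprintf("d%d", 1:D)))
    list(Y = sensitivity_matrix(Yv, scale = "benefit"),
         X = biomarker_matrix(Xv, column_kind = kinds))
  })
}

# full enumeration over (marker, threshold, drug_true, drug_false), written
# independently of find_best_split: naive per-patient summation loops, same
# canonical ordering (marker index, ascending threshold, drug indices) and
# strict ">" replacement
brute_force_split <- function(Y, X, control = odt_control()) {
  fY <- unclass(apply_transform(Y, control$transform))
  kinds <- attr(X, "column_kind")
  Xv <- unclass(X)
  drugs <- colnames(fY)
  best <- NULL
  for (j in seq_len(ncol(Xv))) {
    x <- Xv[, j]
    cands <- if (kinds[[j]] == "binary") list(list(mask = x == 1, th = NULL))
    else {
      v <- sort(unique(x))
      if (length(v) < 2L) list()
      else lapply((v[-length(v)] + v[-1L]) / 2,
                  function(th) list(mask = x >= th, th = th))
    }
    for (cand in cands) {
      m <- cand$mask
      if (!any(m) || all(m)) next
      for (d1 in seq_along(drugs)) for (d2 in seq_along(drugs)) {
        A <- sum(fY[m, d1])       # branch sums in patient order
        B <- sum(fY[!m, d2])
        obj <- A + B
        if (is.null(best) || obj > best$objective)
          best <- list(marker = colnames(Xv)[j], threshold = cand$th,
                       drug_true = drugs[d1], drug_false = drugs[d2],
                       objective = obj)
      }
    }
  }
  best
}

# exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n1 + n2, n1) group labelings (tie-free data only)
enumerate_ranksum <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  center <- n1 * length(g2) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
}

# independent L-BFGS-B optimizer for the penalized soft-label multinomial
# objective; the non-smooth penalty is smoothed with a tiny epsilon, which
# perturbs the optimal objective by at most lambda * M * sqrt(D * eps)
optim_multinomial_objective <- function(X, Z, lambda, penalty,
                                        eps = 1e-12, maxit = 3000L) {
  M <- ncol(X); D <- ncol(Z); P <- nrow(X)
  unpack <- function(par) list(b0 = par[1:D],
                               b = matrix(par[-(1:D)], M, D))
  fn <- function(par) {
    p <- unpack(par)
    W <- sweep(X %*% p$b, 2L, p$b0, "+")
    lse <- apply(W, 1L, function(w) { mx <- max(w); mx + log(sum(exp(w - mx))) })
    nll <- -sum(Z * (W - lse)) / P
    pen <- if (penalty == "lasso") lambda * sum(sqrt(p$b^2 + eps))
           else lambda * sum(sqrt(rowSums(p$b^2) + eps))
    nll + pen
  }
  gr <- function(par) {
    p <- unpack(par)
    W <- sweep(X %*% p$b, 2L, p$b0, "+")
    e <- exp(W - apply(W, 1L, max)); Pm <- e / rowSums(e)
    R <- (Pm - Z) / P
    gpen <- if (penalty == "lasso") lambda * p$b / sqrt(p$b^2 + eps)
            else lambda * p$b / sqrt(rowSums(p$b^2) + eps)
    c(colSums(R), as.numeric(crossprod(X, R) + gpen))
  }
  res <- stats::optim(rep(0, D + M * D), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e1))
  p <- unpack(res$par)
  multinomial_objective(p$b0, p$b, X, Z, lambda, penalty)
}

# tiny deterministic cohort used by several IO / evaluation tests
toy_cohort <- function() {
  Yv <- matrix(c(0.5, -1.2, 0.3,
                 1.0, 3.0, 2.0,
                 -0.5, 0.25, -0.25,
                 2.0, 1.0, 0.0), 4, 3, byrow = TRUE,
               dimnames = list(paste0("P", 1:4), c("dA", "dB", "dC")))
  Xv <- matrix(c(1, 0,
                 0, 1,
                 1, 1,
                 0, 0), 4, 2, byrow = TRUE,
               dimnames = list(paste0("P", 1:4), c("g1", "g2")))
  list(Y = sensitivity_matrix(Yv, scale = "log_ic50"),
       X = biomarker_matrix(Xv))
}
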