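#' Build the probabilistic vote matrix Z
#'
#' Converts a sensitivity matrix into per-patient probabilistic drug labels:
#' each patient splits one vote over the drugs, giving more weight to drugs
#' they are more sensitive to.  Entry (p, d) is proportional to
#' `exp(-K * y_pd / min_p)` where `min_p` scales the exponent.  With
#' `min_scope = "patient"` (default) `min_p` is patient p's minimum response
#' across drugs, so as K grows each row concentrates on that patient's most
#' effective (minimum-y) drug, and K = 0 gives every drug 1/D of the vote.
#' `min_scope = "drug"` instead divides each drug's column by its own minimum
#' across patients (a per-drug standardization variant).
#'
#' The formula assumes strictly positive responses (raw or shifted IC50, not
#' centered IC50*).  Under the default `positivity = "strict"` any
#' non-positive value is an error; `positivity = "shift"` first translates Y
#' by `-min(Y) + 1e-6 * range(Y)` so the scheme applies to centered inputs.
#'
#' @param Y a [sensitivity_matrix()] with no missing entries; lower = better.
#' @param K non-negative vote-concentration temperature.
#' @param positivity `"strict"` (default) or `"shift"`.
#' @param min_scope `"patient"` (row minimum; default) or `"drug"` (column
#'   minimum).
#' @return a `vote_matrix`: P x D matrix with non-negative entries and unit
#'   row sums, with attributes `K`, `min_scope`, `shifted`.
#' @export
build_vote_matrix <- function(Y, K = 1,
                              positivity = c("strict", "shift"),
                              min_scope = c("patient", "drug")) {
  positivity <- match.arg(positivity)
  min_scope <- match.arg(min_scope)
  stopifnot(is.numeric(K), length(K) == 1L, K >= 0)
  v <- unclass(Y)
  if (ncol(v) < 2L) stop("need at least two drugs", call. = FALSE)
  if (anyNA(v))
    stop("vote matrix requires a complete sensitivity matrix", call. = FALSE)
  shifted <- FALSE
  if (any(v <= 0)) {
    if (positivity == "strict")
      stop("non-positive sensitivity values; the vote formula requires ",
           "y > 0.  Feed raw (unlogged, uncentered) IC50-type values or set ",
           "positivity = 'shift'.", call. = FALSE)
    eps <- 1e-6 * (max(v) - min(v))
    if (eps == 0) eps <- 1e-6
    v <- v - min(v) + eps
    shifted <- TRUE
  }
  scaled <- if (min_scope == "patient") {
    mins <- apply(v, 1L, min)
    if (any(mins == 0)) stop("zero per-patient minimum response",
                             call. = FALSE)
    v / mins
  } else {
    mins <- apply(v, 2L, min)
    if (any(mins == 0)) stop("zero per-drug minimum response", call. = FALSE)
    sweep(v, 2L, mins, "/")
  }
  # softmax of -K * scaled, row-wise, numerically stable
  e <- exp(-K * scaled - apply(-K * scaled, 1L, max))
  Z <- e / rowSums(e)
  dimnames(Z) <- dimnames(unclass(Y))
  structure(Z, K = K, min_scope = min_scope, shifted = shifted,
            class = c("vote_matrix", "matrix", "array"))
}

.check_vote_matrix <- function(Z) {
  v <- unclass(Z)
  if (any(v < 0) || any(abs(rowSums(v) - 1) > 1e-10))
    stop("vote matrix rows must be non-negative and sum to 1", call. = FALSE)
  invisible(TRUE)
}

# ---- soft-label penalized multinomial objective ---------------------------

# negative log-likelihood: -(1/P) sum_p sum_d z_pd log softmax_d(b0 + x b)
.soft_nll <- function(beta0, beta, X, Z) {
  W <- sweep(X %*% beta, 2L, beta0, "+")
  lse <- apply(W, 1L, function(w) { m <- max(w); m + log(sum(exp(w - m))) })
  -sum(Z * (W - lse)) / nrow(X)
}

.penalty_value <- function(beta, lambda, penalty) {
  if (penalty == "lasso") lambda * sum(abs(beta))
  else lambda * sum(sqrt(rowSums(beta^2)))
}

#' Penalized soft-label multinomial objective
#'
#' The criterion minimized by [fit_multinomial()]: the soft-label multinomial
#' negative log-likelihood `-(1/P) sum_p sum_d z_pd log softmax_d(b0_d +
#' x_p . beta_d)` plus `lambda * sum_m |beta_m.|_1` (lasso) or
#' `lambda * sum_m ||beta_m.||_2` (grouped lasso); intercepts unpenalized.
#' Exposed so the fitted optimum can be checked against any general-purpose
#' optimizer run on the identical criterion.
#'
#' @param beta0 length-D intercept vector.
#' @param beta M x D coefficient matrix (on the same feature scale as `X`).
#' @param X P x M feature matrix.
#' @param Z P x D vote matrix (rows on the simplex).
#' @param lambda non-negative penalty weight.
#' @param penalty `"lasso"` or `"grouped_lasso"`.
#' @return the objective value (a number).
#' @export
multinomial_objective <- function(beta0, beta, X, Z, lambda,
                                  penalty = c("grouped_lasso", "lasso")) {
  penalty <- match.arg(penalty)
  .soft_nll(beta0, beta, X, Z) + .penalty_value(beta, lambda, penalty)
}

# softmax probabilities, row-stable
.softmax <- function(W) {
  e <- exp(W - apply(W, 1L, max))
  e / rowSums(e)
}

# proximal operator of the penalty at step size t
.prox <- function(beta, t, lambda, penalty) {
  if (penalty == "lasso") {
    sign(beta) * pmax(abs(beta) - t * lambda, 0)
  } else {
    nrm <- sqrt(rowSums(beta^2))
    shrink <- pmax(0, 1 - t * lambda / pmax(nrm, .Machine$double.xmin))
    beta * shrink
  }
}

# Monotone FISTA on the soft-label objective.  Constant step 1/L with
# L = s_max([1 X])^2 / (2P), the Lipschitz bound of the multinomial NLL
# gradient; momentum restarts whenever the accelerated step would increase
# the objective, falling back to a plain (guaranteed-descent) proximal step.
.fista_fit <- function(X, Z, lambda, penalty, beta0, beta,
                       tol = 1e-9, maxit = 2000L) {
  P <- nrow(X); M <- ncol(X); D <- ncol(Z)
  Xa <- cbind(1, X)
  L <- (svd(Xa, nu = 0L, nv = 0L)$d[1L]^2) / (2 * P)
  t_step <- 1 / L
  obj <- function(b0, b)
    .soft_nll(b0, b, X, Z) + .penalty_value(b, lambda, penalty)
  grad <- function(b0, b) {
    Pm <- .softmax(sweep(X %*% b, 2L, b0, "+"))
    R <- (Pm - Z) / P
    list(g0 = colSums(R), g = crossprod(X, R))
  }
  step <- function(b0, b) {
    g <- grad(b0, b)
    list(b0 = b0 - t_step * g$g0,
         b = .prox(b - t_step * g$g, t_step, lambda, penalty))
  }
  x0 <- beta0; xb <- beta          # current iterate
  y0 <- beta0; yb <- beta          # momentum point
  tk <- 1
  f_cur <- obj(x0, xb)
  trace <- f_cur
  for (it in seq_len(maxit)) {
    cand <- step(y0, yb)
    f_cand <- obj(cand$b0, cand$b)
    if (f_cand > f_cur) {          # restart momentum; plain descent step
      cand <- step(x0, xb)
      f_cand <- obj(cand$b0, cand$b)
      tk <- 1
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / tk_new
    y0 <- cand$b0 + mom * (cand$b0 - x0)
    yb <- cand$b + mom * (cand$b - xb)
    x0 <- cand$b0; xb <- cand$b
    tk <- tk_new
    trace <- c(trace, f_cand)
    if (f_cand > f_cur + 1e-6 * (abs(f_cur) + 1))
      stop("solver divergence: objective rose from ", f_cur, " to ", f_cand,
           " at iteration ", it, call. = FALSE)
    done <- abs(f_cur - f_cand) <= tol * (abs(f_cand) + 1e-10)
    f_cur <- f_cand
    if (done) break
  }
  list(beta0 = x0, beta = xb, objective = f_cur, iterations = it,
       converged = it < maxit, trace = trace)
}

# smallest lambda for which beta = 0 is optimal (intercept-only fit gives
# predicted probabilities = column means of Z)
.lambda_max <- function(X, Z, penalty) {
  P <- nrow(X)
  q <- colMeans(Z)
  G <- crossprod(X, matrix(q, P, ncol(Z), byrow = TRUE) - Z) / P
  if (penalty == "lasso") max(abs(G)) else max(sqrt(rowSums(G^2)))
}

#' Fit a soft-label multinomial lasso drug-assignment model
#'
#' Minimizes the soft-label multinomial negative log-likelihood (votes `Z` as
#' probabilistic targets) plus a lasso or grouped-lasso penalty on the
#' marker-by-drug coefficient matrix; intercepts are unpenalized.  The
#' grouped penalty zeroes each marker's coefficients jointly across all
#' drugs, so one small variable set serves the whole drug panel.  Features
#' are standardized internally and coefficients reported on the original
#' scale.  `lambda = "cv"` selects the held-out-deviance-minimizing value on
#' a log-spaced path by k-fold cross-validation (largest lambda on ties).
#'
#' @param X a [biomarker_matrix()] (or plain numeric matrix) of features.
#' @param Z a [build_vote_matrix()] result aligned with `X`.
#' @param penalty `"grouped_lasso"` or `"lasso"`.
#' @param lambda a non-negative number, or `"cv"`.
#' @param nfolds folds for `lambda = "cv"` (>= 2).
#' @param seed seed for the CV fold split; required when `lambda = "cv"`.
#' @param cv_rule how the CV curve is turned into one lambda: `"1se"`
#'   (default) takes the largest lambda whose mean held-out deviance is
#'   within one standard error of the minimum — the parsimony rule that
#'   keeps null (no-signal) data from admitting spurious variables on CV
#'   noise; `"min"` takes the deviance-minimizing lambda itself (largest on
#'   ties).
#' @param nlambda,lambda_min_ratio geometry of the lambda path: `nlambda`
#'   log-spaced values from the smallest all-zero-coefficient lambda down to
#'   `lambda_min_ratio` times it.
#' @param standardize center/scale features internally (default TRUE).
#' @param tol,maxit solver convergence tolerance (relative objective change)
#'   and iteration cap.
#' @return a `multinomial_model`: coefficients `beta` (M x D, original
#'   scale), `intercepts`, `penalty`, `lambda`, the internal
#'   `standardization`, the final penalized `objective` (standardized scale),
#'   and for CV fits a `cv_path` data frame of (lambda, deviance).
#' @export
fit_multinomial <- function(X, Z, penalty = c("grouped_lasso", "lasso"),
                            lambda = "cv", nfolds = 5L, seed = NULL,
                            cv_rule = c("1se", "min"),
                            nlambda = 100L, lambda_min_ratio = 1e-4,
                            standardize = TRUE, tol = 1e-9, maxit = 2000L) {
  penalty <- match.arg(penalty)
  cv_rule <- match.arg(cv_rule)
  .check_vote_matrix(Z)
  Xv <- unclass(X); Zv <- unclass(Z)
  if (nrow(Xv) != nrow(Zv) ||
      (!is.null(rownames(Xv)) && !is.null(rownames(Zv)) &&
       !identical(rownames(Xv), rownames(Zv))))
    stop("feature and vote matrices do not align", call. = FALSE)
  M <- ncol(Xv); D <- ncol(Zv)
  marker_names <- colnames(Xv) %||% paste0("m", seq_len(M))
  drug_names <- colnames(Zv) %||% paste0("drug", seq_len(D))

  if (standardize) {
    center <- colMeans(Xv)
    scl <- apply(Xv, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    center <- rep(0, M); scl <- rep(1, M)
  }
  Xs <- sweep(sweep(Xv, 2L, center), 2L, scl, "/")

  warm0 <- log(pmax(colMeans(Zv), 1e-12))
  warm0 <- warm0 - mean(warm0)
  warm <- matrix(0, M, D)

  fit_at <- function(Xtr, Ztr, lam, b0, b, tol., maxit.)
    .fista_fit(Xtr, Ztr, lam, penalty, b0, b, tol = tol., maxit = maxit.)

  cv_path <- NULL
  if (identical(lambda, "cv")) {
    if (nfolds < 2L) stop("nfolds must be >= 2", call. = FALSE)
    if (is.null(seed))
      stop("lambda = 'cv' requires an explicit seed", call. = FALSE)
    lmax <- max(.lambda_max(Xs, Zv, penalty), 1e-10)
    path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    ids <- rownames(Xv) %||% as.character(seq_len(nrow(Xv)))
    plan <- make_folds(ids, k = nfolds, seed = seed)
    dev <- matrix(NA_real_, nfolds, nlambda)
    for (f in seq_len(nfolds)) {
      tr <- plan$fold != f
      b0 <- {
        q <- log(pmax(colMeans(Zv[tr, , drop = FALSE]), 1e-12)); q - mean(q)
      }
      b <- matrix(0, M, D)
      for (i in seq_along(path)) {
        res <- fit_at(Xs[tr, , drop = FALSE], Zv[tr, , drop = FALSE],
                      path[i], b0, b, tol. = max(tol, 1e-7),
                      maxit. = min(maxit, 500L))
        b0 <- res$beta0; b <- res$beta
        dev[f, i] <- .soft_nll(b0, b, Xs[!tr, , drop = FALSE],
                               Zv[!tr, , drop = FALSE])
      }
    }
    mean_dev <- colMeans(dev)
    se_dev <- apply(dev, 2L, stats::sd) / sqrt(nfolds)
    i_min <- which(mean_dev <= min(mean_dev) + 1e-10)[1L]  # largest on ties
    best <- if (cv_rule == "min") i_min
            else which(mean_dev <= mean_dev[i_min] + se_dev[i_min])[1L]
    lambda <- path[best]
    cv_path <- data.frame(lambda = path, deviance = mean_dev, se = se_dev)
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)

  res <- fit_at(Xs, Zv, lambda, warm0, warm, tol. = tol, maxit. = maxit)
  beta_orig <- res$beta / scl
  intercepts <- res$beta0 - as.numeric(crossprod(beta_orig, center))
  dimnames(beta_orig) <- list(marker_names, drug_names)
  names(intercepts) <- drug_names
  structure(list(beta = beta_orig, intercepts = intercepts,
                 penalty = penalty, lambda = lambda,
                 standardization = list(center = setNames(center,
                                                          marker_names),
                                        scale = setNames(scl, marker_names)),
                 cv_path = cv_path, objective = res$objective,
                 iterations = res$iterations, converged = res$converged,
                 objective_trace = res$trace,
                 marker_names = marker_names, drug_names = drug_names),
            class = "multinomial_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multinomial_model <- function(x, ...) {
  cat(sprintf("multinomial_model: %d markers x %d drugs, penalty %s, lambda %.4g\n",
              nrow(x$beta), ncol(x$beta), x$penalty, x$lambda))
  cat(sprintf("  selected variables: %d; final objective %.6g (%s)\n",
              count_selected_variables(x), x$objective,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Assign each patient the drug with the largest predicted logit
#'
#' @param object a fitted `multinomial_model`.
#' @param X a [biomarker_matrix()] (or matrix) containing every model marker.
#' @param Y optional aligned [sensitivity_matrix()] to fill achieved values.
#' @param ... unused.
#' @return a `drug_assignment` data frame.  Ties go to the lowest drug index.
#' @export
predict.multinomial_model <- function(object, X, Y = NULL, ...) {
  Xv <- unclass(X)
  missing_markers <- setdiff(object$marker_names, colnames(Xv))
  if (length(missing_markers))
    stop("biomarker matrix lacks model marker(s): ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  W <- sweep(Xv[, object$marker_names, drop = FALSE] %*% object$beta,
             2L, object$intercepts, "+")
  idx <- max.col(W, ties.method = "first")
  drugs <- object$drug_names[idx]
  value <- if (is.null(Y)) NA_real_
           else unclass(Y)[cbind(seq_len(nrow(Xv)),
                                 match(drugs, colnames(Y)))]
  new_assignment(rownames(Xv) %||% as.character(seq_len(nrow(Xv))),
                 drugs, value)
}

#' Number of variables a model actually uses
#'
#' The interpretability metric: how many input biomarkers carry any non-zero
#' weight.  For a multinomial model this is the number of coefficient rows
#' with an entry exceeding 1e-8 in absolute value (for the grouped penalty,
#' exactly the number of non-zero groups); for a decision tree, the number
#' of distinct markers appearing in splits.
#'
#' @param model a `multinomial_model` or `decision_tree`.
#' @return integer count.
#' @export
count_selected_variables <- function(model) {
  UseMethod("count_selected_variables")
}

#' @export
count_selected_variables.multinomial_model <- function(model) {
  sum(apply(abs(model$beta) > 1e-8, 1L, any))
}

#' @export
count_selected_variables.decision_tree <- function(model) {
  length(tree_markers(model))
}

#' Serialize / deserialize a multinomial model as JSON
#'
#' @param model a `multinomial_model`.
#' @param path optional output file.
#' @return `write_multinomial`: the JSON text (invisibly when written to
#'   `path`); `read_multinomial`: the reconstructed model.
#' @export
write_multinomial <- function(model, path = NULL) {
  obj <- list(penalty = model$penalty, lambda = model$lambda,
              intercepts = as.list(model$intercepts),
              beta = apply(model$beta, 1L, as.list, simplify = FALSE),
              marker_names = model$marker_names,
              drug_names = model$drug_names,
              standardization = lapply(model$standardization, as.list))
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                       pretty = TRUE))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname write_multinomial
#' @param text JSON text or path produced by [write_multinomial()].
#' @export
read_multinomial <- function(text) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  beta <- do.call(rbind, lapply(obj$beta, function(r) unlist(r)))
  dimnames(beta) <- list(obj$marker_names, obj$drug_names)
  structure(list(beta = beta,
                 intercepts = setNames(unlist(obj$intercepts),
                                       obj$drug_names),
                 penalty = obj$penalty, lambda = obj$lambda,
                 standardization = lapply(obj$standardization,
                                          function(v) unlist(v)),
                 cv_path = NULL, objective = NA_real_,
                 iterations = NA_integer_, converged = NA,
                 marker_names = obj$marker_names,
                 drug_names = obj$drug_names),
            class = "multinomial_model")
}
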