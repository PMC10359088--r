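#' Oracle drug assignment
#'
#' The reference giving each patient the drug with the minimum observed
#' response (maximum, for benefit-scale matrices): the best achievable
#' assignment, defining the lower bound every method is measured against.
#' Ties go to the lowest drug index.
#'
#' @param Y a [sensitivity_matrix()]; each patient needs at least one
#'   observed value.
#' @return a `drug_assignment` with the achieved values filled in.
#' @export
oracle_assign <- function(Y) {
  v <- unclass(Y)
  maximize <- response_scale(Y) == "benefit"
  none <- rowSums(!is.na(v)) == 0L
  if (any(none))
    stop("patient(s) with no observed drug value: ",
         paste(rownames(v)[none], collapse = ", "), call. = FALSE)
  idx <- apply(if (maximize) -v else v, 1L, which.min)
  new_assignment(rownames(v), colnames(v)[idx],
                 v[cbind(seq_len(nrow(v)), idx)])
}

#' Per-patient regret of an assignment (Delta IC50*)
#'
#' For each patient, the achieved response of the assigned drug minus the
#' patient's best observed response — zero iff the assignment matches the
#' Oracle, positive otherwise.  Patients whose assigned drug is unmeasured
#' get `NA` (reported, never imputed as zero).
#'
#' @param assignment a `drug_assignment` (or data frame with `patient_id`,
#'   `drug`).
#' @param Y a [sensitivity_matrix()] covering the assigned patients.
#' @return named numeric vector of non-negative regrets (NA where the
#'   assigned drug is unmeasured).
#' @export
delta_ic50 <- function(assignment, Y) {
  v <- unclass(Y)
  maximize <- response_scale(Y) == "benefit"
  p <- match(assignment$patient_id, rownames(v))
  if (anyNA(p))
    stop("assignment names patients absent from the sensitivity matrix",
         call. = FALSE)
  d <- match(assignment$drug, colnames(v))
  if (anyNA(d))
    stop("assignment names drugs absent from the sensitivity matrix",
         call. = FALSE)
  achieved <- v[cbind(p, d)]
  best <- if (maximize) apply(v[p, , drop = FALSE], 1L, max, na.rm = TRUE)
          else apply(v[p, , drop = FALSE], 1L, min, na.rm = TRUE)
  delta <- if (maximize) best - achieved else achieved - best
  setNames(delta, assignment$patient_id)
}

#' Seeded balanced fold assignment
#'
#' Uniform random partition into k folds with sizes differing by at most
#' one.  The labels are a function of the sorted patient identifiers, the
#' seed, and k — reordering the input does not change any patient's fold.
#'
#' @param patient_ids character vector of unique identifiers.
#' @param k number of folds (>= 2, <= number of patients).
#' @param seed integer seed.
#' @return a `fold_plan`: list with `fold` (named integer vector of labels
#'   1..k, in input order), `k`, `seed`.
#' @export
make_folds <- function(patient_ids, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > length(patient_ids))
    stop("k exceeds the number of patients", call. = FALSE)
  if (anyDuplicated(patient_ids))
    stop("duplicate patient identifiers", call. = FALSE)
  ord <- order(patient_ids)
  labels <- withr::with_seed(seed,
    sample(rep_len(seq_len(k), length(patient_ids))))
  fold <- integer(length(patient_ids))
  fold[ord] <- labels
  structure(list(fold = setNames(fold, patient_ids), k = k, seed = seed),
            class = "fold_plan")
}

#' Method specification for the cross-validation harness
#'
#' Bundles a name with a `fit(Y, X)` function returning a model and a
#' `predict(model, X, Y = NULL)` function returning a `drug_assignment`
#' (the optional `Y` lets reference baselines such as the test-time Oracle
#' peek at the held-out responses; honest methods must ignore it).
#'
#' @param name display name.
#' @param fit,predict the two functions.
#' @return a `method_spec` list.
#' @export
method_spec <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "method_spec")
}

#' Ready-made method specifications
#'
#' `odt_method()` wraps [fit_odt()]; `multinomial_method()` wraps
#' [build_vote_matrix()] + [fit_multinomial()] (vote `positivity = "shift"`
#' by default, since cross-validated inputs are typically centered IC50*);
#' `best_single_drug_method()` always recommends the training cohort's best
#' single drug (the natural no-biomarker baseline); `oracle_method()` is the
#' cheating upper bound that reads the held-out responses at test time.
#'
#' @param control an [odt_control()].
#' @return a [method_spec()].
#' @export
odt_method <- function(control = odt_control()) {
  method_spec("ODT",
              fit = function(Y, X) fit_odt(Y, X, control),
              predict = function(model, X, Y = NULL)
                predict(model, X, Y = Y))
}

#' @rdname odt_method
#' @param K,penalty,lambda,nfolds,seed,positivity passed to
#'   [build_vote_matrix()] / [fit_multinomial()].
#' @export
multinomial_method <- function(K = 1, penalty = "grouped_lasso",
                               lambda = "cv", nfolds = 5L, seed = 1L,
                               positivity = "shift") {
  method_spec("MultinomialLasso",
              fit = function(Y, X) {
                Z <- build_vote_matrix(Y, K = K, positivity = positivity)
                fit_multinomial(X, Z, penalty = penalty, lambda = lambda,
                                nfolds = nfolds, seed = seed)
              },
              predict = function(model, X, Y = NULL)
                predict(model, X, Y = Y))
}

#' @rdname odt_method
#' @export
best_single_drug_method <- function() {
  method_spec("BestSingleDrug",
              fit = function(Y, X) {
                B <- if (response_scale(Y) == "benefit") Y else to_benefit(Y)
                colnames(Y)[which.max(colMeans(unclass(B), na.rm = TRUE))]
              },
              predict = function(model, X, Y = NULL) {
                value <- if (is.null(Y)) NA_real_ else unclass(Y)[, model]
                new_assignment(rownames(X), rep(model, nrow(X)), value)
              })
}

#' @rdname odt_method
#' @export
oracle_method <- function() {
  method_spec("Oracle",
              fit = function(Y, X) NULL,
              predict = function(model, X, Y = NULL) {
                if (is.null(Y))
                  stop("oracle baseline needs the held-out responses",
                       call. = FALSE)
                oracle_assign(Y)
              })
}

#' k-fold cross-validation of a drug-assignment method
#'
#' For each fold: fit on the complementary patients, assign drugs to the
#' held-out patients, and record the held-out patients' own measured
#' response to the assigned drug (never a model-predicted value).  Results
#' are concatenated across folds with the Oracle reference and per-patient
#' regret.
#'
#' @param Y a [sensitivity_matrix()].
#' @param X an aligned [biomarker_matrix()].
#' @param method a [method_spec()].
#' @param k folds (used when `plan` is NULL).
#' @param seed fold seed (used when `plan` is NULL).
#' @param plan optional pre-built [make_folds()] plan.
#' @return an `evaluation_report`: `per_patient` data frame (patient_id,
#'   fold, drug, achieved, oracle, delta), `method`, `n_excluded` (patients
#'   whose assigned drug was unmeasured), `errors` (per-fold failures;
#'   report flagged `partial`), the fold `plan`, and `variable_count` when
#'   the per-fold models expose one (maximum across folds).
#' @export
cross_validate <- function(Y, X, method, k = 5L, seed = 1L, plan = NULL) {
  check_aligned(Y, X)
  stopifnot(inherits(method, "method_spec"))
  if (is.null(plan)) plan <- make_folds(rownames(Y), k = k, seed = seed)
  fold <- plan$fold[rownames(Y)]
  oracle <- oracle_assign(Y)
  rows <- list(); errors <- list(); varcounts <- integer()
  for (f in sort(unique(fold))) {
    test <- fold == f
    res <- tryCatch({
      model <- method$fit(Y[!test, , drop = FALSE], X[!test, , drop = FALSE])
      a <- method$predict(model, X[test, , drop = FALSE],
                          Y = Y[test, , drop = FALSE])
      vc <- tryCatch(count_selected_variables(model), error = function(e)
        NA_integer_)
      list(assignment = a, varcount = vc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(f)]] <- conditionMessage(res)
      next
    }
    a <- res$assignment
    delta <- delta_ic50(a, Y)
    achieved <- unclass(Y)[cbind(match(a$patient_id, rownames(Y)),
                                 match(a$drug, colnames(Y)))]
    rows[[as.character(f)]] <-
      data.frame(patient_id = a$patient_id, fold = f, drug = a$drug,
                 achieved = achieved,
                 oracle = oracle$value[match(a$patient_id,
                                             oracle$patient_id)],
                 delta = as.numeric(delta), stringsAsFactors = FALSE)
    if (!is.na(res$varcount)) varcounts <- c(varcounts, res$varcount)
  }
  per_patient <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(patient_id = character(), fold = integer(),
               drug = character(), achieved = numeric(),
               oracle = numeric(), delta = numeric())
  structure(list(per_patient = per_patient, method = method$name,
                 n_excluded = sum(is.na(per_patient$achieved)),
                 errors = errors, partial = length(errors) > 0L,
                 plan = plan,
                 variable_count = if (length(varcounts)) max(varcounts)
                                  else NA_integer_),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %s, %d patients, %d folds%s\n",
              x$method, nrow(x$per_patient), x$plan$k,
              if (x$partial) " [PARTIAL]" else ""))
  cat(sprintf("  median achieved %.4g | mean delta %.4g | excluded %d\n",
              stats::median(x$per_patient$achieved, na.rm = TRUE),
              mean(x$per_patient$delta, na.rm = TRUE), x$n_excluded))
  invisible(x)
}

#' Intragroup rank-sum validation of one drug recommendation
#'
#' Compares a drug's response between the patients it was recommended to and
#' all other patients, with a two-sided two-sample rank-sum (Mann-Whitney)
#' test.  By default the compared quantity is the drug's per-patient regret
#' (response of the drug minus the patient's best response); set
#' `measure = "value"` for the raw response.  The exact null distribution is
#' used when both groups have at most 12 patients and there are no ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param assignment a `drug_assignment` covering the cohort.
#' @param Y a [sensitivity_matrix()].
#' @param drug the drug to test.
#' @param measure `"delta"` (default) or `"value"`.
#' @return a list: `drug`, `n_recommended`, `n_other`, `statistic` (the
#'   Mann-Whitney U of the recommended group), `p_value`, `exact`, or a
#'   skipped marker with a `reason` when a group is empty.
#' @export
intragroup_test <- function(assignment, Y, drug,
                            measure = c("delta", "value")) {
  measure <- match.arg(measure)
  v <- unclass(Y)
  if (!(drug %in% colnames(v)))
    stop("unknown drug '", drug, "'", call. = FALSE)
  p <- match(assignment$patient_id, rownames(v))
  maximize <- response_scale(Y) == "benefit"
  col <- v[p, drug]
  values <- if (measure == "value") col else {
    best <- if (maximize) apply(v[p, , drop = FALSE], 1L, max, na.rm = TRUE)
            else apply(v[p, , drop = FALSE], 1L, min, na.rm = TRUE)
    if (maximize) best - col else col - best
  }
  in_group <- assignment$drug == drug & !is.na(values)
  out_group <- assignment$drug != drug & !is.na(values)
  if (!any(in_group) || !any(out_group))
    return(list(drug = drug, skipped = TRUE,
                reason = "empty recommended or comparison group",
                n_recommended = sum(in_group), n_other = sum(out_group)))
  g1 <- values[in_group]; g2 <- values[out_group]
  tie_free <- !anyDuplicated(c(g1, g2))
  exact <- tie_free && length(g1) <= 12L && length(g2) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(drug = drug, skipped = FALSE,
       n_recommended = length(g1), n_other = length(g2),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, measure = measure)
}

#' Side-by-side method comparison table
#'
#' @param reports list of `evaluation_report`s over the same cohort.
#' @return data frame with one row per method: median and quartiles of the
#'   achieved response, mean regret, exclusions, and variable count.
#' @export
compare_methods <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "evaluation_report")))
  cohorts <- lapply(reports, function(r) sort(r$per_patient$patient_id))
  if (length(reports) > 1L &&
      !all(vapply(cohorts[-1L], identical, TRUE, cohorts[[1L]])))
    stop("reports do not share the same patient cohort", call. = FALSE)
  do.call(rbind, lapply(reports, function(r) {
    a <- r$per_patient$achieved
    q <- stats::quantile(a, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(method = r$method,
               n = nrow(r$per_patient), n_excluded = r$n_excluded,
               q1 = q[1L], median = q[2L], q3 = q[3L],
               mean_delta = mean(r$per_patient$delta, na.rm = TRUE),
               n_variables = r$variable_count,
               stringsAsFactors = FALSE)
  }))
}
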