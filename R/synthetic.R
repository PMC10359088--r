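#' Random planted assignment tree
#'
#' Builds a complete binary tree of the requested depth over distinct
#' markers, with distinct drugs at the leaves — the ground truth used by
#' [simulate_planted_tree_cohort()].  Continuous markers split at threshold
#' 0 (their generated values are standard normal, so 0 balances the split).
#'
#' @param marker_names pool of marker names.
#' @param drug_names pool of drug names (needs at least `2^depth`).
#' @param depth tree depth, 1..3.
#' @param marker_kinds named character vector (`"binary"`/`"continuous"`);
#'   defaults to all binary.
#' @return a `decision_tree`.
#' @export
random_planted_tree <- function(marker_names, drug_names, depth = 2L,
                                marker_kinds = NULL) {
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, depth <= 3L)
  n_internal <- 2L^depth - 1L
  if (length(marker_names) < n_internal)
    stop("need at least ", n_internal, " markers for depth ", depth,
         call. = FALSE)
  if (length(drug_names) < 2L^depth)
    stop("need at least ", 2L^depth, " drugs for depth ", depth,
         call. = FALSE)
  if (is.null(marker_kinds))
    marker_kinds <- setNames(rep("binary", length(marker_names)),
                             marker_names)
  ms <- sample(marker_names, n_internal)
  ds <- sample(drug_names, 2L^depth)
  i_m <- 0L; i_d <- 0L
  build <- function(level) {
    if (level > depth) {
      i_d <<- i_d + 1L
      return(tree_leaf(ds[i_d]))
    }
    i_m <<- i_m + 1L
    m <- ms[i_m]
    tree_split(m,
               threshold = if (marker_kinds[[m]] == "continuous") 0 else NULL,
               if_true = build(level + 1L), if_false = build(level + 1L))
  }
  decision_tree(build(1L), drug_names = drug_names)
}

# minimum split depth (1 = root) at which each marker appears in a tree
.marker_depths <- function(tree) {
  depths <- integer()
  walk <- function(node, lvl) {
    if (inherits(node, "tree_split")) {
      cur <- depths[node$marker]
      if (is.na(cur) || lvl < cur) depths[node$marker] <<- lvl
      walk(node$if_true, lvl + 1L); walk(node$if_false, lvl + 1L)
    }
  }
  depths <- setNames(rep(NA_integer_, length(tree_markers(tree))),
                     tree_markers(tree))
  walk(tree$root, 1L)
  depths
}

#' Simulate a cohort with planted decision-tree structure
#'
#' Emulates an ex-vivo drug screen whose subgroup structure is driven by a
#' small number of biomarkers: binary markers are Bernoulli(prevalence),
#' continuous markers standard normal; each patient is routed down a planted
#' tree to an intended drug; log-IC50 responses are
#' `baseline_d - effect * [d == intended] + N(0, noise_sd)` with per-drug
#' baselines drawn once from N(0, 1) (so per-drug centering is non-trivially
#' exercised).  Optional missingness masks response entries uniformly but
#' never a patient's intended drug, keeping the Oracle and the regret
#' defined.
#'
#' The planted markers follow a prevalence hierarchy (`planted_prevalence`,
#' one rate per tree level): a balanced, common lesion at the root and rarer
#' subordinate lesions below.  Besides mirroring real mutation-frequency
#' hierarchies, the hierarchy is what makes the planted structure
#' identifiable: with one uniform prevalence for all planted markers the
#' greedy split objective ties *exactly* (in expectation) between the root
#' and the subordinate markers, and the tree is recoverable only up to
#' re-rooting, not as the planted topology.
#'
#' @param n_patients,n_markers,n_drugs cohort dimensions.
#' @param depth planted-tree depth (1..3).
#' @param effect benefit gap (log-IC50 units) between each leaf's intended
#'   drug and all others; must be > 0.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param prevalence Bernoulli rate(s) of the non-planted binary markers
#'   (scalar or one per marker).
#' @param planted_prevalence Bernoulli rate of the planted markers by tree
#'   level (root, children, grandchildren).
#' @param continuous_fraction fraction of markers generated as continuous.
#' @param missing_rate fraction of response entries masked (in [0, 1)).
#' @param seed integer seed; the same spec + seed reproduce the cohort
#'   exactly.
#' @param tree optional planted `decision_tree` to use instead of a random
#'   one (its markers must exist among the generated markers).
#' @return list with `Y` (a log_ic50 [sensitivity_matrix()]), `X` (a
#'   [biomarker_matrix()]), and `truth` (planted `tree`, per-patient
#'   `intended` drug, `baselines`).
#' @export
simulate_planted_tree_cohort <- function(n_patients = 200L, n_markers = 30L,
                                         n_drugs = 4L, depth = 2L,
                                         effect = 1, noise_sd = 0.25,
                                         prevalence = 0.3,
                                         planted_prevalence = c(0.5, 0.3,
                                                                0.3),
                                         continuous_fraction = 0,
                                         missing_rate = 0, seed = 1L,
                                         tree = NULL) {
  stopifnot(effect > 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1,
            continuous_fraction >= 0, continuous_fraction <= 1)
  marker_names <- sprintf("g%02d", seq_len(n_markers))
  drug_names <- sprintf("drug%d", seq_len(n_drugs))
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  prevalence <- rep_len(prevalence, n_markers)
  withr::with_seed(seed, {
    n_cont <- round(continuous_fraction * n_markers)
    kind <- setNames(rep("binary", n_markers), marker_names)
    if (n_cont > 0L) kind[sample(marker_names, n_cont)] <- "continuous"
    if (is.null(tree))
      tree <- random_planted_tree(marker_names, drug_names, depth = depth,
                                  marker_kinds = kind)
    else if (!all(tree_markers(tree) %in% marker_names))
      stop("planted tree uses markers not among the generated markers",
           call. = FALSE)
    lvl <- .marker_depths(tree)
    rates <- setNames(prevalence, marker_names)
    rates[names(lvl)] <-
      planted_prevalence[pmin(lvl, length(planted_prevalence))]
    Xv <- sapply(seq_len(n_markers), function(j)
      if (kind[j] == "binary") stats::rbinom(n_patients, 1L, rates[j])
      else stats::rnorm(n_patients))
    dimnames(Xv) <- list(patient_ids, marker_names)
    X <- biomarker_matrix(Xv, column_kind = unname(kind))
    intended <- predict(tree, X)$drug
    baselines <- setNames(stats::rnorm(n_drugs), drug_names)
    Yv <- matrix(baselines, n_patients, n_drugs, byrow = TRUE) -
      effect * outer(intended, drug_names, "==") +
      matrix(stats::rnorm(n_patients * n_drugs, sd = noise_sd),
             n_patients, n_drugs)
    dimnames(Yv) <- list(patient_ids, drug_names)
    if (missing_rate > 0) {
      eligible <- which(outer(intended, drug_names, "!="))
      mask <- sample(eligible, min(round(missing_rate * length(Yv)),
                                   length(eligible)))
      Yv[mask] <- NA_real_
    }
    list(Y = sensitivity_matrix(Yv, scale = "log_ic50"), X = X,
         truth = list(tree = tree,
                      intended = setNames(intended, patient_ids),
                      baselines = baselines))
  })
}

#' Simulate a cohort with sparse linear vote structure
#'
#' Ground truth for the multinomial-lasso fitter: features are standard
#' normal; only `n_active` marker rows of the true coefficient matrix are
#' non-zero (entries N(0, coefficient_scale^2)); responses are built so that
#' lower response corresponds to higher logit, `y_pd = c_d - logit_pd +
#' noise`, with per-drug baselines c_d ~ N(0, 1), then translated so
#' min(Y) = 1 — strictly positive, as the vote formula's strict policy
#' requires.  Each patient's intended drug is the one the response matrix
#' noiselessly favors: the argmax of `logit_pd - c_d` (equivalently the
#' noiseless row argmin of y); with `n_active = 0` it is determined by the
#' baselines alone.
#'
#' @param n_patients,n_markers,n_drugs cohort dimensions.
#' @param n_active number of truly predictive markers (0 for a null cohort).
#' @param coefficient_scale standard deviation of the active coefficients.
#' @param noise_sd response noise standard deviation.
#' @param seed integer seed.
#' @return list with `Y` (log_ic50-scale, strictly positive), `X`, and
#'   `truth` (`active` marker names, `beta` true M x D coefficients,
#'   `intended` drugs, `baselines`).
#' @export
simulate_sparse_linear_cohort <- function(n_patients = 300L,
                                          n_markers = 100L, n_drugs = 4L,
                                          n_active = 5L,
                                          coefficient_scale = 2,
                                          noise_sd = 0.5, seed = 1L) {
  stopifnot(n_active >= 0L, n_active <= n_markers, noise_sd >= 0)
  marker_names <- sprintf("g%03d", seq_len(n_markers))
  drug_names <- sprintf("drug%d", seq_len(n_drugs))
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  withr::with_seed(seed, {
    Xv <- matrix(stats::rnorm(n_patients * n_markers), n_patients, n_markers,
                 dimnames = list(patient_ids, marker_names))
    beta <- matrix(0, n_markers, n_drugs,
                   dimnames = list(marker_names, drug_names))
    active <- if (n_active > 0L) sample(marker_names, n_active)
              else character()
    if (n_active > 0L)
      beta[active, ] <- matrix(stats::rnorm(n_active * n_drugs,
                                            sd = coefficient_scale),
                               n_active, n_drugs)
    logits <- Xv %*% beta
    baselines <- setNames(stats::rnorm(n_drugs), drug_names)
    # intended = the drug the response matrix actually favors (noiselessly,
    # the row argmin of y), i.e. argmax of logit minus per-drug baseline
    net <- sweep(logits, 2L, baselines)
    intended <- drug_names[max.col(net, ties.method = "first")]
    Yv <- matrix(baselines, n_patients, n_drugs, byrow = TRUE) - logits +
      matrix(stats::rnorm(n_patients * n_drugs, sd = noise_sd),
             n_patients, n_drugs)
    Yv <- Yv - min(Yv) + 1          # strictly positive responses
    dimnames(Yv) <- list(patient_ids, drug_names)
    list(Y = sensitivity_matrix(Yv, scale = "log_ic50"),
         X = biomarker_matrix(Xv),
         truth = list(active = sort(active), beta = beta,
                      intended = setNames(intended, patient_ids),
                      baselines = baselines))
  })
}

#' Structural equality of two decision trees
#'
#' TRUE iff the two trees have the same topology, the same marker (and, for
#' continuous splits, threshold within `tol`) at every internal node, and
#' the same drug at every leaf.  Patient counts and objectives are ignored.
#'
#' @param a,b `decision_tree`s.
#' @param tol threshold comparison tolerance.
#' @return logical.
#' @export
same_tree_structure <- function(a, b, tol = 1e-8) {
  eq <- function(na, nb) {
    if (inherits(na, "tree_leaf") || inherits(nb, "tree_leaf"))
      return(inherits(na, "tree_leaf") && inherits(nb, "tree_leaf") &&
               identical(na$drug, nb$drug))
    if (!identical(na$marker, nb$marker)) return(FALSE)
    if (is.null(na$threshold) != is.null(nb$threshold)) return(FALSE)
    if (!is.null(na$threshold) &&
        abs(na$threshold - nb$threshold) > tol) return(FALSE)
    eq(na$if_true, nb$if_true) && eq(na$if_false, nb$if_false)
  }
  eq(a$root, b$root)
}
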