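#' Control parameters for optimal decision-tree fitting
#'
#' @param min_group_size stop recursing into a branch once it holds fewer
#'   patients than this (>= 2; default 10 keeps leaves clinically readable).
#' @param transform response transform used inside the split objective:
#'   `"identity"` or `"signed_sqrt"` (the outlier-damping variant).
#' @param threshold_policy candidate thresholds for continuous markers:
#'   `"midpoints"` between consecutive distinct observed values (default;
#'   exhausts all distinct partitions) or the `"observed_values"` themselves.
#' @param max_depth maximum number of splits on any root-to-leaf path
#'   (`Inf` = unlimited; stopping is normally driven by `min_group_size`).
#' @param na_action `"error"` requires a complete response matrix;
#'   `"mean"` scores branches by per-drug means over observed entries instead
#'   of sums (a documented deviation that avoids biasing drug choice when
#'   observation counts differ).
#' @return an `odt_control` list.
#' @export
odt_control <- function(min_group_size = 10L,
                        transform = c("identity", "signed_sqrt"),
                        threshold_policy = c("midpoints", "observed_values"),
                        max_depth = Inf,
                        na_action = c("error", "mean")) {
  min_group_size <- as.integer(min_group_size)
  if (is.na(min_group_size) || min_group_size < 2L)
    stop("min_group_size must be an integer >= 2", call. = FALSE)
  if (!(is.infinite(max_depth) || max_depth >= 1))
    stop("max_depth must be >= 1 or Inf", call. = FALSE)
  structure(list(min_group_size = min_group_size,
                 transform = match.arg(transform),
                 threshold_policy = match.arg(threshold_policy),
                 max_depth = max_depth,
                 na_action = match.arg(na_action)),
            class = "odt_control")
}

# per-drug branch score: column sums (or observed-entry means) of the
# already-transformed benefit matrix rows given by `rows`
.branch_drug_scores <- function(fY, rows, na_action) {
  sub <- fY[rows, , drop = FALSE]
  if (na_action == "mean") {
    s <- colMeans(sub, na.rm = TRUE)
    s[is.nan(s)] <- -Inf              # drug unobserved in this branch
    s
  } else {
    colSums(sub)
  }
}

#' Score one fully specified split
#'
#' Evaluates the split objective A + B for a given patient partition and drug
#' pair: A is the summed (transformed) benefit of `drug_true` over the
#' masked-in patients, B that of `drug_false` over the rest.
#'
#' @param Y a benefit-scale [sensitivity_matrix()] restricted to the patients
#'   under consideration.
#' @param mask logical vector (one entry per row of `Y`): `TRUE` = goes to
#'   the `drug_true` branch.
#' @param drug_true,drug_false drug names in `colnames(Y)`.
#' @param transform response transform applied before summation.
#' @param na_action see [odt_control()].
#' @return the objective A + B (a number).
#' @export
score_split <- function(Y, mask, drug_true, drug_false,
                        transform = c("identity", "signed_sqrt"),
                        na_action = c("error", "mean")) {
  transform <- match.arg(transform)
  na_action <- match.arg(na_action)
  if (response_scale(Y) != "benefit")
    stop("score_split expects a benefit-scale matrix (see to_benefit())",
         call. = FALSE)
  if (length(mask) != nrow(Y) || !is.logical(mask))
    stop("mask must be a logical vector with one entry per patient",
         call. = FALSE)
  for (d in c(drug_true, drug_false))
    if (!(d %in% colnames(Y)))
      stop("unknown drug '", d, "'", call. = FALSE)
  if (na_action == "error" && anyNA(Y))
    stop("missing response values; use na_action = 'mean' or impute upstream",
         call. = FALSE)
  fY <- unclass(apply_transform(Y, transform))
  A <- if (any(mask)) .branch_drug_scores(fY, mask, na_action)[[drug_true]]
       else 0
  B <- if (any(!mask)) .branch_drug_scores(fY, !mask, na_action)[[drug_false]]
       else 0
  A + B
}

# candidate thresholds for a continuous marker within the current subset
.threshold_candidates <- function(x, policy) {
  v <- sort(unique(x))
  if (length(v) < 2L) return(numeric())
  if (policy == "midpoints") (v[-length(v)] + v[-1L]) / 2 else v[-1L]
}

# exhaustive best split over markers (and thresholds) for the rows of
# fY / X given by `subset`; fY is the transformed benefit matrix.
# Enumeration order (marker index, ascending threshold) plus strict ">"
# replacement and which.max per branch give the deterministic tie-break:
# lexicographically smallest (marker, threshold, drug_true, drug_false)
# among objective-maximal decisions.
.best_split_core <- function(fY, X, subset, control,
                             exclude_markers = character()) {
  kinds <- attr(X, "column_kind")
  markers <- colnames(X)
  best <- NULL
  for (j in seq_along(markers)) {
    if (markers[j] %in% exclude_markers) next
    x <- unclass(X)[subset, j]
    if (kinds[[j]] == "binary") {
      masks <- list(x == 1)
      ths <- list(NULL)
    } else {
      cand <- .threshold_candidates(x, control$threshold_policy)
      masks <- lapply(cand, function(th) x >= th)
      ths <- as.list(cand)
    }
    for (k in seq_along(masks)) {
      m <- masks[[k]]
      n_true <- sum(m)
      if (n_true == 0L || n_true == length(m)) next
      s_true <- .branch_drug_scores(fY, subset[m], control$na_action)
      s_false <- .branch_drug_scores(fY, subset[!m], control$na_action)
      d1 <- which.max(s_true)
      d2 <- which.max(s_false)
      obj <- s_true[[d1]] + s_false[[d2]]
      if (is.null(best) || obj > best$objective) {
        best <- structure(list(marker = markers[j], threshold = ths[[k]],
                               drug_true = colnames(fY)[d1],
                               drug_false = colnames(fY)[d2],
                               objective = obj,
                               n_true = n_true,
                               n_false = length(m) - n_true),
                          class = "split_decision")
      }
    }
  }
  best
}

#' Find the optimal single split for a patient subset
#'
#' Exhaustively enumerates every biomarker (and, for continuous markers,
#' every candidate threshold), and for each resulting two-sided partition
#' picks the best drug per branch independently — the drug pair maximizing
#' A + B decomposes branch-wise, so the inner search is O(D), not O(D^2).
#' Ties are broken deterministically towards the lexicographically smallest
#' (marker index, threshold, drug_true index, drug_false index).
#'
#' @param Y a benefit-scale [sensitivity_matrix()] (all patients).
#' @param X an aligned [biomarker_matrix()].
#' @param subset integer indices of the patients under consideration
#'   (default: all).
#' @param control an [odt_control()]; its `transform` is applied to `Y`
#'   before scoring.
#' @param exclude_markers marker names not eligible (used by the recursion to
#'   forbid re-use along a path).
#' @return a `split_decision` (marker, threshold or NULL, drug_true,
#'   drug_false, objective, branch sizes), or `NULL` when no marker splits
#'   the subset into two non-empty sides.
#' @export
find_best_split <- function(Y, X, subset = seq_len(nrow(Y)),
                            control = odt_control(),
                            exclude_markers = character()) {
  if (response_scale(Y) != "benefit")
    stop("find_best_split expects a benefit-scale matrix", call. = FALSE)
  check_aligned(Y, X)
  if (control$na_action == "error" && anyNA(unclass(Y)[subset, ]))
    stop("missing response values; use na_action = 'mean'", call. = FALSE)
  if (length(subset) < 2L) return(NULL)
  fY <- unclass(apply_transform(Y, control$transform))
  .best_split_core(fY, X, subset, control)
}

#' Fit an optimal decision tree for drug assignment
#'
#' Recursively partitions the cohort: each node jointly selects the
#' biomarker (and threshold, for continuous markers) and one drug per branch
#' that maximize the summed transformed benefit of the two branches, then
#' recurses into each branch.  A branch becomes a leaf — labelled with its
#' best single drug — when it is smaller than `min_group_size`, when the best
#' split recommends the same drug on both sides, when no valid split exists,
#' or when `max_depth` is reached.  Markers are never re-used along a single
#' root-to-leaf path (re-use across sibling subtrees is allowed).
#'
#' @param Y a [sensitivity_matrix()] on any scale; IC50-type scales are
#'   flipped to benefit internally, so the tree always minimizes the
#'   patient's (transformed) IC50*.
#' @param X an aligned [biomarker_matrix()].
#' @param control an [odt_control()].
#' @return a `decision_tree` whose nodes record patient counts and split
#'   objectives.  The training-time assignment (leaf drug per training
#'   patient) is attached as `attr(tree, "training_assignment")`.
#' @examples
#' sim <- simulate_planted_tree_cohort(n_patients = 120, n_markers = 8,
#'                                     n_drugs = 4, seed = 1)
#' tree <- fit_odt(compute_ic50_star(sim$Y), sim$X)
#' print(tree)
#' @export
fit_odt <- function(Y, X, control = odt_control()) {
  check_aligned(Y, X)
  if (nrow(Y) == 0L) stop("no patients to fit on", call. = FALSE)
  if (control$na_action == "error" && anyNA(unclass(Y)))
    stop("missing response values; set na_action = 'mean' in odt_control()",
         call. = FALSE)
  sense <- if (response_scale(Y) == "benefit") "maximize" else "minimize"
  B <- if (sense == "minimize") to_benefit(Y) else Y
  fY <- unclass(apply_transform(B, control$transform))
  patient_ids <- rownames(Y)
  assigned <- setNames(rep(NA_character_, nrow(Y)), patient_ids)

  make_leaf <- function(subset, drug = NULL) {
    if (is.null(drug)) {
      s <- .branch_drug_scores(fY, subset, control$na_action)
      drug <- colnames(fY)[which.max(s)]
    }
    assigned[patient_ids[subset]] <<- drug
    tree_leaf(drug, n_patients = length(subset))
  }

  recurse <- function(subset, used, depth) {
    if (length(subset) < control$min_group_size || depth >= control$max_depth)
      return(make_leaf(subset))
    s <- .best_split_core(fY, X, subset, control, exclude_markers = used)
    if (is.null(s)) return(make_leaf(subset))
    if (identical(s$drug_true, s$drug_false))
      return(make_leaf(subset, drug = s$drug_true))
    x <- unclass(X)[subset, s$marker]
    m <- if (is.null(s$threshold)) x == 1 else x >= s$threshold
    tree_split(s$marker, threshold = s$threshold,
               if_true = recurse(subset[m], c(used, s$marker), depth + 1L),
               if_false = recurse(subset[!m], c(used, s$marker), depth + 1L),
               n_patients = length(subset), objective = s$objective)
  }

  root <- recurse(seq_len(nrow(Y)), character(), 0L)
  tree <- decision_tree(root, min_group_size = control$min_group_size,
                        transform = control$transform, sense = sense,
                        drug_names = colnames(Y))
  attr(tree, "training_assignment") <-
    new_assignment(patient_ids, assigned,
                   achieved_value = unclass(Y)[cbind(seq_along(assigned),
                                                     match(assigned,
                                                           colnames(Y)))])
  tree
}

#' Route patients down a fitted tree
#'
#' Binary splits send patients with marker value 1 to the true branch;
#' continuous splits send `x >= threshold` to the true branch.
#'
#' @param object a `decision_tree`.
#' @param X a [biomarker_matrix()] containing every marker the tree uses.
#' @param Y optional [sensitivity_matrix()] aligned with `X`; when given, the
#'   achieved response of the assigned drug is filled in.
#' @param ... unused.
#' @return a `drug_assignment` data frame (patient_id, drug, value).
#' @export
predict.decision_tree <- function(object, X, Y = NULL, ...) {
  missing_markers <- setdiff(tree_markers(object), colnames(X))
  if (length(missing_markers))
    stop("biomarker matrix lacks marker(s) used by the tree: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  route <- function(node, p) {
    while (inherits(node, "tree_split")) {
      x <- unclass(X)[p, node$marker]
      go_true <- if (is.null(node$threshold)) x == 1 else x >= node$threshold
      node <- if (go_true) node$if_true else node$if_false
    }
    node$drug
  }
  drugs <- vapply(seq_len(nrow(X)), function(p) route(object$root, p),
                  character(1L))
  value <- if (is.null(Y)) NA_real_
           else {
             check_aligned(Y, X)
             unclass(Y)[cbind(seq_len(nrow(X)), match(drugs, colnames(Y)))]
           }
  new_assignment(rownames(X), drugs, value)
}

# Assignment container: one recommended drug per patient, optionally with the
# measured response that recommendation achieved.
new_assignment <- function(patient_ids, drug, achieved_value = NA_real_) {
  structure(data.frame(patient_id = patient_ids, drug = drug,
                       value = achieved_value,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("drug_assignment", "data.frame"))
}
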