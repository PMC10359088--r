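#' Decision-tree node constructors
#'
#' A fitted drug-assignment tree is built from two node types: internal
#' splits and leaves.  A split tests one biomarker — presence/absence for a
#' binary marker (no threshold), or `x >= threshold` for a continuous marker —
#' and routes patients to `if_true` / `if_false`.  A leaf names the drug
#' recommended to every patient that reaches it.
#'
#' @param drug leaf drug name.
#' @param n_patients number of training patients routed to the node (NA for
#'   hand-built trees).
#' @return a `tree_leaf` / `tree_split` list.
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
tree_leaf <- function(drug, n_patients = NA_integer_) {
  stopifnot(is.character(drug), length(drug) == 1L)
  structure(list(drug = drug, n_patients = as.integer(n_patients)),
            class = "tree_leaf")
}

#' @rdname tree-nodes
#' @param marker biomarker name tested at the split.
#' @param threshold numeric threshold for a continuous marker; `NULL` for a
#'   binary (mutation present/absent) split.
#' @param if_true,if_false child node (`tree_split`/`tree_leaf`) or a drug
#'   name, taken when the condition holds / fails.
#' @param objective value of the optimized split criterion (sum of transformed
#'   benefit over both branches), recorded during fitting.
#' @export
tree_split <- function(marker, threshold = NULL, if_true, if_false,
                       n_patients = NA_integer_, objective = NA_real_) {
  stopifnot(is.character(marker), length(marker) == 1L)
  if (!is.null(threshold)) {
    stopifnot(is.numeric(threshold), length(threshold) == 1L,
              is.finite(threshold))
    threshold <- as.numeric(threshold)
  }
  as_node <- function(x) if (is.character(x)) tree_leaf(x) else x
  structure(list(marker = marker, threshold = threshold,
                 if_true = as_node(if_true), if_false = as_node(if_false),
                 n_patients = as.integer(n_patients),
                 objective = as.numeric(objective)),
            class = "tree_split")
}

#' Assemble a decision tree
#'
#' @param root a `tree_split`, `tree_leaf`, or single drug name.
#' @param min_group_size stopping size used (or to be used) when fitting.
#' @param transform response transform applied inside the split criterion:
#'   `"identity"` or `"signed_sqrt"`.
#' @param sense optimization sense of the original response scale:
#'   `"minimize"` for IC50-type inputs, `"maximize"` for benefit inputs.
#' @param drug_names optional drug vocabulary; when given, every leaf drug
#'   must belong to it.
#' @return a `decision_tree` object.
#' @export
decision_tree <- function(root, min_group_size = 10L,
                          transform = c("identity", "signed_sqrt"),
                          sense = c("minimize", "maximize"),
                          drug_names = NULL) {
  transform <- match.arg(transform)
  sense <- match.arg(sense)
  if (is.character(root)) root <- tree_leaf(root)
  tree <- structure(list(root = root,
                         min_group_size = as.integer(min_group_size),
                         transform = transform, sense = sense),
                    class = "decision_tree")
  validate_tree(tree, drug_names = drug_names)
  tree
}

#' Validate decision-tree invariants
#'
#' Checks that no root-to-leaf path re-uses a marker, that no split carries
#' the same leaf drug on both branches, and (optionally) that all leaf drugs
#' belong to a vocabulary.
#'
#' @param tree a `decision_tree`.
#' @param drug_names optional drug vocabulary.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree, drug_names = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  walk <- function(node, seen) {
    if (inherits(node, "tree_leaf")) {
      if (!is.null(drug_names) && !(node$drug %in% drug_names))
        stop("leaf drug '", node$drug, "' not in the drug vocabulary",
             call. = FALSE)
      return(invisible(NULL))
    }
    if (node$marker %in% seen)
      stop("marker '", node$marker, "' re-used along a root-to-leaf path",
           call. = FALSE)
    if (inherits(node$if_true, "tree_leaf") &&
        inherits(node$if_false, "tree_leaf") &&
        identical(node$if_true$drug, node$if_false$drug))
      stop("split on '", node$marker,
           "' assigns the same drug to both branches", call. = FALSE)
    walk(node$if_true, c(seen, node$marker))
    walk(node$if_false, c(seen, node$marker))
  }
  walk(tree$root, character())
  invisible(tree)
}

#' Markers used by a tree
#' @param tree a `decision_tree`.
#' @return character vector of distinct marker names, in first-use order.
#' @export
tree_markers <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (inherits(node, "tree_split")) {
      out <<- union(out, node$marker)
      walk(node$if_true); walk(node$if_false)
    }
  }
  walk(tree$root)
  out
}

tree_leaves <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (inherits(node, "tree_leaf")) out <<- c(out, node$drug)
    else { walk(node$if_true); walk(node$if_false) }
  }
  walk(tree$root)
  out
}

#' Serialize a decision tree
#'
#' `"json"` round-trips losslessly through [read_tree()]; `"dot"` produces a
#' Graphviz digraph with one node per split/leaf and edges labelled
#' true/false; `"text"` prints one indented line per node.
#'
#' @param tree a fitted or hand-built `decision_tree`.
#' @param format `"json"`, `"dot"` or `"text"`.
#' @param path optional file to write to.
#' @return the serialized text (a character scalar), invisibly if `path`
#'   is given.
#' @export
write_tree <- function(tree, format = c("json", "dot", "text"), path = NULL) {
  format <- match.arg(format)
  if (!inherits(tree, "decision_tree") || is.null(tree$root))
    stop("not a fitted decision tree", call. = FALSE)
  validate_tree(tree)
  out <- switch(format,
                json = .tree_to_json(tree),
                dot = .tree_to_dot(tree),
                text = .tree_to_text(tree))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

.node_to_list <- function(node) {
  if (inherits(node, "tree_leaf")) {
    out <- list(type = "leaf", drug = node$drug)
    if (!is.na(node$n_patients)) out$n_patients <- node$n_patients
    return(out)
  }
  out <- list(type = "split",
              kind = if (is.null(node$threshold)) "binary" else "continuous",
              marker = node$marker)
  if (!is.null(node$threshold)) out$threshold <- node$threshold
  if (!is.na(node$n_patients)) out$n_patients <- node$n_patients
  if (!is.na(node$objective)) out$objective <- node$objective
  out$if_true <- .node_to_list(node$if_true)
  out$if_false <- .node_to_list(node$if_false)
  out
}

.tree_to_json <- function(tree) {
  obj <- list(min_group_size = tree$min_group_size,
              transform = tree$transform, sense = tree$sense,
              root = .node_to_list(tree$root))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null", pretty = TRUE))
}

.tree_to_dot <- function(tree) {
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  counter <- 0L
  emit <- function(node) {
    counter <<- counter + 1L
    id <- paste0("n", counter)
    if (inherits(node, "tree_leaf")) {
      lines <<- c(lines, sprintf("  %s [label=\"%s\", shape=ellipse];",
                                 id, node$drug))
    } else {
      lab <- if (is.null(node$threshold)) node$marker
             else sprintf("%s >= %g", node$marker, node$threshold)
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, lab))
      t_id <- emit(node$if_true)
      f_id <- emit(node$if_false)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"true\"];", id, t_id),
                  sprintf("  %s -> %s [label=\"false\"];", id, f_id))
    }
    id
  }
  emit(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

.tree_to_text <- function(tree) {
  lines <- character()
  walk <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (inherits(node, "tree_leaf")) {
      n <- if (is.na(node$n_patients)) "" else sprintf(" (n=%d)",
                                                       node$n_patients)
      lines <<- c(lines, sprintf("%s%s=> %s%s", pad, prefix, node$drug, n))
    } else {
      cond <- if (is.null(node$threshold)) sprintf("%s == 1", node$marker)
              else sprintf("%s >= %g", node$marker, node$threshold)
      lines <<- c(lines, sprintf("%s%sif %s", pad, prefix, cond))
      walk(node$if_true, indent + 1L, "[true] ")
      walk(node$if_false, indent + 1L, "[false] ")
    }
  }
  walk(tree$root, 0L, "")
  paste(lines, collapse = "\n")
}

#' Deserialize a decision tree from JSON
#'
#' @param text JSON produced by [write_tree()] (or a path to such a file).
#' @param drug_names optional drug vocabulary; leaf drugs outside it error.
#' @return a `decision_tree` equal to the serialized one.
#' @export
read_tree <- function(text, drug_names = NULL) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop("invalid tree JSON: ", conditionMessage(e),
                         call. = FALSE))
  for (f in c("min_group_size", "transform", "sense", "root"))
    if (is.null(obj[[f]]))
      stop("tree JSON missing field '", f, "'", call. = FALSE)
  parse_node <- function(x) {
    if (is.null(x$type)) stop("tree JSON node missing 'type'", call. = FALSE)
    if (x$type == "leaf") {
      return(tree_leaf(x$drug,
                       if (is.null(x$n_patients)) NA_integer_
                       else x$n_patients))
    }
    if (x$type != "split")
      stop("unknown node type '", x$type, "'", call. = FALSE)
    if (identical(x$kind, "binary") && !is.null(x$threshold))
      stop("binary split on '", x$marker,
           "' must not carry a threshold", call. = FALSE)
    if (identical(x$kind, "continuous") && is.null(x$threshold))
      stop("continuous split on '", x$marker,
           "' requires a threshold", call. = FALSE)
    tree_split(x$marker, threshold = x$threshold,
               if_true = parse_node(x$if_true),
               if_false = parse_node(x$if_false),
               n_patients = if (is.null(x$n_patients)) NA_integer_
                            else x$n_patients,
               objective = if (is.null(x$objective)) NA_real_
                           else x$objective)
  }
  decision_tree(parse_node(obj$root),
                min_group_size = obj$min_group_size,
                transform = obj$transform, sense = obj$sense,
                drug_names = drug_names)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("decision_tree (transform: %s, sense: %s, min_group_size: %d)\n",
              x$transform, x$sense, x$min_group_size))
  cat(.tree_to_text(x), "\n")
  invisible(x)
}
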