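#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the
#' closest pair of clusters; distances from the merged cluster to the rest
#' are member-count-weighted averages (equivalently, means over the
#' original pairwise distances).  Node heights are half the merge
#' distance, so the tree is ultrametric.  Ties in the minimum are broken
#' by the lexicographically smallest label pair (a cluster is labelled by
#' its smallest member), making the result fully deterministic.
#'
#' @param dist a [p_distance_matrix()] result, or a symmetric numeric
#'   matrix with dimnames.
#' @return an `upgma_tree`: list with `labels` and `nodes`; each internal
#'   node records `members` (sorted leaf names), `height`, `children`
#'   (leaf names or node indices) and a `support` slot filled by
#'   [bootstrap_support()].
#' @export
upgma <- function(dist) {
  D <- if (inherits(dist, "p_dist")) dist$values else as.matrix(dist)
  stopifnot(nrow(D) >= 2, !is.null(rownames(D)))
  labels <- rownames(D)
  # active cluster bookkeeping
  act <- lapply(labels, function(l)
    list(label = l, members = l, size = 1L, height = 0, node = NA_integer_))
  names(act) <- labels
  Dw <- D
  nodes <- list()
  while (length(act) > 1) {
    labs <- names(act)
    best <- NULL
    for (i in seq_len(length(labs) - 1)) {
      for (j in (i + 1):length(labs)) {
        pair <- sort(c(labs[i], labs[j]))
        d <- Dw[labs[i], labs[j]]
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(d = d, pair = pair)
        }
      }
    }
    ci <- act[[best$pair[1]]]
    cj <- act[[best$pair[2]]]
    node <- list(
      members = sort(c(ci$members, cj$members)),
      height = best$d / 2,
      children = list(
        if (is.na(ci$node)) ci$label else ci$node,
        if (is.na(cj$node)) cj$label else cj$node),
      support = NA_real_)
    nodes[[length(nodes) + 1]] <- node
    new_lab <- best$pair[1]  # smallest member name
    other <- setdiff(names(act), best$pair)
    for (k in other) {
      Dw[new_lab, k] <- Dw[k, new_lab] <-
        (ci$size * Dw[ci$label, k] + cj$size * Dw[cj$label, k]) /
        (ci$size + cj$size)
    }
    act[[best$pair[2]]] <- NULL
    act[[new_lab]] <- list(label = new_lab,
                           members = node$members,
                           size = ci$size + cj$size,
                           height = node$height,
                           node = length(nodes))
  }
  structure(list(labels = sort(labels), nodes = nodes),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", length(x$labels), "leaves, root height",
      format(x$nodes[[length(x$nodes)]]$height, digits = 4), "\n")
  invisible(x)
}

# Sorted-member keys of all internal nodes (used for bootstrap matching
# and group assignment).  Rooted trees: clades, not unrooted bipartitions.
clade_keys <- function(tree) {
  vapply(tree$nodes, function(nd) paste(nd$members, collapse = "\r"),
         character(1))
}

#' Newick string of a UPGMA tree
#'
#' Branch lengths are differences of ultrametric node heights.
#'
#' @param tree an `upgma_tree`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string (terminated by `;`).
#' @export
upgma_newick <- function(tree, digits = 15) {
  root <- length(tree$nodes)
  rec <- function(child, parent_h) {
    if (is.character(child)) {
      sprintf("%s:%s", child, format(parent_h, digits = digits))
    } else {
      nd <- tree$nodes[[child]]
      kids <- vapply(nd$children, rec, character(1), parent_h = nd$height)
      sprintf("(%s):%s", paste(kids, collapse = ","),
              format(parent_h - nd$height, digits = digits))
    }
  }
  nd <- tree$nodes[[root]]
  kids <- vapply(nd$children, rec, character(1), parent_h = nd$height)
  sprintf("(%s);", paste(kids, collapse = ","))
}

#' Bootstrap support for UPGMA clades
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' matrix and UPGMA tree for each pseudo-replicate, and reports for every
#' internal clade of the reference tree the fraction of replicates whose
#' tree contains the same leaf set.  A replicate in which some pair has no
#' co-scored sites is redrawn (at most 10 retries, then an error).
#' Deterministic given the seed.
#'
#' @param seqs named aligned sequences (the alleles being clustered).
#' @param n_reps number of pseudo-replicates (>= 1); 1000 in typical use.
#' @param seed integer seed.
#' @param tree optional precomputed reference `upgma_tree`.
#' @return the reference tree with per-node `support` filled in; the
#'   support vector is attached as attribute `"support"`.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000, seed = 1, tree = NULL) {
  stopifnot(n_reps >= 1)
  mat <- if (is.matrix(seqs)) seqs else seqs_to_matrix(seqs)
  tree <- tree %||% upgma(p_distance_matrix(mat))
  ref_keys <- clade_keys(tree)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  L <- ncol(mat)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      rep_tree <- NULL
      for (attempt in seq_len(10)) {
        cols <- sample.int(L, L, replace = TRUE)
        pd <- tryCatch(p_distance_matrix(mat[, cols, drop = FALSE]),
                       error = function(e) NULL)
        if (!is.null(pd)) {
          rep_tree <- upgma(pd)
          break
        }
      }
      if (is.null(rep_tree)) {
        stop("bootstrap replicate failed 10 times: an all-gap pair keeps ",
             "being resampled")
      }
      hit <- ref_keys %in% clade_keys(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / n_reps
  for (k in seq_along(tree$nodes)) tree$nodes[[k]]$support <- support[[k]]
  attr(tree, "support") <- support
  tree
}

#' Assign alleles to allele groups from a supported UPGMA tree
#'
#' Groups are the maximal clades whose bootstrap support is at least
#' `min_support` and whose node height is at most `max_within_distance`.
#' The root clade qualifies on height alone (its "bipartition" is trivial,
#' so no support requirement applies).  Leaves contained in no qualifying
#' clade become singleton groups.  Group labels are `"A"`, `"B"`, ... in
#' order of decreasing size, ties broken by smallest member id.
#'
#' @param tree an `upgma_tree` with supports (see [bootstrap_support()]);
#'   a tree without supports is accepted only when `min_support = 0`.
#' @param min_support minimum clade bootstrap support (default 0.70).
#' @param max_within_distance maximum clade height (default 0.03).
#' @param locus locus name recorded on the output.
#' @return data frame (`locus`, `allele_id`, `group_label`, `support`,
#'   `is_singleton`), one row per allele.
#' @export
assign_allele_groups <- function(tree, min_support = 0.70,
                                 max_within_distance = 0.03,
                                 locus = "locus") {
  stopifnot(inherits(tree, "upgma_tree"))
  root <- length(tree$nodes)
  groups <- list()
  visit <- function(child) {
    if (is.character(child)) {  # bare leaf -> singleton group
      groups[[length(groups) + 1]] <<- list(members = child,
                                            support = NA_real_)
      return(invisible())
    }
    nd <- tree$nodes[[child]]
    sup <- nd$support
    ok_height <- nd$height <= max_within_distance
    ok_support <- if (child == root) TRUE else
      (!is.na(sup) && sup >= min_support) || min_support <= 0
    if (ok_height && ok_support) {
      groups[[length(groups) + 1]] <<- list(
        members = nd$members,
        support = if (child == root) 1.0 else sup)
    } else {
      for (ch in nd$children) visit(ch)
    }
  }
  visit(root)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  first <- vapply(groups, function(g) min(g$members), character(1))
  ord <- order(-sizes, first)
  groups <- groups[ord]
  labels <- group_labels(length(groups))
  out <- do.call(rbind, lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    data.frame(locus = locus, allele_id = g$members, group_label = labels[k],
               support = if (length(g$members) >= 2) g$support else NA_real_,
               is_singleton = length(g$members) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
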