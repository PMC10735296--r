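#' Parental node of a focal leaf
#'
#' The parental node v of a focal leaf u in a local tree is the first node
#' on the path from u to the root: u's immediate parent. A leaf with no
#' parent edge (detached in this tree) has no parental node; that is an
#' error here — callers that tolerate detachment must catch it and decide
#' how to treat the tree's span.
#'
#' @param tree a [local_tree].
#' @param u focal leaf id.
#' @return the parent node id (integer).
#' @export
parental_node <- function(tree, u) {
  u <- as.integer(u)
  if (!(u %in% tree$leaves)) stop("focal leaf ", u, " is not in the tree")
  p <- tree$parent[u + 1L]
  if (is.na(p)) {
    stop("no parental node: leaf ", u, " is detached in this tree")
  }
  p
}

#' Genealogical neighbor set of a focal leaf
#'
#' All sample leaves descending from the focal leaf's parental node,
#' excluding the focal leaf itself. Under a multifurcating parental node
#' the set simply contains every other leaf child and every leaf of every
#' sibling subtree — the definition needs no modification for polytomies.
#'
#' @param tree a [local_tree].
#' @param u focal leaf id.
#' @return integer vector of leaf ids (never contains `u`; sorted).
#' @export
neighbor_set <- function(tree, u) {
  v <- parental_node(tree, u)
  n <- length(tree$parent)
  children <- vector("list", n)
  for (node in seq_len(n) - 1L) {
    p <- tree$parent[node + 1L]
    if (!is.na(p)) children[[p + 1L]] <- c(children[[p + 1L]], node)
  }
  is_leaf <- rep(FALSE, n)
  is_leaf[tree$leaves + 1L] <- TRUE
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    if (is_leaf[node + 1L]) out <- c(out, node)
    stack <- c(stack, children[[node + 1L]])
  }
  sort(setdiff(out, u))
}

#' Neighbor indicator I_{u,t}(x)
#'
#' 1 if leaf x lies in the neighbor set of focal leaf u in this tree,
#' else 0. Defined on x != u only: the neighbor set excludes the focal
#' leaf by construction.
#'
#' @param tree a [local_tree].
#' @param u focal leaf id.
#' @param x candidate neighbor leaf id, `x != u`.
#' @return 0 or 1 (integer).
#' @export
indicator <- function(tree, u, x) {
  u <- as.integer(u); x <- as.integer(x)
  if (u == x) stop("indicator is defined on X \\ {u}: x must differ from u")
  if (!(x %in% tree$leaves)) stop("leaf ", x, " is not in the tree")
  as.integer(x %in% neighbor_set(tree, u))
}

# ---- per-tree neighbor sets for many focals at once --------------------
#
# One pass over a tree serves every focal leaf: walk each leaf up to the
# root, appending it to the leaf-list of every ancestor; the neighbor set
# of focal u is then leafset[parent(u)] minus u. This path-accumulation
# route is deliberately different from the recursive subtree collection in
# neighbor_set(), so the two act as independent implementations of the
# same definition.
.tree_neighbor_sets <- function(tree, focals) {
  n <- length(tree$parent)
  leafset <- vector("list", n)
  for (l in tree$leaves) {
    v <- tree$parent[l + 1L]
    while (!is.na(v)) {
      leafset[[v + 1L]] <- c(leafset[[v + 1L]], l)
      v <- tree$parent[v + 1L]
    }
  }
  out <- vector("list", length(focals))
  for (i in seq_along(focals)) {
    u <- focals[i]
    p <- tree$parent[u + 1L]
    if (!is.na(p)) {          # detached focals keep their NULL slot
      nb <- leafset[[p + 1L]]
      out[[i]] <- nb[nb != u]
    }
  }
  out
}

#' Span- and tree-weighted neighbor profiles for one or more focal leaves
#'
#' Workhorse behind [span_weighted_gnn()] and [tree_fraction_gnn()]. For
#' each requested focal leaf u it computes, over the tree sequence, for
#' every other leaf x:
#' * `G[u, x]` — the fraction of local trees in which x is a genealogical
#'   neighbor of u, and
#' * `P[u, x]` — the fraction of the genome (span-weighted) for which x is
#'   a neighbor of u.
#'
#' Spans are accumulated as exact base-pair sums and divided once at the
#' end. Trees in which the focal leaf is detached contribute to neither
#' the numerator nor the denominator: `P` is then a proportion of the
#' `effective_span` (the genome where u has a genealogy at all), and `G`
#' a proportion of the attached trees.
#'
#' @param ts a [tree_sequence_view].
#' @param focals integer vector of focal leaf ids; `NULL` means all
#'   sample leaves.
#' @return a named list of `neighbor_profile` objects (names = focal leaf
#'   ids). Each profile carries `span_fraction` / `tree_fraction` (named
#'   numeric vectors over all other leaves, zeros included), the raw
#'   accumulators `span_bp` / `tree_count`, `total_span`, `effective_span`,
#'   `n_trees`, `n_trees_attached`, the per-tree neighbor sets
#'   (`tree_neighbors`, with `NULL` for detached trees) and `tree_spans`.
#' @export
gnn_profiles <- function(ts, focals = NULL) {
  leaf_set <- ts$samples$leaf_id
  if (is.null(focals)) focals <- leaf_set
  focals <- as.integer(focals)
  if (!all(focals %in% leaf_set)) {
    stop("focal leaf(s) not in the sample set: ",
         paste(setdiff(focals, leaf_set), collapse = ", "))
  }
  if (n_trees(ts) < 1L) stop("empty tree sequence")
  nf <- length(focals)
  nl <- length(leaf_set)
  pos <- stats::setNames(seq_len(nl), as.character(leaf_set))
  span_bp <- matrix(0, nrow = nf, ncol = nl)      # numerators, base pairs
  tree_count <- matrix(0L, nrow = nf, ncol = nl)
  eff_span <- numeric(nf)
  n_attached <- integer(nf)
  m <- n_trees(ts)
  tree_nb <- lapply(seq_len(nf), function(i) vector("list", m))
  spans <- vapply(ts$trees, tree_span, numeric(1))
  for (ti in seq_len(m)) {
    nbs <- .tree_neighbor_sets(ts$trees[[ti]], focals)
    lt <- spans[ti]
    for (i in seq_len(nf)) {
      nb <- nbs[[i]]
      if (is.null(nb)) next
      eff_span[i] <- eff_span[i] + lt
      n_attached[i] <- n_attached[i] + 1L
      tree_nb[[i]][[ti]] <- as.integer(nb)
      if (length(nb)) {
        j <- pos[as.character(nb)]
        span_bp[i, j] <- span_bp[i, j] + lt
        tree_count[i, j] <- tree_count[i, j] + 1L
      }
    }
  }
  L <- sum(spans)
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    u <- focals[i]
    if (n_attached[i] == 0L) {
      stop("focal never attached: leaf ", u,
           " is detached in every tree of ", ts$chromosome_id)
    }
    keep <- leaf_set != u
    nm <- as.character(leaf_set[keep])
    out[[i]] <- structure(
      list(
        focal = u,
        chromosome_id = ts$chromosome_id,
        span_fraction = stats::setNames(span_bp[i, keep] / eff_span[i], nm),
        tree_fraction = stats::setNames(tree_count[i, keep] / n_attached[i], nm),
        span_bp = stats::setNames(span_bp[i, keep], nm),
        tree_count = stats::setNames(as.numeric(tree_count[i, keep]), nm),
        total_span = L,
        effective_span = eff_span[i],
        n_trees = m,
        n_trees_attached = n_attached[i],
        tree_spans = spans,
        tree_neighbors = tree_nb[[i]]
      ),
      class = "neighbor_profile"
    )
  }
  stats::setNames(out, as.character(focals))
}

#' @export
print.neighbor_profile <- function(x, ...) {
  cat(sprintf(
    "<neighbor_profile focal=%d %s: %d trees (%d attached), L=%g, effective=%g>\n",
    x$focal, x$chromosome_id, x$n_trees, x$n_trees_attached,
    x$total_span, x$effective_span))
  top <- sort(x$span_fraction, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    show <- utils::head(top, 5L)
    cat("  top P: ", paste(sprintf("%s=%.4f", names(show), show),
                           collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Span-weighted genealogical nearest-neighbor profile P_{u,x}
#'
#' For a focal leaf u, `P[u, x]` is the proportion of the genome for which
#' u and x are genealogical neighbors: the sum of the spans of the local
#' trees where x descends from u's parental node, divided by the total
#' span where u is attached.
#'
#' @param ts a [tree_sequence_view].
#' @param u focal leaf id.
#' @return a `neighbor_profile` (see [gnn_profiles()]).
#' @export
span_weighted_gnn <- function(ts, u) {
  gnn_profiles(ts, focals = u)[[1L]]
}

#' Tree-fraction genealogical nearest-neighbor values G_{u,x}
#'
#' `G[u, x]` is the proportion of local trees in which x is a neighbor of
#' u — the unweighted (per-tree) counterpart of [span_weighted_gnn()].
#'
#' @param ts a [tree_sequence_view].
#' @param u focal leaf id.
#' @return named numeric vector over all other leaves.
#' @export
tree_fraction_gnn <- function(ts, u) {
  gnn_profiles(ts, focals = u)[[1L]]$tree_fraction
}

#' Naive reference implementation of the neighbor profile
#'
#' Loops over every local tree, recomputes the neighbor set from scratch
#' with [neighbor_set()] (recursive subtree collection, no shared state,
#' no incremental updates), and accumulates spans and tree counts. Slow by
#' design; exists as the independent oracle against which
#' [span_weighted_gnn()] must agree to within 1e-12.
#'
#' @param ts a [tree_sequence_view].
#' @param u focal leaf id.
#' @return a `neighbor_profile`.
#' @export
oracle_gnn_prime <- function(ts, u) {
  u <- as.integer(u)
  leaf_set <- ts$samples$leaf_id
  if (!(u %in% leaf_set)) stop("focal leaf ", u, " not in the sample set")
  if (n_trees(ts) < 1L) stop("empty tree sequence")
  others <- setdiff(leaf_set, u)
  nm <- as.character(others)
  span_bp <- stats::setNames(numeric(length(others)), nm)
  tree_count <- stats::setNames(numeric(length(others)), nm)
  eff <- 0; attached <- 0L
  m <- n_trees(ts)
  tree_nb <- vector("list", m)
  spans <- numeric(m)
  for (ti in seq_len(m)) {
    tr <- ts$trees[[ti]]
    spans[ti] <- tree_span(tr)
    nb <- tryCatch(neighbor_set(tr, u), error = function(e) NULL)
    if (is.null(nb)) next
    eff <- eff + spans[ti]
    attached <- attached + 1L
    tree_nb[[ti]] <- nb
    k <- as.character(nb)
    span_bp[k] <- span_bp[k] + spans[ti]
    tree_count[k] <- tree_count[k] + 1
  }
  if (attached == 0L) {
    stop("focal never attached: leaf ", u,
         " is detached in every tree of ", ts$chromosome_id)
  }
  structure(
    list(
      focal = u, chromosome_id = ts$chromosome_id,
      span_fraction = span_bp / eff,
      tree_fraction = tree_count / attached,
      span_bp = span_bp, tree_count = tree_count,
      total_span = sum(spans), effective_span = eff,
      n_trees = m, n_trees_attached = attached,
      tree_spans = spans, tree_neighbors = tree_nb
    ),
    class = "neighbor_profile"
  )
}

#' Aggregate per-chromosome neighbor profiles genome-wide
#'
#' Combines profiles of the same focal leaf across chromosomes by summing
#' the exact base-pair and tree-count accumulators and dividing once:
#' genome-wide P is span-weighted over chromosomes (never an unweighted
#' mean of per-chromosome proportions) and genome-wide G is weighted by
#' per-chromosome attached-tree counts. Per-tree neighbor sets are
#' concatenated so accession-level collapsing still works on the result.
#'
#' @param profiles list of `neighbor_profile` objects, one per chromosome,
#'   same focal leaf and same leaf universe.
#' @return a genome-wide `neighbor_profile` with
#'   `chromosome_id = "genome"`.
#' @export
aggregate_genome <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  chroms <- vapply(profiles, function(p) p$chromosome_id, character(1))
  if (anyDuplicated(chroms)) {
    stop("duplicated chromosome_id: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  focal <- profiles[[1L]]$focal
  nm <- names(profiles[[1L]]$span_bp)
  for (p in profiles[-1L]) {
    if (p$focal != focal) stop("profiles have different focal leaves")
    if (!identical(sort(names(p$span_bp)), sort(nm))) {
      stop("profiles do not share the same leaf universe")
    }
  }
  span_bp <- Reduce(`+`, lapply(profiles, function(p) p$span_bp[nm]))
  tree_count <- Reduce(`+`, lapply(profiles, function(p) p$tree_count[nm]))
  eff <- sum(vapply(profiles, function(p) p$effective_span, numeric(1)))
  attached <- sum(vapply(profiles, function(p) p$n_trees_attached, numeric(1)))
  structure(
    list(
      focal = focal, chromosome_id = "genome",
      span_fraction = span_bp / eff,
      tree_fraction = tree_count / attached,
      span_bp = span_bp, tree_count = tree_count,
      total_span = sum(vapply(profiles, function(p) p$total_span, numeric(1))),
      effective_span = eff,
      n_trees = sum(vapply(profiles, function(p) p$n_trees, numeric(1))),
      n_trees_attached = attached,
      tree_spans = unlist(lapply(profiles, function(p) p$tree_spans),
                          use.names = FALSE),
      tree_neighbors = do.call(c, lapply(profiles,
                                         function(p) p$tree_neighbors))
    ),
    class = "neighbor_profile"
  )
}
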