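#' Local tree over a genomic interval
#'
#' A local tree is one marginal genealogy of an ancestral recombination
#' graph: a rooted tree over a fixed set of sample leaves, valid on a
#' half-open genomic interval `[left, right)`. Nodes are non-negative
#' integer ids; the sample leaves occupy the ids `0 .. n_leaves - 1` and
#' internal node ids are local to the tree. The topology is stored as a
#' parent vector (`parent[i + 1]` is the parent of node `i`, `NA` for a
#' root), which accepts multifurcations: inferred ARGs routinely contain
#' polytomies even though the statistic is usually written down for
#' bifurcating trees.
#'
#' A leaf whose parent is `NA` is detached (isolated) in this tree; it has
#' no parental node and hence no neighbor set.
#'
#' @param left,right interval bounds in base pairs, 0-based half-open;
#'   `right > left`.
#' @param parent integer vector of parent node ids indexed by `node + 1`;
#'   `NA` marks a root.
#' @param leaves integer vector of leaf node ids. If `NULL`, every node
#'   that is not the parent of any other node is taken to be a leaf.
#' @return an object of class `local_tree`.
#' @export
local_tree <- function(left, right, parent, leaves = NULL) {
  stopifnot(is.numeric(left), is.numeric(right), length(left) == 1L,
            length(right) == 1L)
  if (right <= left) {
    stop("invalid interval [", left, ", ", right, "): right must exceed left")
  }
  parent <- as.integer(parent)
  n_nodes <- length(parent)
  if (n_nodes == 0L) stop("a local tree needs at least one node")
  ok <- is.na(parent) | (parent >= 0L & parent < n_nodes)
  if (!all(ok)) stop("parent ids out of range")
  if (is.null(leaves)) {
    leaves <- setdiff(seq_len(n_nodes) - 1L, parent[!is.na(parent)])
  }
  leaves <- sort(as.integer(leaves))
  tr <- structure(
    list(left = as.numeric(left), right = as.numeric(right),
         parent = parent, leaves = leaves),
    class = "local_tree"
  )
  .check_acyclic(tr)
  tr
}

.check_acyclic <- function(tree) {
  n <- length(tree$parent)
  for (node in seq_len(n) - 1L) {
    seen <- 0L
    v <- tree$parent[node + 1L]
    while (!is.na(v)) {
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in parent map at node ", node)
      v <- tree$parent[v + 1L]
    }
  }
  invisible(tree)
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("<local_tree [%g, %g) %d leaves, %d nodes>\n",
              x$left, x$right, length(x$leaves), length(x$parent)))
  invisible(x)
}

#' Genomic span of a local tree
#' @param tree a `local_tree`.
#' @return span in base pairs (`right - left`).
#' @export
tree_span <- function(tree) tree$right - tree$left

#' Tree-sequence view: ordered local trees over a fixed leaf set
#'
#' Container for one chromosome's genealogy sequence: local trees with
#' non-overlapping intervals tiling `[0, L)` contiguously, all sharing the
#' identical leaf set. `samples` maps leaf ids to stable sample names
#' (haplotype labels).
#'
#' @param chromosome_id chromosome name (verbatim, no normalization).
#' @param trees list of [local_tree] objects, already sorted by `left`.
#' @param samples data.frame with columns `leaf_id`, `name`.
#' @return an object of class `tree_sequence_view`.
#' @export
tree_sequence_view <- function(chromosome_id, trees, samples) {
  stopifnot(is.character(chromosome_id), length(chromosome_id) == 1L,
            is.list(trees), length(trees) >= 1L,
            is.data.frame(samples),
            all(c("leaf_id", "name") %in% names(samples)))
  if (anyDuplicated(samples$leaf_id)) stop("duplicate leaf_id in samples")
  leaf_set <- sort(as.integer(samples$leaf_id))
  lefts <- vapply(trees, function(t) t$left, numeric(1))
  rights <- vapply(trees, function(t) t$right, numeric(1))
  if (is.unsorted(lefts, strictly = TRUE) && length(trees) > 1L) {
    stop("trees are not sorted by interval start")
  }
  if (lefts[1] != 0) {
    stop(sprintf("first interval [%g, %g) does not start at 0",
                 lefts[1], rights[1]))
  }
  if (length(trees) > 1L) {
    gap <- which(lefts[-1L] != rights[-length(rights)])
    if (length(gap)) {
      i <- gap[1L]
      stop(sprintf(
        "intervals do not tile: [%g, %g) followed by [%g, %g)",
        lefts[i], rights[i], lefts[i + 1L], rights[i + 1L]))
    }
  }
  for (i in seq_along(trees)) {
    if (!identical(trees[[i]]$leaves, leaf_set)) {
      stop("tree ", i, " has a leaf set differing from the sample set")
    }
  }
  structure(
    list(chromosome_id = chromosome_id, trees = trees,
         samples = samples[order(samples$leaf_id), , drop = FALSE]),
    class = "tree_sequence_view"
  )
}

#' @export
print.tree_sequence_view <- function(x, ...) {
  cat(sprintf("<tree_sequence_view %s: %d trees, %d leaves, L = %g bp>\n",
              x$chromosome_id, length(x$trees), nrow(x$samples),
              total_span(x)))
  invisible(x)
}

#' Total genomic length covered by a tree sequence
#' @param ts a `tree_sequence_view`.
#' @return L, the sum of tree spans in base pairs.
#' @export
total_span <- function(ts) {
  sum(vapply(ts$trees, tree_span, numeric(1)))
}

#' Number of local trees
#' @param ts a `tree_sequence_view`.
#' @export
n_trees <- function(ts) length(ts$trees)

# ---- newick conversion -------------------------------------------------

# Convert one ape "phylo" into a parent-vector local tree. Tip labels are
# mapped to leaf ids through `leaf_ids` (named integer vector); ape
# internal node numbers are renumbered to follow the leaves.
.phylo_to_tree <- function(phy, leaf_ids, left, right) {
  ntip <- length(phy$tip.label)
  if (!all(phy$tip.label %in% names(leaf_ids))) {
    bad <- setdiff(phy$tip.label, names(leaf_ids))
    stop("unknown leaf label(s): ", paste(bad, collapse = ", "))
  }
  n_leaves <- length(leaf_ids)
  n_internal <- phy$Nnode
  id_of <- integer(ntip + n_internal)
  id_of[seq_len(ntip)] <- leaf_ids[phy$tip.label]
  id_of[ntip + seq_len(n_internal)] <- n_leaves + seq_len(n_internal) - 1L
  parent <- rep(NA_integer_, n_leaves + n_internal)
  parent[id_of[phy$edge[, 2L]] + 1L] <- id_of[phy$edge[, 1L]]
  local_tree(left, right, parent, leaves = sort(unname(leaf_ids)))
}

# Render a local tree as a newick string using the given labels
# (character vector named by leaf_id).
.tree_to_newick <- function(tree, labels) {
  n <- length(tree$parent)
  children <- vector("list", n)
  for (node in seq_len(n) - 1L) {
    p <- tree$parent[node + 1L]
    if (!is.na(p)) children[[p + 1L]] <- c(children[[p + 1L]], node)
  }
  leaf <- rep(FALSE, n)
  leaf[tree$leaves + 1L] <- TRUE
  render <- function(node) {
    kids <- children[[node + 1L]]
    if (is.null(kids)) {
      if (!leaf[node + 1L]) stop("internal node ", node, " has no children")
      return(labels[[as.character(node)]])
    }
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","), ")")
  }
  roots <- which(is.na(tree$parent)) - 1L
  roots <- setdiff(roots, tree$leaves[is.na(tree$parent[tree$leaves + 1L])])
  if (length(roots) != 1L) {
    stop("newick export requires exactly one non-leaf root (found ",
         length(roots), ")")
  }
  paste0(render(roots), ";")
}

#' Build a tree sequence from hand-specified topologies and spans
#'
#' Constructs a [tree_sequence_view] from a list of `(newick, span)` pairs:
#' the fixture language used to express the statistic's worked examples.
#' All trees must use the same leaf names; leaves are assigned stable ids
#' in sorted name order (name -> id recorded in `samples`). Trees tile
#' `[0, sum(spans))` in the order given.
#'
#' @param spec a data.frame (or list coercible to one) with columns
#'   `newick` (character, e.g. `"((u,x),y)"`) and `span` (positive bp).
#' @param chromosome_id chromosome name for the resulting view.
#' @return a `tree_sequence_view`.
#' @export
#' @examples
#' ts <- build_toy_tree_sequence(data.frame(
#'   newick = c("((u,x),y)", "((u,y),x)"), span = c(30, 70)))
#' total_span(ts)
build_toy_tree_sequence <- function(spec, chromosome_id = "toy") {
  spec <- as.data.frame(spec)
  stopifnot(all(c("newick", "span") %in% names(spec)), nrow(spec) >= 1L)
  if (any(spec$span <= 0)) stop("all spans must be positive")
  nwk <- trimws(spec$newick)
  nwk <- ifelse(grepl(";\\s*$", nwk), nwk, paste0(nwk, ";"))
  phys <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(phys, "phylo")) phys <- list(phys)
  labels <- sort(phys[[1L]]$tip.label)
  for (i in seq_along(phys)) {
    if (!setequal(phys[[i]]$tip.label, labels)) {
      stop("inconsistent leaf sets across trees (tree ", i, ")")
    }
  }
  leaf_ids <- stats::setNames(seq_along(labels) - 1L, labels)
  breaks <- cumsum(c(0, spec$span))
  trees <- lapply(seq_along(phys), function(i) {
    .phylo_to_tree(phys[[i]], leaf_ids, breaks[i], breaks[i + 1L])
  })
  tree_sequence_view(
    chromosome_id, trees,
    samples = data.frame(leaf_id = unname(leaf_ids), name = labels,
                         stringsAsFactors = FALSE))
}

# ---- plain-text .trees format -----------------------------------------
#
# Header lines:
#   #argneighbor-trees 1
#   #chromosome=<id>
#   #samples=<name>:<leaf_id>,...
# then one tab-separated record per tree: left  right  newick
# Leaf labels in the newick are the sample names.

#' Write a tree sequence to a plain-text .trees file
#'
#' @param ts a `tree_sequence_view`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_sequence <- function(ts, path) {
  labels <- stats::setNames(as.list(ts$samples$name),
                            as.character(ts$samples$leaf_id))
  header <- c(
    "#argneighbor-trees 1",
    paste0("#chromosome=", ts$chromosome_id),
    paste0("#samples=",
           paste(ts$samples$name, ts$samples$leaf_id, sep = ":",
                 collapse = ","))
  )
  body <- vapply(ts$trees, function(t) {
    paste(format(t$left, scientific = FALSE),
          format(t$right, scientific = FALSE),
          .tree_to_newick(t, labels), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a plain-text .trees file
#'
#' Validates the tree-sequence invariants on load (contiguous tiling from
#' 0, identical leaf set in every tree) and fails with the first offending
#' interval on violation.
#'
#' @param path path to a `.trees` text file written by
#'   [write_tree_sequence()] or the bundled simulation glue.
#' @return a `tree_sequence_view`.
#' @export
read_tree_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1L], "#argneighbor-trees")) {
    stop("not an argneighbor .trees file (or truncated): ", path)
  }
  chrom <- sub("^#chromosome=", "", lines[2L])
  smp <- sub("^#samples=", "", lines[3L])
  pairs <- strsplit(strsplit(smp, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  samples <- data.frame(
    leaf_id = vapply(pairs, function(p) as.integer(p[2L]), integer(1)),
    name = vapply(pairs, `[[`, character(1), 1L),
    stringsAsFactors = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("truncated .trees file (no tree records): ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L)) {
    stop("malformed tree record in ", path, " (expected left\\tright\\tnewick)")
  }
  lefts <- vapply(fields, function(f) as.numeric(f[1L]), numeric(1))
  rights <- vapply(fields, function(f) as.numeric(f[2L]), numeric(1))
  nwk <- vapply(fields, `[[`, character(1), 3L)
  phys <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(phys, "phylo")) phys <- list(phys)
  leaf_ids <- stats::setNames(as.integer(samples$leaf_id), samples$name)
  trees <- lapply(seq_along(phys), function(i) {
    .phylo_to_tree(phys[[i]], leaf_ids, lefts[i], rights[i])
  })
  tree_sequence_view(chrom, trees, samples)
}

#' Read a directory of per-chromosome .trees files
#'
#' @param dir directory containing `*.trees` text files.
#' @return named list of `tree_sequence_view`, sorted by chromosome id.
#' @export
read_tree_sequence_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.trees$", full.names = TRUE))
  if (!length(paths)) stop("no .trees files under ", dir)
  views <- lapply(paths, read_tree_sequence)
  names(views) <- vapply(views, function(v) v$chromosome_id, character(1))
  if (anyDuplicated(names(views))) stop("duplicate chromosome ids in ", dir)
  views[order(names(views))]
}

#' Split one tree sequence into consecutive pseudo-chromosomes
#'
#' Partitions the ordered tree list into `n_chunks` consecutive groups at
#' tree boundaries and rebases each chunk's coordinates to start at 0.
#' Used to check that genome-wide aggregation over an arbitrary partition
#' reproduces the unpartitioned statistic.
#'
#' @param ts a `tree_sequence_view`.
#' @param n_chunks number of pieces (at most `n_trees(ts)`).
#' @param seed optional seed controlling the random cut points; `NULL`
#'   cuts into near-equal tree counts.
#' @return named list of `tree_sequence_view`.
#' @export
split_tree_sequence <- function(ts, n_chunks, seed = NULL) {
  m <- n_trees(ts)
  stopifnot(n_chunks >= 1L, n_chunks <= m)
  if (is.null(seed)) {
    cuts <- unique(round(seq(0, m, length.out = n_chunks + 1L)))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    cuts <- c(0L, sort(sample(seq_len(m - 1L), n_chunks - 1L)), m)
  }
  out <- vector("list", length(cuts) - 1L)
  for (i in seq_along(out)) {
    idx <- (cuts[i] + 1L):cuts[i + 1L]
    chunk <- ts$trees[idx]
    offset <- chunk[[1L]]$left
    chunk <- lapply(chunk, function(t) {
      local_tree(t$left - offset, t$right - offset, t$parent, t$leaves)
    })
    out[[i]] <- tree_sequence_view(
      sprintf("%s_part%02d", ts$chromosome_id, i), chunk, ts$samples)
  }
  names(out) <- vapply(out, function(v) v$chromosome_id, character(1))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
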