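#' Read an accession metadata table
#'
#' The table maps each haplotype leaf to its diploid accession:
#' columns `accession_id`, `leaf_id`, `haplotype_index` (0 or 1) and
#' `ancestry_group` (optional; empty string when absent).
#'
#' @param path CSV file path.
#' @return a data.frame of class `accession_table`.
#' @export
read_accession_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  accession_table(tab)
}

#' Construct / validate an accession table
#' @param tab data.frame with columns `accession_id`, `leaf_id`,
#'   `haplotype_index` and optionally `ancestry_group`.
#' @return the validated data.frame, class `accession_table`.
#' @export
accession_table <- function(tab) {
  need <- c("accession_id", "leaf_id", "haplotype_index")
  if (!all(need %in% names(tab))) {
    stop("accession table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"ancestry_group" %in% names(tab)) tab$ancestry_group <- ""
  tab$leaf_id <- as.integer(tab$leaf_id)
  if (anyDuplicated(tab$leaf_id)) {
    stop("leaf_id must map to exactly one accession; duplicates: ",
         paste(unique(tab$leaf_id[duplicated(tab$leaf_id)]), collapse = ", "))
  }
  class(tab) <- c("accession_table", class(tab))
  tab
}

#' Collapse a haplotype neighbor profile to diploid accessions
#'
#' Per local tree, an accession counts as a neighbor of the focal sample
#' if ANY of its haplotype leaves lies in the focal leaf's neighbor set
#' (union rule — a tree where both haplotypes are neighbors still
#' contributes its span once, keeping proportions in `[0, 1]`). The focal
#' accession itself — including the focal sample's other haplotype, which
#' is trivially its nearest relative — is removed from the reported
#' neighbor universe; its spans still count in the denominator.
#'
#' When both haplotypes of the focal accession are analyzed, pass both
#' profiles as a list: the accession-level proportions are the mean of the
#' two per-haplotype collapses.
#'
#' @param profile a `neighbor_profile` (from [gnn_profiles()] /
#'   [span_weighted_gnn()] / [aggregate_genome()]) or a list of such
#'   profiles for the focal accession's haplotypes.
#' @param table an [accession_table()].
#' @param focal_accession accession owning the focal leaf (or leaves).
#' @return an object of class `accession_profile` with
#'   `span_fraction_by_accession` (P) and `tree_fraction_by_accession`
#'   (G), named numeric vectors over all non-focal accessions.
#' @export
accession_collapse <- function(profile, table, focal_accession) {
  table <- accession_table(as.data.frame(table))
  if (inherits(profile, "neighbor_profile")) profile <- list(profile)
  parts <- lapply(profile, .collapse_one, table = table,
                  focal_accession = focal_accession)
  accs <- names(parts[[1L]]$P)
  P <- Reduce(`+`, lapply(parts, function(p) p$P[accs])) / length(parts)
  G <- Reduce(`+`, lapply(parts, function(p) p$G[accs])) / length(parts)
  structure(
    list(
      focal_accession = focal_accession,
      chromosome_id = parts[[1L]]$chromosome_id,
      span_fraction_by_accession = P,
      tree_fraction_by_accession = G,
      n_focal_haplotypes = length(parts),
      effective_span = mean(vapply(parts, function(p) p$effective_span,
                                   numeric(1))),
      per_chromosome_closest = NULL
    ),
    class = "accession_profile"
  )
}

.collapse_one <- function(profile, table, focal_accession) {
  stopifnot(inherits(profile, "neighbor_profile"))
  universe <- c(profile$focal, as.integer(names(profile$span_bp)))
  unmapped <- setdiff(universe, table$leaf_id)
  if (length(unmapped)) {
    stop("leaf id(s) not mapped to an accession: ",
         paste(unmapped, collapse = ", "))
  }
  acc_of <- stats::setNames(table$accession_id, as.character(table$leaf_id))
  if (acc_of[[as.character(profile$focal)]] != focal_accession) {
    stop("focal leaf ", profile$focal, " belongs to accession '",
         acc_of[[as.character(profile$focal)]], "', not '",
         focal_accession, "'")
  }
  accs <- sort(setdiff(unique(table$accession_id[table$leaf_id %in% universe]),
                       focal_accession))
  span_bp <- stats::setNames(numeric(length(accs)), accs)
  tree_count <- stats::setNames(numeric(length(accs)), accs)
  for (ti in seq_along(profile$tree_neighbors)) {
    nb <- profile$tree_neighbors[[ti]]
    if (is.null(nb)) next                      # focal detached in this tree
    if (length(nb)) {
      hit <- setdiff(unique(acc_of[as.character(nb)]), focal_accession)
      if (length(hit)) {
        span_bp[hit] <- span_bp[hit] + profile$tree_spans[ti]
        tree_count[hit] <- tree_count[hit] + 1
      }
    }
  }
  list(P = span_bp / profile$effective_span,
       G = tree_count / profile$n_trees_attached,
       chromosome_id = profile$chromosome_id,
       effective_span = profile$effective_span)
}

#' @export
print.accession_profile <- function(x, ...) {
  cat(sprintf("<accession_profile focal=%s %s: %d accessions>\n",
              x$focal_accession, x$chromosome_id,
              length(x$span_fraction_by_accession)))
  print(utils::head(rank_neighbors(x, 5L)))
  invisible(x)
}

#' Rank closest neighbor accessions by genome proportion
#'
#' Orders accessions by decreasing P; exact ties are broken
#' lexicographically by accession id and flagged rather than silently
#' resolved.
#'
#' @param ap an `accession_profile`.
#' @param k number of rows to return (capped at the number of accessions).
#' @return data.frame with columns `accession_id`, `P`, `G`, `tie`.
#' @export
rank_neighbors <- function(ap, k = 10L) {
  stopifnot(k >= 1L)
  P <- ap$span_fraction_by_accession
  G <- ap$tree_fraction_by_accession
  ord <- order(-P, names(P))
  P <- P[ord]; G <- G[ord]
  tie <- duplicated(P) | duplicated(P, fromLast = TRUE)
  k <- min(as.integer(k), length(P))
  data.frame(
    accession_id = names(P)[seq_len(k)],
    P = unname(P[seq_len(k)]),
    G = unname(G[seq_len(k)]),
    tie = tie[seq_len(k)],
    stringsAsFactors = FALSE
  )
}

#' Closest neighbor accession(s) for each chromosome
#'
#' For every chromosome, the accession(s) attaining the maximal genome
#' proportion P; all ties are reported in lexicographic order.
#'
#' @param per_chrom named list of `accession_profile`, one per chromosome.
#' @return named list: chromosome id -> character vector of accession ids.
#' @export
closest_per_chromosome <- function(per_chrom) {
  stopifnot(length(per_chrom) >= 1L)
  out <- lapply(per_chrom, function(ap) {
    P <- ap$span_fraction_by_accession
    sort(names(P)[P == max(P)])
  })
  nms <- names(out)
  if (is.null(nms)) {
    nms <- vapply(per_chrom, function(ap) ap$chromosome_id, character(1))
    names(out) <- nms
  }
  out
}

#' Full accession-level analysis of one focal accession
#'
#' Convenience pipeline: computes per-haplotype profiles for both leaves
#' of the focal accession on every chromosome, collapses to accession
#' level per chromosome, aggregates genome-wide (span-weighted), and
#' records the per-chromosome closest neighbors.
#'
#' @param views named list of [tree_sequence_view], one per chromosome.
#' @param table an [accession_table()].
#' @param focal_accession accession id to analyze.
#' @return an `accession_profile` for the genome with
#'   `per_chromosome_closest` filled in.
#' @export
accession_analysis <- function(views, table, focal_accession) {
  table <- accession_table(as.data.frame(table))
  focal_leaves <- table$leaf_id[table$accession_id == focal_accession]
  if (!length(focal_leaves)) {
    stop("unknown focal accession: ", focal_accession)
  }
  per_chrom <- lapply(views, function(ts) {
    prof <- gnn_profiles(ts, focals = focal_leaves)
    accession_collapse(prof, table, focal_accession)
  })
  names(per_chrom) <- vapply(views, function(v) v$chromosome_id, character(1))
  genome_profiles <- lapply(focal_leaves, function(u) {
    aggregate_genome(lapply(views, function(ts) {
      gnn_profiles(ts, focals = u)[[1L]]
    }))
  })
  genome <- accession_collapse(genome_profiles, table, focal_accession)
  genome$per_chromosome_closest <- closest_per_chromosome(per_chrom)
  genome
}

# ---- profile serialization --------------------------------------------

#' Write an accession profile to CSV and JSON
#'
#' `<prefix>.csv` holds one row per neighbor accession with fixed column
#' order `focal_accession, neighbor_accession, P, G, chromosome`; a
#' leading `#` comment line carries the package version. `<prefix>.json`
#' holds the full profile (schema-versioned) and round-trips through
#' [read_profile()] exactly.
#'
#' @param ap an `accession_profile`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_profile <- function(ap, prefix) {
  ver <- as.character(utils::packageVersion("argneighbor"))
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  P <- ap$span_fraction_by_accession
  df <- data.frame(
    focal_accession = rep(ap$focal_accession, length(P)),
    neighbor_accession = names(P),
    P = unname(P),
    G = unname(ap$tree_fraction_by_accession[names(P)]),
    chromosome = rep(ap$chromosome_id, length(P)),
    stringsAsFactors = FALSE
  )
  con <- file(csv_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# argneighbor %s accession-profile", ver), con)
  utils::write.csv(df, con, row.names = FALSE)
  payload <- list(
    schema = "argneighbor-profile/1",
    version = ver,
    focal_accession = ap$focal_accession,
    chromosome_id = ap$chromosome_id,
    n_focal_haplotypes = ap$n_focal_haplotypes,
    effective_span = ap$effective_span,
    span_fraction_by_accession = as.list(ap$span_fraction_by_accession),
    tree_fraction_by_accession = as.list(ap$tree_fraction_by_accession),
    per_chromosome_closest = ap$per_chromosome_closest
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read an accession profile back from its JSON serialization
#' @param path a `.json` file written by [write_profile()].
#' @return an `accession_profile`.
#' @export
read_profile <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "argneighbor-profile/1")) {
    stop("unrecognized profile schema in ", path)
  }
  as_named <- function(x) {
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  pcc <- payload$per_chromosome_closest
  if (!is.null(pcc)) {
    pcc <- lapply(pcc, function(v) {
      vapply(v, as.character, character(1), USE.NAMES = FALSE)
    })
  }
  structure(
    list(
      focal_accession = payload$focal_accession,
      chromosome_id = payload$chromosome_id,
      span_fraction_by_accession = as_named(payload$span_fraction_by_accession),
      tree_fraction_by_accession = as_named(payload$tree_fraction_by_accession),
      n_focal_haplotypes = payload$n_focal_haplotypes,
      effective_span = payload$effective_span,
      per_chromosome_closest = pcc
    ),
    class = "accession_profile"
  )
}
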