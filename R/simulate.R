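#' Random tree sequence with polytomies
#'
#' Generates a seeded random [tree_sequence_view]: each local tree is
#' built by repeatedly merging 2–4 random active lineages into a new
#' parent (so multifurcations arise naturally), and spans are random
#' positive integers. Pure function of its arguments — a fixed seed gives
#' an identical object.
#'
#' @param n_leaves number of sample leaves (>= 2).
#' @param n_trees number of local trees (>= 1).
#' @param seed integer seed (mandatory).
#' @param max_span maximum per-tree span in bp.
#' @return a `tree_sequence_view` with leaves `0 .. n_leaves - 1` named
#'   `s0 .. s<n-1>`.
#' @export
random_tree_sequence <- function(n_leaves, n_trees, seed, max_span = 100L) {
  stopifnot(n_leaves >= 2L, n_trees >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  spans <- sample.int(max_span, n_trees, replace = TRUE)
  breaks <- cumsum(c(0L, spans))
  leaves <- seq_len(n_leaves) - 1L
  trees <- vector("list", n_trees)
  for (ti in seq_len(n_trees)) {
    active <- leaves
    parent <- rep(NA_integer_, n_leaves)
    next_id <- n_leaves
    while (length(active) > 1L) {
      k <- min(length(active), sample(2:4, 1L))
      merge <- sample(active, k)
      parent[merge + 1L] <- next_id
      parent <- c(parent, NA_integer_)
      active <- c(setdiff(active, merge), next_id)
      next_id <- next_id + 1L
    }
    trees[[ti]] <- local_tree(breaks[ti], breaks[ti + 1L], parent, leaves)
  }
  tree_sequence_view(
    sprintf("rand%d", seed), trees,
    data.frame(leaf_id = leaves, name = paste0("s", leaves),
               stringsAsFactors = FALSE))
}

#' Configuration for a structured-population coalescent simulation
#'
#' Defaults emulate a deeply diverged two-population panel: 2 demes of 10
#' diploids, effective size 1e4 per deme, a clean split 2e5 generations
#' ago with no subsequent migration, 1 Mb of sequence and a uniform
#' recombination rate of 1e-8 per bp per generation.
#'
#' @param n_demes number of demes.
#' @param samples_per_deme diploid individuals sampled per deme.
#' @param effective_size per-deme (and ancestral) N_e.
#' @param split_time divergence time in generations.
#' @param migration_rate symmetric per-generation migration fraction
#'   between demes after the split (0 = complete isolation).
#' @param sequence_length chromosome length in bp.
#' @param recombination_rate per-bp per-generation crossover rate.
#' @param seed integer seed (mandatory).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 2L, samples_per_deme = 10L,
                       effective_size = 1e4, split_time = 2e5,
                       migration_rate = 0, sequence_length = 1e6,
                       recombination_rate = 1e-8, seed) {
  stopifnot(n_demes >= 1L, samples_per_deme >= 1L, effective_size > 0,
            split_time > 0, migration_rate >= 0, sequence_length > 0,
            recombination_rate >= 0, !missing(seed))
  structure(
    list(n_demes = as.integer(n_demes),
         samples_per_deme = as.integer(samples_per_deme),
         effective_size = effective_size, split_time = split_time,
         migration_rate = migration_rate,
         sequence_length = sequence_length,
         recombination_rate = recombination_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate recombining genealogies for a structured population
#'
#' Runs a coalescent simulation (msprime, through the bundled Python
#' helper) under the demography in `cfg` and returns per-chromosome
#' [tree_sequence_view] objects together with an [accession_table()]
#' carrying the true deme label of every sample — the planted truth the
#' label-recovery tests score against. Deterministic for a fixed config:
#' chromosome c uses msprime seed `cfg$seed + c - 1`.
#'
#' @param cfg a [sim_config()].
#' @param n_chromosomes number of independent chromosomes to simulate
#'   (same demography, consecutive seeds).
#' @param dir directory for the intermediate `.trees` / metadata files
#'   (default: a tempdir).
#' @return list with elements `views` (named list of
#'   `tree_sequence_view`) and `meta` (an `accession_table` with
#'   `ancestry_group` = deme name).
#' @export
simulate_structured <- function(cfg, n_chromosomes = 1L, dir = tempfile("sim")) {
  stopifnot(inherits(cfg, "sim_config"), n_chromosomes >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  helper <- system.file("python", "simulate_structured.py",
                        package = "argneighbor")
  if (helper == "") stop("bundled simulation helper not found")
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") stop("no python interpreter on PATH (needed for msprime)")
  args <- c(
    helper,
    "--n-demes", cfg$n_demes,
    "--samples-per-deme", cfg$samples_per_deme,
    "--ne", format(cfg$effective_size, scientific = FALSE),
    "--split-time", format(cfg$split_time, scientific = FALSE),
    "--migration-rate", format(cfg$migration_rate, scientific = FALSE),
    "--length", format(cfg$sequence_length, scientific = FALSE),
    "--recomb", format(cfg$recombination_rate, scientific = TRUE),
    "--seed", cfg$seed,
    "--n-chromosomes", n_chromosomes,
    "--out-dir", dir
  )
  status <- system2(python, as.character(args), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop("simulation helper failed:\n", paste(status, collapse = "\n"))
  }
  views <- read_tree_sequence_dir(dir)
  meta <- read_accession_table(file.path(dir, "meta.csv"))
  list(views = views, meta = meta)
}

#' Simulate an outgroup genotype matrix with planted polarization failures
#'
#' Builds biallelic sites genotyped in an outgroup of `n_outgroup`
#' diploids (plus `n_ingroup` carrier samples): exactly
#' `round(fail_fraction * n_sites)` sites are planted to violate the
#' majority-concordance rule (the outgroup majority allele is carried by
#' `min_major - 1` of `total` units), and the rest to satisfy it (by
#' `min_major` or all units). The planted truth is returned so tests
#' never re-derive it from the output.
#'
#' @param n_sites number of sites.
#' @param n_outgroup outgroup diploids (default 10).
#' @param fail_fraction fraction of sites planted to fail, in `[0, 1]`.
#' @param seed integer seed.
#' @param n_ingroup additional non-outgroup samples.
#' @param min_major,total the concordance rule being exercised.
#' @return list with `gm` (a `genotype_matrix`), `outgroup` (sample ids)
#'   and `truth` (data.frame `pos`, `planted_fail`).
#' @export
simulate_outgroup_genotypes <- function(n_sites, n_outgroup = 10L,
                                        fail_fraction, seed,
                                        n_ingroup = 4L,
                                        min_major = 9L, total = 10L) {
  stopifnot(fail_fraction >= 0, fail_fraction <= 1, n_sites >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_fail <- round(fail_fraction * n_sites)
  fail <- rep(FALSE, n_sites)
  if (n_fail > 0) fail[sample.int(n_sites, n_fail)] <- TRUE
  out_ids <- paste0("wna", seq_len(n_outgroup))
  in_ids <- if (n_ingroup > 0) paste0("acc", seq_len(n_ingroup)) else character(0)
  samples <- c(out_ids, in_ids)
  a1 <- matrix(NA_integer_, n_sites, length(samples),
               dimnames = list(NULL, samples))
  a2 <- a1
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  for (i in seq_len(n_sites)) {
    major <- sample(0:1, 1L)
    n_major <- if (fail[i]) min_major - 1L else sample(min_major:total, 1L)
    # scale the planted unit counts to the actual outgroup size
    n_major <- round(n_major / total * n_outgroup)
    alleles <- c(rep(major, n_major), rep(1L - major, n_outgroup - n_major))
    alleles <- sample(alleles)
    a1[i, out_ids] <- alleles
    a2[i, out_ids] <- alleles                 # homozygous units
    if (length(in_ids)) {
      g <- matrix(sample(0:1, 2L * length(in_ids), replace = TRUE), nrow = 2L)
      a1[i, in_ids] <- g[1L, ]
      a2[i, in_ids] <- g[2L, ]
    }
  }
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  list(gm = genotype_matrix(sites, a1, a2),
       outgroup = out_ids,
       truth = data.frame(pos = sites$pos, planted_fail = fail))
}

#' Simulate an SDR marker panel and specimen genotypes of known sex
#'
#' Plants genotypes consistent with the requested sex at a panel of SDR
#' markers (half male-class, half female-class, positions inside a 150 kb
#' region of chromosome 2), then corrupts each marker independently with
#' probability `error_rate` by flipping its genotype category
#' (dominant <-> recessive) — a crude model of genotyping error.
#'
#' Planted patterns: a male carries a dominant allele at both loci
#' (active male locus, suppressed female locus); a female is homozygous
#' recessive at both; a hermaphrodite carries the dominant male-locus
#' allele but is homozygous recessive at the female locus (both loci
#' active).
#'
#' @param sex one of `"male"`, `"female"`, `"hermaphrodite"`.
#' @param n_markers total markers (split evenly between locus classes).
#' @param error_rate per-marker category-flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `variants` (specimen calls), `markers`
#'   (an `sdr_markers` table) and `truth` (the planted sex).
#' @export
simulate_sdr_panel <- function(sex = c("male", "female", "hermaphrodite"),
                               n_markers = 60L, error_rate = 0, seed) {
  sex <- match.arg(sex)
  stopifnot(error_rate >= 0, error_rate < 0.5, n_markers >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_male <- n_markers %/% 2L
  n_female <- n_markers - n_male
  pos <- sort(sample(4900000:5050000, n_markers))
  cls <- sample(c(rep("male", n_male), rep("female", n_female)))
  bases <- c("A", "C", "G", "T")
  dom <- sample(bases, n_markers, replace = TRUE)
  rec <- vapply(dom, function(d) sample(setdiff(bases, d), 1L), character(1))
  markers <- sdr_markers(data.frame(
    chrom = "chr2", pos = pos, locus_class = cls,
    dominant = dom, recessive = rec, stringsAsFactors = FALSE))
  wants_dominant <- ifelse(
    cls == "male",
    sex %in% c("male", "hermaphrodite"),
    sex == "male")                            # female locus: dominant = suppressed
  flip <- stats::runif(n_markers) < error_rate
  dominant_gt <- xor(wants_dominant, flip)
  a1 <- ifelse(dominant_gt, dom, rec)
  a2 <- rec                                    # dominant genotypes are het
  variants <- data.frame(chrom = "chr2", pos = pos,
                         allele1 = a1, allele2 = a2,
                         stringsAsFactors = FALSE)
  list(variants = variants, markers = markers, truth = sex)
}
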