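#' Genotype matrix container
#'
#' Sites-by-samples diploid genotype calls with allele indices (0 = REF,
#' 1.. = ALT in order) and `NA` for missing. Positions are 1-based (VCF
#' convention) and sorted within chromosome.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated when multiallelic).
#' @param a1,a2 integer matrices (sites x samples) holding the two allele
#'   indices per call; column names are sample ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, a1, a2) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(a1), is.matrix(a2),
            identical(dim(a1), dim(a2)),
            nrow(a1) == nrow(sites),
            !is.null(colnames(a1)),
            identical(colnames(a1), colnames(a2)))
  for (ch in unique(sites$chrom)) {
    if (is.unsorted(sites$pos[sites$chrom == ch])) {
      stop("positions not sorted within chromosome ", ch)
    }
  }
  n_alleles <- .n_alleles(sites)
  mx <- pmax(a1, a2, na.rm = TRUE)
  mx[is.infinite(mx)] <- NA
  bad <- which(!is.na(mx) & mx >= n_alleles)
  if (length(bad)) {
    stop("allele index out of range at site row ",
         paste(utils::head(unique((bad - 1L) %% nrow(a1) + 1L), 5L),
               collapse = ", "))
  }
  structure(list(sites = sites, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

.n_alleles <- function(sites) {
  alt_n <- ifelse(is.na(sites$alt) | sites$alt == "" | sites$alt == ".",
                  0L, lengths(strsplit(sites$alt, ",", fixed = TRUE)))
  1L + alt_n
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d sites x %d samples>\n",
              nrow(x$sites), ncol(x$a1)))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Retain only biallelic sites
#'
#' Keeps sites whose allele list (REF plus ALT) has exactly two alleles,
#' the precondition for polarization and downstream ARG inference. The
#' number of removed sites is attached as attribute `n_removed` and
#' reported via message.
#'
#' @param gm a `genotype_matrix`.
#' @param quiet suppress the message.
#' @return the filtered `genotype_matrix`.
#' @export
biallelic_filter <- function(gm, quiet = FALSE) {
  keep <- .n_alleles(gm$sites) == 2L
  out <- genotype_matrix(gm$sites[keep, , drop = FALSE],
                         gm$a1[keep, , drop = FALSE],
                         gm$a2[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  if (!quiet) {
    message(sum(!keep), " non-biallelic site(s) removed, ",
            sum(keep), " retained")
  }
  out
}

#' Assign ancestral alleles from an outgroup and filter by concordance
#'
#' The ancestral allele at each biallelic site is the major allele among
#' the outgroup sample; sites where the major allele is carried by fewer
#' than `min_major` of `total` outgroup units are excluded. By default a
#' unit is one outgroup individual's homozygous consensus call:
#' heterozygous or missing individuals contribute no unit and drop out of
#' the denominator, the threshold then applying as the fraction
#' `min_major / total` of contributing units (compared exactly, by integer
#' cross-multiplication). With `unit = "haplotype"` the two alleles of
#' each individual are counted separately instead.
#'
#' Every input site receives exactly one status: `kept`,
#' `excluded_outgroup_rule` (with a `reason` of `below_threshold`, `tie`,
#' or `no_outgroup_data`), or `excluded_not_biallelic`.
#'
#' @param gm a `genotype_matrix`.
#' @param outgroup character vector of outgroup sample ids (columns of
#'   `gm`).
#' @param min_major minimum concordant units (default 9).
#' @param total nominal outgroup size the threshold is quoted against
#'   (default 10).
#' @param unit `"individual"` (default) or `"haplotype"`.
#' @return a data.frame of class `polarized_sites`: columns `chrom`,
#'   `pos`, `status`, `reason`, `ancestral_index`, `ancestral`,
#'   `n_units`, `majority_count`.
#' @export
polarize <- function(gm, outgroup, min_major = 9L, total = 10L,
                     unit = c("individual", "haplotype")) {
  unit <- match.arg(unit)
  stopifnot(length(outgroup) >= 1L, min_major <= total)
  missing_samples <- setdiff(outgroup, colnames(gm$a1))
  if (length(missing_samples)) {
    stop("outgroup sample(s) not in the genotype matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  ns <- n_sites(gm)
  o1 <- gm$a1[, outgroup, drop = FALSE]
  o2 <- gm$a2[, outgroup, drop = FALSE]
  biallelic <- .n_alleles(gm$sites) == 2L

  if (unit == "individual") {
    hom <- !is.na(o1) & !is.na(o2) & o1 == o2
    count0 <- rowSums(hom & o1 == 0L, na.rm = TRUE)
    count1 <- rowSums(hom & o1 == 1L, na.rm = TRUE)
  } else {
    count0 <- rowSums(o1 == 0L, na.rm = TRUE) + rowSums(o2 == 0L, na.rm = TRUE)
    count1 <- rowSums(o1 == 1L, na.rm = TRUE) + rowSums(o2 == 1L, na.rm = TRUE)
  }
  n_units <- count0 + count1
  majority <- pmax(count0, count1)
  anc_idx <- ifelse(count0 > count1, 0L, ifelse(count1 > count0, 1L, NA))
  # fraction test: majority / n_units >= min_major / total, exactly
  passes <- n_units > 0 & !is.na(anc_idx) &
    (majority * total >= min_major * n_units)

  status <- rep("excluded_outgroup_rule", ns)
  reason <- rep("below_threshold", ns)
  status[!biallelic] <- "excluded_not_biallelic"
  reason[!biallelic] <- "not_biallelic"
  sel <- biallelic & n_units == 0
  reason[sel] <- "no_outgroup_data"
  sel <- biallelic & n_units > 0 & is.na(anc_idx)
  reason[sel] <- "tie"
  sel <- biallelic & passes
  status[sel] <- "kept"
  reason[sel] <- ""
  anc_idx[status != "kept"] <- NA

  alleles <- Map(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1L]]),
                 gm$sites$ref,
                 ifelse(is.na(gm$sites$alt) | gm$sites$alt == ".",
                        "", gm$sites$alt))
  anc <- vapply(seq_len(ns), function(i) {
    if (is.na(anc_idx[i])) NA_character_ else alleles[[i]][anc_idx[i] + 1L]
  }, character(1))

  out <- data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    status = status, reason = reason,
    ancestral_index = anc_idx, ancestral = anc,
    n_units = n_units, majority_count = majority,
    stringsAsFactors = FALSE
  )
  class(out) <- c("polarized_sites", class(out))
  attr(out, "min_major") <- min_major
  attr(out, "total") <- total
  attr(out, "unit") <- unit
  out
}

#' Subset a genotype matrix to the sites kept by polarization
#' @param gm a `genotype_matrix`.
#' @param pol the matching `polarized_sites`.
#' @return the kept-site `genotype_matrix`.
#' @export
kept_sites <- function(gm, pol) {
  stopifnot(nrow(pol) == n_sites(gm))
  keep <- pol$status == "kept"
  genotype_matrix(gm$sites[keep, , drop = FALSE],
                  gm$a1[keep, , drop = FALSE],
                  gm$a2[keep, , drop = FALSE])
}

#' Write the per-site polarization status table
#' @param pol a `polarized_sites` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_status <- function(pol, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf(
    "# argneighbor %s polarization min_major=%d total=%d unit=%s",
    as.character(utils::packageVersion("argneighbor")),
    attr(pol, "min_major"), attr(pol, "total"), attr(pol, "unit")), con)
  utils::write.table(pol, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- VCF boundary ------------------------------------------------------
# VCF is 1-based; coordinates cross into the package unchanged because
# genotype positions are only ever matched by (chrom, pos), never used as
# interval arithmetic. Tree-sequence coordinates are 0-based half-open.

#' Read diploid genotypes from a VCF file
#'
#' Thin wrapper over `vcfR::read.vcfR()`: extracts GT into the package's
#' allele-index representation. Both phased (`|`) and unphased (`/`)
#' separators are accepted; half-missing calls become fully missing.
#'
#' @param path VCF (possibly gzipped) file path.
#' @return a `genotype_matrix`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  split_gt <- function(which_allele) {
    apply(gt, 2L, function(col) {
      parts <- strsplit(col, "[/|]")
      vapply(parts, function(p) {
        if (length(p) < 2L || any(p %in% c(".", ""))) return(NA_integer_)
        as.integer(p[which_allele])
      }, integer(1))
    })
  }
  a1 <- split_gt(1L); a2 <- split_gt(2L)
  if (is.null(dim(a1))) {                      # single site edge case
    a1 <- matrix(a1, nrow = 1L, dimnames = list(NULL, colnames(gt)))
    a2 <- matrix(a2, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  genotype_matrix(sites, a1, a2)
}

#' Write a genotype matrix as VCF text
#'
#' Plain VCF 4.2 text (readable by any VCF tool; compress externally if
#' needed). `info` optionally supplies one INFO string per site.
#'
#' @param gm a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @param info optional character vector of INFO fields (length
#'   `n_sites(gm)`); default `"."`.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, info = NULL) {
  if (is.null(info)) info <- rep(".", n_sites(gm))
  stopifnot(length(info) == n_sites(gm))
  samples <- colnames(gm$a1)
  gt <- matrix(paste(ifelse(is.na(gm$a1), ".", gm$a1),
                     ifelse(is.na(gm$a2), ".", gm$a2), sep = "|"),
               nrow = n_sites(gm))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=argneighbor-%s",
            as.character(utils::packageVersion("argneighbor"))),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(n_sites(gm)), function(i) {
    paste(c(gm$sites$chrom[i], gm$sites$pos[i], ".", gm$sites$ref[i],
            gm$sites$alt[i], ".", "PASS", info[i], "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a polarized genotype matrix as VCF text
#'
#' Emits the kept sites with the assigned ancestral allele in the `AA`
#' INFO tag.
#'
#' @param gm a `genotype_matrix` (typically already [kept_sites()]).
#' @param pol the matching `polarized_sites` rows for `gm`'s sites.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_polarized_vcf <- function(gm, pol, path) {
  pol <- pol[pol$status == "kept", , drop = FALSE]
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  key_pol <- paste(pol$chrom, pol$pos)
  idx <- match(key_gm, key_pol)
  if (anyNA(idx)) stop("polarization table does not cover all sites")
  write_genotype_vcf(gm, path, info = paste0("AA=", pol$ancestral[idx]))
}
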