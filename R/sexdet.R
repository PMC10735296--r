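#' Read an SDR marker table
#'
#' Markers of the grapevine sex-determination region (~150 kb on
#' chromosome 2). Each marker belongs to a locus class — `male` (the
#' male-fertility locus, dominant allele = active male locus) or `female`
#' (the female-fertility locus, recessive homozygote = active female
#' locus) — and declares its dominant and recessive alleles.
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `locus_class`,
#'   `dominant`, `recessive`.
#' @return a validated data.frame of class `sdr_markers`.
#' @export
read_sdr_markers <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  sdr_markers(tab)
}

#' Construct / validate an SDR marker table
#' @param tab data.frame with columns `chrom`, `pos`, `locus_class`,
#'   `dominant`, `recessive`.
#' @return the validated data.frame, class `sdr_markers`.
#' @export
sdr_markers <- function(tab) {
  need <- c("chrom", "pos", "locus_class", "dominant", "recessive")
  if (!all(need %in% names(tab))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$locus_class %in% c("male", "female"))) {
    stop("locus_class must be 'male' or 'female'")
  }
  if (any(tab$dominant == tab$recessive)) {
    stop("dominant and recessive alleles must differ at every marker")
  }
  key <- paste(tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    stop("duplicate marker position(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(tab) <- c("sdr_markers", "data.frame")
  tab
}

#' Count genotype categories at SDR markers
#'
#' Classifies a specimen's genotype at each marker: a genotype carrying at
#' least one dominant allele falls in the dominant category of the
#' marker's locus class (Mm/MM at male-class markers, Ff/FF at
#' female-class), a homozygous-recessive genotype in the recessive
#' category (mm or ff). Markers with a missing genotype are skipped and
#' counted in `n_missing`; genotypes carrying an allele that is neither
#' the dominant nor the recessive allele are counted as unclassifiable.
#'
#' @param variants data.frame of the specimen's calls: columns `chrom`,
#'   `pos`, `allele1`, `allele2` (bases as characters, `NA` = missing).
#' @param markers an [sdr_markers()] table.
#' @return an object of class `sdr_counts` with fields `n_male_dominant`,
#'   `n_male_recessive`, `n_female_dominant`, `n_female_recessive`,
#'   `n_missing`, `n_unclassifiable`.
#' @export
count_sdr_genotypes <- function(variants, markers) {
  markers <- sdr_markers(as.data.frame(markers))
  stopifnot(nrow(markers) >= 1L)
  vkey <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(vkey)) {
    stop("duplicate variant record(s) at: ",
         paste(unique(vkey[duplicated(vkey)]), collapse = "; "))
  }
  idx <- match(paste(markers$chrom, markers$pos), vkey)
  counts <- c(male_dominant = 0L, male_recessive = 0L,
              female_dominant = 0L, female_recessive = 0L)
  n_missing <- 0L; n_unclassifiable <- 0L
  for (i in seq_len(nrow(markers))) {
    if (is.na(idx[i])) { n_missing <- n_missing + 1L; next }
    a <- c(variants$allele1[idx[i]], variants$allele2[idx[i]])
    if (anyNA(a)) { n_missing <- n_missing + 1L; next }
    dom <- markers$dominant[i]; rec <- markers$recessive[i]
    if (!all(a %in% c(dom, rec))) { n_unclassifiable <- n_unclassifiable + 1L; next }
    cls <- markers$locus_class[i]
    if (any(a == dom)) {
      key <- paste0(cls, "_dominant")
    } else {
      key <- paste0(cls, "_recessive")
    }
    counts[key] <- counts[key] + 1L
  }
  sdr_counts(counts[["male_dominant"]], counts[["male_recessive"]],
             counts[["female_dominant"]], counts[["female_recessive"]],
             n_missing = n_missing, n_unclassifiable = n_unclassifiable)
}

#' Construct SDR genotype-category counts
#'
#' The four categories are, at male-class markers, genotypes with a
#' dominant allele (Mm/MM, active male locus) vs homozygous recessive
#' (mm, inactive male locus); at female-class markers, dominant (Ff/FF,
#' inactive female locus / female sterility) vs homozygous recessive
#' (ff, active female locus / female fertility).
#'
#' @param n_male_dominant,n_male_recessive counts at male-class markers.
#' @param n_female_dominant,n_female_recessive counts at female-class
#'   markers.
#' @param n_missing,n_unclassifiable skipped-marker tallies.
#' @return an object of class `sdr_counts`.
#' @export
sdr_counts <- function(n_male_dominant, n_male_recessive,
                       n_female_dominant, n_female_recessive,
                       n_missing = 0L, n_unclassifiable = 0L) {
  vals <- c(n_male_dominant, n_male_recessive,
            n_female_dominant, n_female_recessive,
            n_missing, n_unclassifiable)
  if (any(vals < 0)) stop("counts must be non-negative")
  structure(
    list(n_male_dominant = as.integer(n_male_dominant),
         n_male_recessive = as.integer(n_male_recessive),
         n_female_dominant = as.integer(n_female_dominant),
         n_female_recessive = as.integer(n_female_recessive),
         n_missing = as.integer(n_missing),
         n_unclassifiable = as.integer(n_unclassifiable)),
    class = "sdr_counts"
  )
}

#' @export
print.sdr_counts <- function(x, ...) {
  cat(sprintf(
    "<sdr_counts male Mm/MM=%d mm=%d | female Ff/FF=%d ff=%d (missing=%d, unclassifiable=%d)>\n",
    x$n_male_dominant, x$n_male_recessive,
    x$n_female_dominant, x$n_female_recessive,
    x$n_missing, x$n_unclassifiable))
  invisible(x)
}

#' Call the sex of a specimen from SDR genotype counts
#'
#' Summarizes the counts as two fractions: the male-dominant fraction
#' (share of genotyped male-class markers with an active-male genotype)
#' and the female-recessive fraction (share of genotyped female-class
#' markers with an active-female genotype). The call is:
#' * `male` — active male locus and inactive female locus:
#'   male-dominant fraction >= `male_dom_min` AND female-recessive
#'   fraction <= `female_rec_max` (both thresholds inclusive);
#' * `female` — inactive male locus and active female locus:
#'   male-dominant fraction <= `1 - male_dom_min` AND female-recessive
#'   fraction >= `1 - female_rec_max`;
#' * `hermaphrodite` — both loci active (the recombinant haplotype
#'   signature of domesticated, self-fertile vines): male-dominant
#'   fraction >= `male_dom_min` AND female-recessive fraction >=
#'   `1 - female_rec_max`;
#' * `undetermined` otherwise, or when a locus class has no genotyped
#'   marker (`reason` records which).
#'
#' @param counts an [sdr_counts()] object.
#' @param male_dom_min minimum male-dominant fraction for an active male
#'   locus (default 0.8).
#' @param female_rec_max maximum female-recessive fraction for an
#'   inactive female locus (default 0.2).
#' @return an object of class `sex_call` with fields `call`,
#'   `male_dominant_fraction`, `female_recessive_fraction`, `thresholds`,
#'   `reason`.
#' @export
call_sex <- function(counts, male_dom_min = 0.8, female_rec_max = 0.2) {
  stopifnot(inherits(counts, "sdr_counts"),
            male_dom_min > 0, male_dom_min <= 1,
            female_rec_max >= 0, female_rec_max < 1)
  n_male <- counts$n_male_dominant + counts$n_male_recessive
  n_female <- counts$n_female_dominant + counts$n_female_recessive
  mk <- function(call, mdf, frf, reason = "") {
    structure(
      list(call = call,
           male_dominant_fraction = mdf,
           female_recessive_fraction = frf,
           thresholds = c(male_dom_min = male_dom_min,
                          female_rec_max = female_rec_max),
           reason = reason),
      class = "sex_call")
  }
  if (n_male == 0L || n_female == 0L) {
    why <- paste0("no genotyped ",
                  paste(c("male", "female")[c(n_male == 0L, n_female == 0L)],
                        collapse = " and "),
                  "-class markers")
    return(mk("undetermined",
              if (n_male) counts$n_male_dominant / n_male else NA_real_,
              if (n_female) counts$n_female_recessive / n_female else NA_real_,
              why))
  }
  mdf <- counts$n_male_dominant / n_male
  frf <- counts$n_female_recessive / n_female
  call <- if (mdf >= male_dom_min && frf <= female_rec_max) {
    "male"
  } else if (mdf <= 1 - male_dom_min && frf >= 1 - female_rec_max) {
    "female"
  } else if (mdf >= male_dom_min && frf >= 1 - female_rec_max) {
    "hermaphrodite"
  } else {
    "undetermined"
  }
  mk(call, mdf, frf,
     if (call == "undetermined") "fractions match no locus-activity pattern"
     else "")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf(
    "<sex_call %s: male-dominant %.3f, female-recessive %.3f (thresholds %.2f/%.2f)%s>\n",
    x$call, x$male_dominant_fraction, x$female_recessive_fraction,
    x$thresholds[["male_dom_min"]], x$thresholds[["female_rec_max"]],
    if (nzchar(x$reason)) paste0(" — ", x$reason) else ""))
  invisible(x)
}

#' Write a sex-call report as JSON
#' @param counts an `sdr_counts`.
#' @param sc the matching `sex_call`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sex_report <- function(counts, sc, path) {
  payload <- list(
    schema = "argneighbor-sexdet/1",
    version = as.character(utils::packageVersion("argneighbor")),
    counts = unclass(counts),
    fractions = list(
      male_dominant = sc$male_dominant_fraction,
      female_recessive = sc$female_recessive_fraction),
    thresholds = as.list(sc$thresholds),
    call = sc$call,
    reason = sc$reason
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a specimen's calls at marker positions from a genotype matrix
#'
#' Converts allele indices back to bases for one sample, yielding the
#' `variants` data.frame shape [count_sdr_genotypes()] expects.
#'
#' @param gm a `genotype_matrix`.
#' @param sample sample id (a column of `gm`).
#' @return data.frame with `chrom`, `pos`, `allele1`, `allele2`.
#' @export
specimen_calls <- function(gm, sample) {
  if (!(sample %in% colnames(gm$a1))) stop("unknown sample: ", sample)
  alleles <- Map(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1L]]),
                 gm$sites$ref,
                 ifelse(is.na(gm$sites$alt) | gm$sites$alt == ".",
                        "", gm$sites$alt))
  decode <- function(idx) {
    vapply(seq_len(n_sites(gm)), function(i) {
      if (is.na(idx[i])) NA_character_ else alleles[[i]][idx[i] + 1L]
    }, character(1))
  }
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    allele1 = decode(gm$a1[, sample]),
    allele2 = decode(gm$a2[, sample]),
    stringsAsFactors = FALSE
  )
}
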