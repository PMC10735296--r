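#!/usr/bin/env Rscript
# Stage 2 — ancestral-allele polarization.
#
# Reads the outgroup VCF from stage 1, assigns ancestral alleles as the
# outgroup major allele, and excludes sites where fewer than 9 of 10
# outgroup units agree. Writes results/polarization/site_status.tsv, the
# polarized VCF (kept sites, AA tag), and prints the status breakdown
# against the planted truth.

suppressPackageStartupMessages(library(argneighbor))

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "polarization")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

gm <- read_genotype_vcf(file.path(data_dir, "outgroup.vcf"))
outgroup <- readLines(file.path(data_dir, "outgroup_ids.txt"))
truth <- read.csv(file.path(data_dir, "outgroup_truth.csv"))

message("Polarizing ", n_sites(gm), " sites against ", length(outgroup),
        " outgroup individuals (>= 9/10 concordance) ...")
pol <- polarize(gm, outgroup, min_major = 9, total = 10)
print(table(pol$status))

write_site_status(pol, file.path(out_dir, "site_status.tsv"))
write_polarized_vcf(kept_sites(gm, pol), pol,
                    file.path(out_dir, "polarized.vcf"))

agree <- all((pol$status == "kept") == !truth$planted_fail)
message("kept sites: ", sum(pol$status == "kept"),
        " — matches planted truth: ", agree)
message("Done: outputs under ", out_dir)
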