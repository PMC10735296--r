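#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Produces, under results/data/:
#   trees/chr*.trees + meta.csv : a 2-deme structured panel (10 diploids
#       per deme, deep split, 5 chromosomes of 200 kb) with true deme
#       labels — stands in for per-chromosome inferred ARGs.
#   outgroup.vcf                : biallelic genotypes for 10 outgroup
#       diploids plus 4 carriers, with 25% of sites planted to violate
#       the 9-of-10 concordance rule.
#   sdr_markers.tsv, sdr_specimen.csv : an SDR marker panel and the
#       genotypes of a specimen of known (male) sex at 5% error.

suppressPackageStartupMessages(library(argneighbor))

seed <- 20260926L
data_dir <- file.path("results", "data")
trees_dir <- file.path(data_dir, "trees")
dir.create(trees_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating 2-deme structured panel (5 chromosomes x 200 kb) ...")
sim <- simulate_structured(
  sim_config(seed = seed, sequence_length = 2e5),
  n_chromosomes = 5, dir = trees_dir)
n_tr <- vapply(sim$views, n_trees, numeric(1))
message("  ", length(sim$views), " chromosomes, ",
        sum(n_tr), " local trees in total (",
        paste(n_tr, collapse = ", "), ")")
message("  panel: ", length(unique(sim$meta$accession_id)),
        " diploid accessions across ",
        length(unique(sim$meta$ancestry_group)), " demes")

message("Simulating outgroup genotypes (100 sites, 25% planted failures) ...")
og <- simulate_outgroup_genotypes(100, fail_fraction = 0.25, seed = seed + 1)
write_genotype_vcf(og$gm, file.path(data_dir, "outgroup.vcf"))
writeLines(og$outgroup, file.path(data_dir, "outgroup_ids.txt"))
write.csv(og$truth, file.path(data_dir, "outgroup_truth.csv"),
          row.names = FALSE)
message("  planted failures: ", sum(og$truth$planted_fail), " of 100")

message("Simulating SDR panel for a known male specimen (5% error) ...")
panel <- simulate_sdr_panel("male", n_markers = 60, error_rate = 0.05,
                            seed = seed + 2)
write.table(panel$markers, file.path(data_dir, "sdr_markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(panel$variants, file.path(data_dir, "sdr_specimen.csv"),
          row.names = FALSE)
message("  ", nrow(panel$markers), " markers written; planted sex: ",
        panel$truth)
message("Done: inputs under ", data_dir)
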