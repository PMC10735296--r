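#!/usr/bin/env Rscript
# Stage 3 — genealogical nearest-neighbor proportions.
#
# Loads the per-chromosome tree sequences and accession metadata from
# stage 1, computes span-weighted neighbor profiles for one focal
# accession (both haplotypes), collapses to accession level, aggregates
# genome-wide, ranks closest neighbors and reports the per-chromosome
# winners. Writes results/gnn/<focal>.{csv,json} and a ranking table.

suppressPackageStartupMessages(library(argneighbor))

trees_dir <- file.path("results", "data", "trees")
out_dir <- file.path("results", "gnn")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

views <- read_tree_sequence_dir(trees_dir)
meta <- read_accession_table(file.path(trees_dir, "meta.csv"))
focal <- meta$accession_id[1]

message("Panel: ", length(unique(meta$accession_id)), " accessions, ",
        length(views), " chromosomes, ",
        sum(vapply(views, n_trees, numeric(1))), " local trees")
message("Focal accession: ", focal, " (deme ",
        unique(meta$ancestry_group[meta$accession_id == focal]), ")")

ap <- accession_analysis(views, meta, focal)
paths <- write_profile(ap, file.path(out_dir, focal))

top <- rank_neighbors(ap, 10)
message("\nClosest genome-wide neighbors (proportion of genome as neighbor):")
print(top, digits = 3)
write.csv(top, file.path(out_dir, paste0(focal, "_top10.csv")),
          row.names = FALSE)

message("\nClosest neighbor per chromosome:")
for (chrom in names(ap$per_chromosome_closest)) {
  message("  ", chrom, ": ",
          paste(ap$per_chromosome_closest[[chrom]], collapse = ", "))
}
deme_of <- tapply(meta$ancestry_group, meta$accession_id, unique)
same <- vapply(ap$per_chromosome_closest, function(w) {
  all(deme_of[w] == deme_of[[focal]])
}, logical(1))
message(sprintf("Same-deme closest neighbor on %d/%d chromosomes",
                sum(same), length(same)))
message("Done: profile at ", paths[["json"]])
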