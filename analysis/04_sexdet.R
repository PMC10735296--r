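#!/usr/bin/env Rscript
# Stage 4 — sex determination from SDR genotypes.
#
# Classifies the synthetic specimen's genotypes at the stage-1 SDR marker
# panel into the four locus categories (Mm/MM, mm, Ff/FF, ff), calls its
# sex, and repeats the call on the published genotype-category counts of
# a historical wild grapevine specimen (1087, 21, 225, 28). Writes JSON
# reports under results/sexdet/.

suppressPackageStartupMessages(library(argneighbor))

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "sexdet")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

markers <- read_sdr_markers(file.path(data_dir, "sdr_markers.tsv"))
variants <- read.csv(file.path(data_dir, "sdr_specimen.csv"))

message("Counting genotype states at ", nrow(markers), " SDR markers ...")
cnt <- count_sdr_genotypes(variants, markers)
print(cnt)
sc <- call_sex(cnt)
print(sc)
write_sex_report(cnt, sc, file.path(out_dir, "synthetic_specimen.json"))

message("\nPublished genotype-category counts of the historical specimen:")
cnt_pub <- sdr_counts(n_male_dominant = 1087, n_male_recessive = 21,
                      n_female_dominant = 225, n_female_recessive = 28)
print(cnt_pub)
sc_pub <- call_sex(cnt_pub)
print(sc_pub)
write_sex_report(cnt_pub, sc_pub,
                 file.path(out_dir, "historical_specimen.json"))
message("Done: reports under ", out_dir)
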