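Package: argneighbor
Title: Genealogical Nearest-Neighbor Proportions over Tree Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes span-weighted genealogical nearest-neighbor
    proportions for focal samples along ancestral recombination graphs
    represented as sequences of local trees. For a focal haplotype the
    package measures, for every other haplotype or accession, the
    proportion of the genome (and of local trees) for which the two are
    genealogical neighbors, aggregates the statistic across chromosomes,
    collapses haplotypes to diploid accessions, and ranks closest
    neighbors per chromosome and genome-wide. Also provides outgroup-based
    ancestral-allele polarization with a majority-concordance site filter,
    a sex-determination-region genotype classifier for dioecious
    grapevine, and coalescent-backed synthetic data generators so the
    whole pipeline runs on simulated inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
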