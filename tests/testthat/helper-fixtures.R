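# Shared fixtures, all built in code.

# The 30/70 two-tree fixture: x is u's neighbor only on the first 30 bp,
# y only on the remaining 70 bp.
toy_30_70 <- function() {
  build_toy_tree_sequence(data.frame(
    newick = c("((u,x),y)", "((u,y),x)"),
    span = c(30, 70)), chromosome_id = "toy")
}

toy_leaf <- function(ts, name) {
  ts$samples$leaf_id[ts$samples$name == name]
}

# A diploid panel over 4 accessions (8 haplotype leaves a1,a2,...,d2),
# built from hand-specified topologies so accession-level union spans are
# known by construction.
toy_accession_table <- function() {
  accession_table(data.frame(
    accession_id = rep(c("accA", "accB", "accC", "accD"), each = 2),
    leaf_id = 0:7,
    haplotype_index = rep(0:1, 4),
    ancestry_group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    stringsAsFactors = FALSE
  ))
}

# Leaf names matching toy_accession_table: sorted order a1,a2,b1,...,d2
# maps to leaf ids 0..7.
toy_diploid_ts <- function(specs) {
  build_toy_tree_sequence(specs, chromosome_id = "toydip")
}
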