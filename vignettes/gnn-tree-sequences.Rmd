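---
title: "Span-weighted genealogical nearest neighbors over tree sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span-weighted genealogical nearest neighbors over tree sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argneighbor)
```

## The problem

Relatedness between grapevine accessions (cultivars and wild *Vitis
vinifera* ssp. *sylvestris* specimens) is usually summarized by genome-wide
averages — identity-by-state distances, admixture proportions, principal
components. Those averages hide the fact that, because of recombination,
the genealogy relating a set of sequenced chromosomes changes along the
genome: an accession can be the closest relative of a focal vine on one
chromosome segment and unrelated on the next. The ancestral recombination
graph (ARG) makes this explicit. In its tree-sequence representation, a
chromosome is covered by an ordered set of local trees, each valid on a
genomic interval whose boundaries are recombination breakpoints, all trees
sharing the same sample leaves (two haplotype leaves per phased diploid
accession).

This package quantifies pairwise genealogical proximity directly on that
structure, per accession rather than per ancestry group: for a focal
haplotype it asks, for every other haplotype, *on what fraction of the
genome are the two genealogical nearest neighbors?* That is the quantity
needed to say things like "for roughly 15% of its genome, this cultivar's
closest relatives in the panel are these two varieties".

## The statistic

Let $X$ be the leaf set and $T$ the ordered local trees of one
chromosome's tree sequence. For a focal leaf $u \in X$, the *parental
node* $v$ in a tree $t$ is the first node on the path from $u$ to the
root, and the neighbor set $N_t(u) \subseteq X \setminus \{u\}$ contains
every other leaf descending from $v$. The indicator
$I_{u,t}(x) \in \{0, 1\}$ records whether $x \in N_t(u)$.

Two normalizations are reported:

$$G_{u,x} = \frac{1}{|T|} \sum_{t \in T} I_{u,t}(x), \qquad
  P_{u,x} = \frac{1}{L} \sum_{t \in T} L_t \, I_{u,t}(x),$$

where $L_t$ is the genomic span of tree $t$ in base pairs and
$L = \sum_t L_t$. $G$ is the fraction of local trees in which $x$ is a
neighbor of $u$; $P$ weights each tree by its span and is the fraction of
the *genome* for which the two are neighbors. The two differ whenever
tree spans are uneven — the package's two-tree worked example (spans
30 bp and 70 bp, with $x$ a neighbor only in the first tree and $y$ only
in the second) gives $G_{u,x} = G_{u,y} = 0.5$ but $P_{u,x} = 0.3$,
$P_{u,y} = 0.7$:

```{r toy}
ts <- build_toy_tree_sequence(data.frame(
  newick = c("((u,x),y)", "((u,y),x)"), span = c(30, 70)))
p <- span_weighted_gnn(ts, 0)        # leaf 0 is "u" (sorted label order)
p$span_fraction
tree_fraction_gnn(ts, 0)
```

This is a per-accession variant of the genealogical-nearest-neighbors
idea: the classic statistic reports, for a focal sample, the *ancestry
group* composition of its neighbors; here the identity of each individual
neighbor is retained, because the questions of interest (which named
cultivar is the closest relative, and on how much of the genome) are
about single accessions.

### Polytomies

The formulas above are usually written for bifurcating trees, but tree
sequences inferred from data routinely contain multifurcations (unresolved
nodes). The parental-node formulation needs no modification: under a
polytomy, $N_t(u)$ simply contains every other leaf child of $v$ and all
leaves of every sibling subtree. The package accepts polytomies
everywhere, and the random tree-sequence generator used in the property
tests produces them deliberately (merging 2–4 lineages at a time).

### Detached focal leaves

A leaf can, in principle, be isolated in some local tree (no parent
edge). A proportion "of the genome for which $u$ and $x$ are neighbors"
is undefined where $u$ has no genealogy, so such trees are excluded from
both the numerator and the denominator: $P$ is reported relative to the
`effective_span` (the genome where the focal leaf is attached) and,
symmetrically, $G$ relative to the attached-tree count. Both spans are
recorded on every profile; a focal leaf detached in *every* tree is an
error, not a silent zero. Single per-tree queries (`parental_node`,
`neighbor_set`) raise an error on a detached focal leaf rather than
returning a sentinel, leaving span handling to the caller.

### From haplotypes to accessions

The formulas are per-leaf (per sequence); results are wanted per diploid
accession. Three rules connect the two, all chosen to keep proportions in
$[0, 1]$ and interpretable as "fraction of the genome where this
*accession* is among the closest neighbors":

* **Union rule.** Per tree, an accession is a neighbor if *any* of its
  haplotype leaves is in $N_t(u)$; a tree where both haplotypes are
  neighbors contributes its span once, not twice.
* **Self-exclusion.** The focal accession (in particular the focal
  sample's other haplotype, which is trivially its nearest relative and
  carries no information about relatedness to other accessions) is
  removed from the reported neighbor universe. Its spans still count in
  the denominator.
* **Focal averaging.** When both haplotypes of the focal accession are
  analyzed, the accession-level proportion is the mean of the two
  per-haplotype collapses.

### Aggregation across chromosomes

Genome-wide values combine per-chromosome profiles by summing the exact
base-pair numerators and effective spans and dividing once — a
span-weighted combination, never an unweighted mean of per-chromosome
proportions (chromosomes differ in length, and an unweighted mean would
let a short chromosome move the genome-wide value disproportionately).
$G$ aggregates with attached-tree-count weights for the same reason.
Because the combination is performed on the raw accumulators, aggregating
over *any* partition of one tree sequence reproduces the unpartitioned
profile exactly; the test suite asserts this identity on simulated data.

Ranking reports ties explicitly: equal proportions are ordered
lexicographically by accession id and flagged, and the per-chromosome
closest-neighbor summary returns *all* tied winners — never a silent
arbitrary choice.

## Ancestral-allele polarization

Upstream ARG inference requires polarized (ancestral/derived) alleles.
The package implements an outgroup rule: at each biallelic site, the
ancestral allele is the major allele among a panel of wild outgroup
individuals (a wild North American panel in the motivating application,
$n = 10$ diploids), and sites whose major allele is supported by fewer
than 9 of 10 outgroup units are excluded. Sites with more than two
alleles are excluded before the rule applies, and every input site
receives exactly one status (`kept`, `excluded_outgroup_rule`,
`excluded_not_biallelic`) so the three categories always sum to the input
count.

Two details of the counting are genuine design choices, stated here
because the "9 out of 10" arithmetic alone does not fix them:

* **Counting unit.** With 10 diploid outgroup individuals, "out of 10"
  is naturally one unit per *individual*. The default therefore counts
  per-individual consensus alleles: a homozygous individual contributes
  one unit of its allele; heterozygous individuals contribute no unit. A
  `unit = "haplotype"` switch counts the 20 alleles instead, with the
  threshold applied as the fraction $\geq 9/10$.
* **Missing data.** Units with missing calls drop out of the
  denominator; the threshold then applies as a fraction
  `min_major / total` of contributing units, compared exactly by integer
  cross-multiplication (never by floating-point division). A site whose
  outgroup is entirely missing or entirely heterozygous is excluded with
  the distinct reason `no_outgroup_data`; an exact 50/50 split has no
  major allele and is excluded as a `tie`, never resolved by coin flip.

The rule is idempotent (re-running on the kept subset changes nothing)
and symmetric under REF/ALT relabeling; both are asserted as property
tests.

## Sex determination from the SDR

Grapevine dioecy is controlled by a sex-determination region of roughly
150 kb on chromosome 2. At markers in this region, two locus classes are
scored for a specimen: at *male-locus* markers, a genotype carrying at
least one dominant allele (Mm/MM) indicates an active male locus (male
fertility) while a homozygous recessive genotype (mm) indicates an
inactive one; at *female-locus* markers, a dominant genotype (Ff/FF)
indicates a *suppressed* female locus (female sterility) while the
homozygous recessive (ff) indicates an active, female-fertile locus.
Counting the four categories over a marker panel summarizes a specimen as
two fractions: the male-dominant fraction (active-male evidence) and the
female-recessive fraction (active-female evidence).

The source material calls sex qualitatively ("a high number of dominant
alleles at the male locus"). The package operationalizes this with two
declared, configurable thresholds, both inclusive and both printed in
every report: an active male locus requires a male-dominant fraction
$\geq 0.8$ (`male_dom_min`), an inactive female locus a female-recessive
fraction $\leq 0.2$ (`female_rec_max`). The defaults are deliberately
loose: a genotyped wild male specimen in the motivating study shows
fractions near 0.98 and 0.11, which pass with a wide margin, and the
package's error model (5% genotype flips over 60 markers) keeps both
fractions far from the boundaries. The calls are then:

| call | male locus | female locus |
|---|---|---|
| male | active (fraction $\geq$ 0.8) | suppressed (fraction $\leq$ 0.2) |
| female | inactive (fraction $\leq$ 0.2) | active (fraction $\geq$ 0.8) |
| hermaphrodite | active | active |
| undetermined | anything else, or an ungenotyped locus class | |

The hermaphrodite row is a heuristic operationalization of the
recombinant-haplotype model of domesticated, self-fertile vines: loss of
dioecy is attributed to a rare recombination that put male fertility and
female fertility on the same haplotype, so a hermaphrodite shows *both*
loci active — dominant alleles at the male locus together with a high
female-recessive fraction. It is monotone in the evidence (adding
male-dominant observations can never flip a male call away from male) and
should be read as a screening classification, not a validated assay.

## The synthetic-data generators

All tests and the acceptance analysis run on synthetic inputs; the
generators are first-class, seeded, pure functions of their configuration,
and every planted truth (deme labels, failure counts, sex) is returned
alongside the data so tests never re-derive truth from outputs.

* `random_tree_sequence()` draws arbitrary multifurcating topologies and
  integer spans — the stress input for the oracle-equivalence property.
* `simulate_structured()` delegates to a standard coalescent simulator
  (msprime, via the bundled Python helper) under a clean island-split
  demography. The defaults — 2 demes of 10 diploids, $N_e = 10^4$ per
  deme, a split $2 \times 10^5$ generations ago with no subsequent
  migration, 1 Mb of sequence at a recombination rate of
  $10^{-8}$/bp/generation — describe a deeply structured panel in which
  lineages coalesce within their deme long before the split, so the true
  closest neighbor of every sample is a same-deme sample. That planted
  signal is what the label-recovery checks score: the top-ranked neighbor
  of each focal accession on a 1 Mb chromosome, and the per-chromosome
  closest neighbor over a 19-chromosome run (150 kb per chromosome, kept
  short because the per-chromosome statistic only needs a few hundred
  trees to stabilize).
* `simulate_outgroup_genotypes()` plants an exact number of
  concordance-rule violations (majority carried by 8 of 10 units) so the
  kept-site count is known by construction.
* `simulate_sdr_panel()` plants sex-consistent genotypes at 60 markers
  (30 per locus class) and flips each marker's category independently
  with the requested error probability.

What the simulations do *not* emulate matters for interpreting green
tests: local trees are taken as known, so nothing here measures
robustness to ARG-inference error, phasing switch errors, or genotyping
noise upstream of the tree sequence; the demography is a caricature (no
domestication bottlenecks, gene flow, or selection); and the SDR error
model flips categories independently, unlike real mapping artifacts which
cluster. Passing tests show the statistic and its bookkeeping are
correct, not that inferred ARGs from real grapevine panels are.

## Numerical contract and problem sizes

Spans are accumulated as exact integer base-pair sums and divided once at
the end, so all proportion identities (partition/concatenation
equivalence, permutation invariance of tree order) hold to machine
precision; the cross-implementation tolerance between the production
profile (one shared pass per tree serving all focal leaves) and the naive
per-tree oracle (independent recursive recount) is $10^{-12}$. The
default validation scales — 100 random tree sequences of 2–40 leaves and
1–200 trees for the equivalence property, one 1 Mb and nineteen 150 kb
coalescent chromosomes for label recovery, 1,000 SDR panels at 5% error —
were chosen once as the smallest sizes at which each property is
informative, and run in a few minutes on one CPU.

## Limitations

* The package consumes tree sequences; it does not infer them. The
  plain-text `.trees` format it reads and writes is a minimal interchange
  representation (intervals + newick over named leaves), not the binary
  succinct tree-sequence format of the tskit ecosystem.
* Accession collapsing assumes at most two haplotypes per accession in
  the sense that the focal average is defined over the haplotypes
  supplied; higher ploidy has not been exercised.
* The sex caller classifies marker-count summaries; it does not model
  linkage among SDR markers or read-level evidence, and the
  hermaphrodite rule in particular is a declared heuristic.
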