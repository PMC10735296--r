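# argneighbor

Span-weighted genealogical nearest-neighbor proportions over ancestral
recombination graphs, for population-genetic analyses of phased diploid
panels — written for grapevine (*Vitis vinifera*) accession panels, but
generic over any tree-sequence input.

## What it computes

A recombining genome is related to its neighbors through a *sequence* of
genealogies: each local tree of an ARG covers a genomic interval, and the
identity of a sample's closest relatives changes from interval to
interval. For a focal haplotype leaf *u*, define in each local tree *t*
the parental node *v* (the first node on the path from *u* to the root)
and the neighbor set *N* (all other leaves descending from *v*), with
indicator I<sub>u,t</sub>(x) = 1 iff x ∈ N. The package reports, for
every other leaf or accession *x*:

* **G<sub>u,x</sub>** = (1/|T|) Σ<sub>t</sub> I<sub>u,t</sub>(x) — the
  fraction of local trees where *x* is a genealogical neighbor of *u*;
* **P<sub>u,x</sub>** = (1/L) Σ<sub>t</sub> L<sub>t</sub> I<sub>u,t</sub>(x)
  — the fraction of the *genome* (span-weighted, L<sub>t</sub> = tree
  span in bp, L = Σ L<sub>t</sub>) for which *u* and *x* are neighbors.

On top of the per-leaf statistic the package collapses haplotypes to
diploid accessions (any-haplotype union rule, focal-haplotype averaging,
self-exclusion), aggregates across chromosomes by exact span weighting,
ranks closest neighbors with explicit tie handling, and reports
per-chromosome closest neighbors. Two companion modules cover the
flanking steps of the same study design: outgroup-based ancestral-allele
polarization (major allele among 10 wild outgroup individuals, sites
below 9-of-10 concordance excluded) and a sex-determination-region (SDR)
genotype classifier for dioecious grapevine. A synthetic-data module
(hand-specified toy tree sequences, msprime-backed structured coalescent
panels with known deme labels, planted-truth outgroup matrices and SDR
panels) lets the whole pipeline run with no external data.

## Worked example

The defining contrast between G and P in two lines — two trees spanning
30 and 70 bp, where `x` is the focal leaf's neighbor only in the first
tree and `y` only in the second:

```r
library(argneighbor)
ts <- build_toy_tree_sequence(data.frame(
  newick = c("((u,x),y)", "((u,y),x)"), span = c(30, 70)))
span_weighted_gnn(ts, 0)$span_fraction   # leaf 0 = "u"; 1 = "x"; 2 = "y"
#>   1   2
#> 0.3 0.7
tree_fraction_gnn(ts, 0)
#>   1   2
#> 0.5 0.5
```

Both leaves are neighbors in half of the trees (G = 0.5), but `y` is a
neighbor on 70% of the genome (P = 0.7): span weighting is the statistic.

A full accession-level run on a simulated two-deme panel (10 diploids per
deme, deep split; `analysis/03_gnn.R` prints this):

```
Focal accession: deme0_ind000 (deme deme0)
Closest genome-wide neighbors (proportion of genome as neighbor):
   accession_id     P     G   tie
1  deme0_ind005 0.363 0.363 FALSE
2  deme0_ind006 0.280 0.275 FALSE
3  deme0_ind002 0.268 0.277 FALSE
...
Same-deme closest neighbor on 5/5 chromosomes
```

Every top neighbor comes from the focal sample's own deme — the planted
label structure is recovered from the genealogies alone. And the sex
caller on the published SDR genotype-category counts of a historical
wild grapevine specimen (1087 Mm/MM, 21 mm, 225 Ff/FF, 28 ff):

```r
call_sex(sdr_counts(1087, 21, 225, 28))
#> <sex_call male: male-dominant 0.981, female-recessive 0.111 (thresholds 0.80/0.20)>
```

A high male-dominant fraction with a low female-recessive fraction is the
signature of an active male locus and a suppressed female locus: a male
specimen.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
inputs and write their tables under `results/`:

1. `01_simulate.R` — structured coalescent panel, outgroup VCF with
   planted polarization failures, SDR marker panel of known sex;
2. `02_polarize.R` — ancestral-allele assignment and the 9-of-10 site
   filter, with the status breakdown checked against the planted truth;
3. `03_gnn.R` — per-chromosome and genome-wide neighbor profiles,
   accession ranking, per-chromosome closest neighbors;
4. `04_sexdet.R` — SDR genotype counting and sex calls for the synthetic
   specimen and the published counts.

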