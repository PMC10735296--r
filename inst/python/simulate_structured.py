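"""Coalescent simulation glue: msprime -> plain-text .trees files.

Simulates a structured population (n demes splitting from a common
ancestor, optional symmetric migration afterwards) and writes, per
chromosome, the local trees as a text file the R package reads:

    #argneighbor-trees 1
    #chromosome=<id>
    #samples=<name>:<leaf_id>,...
    left<TAB>right<TAB>newick

plus one meta.csv mapping haplotype leaves to diploid accessions and
their true deme (the planted ancestry label).
"""

import argparse
import os

import msprime


def build_demography(n_demes, ne, split_time, migration_rate):
    demography = msprime.Demography()
    for d in range(n_demes):
        demography.add_population(name=f"deme{d}", initial_size=ne)
    if n_demes > 1:
        demography.add_population(name="anc", initial_size=ne)
        demography.add_population_split(
            time=split_time,
            derived=[f"deme{d}" for d in range(n_demes)],
            ancestral="anc",
        )
        if migration_rate > 0:
            for a in range(n_demes):
                for b in range(n_demes):
                    if a != b:
                        demography.set_migration_rate(
                            source=f"deme{a}", dest=f"deme{b}",
                            rate=migration_rate)
    return demography


def write_trees(ts, chrom, path):
    with open(path, "w") as fh:
        fh.write("#argneighbor-trees 1\n")
        fh.write(f"#chromosome={chrom}\n")
        names = ",".join(f"n{u}:{u}" for u in ts.samples())
        fh.write(f"#samples={names}\n")
        for tree in ts.trees():
            left = int(tree.interval.left)
            right = int(tree.interval.right)
            nwk = tree.as_newick(include_branch_lengths=False)
            fh.write(f"{left}\t{right}\t{nwk}\n")


def write_meta(ts, path):
    pop_name = {p.id: p.metadata.get("name", str(p.id))
                for p in ts.populations()}
    with open(path, "w") as fh:
        fh.write("accession_id,leaf_id,haplotype_index,ancestry_group\n")
        for u in ts.samples():
            node = ts.node(u)
            ind = node.individual
            deme = pop_name[node.population]
            hap = list(ts.individual(ind).nodes).index(u)
            fh.write(f"{deme}_ind{ind:03d},{u},{hap},{deme}\n")


def main():
    p = argparse.ArgumentParser()
    p.add_argument("--n-demes", type=int, default=2)
    p.add_argument("--samples-per-deme", type=int, default=10)
    p.add_argument("--ne", type=float, default=1e4)
    p.add_argument("--split-time", type=float, default=2e5)
    p.add_argument("--migration-rate", type=float, default=0.0)
    p.add_argument("--length", type=float, default=1e6)
    p.add_argument("--recomb", type=float, default=1e-8)
    p.add_argument("--seed", type=int, required=True)
    p.add_argument("--n-chromosomes", type=int, default=1)
    p.add_argument("--out-dir", required=True)
    args = p.parse_args()

    os.makedirs(args.out_dir, exist_ok=True)
    demography = build_demography(args.n_demes, args.ne, args.split_time,
                                  args.migration_rate)
    samples = {f"deme{d}": args.samples_per_deme
               for d in range(args.n_demes)}
    for c in range(args.n_chromosomes):
        ts = msprime.sim_ancestry(
            samples=samples,
            demography=demography,
            sequence_length=args.length,
            recombination_rate=args.recomb,
            ploidy=2,
            random_seed=args.seed + c,
        )
        chrom = f"chr{c + 1:02d}"
        write_trees(ts, chrom, os.path.join(args.out_dir, f"{chrom}.trees"))
        if c == 0:
            write_meta(ts, os.path.join(args.out_dir, "meta.csv"))


if __name__ == "__main__":
    main()
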