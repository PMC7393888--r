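# plastmut

Directions, spectra and rates of nucleotide and structural mutations in
chloroplast-genome alignments.

Comparative plastome studies need more than a SNP count: for every
mutation they ask *which state is ancestral*, *on which branch did it
arise*, and *how fast does each mutation class accumulate*. `plastmut`
implements that census for a small clade with a self-evident phylogeny —
five ingroup plastomes spanning two subfamilies and three genera
(the Calycanthaceae design: two *Calycanthus*, two *Chimonanthus*,
*Idiospermum*), with two Magnoliaceae outgroups — where the tree shape at
subfamily, genus and species rank has only one possibility, so mutation
directions can be read off hierarchical outgroups instead of being
inferred from the same data. It is aimed at molecular evolution and
organellar genomics researchers who want reproducible event-level counts
rather than model-based summaries.

## What it computes

Given a whole-plastome multiple alignment (FASTA), a reference annotation
(GFF3) and a dated topology (Newick with node ages in My):

* **Nucleotide substitutions** — polymorphic columns among the ingroup,
  mapped to branches by Fitch parsimony on the fixed topology, polarized
  against rank-appropriate outgroups (plesiomorphic = shared with the
  outgroups, apomorphic = derived), and classified into the 12 directed /
  6 pooled substitution classes, transitions vs transversions (Ts/Tv),
  and synonymous vs nonsynonymous effects under the plastid genetic code.
  dN/dS here is the raw event-count ratio of the source tables, not a
  codon-model estimate.
* **Structural mutations** — alignment gap runs classified by cascade into
  microsatellites (1–3 bp motif, slippage-scale runs), tandem repeats
  (segment duplicating its adjacent flank) and plain indels, each
  polarized as insertion or deletion; plus stem-loop **inversions**
  (a reverse-complemented loop between a flanking inverted-repeat pair),
  detected directly from the alignment and treated as single
  non-directional events whose loop columns are masked from the SNP
  census.
* **Association** — for each comparison pair, the genetic distance of
  annotation units containing structural events (gdS) versus units
  without (gdN), plus the N/S count ratio.
* **Rates** — per-site per-year rates via μ = m/(nT) with Poisson
  standard error √m/(nT); substitution rates per rank use the rank's
  divergence age, structural rates the additive ingroup branch time
  (250.1 My at the default ages 108.8/18.7/7.6/6.2).
* **A plastome evolution simulator** — generates an annotated
  plastome-like genome and evolves it along the dated tree under
  calibrated substitution/indel/repeat/slippage/inversion processes,
  emitting the true alignment plus a complete event log, so every stage
  above is testable against known truth (`score_recovery()`).

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → call → associate → rates → score), writing tables under
`results/`. Running them in order on the default 20 kb study
configuration (seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_mutations.R
Rscript analysis/05_recovery.R
```

prints, among other things:

```
simulated 20509-column alignment of 7 taxa (seed 1)
truth log: 2327 events (indel=63, inversion=4, microsatellite=23, repeat=42, substitution=2195)
945 polymorphic sites: 940 biallelic, 5 triallelic+, 39 parallel
direction inferred for 842 sites (89.1%)
indel deletions:insertions = 18:3 (exact p = 0.0015)
SNP polarization accuracy: 0.9976 (n=839); rank accuracy: 1.0000
```

Reading this: of 945 polymorphic columns, 940 are biallelic and 39 are
parallel mutations (independent gains of the same allele, excluded from
direction analyses); hierarchical outgroups polarize 89% of sites; called
indels show the configured deletion bias (exact binomial p ≈ 0.002); and
checked against the simulator's truth log, 99.8% of polarized SNPs have
the correct ancestral state. Equivalent library calls:

```r
library(plastmut)
topo <- calycanthaceae_topology()
sim  <- simulate_plastomes(sim_config(), seed = 1)
inv  <- detect_inversions(sim$aln, topo)
snps <- annotate_snps(sim$aln, topo, sim$regions,
                      mask_columns = inversion_mask(inv))
ev   <- call_structural_events(sim$aln, topo, sim$regions, inversions = inv)
score_recovery(sim$truth, snps, ev, topo)
```

`run_all()` wires the whole pipeline over files and writes the report
bundle (`snps.tsv`, `spectrum.tsv`, `table2.tsv`, `table3.tsv`,
`inversions.tsv`, `table5.tsv`, `rates.tsv`, `codon_usage.tsv`,
`genegroups.tsv` and a checksummed manifest).

The methods vignette (`vignettes/plastmut-methods.Rmd`) documents the
model, every tunable threshold, the simulator's scope, and known
limitations.

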