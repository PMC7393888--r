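---
title: "Methods: calling, polarizing and dating plastome mutations"
author: "plastmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, polarizing and dating plastome mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the design of the study system

Chloroplast genomes accumulate point substitutions and a small repertoire
of structural changes — insertions/deletions, tandem duplications,
microsatellite slippage, and short stem-loop inversions. Counting these
events and, crucially, assigning each one a *direction* (which state is
ancestral, which derived) requires a phylogeny whose shape is not in
doubt. `plastmut` implements this census for a fixed seven-taxon system:
five ingroup plastomes spanning two subfamilies, three genera and two
two-species genera — the Calycanthaceae sampling, with *Idiospermum* as
the monotypic sister subfamily — plus two successively more distant
outgroups (Magnoliaceae). On this shape every branch has a taxonomic rank
(subfamily, genus, species), and each rank has a natural polarizing
outgroup set:

* subfamily-rank changes are polarized against the two external outgroups;
* genus-rank changes against the monotypic subfamily tip;
* species-rank changes against the two species of the sister genus.

Node ages (108.8, 18.7, 7.6 and 6.2 My at the crown nodes by default)
convert event counts into per-site, per-year rates.

## Nucleotide substitutions

**Calling.** A column is a polymorphic site when at least two distinct
bases occur among the five ingroup taxa and no ingroup taxon carries a gap
or N there. Gapped columns belong to structural events — keeping the two
censuses disjoint — and outgroup gaps only make a site's direction
uncertain, never uncalled. Columns inside detected inversion loops are
masked: a reverse-complemented loop shows every mismatching column as a
spurious substitution of the complementary class (A↔T, G↔C), which would
bias exactly the rarest classes of the spectrum. This mirrors the standard
practice of recognizing inversions at alignment time and treating each as
one event.

**Branch and rank.** Each biallelic site is mapped by small parsimony on
the fixed topology. The minimum change count comes from a Fitch down-pass;
single-change placement uses the exact bipartition rule (a single change
on a branch explains the site iff the tips below it are monochrome in one
state and all others monochrome in a different state, missing states
matching anything). Ties between placements that all sit on branches of
one rank resolve to that rank with no specific branch — notably, an
autapomorphy of the outermost outgroup always ties between the two
root-child edges of the rooted tree, which are one unrooted edge. Sites
needing two or more changes are checked, by enumerating minimal
reconstructions over the observed alleles (six internal nodes, so the
enumeration is tiny), for a parallel gain — two changes to the same
derived state — and are excluded from downstream direction and spectrum
analyses, as are triallelic sites.

**Direction and classes.** If all rank-outgroup taxa share one of the two
ingroup alleles, that allele is ancestral; otherwise the site is counted
but unpolarized. Polarized changes are classified into the 12 directed
classes, pooled into 6 complementary-strand pairs (an unstranded genome
cannot tell A→G from T→C), and into transitions versus transversions.

**Coding effect.** For exon sites the ancestral codon is rebuilt by
placing the ancestral base into the reference codon context (strand-aware;
minus-strand genes are read on the annotated strand), the derived base is
substituted, and both are translated under the bacterial/plastid genetic
code (table 11, read per-codon with no initiator special-casing). dN/dS is
deliberately a **raw count ratio** of nonsynonymous to synonymous events —
the arithmetic of the source tables — not a per-site-normalized estimate;
multi-SNP codons are evaluated per SNP against the ancestral context and
flagged. The G-test of class-proportion bias is the plain likelihood-ratio
statistic with a chi-square reference; expected counts below 1 raise a
warning because the approximation degrades there.

## Structural mutations

**Extraction.** Maximal runs of columns with an identical gap pattern
(the same set of taxa gapped) are one candidate event; overlapping
distinct patterns split at pattern boundaries. Pieces of one pattern
separated only by columns that are *also* gapped in all of its taxa — the
footprint of another lineage's insertion inside a deleted span — are
re-joined, and the interrupting columns are excluded from the event's
core and length. Branch, rank and carriers come from the same parsimony
machinery applied to the binary present/absent character.

**Classification cascade** (microsatellite → repeat → indel, mirroring the
carve-out of microsatellites from both other categories):

1. *Microsatellite* — the segment is whole copies of a 1–3 bp motif and
   the flanking run in the longer allele totals ≥ 8 bp (mononucleotide) or
   ≥ 3 copies (di-/trinucleotide). These are conventional cpSSR minima and
   are arguments. Run counting tolerates one interrupted motif copy:
   imperfect microsatellites — runs nicked by a later substitution — are
   still slippage loci.
2. *Repeat* — the segment (≥ 3 bp; shorter duplications are
   indistinguishable from chance) duplicates the immediately adjacent
   upstream or downstream flank. Segments of ≥ 5 bp may differ from the
   flank copy at one position: after a duplication arises, both copies
   drift apart by substitution, and on the deep branches of this system a
   strictly exact rule demonstrably misses a substantial fraction of true
   duplications while a one-mismatch allowance on ≥ 5 bp segments adds
   only a small chance-match risk (about 3% for a random 5-mer). Both
   thresholds are arguments.
3. *Indel* otherwise.

The segment and flanks are read from the taxon phylogenetically closest to
the gapped set that still carries the segment; if its context yields plain
indel, the remaining donors are consulted in closeness order — one intact
witness of the duplication or motif structure suffices.

**Direction.** Rank outgroups are read over the event's core columns: all
carrying the segment means the derived state is absence (deletion), all
lacking it means insertion; any disagreement or partial gap leaves the
direction uncertain. Inversions are non-directional; their orientation
polarity is reported (from the rank outgroups) but never used as a filter.

**Inversions.** The detector scans each ingroup taxon against each
outgroup for windows where one row is the reverse complement of the other
at homologous columns. A window must start and end on mismatching columns
(which anchors it canonically), reach a reverse-complement identity of at
least `loop_identity` (default 0.8) exceeding the direct identity, keep
its loop within `[2, max_loop]` bp, and be flanked in both rows by an
inverted repeat of at least `min_stem` bp, tolerating `stem_mismatch`
(default 2) mismatched pairs per arm — after an inversion arises, both
loop and stem decay by substitution, so exact matching (obtainable with
`loop_identity = 1`) is only appropriate for undiverged sequence. Windows
found in different taxon pairs are merged by reciprocal overlap; each
taxon is then assigned an orientation by similarity, carriers are mapped
by parsimony, and convergent occurrences in non-sister taxa are reported
per carrier clade, never merged. Loops identical to their own reverse
complement are undetectable in principle. The candidate enumeration is
anchored on mismatch clusters, and on planted fixtures it agrees exactly
with a brute-force scan over all windows.

## Association and rates

`associate()` partitions the alignment into annotation units — each
gene's exon set, each intron, each spacer (units, not fixed windows,
because units are reproducible and annotation-anchored). For a comparison
pair, a unit is "with structural mutation" if an event whose carriers
distinguish the pair starts inside it; gdS and gdN are uncorrected
p-distances over the concatenated columns of the two unit classes
(a Jukes–Cantor hook exists, but at the distances involved, below 0.04,
the correction is negligible and the plain distance is exactly testable).
Inversion-loop columns are excluded from both distances for the same
reason they are masked from SNP calling.

Rates use μ = m/(nT): per-rank substitution rates take the rank's
divergence node age as T, structural rates take the additive ingroup
branch time (the sum of the eight ingroup branch durations, 250.1 My on
the default ages). Ages are supplied in My and converted to years in
exactly one place. The standard error is the Poisson √m/(nT) — the
printed variance formula of the source is self-referential, and this is
its natural reading. The exact test of direction bias against 1:1 is the
two-sided binomial test; the loop-stem length correlation is a Pearson
test, undefined below three points or at zero variance.

## The simulator

`generate_root()` lays out genes (ATG + stop-free codons + stop, ~30% on
the minus strand, a quarter carrying one intron), introns and spacers at
the configured fractions (defaults ≈ 0.53/0.11/0.33 coding/intron/spacer)
and GC (0.39), and plants two substrate classes in spacers:
microsatellite runs (motif mix ≈ 96:13:8:2 mono-A/T : mono-C/G : di :
tri) and inverted-repeat pairs (stems 7–36 bp, loops 2–92 bp, loops
resampled if self-reverse-complementary). `evolve()` draws events per
branch as Poisson(rate × length × duration):

* substitutions pick a directed class from the 12-class weights first and
  then a uniform site carrying the source base, so realized classes follow
  the weights exactly; the default weights give Ts/Tv ≈ 1.6 with the A↔T
  and G↔C pools depressed to 2.84% and 3.65%;
* indels (default 5.5 × 10⁻⁶ /site/My, the density implied by 178 events
  over 130,345 bp × 250.1 My) are deletion-biased 8.5:1 with the
  published size-class mix (75.8% ≤ 10 bp, up to 364 bp);
* repeats (3.6 × 10⁻⁶) are tandem duplications of an adjacent segment,
  85.3% gains; losses delete one copy of an existing tandem pair;
* microsatellites slip by whole motif copies at planted loci, acting on a
  random copy, only while the run is intact, and never below the
  classification minima;
* inversions (4 × 10⁻⁷) reverse-complement the loop of a planted
  substrate, once per lineage, so convergent flips in separate lineages
  remain possible (and observable, except when the two lineages flanking
  the ingroup root both flip the same substrate — a genuine
  identifiability limit that recovery scoring sets aside).

Structural events are restricted to noncoding sequence (matching the
observed locations: 10 of 178 indels in coding, all microsatellites
noncoding) and avoid the planted substrate loci, which have their own
processes; same-branch events reject-and-redraw on overlap. The true
alignment is emitted from the event bookkeeping itself — global column
identifiers, never a realignment step — so caller tests measure calling
error only, and replaying the log must reproduce every tip byte for byte
(a tested invariant). Branch durations come from the dated topology, so
simulated data exercise the same rate-estimation path as real data.

An optional hotspot mode multiplies substitution and indel/repeat rates
in a fraction of noncoding units (the co-localization scenario behind the
gdS/gdN property; the tested dose is ×8 on 25% of noncoding units, chosen
as a strong-contrast treatment). Hotspots are noncoding because exons
cannot host structural events — a hot exon would only inflate gdN.

**What the simulator does not emulate.** No quadripartite LSC/IR/SSC
architecture or IR-duplicated genes (the analysis assumes each locus
appears once), no tRNA/rRNA gene structure, no selection (so dN/dS ≈ 1 by
construction), no site-rate heterogeneity outside hotspot mode, no
recombination, and no alignment error (real pipelines inherit aligner
artifacts that these tests deliberately exclude). Passing recovery tests
therefore demonstrates the correctness of the calling logic under known
history, not robustness to misalignment.

## Problem sizes and determinism

The validation suites run on 20 kb genomes (≈ 1,500–2,300 substitutions
and ≈ 130 structural events per replicate across the whole tree, the
event density of the real system) with five fixed seeds for recovery and
spectrum properties, and twenty 10 kb replicates per arm for the
null/hotspot association property. All analysis stages are deterministic;
the only randomness in the package is the simulator's, driven by one seed
per run. Reports are TSV with `#` metadata and fixed rounding (percents
and ratios to 2 dp, rates to 2 significant figures), and reruns on
identical inputs are byte-identical.

## Known limitations

* The census is defined for the fixed 7-taxon shape; other clades require
  the same structure (two 2-species genera, a monotypic sister subfamily,
  two successive outgroups).
* Parallel and triallelic sites are counted but excluded from direction
  and spectrum analyses; with deep outgroups a site whose outgroup carries
  a third allele is likewise set aside, which is conservative.
* Apparent-class composites at multiply-hit columns are irreducible at
  realistic densities; the inversion mask removes the largest such bias,
  but two same-path point substitutions can still masquerade as one event
  of a different class.
* dN/dS as a count ratio is not comparable to codon-model estimates and
  is undefined when no synonymous events are observed.
* The inversion detector requires intact flanking stems in both compared
  rows; inversions whose stems have eroded below `min_stem` (less the
  mismatch allowance) are not called.
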