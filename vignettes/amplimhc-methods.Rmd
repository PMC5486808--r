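---
title: "Genotyping MHC class I from deep amplicon sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping MHC class I from deep amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimhc)
```

## The problem

Classical MHC class I genes are often present in variable, unknown copy
number, so a PCR amplicon from one individual mixes reads from one to
several loci. Deep sequencing of such amplicons yields, per individual, a
tally of sequence variants in which true alleles sit alongside three kinds
of PCR artefact: single/double-substitution derivatives of an abundant
parent, chimeric prefix/suffix recombinants of two co-amplified alleles,
and sheer depth noise. `amplimhc` implements a filtering cascade that
separates these classes, plus the downstream molecular-evolution statistics
used to characterize the resulting allele set (diversity, divergence,
PBR-partitioned dN/dS, per-site selection), and a simulator that generates
data with exactly this structure together with a truth table, so the whole
chain is testable end to end.

The package is designed around exon 3 of a shorebird-type MHC-I system: a
247-nt amplicon covering alignment codons 93–173 of the α2 domain, with a
2-nt incomplete codon at each end, and a second allele class of 244 nt
carrying a 3-bp deletion at alignment codon 147. Both length classes are
treated as real alleles throughout; they are never merged with one another.

## The filtering cascade

1. **Depth gate.** Amplicons with fewer than `min_amplicon_depth` reads
   (default 4000) are removed; per-allele frequencies are meaningless at
   low depth.
2. **Artefact clustering.** Variants are visited in depth order (ties
   broken lexicographically). A variant within 1–2 substitutions of an
   existing cluster's dominant sequence *and* at ≤25% of that dominant's
   depth is merged into the deepest eligible cluster; a variant passing the
   distance rule but exceeding the depth ratio founds a new cluster flagged
   *subdominant* (a plausible real allele one or two substitutions from a
   commoner one); anything else founds a new unflagged cluster. Distances
   are Hamming distances between equal-length sequences only: the 244/247
   length classes can never absorb each other, and PCR indels are not part
   of the artefact model.
3. **Threshold calibration.** The per-amplicon frequency cutoff that
   separates alleles from residual artefacts is not fixed a priori.
   Individuals sequenced twice (technical duplicates) should receive
   identical genotypes; the cascade therefore scans a threshold grid
   (default 0.5–10% in 0.1% steps) and scores each value by the number of
   duplicate pairs with identical provisional allele sets, then by the mean
   Jaccard similarity across pairs. The smallest threshold attaining the
   lexicographic maximum is chosen, which retains maximal allele diversity
   at equal concordance.
4. **Chimera screening.** A cluster is flagged chimeric iff its dominant
   equals, for some breakpoint, the prefix of one deeper cluster's dominant
   joined to the suffix of another's (equal lengths, both parents deeper,
   neither identical to the candidate). All breakpoints are examined via
   longest-common-prefix/suffix bounds, so the check is exact.

Design points that the procedure leaves open, and the choices made here:

* **Frequency denominator.** Cluster frequency is cluster depth divided by
  the amplicon's total post-demultiplexing depth, computed after merging
  and before chimera removal. Using total depth is the most conservative
  reading (frequencies sum to 1 over everything observed).
* **Merge reference depth.** The ≤25% rule compares a variant against the
  *dominant's own* depth, not the cluster's running depth after earlier
  merges. With the alternative, merge order would feed back into
  eligibility; comparing to the dominant keeps the rule order-independent
  for a fixed dominant set.
* **Chimera ordering.** Chimera flags are computed before the frequency
  threshold and remove flagged clusters regardless of frequency. In
  practice chimera clusters sit far below any plausible threshold, so the
  ordering is observationally equivalent, but it is fixed here so that the
  calibration objective never sees chimeras.
* **Duplicate disagreement.** If a duplicate pair disagrees at the final
  threshold, the deeper amplicon's genotype is used and the individual is
  flagged in the report.

## Allele validation

Called alleles are classified by length (247 = long, 244 = short, anything
else rejected with a reason), translated after trimming the 2-nt
incomplete codon at each end (81 or 80 residues; an internal stop flags the
allele non-functional), collapsed into identical-protein classes, and
annotated: the residue at alignment position 170 (a conserved main-chain
tyrosine in classical MHC-I, occasionally replaced by histidine or
phenylalanine), the long-allele motif EDGTV at 147–151, and the
short-allele motif GENE at 148–151. Fragment residues are mapped into the
alignment frame by ungapped anchoring with the first complete codon at
position 93; short alleles skip position 147. Alleles get stable
Klein-style names (`UA*01`, `UA*02`, ...) in canonical order (total called
depth descending, then lexicographic); an existing registry is always
respected, so re-running on extended data never renames an allele.

## Diversity and divergence statistics

All statistics use **pairwise deletion** of gap positions, so the 3-bp
deletion column still contributes to long×long pairs. Available per allele
set: segregating sites (columns with ≥2 distinct non-gap states),
nucleotide diversity π (mean pairwise per-site p-distance), and mean
divergence under either the p-distance or the Kimura two-parameter model,
optionally gamma-corrected (α = 1 is the convention adopted for nucleotide
divergence here; amino-acid divergence uses the p-distance). Standard
errors come from resampling alignment columns (default 1000 replicates,
seeded).

dN/dS follows Nei–Gojobori pathway counting. Potential-site counts treat
substitutions that would create stop codons as undefined: at each codon
position the synonymous fraction is taken among the non-stop alternatives,
so synonymous plus nonsynonymous potential is exactly 3 per codon.
Differences between codons differing at 2–3 positions are averaged over
all substitution orderings that avoid stop intermediates (all orderings if
every one is blocked). Proportions are Jukes–Cantor corrected and averaged
over sequence pairs — the "corrected, pairwise-averaged" lineage of the
method, which is what desktop phylogenetics packages compute by default.
Codon-bootstrap SEs and a one-tailed Z-test for dN > dS (bootstrap
variance of the difference) accompany the estimates. Pairs whose corrected
proportion would hit the Jukes–Cantor ceiling (p ≥ 3/4) are excluded from
the pair average rather than truncated.

The PBR partition defaults to the 12-codon exon-3 set
{96, 98, 112, 114, 121, 149, 151, 154, 155, 159, 162, 166}; the full
exon-3 and exon-2 PBR sets are also shipped (`pbr_mask()`).

## Per-site selection

The per-site test is the counting (SLAC-style) member of the selection-test
family: a neighbor-joining tree on K2P distances, parsimony ancestral
codons, and per-site change counts along branches.

* **Tree.** NJ on K2P distances with pairwise deletion; pairs where the K2P
  logarithms are undefined fall back to the p-distance (logged). Negative
  NJ branch estimates are clamped to zero and the clamped total recorded.
* **Ancestral codons.** Each codon site is a 64-state character solved by
  dynamic programming; ties among minimum-change assignments are broken by
  minimizing implied nonsynonymous changes, then lexicographically, making
  the reconstruction deterministic. Leaves with a gap at a site are
  unconstrained there, so their pendant branches contribute no changes —
  the per-site analogue of taxon exclusion.
* **Test.** Observed synonymous/nonsynonymous changes per site are summed
  over branches (pathway-averaged via the same Nei–Gojobori tables). The
  expected synonymous fraction is the mean synonymous potential of the
  codons observed at the site divided by 3; a two-tailed binomial test of
  the (rounded) observed synonymous count against this fraction gives the
  p-value, and sites are classified positive/negative/neutral at P = 0.1.
  Rounding fractional pathway-averaged counts to integers is a deliberate
  simplification; it only matters at sites with multi-step codon changes,
  and the classification is monotone in P either way.

Because the tree here is NJ-based while published analyses of this kind
often combine several likelihood methods on recombination-aware trees,
site lists should be compared qualitatively, not expected to match a
specific published ensemble.

## What the simulator emulates — and what it does not

`simulation_config()` defaults *are* the study conditions the pipeline
targets: 38 long + 9 short alleles, 84 individuals, 1–4 loci each (two
draws per locus with replacement, so 1–8 distinct alleles), negative
binomial depths with mean 11000 (dispersion 12, chosen so that the CV of
amplicon depth is ≈ 0.3 and the 4000-read gate is actually exercised), 6
technical duplicate pairs re-drawn independently from the same genotype,
lognormal per-allele amplification bias (log-SD 0.3), a 2% per-read
probability of a 1–2-substitution artefact and 0.3% per-read chimera
probability (published chimera frequencies in this design peak around
0.6% per cluster; a 0.3% per-read rate keeps per-cluster chimera
frequencies comfortably in that regime). Population allele frequencies are
symmetric-Dirichlet, giving a natural common-to-rare spread. The artefact
and chimera rates and the bias SD are modelling choices — the real
per-read artefact distribution of a two-step PCR is not published — and
are exposed in the config.

The allele pool concentrates polymorphism at the PBR mask via per-position
codon repertoires whose alternatives are mostly nonsynonymous (so pool
dN/dS is elevated at the PBR), keeps the class-diagnostic motifs invariant
within each length class, and enforces three identifiability guarantees:
all alleles pairwise distinct, same-length alleles at Hamming distance ≥ 3,
and no allele an exact breakpoint splice of two others of its length class
(enforced with private synonymous substitutions where needed). Without the
distance guarantee a rare allele two substitutions from a common one would
be *correctly* merged by the 1–2 bp rule and lost — a genuine limitation
of the artefact-reassignment design that real datasets with very similar
alleles inherit; the simulator makes the recoverable regime explicit
rather than hiding it.

Not modelled: sequencing quality scores, index hopping, PCR indels,
length-heterogeneous chimeras (a 244×247 splice would be off-length and
trivially discarded), and contamination. Passing tests on simulated data
therefore certify the cascade's behaviour under its own artefact model,
not performance on any particular real run.

## Determinism and problem sizes

Every stochastic step is seeded: the simulator derives per-amplicon
substreams from one master seed, so subsets are reproducible; all
bootstraps take explicit seeds. The test suite runs the full default
configuration (90 amplicons, ≈10⁶ reads handled as tallies) for the
duplicate-concordance and truth-recovery checks, a 20-seed zero-noise
sweep at 15 individuals for the threshold-independence property, and
smaller configurations (6–12 alleles, 8–15 individuals, depth 5–6k)
elsewhere; statistical unit tests use 20–500 bootstrap replicates while
the user-facing default stays at 1000.

## Known limitations

* Alleles closer than 3 substitutions within a length class can be merged
  as artefacts when their depth ratio is below 25%; duplicate calibration
  cannot detect this failure mode because it is consistent across
  duplicates.
* The binomial site test treats branch counts as independent trials;
  phylogenetic correlation makes it anti-conservative at deep sites, which
  is inherent to counting methods.
* The NJ tree is a single point estimate; recombination within the
  amplicon (documented in this gene family) violates the single-tree
  assumption, and the per-site test inherits that bias.
* Amino-acid divergence is p-distance only; no rate-corrected protein
  model is provided.
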