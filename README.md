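# amplimhc

Genotyping classical MHC class I alleles from deep amplicon sequencing,
and characterizing their molecular evolution.

When MHC loci exist in variable, unknown copy number, a per-individual
amplicon mixes reads from 1–4 loci, and the variant tally contains true
alleles alongside PCR substitution artefacts, PCR chimeras and depth
noise. `amplimhc` is for researchers running exactly this design — one
deep-sequenced amplicon per individual, a handful of technical duplicates
— on an exon-3 (α2 domain) MHC-I system with two allele length classes
(247 nt, and 244 nt with a 3-bp deletion at alignment codon 147).

The package provides:

* **A four-step filtering cascade** turning per-amplicon read tallies into
  verified genotypes:
  1. depth gate (≥ 4000 reads per amplicon);
  2. greedy depth-ordered clustering that merges a variant into a parent
     cluster when it is 1–2 substitutions away at ≤ 25% of the dominant's
     depth, and flags near-but-deep variants as subdominants;
  3. a per-amplicon frequency threshold calibrated automatically by
     maximizing technical-duplicate genotype concordance over a grid
     (0.5–10%, step 0.1%), taking the smallest optimal value;
  4. exact chimera screening: a cluster is removed iff its dominant is a
     prefix/suffix splice of two deeper, equal-length cluster dominants.
* **Allele validation**: 244/247 length classing, frame-offset translation
  (2-nt incomplete codon at each end), collapsing to unique proteins,
  motif annotation (EDGTV at 147–151 for long alleles, GENE at 148–151
  for short ones, the conserved main-chain Tyr-170), and stable `UA*xx`
  naming against a registry.
* **Diversity and divergence statistics**: segregating sites S,
  nucleotide diversity π, mean divergence d under p-distance or Kimura
  2-parameter (optionally gamma-corrected, α = 1) with site-bootstrap
  SEs, and Nei–Gojobori dN/dS (pathway counting, Jukes–Cantor corrected,
  pairwise-averaged) partitioned over the 12-codon peptide-binding-residue
  (PBR) set {96, 98, 112, 114, 121, 149, 151, 154, 155, 159, 162, 166}
  versus non-PBR codons, with codon-bootstrap SEs and a Z-test for
  dN > dS.
* **A counting-based per-site selection test** (SLAC family): NJ tree on
  K2P distances, parsimony ancestral codons (64-state DP with a
  nonsynonymous-minimizing tie-break), per-site syn/nonsyn change counts,
  binomial p-values, classification at P = 0.1.
* **A simulator** generating allele pools, multi-locus genotypes and
  amplicon read sets with PCR artefacts, chimeras, amplification bias,
  overdispersed depths and technical duplicates — plus a complete truth
  table, so every stage is testable without any external data.

## Worked example

Simulate a full study at default settings (38 long + 9 short alleles, 84
individuals, 6 duplicate pairs, mean depth 11000) and run the whole
pipeline:

```r
library(amplimhc)
cfg <- pipeline_config(sim = simulation_config(seed = 7),
                       bootstrap = 200, seed = 7)
rep <- run_pipeline(cfg)
print(rep)
#> MHC amplicon genotyping run
#>   amplicons: 90 in, 0 dropped by depth gate
#>   variants merged as artefacts: 18872; subdominants: 251
#>   chimera clusters: 1238 (max frequency 0.0008)
#>   frequency threshold: 0.005 (auto-calibrated)
#>   duplicate pairs matching: 6/6
#>   alleles: 45 (36 long / 9 short), 45 protein classes
#>   alleles per individual: 4.65 +/- 2.07
#>   dN/dS: PBR 0.97, non-PBR 0.352
```

Reading the report: ~19k low-frequency 1–2-substitution variants were
reassigned to their parent alleles; 1238 chimeric clusters were flagged,
all far below any plausible allele frequency (max 0.08% of amplicon
depth); all 6 technical duplicate pairs got identical genotypes at the
auto-calibrated threshold; 45 of the 47 simulated alleles were present in
the sampled individuals and every genotype matches the simulator's truth
table. dN/dS is elevated at PBR codons relative to non-PBR codons, as
built into the simulated pool.

The same stages are scriptable from a shell via the thin CLI in
`inst/exec/amplimhc` (`simulate`, `call`, `validate`, `diversity`,
`selection`, `run-all`).

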