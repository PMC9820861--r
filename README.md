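# qtlcloner

Positional cloning of diabetes QTL in mouse backcross populations.

Linkage studies in experimental mouse crosses — such as New Zealand obese
(NZO) x C3H backcrosses — map quantitative trait loci (QTL) for blood
glucose, then narrow a multi-megabase locus down to a handful of candidate
genes by layering orthogonal genomic evidence.  qtlcloner implements that
whole chain as tested, reusable R functions for geneticists who want to run
or audit such an analysis:

1. **QTL scan** — marker-regression LOD scores over an N2 backcross,

   LOD = (n/2) log10(RSS0/RSS1) = -(n/2) log10(1 - r²),

   with a permutation genome-wide threshold (ceil-rank order statistic of
   per-permutation maximum LODs) and a 1.5-LOD support interval snapped
   outward to the nearest genotyped marker.
2. **Diabetes phenotype metrics** — diabetic = random glucose >= 300 mg/dL
   for >= 3 consecutive weeks; case fatality rate among diabetic animals by
   week 20; severe hyperglycemia = glucose > 500 mg/dL at week 15;
   islet-size histograms.
3. **Haplotype blocks** — discordant SNPs between two inbred strains counted
   in tiling windows; polymorphic (non-IBD) windows called at > 50 SNPs per
   150 kb (or >= 100 per 250 kb, both dialects implemented) and merged into
   blocks.
4. **Variant prioritization** — genes retained with a HIGH-impact variant or
   a MODERATE-impact variant with SIFT < 0.5; restriction to polymorphic
   blocks; conservation flagging of mutated residues from a protein
   alignment.
5. **Expression specificity** — per-strain, per-tissue log2 islet/other
   ratios standardized to Z-scores across genes (population SD), combined by
   the minimum across all strain x tissue cells; delta-Ct qPCR comparison,
   2^-(Ct_target - Ct_reference).
6. **Pipeline** — one call chains blocks -> impact/SIFT -> expression into a
   ranked candidate report with filter-funnel counts.

Cohort data of this kind are rarely public, so the package includes a
synthetic-data generator (`simulate_study()`) that plants a known causal
gene — a protective QTL, polymorphic blocks, a deleterious missense variant,
islet-specific expression, a conserved mutated residue, and a qPCR
knockdown — making every stage verifiable end to end.

## Worked example

```r
library(qtlcloner)

study  <- simulate_study(seed = 1)                      # 150 backcross mice
report <- run_positional_cloning(study, pipeline_config(seed = 1))

report$candidates[, c("symbol", "sublocus", "impact", "min_sift",
                      "combined_z", "conserved_site", "final_rank")]
#>   symbol sublocus   impact min_sift combined_z conserved_site final_rank
#> 1 Kdelr3   distal MODERATE     0.04   2.022666           TRUE          1

report$stage_counts
#>     total_genes     impact_pass      block_pass expression_pass
#>              12               2               1               1

report$qtl$peak_marker; round(report$qtl$peak_lod, 1); round(report$qtl$threshold, 2)
#> [1] "mk30"
#> [1] 125.3
#> [1] 1.36

cohort_summary(study$phenotypes)
#>   group  n prevalence   cfr severe_fraction
#> 1   N/C 73          0    NA           0.000
#> 2   N/N 77          1 0.312           0.541
```

Reading: of 12 genes in the locus, 2 carry deleterious-grade variants, 1 of
those lies in a polymorphic (non-IBD) block, and that one is also
islet-specific in all three strains — the planted causal gene, ranked first
with its conserved-site flag set.  The scan confirms the locus (peak LOD
125.3 at marker mk30, far above the genome-wide threshold 1.36 from 100
permutations; the planted phenotype is fully penetrant, hence the large
LOD).  The cohort panel shows the planted protection: homozygous N/N
controls are all diabetic, 54% severely hyperglycemic at week 15, with a
case fatality rate of 0.31, while heterozygous N/C carriers never convert
(their CFR is undefined, reported as NA).

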