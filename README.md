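# mmcsig

Mutational-signature analysis of mitomycin C (MMC) mutagenesis in
*Caenorhabditis elegans*.

MMC is a clinically used chemotherapeutic that forms DNA interstrand
crosslinks, preferentially at duplex 5'-CpG-3' motifs. Its in-vivo genomic
footprint can be characterised by combining a balancer-based forward
genetic screen — which captures recessive lethal mutations as stable
heterozygotes — with whole-genome sequencing of the mutagenized strains.
`mmcsig` implements the downstream analysis for this kind of experiment,
for geneticists and bioinformaticians working with mutation-accumulation
cohorts:

* **Screen genetics** — forward mutation frequency
  (100 × lethals / F1s tested); three-factor map distance from brood
  counts via R = 2·DpyUnc / ((4/3)·WT) and p = 1 − √(1 − 2R), with exact
  Clopper–Pearson 95% limits transformed through the same formula; zone
  classification of mapped positions relative to the dpy-5 / unc-13
  marker pair.
* **Strain-specific variant filtering** — zygosity from variant-read
  fraction (hom ≥ 0.90, het ≈ 50%, depth > 7), presence in exactly one
  cohort strain, absence from the composite parental; deletion matching
  by reciprocal overlap, with a homopolymer-run filter.
* **Substitution spectra** — the six complementary classes
  (G:C>C:G, A:T>C:G, A:T>G:C, G:C>T:A, A:T>T:A, G:C>A:T) and Pearson
  chi-square comparison of two spectra.
* **Deletion sequence context** — 15-nt flank extraction, overlapping
  dinucleotide profiles, CpG fold-enrichment versus a genomic background,
  the 4 × 16 heatmap matrix, and junction microhomology (longest common
  prefix/suffix between the deleted segment and its flanks, the
  alt-NHEJ-consistent alignments).
* **Balancer breakpoints** — major coverage drops in 5/10-kb binned depth
  tracks, with a median persistence guard.
* **A synthetic mutagenesis simulator** — seeded genomes with
  controllable dinucleotide composition, cohorts with CpG-biased
  deletions and engineered junction microhomology, binomial read-count
  evidence at Poisson depths, coverage tracks with a boundary drop, and
  brood counts from the mapping-cross zygote model — with full ground
  truth, so every stage is testable without sequencing data.

The package bundles the published summary tables of an MMC screen
(tallies, mapped lethal deletions, junction sequences) as plain-text
reference data under `inst/extdata/`.

## Worked example

```r
library(mmcsig)

# Forward mutation frequencies from the bundled screen tallies
tally <- mmc_screen_tally()
tally$frequency_pct <- format_percent(
  forward_mutation_frequency(tally$n_lethal, tally$n_f1))
tally[, c("batch", "dose_uM", "n_f1", "n_lethal", "frequency_pct")]
#>   batch dose_uM n_f1 n_lethal frequency_pct
#> 1     1     750  437       24           5.5
#> 2     1     750  550       25           4.5
#> 3     1     750  436       24           5.5
#> 4     2     375  145        3           2.1
#> 5     2     750  580       13           2.2
#> 6     2    1400  145        1           0.7

# Map distance from a brood of 300 wild-type and 10 Dpy-Unc recombinants
round(estimate_map_distance(wt = 300, dpy_unc = 10)[
  , c("R", "p", "map_units", "ci_low", "ci_high")], 3)
#>      R     p map_units ci_low ci_high
#> 1 0.05 0.051     5.132   2.44   9.555

# Junction microhomology across the bundled, fully printed junctions
jx <- parse_junction(mmc_deletion_junctions()$junction)
full <- jx[jx$full, ]
mh <- microhomology(full$deleted, full$left_flank, full$right_flank)
c(scored = nrow(full), with_mh = sum(mh$mh > 0), max_bp = max(mh$mh))
#>  scored with_mh  max_bp
#>      16      15      20
```

The 20-bp maximum comes from a 21-bp deletion whose deleted segment
almost exactly repeats its right flank — the hallmark of repair by
microhomology-mediated end joining.

A simulated cohort exercises the filtering and context stages end to end:

```r
co <- simulate_cohort(sim_config(genome_length = 2e5, n_strains = 3,
                                 n_deletions_per_strain = 5,
                                 n_snvs_per_strain = 8, n_shared_snvs = 4,
                                 seed = 11))
snvs <- filter_strain_specific_snvs(co$tables$strain_snv_tables,
                                    co$tables$parental_snv_table)
classify_snv_spectrum(snvs)
#> G:C>C:G A:T>C:G A:T>G:C G:C>T:A A:T>T:A G:C>A:T
#>       1       4       6       5       6       2

dels <- filter_strain_specific_deletions(co$tables$strain_del_tables,
                                         co$tables$parental_del_table,
                                         co$genome)
ctx <- deletion_contexts(co$genome, dels)
fold_enrichment(ctx$deleted_seq, dinucleotide_profile(co$genome))
#> [1] 1.44      # deleted segments are CpG-enriched (cpg_bias = 3 default)
mean(ctx$mh > 0)
#> [1] 0.73      # fraction of junctions with microhomology
```

`run_pipeline(pipeline_config(...))` chains all stages over files
(FASTA reference, per-strain minimal VCF or TSV variant tables,
bedGraph-like depth tracks, brood-count TSV) and writes per-stage TSV
tables plus a machine-readable `report.json`.

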