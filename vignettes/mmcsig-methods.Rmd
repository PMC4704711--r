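---
title: "Methods: mutational-signature analysis of mitomycin C mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational-signature analysis of mitomycin C mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcsig)
```

# The biological problem

Mitomycin C (MMC) is a chemotherapeutic agent that forms DNA interstrand
crosslinks with a strong preference for the duplex 5'-CpG-3' motif. In
*C. elegans*, its genome-wide footprint can be characterised by combining a
balancer-based forward genetic screen (which captures recessive lethal
mutations as stable heterozygotes) with whole-genome sequencing of the
mutagenized strains. `mmcsig` implements the downstream analysis of such an
experiment:

* screen genetics — forward mutation frequency and three-factor map-distance
  estimation from brood counts, with exact binomial confidence limits;
* strain-specific variant filtering across a sequenced cohort, with zygosity
  calling from read counts;
* the six-class substitution spectrum and its chi-square comparison between
  cohorts;
* deletion sequence context — dinucleotide profiles, CpG fold-enrichment
  against a genomic background, and junction microhomology;
* detection of balancer rearrangement boundaries as major drops in binned
  read coverage.

Because the raw sequencing data of any particular experiment may be
unavailable, the package also contains a synthetic mutagenesis simulator
that generates genomes, mutagenized cohorts, coverage tracks and brood
counts with known ground truth, so every analysis stage is testable.

# Screen genetics

## Forward mutation frequency

`forward_mutation_frequency()` is the standard potency measure: isolated
lethal mutations per F1 animal screened, times 100. Reporting uses
one-decimal rounding (`format_percent()`, half away from zero, as printed
tables do).

## The mapping-cross zygote model

A strain carrying a balancer-maintained lethal linked to the visible
markers dpy and unc (`lethal dpy unc / + + +` after outcrossing) segregates
four scored classes in its self progeny: wild-type-appearing, Dpy-Unc,
Dpy, and Unc. With recombination fraction $p$ between the lethal and the
marker pair, the zygote classes have probabilities

* viable Dpy-Unc recombinants: $p/2 - p^2/4$,
* dead Dpy-Unc (lethal homozygotes, never scored): $((1-p)/2)^2$,
* wild-type-appearing: $3/4$.

These sum to one; the single-marker recombinant classes carry no mass in
this reduced model and are accepted but unused by the estimator (as in
practice). `simulate_brood()` draws zygotes from this multinomial and
discards the dead class before counting, mirroring that only surviving
animals are scored.

## The estimator

`estimate_map_distance()` computes the recombinant fraction

$$ R = \frac{2 \cdot \mathrm{DpyUnc}}{\tfrac{4}{3}\,\mathrm{WT}} $$

(the $4/3$ factor reconstructs total progeny from the wild-type class,
because one quarter of zygotes die as lethal homozygotes) and inverts it
with the phase-known formula $p = 1 - \sqrt{1 - 2R}$, reported in map
units ($100p$). The inversion is exact for the zygote model above:
$E[R] = p - p^2/2$ and $1 - \sqrt{1 - 2(p - p^2/2)} = p$.

Confidence limits use the exact Clopper–Pearson binomial interval on the
Dpy-Unc count out of $\mathrm{round}(\tfrac{4}{3}\mathrm{WT})$ trials,
with each bound transformed through the same formula. The exact interval
was chosen over a normal approximation because recombinant counts in real
broods are small (often below 20); the cost is the usual slight
conservatism. Calibration is verified by simulation in the test suite:
at $p = 0.08$ with 2,000 zygotes per brood the 95% interval covers the
truth in about 95% of replicates.

$R$ values above 0.5 (possible by sampling noise) are clamped and the
estimate flagged rather than producing a complex square root.

## Zone classification

`classify_map_positions()` partitions signed map positions relative to the
two markers. Positions exactly on a marker are classified "between" — an
arbitrary but deterministic tie-break, documented so that counts are
reproducible.

# Variant filtering

Zygosity is called from the variant-read fraction (`call_zygosity()`):
homozygous at $\ge 0.90$ (inclusive, matching the 0.9 consensus-caller
threshold), heterozygous in $[0.35, 0.65]$ (operationalising
"approximately 50%"), reference at $\le 0.10$, ambiguous otherwise.

A strain-specific SNV (`filter_strain_specific_snvs()`) must be
homozygous, covered by more than seven reads (depth $\ge 8$), observed in
exactly one cohort strain, and absent from the composite parental.
"Observed" means any non-reference evidence, so a heterozygous second
strain also disqualifies a site. The composite parental is treated as the
union of variant keys of its constituent tables: the original analysis
merged parental alignments, and at call-level granularity the union gives
the same exclusion semantics.

Deletions (`filter_strain_specific_deletions()`) match across strains by
reciprocal overlap (default $\ge 80\%$ on the same chromosome counts as
the same event) rather than exact coordinates, because split-read callers
jitter endpoints; the threshold is exposed. Deletions contained in a
single-base homopolymer run are removed, with the run measured as the
maximal run in the reference containing the deleted segment (default
$\ge 6$ bp; indel callers routinely filter these as artefact-prone). The
run-length parameter has no published value and is configurable.

Lethal-candidate nomination (`identify_lethal_candidates()`) applies the
three published criteria: heterozygous allelic ratio (the balancer keeps
the lethal chromosome heterozygous), position within the genetically
mapped interval, and uniqueness to the strain.

# Substitution spectra

`classify_snv_spectrum()` maps each SNV to one of the six complementary
classes (G:C>C:G, A:T>C:G, A:T>G:C, G:C>T:A, A:T>T:A, G:C>A:T); a
substitution and its reverse complement land in the same class, and the
class total always equals the number of accepted SNVs.
`compare_spectra_chisq()` compares two pooled spectra with a Pearson
chi-square on the 2 × 6 table (no continuity correction), dropping classes
empty in both spectra and adjusting the degrees of freedom; a flag is
raised when any expected count is below 5. No multiple-testing correction
is applied — the analysis performs a single planned comparison and
reports the exact p-value.

# Deletion sequence context

Coordinates are 1-based inclusive throughout, so a deletion's length is
$end - start + 1$; conversion to 0-based half-open happens only at the
BED/VCF boundary. `check_size_consistency()` recomputes published deletion
sizes from their coordinates and flags internally inconsistent rows
instead of silently correcting them.

`extract_flanks()` takes the 15 nucleotides (more than one helical turn)
on each side of a deletion, truncating at chromosome ends.
`dinucleotide_profile()` tallies all overlapping width-2 windows within
each sequence — never across sequence boundaries — into the 16 ordered
dinucleotides on the given strand, skipping windows that contain N.
Counts are pooled across all deletions before proportions are computed,
matching the pooled published analysis; `fold_enrichment()` is then the
ratio of CG proportions in target versus background and is scale-free.
Dinucleotides are not collapsed with their reverse complements (CG is
unaffected either way), giving the 16-column heatmap axis
(`heatmap_matrix()`, rows: deleted, left flank, right flank, background).

## Junction microhomology

`microhomology()` scores the two junction alignments consistent with
repair by (alternative) non-homologous end joining: the longest common
prefix of the deleted segment and the right flank (5' side) and the
longest common suffix of the deleted segment and the left flank (3'
side), case-insensitively; `mh` is the larger. The cap defaults to 25 bp
because observed microhomologies reach 20 bp — longer than the 15-nt
stored flanks — so `deletion_contexts()` rescores junctions with
cap-width flanks taken directly from the reference. The scorer is tested
against a brute-force oracle that tries every length on both sides.

# Balancer breakpoint detection

`bin_depth()` averages per-position depth into fixed-width bins (5 or
10 kb in typical use), the final partial bin over its actual width.
`detect_coverage_drop()` scans every bin boundary: a boundary qualifies
when the median of the following `min_run` bins falls below `drop_ratio`
times the median of the preceding `min_run` bins; adjacent qualifying
boundaries are merged to the one with the smallest mean-based post/pre
ratio (leftmost on ties). Medians make qualification robust to single-bin
dropouts; the mean-based ratio pinpoints the edge, and on a noiseless
two-level track the merged call lands exactly on the true boundary.

There is no canonical definition of a "major drop", so both knobs are
configuration. The defaults (`drop_ratio = 0.7`, `min_run = 5`) are sized
for the halving of coverage expected at a heterozygous balancer boundary
under realistic noise: with per-bin standard deviation 3 at mean depth 30
(coefficient of variation 0.2 on the low side of the drop), a 3-bin
median window misses the qualifying comparison at the true boundary about
14% of the time, whereas the 5-bin window with a 30% drop threshold
recovers the boundary within one bin in about 98% of simulated tracks
while still producing no false calls on flat tracks at coefficients of
variation up to 0.1. When several drops qualify on one track, the call
with the smallest post/pre ratio is the breakpoint call.

Base-pair-level refinement of a breakpoint requires soft-clipped read
evidence from alignments and is out of scope; calls are reported at bin
edges.

# The synthetic mutagenesis simulator

The simulator exists to give every analysis stage a ground truth. Its
defaults describe the cohort design the analysis assumes: ten mutagenized
strains on a 1-Mb chromosome, each with 25 strain-specific homozygous
SNVs, 20 strain-specific homozygous deletions and one heterozygous
balancer-maintained lethal deletion, ten shared parental background SNVs,
mean depth 30, error rate 1%.

**Genome.** `simulate_genome()` draws a first-order Markov chain over
A/C/G/T whose transition matrix derives from the 16 target dinucleotide
proportions. A pair distribution can only be stationary for such a chain
when its first- and second-letter marginals agree; user targets violating
this are projected by iterative proportional fitting before the chain is
built. The packaged default composition (`dinuc_freqs_cg_depleted()`) is
exactly balanced by construction and CpG-depleted (CG proportion 0.01,
with AT lowered equally and CT/AG absorbing the mass so every base keeps
marginal 1/4). The CpG-scarce background is a deliberate design choice:
on a near-uniform composition essentially every segment of 50 bp or more
contains a CpG, so a containment-based damage bias would be
unobservable; depleting CpG gives the mechanism dynamic range, at the
price that the background is not a literal nematode composition (real
*C. elegans* sequence has near-expected CpG content).

**Deletions.** `inject_deletions()` draws sizes from a configurable
distribution (default: lognormal around ~60 bp, truncated to 2–5000 bp —
the published size range spans 2 bp to hundreds of kb, but the upper tail
is capped to keep many events placeable on a 1-Mb chromosome) and places
intervals with probability weight `cpg_bias` when the candidate deleted
segment contains at least one CpG. Junction microhomology of length
$k > 0$ is engineered on the 5' side by placing endpoints where the
first $k$ deleted bases equal the first $k$ right-flank bases (a lag-$k$
self-match of the genome); chance matches can extend either side, so the
measured value is $\ge k$. The default microhomology distribution assigns
mass 9/29 to zero and decreasing mass to 1–6 bp, the shape observed in
MMC junction data. Truth deletions are non-overlapping within a strain,
never duplicated across strains (at the 80% reciprocal-overlap
definition), and never homopolymer-contained — events the filters are
designed to discard are not injected as truth, which keeps noiseless
precision/recall well-defined.

**Read evidence.** `simulate_strain_tables()` gives every truth SNV site
in every strain a record with depth ~ Poisson(mean) (truncated at 1, or
exactly the mean under `fixed_depth`) and variant reads ~ Binomial(depth,
f), with f = 1 − error at homozygous sites, 0.5 at heterozygous sites and
error at reference sites. Deletion tables carry supporting reads for the
strain's own deletions only, matching how split-read callers report
absence. The composite parental table contains the shared background
variants.

**Determinism.** Every stochastic operation takes an explicit integer
seed; cohort simulation derives per-stage and per-strain sub-seeds
deterministically from the master seed, so a fixed configuration
reproduces byte-identical output.

**What is not emulated.** Read-level artefacts (FASTQ, alignment,
mapping-quality structure), sequencing-error haplotypes, insertions, and
balancer translocation sequence assembly. Passing recovery tests on this
simulator therefore demonstrates the correctness of the filtering and
context logic under the stated statistical model, not robustness to
alignment artefacts in real data.

# Problem sizes and numerical choices

The test suite simulates cohorts of 3–10 strains on 0.03–1 Mb genomes,
200-replicate recovery batches for breakpoints and brood estimates, a
500-replicate interval-calibration batch, 1,000 null replicates for the
chi-square type-I check and 10,000 random junctions against the
microhomology oracle — sizes at which the Monte-Carlo error of each check
is comfortably inside its acceptance band. Degenerate inputs are handled
explicitly: zero-window profiles flag undefined proportions; empty
variant files warn and return empty record sets; malformed records are
rejected per-record with a reason rather than aborting a run.

# Known limitations

* The estimator treats the wild-type class as exactly 3/4 of viable
  progeny; real broods with differential viability among classes will
  bias $R$.
* Spectrum comparison relies on the asymptotic chi-square; with fewer
  than ~5 expected counts per class the flag should prompt an exact test.
* Breakpoint calls are bin-edge resolution only.
* The homopolymer rule considers single-base runs, not short tandem
  repeats.
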