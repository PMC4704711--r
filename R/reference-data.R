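# Bundled summary data from a balancer-based mitomycin-C mutagenesis
# screen in C. elegans: the published screen tallies, the mapped lethal
# deletions with their printed sizes, and the deletion junction sequences
# (lower case = deleted segment, upper case = flanks, long segments elided
# as <n>). These serve as reference inputs for the reporting helpers and
# for validating the coordinate and microhomology conventions.

mmc_extdata <- function(name) {
  path <- system.file("extdata", name, package = "mmcsig")
  if (!nzchar(path)) stop_mmcsig("bundled data file not found: ", name)
  path
}

#' Bundled screen tallies of an MMC forward mutation screen
#'
#' Per-batch, per-dose counts of F1 animals tested and lethal mutations
#' isolated, with the published forward mutation frequency (one decimal).
#'
#' @return data frame: batch, dose_uM, n_f1, n_lethal,
#'   printed_frequency_pct
#' @examples
#' tally <- mmc_screen_tally()
#' forward_mutation_frequency(tally$n_lethal, tally$n_f1)
#' @export
mmc_screen_tally <- function() read_tsv(mmc_extdata("mmc_screen_tally.tsv"))

#' Bundled mapped lethal deletions (coordinates and printed sizes)
#'
#' The lethal deletions identified in the balanced chromosome I region,
#' with 1-based inclusive physical coordinates, printed deletion sizes,
#' and genetic map positions relative to dpy-5 (the h2755 entry lies
#' between the markers and has no signed position).
#'
#' @return data frame: strain, allele, chrom, start, end, printed_size_bp,
#'   map_units, map_err
#' @export
mmc_lethal_deletions <- function()
  read_tsv(mmc_extdata("mmc_lethal_deletions.tsv"))

#' Bundled genome-wide deletion junction sequences
#'
#' The 29 strain-specific deletion junctions with deleted segments in
#' lower case and flanking sequence in upper case; deleted segments longer
#' than 10 bp are printed as prefix, elided middle (`<n>`) and suffix.
#' Parse with [parse_junction()].
#'
#' @return data frame: allele, detection, size_bp, junction
#' @examples
#' jx <- mmc_deletion_junctions()
#' parsed <- parse_junction(jx$junction)
#' @export
mmc_deletion_junctions <- function()
  read_tsv(mmc_extdata("mmc_deletion_junctions.tsv"))
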