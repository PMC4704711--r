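#' Configuration for the synthetic mutagenesis simulator
#'
#' Bundles and validates every knob of the simulator. The defaults describe
#' the cohort the analysis is designed around: a 1-Mb CpG-depleted
#' chromosome, 10 mutagenized strains each carrying 25 strain-specific
#' homozygous SNVs, 20 strain-specific homozygous deletions and one
#' heterozygous (balancer-maintained) lethal deletion, sequenced to a mean
#' depth of 30 reads with a 1% per-read error rate. `cpg_bias` weights
#' candidate deleted segments that contain at least one CG dinucleotide;
#' `mh_length_dist` draws the engineered junction-microhomology length per
#' deletion (0 allowed).
#'
#' @param genome_length simulated chromosome length, bp
#' @param dinuc_freqs 16 target dinucleotide proportions (sum 1)
#' @param n_strains number of mutagenized strains
#' @param n_deletions_per_strain homozygous strain-specific deletions per strain
#' @param deletion_size_dist deletion size distribution: a list with element
#'   `dist` one of `"fixed"` (`size`), `"uniform"` (`min`, `max`) or
#'   `"lognormal"` (`meanlog`, `sdlog`, optional truncation `min`, `max`)
#' @param cpg_bias relative sampling weight (>= 1) for candidate deleted
#'   segments containing >= 1 CpG
#' @param mh_length_dist engineered microhomology length distribution:
#'   list with integer `lengths` and matching `probs`, or a single fixed
#'   integer length
#' @param n_snvs_per_strain strain-specific homozygous SNVs per strain
#' @param n_shared_snvs background SNVs present in the composite parental
#'   and in every strain (removed by the strain-specific filter)
#' @param n_het_deletions_per_strain heterozygous deletions per strain
#'   (emulating balancer-maintained lethal mutations)
#' @param mean_depth mean sequencing depth, reads
#' @param error_rate per-read error fraction in \[0, 0.5)
#' @param fixed_depth if `TRUE`, every site has exactly `mean_depth` reads
#'   instead of Poisson-distributed depth (noiseless settings)
#' @param seed integer master seed; per-strain sub-seeds are derived
#'   deterministically from it
#' @return a validated list of class `sim_config`
#' @examples
#' cfg <- sim_config(genome_length = 1e5, n_strains = 3, seed = 7)
#' @export
sim_config <- function(genome_length = 1e6,
                       dinuc_freqs = dinuc_freqs_cg_depleted(0.01),
                       n_strains = 10L,
                       n_deletions_per_strain = 20L,
                       deletion_size_dist = list(dist = "lognormal",
                                                 meanlog = log(60),
                                                 sdlog = 1.3,
                                                 min = 2, max = 5000),
                       cpg_bias = 3,
                       mh_length_dist = list(lengths = 0:6,
                                             probs = c(9, 6, 5, 4, 2, 2, 1) / 29),
                       n_snvs_per_strain = 25L,
                       n_shared_snvs = 10L,
                       n_het_deletions_per_strain = 1L,
                       mean_depth = 30,
                       error_rate = 0.01,
                       fixed_depth = FALSE,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              dinuc_freqs = validate_dinuc_freqs(dinuc_freqs),
              n_strains = as.integer(n_strains),
              n_deletions_per_strain = as.integer(n_deletions_per_strain),
              deletion_size_dist = deletion_size_dist,
              cpg_bias = cpg_bias,
              mh_length_dist = normalize_mh_dist(mh_length_dist),
              n_snvs_per_strain = as.integer(n_snvs_per_strain),
              n_shared_snvs = as.integer(n_shared_snvs),
              n_het_deletions_per_strain = as.integer(n_het_deletions_per_strain),
              mean_depth = mean_depth,
              error_rate = error_rate,
              fixed_depth = isTRUE(fixed_depth),
              seed = as.integer(seed))
  counts <- c(cfg$n_strains, cfg$n_deletions_per_strain, cfg$n_snvs_per_strain,
              cfg$n_shared_snvs, cfg$n_het_deletions_per_strain)
  if (any(counts < 0L)) stop_mmcsig("all counts must be >= 0")
  if (cfg$genome_length < 2L) stop_mmcsig("'genome_length' must be >= 2")
  if (cfg$mean_depth <= 0) stop_mmcsig("'mean_depth' must be > 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop_mmcsig("'error_rate' must be in [0, 0.5)")
  if (cfg$cpg_bias < 1) stop_mmcsig("'cpg_bias' must be >= 1")
  validate_size_dist(cfg$deletion_size_dist)
  structure(cfg, class = "sim_config")
}

normalize_mh_dist <- function(d) {
  if (is.numeric(d) && length(d) == 1L)
    d <- list(lengths = as.integer(d), probs = 1)
  if (!is.list(d) || is.null(d$lengths) || is.null(d$probs) ||
      length(d$lengths) != length(d$probs))
    stop_mmcsig("'mh_length_dist' must be a fixed length or list(lengths, probs)")
  if (any(d$lengths < 0L)) stop_mmcsig("microhomology lengths must be >= 0")
  if (any(d$probs < 0) || sum(d$probs) <= 0)
    stop_mmcsig("'mh_length_dist' probabilities must be non-negative")
  d$lengths <- as.integer(d$lengths)
  d$probs <- d$probs / sum(d$probs)
  d
}

validate_size_dist <- function(d) {
  if (!is.list(d) || is.null(d$dist))
    stop_mmcsig("'deletion_size_dist' must be a list with a 'dist' element")
  ok <- switch(d$dist,
               fixed = !is.null(d$size) && d$size >= 1,
               uniform = !is.null(d$min) && !is.null(d$max) &&
                 d$min >= 1 && d$max >= d$min,
               lognormal = !is.null(d$meanlog) && !is.null(d$sdlog),
               FALSE)
  if (!isTRUE(ok))
    stop_mmcsig("unsupported or incomplete 'deletion_size_dist' (dist = ",
                d$dist %||% "NULL", ")")
  invisible(d)
}

draw_deletion_sizes <- function(d, n) {
  if (n == 0L) return(integer(0))
  sizes <- switch(d$dist,
    fixed = rep(as.integer(d$size), n),
    uniform = sample(seq.int(d$min, d$max), n, replace = TRUE),
    lognormal = {
      x <- round(stats::rlnorm(n, d$meanlog, d$sdlog))
      lo <- d$min %||% 1
      hi <- d$max %||% Inf
      pmin(pmax(x, lo), hi)
    })
  as.integer(sizes)
}

draw_mh_lengths <- function(d, n) {
  if (n == 0L) return(integer(0))
  if (length(d$lengths) == 1L) return(rep(d$lengths, n))
  sample(d$lengths, n, replace = TRUE, prob = d$probs)
}
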