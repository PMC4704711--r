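#' Simulate a binned coverage track with a balancer-boundary drop
#'
#' Per-bin mean depths are Normal(`mean_depth`, `sd`) up to and including
#' the bin containing `breakpoint`, and Normal(`mean_depth * drop_fraction`,
#' `sd_post`) after it, truncated at zero — the coverage signature of a
#' rearrangement boundary in a heterozygous balancer strain. With
#' `breakpoint = NULL` the track is flat.
#'
#' @param chrom_length chromosome length, bp
#' @param bin_width bin width, bp (> 0)
#' @param breakpoint true boundary position, bp (or `NULL` for no drop)
#' @param drop_fraction post-boundary mean depth as a fraction of
#'   `mean_depth`, in (0, 1]
#' @param mean_depth pre-boundary mean depth, reads
#' @param sd per-bin standard deviation before the boundary (0 = noiseless)
#' @param sd_post per-bin standard deviation after the boundary
#' @param seed integer seed
#' @param chrom chromosome label
#' @return a `depth_track` data frame (chrom, bin, start, end, mean_depth)
#'   with attributes `bin_width` and `truth_breakpoint_bin` (last bin at the
#'   pre-drop level, `NA` for a flat track)
#' @examples
#' tr <- simulate_depth_track(1e5, bin_width = 5000, breakpoint = 6e4,
#'                            drop_fraction = 0.5, seed = 1)
#' @export
simulate_depth_track <- function(chrom_length, bin_width = 5000L,
                                 breakpoint = NULL, drop_fraction = 0.5,
                                 mean_depth = 30, sd = 3, sd_post = sd,
                                 seed = 1L, chrom = "chrI") {
  if (bin_width <= 0) stop_mmcsig("'bin_width' must be > 0")
  if (!is.null(breakpoint)) {
    if (drop_fraction <= 0 || drop_fraction > 1)
      stop_mmcsig("'drop_fraction' must be in (0, 1]")
    if (breakpoint < 1 || breakpoint > chrom_length)
      stop_mmcsig("'breakpoint' must lie within the chromosome")
  }
  n_bins <- as.integer(ceiling(chrom_length / bin_width))
  start <- (seq_len(n_bins) - 1L) * as.integer(bin_width) + 1L
  end <- pmin(start + as.integer(bin_width) - 1L, as.integer(chrom_length))
  mu <- rep(mean_depth, n_bins)
  sds <- rep(sd, n_bins)
  bp_bin <- NA_integer_
  if (!is.null(breakpoint) && drop_fraction < 1) {
    bp_bin <- as.integer(ceiling(breakpoint / bin_width))
    post <- seq_len(n_bins) > bp_bin
    mu[post] <- mean_depth * drop_fraction
    sds[post] <- sd_post
  }
  means <- withr::with_seed(as.integer(seed), pmax(rnorm(n_bins, mu, sds), 0))
  track <- data.frame(chrom = chrom, bin = seq_len(n_bins), start = start,
                      end = end, mean_depth = means, stringsAsFactors = FALSE)
  attr(track, "bin_width") <- as.integer(bin_width)
  attr(track, "truth_breakpoint_bin") <- bp_bin
  class(track) <- c("depth_track", "data.frame")
  track
}
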