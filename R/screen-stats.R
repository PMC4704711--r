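#' Forward mutation frequency of a balancer screen
#'
#' Recovered lethal mutations per F1 animal screened, as a percentage:
#' `100 * n_lethal / n_f1`. This is the standard potency measure for a
#' mutagen in a balancer-based forward genetic screen.
#'
#' @param n_lethal number of isolated lethal mutations (vectorized)
#' @param n_f1 number of F1 animals tested (> 0)
#' @return percentage(s); round with `digits = 1` for reporting via
#'   [format_percent()]
#' @examples
#' forward_mutation_frequency(24, 437)   # 5.49...
#' @export
forward_mutation_frequency <- function(n_lethal, n_f1) {
  if (any(n_f1 <= 0)) stop_mmcsig("'n_f1' must be > 0")
  if (any(n_lethal < 0) || any(n_lethal > n_f1))
    stop_mmcsig("'n_lethal' must be in [0, n_f1]")
  100 * n_lethal / n_f1
}

#' Format a percentage to one decimal, as printed screen tables do
#' @param x numeric percentages
#' @param digits decimal places (default 1)
#' @return numeric rounded half away from zero
#' @export
format_percent <- function(x, digits = 1) round_half_up(x, digits)

#' Three-factor map-distance estimate with exact binomial confidence limits
#'
#' Phase-known estimator for the distance between a balancer-maintained
#' recessive lethal and the flanking marker pair, from brood counts of a
#' `lethal dpy unc / + + +` self cross. The recombinant fraction is
#' `R = 2 * dpy_unc / ((4/3) * wt)` — twice the viable Dpy-Unc recombinants
#' over the total progeny reconstructed from the wild-type class (the 4/3
#' factor restores the quarter of zygotes lost as lethal homozygotes) — and
#' the recombination frequency is `p = 1 - sqrt(1 - 2R)`, reported in map
#' units (100 p). Confidence limits use the exact Clopper-Pearson binomial
#' interval on `dpy_unc` successes out of `round((4/3) * wt)` trials, each
#' bound transformed through the same `p` formula; the exact interval is
#' preferred because recombinant counts are typically small. Single Dpy and
#' Unc classes, when supplied, are carried along but do not enter the
#' estimator.
#'
#' @param wt wild-type count (> 0); vectorized
#' @param dpy_unc viable Dpy-Unc (recombinant) count
#' @param conf confidence level (default 0.95)
#' @return data frame (one row per brood): wt, dpy_unc, R, p, map_units,
#'   ci_low, ci_high (map units) and `flagged` (TRUE when R had to be
#'   clamped at 0.5)
#' @examples
#' estimate_map_distance(wt = 300, dpy_unc = 10)  # ~5.13 map units
#' @export
estimate_map_distance <- function(wt, dpy_unc, conf = 0.95) {
  if (inherits(wt, "data.frame")) {
    brood <- wt
    wt <- brood$wt
    dpy_unc <- brood$dpy_unc
  }
  if (any(wt <= 0)) stop_mmcsig("'wt' must be > 0")
  if (any(dpy_unc < 0)) stop_mmcsig("'dpy_unc' must be >= 0")
  R <- 2 * dpy_unc / ((4 / 3) * wt)
  flagged <- R > 0.5
  if (any(flagged))
    warning("recombinant fraction R > 0.5 clamped to 0.5; estimate flagged")
  R <- pmin(R, 0.5)
  p <- 1 - sqrt(1 - 2 * R)

  alpha <- 1 - conf
  n <- round((4 / 3) * wt)
  x <- pmin(dpy_unc, n)
  lo_prop <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi_prop <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  p_lo <- 1 - sqrt(pmax(1 - 2 * pmin(2 * lo_prop, 0.5), 0))
  p_hi <- 1 - sqrt(pmax(1 - 2 * pmin(2 * hi_prop, 0.5), 0))
  data.frame(wt = wt, dpy_unc = dpy_unc, R = R, p = p,
             map_units = 100 * p, ci_low = 100 * p_lo, ci_high = 100 * p_hi,
             flagged = flagged)
}

#' Classify mapped positions relative to two linked markers
#'
#' Partitions signed map positions into three zones relative to a marker
#' pair (e.g. dpy-5 and unc-13 on chromosome I): strictly left of the left
#' marker, strictly right of the right marker, or between. Positions
#' exactly on a marker classify as "between" (deterministic tie-break).
#'
#' @param positions signed map positions (map units)
#' @param left_marker position of the left marker
#' @param right_marker position of the right marker (>= left_marker)
#' @return data frame with one row per zone (left, between, right): count
#'   `n` and `percent` (one decimal); percents are `NA` for empty input
#' @examples
#' classify_map_positions(c(-13.2, -6.1, 1.0, 5.4), 0, 2.07)
#' @export
classify_map_positions <- function(positions, left_marker, right_marker) {
  if (left_marker > right_marker)
    stop_mmcsig("'left_marker' must be <= 'right_marker'")
  zones <- c("left", "between", "right")
  if (length(positions) == 0L)
    return(data.frame(zone = zones, n = 0L, percent = NA_real_))
  z <- ifelse(positions < left_marker, "left",
              ifelse(positions > right_marker, "right", "between"))
  n <- vapply(zones, function(w) sum(z == w), 0L)
  data.frame(zone = zones, n = as.integer(n),
             percent = round_half_up(100 * n / length(positions), 1),
             row.names = NULL)
}
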