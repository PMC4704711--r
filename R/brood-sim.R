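#' Simulate brood counts from a three-factor mapping cross
#'
#' Zygote model for the self-progeny of a `lethal dpy unc / + + +`
#' hermaphrodite carrying a recessive lethal at recombination fraction `p`
#' from the marker pair. Each zygote falls in one of four classes:
#' \itemize{
#'   \item viable Dpy-Unc (recombinant): probability `p/2 - p^2/4`
#'   \item dead (lethal Dpy-Unc homozygote, never scored): `((1-p)/2)^2`
#'   \item wild-type-appearing: `3/4`
#'   \item remaining mass (split between single Dpy and Unc classes):
#'     zero under this model
#' }
#' Dead zygotes are simulated and then discarded before counting, mirroring
#' scoring of surviving animals only; this is exactly the model inverted by
#' the map-distance estimator, since
#' `E[2 * DpyUnc / ((4/3) * WT)] = p - p^2/2` and
#' `1 - sqrt(1 - 2(p - p^2/2)) = p`.
#'
#' @param p recombination fraction, in \[0, 0.5\]
#' @param n_zygotes number of zygotes drawn
#' @param seed integer seed
#' @return one-row data frame (class `brood_count`): wt, dpy_unc, dpy, unc,
#'   plus bookkeeping columns n_zygotes and n_dead
#' @examples
#' simulate_brood(0.10, 2000, seed = 1)
#' @export
simulate_brood <- function(p, n_zygotes, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 0.5)
    stop_mmcsig("'p' must be a single value in [0, 0.5]")
  if (n_zygotes < 1) stop_mmcsig("'n_zygotes' must be >= 1")
  probs <- brood_class_probs(p)
  counts <- withr::with_seed(as.integer(seed),
                             drop(rmultinom(1L, as.integer(n_zygotes), probs)))
  out <- data.frame(wt = counts[["wt"]], dpy_unc = counts[["dpy_unc"]],
                    dpy = counts[["dpy"]], unc = counts[["unc"]],
                    n_zygotes = as.integer(n_zygotes),
                    n_dead = counts[["dead"]])
  class(out) <- c("brood_count", "data.frame")
  out
}

#' Zygote class probabilities of the mapping-cross model
#' @param p recombination fraction in \[0, 0.5\]
#' @return named probability vector (wt, dpy_unc, dpy, unc, dead)
#' @export
brood_class_probs <- function(p) {
  dpy_unc <- p / 2 - p^2 / 4
  dead <- ((1 - p) / 2)^2
  wt <- 3 / 4
  rest <- max(0, 1 - wt - dpy_unc - dead)
  c(wt = wt, dpy_unc = dpy_unc, dpy = rest / 2, unc = rest / 2, dead = dead)
}
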