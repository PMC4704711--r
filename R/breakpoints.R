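#' Bin per-position read depths into a fixed-width coverage track
#'
#' Averages read depth over consecutive fixed-width bins (5 kb or 10 kb in
#' typical use); the final partial bin is averaged over its actual width.
#'
#' @param depth data frame with `pos` and `depth` columns (1-based
#'   positions), or a numeric vector of per-position depths at positions
#'   1..length
#' @param bin_width bin width, bp (> 0)
#' @param chrom chromosome label
#' @return a `depth_track` data frame (chrom, bin, start, end, mean_depth)
#' @examples
#' bin_depth(rep(30, 10000), bin_width = 5000)
#' @export
bin_depth <- function(depth, bin_width = 5000L, chrom = "chrI") {
  if (bin_width <= 0) stop_mmcsig("'bin_width' must be > 0")
  if (is.numeric(depth) && is.null(dim(depth))) {
    pos <- seq_along(depth)
    d <- as.numeric(depth)
  } else if (is.data.frame(depth)) {
    if (!all(c("pos", "depth") %in% names(depth)))
      stop_mmcsig("'depth' data frame needs 'pos' and 'depth' columns")
    ord <- order(depth$pos)
    pos <- depth$pos[ord]
    d <- as.numeric(depth$depth[ord])
  } else {
    stop_mmcsig("'depth' must be a numeric vector or a data frame")
  }
  if (length(pos) == 0L) stop_mmcsig("no depth observations")
  bin <- (pos - 1L) %/% as.integer(bin_width) + 1L
  sums <- tapply(d, bin, sum)
  counts <- tapply(d, bin, length)
  bins <- as.integer(names(sums))
  track <- data.frame(chrom = chrom, bin = bins,
                      start = (bins - 1L) * as.integer(bin_width) + 1L,
                      end = pmin(bins * as.integer(bin_width),
                                 as.integer(max(pos))),
                      mean_depth = as.numeric(sums / counts),
                      stringsAsFactors = FALSE)
  attr(track, "bin_width") <- as.integer(bin_width)
  class(track) <- c("depth_track", "data.frame")
  track
}

#' Detect major coverage drops (balancer rearrangement boundaries)
#'
#' Scans every boundary between bins of a coverage track: a boundary
#' qualifies as a "major drop" when the median of the following `min_run`
#' bins falls below `drop_ratio` times the median of the preceding
#' `min_run` bins. Runs of adjacent qualifying boundaries (a drop plateau
#' produces several) are merged to the boundary with the smallest
#' mean-based post/pre ratio, leftmost on ties; medians make the
#' qualification robust to single-bin dropouts while the mean ratio
#' pinpoints the edge. The scan can be restricted to a previously mapped
#' region via `search_bins`. The defaults (30% drop sustained over a
#' 5-bin median) are sized for the halving of coverage expected at a
#' heterozygous balancer boundary under realistic bin-level noise
#' (coefficient of variation up to ~0.2 on the low side of the drop);
#' both knobs are exposed because a "major drop" has no canonical
#' definition.
#'
#' @param track a `depth_track` from [bin_depth()] or
#'   [simulate_depth_track()], or a numeric vector of bin means
#' @param drop_ratio ratio threshold defining a major drop
#' @param min_run persistence window, bins
#' @param search_bins optional `c(first, last)` bin range to scan
#' @return data frame of breakpoint calls: chrom, boundary_bin (last bin
#'   before the drop), boundary_pos (bin edge, bp), pre_mean, post_mean,
#'   ratio; zero rows when no drop qualifies
#' @examples
#' tr <- c(rep(30, 20), rep(12, 20))
#' detect_coverage_drop(tr)
#' @export
detect_coverage_drop <- function(track, drop_ratio = 0.7, min_run = 5L,
                                 search_bins = NULL) {
  if (is.numeric(track) && is.null(dim(track))) {
    m <- as.numeric(track)
    chrom <- "chrI"
    bin_width <- NA_integer_
    bins <- seq_along(m)
  } else {
    m <- track$mean_depth
    chrom <- track$chrom[1L]
    bin_width <- attr(track, "bin_width") %||%
      as.integer(track$end[1L] - track$start[1L] + 1L)
    bins <- track$bin
  }
  n <- length(m)
  if (n < 2L * min_run)
    stop_mmcsig("track too short: need at least ", 2L * min_run, " bins")
  cand <- seq.int(min_run, n - min_run)
  if (!is.null(search_bins)) {
    inside <- which(bins >= search_bins[1L] & bins <= search_bins[2L])
    if (length(inside) == 0L)
      stop_mmcsig("'search_bins' outside the track")
    cand <- cand[cand >= inside[1L] & cand <= inside[length(inside)]]
  }
  if (length(cand) == 0L) return(empty_breakpoint_calls())

  pre_med <- vapply(cand, function(b)
    median(m[seq.int(b - min_run + 1L, b)]), 0)
  post_med <- vapply(cand, function(b)
    median(m[seq.int(b + 1L, b + min_run)]), 0)
  pre_mean <- vapply(cand, function(b)
    mean(m[seq.int(b - min_run + 1L, b)]), 0)
  post_mean <- vapply(cand, function(b)
    mean(m[seq.int(b + 1L, b + min_run)]), 0)
  qual <- pre_med > 0 & post_med < drop_ratio * pre_med
  if (!any(qual)) return(empty_breakpoint_calls())

  qb <- cand[qual]
  ratio <- ifelse(pre_mean[qual] > 0, post_mean[qual] / pre_mean[qual], Inf)
  grp <- cumsum(c(1L, diff(qb) > 1L))
  picked <- vapply(split(seq_along(qb), grp), function(ix) {
    ix[which.min(ratio[ix])]   # leftmost on exact ties
  }, 0L)
  sel <- sort(picked)
  out <- data.frame(chrom = chrom,
                    boundary_bin = bins[qb[sel]],
                    boundary_pos = if (is.na(bin_width)) NA_integer_
                                   else bins[qb[sel]] * bin_width,
                    pre_mean = pre_mean[qual][sel],
                    post_mean = post_mean[qual][sel],
                    ratio = ratio[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_breakpoint_calls <- function() {
  data.frame(chrom = character(0), boundary_bin = integer(0),
             boundary_pos = integer(0), pre_mean = numeric(0),
             post_mean = numeric(0), ratio = numeric(0),
             stringsAsFactors = FALSE)
}
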