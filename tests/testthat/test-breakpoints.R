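test_that("depth binning averages fixed-width bins, partial bin included", {
  tr <- bin_depth(rep(30, 10000), bin_width = 5000)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$mean_depth, c(30, 30))
  # two-level positions
  tr2 <- bin_depth(c(rep(30, 5000), rep(15, 5000)), bin_width = 5000)
  expect_equal(tr2$mean_depth, c(30, 15))
  # partial final bin averaged over its actual width
  tr3 <- bin_depth(c(rep(10, 5000), rep(40, 100)), bin_width = 5000)
  expect_equal(tr3$mean_depth, c(10, 40))
  expect_equal(tr3$end, c(5000L, 5100L))
  # data-frame input with unsorted positions
  df <- data.frame(pos = sample(1:1000), depth = 7)
  expect_equal(bin_depth(df, bin_width = 500)$mean_depth, c(7, 7))
  expect_error(bin_depth(rep(1, 10), bin_width = 0), "bin_width")
})

test_that("a clean two-level track yields one exact boundary call", {
  m <- c(rep(30, 200), rep(15, 200))
  calls <- detect_coverage_drop(m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$boundary_bin, 200L)
  expect_equal(calls$pre_mean, 30)
  expect_equal(calls$post_mean, 15)
  expect_equal(calls$ratio, 0.5)
  # flat tracks produce no calls
  expect_equal(nrow(detect_coverage_drop(rep(30, 100))), 0L)
  # a drop milder than the threshold is not "major"
  expect_equal(nrow(detect_coverage_drop(c(rep(30, 50), rep(25, 50)))), 0L)
  expect_error(detect_coverage_drop(rep(30, 5)), "too short")
})

test_that("detection is translation-equivariant", {
  for (shift in c(-30, 0, 45)) {
    b <- 150 + shift
    m <- c(rep(30, b), rep(12, 300 - b))
    expect_equal(detect_coverage_drop(m)$boundary_bin, b)
  }
})

test_that("the search interval restricts where drops are reported", {
  m <- c(rep(30, 100), rep(10, 100), rep(30, 10), rep(9, 90))
  all_calls <- detect_coverage_drop(m)
  expect_true(all(c(100L, 210L) %in% all_calls$boundary_bin))
  only_first <- detect_coverage_drop(m, search_bins = c(80, 120))
  expect_equal(only_first$boundary_bin, 100L)
  expect_error(detect_coverage_drop(m, search_bins = c(900, 950)), "outside")
})

test_that("simulated noisy tracks are recovered within one bin", {
  hits <- vapply(1:100, function(i) {
    tr <- simulate_depth_track(2e6, 5000, breakpoint = 1e6,
                               drop_fraction = 0.5, mean_depth = 30, sd = 3,
                               seed = 600 + i)
    calls <- detect_coverage_drop(tr)
    nrow(calls) > 0 &&
      abs(calls$boundary_bin[which.min(calls$ratio)] - 200) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # noiseless simulation: exact recovery, and boundary_pos is the bin edge
  tr0 <- simulate_depth_track(2e6, 5000, breakpoint = 1e6,
                              drop_fraction = 0.5, mean_depth = 30, sd = 0,
                              seed = 1)
  call0 <- detect_coverage_drop(tr0)
  expect_equal(call0$boundary_bin, 200L)
  expect_equal(call0$boundary_pos, 1000000L)
  # no drop configured -> no candidate
  flat <- simulate_depth_track(1e6, 5000, breakpoint = NULL, mean_depth = 30,
                               sd = 3, seed = 2)
  expect_equal(nrow(detect_coverage_drop(flat)), 0L)
})

test_that("flat noisy tracks yield no false calls at moderate noise", {
  fp <- vapply(1:100, function(i) {
    tr <- simulate_depth_track(1e6, 5000, breakpoint = NULL, mean_depth = 30,
                               sd = 3, seed = 3000 + i)
    nrow(detect_coverage_drop(tr)) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.01)
})

test_that("depth tracks round-trip through bedGraph", {
  tr <- simulate_depth_track(50000, 5000, breakpoint = 30000,
                             drop_fraction = 0.4, seed = 9)
  d <- withr::local_tempdir()
  write_depth_bedgraph(tr, file.path(d, "t.bedgraph"))
  back <- read_depth_bedgraph(file.path(d, "t.bedgraph"))
  expect_equal(back$bin, tr$bin)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$mean_depth, tr$mean_depth, tolerance = 1e-8)
})
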