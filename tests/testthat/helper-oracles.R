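# Independent oracles and shared fixtures for the test suite.

# Brute-force microhomology oracle: tries every k from the cap down to 0 on
# both junction sides, case-insensitively. Kept deliberately naive and
# independent of the package's scorer.
mh_oracle <- function(deleted, left, right, cap = 25L) {
  deleted <- toupper(deleted); left <- toupper(left); right <- toupper(right)
  five <- 0L
  for (k in seq.int(min(cap, nchar(deleted), nchar(right)), 0L)) {
    if (k == 0L) break
    if (substr(deleted, 1L, k) == substr(right, 1L, k)) { five <- k; break }
  }
  three <- 0L
  nd <- nchar(deleted); nl <- nchar(left)
  for (k in seq.int(min(cap, nd, nl), 0L)) {
    if (k == 0L) break
    if (substr(deleted, nd - k + 1L, nd) == substr(left, nl - k + 1L, nl)) {
      three <- k; break
    }
  }
  c(five = five, three = three, mh = max(five, three))
}

# Random junction generator for property tests: plants a known shared
# prefix/suffix with probability 1/2 so both zero and positive scores occur.
random_junction <- function() {
  rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  del <- rseq(sample(1:30, 1))
  left <- rseq(sample(0:20, 1))
  right <- rseq(sample(0:20, 1))
  if (runif(1) < 0.5 && nchar(right) > 0) {
    k <- sample(seq_len(min(nchar(del), nchar(right))), 1)
    right <- paste0(substr(del, 1, k), substr(right, k + 1, nchar(right)))
  }
  list(deleted = del, left = left, right = right)
}

# One small simulated cohort shared across test files (memoised).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        genome_length = 2e5, n_strains = 3, n_deletions_per_strain = 5,
        n_snvs_per_strain = 8, n_shared_snvs = 4, seed = 11))
    }
    cache
  }
})
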