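#' Dinucleotide target frequencies with a depleted CpG content
#'
#' Builds a 16-element dinucleotide frequency vector whose row and column
#' marginals are balanced (each base 1/4), so the target is exactly
#' attainable by a stationary first-order Markov chain. Starting from the
#' uniform 1/16 table, the CG cell is set to `cg` and, to keep every
#' marginal at 1/4, the AT cell is lowered to `cg` while the CT and AG cells
#' absorb the displaced mass. This emulates a CpG-scarce genomic background
#' against which CpG-targeted damage is observable.
#'
#' @param cg target proportion of overlapping CG dinucleotides, in (0, 1/8]
#' @return named numeric vector of length 16 summing to 1
#' @examples
#' f <- dinuc_freqs_cg_depleted(0.01)
#' sum(f)          # 1
#' f[["CG"]]       # 0.01
#' @export
dinuc_freqs_cg_depleted <- function(cg = 0.01) {
  if (!is.numeric(cg) || length(cg) != 1L || cg <= 0 || cg > 1 / 8)
    stop_mmcsig("'cg' must be a single value in (0, 1/8]")
  f <- setNames(rep(1 / 16, 16L), DINUCS)
  f[["CG"]] <- cg
  f[["AT"]] <- cg
  f[["CT"]] <- 2 / 16 - cg
  f[["AG"]] <- 2 / 16 - cg
  f
}

validate_dinuc_freqs <- function(freqs) {
  if (length(freqs) != 16L || !is.numeric(freqs))
    stop_mmcsig("'dinuc_freqs' must be a numeric vector of length 16")
  if (is.null(names(freqs))) names(freqs) <- DINUCS
  if (!setequal(names(freqs), DINUCS))
    stop_mmcsig("'dinuc_freqs' names must be the 16 dinucleotides AA..TT")
  freqs <- freqs[DINUCS]
  if (any(freqs < 0)) stop_mmcsig("'dinuc_freqs' must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_mmcsig("'dinuc_freqs' must sum to 1 (within 1e-9)")
  freqs
}

# Balance row/column marginals of a 4x4 pair-frequency matrix by iterative
# proportional fitting. A pair distribution can only be the stationary
# dinucleotide distribution of a first-order chain when the marginal of the
# first letter equals that of the second; user targets that violate this are
# projected to the nearest balanced table.
balance_pair_matrix <- function(F, max_iter = 200L, tol = 1e-12) {
  for (i in seq_len(max_iter)) {
    rs <- rowSums(F); cs <- colSums(F)
    if (max(abs(rs - cs)) < tol) break
    m <- (rs + cs) / 2
    sc <- ifelse(rs > 0, m / rs, 1)
    F <- F * sc
    cs <- colSums(F)
    sc <- ifelse(cs > 0, m / cs, 1)
    F <- sweep(F, 2L, sc, "*")
    F <- F / sum(F)
  }
  F
}

#' Simulate a genome as a first-order Markov chain over A,C,G,T
#'
#' The transition matrix is derived from the target overlapping-dinucleotide
#' proportions: conditional on the current base x, the next base y is drawn
#' with probability f(x,y)/sum_y f(x,y). Targets whose first- and
#' second-letter marginals disagree are first balanced by iterative
#' proportional fitting (no stationary chain can realise them exactly);
#' after balancing, realized dinucleotide proportions converge to the
#' (balanced) targets as the length grows.
#'
#' @param length genome length in bp (>= 2)
#' @param dinuc_freqs named numeric vector of 16 target dinucleotide
#'   proportions (see [dinuc_freqs_cg_depleted()]); default uniform
#' @param seed integer seed; the same seed yields a byte-identical genome
#' @param chrom name given to the simulated chromosome
#' @return a [Biostrings::DNAStringSet] of one sequence
#' @examples
#' g <- simulate_genome(2000, seed = 1)
#' @export
simulate_genome <- function(length,
                            dinuc_freqs = setNames(rep(1 / 16, 16L), DINUCS),
                            seed = 1L,
                            chrom = "chrI") {
  if (!is.numeric(length) || length(length) != 1L || length < 2)
    stop_mmcsig("'length' must be a single integer >= 2")
  length <- as.integer(length)
  freqs <- validate_dinuc_freqs(dinuc_freqs)
  F <- matrix(freqs, nrow = 4L, byrow = TRUE, dimnames = list(BASES, BASES))

  rs <- rowSums(F); cs <- colSums(F)
  # a base that is demanded as a second letter but can never emit a
  # successor makes the conditional matrix non-normalizable
  if (any(rs == 0 & cs > 0))
    stop_mmcsig("non-normalizable 'dinuc_freqs': base(s) ",
                paste(BASES[rs == 0 & cs > 0], collapse = ","),
                " occur as second letter but have an all-zero row")
  F <- balance_pair_matrix(F)
  rs <- rowSums(F)
  P <- F / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 1 / 4   # unreachable states; never started from
  start <- ifelse(rs > 0, rs, 0)
  start <- start / sum(start)

  cum <- t(apply(P, 1L, cumsum))
  th1 <- cum[, 1L]; th2 <- cum[, 2L]; th3 <- cum[, 3L]
  states <- withr::with_seed(as.integer(seed), {
    s <- integer(length)
    k <- sample.int(4L, 1L, prob = start)
    s[1L] <- k
    u <- runif(length)
    for (i in 2:length) {
      k <- 1L + (u[i] > th1[k]) + (u[i] > th2[k]) + (u[i] > th3[k])
      s[i] <- k
    }
    s
  })
  seq <- paste(BASES[states], collapse = "")
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- chrom
  out
}

# Coerce a genome argument (DNAStringSet, DNAString, or named character
# vector) to a named character vector of upper-case sequences.
genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (methods::is(genome, "DNAString")) {
    out <- setNames(as.character(genome), "chrI")
  } else if (is.character(genome)) {
    out <- genome
    if (is.null(names(out)) && length(out) == 1L) names(out) <- "chrI"
  } else {
    stop_mmcsig("'genome' must be a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)))
    stop_mmcsig("genome sequences must be named")
  toupper(out)
}

genome_chrom <- function(genome, chrom) {
  g <- genome_as_character(genome)
  if (!chrom %in% names(g))
    stop_mmcsig("chromosome '", chrom, "' not found in genome")
  g[[chrom]]
}
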