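test_that("deletion length follows the 1-based inclusive convention", {
  expect_equal(deletion_length(753745, 1072570), 318826L)
  expect_equal(deletion_length(1742835, 1745216), 2382L)
  expect_equal(deletion_length(5, 5), 1L)
  expect_error(deletion_length(10, 9), "start")
})

test_that("published deletion sizes are validated, discordant rows flagged", {
  sizes <- check_size_consistency(mmc_lethal_deletions())
  conc <- sizes[sizes$concordant, ]
  expect_setequal(conc$printed_size_bp, c(318826, 2382, 8, 4962, 4877))
  disc <- sizes[!sizes$concordant, ]
  expect_setequal(disc$allele, c("h2718", "h2787"))
  expect_equal(disc$computed_size[disc$allele == "h2718"], 23L)
  expect_equal(disc$computed_size[disc$allele == "h2787"], 15061L)
})

test_that("flank extraction is adjacent, truncated at ends, and exact", {
  g <- c(chrI = "AAACCCGGGTTT")
  ctx <- extract_flanks(g, "chrI", 4, 6, flank = 3)
  expect_equal(ctx$deleted_seq, "CCC")
  expect_equal(ctx$left_flank, "AAA")
  expect_equal(ctx$right_flank, "GGG")
  # truncation at the chromosome start, not an error
  ctx2 <- extract_flanks(g, "chrI", 2, 3, flank = 5)
  expect_equal(ctx2$left_flank, "A")
  expect_equal(ctx2$right_flank, "CCCGG")
  # zero flanks
  ctx3 <- extract_flanks(g, "chrI", 4, 6, flank = 0)
  expect_equal(ctx3$left_flank, "")
  expect_equal(ctx3$deleted_seq, "CCC")
  expect_error(extract_flanks(g, "chrI", 10, 13), "outside")
  expect_error(extract_flanks(g, "chrX", 1, 2), "chrX")
})

test_that("dinucleotide profiles count overlapping windows exactly", {
  p <- dinucleotide_profile("ACGCGT")
  expect_equal(p$n_windows, 5L)
  expect_equal(p$proportions[["CG"]], 2 / 5)   # windows AC CG GC CG GT
  expect_equal(p$proportions[["AC"]], 1 / 5)
  expect_equal(dinucleotide_profile("AA")$proportions[["AA"]], 1)
  # windows never span sequence boundaries; N windows skipped
  p2 <- dinucleotide_profile(c("ACG", "NTT", "A"))
  expect_equal(p2$n_windows, 3L)   # AC CG from seq1; TT from seq2
  expect_equal(p2$counts[["TT"]], 1L)
  # degenerate input: no windows, proportions undefined
  p3 <- dinucleotide_profile(c("A", "C"))
  expect_equal(p3$n_windows, 0L)
  expect_true(all(is.na(p3$proportions)))
  # case-insensitive
  expect_equal(dinucleotide_profile("acgcgt")$counts,
               dinucleotide_profile("ACGCGT")$counts)
})

test_that("profile counts agree with Biostrings on random sequences", {
  set.seed(31)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(2:200, 1), TRUE),
          collapse = ""), "")
  mine <- dinucleotide_profile(seqs)
  ext <- colSums(Biostrings::dinucleotideFrequency(
    Biostrings::DNAStringSet(seqs)))
  expect_equal(unclass(mine$counts), ext[names(mine$counts)],
               ignore_attr = TRUE)
  expect_equal(mine$n_windows, sum(nchar(seqs) - 1L))
})

test_that("fold enrichment is a scale-free ratio of CG proportions", {
  target <- c("ACGT", "CCGG")
  bg <- c("ATAT", "ACGT")
  f <- fold_enrichment(target, bg)
  # oracle by hand: target CG 2/6, background CG 1/6
  expect_equal(f, 2)
  expect_equal(fold_enrichment(bg, bg), 1)
  expect_equal(fold_enrichment(c(target, target), c(bg, bg, bg)), f)
  expect_error(fold_enrichment(target, "ATAT"), "zero")
  # illustrative proportions reproducing the reported 3.4-fold
  prof <- function(p) {
    v <- setNames(rep((1 - p) / 15, 16), mmcsig:::DINUCS)
    v[["CG"]] <- p
    structure(list(proportions = v, n_windows = 1000L),
              class = "dinuc_profile")
  }
  expect_equal(fold_enrichment(prof(0.068), prof(0.020)), 3.4)
})

test_that("heatmap matrix has the four context rows, each summing to one", {
  g <- simulate_genome(5000, seed = 13)
  cfg <- sim_config(genome_length = 5000, n_strains = 1,
                    n_deletions_per_strain = 5,
                    deletion_size_dist = list(dist = "fixed", size = 30),
                    mh_length_dist = 0, n_het_deletions_per_strain = 0,
                    seed = 3)
  ctx <- deletion_contexts(g, inject_deletions(g, cfg))
  mat <- heatmap_matrix(ctx$deleted_seq, ctx$left_flank, ctx$right_flank,
                        as.character(g))
  expect_equal(dim(mat), c(4L, 16L))
  expect_equal(rownames(mat),
               c("deleted", "left_flank", "right_flank", "background"))
  expect_equal(unname(rowSums(mat)), rep(1, 4))
  same <- heatmap_matrix("ACGT", "ACGT", "ACGT", "ACGT")
  expect_true(all(apply(same, 2, function(x) length(unique(x)) == 1)))
  expect_error(heatmap_matrix(character(0), "A", "A", "A"), "empty")
})

test_that("microhomology matches hand-scored published junctions", {
  # fully printed 21-bp junction: 20-bp five-prime microhomology
  mh1 <- microhomology("tcctcagcttcagcagaatac", "GAC",
                       "TCCTCAGCTTCAGCAGAATATCCATG")
  expect_equal(mh1$five_prime_len, 20L)
  expect_equal(mh1$mh, 20L)
  # 4-bp junction: single-base match on the five-prime side only
  mh2 <- microhomology("cgcg", "ATCCAATTTTCCGC", "CAGTCGCCAAAAAGG")
  expect_equal(mh2$five_prime_len, 1L)
  expect_equal(mh2$three_prime_len, 0L)
  expect_equal(mh2$mh, 1L)
  # no homology at all
  expect_equal(microhomology("aaaa", "CCCC", "GGGG")$mh, 0L)
  # cap limits the reported length
  expect_equal(microhomology(strrep("A", 40), "", strrep("A", 40),
                             cap = 25)$mh, 25L)
  expect_error(microhomology("", "A", "A"), "empty")
})

test_that("microhomology equals the brute-force oracle on random junctions", {
  set.seed(17)
  for (i in 1:500) {
    j <- random_junction()
    got <- microhomology(j$deleted, j$left, j$right)
    o <- mh_oracle(j$deleted, j$left, j$right)
    expect_equal(got$five_prime_len, unname(o[["five"]]))
    expect_equal(got$three_prime_len, unname(o[["three"]]))
  }
})

test_that("printed junction strings parse into flanks and deleted segments", {
  p <- parse_junction("ATCCAATTTTCCGCcgcgCAGTCGCCAAAAAGG")
  expect_equal(p$left_flank, "ATCCAATTTTCCGC")
  expect_equal(p$deleted, "cgcg")
  expect_equal(p$right_flank, "CAGTCGCCAAAAAGG")
  expect_true(p$full)
  expect_equal(p$size_bp, 4L)
  # elided long segment
  q <- parse_junction("CTTTTATACGTAACCtttcc<48>ataaaTGAAAAATTGCTTCC")
  expect_false(q$full)
  expect_equal(q$size_bp, 58L)
  expect_equal(q$deleted_prefix, "tttcc")
  expect_equal(q$deleted_suffix, "ataaa")
  expect_error(parse_junction("123"), "unparseable")
  # every bundled junction parses and reproduces its printed size
  jx <- mmc_deletion_junctions()
  parsed <- parse_junction(jx$junction)
  expect_equal(parsed$size_bp, jx$size_bp)
  expect_equal(sum(parsed$full), 16L)
})
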