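cohort_for_tests <- NULL  # built once by the first test via small_cohort()

test_that("injected deletions respect truth invariants", {
  co <- small_cohort()
  dels <- co$truth$deletions
  cfg <- co$config
  expect_equal(nrow(dels),
               cfg$n_strains * (cfg$n_deletions_per_strain +
                                  cfg$n_het_deletions_per_strain))
  expect_true(all(dels$start >= 1 & dels$end <= cfg$genome_length))
  expect_equal(dels$size, dels$end - dels$start + 1L)
  # non-overlapping within a strain
  for (st in unique(dels$strain)) {
    d <- dels[dels$strain == st, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # never homopolymer-contained (would be invisible to the filters)
  s <- as.character(co$genome)[[1]]
  expect_false(any(vapply(seq_len(nrow(dels)), function(i)
    is_homopolymer_deletion(s, dels$start[i], dels$end[i]), logical(1))))
})

test_that("engineered microhomology is realized at the junction", {
  co <- small_cohort()
  dels <- co$truth$deletions
  ctx <- deletion_contexts(co$genome, dels)
  # brute-force oracle on every injected junction: realized >= engineered
  for (i in seq_len(nrow(ctx))) {
    o <- mh_oracle(ctx$deleted_seq[i], ctx$left_flank[i], ctx$right_flank[i])
    expect_gte(o[["mh"]], dels$engineered_mh[i])
    expect_equal(ctx$mh[i], o[["mh"]])
  }
  expect_true(any(dels$engineered_mh > 0))  # the distribution exercises mh
})

test_that("a fixed engineered microhomology is always attained", {
  g <- simulate_genome(5e4, seed = 21)
  cfg <- sim_config(genome_length = 5e4, n_strains = 1,
                    n_deletions_per_strain = 10,
                    deletion_size_dist = list(dist = "fixed", size = 40),
                    mh_length_dist = 5, n_het_deletions_per_strain = 0,
                    cpg_bias = 1, seed = 4)
  dels <- inject_deletions(g, cfg)
  ctx <- deletion_contexts(g, dels)
  expect_true(all(ctx$five_prime_len >= 5))
})

test_that("unbiased placement leaves CpG content unenriched", {
  g <- simulate_genome(1e6, dinuc_freqs_cg_depleted(0.01), seed = 101)
  cfg <- sim_config(genome_length = 1e6, n_strains = 1,
                    n_deletions_per_strain = 200,
                    deletion_size_dist = list(dist = "fixed", size = 50),
                    mh_length_dist = 0, n_het_deletions_per_strain = 0,
                    cpg_bias = 1, seed = 77)
  dels <- inject_deletions(g, cfg)
  fold <- fold_enrichment(deletion_contexts(g, dels)$deleted_seq,
                          dinucleotide_profile(g))
  expect_gt(fold, 0.8)
  expect_lt(fold, 1.2)
})

test_that("impossible placements raise simulation errors", {
  g <- simulate_genome(200, seed = 1)
  cfg <- sim_config(genome_length = 200, n_strains = 1,
                    n_deletions_per_strain = 1,
                    deletion_size_dist = list(dist = "fixed", size = 190),
                    mh_length_dist = 0, n_het_deletions_per_strain = 0,
                    seed = 1)
  expect_error(inject_deletions(g, cfg), "too short")
  cfg2 <- sim_config(genome_length = 5000, n_strains = 1,
                     n_deletions_per_strain = 1,
                     deletion_size_dist = list(dist = "fixed", size = 50),
                     mh_length_dist = 20, n_het_deletions_per_strain = 0,
                     seed = 1)
  g2 <- simulate_genome(5000, seed = 2)
  expect_error(inject_deletions(g2, cfg2), "microhomology")
})

test_that("read-count evidence follows the configured zygosity model", {
  co <- small_cohort()
  cfg <- co$config
  tab <- co$tables$strain_snv_tables$strain01
  own <- co$truth$snvs[co$truth$snvs$strain == "strain01", ]
  own_rows <- tab[tab$pos %in% own$pos, ]
  other_rows <- tab[!tab$pos %in% c(own$pos, co$truth$shared_snvs$pos), ]
  expect_gt(mean(own_rows$alt_reads / own_rows$depth), 0.95)
  expect_lt(mean(other_rows$alt_reads / other_rows$depth), 0.05)
  # het deletions concentrate near 0.5 supporting fraction
  del_tab <- do.call(rbind, co$tables$strain_del_tables)
  het <- merge(del_tab, co$truth$deletions[co$truth$deletions$zygosity == "het",
                                           c("strain", "start", "zygosity")],
               by = c("strain", "start"))
  expect_true(all(abs(het$supporting_reads / het$depth - 0.5) < 0.35))
  # parental carries exactly the shared background variants
  expect_setequal(co$tables$parental_snv_table$pos, co$truth$shared_snvs$pos)
})

test_that("cohort simulation is deterministic and writers round-trip truth", {
  cfg <- sim_config(genome_length = 3e4, n_strains = 2,
                    n_deletions_per_strain = 3, n_snvs_per_strain = 4,
                    n_shared_snvs = 2, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.character(c1$genome), as.character(c2$genome))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$tables, c2$tables)

  d <- withr::local_tempdir()
  write_truth_tsv(c1$truth, file.path(d, "truth.tsv"))
  back <- read_truth_tsv(file.path(d, "truth.tsv"))
  expect_equal(back$deletions[, c("strain", "chrom", "start", "end")],
               c1$truth$deletions[, c("strain", "chrom", "start", "end")])
  expect_equal(back$snvs$pos, c1$truth$snvs$pos)
  write_deletions_bed(c1$truth$deletions, file.path(d, "dels.bed"))
  bed <- read_deletions_bed(file.path(d, "dels.bed"))
  expect_equal(bed$start, c1$truth$deletions$start)
  expect_equal(bed$end, c1$truth$deletions$end)
})
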