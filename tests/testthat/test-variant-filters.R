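test_that("zygosity bands follow the read-ratio rules", {
  expect_equal(call_zygosity(20, 19), "hom")        # 0.95 >= 0.90
  expect_equal(call_zygosity(20, 18), "hom")        # 0.90 inclusive
  expect_equal(call_zygosity(20, 10), "het")        # 0.50
  expect_equal(call_zygosity(20, 15), "ambiguous")  # 0.75 between bands
  expect_equal(call_zygosity(20, 2), "ref")         # 0.10 inclusive
  expect_equal(call_zygosity(20, 5), "ambiguous")   # 0.25 below het band
  expect_error(call_zygosity(0, 0), "depth")
  expect_error(call_zygosity(10, 11), "variant_reads")
})

make_snv <- function(strain, pos, alt = "T", depth = 10L, alt_reads = depth,
                     ref = "A") {
  data.frame(strain = strain, chrom = "chrI", pos = pos, ref = ref,
             alt = alt, depth = depth, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

test_that("strain-specific SNV filter applies all four criteria", {
  cohort <- rbind(
    make_snv("s1", 100),                      # unique hom, depth 10 -> keep
    make_snv("s2", 200), make_snv("s3", 200), # hom in two strains -> drop both
    make_snv("s1", 300, depth = 7L),          # depth 7 not > 7 -> drop
    make_snv("s1", 400, depth = 8L),          # depth 8 -> keep
    make_snv("s2", 500),                      # in parental -> drop
    make_snv("s1", 600, depth = 20L, alt_reads = 10L),  # het -> drop
    make_snv("s2", 700),                      # hom here...
    make_snv("s3", 700, depth = 20L, alt_reads = 10L),  # ...het there -> drop
    make_snv("s3", 800))
  parental <- make_snv("parental", 500)
  kept <- filter_strain_specific_snvs(cohort, parental)
  expect_setequal(kept$pos, c(100, 400, 800))
  expect_true(all(kept$zygosity_call == "hom"))
})

test_that("malformed SNV records are rejected individually, not fatally", {
  cohort <- rbind(
    make_snv("s1", 10),
    make_snv("s2", 20, ref = "A", alt = "A"),   # ref == alt
    make_snv("s2", 30, alt = "N"),              # invalid base
    make_snv("s2", 40, depth = 5L, alt_reads = 9L),  # counts impossible
    make_snv("s2", 50))
  kept <- filter_strain_specific_snvs(cohort)
  expect_setequal(kept$pos, c(10, 50))
  rej <- attr(kept, "rejected")
  expect_equal(nrow(rej), 3)
  expect_setequal(rej$reason,
                  c("ref equals alt", "invalid base", "invalid read counts"))
  expect_error(filter_strain_specific_snvs(make_snv("s1", 1)), "2 strains")
})

make_del <- function(strain, start, end, depth = 20L, sup = 19L) {
  data.frame(strain = strain, chrom = "chrI", start = start, end = end,
             depth = depth, supporting_reads = sup, stringsAsFactors = FALSE)
}

test_that("strain-specific deletion filter: uniqueness, parental, homopolymer", {
  #         1         2         3         4
  # 123456789012345678901234567890123456789012345
  g <- c(chrI = "ACGTACGTACAAAAAAAATTGCGCATCGATCGATCGTACGTACGT")
  cohort <- rbind(
    make_del("s1", 21, 26),                 # unique, mixed seq -> keep
    make_del("s2", 30, 34), make_del("s3", 30, 34),  # same event twice -> drop
    make_del("s1", 12, 14),                 # AAA inside the 8-A run -> drop
    make_del("s2", 5, 10, sup = 10L),       # het -> drop
    make_del("s3", 40, 42))                 # matches parental -> drop
  parental <- make_del("parental", 40, 42)
  kept <- filter_strain_specific_deletions(cohort, parental, g)
  expect_equal(kept[, c("strain", "start", "end")],
               data.frame(strain = "s1", start = 21L, end = 26L))
  # out-of-reference coordinates are rejected with a reason
  bad <- rbind(cohort[1, ], make_del("s1", 40, 99), make_del("s1", 1, 2)[
    , ])
  bad$chrom[3] <- "chrX"
  kept2 <- filter_strain_specific_deletions(bad, NULL, g)
  rej <- attr(kept2, "rejected")
  expect_setequal(rej$reason,
                  c("coordinates outside reference", "unknown chromosome"))
})

test_that("reciprocal-overlap matching tolerates caller jitter", {
  g <- c(chrI = strrep("ACGT", 100))
  # 100-bp deletions offset by 10 bp: 90% reciprocal overlap -> same event
  cohort <- rbind(make_del("s1", 101, 200), make_del("s2", 111, 210))
  expect_equal(nrow(filter_strain_specific_deletions(cohort, NULL, g)), 0)
  # offset by 50 bp: 50% overlap -> distinct events, both kept
  cohort2 <- rbind(make_del("s1", 101, 200), make_del("s2", 151, 250))
  expect_equal(nrow(filter_strain_specific_deletions(cohort2, NULL, g)), 2)
})

test_that("homopolymer containment uses the maximal run in the reference", {
  g <- c(chrI = "GGTAAAAAAAATGG")   # 8-A run at positions 4-11
  expect_true(is_homopolymer_deletion(g[[1]], 6, 8))    # AAA inside the run
  expect_false(is_homopolymer_deletion(g[[1]], 3, 8))   # TAAAAAA not monobase
  expect_false(is_homopolymer_deletion("GGTAAAATGG", 4, 7))  # run of 4 < 6
})

test_that("lethal candidates need het zygosity, interval overlap, uniqueness", {
  dels <- rbind(
    make_del("s1", 1000, 1100, sup = 10L),   # het, inside -> candidate
    make_del("s1", 2000, 2100),              # hom, inside -> excluded
    make_del("s1", 9000, 9100, sup = 10L))   # het, outside -> excluded
  cand <- identify_lethal_candidates(dels, "chrI", 500, 5000)
  expect_equal(cand$start, 1000L)
  # the same event in another strain removes uniqueness
  other <- make_del("s2", 1001, 1099)
  cand2 <- identify_lethal_candidates(dels, "chrI", 500, 5000,
                                      cohort_dels = other)
  expect_equal(nrow(cand2), 0)
  expect_error(identify_lethal_candidates(dels, "chrI", 10, 5), "interval")
})

test_that("noiseless synthetic cohorts are recovered with precision = recall = 1", {
  cfg <- sim_config(genome_length = 1.5e5, n_strains = 4,
                    n_deletions_per_strain = 6, n_snvs_per_strain = 10,
                    n_shared_snvs = 5, error_rate = 0, fixed_depth = TRUE,
                    seed = 71)
  co <- simulate_cohort(cfg)
  fs <- filter_strain_specific_snvs(co$tables$strain_snv_tables,
                                    co$tables$parental_snv_table)
  expect_setequal(paste(fs$strain, fs$pos, fs$alt),
                  paste(co$truth$snvs$strain, co$truth$snvs$pos,
                        co$truth$snvs$alt))
  fd <- filter_strain_specific_deletions(co$tables$strain_del_tables,
                                         co$tables$parental_del_table,
                                         co$genome)
  hom <- co$truth$deletions[co$truth$deletions$zygosity == "hom", ]
  expect_setequal(paste(fd$strain, fd$start, fd$end),
                  paste(hom$strain, hom$start, hom$end))
})
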