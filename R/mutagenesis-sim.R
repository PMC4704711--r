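# Margin kept free of events at both chromosome ends so that full flanks
# (up to the default microhomology cap) are always extractable.
SIM_MARGIN <- 30L

#' Derive a deterministic sub-seed from a master seed
#' @keywords internal
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + as.double(k) * 9973) %% 2147483629 + 1)
}

strain_names <- function(n) sprintf("strain%02d", seq_len(n))

empty_deletion_truth <- function() {
  data.frame(strain = character(0), chrom = character(0),
             start = integer(0), end = integer(0), size = integer(0),
             engineered_mh = integer(0), zygosity = character(0),
             stringsAsFactors = FALSE)
}

empty_snv_truth <- function() {
  data.frame(strain = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), stringsAsFactors = FALSE)
}

# Start positions where the k-base prefix of a deleted segment of length L
# equals the k-base prefix of its right flank, i.e. seq[s..s+k-1] ==
# seq[s+L..s+L+k-1] -- the 5' alt-NHEJ-consistent microhomology construction.
mh_match_starts <- function(codes, L, k) {
  n <- length(codes)
  if (n - L < k) return(integer(0))
  eq <- codes[seq_len(n - L)] == codes[seq.int(1L + L, n)]
  cs <- c(0L, cumsum(eq))
  s <- seq_len(n - L - k + 1L)
  s[cs[s + k] - cs[s] == k]
}

#' Inject strain-specific deletions with CpG bias and engineered microhomology
#'
#' Samples deletion intervals on the simulated genome. Candidate segments
#' containing at least one CG dinucleotide are sampled with relative weight
#' `cpg_bias` (weight 1 otherwise). For an engineered microhomology of
#' length k > 0 the endpoints are placed so that the first k bases of the
#' deleted segment equal the first k bases of the right flank; by chance the
#' realized microhomology can exceed k. Truth intervals are non-overlapping
#' within a strain, are never the "same event" across strains (>= 80%
#' reciprocal overlap), and never lie inside a single-base homopolymer run
#' (>= 6 bp), so they remain visible to the downstream filters.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector
#' @param config a [sim_config()]
#' @param chrom chromosome to mutate (default: first sequence)
#' @param max_retries placement attempts per deletion before giving up
#' @return data frame with columns strain, chrom, start, end, size,
#'   engineered_mh, zygosity (1-based inclusive coordinates)
#' @export
inject_deletions <- function(genome, config, chrom = NULL,
                             max_retries = 1000L) {
  seqs <- genome_as_character(genome)
  chrom <- chrom %||% names(seqs)[1L]
  s <- genome_chrom(seqs, chrom)
  n <- nchar(s)
  codes <- utf8ToInt(s)
  n_hom <- config$n_deletions_per_strain
  n_het <- config$n_het_deletions_per_strain
  per_strain <- n_hom + n_het
  if (per_strain == 0L || config$n_strains == 0L) return(empty_deletion_truth())
  strains <- strain_names(config$n_strains)

  cand_cache <- new.env(parent = emptyenv())
  eligible_starts <- function(L, k) {
    key <- paste0(L, "_", k)
    if (!is.null(cand_cache[[key]])) return(cand_cache[[key]])
    st <- mh_match_starts(codes, L, k)
    st <- st[st > SIM_MARGIN & st + L - 1L <= n - SIM_MARGIN]
    cand_cache[[key]] <- st
    st
  }

  place_one <- function(L, k, strain, acc) {
    n_free <- n - 2L * SIM_MARGIN - L + 1L
    if (n_free < 1L)
      stop_mmcsig("genome too short for a ", L, "-bp deletion")
    cand <- if (k > 0L) eligible_starts(L, k) else integer(0)
    if (k > 0L && length(cand) == 0L)
      stop_mmcsig("no position supports a ", L, "-bp deletion with ",
                  k, "-bp engineered microhomology")
    for (i in seq_len(max_retries)) {
      st <- if (k > 0L) cand[sample.int(length(cand), 1L)]
            else sample.int(n_free, 1L) + SIM_MARGIN
      en <- st + L - 1L
      seg <- substr(s, st, en)
      if (!grepl("CG", seg, fixed = TRUE) &&
          runif(1L) >= 1 / config$cpg_bias) next
      hit <- acc$start <= en & acc$end >= st
      if (any(hit & acc$strain == strain)) next
      other <- acc[hit & acc$strain != strain, , drop = FALSE]
      if (nrow(other) > 0L) {
        inter <- pmin(other$end, en) - pmax(other$start, st) + 1L
        if (any(inter >= 0.8 * pmax(other$end - other$start + 1L, L))) next
      }
      if (is_homopolymer_deletion(s, st, en, run = 6L)) next
      return(c(st, en))
    }
    stop_mmcsig("could not place a ", L, "-bp deletion (engineered mh ", k,
                ") after ", max_retries, " retries")
  }

  withr::with_seed(sub_seed(config$seed, 1L), {
    total <- per_strain * config$n_strains
    sizes <- draw_deletion_sizes(config$deletion_size_dist, total)
    mhs <- draw_mh_lengths(config$mh_length_dist, total)
    acc <- data.frame(strain = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    out <- vector("list", total)
    idx <- 0L
    for (strain in strains) {
      zyg <- c(rep("hom", n_hom), rep("het", n_het))
      for (j in seq_len(per_strain)) {
        idx <- idx + 1L
        pe <- place_one(sizes[idx], mhs[idx], strain, acc)
        acc <- rbind(acc, data.frame(strain = strain, start = pe[1L],
                                     end = pe[2L], stringsAsFactors = FALSE))
        out[[idx]] <- data.frame(strain = strain, chrom = chrom,
                                 start = pe[1L], end = pe[2L],
                                 size = pe[2L] - pe[1L] + 1L,
                                 engineered_mh = mhs[idx],
                                 zygosity = zyg[j],
                                 stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Inject strain-specific and shared background SNVs
#'
#' Positions are drawn without replacement (all SNVs in the cohort occupy
#' distinct sites); each strain receives `n_snvs_per_strain` strain-specific
#' homozygous SNVs, and `n_shared_snvs` additional sites are present in the
#' composite parental and in every strain (pre-existing background the
#' strain-specific filter must remove). Alternate alleles are uniform over
#' the three non-reference bases.
#'
#' @inheritParams inject_deletions
#' @return list with data frames `snvs` (strain-specific truth) and
#'   `shared_snvs` (parental background; no strain column)
#' @export
inject_snvs <- function(genome, config, chrom = NULL) {
  seqs <- genome_as_character(genome)
  chrom <- chrom %||% names(seqs)[1L]
  s <- genome_chrom(seqs, chrom)
  n <- nchar(s)
  n_specific <- config$n_strains * config$n_snvs_per_strain
  n_total <- n_specific + config$n_shared_snvs
  if (n_total == 0L)
    return(list(snvs = empty_snv_truth(),
                shared_snvs = empty_snv_truth()[, -1L]))
  pool <- seq.int(SIM_MARGIN + 1L, n - SIM_MARGIN)
  if (length(pool) < n_total)
    stop_mmcsig("genome too short for ", n_total, " distinct SNV sites")
  withr::with_seed(sub_seed(config$seed, 2L), {
    pos <- sort(sample(pool, n_total))
    ref <- strsplit(substr(s, 1L, n), "")[[1L]][pos]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    pick <- sample(seq_len(n_total), n_specific)
    strain <- rep(strain_names(config$n_strains),
                  each = config$n_snvs_per_strain)
    snvs <- data.frame(strain = strain, chrom = chrom, pos = pos[pick],
                       ref = ref[pick], alt = alt[pick],
                       stringsAsFactors = FALSE)
    snvs <- snvs[order(snvs$strain, snvs$pos), , drop = FALSE]
    rownames(snvs) <- NULL
    rest <- setdiff(seq_len(n_total), pick)
    shared <- data.frame(chrom = chrom, pos = pos[rest], ref = ref[rest],
                         alt = alt[rest], stringsAsFactors = FALSE)
    list(snvs = snvs, shared_snvs = shared)
  })
}

draw_depth <- function(n, config) {
  if (config$fixed_depth) return(rep(as.integer(round(config$mean_depth)), n))
  pmax(rpois(n, config$mean_depth), 1L)
}

#' Simulate per-strain variant tables with read-count evidence
#'
#' For every truth SNV site of the cohort, every strain receives a record
#' with depth ~ Poisson(`mean_depth`) (or exactly `mean_depth` when
#' `fixed_depth`) and variant reads ~ Binomial(depth, f), where f is
#' `1 - error_rate` at sites homozygous in that strain (own and shared
#' background sites), 0.5 at heterozygous sites, and `error_rate` at
#' reference sites. Deletion tables carry supporting-read evidence for the
#' strain's own deletions only (absence of a call is how a deletion caller
#' reports absence). The composite parental table contains the configured
#' shared background variants.
#'
#' @param genome simulated genome
#' @param truth list with elements `snvs`, `shared_snvs`, `deletions` as
#'   produced by [inject_snvs()] and [inject_deletions()]
#' @param config a [sim_config()]
#' @return list with `strain_snv_tables`, `strain_del_tables` (named lists
#'   of data frames), `parental_snv_table` and `parental_del_table`
#' @export
simulate_strain_tables <- function(genome, truth, config) {
  strains <- strain_names(config$n_strains)
  snvs <- truth$snvs
  shared <- truth$shared_snvs
  dels <- truth$deletions
  f_hom <- 1 - config$error_rate
  f_err <- config$error_rate

  sites <- rbind(
    if (nrow(snvs)) cbind(snvs, owner = snvs$strain),
    if (nrow(shared)) cbind(strain = NA_character_, shared, owner = "shared")
  )
  snv_tables <- list()
  del_tables <- list()
  for (i in seq_along(strains)) {
    st <- strains[i]
    snv_tables[[st]] <- withr::with_seed(sub_seed(config$seed, 100L + i), {
      if (is.null(sites) || nrow(sites) == 0L) {
        data.frame(strain = character(0), chrom = character(0),
                   pos = integer(0), ref = character(0), alt = character(0),
                   depth = integer(0), alt_reads = integer(0),
                   stringsAsFactors = FALSE)
      } else {
        f <- ifelse(sites$owner %in% c(st, "shared"), f_hom, f_err)
        depth <- draw_depth(nrow(sites), config)
        alt_reads <- rbinom(nrow(sites), depth, f)
        data.frame(strain = st, chrom = sites$chrom, pos = sites$pos,
                   ref = sites$ref, alt = sites$alt, depth = depth,
                   alt_reads = alt_reads, stringsAsFactors = FALSE)
      }
    })
    del_tables[[st]] <- withr::with_seed(sub_seed(config$seed, 500L + i), {
      own <- dels[dels$strain == st, , drop = FALSE]
      if (nrow(own) == 0L) {
        data.frame(strain = character(0), chrom = character(0),
                   start = integer(0), end = integer(0), depth = integer(0),
                   supporting_reads = integer(0), stringsAsFactors = FALSE)
      } else {
        f <- ifelse(own$zygosity == "het", 0.5, f_hom)
        depth <- draw_depth(nrow(own), config)
        data.frame(strain = st, chrom = own$chrom, start = own$start,
                   end = own$end, depth = depth,
                   supporting_reads = rbinom(nrow(own), depth, f),
                   stringsAsFactors = FALSE)
      }
    })
  }
  parental <- withr::with_seed(sub_seed(config$seed, 100L), {
    if (is.null(shared) || nrow(shared) == 0L) {
      data.frame(strain = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 depth = integer(0), alt_reads = integer(0),
                 stringsAsFactors = FALSE)
    } else {
      depth <- draw_depth(nrow(shared), config)
      data.frame(strain = "parental", chrom = shared$chrom, pos = shared$pos,
                 ref = shared$ref, alt = shared$alt, depth = depth,
                 alt_reads = rbinom(nrow(shared), depth, f_hom),
                 stringsAsFactors = FALSE)
    }
  })
  list(strain_snv_tables = snv_tables,
       strain_del_tables = del_tables,
       parental_snv_table = parental,
       parental_del_table = del_tables[[1L]][0L, , drop = FALSE])
}

#' Simulate a complete mutagenized cohort with ground truth
#'
#' Convenience wrapper: simulates the genome, injects deletions and SNVs,
#' and generates per-strain variant tables plus the composite parental
#' table. All randomness derives deterministically from `config$seed`.
#'
#' @param config a [sim_config()]
#' @param chrom name of the simulated chromosome
#' @return list of class `mmc_cohort` with elements `genome`, `truth`
#'   (list: `snvs`, `shared_snvs`, `deletions`), `tables` (see
#'   [simulate_strain_tables()]) and `config`
#' @examples
#' cohort <- simulate_cohort(sim_config(genome_length = 5e4, n_strains = 2,
#'                                      n_deletions_per_strain = 3,
#'                                      n_snvs_per_strain = 5, seed = 42))
#' @export
simulate_cohort <- function(config, chrom = "chrI") {
  genome <- simulate_genome(config$genome_length, config$dinuc_freqs,
                            seed = sub_seed(config$seed, 0L), chrom = chrom)
  deletions <- inject_deletions(genome, config, chrom = chrom)
  snv_truth <- inject_snvs(genome, config, chrom = chrom)
  truth <- list(snvs = snv_truth$snvs, shared_snvs = snv_truth$shared_snvs,
                deletions = deletions)
  tables <- simulate_strain_tables(genome, truth, config)
  structure(list(genome = genome, truth = truth, tables = tables,
                 config = config),
            class = "mmc_cohort")
}
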