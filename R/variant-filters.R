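#' Call zygosity from read counts
#'
#' Band rules used throughout the pipeline: homozygous when the variant
#' read fraction is at least `hom_threshold` (>= 0.90, the same threshold
#' passed to the consensus caller), heterozygous when the fraction is
#' "approximately 50%" (inside `het_band`), reference when at most
#' `ref_threshold`, otherwise ambiguous.
#'
#' @param depth total read depth (>= 1); vectorized
#' @param variant_reads reads supporting the variant (<= depth)
#' @param hom_threshold homozygous fraction threshold (inclusive)
#' @param het_band inclusive \[low, high\] band for heterozygous calls
#' @param ref_threshold reference fraction threshold (inclusive)
#' @return character vector of calls: "hom", "het", "ref" or "ambiguous"
#' @examples
#' call_zygosity(20, c(19, 10, 15, 1))
#' @export
call_zygosity <- function(depth, variant_reads, hom_threshold = 0.90,
                          het_band = c(0.35, 0.65), ref_threshold = 0.10) {
  if (any(depth < 1)) stop_mmcsig("'depth' must be >= 1")
  if (any(variant_reads < 0) || any(variant_reads > depth))
    stop_mmcsig("'variant_reads' must be in [0, depth]")
  f <- variant_reads / depth
  ifelse(f >= hom_threshold, "hom",
         ifelse(f <= ref_threshold, "ref",
                ifelse(f >= het_band[1L] & f <= het_band[2L], "het",
                       "ambiguous")))
}

# Bind a cohort given either as one data frame with a strain column or a
# (possibly named) list of per-strain data frames.
bind_cohort <- function(tables) {
  if (is.data.frame(tables)) return(tables)
  if (is.list(tables)) {
    out <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
    return(out)
  }
  stop_mmcsig("cohort tables must be a data frame or a list of data frames")
}

#' Filter a cohort for strain-specific homozygous SNVs
#'
#' Reproduces the post-caller filtering of a mutation-accumulation cohort:
#' a retained SNV is homozygous (per [call_zygosity()]), covered by at
#' least `min_depth` reads (default 8, i.e. strictly more than 7), observed
#' at its (chrom, pos, alt) key in exactly one cohort strain, and absent
#' from the composite parental table. "Observed" means any non-reference
#' evidence (variant fraction above the reference band), so a second strain
#' carrying the allele heterozygously also disqualifies the site. Malformed
#' records are rejected individually with a reason, not by aborting.
#'
#' @param cohort_tables data frame with columns strain, chrom, pos, ref,
#'   alt, depth, alt_reads — or a list of such per-strain data frames
#' @param parental_table composite parental table (same columns; `NULL` for
#'   none). Modeled as the union of variant keys of its constituents.
#' @param min_depth minimum read depth (inclusive)
#' @param hom_threshold homozygous variant-read fraction (inclusive)
#' @return data frame of retained records with a `zygosity_call` column;
#'   rejected records with reasons in `attr(, "rejected")`
#' @export
filter_strain_specific_snvs <- function(cohort_tables, parental_table = NULL,
                                        min_depth = 8L, hom_threshold = 0.90) {
  tab <- bind_cohort(cohort_tables)
  if (length(unique(tab$strain)) < 2L)
    stop_mmcsig("cohort must contain at least 2 strains")
  need <- c("strain", "chrom", "pos", "ref", "alt", "depth", "alt_reads")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_mmcsig("cohort table lacks column(s): ",
                paste(missing_cols, collapse = ", "))

  bad <- rep(NA_character_, nrow(tab))
  bad[!(tab$ref %in% BASES) | !(tab$alt %in% BASES)] <- "invalid base"
  bad[is.na(bad) & tab$ref == tab$alt] <- "ref equals alt"
  bad[is.na(bad) & (tab$depth < 1 | tab$alt_reads < 0 |
                      tab$alt_reads > tab$depth)] <- "invalid read counts"
  rejected <- tab[!is.na(bad), , drop = FALSE]
  rejected$reason <- bad[!is.na(bad)]
  ok <- tab[is.na(bad), , drop = FALSE]

  if (nrow(ok) > 0L) {
    ok$zygosity_call <- call_zygosity(ok$depth, ok$alt_reads,
                                      hom_threshold = hom_threshold)
    key <- paste(ok$chrom, ok$pos, ok$alt, sep = ":")
    observed <- ok$zygosity_call != "ref"
    strains_per_key <- tapply(ok$strain[observed], key[observed],
                              function(s) length(unique(s)))
    n_strains_at_key <- strains_per_key[key]
    n_strains_at_key[is.na(n_strains_at_key)] <- 0L

    parental_keys <- character(0)
    if (!is.null(parental_table) && nrow(parental_table) > 0L) {
      ptab <- parental_table
      if (!is.null(ptab$depth) && !is.null(ptab$alt_reads)) {
        pcall <- call_zygosity(pmax(ptab$depth, 1), ptab$alt_reads,
                               hom_threshold = hom_threshold)
        ptab <- ptab[pcall != "ref", , drop = FALSE]
      }
      parental_keys <- paste(ptab$chrom, ptab$pos, ptab$alt, sep = ":")
    }
    keep <- ok$zygosity_call == "hom" &
      ok$depth >= min_depth &
      n_strains_at_key == 1L &
      !(key %in% parental_keys)
    out <- ok[keep, , drop = FALSE]
  } else {
    out <- ok
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# Fraction of reciprocal overlap between one interval and a set of
# intervals on the same chromosome: intersection over the larger length
# (>= cut iff both one-sided fractions are >= cut).
reciprocal_overlap <- function(start, end, starts, ends) {
  inter <- pmin(ends, end) - pmax(starts, start) + 1
  inter <- pmax(inter, 0)
  inter / pmax(ends - starts + 1, end - start + 1)
}

#' Is a deletion contained in a single-base homopolymer run?
#'
#' TRUE when the deleted segment consists of a single repeated base and the
#' maximal run of that base containing the segment in the reference is at
#' least `run` long. Such deletions are artefact-prone (indel callers
#' routinely filter them) and are excluded from strain-specific sets.
#'
#' @param chrom_seq chromosome sequence (single character string)
#' @param start,end 1-based inclusive deletion coordinates
#' @param run minimum run length, bp
#' @return logical
#' @export
is_homopolymer_deletion <- function(chrom_seq, start, end, run = 6L) {
  seg <- substr(chrom_seq, start, end)
  b <- substr(seg, 1L, 1L)
  if (seg != strrep(b, nchar(seg))) return(FALSE)
  n <- nchar(chrom_seq)
  left <- start
  while (left > 1L && substr(chrom_seq, left - 1L, left - 1L) == b)
    left <- left - 1L
  right <- end
  while (right < n && substr(chrom_seq, right + 1L, right + 1L) == b)
    right <- right + 1L
  (right - left + 1L) >= run
}

#' Filter a cohort for strain-specific homozygous deletions
#'
#' A retained deletion is homozygous (from its supporting-read fraction or
#' a supplied `zygosity_call` column), unique to its strain — no deletion
#' in another strain (or in the composite parental) matches it with at
#' least `min_overlap` reciprocal overlap on the same chromosome — and not
#' contained in a single-base homopolymer run of at least
#' `homopolymer_run` bp. Records with coordinates outside the reference are
#' rejected with a reason.
#'
#' @param cohort_dels data frame (strain, chrom, start, end, depth,
#'   supporting_reads and/or zygosity_call) or list of per-strain frames
#' @param parental_dels composite parental deletion calls (or `NULL`)
#' @param genome reference genome (needed for the homopolymer check)
#' @param min_overlap reciprocal-overlap fraction above which two calls in
#'   different strains count as the same event
#' @param homopolymer_run homopolymer run length threshold, bp
#' @param hom_threshold homozygous supporting-read fraction
#' @return data frame of retained deletions with `zygosity_call`; rejected
#'   records with reasons in `attr(, "rejected")`
#' @export
filter_strain_specific_deletions <- function(cohort_dels,
                                             parental_dels = NULL,
                                             genome,
                                             min_overlap = 0.8,
                                             homopolymer_run = 6L,
                                             hom_threshold = 0.90) {
  tab <- bind_cohort(cohort_dels)
  seqs <- genome_as_character(genome)
  if (nrow(tab) == 0L) {
    attr(tab, "rejected") <- tab
    return(tab)
  }

  bad <- rep(NA_character_, nrow(tab))
  bad[!(tab$chrom %in% names(seqs))] <- "unknown chromosome"
  inb <- is.na(bad)
  lens <- nchar(seqs)[tab$chrom[inb]]
  oob <- tab$start[inb] < 1L | tab$end[inb] > lens | tab$start[inb] > tab$end[inb]
  bad[inb][oob] <- "coordinates outside reference"
  rejected <- tab[!is.na(bad), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- bad[!is.na(bad)]
  ok <- tab[is.na(bad), , drop = FALSE]
  if (nrow(ok) == 0L) {
    attr(ok, "rejected") <- rejected
    return(ok)
  }

  if (is.null(ok$zygosity_call)) {
    ok$zygosity_call <- call_zygosity(ok$depth, ok$supporting_reads,
                                      hom_threshold = hom_threshold)
  }

  n_match <- integer(nrow(ok))
  par_match <- logical(nrow(ok))
  for (i in seq_len(nrow(ok))) {
    same_chrom <- ok$chrom == ok$chrom[i] & ok$strain != ok$strain[i]
    if (any(same_chrom)) {
      fr <- reciprocal_overlap(ok$start[i], ok$end[i],
                               ok$start[same_chrom], ok$end[same_chrom])
      n_match[i] <- sum(fr >= min_overlap)
    }
    if (!is.null(parental_dels) && nrow(parental_dels) > 0L) {
      pc <- parental_dels$chrom == ok$chrom[i]
      if (any(pc)) {
        fr <- reciprocal_overlap(ok$start[i], ok$end[i],
                                 parental_dels$start[pc],
                                 parental_dels$end[pc])
        par_match[i] <- any(fr >= min_overlap)
      }
    }
  }
  homopoly <- vapply(seq_len(nrow(ok)), function(i) {
    is_homopolymer_deletion(seqs[[ok$chrom[i]]], ok$start[i], ok$end[i],
                            run = homopolymer_run)
  }, logical(1L))

  keep <- ok$zygosity_call == "hom" & n_match == 0L & !par_match & !homopoly
  out <- ok[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Identify candidate balancer-maintained lethal mutations
#'
#' Applies the three criteria used to nominate a lethal mutation site in a
#' sequenced balancer strain: (1) heterozygous allelic ratio (the balancer
#' keeps the lethal chromosome heterozygous), (2) located within the
#' genetically mapped interval, and (3) unique to the strain analysed.
#'
#' @param dels deletion calls for one strain (chrom, start, end, and read
#'   counts or `zygosity_call`)
#' @param chrom chromosome of the mapped interval
#' @param interval_start,interval_end physical range (1-based inclusive)
#' @param cohort_dels deletion calls of the other strains, used for the
#'   uniqueness criterion (optional)
#' @param min_overlap reciprocal-overlap fraction defining "same event"
#' @param hom_threshold passed to [call_zygosity()]
#' @return data frame of candidate deletions
#' @export
identify_lethal_candidates <- function(dels, chrom, interval_start,
                                       interval_end, cohort_dels = NULL,
                                       min_overlap = 0.8,
                                       hom_threshold = 0.90) {
  if (interval_start > interval_end)
    stop_mmcsig("empty mapped interval")
  if (nrow(dels) == 0L) return(dels)
  if (is.null(dels$zygosity_call))
    dels$zygosity_call <- call_zygosity(dels$depth, dels$supporting_reads,
                                        hom_threshold = hom_threshold)
  in_interval <- dels$chrom == chrom &
    dels$start <= interval_end & dels$end >= interval_start
  unique_to_strain <- rep(TRUE, nrow(dels))
  if (!is.null(cohort_dels) && nrow(cohort_dels) > 0L) {
    for (i in seq_len(nrow(dels))) {
      other <- cohort_dels[cohort_dels$chrom == dels$chrom[i] &
                             cohort_dels$strain != dels$strain[i], ,
                           drop = FALSE]
      if (nrow(other) > 0L) {
        fr <- reciprocal_overlap(dels$start[i], dels$end[i],
                                 other$start, other$end)
        unique_to_strain[i] <- !any(fr >= min_overlap)
      }
    }
  }
  out <- dels[dels$zygosity_call == "het" & in_interval & unique_to_strain, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
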