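#' Deletion length under 1-based inclusive coordinates
#'
#' @param start,end 1-based inclusive endpoints (start <= end); vectorized
#' @return length in bp: `end - start + 1`
#' @examples
#' deletion_length(753745, 1072570)  # 318826
#' @export
deletion_length <- function(start, end) {
  if (any(start > end)) stop_mmcsig("'start' must be <= 'end'")
  as.integer(end - start + 1)
}

#' Check printed deletion sizes against their coordinates
#'
#' Recomputes each deletion's length from its coordinates and compares with
#' the reported size. Internally inconsistent rows are flagged, never
#' silently corrected: published tables occasionally disagree with their
#' own coordinates and the discrepancy is part of the record.
#'
#' @param dels data frame with `start`, `end` and a reported size column
#' @param size_col name of the reported size column
#' @return `dels` with added `computed_size` and logical `concordant`
#' @export
check_size_consistency <- function(dels, size_col = "printed_size_bp") {
  if (!size_col %in% names(dels))
    stop_mmcsig("column '", size_col, "' not found")
  dels$computed_size <- deletion_length(dels$start, dels$end)
  dels$concordant <- dels$computed_size == dels[[size_col]]
  dels
}

#' Extract a deleted segment and its flanking sequences
#'
#' Returns the deleted segment (1-based inclusive `[start, end]`) together
#' with the `flank` nucleotides immediately adjacent on each side (default
#' 15 nt, more than one helical turn of DNA). Flanks are truncated at the
#' chromosome ends rather than erroring; the interval itself must lie
#' within the chromosome.
#'
#' @param genome reference ([Biostrings::DNAStringSet] or named character)
#' @param chrom chromosome name
#' @param start,end 1-based inclusive deletion coordinates
#' @param flank flank width, bp (0 gives empty flanks)
#' @return list of class `deletion_context`: chrom, start, end,
#'   deleted_seq, left_flank, right_flank
#' @examples
#' g <- c(chrI = "AAACCCGGGTTT")
#' extract_flanks(g, "chrI", 4, 6, flank = 3)
#' @export
extract_flanks <- function(genome, chrom, start, end, flank = 15L) {
  s <- genome_chrom(genome, chrom)
  n <- nchar(s)
  if (start < 1L || end > n || start > end)
    stop_mmcsig("interval [", start, ", ", end, "] outside chromosome '",
                chrom, "' (length ", n, ")")
  if (flank < 0L) stop_mmcsig("'flank' must be >= 0")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 deleted_seq = substr(s, start, end),
                 left_flank = if (flank == 0L) "" else
                   substr(s, max(1L, start - flank), start - 1L),
                 right_flank = if (flank == 0L) "" else
                   substr(s, end + 1L, min(n, end + flank))),
            class = "deletion_context")
}

# Integer base codes 0..3 for A,C,G,T; NA for anything else (N etc.).
base_codes <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code[x]
}

#' Overlapping dinucleotide profile of a sequence collection
#'
#' Tallies all overlapping width-2 windows within each sequence (never
#' across sequence boundaries) into the 16 ordered dinucleotide categories
#' on the given strand, pooling counts across sequences before computing
#' proportions. Windows containing a non-ACGT character (e.g. N) are
#' skipped rather than failing, so real references are handled.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet]
#' @return list of class `dinuc_profile`: `counts` (16 named integers),
#'   `proportions` (sum 1; all `NA` when no window could be tallied) and
#'   `n_windows`
#' @examples
#' dinucleotide_profile("ACGCGT")$proportions[["CG"]]  # 2/5
#' @export
dinucleotide_profile <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet") ||
      methods::is(sequences, "DNAString"))
    sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  counts <- setNames(integer(16L), DINUCS)
  for (s in sequences) {
    n <- nchar(s)
    if (is.na(n) || n < 2L) next
    code <- base_codes(s)
    d <- 4L * code[-n] + code[-1L] + 1L   # NA wherever either base is non-ACGT
    tb <- tabulate(d, nbins = 16L)
    counts <- counts + tb
  }
  n_windows <- sum(counts)
  props <- if (n_windows > 0L) counts / n_windows
           else setNames(rep(NA_real_, 16L), DINUCS)
  structure(list(counts = counts, proportions = props,
                 n_windows = as.integer(n_windows)),
            class = "dinuc_profile")
}

as_dinuc_profile <- function(x) {
  if (inherits(x, "dinuc_profile")) return(x)
  dinucleotide_profile(x)
}

#' Fold enrichment of a dinucleotide in a target versus a background
#'
#' Ratio of the target proportion of `dinuc` to the background proportion —
#' e.g. the CpG content of deleted segments relative to the untreated
#' genome. Scale-free: duplicating every input sequence leaves it
#' unchanged.
#'
#' @param target,background `dinuc_profile` objects (or sequence
#'   collections, which are profiled first)
#' @param dinuc dinucleotide of interest (default `"CG"`, i.e. 5'-CpG-3')
#' @return fold enrichment (dimensionless)
#' @export
fold_enrichment <- function(target, background, dinuc = "CG") {
  if (!dinuc %in% DINUCS) stop_mmcsig("'dinuc' must be one of AA..TT")
  tp <- as_dinuc_profile(target)$proportions[[dinuc]]
  bp <- as_dinuc_profile(background)$proportions[[dinuc]]
  if (is.na(bp) || bp <= 0)
    stop_mmcsig("background proportion of ", dinuc, " is zero or undefined")
  if (is.na(tp))
    stop_mmcsig("target profile has no tallied windows")
  unname(tp / bp)
}

#' Dinucleotide heatmap matrix for deletions, flanks and background
#'
#' Builds the 4 x 16 matrix of dinucleotide proportions (rows: deleted
#' segments, left flanks, right flanks, genomic background) underlying the
#' sequence-context heatmap; each row sums to 1. Rendering is optional —
#' see [plot_dinuc_heatmap()].
#'
#' @param deleted,left_flanks,right_flanks,background sequence collections
#'   or `dinuc_profile` objects; `deleted` must be non-empty
#' @return numeric matrix with rownames
#'   (deleted, left_flank, right_flank, background) and the 16
#'   dinucleotides as colnames
#' @export
heatmap_matrix <- function(deleted, left_flanks, right_flanks, background) {
  if (!inherits(deleted, "dinuc_profile") && length(deleted) == 0L)
    stop_mmcsig("empty deletion set")
  rows <- list(deleted = deleted, left_flank = left_flanks,
               right_flank = right_flanks, background = background)
  mat <- t(vapply(rows, function(x) as_dinuc_profile(x)$proportions,
                  numeric(16L)))
  colnames(mat) <- DINUCS
  mat
}

#' Render the dinucleotide context heatmap
#'
#' Thin wrapper around \pkg{pheatmap} (if installed) for the matrix from
#' [heatmap_matrix()].
#'
#' @param mat matrix from [heatmap_matrix()]
#' @param ... passed to [pheatmap::pheatmap()]
#' @return the pheatmap object, invisibly
#' @export
plot_dinuc_heatmap <- function(mat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop_mmcsig("package 'pheatmap' is required for rendering")
  invisible(pheatmap::pheatmap(mat, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}

longest_common_prefix <- function(a, b, cap) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0L) return(0L)
  av <- utf8ToInt(toupper(substr(a, 1L, n)))
  bv <- utf8ToInt(toupper(substr(b, 1L, n)))
  mism <- which(av != bv)
  if (length(mism) == 0L) as.integer(n) else mism[1L] - 1L
}

reverse_chars <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Junction microhomology of a deletion
#'
#' Scores the two alt-NHEJ-consistent junction alignments: the 5' score is
#' the longest case-insensitive common prefix of the deleted segment and
#' the right flank, the 3' score the longest common suffix of the deleted
#' segment and the left flank; `mh` is the larger of the two. Both are
#' capped at `cap` (default 25, above the largest observed microhomology)
#' and at the available sequence lengths, so flanks extracted directly from
#' the reference should be at least `cap` long when possible.
#'
#' @param deleted deleted segment(s); or a `deletion_context` object
#' @param left_flank,right_flank flanking sequences (ignored when `deleted`
#'   is a `deletion_context`)
#' @param cap maximum reported length, bp
#' @return data frame: five_prime_len, three_prime_len, mh (bp)
#' @examples
#' microhomology("cgcg", "ATCCAATTTTCCGC", "CAGTCGCCAAAAAGG")  # mh 1
#' @export
microhomology <- function(deleted, left_flank = NULL, right_flank = NULL,
                          cap = 25L) {
  if (inherits(deleted, "deletion_context")) {
    left_flank <- deleted$left_flank
    right_flank <- deleted$right_flank
    deleted <- deleted$deleted_seq
  }
  if (any(nchar(deleted) == 0L)) stop_mmcsig("deleted sequence is empty")
  m <- max(length(deleted), length(left_flank), length(right_flank))
  deleted <- rep_len(deleted, m)
  left_flank <- rep_len(left_flank %||% "", m)
  right_flank <- rep_len(right_flank %||% "", m)
  five <- mapply(longest_common_prefix, deleted, right_flank,
                 MoreArgs = list(cap = cap), USE.NAMES = FALSE)
  three <- mapply(longest_common_prefix, reverse_chars(deleted),
                  reverse_chars(left_flank),
                  MoreArgs = list(cap = cap), USE.NAMES = FALSE)
  data.frame(five_prime_len = as.integer(five),
             three_prime_len = as.integer(three),
             mh = as.integer(pmax(five, three)))
}

#' Annotate a deletion set with sequence context and microhomology
#'
#' For each deletion: extracts the deleted segment and `flank`-nt flanks,
#' and scores junction microhomology using `mh_cap`-nt flanks taken
#' directly from the reference (so microhomology longer than the stored
#' flanks is still measured).
#'
#' @param genome reference genome
#' @param dels data frame with chrom, start, end
#' @param flank stored flank width, bp
#' @param mh_cap microhomology cap, bp
#' @return `dels` with added columns deleted_seq, left_flank, right_flank,
#'   five_prime_len, three_prime_len, mh
#' @export
deletion_contexts <- function(genome, dels, flank = 15L, mh_cap = 25L) {
  if (nrow(dels) == 0L) {
    add <- data.frame(deleted_seq = character(0), left_flank = character(0),
                      right_flank = character(0), five_prime_len = integer(0),
                      three_prime_len = integer(0), mh = integer(0))
    return(cbind(dels, add))
  }
  ctx <- lapply(seq_len(nrow(dels)), function(i)
    extract_flanks(genome, dels$chrom[i], dels$start[i], dels$end[i],
                   flank = flank))
  wide <- lapply(seq_len(nrow(dels)), function(i)
    extract_flanks(genome, dels$chrom[i], dels$start[i], dels$end[i],
                   flank = mh_cap))
  mh <- do.call(rbind, lapply(wide, microhomology, cap = mh_cap))
  dels$deleted_seq <- vapply(ctx, `[[`, "", "deleted_seq")
  dels$left_flank <- vapply(ctx, `[[`, "", "left_flank")
  dels$right_flank <- vapply(ctx, `[[`, "", "right_flank")
  cbind(dels, mh)
}

#' Parse a printed deletion-junction string
#'
#' Printed junction strings show flanking sequence in upper case and the
#' deleted segment in lower case; long deleted segments are abbreviated as
#' a lower-case prefix, an elided middle written `<n>`, and a lower-case
#' suffix. Emphasis markers (`*`) and whitespace are ignored.
#'
#' @param x character vector of junction strings
#' @return data frame: left_flank, deleted_prefix, gap_bp, deleted_suffix,
#'   right_flank, deleted (full segment, `NA` when elided), size_bp
#'   (total deleted length) and logical `full`
#' @examples
#' parse_junction("ATCCAATTTTCCGCcgcgCAGTCGCCAAAAAGG")
#' @export
parse_junction <- function(x) {
  x <- gsub("[*[:space:]]", "", x)
  m <- regmatches(x, regexec(
    "^([ACGTN]*)([acgtn]+)(?:<([0-9]+)>([acgtn]+))?([ACGTN]*)$", x))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad))
    stop_mmcsig("unparseable junction string: ", x[bad][1L])
  parts <- do.call(rbind, m)
  gap <- suppressWarnings(as.integer(parts[, 4L]))
  gap[parts[, 4L] == ""] <- NA_integer_
  full <- is.na(gap)
  deleted <- ifelse(full, parts[, 3L], NA_character_)
  size <- ifelse(full, nchar(parts[, 3L]),
                 nchar(parts[, 3L]) + gap + nchar(parts[, 5L]))
  data.frame(left_flank = parts[, 2L],
             deleted_prefix = parts[, 3L],
             gap_bp = gap,
             deleted_suffix = ifelse(full, NA_character_, parts[, 5L]),
             right_flank = parts[, 6L],
             deleted = deleted,
             size_bp = as.integer(size),
             full = full,
             stringsAsFactors = FALSE)
}
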