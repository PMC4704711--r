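# Standard-format I/O. Internal coordinates are 1-based inclusive
# everywhere; conversion happens only at the BED (0-based half-open) and
# VCF (left-anchored) boundaries.

#' Read a reference genome from FASTA
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path))
    stop_mmcsig("reference file not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Write a genome to FASTA
#' @param genome [Biostrings::DNAStringSet] or named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome_as_character(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", ...)
}

#' Write / read a simulation truth table
#'
#' TSV with one row per event (strain, chrom, start, end, type, plus
#' event-specific columns); coordinates 1-based inclusive, so truth
#' round-trips unchanged.
#'
#' @param truth truth list from [simulate_cohort()] (elements `snvs`,
#'   `shared_snvs`, `deletions`)
#' @param path file path
#' @return `path` / the truth list
#' @export
write_truth_tsv <- function(truth, path) {
  snv <- truth$snvs
  del <- truth$deletions
  shared <- truth$shared_snvs
  rows <- rbind(
    if (nrow(snv)) data.frame(strain = snv$strain, chrom = snv$chrom,
                              start = snv$pos, end = snv$pos, type = "snv",
                              ref = snv$ref, alt = snv$alt,
                              engineered_mh = NA_integer_,
                              zygosity = "hom"),
    if (nrow(shared)) data.frame(strain = "shared", chrom = shared$chrom,
                                 start = shared$pos, end = shared$pos,
                                 type = "snv", ref = shared$ref,
                                 alt = shared$alt,
                                 engineered_mh = NA_integer_,
                                 zygosity = "hom"),
    if (nrow(del)) data.frame(strain = del$strain, chrom = del$chrom,
                              start = del$start, end = del$end,
                              type = "deletion", ref = NA_character_,
                              alt = NA_character_,
                              engineered_mh = del$engineered_mh,
                              zygosity = del$zygosity))
  write_tsv(rows, path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  rows <- read_tsv(path)
  snv <- rows[rows$type == "snv" & rows$strain != "shared", , drop = FALSE]
  shared <- rows[rows$type == "snv" & rows$strain == "shared", , drop = FALSE]
  del <- rows[rows$type == "deletion", , drop = FALSE]
  list(
    snvs = data.frame(strain = snv$strain, chrom = snv$chrom, pos = snv$start,
                      ref = snv$ref, alt = snv$alt, stringsAsFactors = FALSE),
    shared_snvs = data.frame(chrom = shared$chrom, pos = shared$start,
                             ref = shared$ref, alt = shared$alt,
                             stringsAsFactors = FALSE),
    deletions = data.frame(strain = del$strain, chrom = del$chrom,
                           start = del$start, end = del$end,
                           size = del$end - del$start + 1L,
                           engineered_mh = del$engineered_mh,
                           zygosity = del$zygosity, stringsAsFactors = FALSE))
}

#' Convert 1-based inclusive intervals to a BED data frame and write it
#'
#' BED uses 0-based half-open coordinates: `start0 = start - 1`,
#' `end = end`.
#'
#' @param dels data frame with chrom, start, end (+ optional strain)
#' @param path output file
#' @return the BED data frame (invisibly, after writing)
#' @export
write_deletions_bed <- function(dels, path) {
  bed <- data.frame(chrom = dels$chrom,
                    start = dels$start - 1L,
                    end = dels$end,
                    name = if (!is.null(dels$strain)) dels$strain
                           else seq_len(nrow(dels)))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bed)
}

#' Read a BED file of deletions into 1-based inclusive coordinates
#' @param path BED file (first 3-4 columns used)
#' @return data frame: chrom, start, end, strain (from the name column)
#' @export
read_deletions_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1L]], start = bed[[2L]] + 1L, end = bed[[3L]],
             strain = if (ncol(bed) >= 4L) as.character(bed[[4L]])
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write SNV and deletion calls for one strain as minimal VCF
#'
#' CHROM POS ID REF ALT QUAL FILTER INFO records with read counts in INFO
#' (`DP` total depth, `VR` variant-supporting reads). Deletions use the
#' left-anchored VCF convention: POS is the base before the deletion, REF
#' is that base plus the deleted segment, ALT the anchor base alone. The
#' strain label is recorded in a `##strain=` header line.
#'
#' @param snvs SNV records (chrom, pos, ref, alt, depth, alt_reads); may be
#'   `NULL`
#' @param dels deletion records (chrom, start, end, depth,
#'   supporting_reads); may be `NULL`
#' @param genome reference genome (needed for deletion REF anchors)
#' @param path output file
#' @param strain strain label
#' @return `path`, invisibly
#' @export
write_variants_vcf <- function(snvs, dels, genome, path, strain) {
  seqs <- genome_as_character(genome)
  header <- c("##fileformat=VCFv4.2",
              paste0("##strain=", strain),
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
              "##INFO=<ID=VR,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
              paste0("##contig=<ID=", names(seqs), ",length=", nchar(seqs), ">"),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (!is.null(snvs) && nrow(snvs) > 0L) {
    body <- c(body, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;VR=%d",
                            snvs$chrom, snvs$pos, snvs$ref, snvs$alt,
                            snvs$depth, snvs$alt_reads))
  }
  if (!is.null(dels) && nrow(dels) > 0L) {
    if (any(dels$start < 2L))
      stop_mmcsig("deletion at position 1 cannot be left-anchored in VCF")
    anchor_pos <- dels$start - 1L
    ref_alleles <- vapply(seq_len(nrow(dels)), function(i)
      substr(seqs[[dels$chrom[i]]], anchor_pos[i], dels$end[i]), "")
    alt_alleles <- substr(ref_alleles, 1L, 1L)
    body <- c(body, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;VR=%d",
                            dels$chrom, anchor_pos, ref_alleles, alt_alleles,
                            dels$depth, dels$supporting_reads))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a variant table (minimal VCF or TSV dialect)
#'
#' Reads per-strain variant records with read-count evidence into the
#' package's 1-based inclusive representation. The VCF dialect is parsed
#' with \pkg{vcfR}; rows with single-base REF and ALT become SNV records,
#' rows with multi-base REF and single-base ALT become deletion records
#' with `start = POS + 1`, `end = POS + nchar(REF) - 1` (the VCF
#' left-anchored convention mapped back to inclusive coordinates). The TSV
#' dialect expects the column layout written by [write_tsv()]-based
#' writers: SNVs (strain, chrom, pos, ref, alt, depth, alt_reads) or
#' deletions (strain, chrom, start, end, depth, supporting_reads).
#'
#' @param path input file
#' @param dialect `"vcf-min"` or `"tsv"`
#' @param strain strain label override; for VCF the `##strain=` header is
#'   used when present, else the file name
#' @return list with data frames `snvs` and `deletions`
#' @export
parse_variant_table <- function(path, dialect = c("vcf-min", "tsv"),
                                strain = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mmcsig("variant table not found: ", path)
  if (dialect == "tsv") return(parse_variant_tsv(path, strain))

  lines <- readLines(path)
  n_records <- sum(!startsWith(lines, "#") & nzchar(lines))
  meta_strain <- sub("^##strain=", "", grep("^##strain=", lines, value = TRUE))
  strain <- strain %||% (if (length(meta_strain)) meta_strain[1L] else
                           sub("\\.vcf$", "", basename(path)))
  if (n_records == 0L) {
    warning("no variant records in ", path)
    return(list(snvs = empty_snv_records(strain),
                deletions = empty_del_records(strain)))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  dp <- as.integer(vcfR::extract.info(vcf, "DP"))
  vr <- as.integer(vcfR::extract.info(vcf, "VR"))
  pos <- as.integer(fix$POS)
  bad <- is.na(pos) | is.na(fix$REF) | is.na(fix$ALT)
  if (any(bad))
    stop_mmcsig("malformed VCF record at data line ", which(bad)[1L],
                " of ", path)
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  is_del <- nchar(fix$REF) > 1L & nchar(fix$ALT) == 1L
  snvs <- data.frame(strain = strain, chrom = fix$CHROM[is_snv],
                     pos = pos[is_snv], ref = fix$REF[is_snv],
                     alt = fix$ALT[is_snv], depth = dp[is_snv],
                     alt_reads = vr[is_snv], stringsAsFactors = FALSE)
  dels <- data.frame(strain = strain, chrom = fix$CHROM[is_del],
                     start = pos[is_del] + 1L,
                     end = pos[is_del] + nchar(fix$REF[is_del]) - 1L,
                     depth = dp[is_del], supporting_reads = vr[is_del],
                     stringsAsFactors = FALSE)
  list(snvs = snvs, deletions = dels)
}

empty_snv_records <- function(strain = character(0)) {
  data.frame(strain = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), depth = integer(0),
             alt_reads = integer(0), stringsAsFactors = FALSE)
}

empty_del_records <- function(strain = character(0)) {
  data.frame(strain = character(0), chrom = character(0), start = integer(0),
             end = integer(0), depth = integer(0),
             supporting_reads = integer(0), stringsAsFactors = FALSE)
}

parse_variant_tsv <- function(path, strain = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    warning("no variant records in ", path)
    return(list(snvs = empty_snv_records(), deletions = empty_del_records()))
  }
  tab <- tryCatch(read_tsv(path), error = function(e)
    stop_mmcsig("malformed variant TSV ", path, ": ", conditionMessage(e)))
  if (nrow(tab) == 0L) {
    warning("no variant records in ", path)
    return(list(snvs = empty_snv_records(), deletions = empty_del_records()))
  }
  if (!is.null(strain)) tab$strain <- strain
  if (all(c("pos", "ref", "alt") %in% names(tab))) {
    list(snvs = tab, deletions = empty_del_records())
  } else if (all(c("start", "end") %in% names(tab))) {
    list(snvs = empty_snv_records(), deletions = tab)
  } else {
    stop_mmcsig("unrecognised variant TSV layout in ", path)
  }
}

#' Write / read a coverage track as bedGraph-like TSV
#'
#' Columns chrom, start (0-based), end, mean_depth; converted to/from the
#' package's 1-based bins.
#'
#' @param track a `depth_track`
#' @param path file path
#' @return `path` / a `depth_track`
#' @export
write_depth_bedgraph <- function(track, path) {
  out <- data.frame(chrom = track$chrom, start = track$start - 1L,
                    end = track$end, mean_depth = track$mean_depth)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_bedgraph
#' @export
read_depth_bedgraph <- function(path) {
  bg <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "mean_depth"))
  width <- bg$end - bg$start
  bin_width <- max(width)
  track <- data.frame(chrom = bg$chrom,
                      bin = bg$start %/% bin_width + 1L,
                      start = bg$start + 1L, end = bg$end,
                      mean_depth = bg$mean_depth, stringsAsFactors = FALSE)
  attr(track, "bin_width") <- as.integer(bin_width)
  class(track) <- c("depth_track", "data.frame")
  track
}

#' Write an entire simulated cohort to disk
#'
#' Materialises a [simulate_cohort()] result in standard formats: the
#' genome as FASTA, truth as TSV and BED, each strain's variants as
#' minimal VCF plus the equivalent TSV pair, and the composite parental
#' table.
#'
#' @param cohort an `mmc_cohort`
#' @param outdir output directory (created if needed)
#' @return named list of written paths, invisibly
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list(genome = file.path(outdir, "genome.fa"),
            truth = file.path(outdir, "truth.tsv"),
            truth_bed = file.path(outdir, "truth_deletions.bed"),
            parental_snv = file.path(outdir, "parental.snv.tsv"),
            parental_del = file.path(outdir, "parental.del.tsv"))
  write_genome_fasta(cohort$genome, p$genome)
  write_truth_tsv(cohort$truth, p$truth)
  write_deletions_bed(cohort$truth$deletions, p$truth_bed)
  write_tsv(cohort$tables$parental_snv_table, p$parental_snv)
  write_tsv(cohort$tables$parental_del_table, p$parental_del)
  strains <- names(cohort$tables$strain_snv_tables)
  p$strain_vcf <- setNames(file.path(outdir, paste0(strains, ".vcf")), strains)
  p$strain_snv <- setNames(file.path(outdir, paste0(strains, ".snv.tsv")),
                           strains)
  p$strain_del <- setNames(file.path(outdir, paste0(strains, ".del.tsv")),
                           strains)
  for (st in strains) {
    write_variants_vcf(cohort$tables$strain_snv_tables[[st]],
                       cohort$tables$strain_del_tables[[st]],
                       cohort$genome, p$strain_vcf[[st]], st)
    write_tsv(cohort$tables$strain_snv_tables[[st]], p$strain_snv[[st]])
    write_tsv(cohort$tables$strain_del_tables[[st]], p$strain_del[[st]])
  }
  invisible(p)
}
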