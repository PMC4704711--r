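#' Configuration for the end-to-end analysis pipeline
#'
#' Collects input paths and every tunable threshold of the analysis
#' stages. File existence is checked when [run_pipeline()] runs, not at
#' construction.
#'
#' @param reference path to the reference FASTA
#' @param snv_tables named character vector of per-strain variant tables
#'   (names are strain labels); with `dialect = "vcf-min"` each file may
#'   carry both SNVs and deletions
#' @param del_tables named character vector of per-strain deletion tables
#'   (TSV dialect; `NULL` when the VCFs carry deletions)
#' @param dialect `"tsv"` or `"vcf-min"` (see [parse_variant_table()])
#' @param parental_snv,parental_del composite parental tables (optional)
#' @param depth_track bedGraph-like coverage track (optional)
#' @param brood_table TSV of brood counts with columns wt, dpy_unc, dpy,
#'   unc (optional; extra columns such as strain are carried through)
#' @param mapped_interval optional list(strain, chrom, start, end): the
#'   physically mapped region in which to nominate lethal candidates
#' @param min_depth,hom_threshold,het_band,min_overlap,homopolymer_run
#'   variant-filter thresholds (see the filter functions)
#' @param flank,mh_cap sequence-context parameters, bp
#' @param drop_ratio,min_run,search_bins breakpoint-detection parameters
#' @param outdir output directory
#' @param seed integer seed recorded in the report (the analysis itself is
#'   deterministic)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(reference, snv_tables, del_tables = NULL,
                            dialect = c("tsv", "vcf-min"),
                            parental_snv = NULL, parental_del = NULL,
                            depth_track = NULL, brood_table = NULL,
                            mapped_interval = NULL,
                            min_depth = 8L, hom_threshold = 0.90,
                            het_band = c(0.35, 0.65), min_overlap = 0.8,
                            homopolymer_run = 6L, flank = 15L, mh_cap = 25L,
                            drop_ratio = 0.7, min_run = 5L,
                            search_bins = NULL,
                            outdir = tempfile("mmcsig_run_"), seed = 1L) {
  structure(list(reference = reference, snv_tables = snv_tables,
                 del_tables = del_tables, dialect = match.arg(dialect),
                 parental_snv = parental_snv, parental_del = parental_del,
                 depth_track = depth_track, brood_table = brood_table,
                 mapped_interval = mapped_interval, min_depth = min_depth,
                 hom_threshold = hom_threshold, het_band = het_band,
                 min_overlap = min_overlap,
                 homopolymer_run = homopolymer_run, flank = flank,
                 mh_cap = mh_cap, drop_ratio = drop_ratio,
                 min_run = min_run, search_bins = search_bins,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage=", name, "\nerror=", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop_mmcsig("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading, strain-specific SNV filtering,
#' substitution-spectrum tabulation, strain-specific deletion filtering,
#' deletion sequence-context and microhomology analysis (profiles, CpG
#' fold-enrichment, heatmap matrix), map-distance estimation from brood
#' counts, coverage-based breakpoint detection, and lethal-candidate
#' nomination when a mapped interval is supplied. The run is deterministic
#' given the inputs; every number in the report is the direct output of
#' one documented operation. Tables are written as TSV and the report as
#' JSON into `config$outdir`; a stage failure aborts with a stage-labelled
#' error and leaves a `FAILED` marker beside any partial outputs.
#'
#' @param config a [pipeline_config()]
#' @return the report, an `mmc_report` list (invisibly also written to
#'   `outdir/report.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))

  inputs <- run_stage("load", outdir, {
    for (p in c(config$reference, config$snv_tables, config$del_tables,
                config$parental_snv, config$parental_del,
                config$depth_track, config$brood_table)) {
      if (!is.null(p) && !file.exists(p))
        stop_mmcsig("input file not found: ", p)
    }
    genome <- read_genome_fasta(config$reference)
    strains <- names(config$snv_tables) %||%
      sub("\\.[^.]*$", "", basename(config$snv_tables))
    parsed <- lapply(seq_along(config$snv_tables), function(i)
      parse_variant_table(config$snv_tables[[i]], dialect = config$dialect,
                          strain = strains[i]))
    snvs <- do.call(rbind, lapply(parsed, `[[`, "snvs"))
    dels <- do.call(rbind, lapply(parsed, `[[`, "deletions"))
    if (!is.null(config$del_tables)) {
      dparsed <- lapply(seq_along(config$del_tables), function(i)
        parse_variant_table(config$del_tables[[i]], dialect = "tsv",
                            strain = strains[i]))
      dels <- rbind(dels, do.call(rbind, lapply(dparsed, `[[`, "deletions")))
    }
    # an empty parental table is a legitimate "no pre-existing variants"
    # state, so the empty-file warning is silenced for these two inputs
    parental_snv <- if (!is.null(config$parental_snv))
      suppressWarnings(
        parse_variant_table(config$parental_snv, dialect = "tsv")$snvs)
    parental_del <- if (!is.null(config$parental_del))
      suppressWarnings(
        parse_variant_table(config$parental_del, dialect = "tsv")$deletions)
    list(genome = genome, strains = strains, snvs = snvs, dels = dels,
         parental_snv = parental_snv, parental_del = parental_del)
  })

  snv_filtered <- run_stage("filter_snv", outdir, {
    out <- filter_strain_specific_snvs(inputs$snvs, inputs$parental_snv,
                                       min_depth = config$min_depth,
                                       hom_threshold = config$hom_threshold)
    write_tsv(out, file.path(outdir, "filtered_snvs.tsv"))
    out
  })

  spectrum <- run_stage("spectrum", outdir, {
    sp <- classify_snv_spectrum(snv_filtered)
    write_tsv(data.frame(class = names(sp), count = as.integer(sp)),
              file.path(outdir, "spectrum.tsv"))
    sp
  })

  del_filtered <- run_stage("filter_del", outdir, {
    out <- filter_strain_specific_deletions(
      inputs$dels, inputs$parental_del, inputs$genome,
      min_overlap = config$min_overlap,
      homopolymer_run = config$homopolymer_run,
      hom_threshold = config$hom_threshold)
    write_tsv(out, file.path(outdir, "filtered_deletions.tsv"))
    if (nrow(out) > 0L)
      write_deletions_bed(out, file.path(outdir, "filtered_deletions.bed"))
    out
  })

  context <- run_stage("context", outdir, {
    if (nrow(del_filtered) == 0L) {
      NULL
    } else {
      ctx <- deletion_contexts(inputs$genome, del_filtered,
                               flank = config$flank, mh_cap = config$mh_cap)
      write_tsv(ctx, file.path(outdir, "deletion_contexts.tsv"))
      mat <- heatmap_matrix(ctx$deleted_seq, ctx$left_flank,
                            ctx$right_flank,
                            genome_as_character(inputs$genome))
      write_tsv(data.frame(region = rownames(mat), mat,
                           check.names = FALSE),
                file.path(outdir, "heatmap_matrix.tsv"))
      fold <- fold_enrichment(ctx$deleted_seq,
                              genome_as_character(inputs$genome))
      list(contexts = ctx, heatmap = mat, cg_fold = fold,
           mh_fraction = mean(ctx$mh > 0),
           mh_range = range(ctx$mh))
    }
  })

  mapping <- run_stage("mapping", outdir, {
    if (is.null(config$brood_table)) NULL else {
      broods <- read_tsv(config$brood_table)
      est <- estimate_map_distance(broods$wt, broods$dpy_unc)
      if (!is.null(broods$strain)) est <- cbind(strain = broods$strain, est)
      write_tsv(est, file.path(outdir, "map_estimates.tsv"))
      est
    }
  })

  breakpoints <- run_stage("breakpoints", outdir, {
    if (is.null(config$depth_track)) NULL else {
      track <- read_depth_bedgraph(config$depth_track)
      calls <- detect_coverage_drop(track, drop_ratio = config$drop_ratio,
                                    min_run = config$min_run,
                                    search_bins = config$search_bins)
      write_tsv(calls, file.path(outdir, "breakpoints.tsv"))
      calls
    }
  })

  candidates <- run_stage("candidates", outdir, {
    mi <- config$mapped_interval
    if (is.null(mi)) NULL else {
      strain_dels <- inputs$dels[inputs$dels$strain == mi$strain, ,
                                 drop = FALSE]
      cand <- identify_lethal_candidates(
        strain_dels, mi$chrom, mi$start, mi$end,
        cohort_dels = inputs$dels[inputs$dels$strain != mi$strain, ,
                                  drop = FALSE],
        min_overlap = config$min_overlap,
        hom_threshold = config$hom_threshold)
      write_tsv(cand, file.path(outdir, "lethal_candidates.tsv"))
      if (nrow(cand) > 0L)
        write_deletions_bed(cand, file.path(outdir, "lethal_candidates.bed"))
      cand
    }
  })

  report <- run_stage("report", outdir, {
    count_by <- function(df) {
      n <- vapply(inputs$strains, function(s) sum(df$strain == s), 0L)
      as.list(setNames(as.integer(n), inputs$strains))
    }
    rep <- list(
      per_strain = list(snvs = count_by(snv_filtered),
                        deletions = count_by(del_filtered)),
      totals = list(snvs = nrow(snv_filtered),
                    deletions = nrow(del_filtered)),
      spectrum = as.list(setNames(as.integer(spectrum), names(spectrum))),
      context = if (is.null(context)) NULL else
        list(cg_fold_enrichment = context$cg_fold,
             mh_fraction = context$mh_fraction,
             mh_min = context$mh_range[1L],
             mh_max = context$mh_range[2L]),
      map_estimates = mapping,
      breakpoints = breakpoints,
      lethal_candidates = candidates,
      provenance = list(package = "mmcsig",
                        version = as.character(packageVersion("mmcsig")),
                        seed = config$seed,
                        dialect = config$dialect,
                        thresholds = list(
                          min_depth = config$min_depth,
                          hom_threshold = config$hom_threshold,
                          min_overlap = config$min_overlap,
                          homopolymer_run = config$homopolymer_run,
                          flank = config$flank, mh_cap = config$mh_cap,
                          drop_ratio = config$drop_ratio,
                          min_run = config$min_run)))
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    rep
  })
  class(report) <- c("mmc_report", "list")
  invisible(report)
}

#' Reproduce the bundled published summary tables
#'
#' Self-test reporting on the packaged reference data: recomputes the
#' forward mutation frequencies from the screen tallies, the deletion
#' lengths from the mapped coordinates (flagging internally inconsistent
#' rows), and junction microhomology for every fully printed junction.
#'
#' @return list with data frames `screen`, `deletion_sizes`, `junction_mh`
#' @examples
#' ref <- mmc_reference_report()
#' max(ref$junction_mh$mh)
#' @export
mmc_reference_report <- function() {
  tally <- mmc_screen_tally()
  tally$computed_frequency_pct <-
    format_percent(forward_mutation_frequency(tally$n_lethal, tally$n_f1))

  sizes <- check_size_consistency(mmc_lethal_deletions())

  jx <- mmc_deletion_junctions()
  parsed <- parse_junction(jx$junction)
  full <- which(parsed$full)
  mh <- microhomology(parsed$deleted[full], parsed$left_flank[full],
                      parsed$right_flank[full])
  junction_mh <- cbind(jx[full, c("allele", "detection", "size_bp")], mh)
  rownames(junction_mh) <- NULL

  list(screen = tally, deletion_sizes = sizes, junction_mh = junction_mh)
}
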