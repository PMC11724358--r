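#' Run the full annotation pipeline
#'
#' Ingest raw calls, screen raw repeats, correct breakpoints, re-screen
#' corrected coordinates, annotate repair signatures, classify TMEJ/SSA,
#' and write the TSV/BED/CSV/JSON outputs (and summary plots). Every
#' per-variant step is a pure function of its inputs and the config, so
#' reruns and parallel runs are byte-identical.
#'
#' @param ref,query [genome_store()]s or FASTA paths
#' @param vcf raw-variant data.frame (as from [read_variant_vcf()]) or a
#'   VCF path
#' @param cfg a [run_config()]
#' @param out_prefix if non-NULL, output files `<prefix>.tsv/.bed/
#'   .class.csv/.summary.json/.meta.json` (and plots) are written
#' @param plots write summary plots (default TRUE when `out_prefix` given)
#' @return list with `annotations`, `classes`, `summary`, `density`,
#'   `tallies` (per-stage class counts) and `paths`
#' @export
run_pipeline <- function(ref, query, vcf, cfg = run_config(),
                         out_prefix = NULL, plots = !is.null(out_prefix)) {
  if (is.character(ref)) ref <- read_fasta(ref)
  if (is.character(query)) query <- read_fasta(query)
  if (is.character(vcf)) vcf <- read_variant_vcf(vcf, cfg$min_sv_size)

  n_raw <- nrow(vcf)
  message("ingested ", n_raw, " raw variant(s)")

  # stage 1: raw repeat screen (variant body + repeat_find_len flanks)
  raw_rep <- if (n_raw) vapply(seq_len(n_raw), function(i) {
    repeat_screen_raw(vcf[i, ], ref, cfg$repeat_find_len, cfg)$is_repetitive
  }, logical(1)) else logical(0)
  raw_kept <- vcf[!raw_rep, , drop = FALSE]
  message(sum(raw_rep), " raw variant(s) repetitive")

  # stage 2: breakpoint correction
  corrected <- if (nrow(raw_kept)) {
    correct_variants(raw_kept, ref, query, cfg)
  } else {
    data.frame(id = character(), ref_chrom = character(),
               ref_start = integer(), ref_end = integer(),
               query_chrom = character(), query_start = integer(),
               query_end = integer(), klass = character(),
               trim_rounds_used = integer(), reason = character(),
               stringsAsFactors = FALSE)
  }

  # stage 3: second-pass repeat screen on corrected coordinates
  res <- rescreen_corrected(corrected, ref, query, cfg)
  n_repeat <- sum(raw_rep) + nrow(res$repetitive)
  tallies <- tally_classes(res$kept, repeats = n_repeat)
  message("classes: ", paste(names(tallies), tallies, sep = "=",
                             collapse = " "))

  classes <- data.frame(
    variant_id = c(vcf$id[raw_rep], res$repetitive$id, res$kept$id),
    class = c(rep("REPEAT", sum(raw_rep) + nrow(res$repetitive)),
              res$kept$klass),
    stringsAsFactors = FALSE)

  # stage 4: signature annotation
  keep <- res$kept[res$kept$klass != "EXCEPTION", , drop = FALSE]
  annots <- annotate_variants(keep, ref, query, cfg)
  td <- remove_tandem_duplications(annots, cfg$tandem_dup_frac)

  # stage 5: mechanism classification
  cls <- classify_mechanisms(td$kept, ref, cfg)
  annotations <- rbind(cls$annotations, td$tandem_dups)
  if (nrow(annotations)) {
    annotations <- annotations[order(annotations$ref_chrom,
                                     annotations$ref_start), , drop = FALSE]
    rownames(annotations) <- NULL
  }

  paths <- NULL
  if (!is.null(out_prefix)) {
    paths <- write_outputs(annotations, classes, out_prefix)
    summary_json <- paste0(out_prefix, ".summary.json")
    s <- cls$summary
    jsonlite::write_json(list(
      histogram = as.list(s$histogram), baseline = s$baseline,
      lambda_tmej = s$lambda_tmej, lambda_ssa = s$lambda_ssa,
      weight_tmej = s$weight_tmej, weight_ssa = s$weight_ssa,
      overlap_tmej_over_baseline = s$overlap_tmej_over_baseline,
      overlap_ssa_under_baseline = s$overlap_ssa_under_baseline,
      tallies = as.list(tallies)),
      summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    meta_json <- paste0(out_prefix, ".meta.json")
    jsonlite::write_json(
      c(cfg[!vapply(cfg, is.function, logical(1))],
        list(package_version = as.character(utils::packageVersion("dsbsig")))),
      meta_json, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, summary = summary_json, meta = meta_json)
    if (plots) {
      paths <- c(paths, plot_run_summary(annotations, tallies, cls$summary,
                                         cls$density, out_prefix))
    }
  }

  list(annotations = annotations, classes = classes, summary = cls$summary,
       density = cls$density, tallies = tallies, paths = paths)
}

#' Generate a synthetic fixture bundle on disk
#'
#' Thin wrapper over [simulate_genomes()] that always writes the FASTA/VCF/
#' truth files plus a metadata JSON recording the seed and event counts.
#'
#' @param out_dir output directory
#' @param ... passed to [simulate_genomes()]
#' @return the [simulate_genomes()] result (with `paths`)
#' @export
simulate_bundle <- function(out_dir, ...) {
  sim <- simulate_genomes(..., out_dir = out_dir)
  args <- list(...)
  meta <- file.path(out_dir, "meta.json")
  jsonlite::write_json(
    list(seed = args$seed %||% 1L,
         events = as.list(args$events %||%
                            eval(formals(simulate_genomes)$events))),
    meta, auto_unbox = TRUE, force = TRUE, pretty = TRUE)
  sim$paths <- c(sim$paths, meta = meta)
  sim
}
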