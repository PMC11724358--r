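# Breakpoint correction: re-locate each raw call's reference flanks in the
# query assembly, trim overlapping placements (up to three rounds), and settle
# the final class from how the flank inner ends relate in the two genomes:
# separated in reference + contiguous in query -> deletion; contiguous in
# reference + separated in query -> insertion; separated in both -> complex
# substitution candidate, verified for hidden indels.

#' Default correction configuration
#'
#' @param sv_find_len flank length used to locate variants (bp, default 2000)
#' @param repeat_find_len flank length scanned for repeats (bp, default 50)
#' @param min_sv_size minimum variant size retained (bp, default 10)
#' @param max_trim_rounds maximum overlap-trim rounds (default 3)
#' @param min_flank minimum usable flank after chromosome-end truncation
#' @param min_identity,min_coverage flank-hit acceptance thresholds
#' @param hint_span search window half-width around the expected placement
#' @param hom_window junction window scanned for micro/homology (bp)
#' @param mismatch_free_len below this length micro/homology must be exact
#' @param min_signal_len minimum micro/homology called a signature (bp)
#' @param template_window distance scanned for a templated-insertion source
#' @param tandem_dup_frac homology/size fraction above which an indel is a
#'   tandem duplication (strict inequality, default 0.9)
#' @param baseline `"auto"` or a fixed integer micro/homology split (bp)
#' @param lambda_tmej_box,lambda_ssa_box Poisson rate boxes for the two
#'   mechanism components
#' @param span local-regression span used to find the baseline
#' @param seed top-level random seed recorded in run metadata
#' @param workers number of worker processes for per-variant steps
#' @return a named list of class `dsbsig_config`
#' @export
run_config <- function(sv_find_len = 2000L, repeat_find_len = 50L,
                       min_sv_size = 10L, max_trim_rounds = 3L,
                       min_flank = 200L, min_identity = 0.9,
                       min_coverage = 0.8, hint_span = 1000000L,
                       hom_window = 200L, mismatch_free_len = 10L,
                       min_signal_len = 2L, template_window = 2000L,
                       tandem_dup_frac = 0.9, baseline = "auto",
                       lambda_tmej_box = c(5, 20),
                       lambda_ssa_box = c(37, 50),
                       span = 0.3, seed = 1L, workers = 1L) {
  structure(as.list(environment()), class = "dsbsig_config")
}

.exception <- function(id, chrom, reason, rounds = 0L) {
  list(id = id, ref_chrom = chrom,
       ref_start = NA_integer_, ref_end = NA_integer_,
       query_chrom = NA_character_,
       query_start = NA_integer_, query_end = NA_integer_,
       klass = "EXCEPTION", trim_rounds_used = as.integer(rounds),
       reason = reason)
}

#' Correct one raw variant call
#'
#' Runs the flank-placement state machine for a single raw record and returns
#' the corrected variant with exact reference and query intervals, or an
#' EXCEPTION with a reason code. Flanks still overlapping in the query after
#' `max_trim_rounds` trim rounds (tandem-array context) give an EXCEPTION.
#'
#' @param raw one-row data.frame or list with `id`, `chrom`, `pos` (0-based
#'   first affected base), `ref_allele`, `alt_allele`, `caller_type`
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return list with `id`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `query_chrom`, `query_start`, `query_end`, `klass` (INS/DEL/SUB/
#'   EXCEPTION), `trim_rounds_used`, `reason`
#' @export
correct_variant <- function(raw, ref, query, cfg = run_config()) {
  id <- raw$id; chrom <- raw$chrom
  var_start <- as.integer(raw$pos)
  var_end <- var_start + max(0L, nchar(raw$ref_allele) - 1L)
  if (!chrom %in% names(query$sequences)) {
    return(.exception(id, chrom, "chromosome_missing_in_query"))
  }
  win <- c(var_start - cfg$hint_span, var_end + cfg$hint_span)

  t_l <- 0L; t_r <- 0L; rounds <- 0L
  repeat {
    fl <- extract_flanks(ref, chrom, max(0L, var_start - t_l),
                         min(ref$lengths[[chrom]], var_end + t_r),
                         flank_len = cfg$sv_find_len,
                         min_flank = cfg$min_flank)
    if (fl$too_short) {
      return(.exception(id, chrom, "flank_too_short", rounds))
    }
    lh <- locate_flank(query, fl$left, chrom, win,
                       min_identity = cfg$min_identity,
                       min_coverage = cfg$min_coverage, inner = "3p")
    rh <- locate_flank(query, fl$right, chrom, win,
                       min_identity = cfg$min_identity,
                       min_coverage = cfg$min_coverage, inner = "5p")
    pf <- pair_flanks(lh, rh)
    if (pf$relation == "DISCORDANT") {
      return(.exception(id, chrom, "discordant_flanks", rounds))
    }
    if (pf$relation != "OVERLAPPING") break
    if (rounds >= cfg$max_trim_rounds) {
      return(.exception(id, chrom, "still_overlapping", rounds))
    }
    rounds <- rounds + 1L
    t_l <- t_l + (-pf$separation) + 1L
    t_r <- t_r + (-pf$separation) + 1L
  }

  # inner ends, pulled back by any unaligned flank overhang
  left_ref_end0 <- var_start - t_l
  right_ref_start0 <- var_end + t_r
  left_inner <- left_ref_end0 - (nchar(fl$left) - lh$pattern_end)
  right_inner <- right_ref_start0 + (rh$pattern_start - 1L)
  q_left <- lh$query_end
  q_right <- rh$query_start
  r_sep <- right_inner - left_inner
  q_sep <- q_right - q_left
  if (r_sep < 0L || q_sep < 0L) {
    return(.exception(id, chrom, "degenerate_placement", rounds))
  }

  cv <- list(id = id, ref_chrom = chrom,
             ref_start = as.integer(left_inner),
             ref_end = as.integer(right_inner),
             query_chrom = lh$query_chrom,
             query_start = as.integer(q_left),
             query_end = as.integer(q_right),
             klass = NA_character_,
             trim_rounds_used = rounds, reason = NA_character_)
  if (r_sep == 0L && q_sep == 0L) {
    return(.exception(id, chrom, "no_net_change", rounds))
  }
  if (r_sep > 0L && q_sep == 0L) {
    if (r_sep < cfg$min_sv_size) {
      return(.exception(id, chrom, "below_min_size", rounds))
    }
    cv$klass <- "DEL"
    return(cv)
  }
  if (r_sep == 0L && q_sep > 0L) {
    if (q_sep < cfg$min_sv_size) {
      return(.exception(id, chrom, "below_min_size", rounds))
    }
    cv$klass <- "INS"
    return(cv)
  }
  cv$klass <- "SUB"
  verify_substitution(cv, ref, query, cfg)
}

#' Verify a complex-substitution candidate
#'
#' A candidate whose substituted sequences are nested (one is a
#' prefix+suffix-preserving sub-sequence of the other, e.g. `ATGCT...GC`
#' versus `AT`) is really a plain indel with a shifted breakpoint; it is
#' reclassified with adjusted intervals, validated by an exact
#' reference-to-query round trip. Identical substituted sequences are a
#' caller artifact (EXCEPTION). Everything else is a confirmed SUB.
#'
#' @param cand corrected variant with `klass == "SUB"`
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return the (possibly reclassified) corrected variant
#' @export
verify_substitution <- function(cand, ref, query, cfg = run_config()) {
  sr <- genome_seq(ref, cand$ref_chrom, cand$ref_start, cand$ref_end)
  sq <- genome_seq(query, cand$query_chrom, cand$query_start, cand$query_end)
  if (identical(sr, sq)) {
    e <- .exception(cand$id, cand$ref_chrom, "caller_artifact",
                    cand$trim_rounds_used)
    return(e)
  }
  nr <- nchar(sr); nq <- nchar(sq)
  nshort <- min(nr, nq)
  p <- lcp_len(sr, sq)
  s <- lcs_len(sr, sq)
  if (p + s >= nshort) {
    klass <- if (nr > nq) "DEL" else "INS"
    if (abs(nr - nq) >= cfg$min_sv_size) {
      # prefer the prefix side, then fall back across the valid splits
      for (p0 in seq.int(min(p, nshort), max(0L, nshort - s))) {
        s0 <- nshort - p0
        cv <- cand
        cv$ref_start <- cand$ref_start + p0
        cv$ref_end <- cand$ref_end - s0
        cv$query_start <- cand$query_start + p0
        cv$query_end <- cand$query_end - s0
        cv$klass <- klass
        if (edit_roundtrips(ref, query, cv)) return(cv)
      }
    }
  }
  cand
}

#' Check that a corrected edit reproduces the query locally
#'
#' Applies the corrected edit (delete the reference interval, insert the
#' query interval content) and tests exact string equality against the query
#' over a window around the variant.
#'
#' @param ref,query [genome_store()]s
#' @param cv a corrected variant (non-EXCEPTION)
#' @param w flanking window checked on each side (bp)
#' @return logical scalar
#' @export
edit_roundtrips <- function(ref, query, cv, w = 50L) {
  if (cv$klass == "EXCEPTION") return(NA)
  lw <- min(w, cv$ref_start, cv$query_start)
  rw <- min(w, ref$lengths[[cv$ref_chrom]] - cv$ref_end,
            query$lengths[[cv$query_chrom]] - cv$query_end)
  left_ok <- identical(
    genome_seq(ref, cv$ref_chrom, cv$ref_start - lw, cv$ref_start),
    genome_seq(query, cv$query_chrom, cv$query_start - lw, cv$query_start))
  right_ok <- identical(
    genome_seq(ref, cv$ref_chrom, cv$ref_end, cv$ref_end + rw),
    genome_seq(query, cv$query_chrom, cv$query_end, cv$query_end + rw))
  left_ok && right_ok
}

#' Correct a set of raw variants
#'
#' Per-variant processing is a pure function of inputs and config, so the
#' result is independent of ordering and of the number of workers.
#'
#' @param raw data.frame from [read_variant_vcf()]
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return data.frame of corrected variants, one row per input record
#' @export
correct_variants <- function(raw, ref, query, cfg = run_config()) {
  rows <- split(raw, seq_len(nrow(raw)))
  fun <- function(r) as.data.frame(correct_variant(r, ref, query, cfg),
                                   stringsAsFactors = FALSE)
  out <- if (cfg$workers > 1L) {
    parallel::mclapply(rows, fun, mc.cores = cfg$workers)
  } else {
    lapply(rows, fun)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally correction classes
#'
#' @param variants data.frame of corrected variants
#' @param repeats number of variants removed as repetitive
#' @return named integer vector over INS, DEL, SUB, REPEAT, EXCEPTION
#' @export
tally_classes <- function(variants, repeats = 0L) {
  lv <- c("INS", "DEL", "SUB", "EXCEPTION")
  n <- if (nrow(variants)) table(factor(variants$klass, levels = lv))
       else stats::setNames(rep(0L, 4L), lv)
  out <- c(as.integer(n[lv]), as.integer(repeats))
  stats::setNames(out, c(lv, "REPEAT"))[c("INS", "DEL", "SUB", "REPEAT",
                                          "EXCEPTION")]
}
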