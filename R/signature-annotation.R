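# Junctional micro/homology detection. Homologies below mismatch_free_len
# must be exact; longer ones may extend through occasional mismatches, but
# the running identity of the whole match AND of the extension beyond the
# exact core must both stay >= 90%, and a match ends on a matching base.
# Windows containing N never match (N is a permanent mismatch).

# longest match between the prefixes of a and b under the rules above
.junction_match <- function(a, b, mismatch_free_len = 10L,
                            min_extend_identity = 0.9) {
  e <- lcp_len(a, b)
  if (e < mismatch_free_len) return(e)
  n <- min(nchar(a), nchar(b))
  if (e >= n) return(e)
  ra <- seq_bytes(substr(a, 1L, n))
  rb <- seq_bytes(substr(b, 1L, n))
  m <- ra == rb & ra != RAW_N
  cum <- cumsum(m)
  idx <- seq_len(n)
  total_ok <- cum / idx >= min_extend_identity
  ext_ok <- c(rep(TRUE, e), (cum[(e + 1L):n] - cum[e]) /
                ((e + 1L):n - e) >= min_extend_identity)
  cand <- which(m & total_ok & ext_ok)
  if (length(cand) == 0L) return(e)
  max(e, max(cand))
}

#' Micro/homology at an indel junction
#'
#' Let V be the inserted/deleted sequence, L the sequence immediately 5' and
#' R the sequence immediately 3' of the variant, all taken from the genome
#' that carries V (reference for deletions, query for insertions). The
#' micro/homology is the longer of (prefix of V vs prefix of R) and
#' (suffix of V vs suffix of L); ties go to the prefix side. Matches shorter
#' than `cfg$mismatch_free_len` are exact; longer matches tolerate mismatches
#' at >= 90% running identity.
#'
#' @param variant corrected variant with `klass` INS or DEL
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return list with `hom_len`, `hom_seq` (matched string on the V side) and
#'   `side` ("prefix"/"suffix"/`NA` when `hom_len` is 0)
#' @export
junction_microhomology <- function(variant, ref, query, cfg = run_config()) {
  stopifnot(variant$klass %in% c("INS", "DEL"))
  w <- cfg$hom_window
  if (variant$klass == "DEL") {
    gs <- ref; chrom <- variant$ref_chrom
    vs <- variant$ref_start; ve <- variant$ref_end
  } else {
    gs <- query; chrom <- variant$query_chrom
    vs <- variant$query_start; ve <- variant$query_end
  }
  v <- genome_seq(gs, chrom, vs, ve)
  lseq <- genome_seq(gs, chrom, vs - w, vs)
  rseq <- genome_seq(gs, chrom, ve, ve + w)
  pre <- .junction_match(v, rseq, cfg$mismatch_free_len)
  suf <- .junction_match(rev_string(v), rev_string(lseq),
                         cfg$mismatch_free_len)
  if (pre >= suf) {
    list(hom_len = pre, hom_seq = substr(v, 1L, pre),
         side = if (pre > 0L) "prefix" else NA_character_)
  } else {
    list(hom_len = suf, hom_seq = substr(v, nchar(v) - suf + 1L, nchar(v)),
         side = "suffix")
  }
}

#' Classify an indel mechanism from its micro/homology length
#'
#' Lengths below `min_signal_len` carry no signature; lengths up to and
#' including the baseline are TMEJ; longer homologies are SSA.
#'
#' @param hom_len micro/homology length (bp, >= 0)
#' @param baseline TMEJ/SSA separation length (bp, >= 1)
#' @param min_signal_len minimum length called a signature (default 2)
#' @return one of "NO_SIGNATURE", "TMEJ", "SSA"
#' @export
classify_indel <- function(hom_len, baseline, min_signal_len = 2L) {
  stopifnot(baseline >= 1L, all(hom_len >= 0L))
  ifelse(hom_len < min_signal_len, "NO_SIGNATURE",
         ifelse(hom_len <= baseline, "TMEJ", "SSA"))
}

#' Remove tandem duplications
#'
#' An indel whose homology length strictly exceeds
#' `tandem_dup_frac` (90%) of its size is an insertion duplicating the
#' adjacent locus, not an end-joining scar; it is labelled TANDEM_DUP and
#' excluded from mechanism statistics.
#'
#' @param annots annotation data.frame (needs `hom_len` and interval columns)
#' @param tandem_dup_frac strict threshold fraction (default 0.9)
#' @return list with data.frames `kept` and `tandem_dups`
#' @export
remove_tandem_duplications <- function(annots, tandem_dup_frac = 0.9) {
  if (nrow(annots) == 0L) {
    return(list(kept = annots, tandem_dups = annots[0, , drop = FALSE]))
  }
  len <- pmax(annots$ref_end - annots$ref_start,
              annots$query_end - annots$query_start)
  dup <- annots$hom_len > tandem_dup_frac * len
  flagged <- annots[dup, , drop = FALSE]
  if (nrow(flagged)) flagged$mechanism <- "TANDEM_DUP"
  list(kept = annots[!dup, , drop = FALSE], tandem_dups = flagged)
}

#' Detect a templated-insertion signature at a complex substitution
#'
#' A complex substitution is a TMEJ templated insertion when (a) its query
#' substituted sequence aligns at >= 90% identity over >= 90% of its length
#' somewhere within `cfg$template_window` of the reference locus, and (b)
#' micro/homology of at least 1 bp is present at both junctions (prefix and
#' suffix of the substituted sequences).
#'
#' @param variant corrected variant with `klass == "SUB"`
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return list with `mechanism` ("TEMPLATED_INS"/"NO_SIGNATURE"),
#'   `hom_len`, `hom_seq`, `second_hom_len`, `template_start`,
#'   `template_end` (reference interval of the template, or `NA`)
#' @export
detect_templated_insertion <- function(variant, ref, query,
                                       cfg = run_config()) {
  stopifnot(variant$klass == "SUB")
  sr <- genome_seq(ref, variant$ref_chrom, variant$ref_start,
                   variant$ref_end)
  sq <- genome_seq(query, variant$query_chrom, variant$query_start,
                   variant$query_end)
  none <- list(mechanism = "NO_SIGNATURE", hom_len = 0L, hom_seq = "",
               second_hom_len = 0L, template_start = NA_integer_,
               template_end = NA_integer_)
  mh1 <- .junction_match(sq, sr, cfg$mismatch_free_len)
  mh2 <- .junction_match(rev_string(sq), rev_string(sr),
                         cfg$mismatch_free_len)
  if (mh1 < 1L || mh2 < 1L) return(none)

  tw <- cfg$template_window
  w0 <- max(0L, variant$ref_start - tw)
  w1 <- min(ref$lengths[[variant$ref_chrom]], variant$ref_end + tw)
  win <- genome_seq(ref, variant$ref_chrom, w0, w1)
  if (nchar(win) < nchar(sq)) return(none)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sq), Biostrings::DNAString(win), type = "local",
    substitutionMatrix = .dsbsig_submat, gapOpening = 4, gapExtension = 1)
  alen <- Biostrings::nchar(aln)
  if (alen == 0L) return(none)
  ident <- Biostrings::nmatch(aln) / alen
  cov <- (BiocGenerics::end(Biostrings::pattern(aln)) -
            BiocGenerics::start(Biostrings::pattern(aln)) + 1L) / nchar(sq)
  if (ident < 0.9 || cov < 0.9) return(none)
  list(mechanism = "TEMPLATED_INS",
       hom_len = mh1, hom_seq = substr(sq, 1L, mh1),
       second_hom_len = mh2,
       template_start = w0 + BiocGenerics::start(Biostrings::subject(aln)) - 1L,
       template_end = w0 + BiocGenerics::end(Biostrings::subject(aln)))
}

#' Annotate corrected, repeat-filtered variants with repair signatures
#'
#' Indels get their junctional micro/homology; complex substitutions are
#' tested for the templated-insertion signature; tandem duplications are
#' split off. Indels with a signature are left as NOT_DETERMINED here and
#' receive their TMEJ/SSA call in [classify_mechanisms()] once the baseline
#' is known.
#'
#' @param variants data.frame of kept corrected variants (INS/DEL/SUB rows)
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return annotation data.frame (one row per input variant) with columns
#'   `mechanism`, `hom_len`, `hom_seq`, `second_hom_len`, `template_start`,
#'   `template_end` added
#' @export
annotate_variants <- function(variants, ref, query, cfg = run_config()) {
  base_cols <- function(df) {
    df$mechanism <- character(nrow(df)); df$hom_len <- integer(nrow(df))
    df$hom_seq <- character(nrow(df))
    df$second_hom_len <- integer(nrow(df))
    df$template_start <- rep(NA_integer_, nrow(df))
    df$template_end <- rep(NA_integer_, nrow(df))
    df
  }
  out <- base_cols(variants)
  if (nrow(out) == 0L) return(out)
  one <- function(i) {
    v <- variants[i, ]
    if (v$klass %in% c("INS", "DEL")) {
      h <- junction_microhomology(v, ref, query, cfg)
      mech <- if (h$hom_len < cfg$min_signal_len) "NO_SIGNATURE"
              else "NOT_DETERMINED"
      list(mechanism = mech, hom_len = h$hom_len, hom_seq = h$hom_seq,
           second_hom_len = 0L, template_start = NA_integer_,
           template_end = NA_integer_)
    } else {
      detect_templated_insertion(v, ref, query, cfg)
    }
  }
  idx <- seq_len(nrow(out))
  res <- if (cfg$workers > 1L) {
    parallel::mclapply(idx, one, mc.cores = cfg$workers)
  } else {
    lapply(idx, one)
  }
  out$mechanism <- vapply(res, `[[`, character(1), "mechanism")
  out$hom_len <- vapply(res, function(r) as.integer(r$hom_len), integer(1))
  out$hom_seq <- vapply(res, `[[`, character(1), "hom_seq")
  out$second_hom_len <- vapply(res, function(r) as.integer(r$second_hom_len),
                               integer(1))
  out$template_start <- vapply(res, function(r) as.integer(r$template_start),
                               integer(1))
  out$template_end <- vapply(res, function(r) as.integer(r$template_end),
                             integer(1))
  out
}
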