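# Internal tandem-repeat detector with the intent of the classic
# tandem-repeat-finder parameterisation 2 5 7 80 10 50 500: match +2,
# mismatch -5 (indels are not modelled), array identity >= 80%, alignment
# score >= 50, period <= 500, at least two copies. Periods are scanned
# directly: for period p the boolean vector m[i] = (s[i] == s[i+p]) is
# computed in one vectorised pass, a cheap rolling-density filter rejects
# periods that cannot host a qualifying array, and surviving periods are
# searched over match-run-bounded windows (optimal arrays always start and
# end on matches).

.canonical_arrays <- function(arrays) {
  if (nrow(arrays) == 0L) return(arrays)
  arrays <- arrays[order(arrays$period, -arrays$score), , drop = FALSE]
  keep <- logical(nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    a <- arrays[i, ]
    covered <- FALSE
    if (any(keep)) {
      k <- arrays[keep, , drop = FALSE]
      ov <- pmax(0L, pmin(k$end, a$end) - pmax(k$start, a$start))
      covered <- any(ov >= 0.9 * (a$end - a$start))
    }
    keep[i] <- !covered
  }
  out <- arrays[keep, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect tandem repeat arrays in a sequence
#'
#' @param seq nucleotide string (length >= 10)
#' @param min_score minimum array alignment score under match +2 /
#'   mismatch -5 (default 50)
#' @param max_period maximum repeat period in bp (default 500)
#' @param min_identity minimum within-array identity (default 0.8)
#' @param merge_cap maximum number of match runs merged into one array
#'   (approximation bound for long degenerate arrays; default 64)
#' @return data.frame of arrays sorted by start: `start`, `end` (0-based
#'   half-open, spanning all copies), `period`, `copy_number`,
#'   `percent_identity`, `score`
#' @export
find_tandem_repeats <- function(seq, min_score = 50L, max_period = 500L,
                                min_identity = 0.8, merge_cap = 64L) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = double(), percent_identity = double(),
                      score = double())
  if (n < 10L) stop("sequence shorter than 10 bp")
  x <- seq_bytes(seq)
  notN <- x != RAW_N
  m_min <- as.integer(ceiling(min_score / 2))          # minimum matches
  res <- list()
  for (p in seq_len(min(max_period, n %/% 2L))) {
    L <- n - p
    if (L < m_min) break
    m <- (x[seq_len(L)] == x[(p + 1L):n]) & notN[seq_len(L)] &
      notN[(p + 1L):n]
    # sound necessary condition: some window must reach min_score under
    # +2/-5; the best window sum is max_j (P[j] - min_{i<j} P[i])
    pref <- cumsum(ifelse(m, 2L, -5L))
    if (max(pref - cummin(c(0L, pref[-L]))) < min_score) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mi <- which(r$values)               # match runs
    k <- length(mi)
    if (k == 0L) next
    ms <- starts[mi]; me <- ends[mi]
    cumM <- cumsum(me - ms + 1L)
    cap <- min(merge_cap, k)
    ii <- rep.int(seq_len(k), cap)
    jj <- ii + rep(seq_len(cap) - 1L, each = k)
    sel <- jj <= k
    ii <- ii[sel]; jj <- jj[sel]
    M <- cumM[jj] - c(0L, cumM)[ii]
    W <- me[jj] - ms[ii] + 1L
    X <- W - M
    sc <- 2L * M - 5L * X
    ok <- (M >= min_identity * W) & (sc >= min_score) & (W >= p)
    if (!any(ok)) next
    ii <- ii[ok]; jj <- jj[ok]; M <- M[ok]; W <- W[ok]; sc <- sc[ok]
    # greedy non-overlapping selection per period, best score first
    o <- order(-sc, ms[ii], -W)
    taken_s <- integer(0); taken_e <- integer(0)
    for (q in o) {
      s0 <- ms[ii[q]]; e0 <- me[jj[q]] + p      # 1-based closed array span
      if (length(taken_s) &&
          any(pmin(taken_e, e0) > pmax(taken_s, s0))) next
      taken_s <- c(taken_s, s0); taken_e <- c(taken_e, e0)
      res[[length(res) + 1L]] <- data.frame(
        start = s0 - 1L, end = e0, period = p,
        copy_number = (W[q] + p) / p,
        percent_identity = 100 * M[q] / W[q],
        score = sc[q])
    }
  }
  if (length(res) == 0L) return(empty)
  .canonical_arrays(do.call(rbind, res))
}

.screen_seq <- function(s, cfg) {
  none <- list(is_repetitive = FALSE, kind = "NONE", period = NA_integer_,
               copy_number = NA_real_, matched_fraction = 0)
  if (nchar(s) < 10L) return(none)
  arr <- find_tandem_repeats(s)
  if (nrow(arr)) {
    cov <- sum(arr$end - arr$start)  # canonical arrays rarely overlap much
    top <- arr[which.max(arr$score), ]
    return(list(is_repetitive = TRUE, kind = "TANDEM",
                period = top$period, copy_number = top$copy_number,
                matched_fraction = min(1, cov / nchar(s))))
  }
  hook <- cfg$interspersed_hook
  if (!is.null(hook) && isTRUE(hook(s))) {
    return(list(is_repetitive = TRUE, kind = "INTERSPERSED",
                period = NA_integer_, copy_number = NA_real_,
                matched_fraction = NA_real_))
  }
  none
}

#' Screen a variant (plus flanks) for repetitive sequence
#'
#' Scans the variant sequence and `repeat_find_len` bp of flank on each side,
#' taken from the genome that carries the variant sequence (reference for
#' deletions, query for insertions, both for complex substitutions).
#' `repeat_find_len = 0` disables flank scanning; the variant body is still
#' scanned.
#'
#' @param variant corrected variant (list or one-row data.frame) with a
#'   non-EXCEPTION `klass`
#' @param ref,query [genome_store()]s
#' @param repeat_find_len flank length scanned (bp, default 50)
#' @param cfg a [run_config()] (carries the optional interspersed-repeat hook)
#' @return repeat verdict: list with `is_repetitive`, `kind`
#'   (TANDEM/INTERSPERSED/NONE), `period`, `copy_number`, `matched_fraction`
#' @export
repeat_screen <- function(variant, ref, query, repeat_find_len = 50L,
                          cfg = run_config()) {
  rfl <- as.integer(repeat_find_len)
  windows <- character(0)
  if (variant$klass %in% c("DEL", "SUB")) {
    windows <- c(windows, genome_seq(
      ref, variant$ref_chrom,
      variant$ref_start - rfl, variant$ref_end + rfl))
  }
  if (variant$klass %in% c("INS", "SUB")) {
    windows <- c(windows, genome_seq(
      query, variant$query_chrom,
      variant$query_start - rfl, variant$query_end + rfl))
  }
  for (w in windows) {
    v <- .screen_seq(w, cfg)
    if (v$is_repetitive) return(v)
  }
  list(is_repetitive = FALSE, kind = "NONE", period = NA_integer_,
       copy_number = NA_real_, matched_fraction = 0)
}

#' Screen a raw (uncorrected) call for repetitive sequence
#'
#' First-pass screen before breakpoint correction: the allele body (the
#' longer allele minus its anchor base) flanked by `repeat_find_len` bp of
#' reference sequence around the call position.
#'
#' @param raw one raw record (list or one-row data.frame)
#' @param ref reference [genome_store()]
#' @param repeat_find_len flank length scanned (bp)
#' @param cfg a [run_config()]
#' @return repeat verdict as in [repeat_screen()]
#' @export
repeat_screen_raw <- function(raw, ref, repeat_find_len = 50L,
                              cfg = run_config()) {
  rfl <- as.integer(repeat_find_len)
  body <- if (raw$caller_type == "DEL") {
    substr(raw$ref_allele, 2L, nchar(raw$ref_allele))
  } else {
    substr(raw$alt_allele, 2L, nchar(raw$alt_allele))
  }
  var_start <- as.integer(raw$pos)
  var_end <- var_start + max(0L, nchar(raw$ref_allele) - 1L)
  left <- genome_seq(ref, raw$chrom, var_start - rfl, var_start)
  right <- genome_seq(ref, raw$chrom, var_end, var_end + rfl)
  s <- if (raw$caller_type == "DEL") paste0(left, body, right)
       else paste0(left, body, right)
  .screen_seq(s, cfg)
}

#' Second-pass repeat screen on corrected coordinates
#'
#' Re-screens corrected variants (their corrected intervals can shift into a
#' tandem array the raw screen missed). EXCEPTION rows pass through to
#' `kept` untouched.
#'
#' @param variants data.frame of corrected variants
#' @param ref,query [genome_store()]s
#' @param cfg a [run_config()]
#' @return list with data.frames `kept` and `repetitive`
#'   (kept + repetitive = input)
#' @export
rescreen_corrected <- function(variants, ref, query, cfg = run_config()) {
  if (nrow(variants) == 0L) {
    return(list(kept = variants, repetitive = variants[0, , drop = FALSE]))
  }
  rep_flag <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$klass == "EXCEPTION") return(FALSE)
    repeat_screen(v, ref, query, cfg$repeat_find_len, cfg)$is_repetitive
  }, logical(1))
  list(kept = variants[!rep_flag, , drop = FALSE],
       repetitive = variants[rep_flag, , drop = FALSE])
}
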