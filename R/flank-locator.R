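# Flank placement: fills the role a plus-strand megablast search would play
# with an external aligner. Exact 24-mer seeds are matched with Biostrings,
# seed diagonals are clustered, and each candidate region is refined with a
# local Smith-Waterman (Biostrings::pairwiseAlignment) under the fixed scoring
# match=+1, mismatch=-2, gap open 4, gap extend 1. Only the plus strand is
# ever searched.

# scoring matrix: N is always a mismatch, including against itself
.dsbsig_submat <- local({
  m <- matrix(-2L, 5L, 5L,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- 1L
  m["N", "N"] <- -2L
  m
})

#' Extract the two reference flanks of a variant
#'
#' Returns the `flank_len` bp immediately 5' and 3' of the variant interval,
#' truncated (never padded) at chromosome ends. Flanks shorter than
#' `min_flank` after truncation are reported so the caller can route the
#' variant to EXCEPTION.
#'
#' @param genome a [genome_store()]
#' @param chrom chromosome name
#' @param var_start,var_end 0-based half-open variant interval
#' @param flank_len flank length in bp (default 2000, the `sv_find_len`
#'   parameter)
#' @param min_flank minimum usable flank length after truncation (default 200)
#' @return list with `left`, `right` (sequences), `left_start`, `right_start`
#'   (0-based starts of the extracted flanks), `truncated` and `too_short`
#'   logicals
#' @export
extract_flanks <- function(genome, chrom, var_start, var_end,
                           flank_len = 2000L, min_flank = 200L) {
  clen <- genome$lengths[[chrom]]
  stopifnot(var_start >= 0L, var_start <= var_end, var_end <= clen)
  ls <- max(0L, var_start - flank_len)
  re <- min(clen, var_end + flank_len)
  left <- genome_seq(genome, chrom, ls, var_start)
  right <- genome_seq(genome, chrom, var_end, re)
  truncated <- nchar(left) < flank_len || nchar(right) < flank_len
  if (truncated) {
    message("flank truncated at chromosome end (", chrom, ":", var_start, ")")
  }
  list(left = left, right = right,
       left_start = ls, right_start = as.integer(var_end),
       truncated = truncated,
       too_short = nchar(left) < min_flank || nchar(right) < min_flank)
}

#' Locate one flank sequence in the query genome
#'
#' Seed-and-refine search for the best plus-strand local placement of
#' `flank_seq` on `hint_chrom`, restricted to `hint_window` when given.
#' A hit must reach `min_identity` over at least `min_coverage` of the flank;
#' otherwise the result is absent (`NULL`). Equal-scoring hits are broken by
#' smallest query start, then longest aligned length.
#'
#' @param query a [genome_store()] for the query assembly
#' @param flank_seq flank nucleotide sequence (>= 50 bp)
#' @param hint_chrom chromosome to search
#' @param hint_window optional 0-based half-open `c(start, end)` window
#' @param min_identity minimum alignment identity (default 0.9)
#' @param min_coverage minimum aligned fraction of the flank (default 0.8)
#' @param seed_k exact seed length (default 24)
#' @param seed_step spacing between seeds along the flank (default 100)
#' @param inner which flank end abuts the variant: `"3p"` (left flank),
#'   `"5p"` (right flank) or `"none"`. The placement is trimmed so that the
#'   inner terminus sits at the end of a run of at least `anchor_run` exact
#'   matches; chance matches glued onto an unplaceable flank overhang would
#'   otherwise shift the inferred breakpoint by a few bases.
#' @param anchor_run exact-match run length anchoring the inner end
#' @return a flank hit: list with `query_chrom`, `query_start`, `query_end`
#'   (0-based half-open), `identity`, `aligned_len`, `score`,
#'   `pattern_start`, `pattern_end` (1-based aligned range within the flank);
#'   or `NULL` if nothing passes the thresholds
#' @export
locate_flank <- function(query, flank_seq, hint_chrom, hint_window = NULL,
                         min_identity = 0.9, min_coverage = 0.8,
                         seed_k = 24L, seed_step = 100L,
                         inner = c("none", "3p", "5p"), anchor_run = 8L) {
  inner <- match.arg(inner)
  flen <- nchar(flank_seq)
  if (flen < 50L) return(NULL)
  if (!hint_chrom %in% names(query$sequences)) return(NULL)
  chrom_seq <- query$sequences[[hint_chrom]]
  clen <- nchar(chrom_seq)
  w0 <- 0L; w1 <- clen
  if (!is.null(hint_window)) {
    w0 <- max(0L, as.integer(hint_window[1L]))
    w1 <- min(clen, as.integer(hint_window[2L]))
    if (w1 - w0 < flen) { w0 <- 0L; w1 <- clen }
  }
  subject <- Biostrings::DNAString(seq_slice(chrom_seq, w0, w1))

  seed_pos <- seq.int(1L, max(1L, flen - seed_k + 1L), by = seed_step)
  seeds <- substring(flank_seq, seed_pos, seed_pos + seed_k - 1L)
  ok <- nchar(seeds) == seed_k & !grepl("N", seeds, fixed = TRUE)
  seeds <- seeds[ok]; seed_pos <- seed_pos[ok]
  if (length(seeds) == 0L) return(NULL)

  starts <- lapply(seeds, function(s)
    BiocGenerics::start(Biostrings::matchPattern(s, subject)))
  nh <- lengths(starts)
  if (sum(nh) == 0L) return(NULL)
  diag <- unlist(starts, use.names = FALSE) -
    rep.int(seed_pos, nh)  # subject pos of flank base 1, minus 1

  # cluster diagonals: group sorted diagonals, breaking when the gap exceeds
  # 100 bp or the cluster span exceeds 300 bp (keeps refinement regions small
  # inside huge tandem arrays)
  d <- sort(diag)
  brk <- c(TRUE, diff(d) > 100L)
  grp <- cumsum(brk)
  span_ok <- function(x) {
    # further split clusters wider than 300 bp
    out <- integer(length(x)); g <- 1L; anchor <- x[1L]
    for (i in seq_along(x)) {
      if (x[i] - anchor > 300L) { g <- g + 1L; anchor <- x[i] }
      out[i] <- g
    }
    out
  }
  grp <- paste(grp, stats::ave(d, grp, FUN = span_ok))
  tab <- vapply(split(d, grp), length, integer(1))
  dmin <- vapply(split(d, grp), min, double(1))
  dmax <- vapply(split(d, grp), max, double(1))
  o <- order(-tab, dmin)
  take <- utils::head(o, 4L)

  best <- NULL
  for (i in take) {
    rs <- max(0L, as.integer(dmin[i]) - 64L)             # 0-based in window
    re <- min(w1 - w0, as.integer(dmax[i]) + flen + 64L)
    if (re - rs < seed_k) next
    region <- Biostrings::subseq(subject, rs + 1L, re)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(flank_seq), region, type = "local",
      substitutionMatrix = .dsbsig_submat,
      gapOpening = 4, gapExtension = 1)
    alen <- Biostrings::nchar(aln)
    if (alen == 0L) next
    ident <- Biostrings::nmatch(aln) / alen
    pr <- c(BiocGenerics::start(Biostrings::pattern(aln)),
            BiocGenerics::end(Biostrings::pattern(aln)))
    cov <- (pr[2L] - pr[1L] + 1L) / flen
    if (ident < min_identity || cov < min_coverage) next
    ss <- BiocGenerics::start(Biostrings::subject(aln))
    se <- BiocGenerics::end(Biostrings::subject(aln))
    # anchor the inner terminus on >= anchor_run consecutive exact matches
    if (inner != "none") {
      ap <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
      as_ <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
      mcol <- ap == as_ & ap != "-" & ap != "N"
      r <- rle(mcol)
      rend <- cumsum(r$lengths)
      ok <- r$values & r$lengths >= anchor_run
      if (!any(ok)) next
      if (inner == "3p") {
        cut <- rend[max(which(ok))]                  # keep columns 1..cut
        drop <- seq_along(mcol) > cut
      } else {
        cut <- rend[min(which(ok))] - r$lengths[min(which(ok))] + 1L
        drop <- seq_along(mcol) < cut                # keep columns cut..n
      }
      if (any(drop)) {
        dp <- sum(ap[drop] != "-"); ds <- sum(as_[drop] != "-")
        if (inner == "3p") { pr[2L] <- pr[2L] - dp; se <- se - ds }
        else { pr[1L] <- pr[1L] + dp; ss <- ss + ds }
      }
    }
    hit <- list(
      query_chrom = hint_chrom,
      query_start = w0 + rs + ss - 1L,
      query_end = w0 + rs + se,
      identity = ident,
      aligned_len = alen,
      score = Biostrings::score(aln),
      pattern_start = pr[1L],
      pattern_end = pr[2L])
    if (is.null(best) ||
        hit$score > best$score ||
        (hit$score == best$score && hit$query_start < best$query_start) ||
        (hit$score == best$score && hit$query_start == best$query_start &&
         hit$aligned_len > best$aligned_len)) {
      best <- hit
    }
  }
  best
}

#' Relate the placements of a variant's two flanks
#'
#' @param left_hit,right_hit flank hits from [locate_flank()], or `NULL`
#' @return list with `relation` (one of CONTIGUOUS, SEPARATED, OVERLAPPING,
#'   DISCORDANT) and `separation` (`right$query_start - left$query_end`,
#'   `NA` when discordant)
#' @export
pair_flanks <- function(left_hit, right_hit) {
  if (is.null(left_hit) || is.null(right_hit) ||
      !identical(left_hit$query_chrom, right_hit$query_chrom) ||
      right_hit$query_end < left_hit$query_start) {
    return(list(relation = "DISCORDANT", separation = NA_integer_))
  }
  sep <- as.integer(right_hit$query_start - left_hit$query_end)
  rel <- if (sep == 0L) "CONTIGUOUS" else if (sep > 0L) "SEPARATED"
         else "OVERLAPPING"
  list(relation = rel, separation = sep)
}
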