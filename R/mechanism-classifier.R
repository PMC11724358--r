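# Separation of the pooled micro/homology length distribution into TMEJ and
# SSA components: a local-regression minimum fixes the baseline, then each
# side is fit by a weighted Poisson component with the rate boxed to the
# biochemically plausible range (5-20 bp for TMEJ, 37-50 bp for SSA).

#' Tabulate micro/homology lengths into a 1-bp histogram
#' @param hom_lens integer vector of homology lengths (>= 1)
#' @return named integer vector of counts, names are lengths 1..max
#' @export
hom_histogram <- function(hom_lens) {
  hom_lens <- hom_lens[hom_lens >= 1L]
  if (length(hom_lens) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  counts <- tabulate(hom_lens, nbins = max(hom_lens))
  stats::setNames(as.integer(counts), as.character(seq_along(counts)))
}

#' Find the TMEJ/SSA separation baseline
#'
#' Smooths the histogram with local linear regression (tricube weights) over
#' the `lo`-`hi` bp range and returns the length at the smoothed curve's
#' global minimum. If the histogram has no mass on one side of 20 bp, or the
#' minimum sits on the range boundary (no interior minimum), the fixed
#' fallback (29 bp, the human pangenome setting) is returned with a warning.
#'
#' @param histogram named counts per 1-bp length bin (see [hom_histogram()])
#' @param span local-regression span (default 0.3)
#' @param lo,hi search range in bp (default 10-60)
#' @param fallback baseline used when no interior minimum exists (default 29)
#' @return integer baseline in bp
#' @export
find_baseline <- function(histogram, span = 0.3, lo = 10L, hi = 60L,
                          fallback = 29L) {
  if (length(histogram) == 0L || sum(histogram) == 0)
    stop("empty micro/homology histogram")
  lens <- as.integer(names(histogram))
  if (sum(histogram[lens > 20L]) == 0 || sum(histogram[lens <= 20L]) == 0) {
    warning("homology mass only on one side of 20 bp; using fallback ",
            fallback, " bp baseline")
    return(as.integer(fallback))
  }
  x <- lo:hi
  y <- as.numeric(histogram[match(x, lens)])
  y[is.na(y)] <- 0
  fit <- suppressWarnings(
    stats::loess(y ~ x, span = span, degree = 1,
                 control = stats::loess.control(surface = "direct")))
  sm <- stats::predict(fit, data.frame(x = x))
  i <- which.min(sm)
  if (i == 1L || i == length(x)) {
    warning("no interior minimum in ", lo, "-", hi,
            " bp; using fallback ", fallback, " bp baseline")
    return(as.integer(fallback))
  }
  as.integer(x[i])
}

.fit_poisson_side <- function(lens, counts, box) {
  if (length(lens) == 0L || sum(counts) == 0) return(NULL)
  obj <- function(par) {
    mu <- par[2L] * stats::dpois(lens, par[1L])
    sum((counts - mu)^2 / pmax(counts, 1))
  }
  lam0 <- min(max(sum(lens * counts) / sum(counts), box[1L]), box[2L])
  fit <- stats::optim(c(lam0, sum(counts)), obj, method = "L-BFGS-B",
                      lower = c(box[1L], 0), upper = c(box[2L], Inf))
  list(lambda = fit$par[1L], weight = fit$par[2L])
}

#' Fit the dual-Poisson mechanism model
#'
#' Weighted least squares (Poisson-variance weights, floor 1) of
#' `w1 * Pois(lambda1)` to the bins at or below the baseline and
#' `w2 * Pois(lambda2)` to the bins above it, with the rates box-constrained.
#' Overlap fractions are the fitted components' probability mass on the wrong
#' side of the baseline (exact Poisson CDF arithmetic).
#'
#' @param histogram named counts per 1-bp length bin
#' @param baseline separation length in bp
#' @param lambda_tmej_box,lambda_ssa_box rate constraint boxes
#' @return object of class `mechanism_summary` with the histogram, baseline,
#'   fitted `lambda_tmej`/`lambda_ssa`, component weights, and
#'   `overlap_tmej_over_baseline` / `overlap_ssa_under_baseline`
#' @export
fit_dual_poisson <- function(histogram, baseline,
                             lambda_tmej_box = c(5, 20),
                             lambda_ssa_box = c(37, 50)) {
  lens <- as.integer(names(histogram))
  counts <- as.numeric(histogram)
  lo_side <- lens <= baseline
  f1 <- .fit_poisson_side(lens[lo_side], counts[lo_side], lambda_tmej_box)
  f2 <- .fit_poisson_side(lens[!lo_side], counts[!lo_side], lambda_ssa_box)
  structure(list(
    histogram = histogram,
    baseline = as.integer(baseline),
    lambda_tmej = if (is.null(f1)) NA_real_ else f1$lambda,
    lambda_ssa = if (is.null(f2)) NA_real_ else f2$lambda,
    weight_tmej = if (is.null(f1)) 0 else f1$weight,
    weight_ssa = if (is.null(f2)) 0 else f2$weight,
    overlap_tmej_over_baseline = if (is.null(f1)) 0 else
      stats::ppois(baseline, f1$lambda, lower.tail = FALSE),
    overlap_ssa_under_baseline = if (is.null(f2)) 0 else
      stats::ppois(baseline, f2$lambda)),
    class = "mechanism_summary")
}

#' @export
print.mechanism_summary <- function(x, ...) {
  cat("mechanism summary: baseline", x$baseline, "bp\n")
  cat(sprintf("  TMEJ: lambda %.2f weight %.1f (%.3g%% above baseline)\n",
              x$lambda_tmej, x$weight_tmej,
              100 * x$overlap_tmej_over_baseline))
  cat(sprintf("  SSA:  lambda %.2f weight %.1f (%.3g%% at/below baseline)\n",
              x$lambda_ssa, x$weight_ssa,
              100 * x$overlap_ssa_under_baseline))
  invisible(x)
}

#' Variant density along chromosomes
#'
#' @param annots annotation data.frame with `ref_chrom`, `ref_start`,
#'   `mechanism`
#' @param genome reference [genome_store()]
#' @param window window width in bp (default 1 Mb)
#' @return data.frame with `chrom`, `window_start`, `mechanism`, `count`;
#'   counts sum to the number of annotated variants
#' @export
chromosome_density <- function(annots, genome, window = 1000000L) {
  if (nrow(annots) == 0L) {
    return(data.frame(chrom = character(), window_start = integer(),
                      mechanism = character(), count = integer()))
  }
  win <- (annots$ref_start %/% window) * window
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(annots))),
    by = list(chrom = annots$ref_chrom, window_start = win,
              mechanism = annots$mechanism),
    FUN = sum)
  agg[order(agg$chrom, agg$window_start, agg$mechanism), , drop = FALSE]
}

#' Assign TMEJ/SSA calls and build the mechanism summary
#'
#' Builds the micro/homology histogram from signature-bearing indels,
#' resolves the baseline (`cfg$baseline` = "auto" uses [find_baseline()],
#' an integer fixes it), classifies each indel, and fits the dual-Poisson
#' summary.
#'
#' @param annots annotation data.frame from [annotate_variants()] (after
#'   tandem-duplication removal)
#' @param ref reference [genome_store()] (for chromosome densities)
#' @param cfg a [run_config()]
#' @return list with `annotations` (mechanisms finalized), `summary`
#'   (a `mechanism_summary`), and `density`
#' @export
classify_mechanisms <- function(annots, ref, cfg = run_config()) {
  todo <- annots$mechanism == "NOT_DETERMINED"
  hist <- hom_histogram(annots$hom_len[todo])
  baseline <- if (identical(cfg$baseline, "auto")) {
    tryCatch(find_baseline(hist, span = cfg$span),
             error = function(e) {
               warning("baseline fallback: ", conditionMessage(e))
               29L
             })
  } else {
    as.integer(cfg$baseline)
  }
  if (any(todo)) {
    annots$mechanism[todo] <- classify_indel(
      annots$hom_len[todo], baseline, cfg$min_signal_len)
  }
  summ <- fit_dual_poisson(hist, baseline,
                           cfg$lambda_tmej_box, cfg$lambda_ssa_box)
  list(annotations = annots, summary = summ,
       density = chromosome_density(annots, ref))
}
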