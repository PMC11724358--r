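#' Read raw structural-variant calls from a VCF
#'
#' Ingests an assembly-based caller's VCF (4.2, explicit REF/ALT sequences)
#' into a raw-variant table. Records whose allele-length difference is below
#' `min_sv_size` are dropped; symbolic ALTs (e.g. `<DUP>`) are skipped with a
#' warning because they carry no breakpoint sequence to correct. Positions are
#' converted to the package-internal 0-based convention: `pos` is the 0-based
#' coordinate of the first affected base (the base *after* the VCF anchor
#' base).
#'
#' @param path VCF file (plain text or bgzipped)
#' @param min_sv_size minimum allele-length difference in bp (default 10)
#' @return data.frame with columns `id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `caller_type` ("INS"/"DEL"), sorted by (chrom, pos).
#'   Attributes `n_dropped` and `n_skipped` carry ingestion bookkeeping so
#'   that retained + dropped + skipped equals the record count in the file.
#' @export
read_variant_vcf <- function(path, min_sv_size = 10L) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  n <- nrow(vcf)
  empty <- data.frame(
    id = character(), chrom = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(),
    caller_type = character(), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "n_dropped") <- 0L; attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  alt <- vapply(alt_l, function(x) if (length(x)) as.character(x)[1L] else "",
                character(1))
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("var%06d", seq_len(n))
  symbolic <- grepl("<", alt, fixed = TRUE) | grepl("[", alt, fixed = TRUE) |
    grepl("]", alt, fixed = TRUE) | !nzchar(alt)
  if (any(symbolic)) {
    warning(sum(symbolic), " symbolic/sequence-less record(s) skipped")
  }
  keep <- !symbolic
  df <- data.frame(
    id = ids[keep],
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],      # 1-based anchor position
    ref_allele = ref[keep],
    alt_allele = alt[keep],
    stringsAsFactors = FALSE)
  df$caller_type <- ifelse(nchar(df$alt_allele) > nchar(df$ref_allele),
                           "INS", "DEL")
  # 0-based coordinate of first affected base: VCF pos is 1-based anchor,
  # so the anchor's 0-based index is pos-1 and the first affected base is pos.
  df$pos <- as.integer(df$pos)
  size <- abs(nchar(df$alt_allele) - nchar(df$ref_allele))
  small <- size < min_sv_size
  n_dropped <- sum(small)
  if (n_dropped > 0L) {
    message(n_dropped, " record(s) below min_sv_size=", min_sv_size,
            " dropped")
  }
  df <- df[!small, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  attr(df, "n_skipped") <- sum(symbolic)
  df
}

#' Write a raw-variant table as a VCF 4.2 file
#'
#' Emits the minimal single-sample-free VCF used by the synthetic generator:
#' explicit REF/ALT sequences, an `SVTYPE` INFO tag, contig header lines.
#'
#' @param variants data.frame as returned by [read_variant_vcf()] (columns
#'   `id`, `chrom`, `pos` (1-based anchor), `ref_allele`, `alt_allele`,
#'   `caller_type`)
#' @param gs `genome_store` of the reference (for contig lengths)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variant_vcf <- function(variants, gs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(gs$lengths),
            as.integer(gs$lengths)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")), con)
  if (nrow(variants)) {
    o <- order(variants$chrom, variants$pos)
    v <- variants[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=%s",
                       v$chrom, as.integer(v$pos), v$id,
                       v$ref_allele, v$alt_allele, v$caller_type), con)
  }
  invisible(path)
}
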