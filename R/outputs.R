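#' Write the final annotation tables
#'
#' Emits the three standard result files: a TSV with reference position,
#' query position, variant type, annotated DSB repair mechanism, homology
#' length and homology sequence; a BED (0-based half-open) with reference
#' positions and homology lengths; and a CSV tallying the correction-stage
#' class of every ingested variant (insertion, deletion, complex
#' substitution, repeat, exception).
#'
#' @param annotations data.frame of signature annotations (see
#'   [annotate_variants()]); may have zero rows
#' @param classes data.frame with columns `variant_id`, `class` covering
#'   every raw variant
#' @param prefix output path prefix; files `<prefix>.tsv`, `<prefix>.bed`,
#'   `<prefix>.class.csv` are written
#' @return named character vector of the three paths, invisibly
#' @export
write_outputs <- function(annotations, classes, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  csv <- paste0(prefix, ".class.csv")

  cols <- c("variant_id", "ref_chrom", "ref_start", "ref_end",
            "query_chrom", "query_start", "query_end",
            "variant_type", "mechanism", "hom_len", "hom_seq")
  tab <- if (nrow(annotations)) {
    data.frame(variant_id = annotations$id,
               ref_chrom = annotations$ref_chrom,
               ref_start = annotations$ref_start,
               ref_end = annotations$ref_end,
               query_chrom = annotations$query_chrom,
               query_start = annotations$query_start,
               query_end = annotations$query_end,
               variant_type = annotations$klass,
               mechanism = annotations$mechanism,
               hom_len = annotations$hom_len,
               hom_seq = annotations$hom_seq,
               stringsAsFactors = FALSE)
  } else {
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  }
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  bed_tab <- tab[, c("ref_chrom", "ref_start", "ref_end", "hom_len")]
  names(bed_tab) <- c("chrom", "start", "end", "hom_len")
  utils::write.table(bed_tab, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cls <- if (nrow(classes)) {
    classes[, c("variant_id", "class")]
  } else {
    data.frame(variant_id = character(), class = character())
  }
  utils::write.table(cls, csv, sep = ",", quote = FALSE, row.names = FALSE)

  invisible(c(tsv = tsv, bed = bed, csv = csv))
}
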