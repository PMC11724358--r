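#' In-memory genome store
#'
#' A `genome_store` holds chromosome-keyed uppercase nucleotide sequences
#' (alphabet A/C/G/T/N) for either the reference genome or a query assembly,
#' together with per-chromosome lengths. All accessors use 0-based half-open
#' coordinates.
#'
#' @param sequences named character vector or list of nucleotide strings,
#'   one per chromosome. Lowercase letters are uppercased; IUPAC ambiguity
#'   codes other than N are mapped to N with a warning.
#' @return object of class `genome_store` with elements `sequences`
#'   (named character) and `lengths` (named integer).
#' @examples
#' gs <- genome_store(c(chr1 = "acgtACGT", chr2 = "NNNN"))
#' genome_lengths(gs)
#' genome_seq(gs, "chr1", 0, 4)
#' @export
genome_store <- function(sequences) {
  sequences <- unlist(as.list(sequences))
  if (length(sequences) == 0L) stop("genome store needs at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1L])
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    warning("ambiguity codes mapped to N in: ",
            paste(nm[bad], collapse = ", "))
    sequences[bad] <- gsub("[^ACGTN]", "N", sequences[bad])
  }
  if (any(!nzchar(sequences))) {
    stop("empty sequence for chromosome: ", nm[!nzchar(sequences)][1L])
  }
  structure(
    list(sequences = sequences,
         lengths = stats::setNames(nchar(sequences), nm)),
    class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store:", length(x$sequences), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome store
#' @param gs a `genome_store`
#' @return named integer vector of chromosome lengths in bp
#' @export
genome_lengths <- function(gs) gs$lengths

#' Extract a subsequence (0-based half-open)
#' @param gs a `genome_store`
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval, clamped to the chromosome
#' @return character scalar
#' @export
genome_seq <- function(gs, chrom, start, end) {
  if (!chrom %in% names(gs$sequences)) stop("unknown chromosome: ", chrom)
  s <- gs$sequences[[chrom]]
  n <- nchar(s)
  seq_slice(s, max(0L, as.integer(start)), min(n, as.integer(end)))
}

#' Read a FASTA file into a genome store
#'
#' Sequences are uppercased and ambiguity codes other than N become N
#' (with a warning). Duplicate record names or an empty file are errors.
#'
#' @param path path to a (possibly line-wrapped) multi-record FASTA file
#' @return a [genome_store()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))  # first token of the description line
  seqs <- stats::setNames(as.character(ss), nm)
  genome_store(seqs)
}

#' Write a genome store to FASTA
#' @param gs a `genome_store`
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(gs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(gs$sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
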