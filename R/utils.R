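# Low-level string helpers shared across modules. All coordinates in this
# package are 0-based half-open unless a function says otherwise; conversion
# to/from 1-based happens only at the VCF and substr() boundaries.

#' @keywords internal
#' @noRd
seq_slice <- function(s, start, end) {
  # 0-based half-open slice of a character scalar
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# split a nucleotide string into a raw byte vector (fast elementwise compare)
#' @keywords internal
#' @noRd
seq_bytes <- function(s) charToRaw(s)

RAW_N <- charToRaw("N")

# longest exact common prefix of two strings, N never matches
#' @keywords internal
#' @noRd
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- seq_bytes(substr(a, 1L, n))
  rb <- seq_bytes(substr(b, 1L, n))
  ok <- ra == rb & ra != RAW_N
  if (all(ok)) return(n)
  which.min(ok) - 1L
}

# longest exact common suffix
#' @keywords internal
#' @noRd
lcs_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  ra <- seq_bytes(substr(a, na - n + 1L, na))
  rb <- seq_bytes(substr(b, nb - n + 1L, nb))
  ok <- rev(ra == rb & ra != RAW_N)
  if (all(ok)) return(n)
  which.min(ok) - 1L
}

#' @keywords internal
#' @noRd
rev_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
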