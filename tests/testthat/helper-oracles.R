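# Independent brute-force oracles and fixture builders. These deliberately
# use naive character loops / exhaustive scans, not the package's code paths.

rand_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

str_rev <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

# longest exact common prefix, naive loop, N never matches
oracle_lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n) {
    ca <- substr(a, i + 1L, i + 1L)
    if (ca != substr(b, i + 1L, i + 1L) || ca == "N") break
    i <- i + 1L
  }
  i
}

# brute-force junction micro/homology: max of prefix(V,R) and suffix(V,L)
oracle_mh <- function(v, l, r) {
  max(oracle_lcp(v, r), oracle_lcp(str_rev(v), str_rev(l)))
}

# exhaustive all-period, all-window tandem check at the detector thresholds
oracle_has_tandem <- function(s, min_score = 50, max_period = 500,
                              min_identity = 0.8) {
  x <- charToRaw(s); n <- length(x); rawN <- charToRaw("N")
  for (p in seq_len(min(max_period, n %/% 2))) {
    L <- n - p
    m <- (x[seq_len(L)] == x[(p + 1):n]) &
      x[seq_len(L)] != rawN & x[(p + 1):n] != rawN
    cm <- cumsum(c(0L, as.integer(m)))
    for (i in seq_len(L)) {
      j <- i:L
      M <- cm[j + 1L] - cm[i]
      W <- j - i + 1L
      ok <- (M >= min_identity * W) & (2 * M - 5 * (W - M) >= min_score) &
        (W >= p)
      if (any(ok)) return(TRUE)
    }
  }
  FALSE
}

# build a deletion fixture genome with an exact planted prefix-side MH:
# ref = L + V + R with V[1..mh] == R[1..mh], boundaries forced to mismatch
make_mh_fixture <- function(mh, v_len = max(mh + 5L, 20L), wing = 300L) {
  stopifnot(mh <= v_len - 2L)
  v <- strsplit(rand_dna(v_len), "")[[1]]
  l <- strsplit(rand_dna(wing), "")[[1]]
  r <- strsplit(rand_dna(wing), "")[[1]]
  if (mh > 0L) r[seq_len(mh)] <- v[seq_len(mh)]
  r[mh + 1L] <- sample(setdiff(c("A", "C", "G", "T"), v[mh + 1L]), 1L)
  if (mh == 0L) r[1L] <- sample(setdiff(c("A", "C", "G", "T"), v[1L]), 1L)
  # keep the suffix side quiet so the planted prefix value is the max
  l[wing] <- sample(setdiff(c("A", "C", "G", "T"), v[v_len]), 1L)
  list(v = paste(v, collapse = ""), l = paste(l, collapse = ""),
       r = paste(r, collapse = ""))
}

# wrap a (L, V, R) junction fixture into genomes + a corrected DEL row
fixture_del_variant <- function(fx) {
  refseq <- paste0(fx$l, fx$v, fx$r)
  list(ref = genome_store(c(chrT = refseq)),
       query = genome_store(c(chrT = paste0(fx$l, fx$r))),
       variant = list(id = "fx", klass = "DEL", ref_chrom = "chrT",
                      ref_start = nchar(fx$l),
                      ref_end = nchar(fx$l) + nchar(fx$v),
                      query_chrom = "chrT", query_start = nchar(fx$l),
                      query_end = nchar(fx$l)))
}

# rebuild the query chromosome from the reference plus the truth edits
# (deleting each truth ref interval, inserting the truth query interval
# content); equality with the stored query validates every planted interval
rebuild_query <- function(ref, query, truth, chrom) {
  tr <- truth[truth$ref_chrom == chrom, , drop = FALSE]
  tr <- tr[order(tr$ref_start), , drop = FALSE]
  pieces <- character(0); prev <- 0L
  for (i in seq_len(nrow(tr))) {
    pieces <- c(pieces, genome_seq(ref, chrom, prev, tr$ref_start[i]),
                genome_seq(query, chrom, tr$query_start[i],
                           tr$query_end[i]))
    prev <- tr$ref_end[i]
  }
  paste(c(pieces, genome_seq(ref, chrom, prev, ref$lengths[[chrom]])),
        collapse = "")
}
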