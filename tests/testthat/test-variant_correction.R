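# small genomes built base by base so every expected interval is forced by
# construction

test_that("a correctly called insertion is accepted with zero trims", {
  sim <- simulate_genomes(events = c(tmej_ins = 3), seed = 41,
                          miscall_frac = 0)
  cfg <- run_config()
  for (i in seq_len(nrow(sim$vcf))) {
    cv <- correct_variant(sim$vcf[i, ], sim$ref, sim$query, cfg)
    tr <- sim$truth[sim$truth$event_id == cv$id, ]
    expect_identical(cv$klass, "INS")
    expect_identical(cv$trim_rounds_used, 0L)
    expect_identical(cv$query_start, tr$query_start)
    expect_identical(cv$query_end, tr$query_end)
    expect_identical(cv$ref_start, cv$ref_end)
    expect_true(edit_roundtrips(sim$ref, sim$query, cv))
  }
})

test_that("miscalled breakpoints are corrected to a round-tripping edit", {
  sim <- simulate_genomes(events = c(tmej_del = 6, tmej_ins = 4, nhej = 4),
                          seed = 42, miscall_frac = 1)
  cfg <- run_config()
  expect_true(any(sim$truth$miscall_offset != 0L))
  for (i in seq_len(nrow(sim$vcf))) {
    cv <- correct_variant(sim$vcf[i, ], sim$ref, sim$query, cfg)
    expect_false(cv$klass == "EXCEPTION")
    expect_true(edit_roundtrips(sim$ref, sim$query, cv))
    tr <- sim$truth[sim$truth$event_id == cv$id, ]
    # same net size, possibly a shifted-but-equivalent representation
    expect_identical((cv$ref_end - cv$ref_start) -
                       (cv$query_end - cv$query_start),
                     (tr$ref_end - tr$ref_start) -
                       (tr$query_end - tr$query_start))
  }
})

test_that("nested substituted sequences are reclassified as indels", {
  set.seed(43)
  l <- rand_dna(5000); r <- rand_dna(5000)
  sr <- paste0("AT", "GCTGGTCAAGGTCCGATCGC")   # 22 bp, starts with "AT"
  ref <- genome_store(c(chr1 = paste0(l, sr, r)))
  qry <- genome_store(c(chr1 = paste0(l, "AT", r)))
  cand <- list(id = "s1", ref_chrom = "chr1", ref_start = 5000L,
               ref_end = 5000L + 22L, query_chrom = "chr1",
               query_start = 5000L, query_end = 5002L, klass = "SUB",
               trim_rounds_used = 0L, reason = NA_character_)
  cv <- verify_substitution(cand, ref, qry, run_config())
  expect_identical(cv$klass, "DEL")
  expect_identical(cv$ref_end - cv$ref_start, 20L)
  expect_true(edit_roundtrips(ref, qry, cv))
})

test_that("dissimilar equal-length substitutions stay SUB", {
  set.seed(44)
  l <- rand_dna(5000); r <- rand_dna(5000)
  sr <- strrep("ACGT", 10)
  sq <- strrep("TGCA", 10)                       # identity far below 0.5
  ref <- genome_store(c(chr1 = paste0(l, sr, r)))
  qry <- genome_store(c(chr1 = paste0(l, sq, r)))
  cand <- list(id = "s2", ref_chrom = "chr1", ref_start = 5000L,
               ref_end = 5040L, query_chrom = "chr1", query_start = 5000L,
               query_end = 5040L, klass = "SUB", trim_rounds_used = 0L,
               reason = NA_character_)
  expect_identical(verify_substitution(cand, ref, qry)$klass, "SUB")

  # identical substituted sequences are a caller artifact
  cand_id <- cand
  cand_id$query_start <- 5000L; cand_id$query_end <- 5040L
  qry2 <- genome_store(c(chr1 = paste0(l, sr, r)))
  cv <- verify_substitution(cand_id, ref, qry2)
  expect_identical(cv$klass, "EXCEPTION")
  expect_identical(cv$reason, "caller_artifact")
})

test_that("variants deep inside long tandem arrays hit the trim limit", {
  set.seed(45)
  l <- rand_dna(20000); r <- rand_dna(20000)
  arr <- strrep("TA", 10000)                     # 20 kb array
  refseq <- paste0(l, arr, r)
  ds <- 20000L + 10000L; dl <- 400L
  qryseq <- paste0(substr(refseq, 1, ds),
                   substr(refseq, ds + dl + 1, nchar(refseq)))
  ref <- genome_store(c(chr1 = refseq))
  qry <- genome_store(c(chr1 = qryseq))
  raw <- list(id = "arr1", chrom = "chr1", pos = ds,
              ref_allele = substr(refseq, ds, ds + dl),
              alt_allele = substr(refseq, ds, ds), caller_type = "DEL")
  cv <- correct_variant(raw, ref, qry, run_config())
  expect_identical(cv$klass, "EXCEPTION")
  expect_identical(cv$reason, "still_overlapping")
  expect_identical(cv$trim_rounds_used, 3L)
})

test_that("a variant at a chromosome end routes to EXCEPTION", {
  set.seed(46)
  gs <- genome_store(c(chr1 = rand_dna(3000)))
  raw <- list(id = "e1", chrom = "chr1", pos = 50L,
              ref_allele = genome_seq(gs, "chr1", 49, 80),
              alt_allele = genome_seq(gs, "chr1", 49, 50),
              caller_type = "DEL")
  cv <- suppressMessages(correct_variant(raw, gs, gs, run_config()))
  expect_identical(cv$klass, "EXCEPTION")
  expect_identical(cv$reason, "flank_too_short")
})

test_that("swapping reference and query maps DEL onto INS", {
  sim <- simulate_genomes(events = c(tmej_del = 2), seed = 47,
                          miscall_frac = 0)
  cfg <- run_config()
  tr <- sim$truth[1, ]
  raw <- sim$vcf[sim$vcf$id == tr$event_id, ]
  del <- correct_variant(raw, sim$ref, sim$query, cfg)
  expect_identical(del$klass, "DEL")
  # the same event seen from the query side is an insertion of equal length
  dseq <- genome_seq(sim$ref, tr$ref_chrom, tr$ref_start, tr$ref_end)
  anchor <- genome_seq(sim$query, tr$query_chrom, tr$query_start - 1L,
                       tr$query_start)
  raw_sw <- list(id = "sw", chrom = tr$query_chrom, pos = tr$query_start,
                 ref_allele = anchor, alt_allele = paste0(anchor, dseq),
                 caller_type = "INS")
  ins <- correct_variant(raw_sw, sim$query, sim$ref, cfg)
  expect_identical(ins$klass, "INS")
  expect_identical(ins$query_end - ins$query_start,
                   del$ref_end - del$ref_start)
})

test_that("class tallies partition the input", {
  df <- data.frame(klass = c("INS", "DEL", "DEL", "SUB", "EXCEPTION"))
  tl <- tally_classes(df, repeats = 2L)
  expect_identical(sum(tl), nrow(df) + 2L)
  expect_identical(unname(tl[c("INS", "DEL", "SUB", "REPEAT", "EXCEPTION")]),
                   c(1L, 2L, 1L, 2L, 1L))
  expect_identical(sum(tally_classes(df[0, , drop = FALSE])), 0L)
})
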