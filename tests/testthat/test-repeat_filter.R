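test_that("canonical arrays match hand-computed examples", {
  at <- find_tandem_repeats(strrep("AT", 25))
  expect_identical(nrow(at), 1L)
  expect_identical(at$period, 2L)
  expect_identical(at$copy_number, 25)
  expect_identical(at$percent_identity, 100)
  expect_identical(c(at$start, at$end), c(0L, 50L))

  a30 <- find_tandem_repeats(strrep("A", 30))
  expect_identical(nrow(a30), 1L)
  expect_identical(a30$period, 1L)
  expect_identical(a30$copy_number, 30)
})

test_that("random sequence carries no qualifying array", {
  set.seed(61)
  s <- rand_dna(60)
  expect_identical(nrow(find_tandem_repeats(s)), 0L)
  expect_false(oracle_has_tandem(s))
  expect_error(find_tandem_repeats("ACGTACGT"), "shorter")
})

test_that("detector verdicts agree with the exhaustive all-window oracle", {
  set.seed(62)
  cases <- c(
    lapply(c(40, 80, 150, 200), rand_dna),
    # salted: a random backbone with an embedded imperfect array
    lapply(c(3, 7, 12), function(p) {
      unit <- rand_dna(p)
      arr <- strsplit(strrep(unit, ceiling(120 / p)), "")[[1]]
      mut <- sample(length(arr), 3)
      arr[mut] <- vapply(arr[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste0(rand_dna(40), paste(arr, collapse = ""), rand_dna(40))
    }),
    # borderline: short pure arrays around the score threshold
    list(paste0(rand_dna(50), strrep("AC", 12), rand_dna(50)),   # 24 bp unit
         paste0(rand_dna(50), strrep("AC", 14), rand_dna(50))))  # 28 bp
  for (s in cases) {
    expect_identical(nrow(find_tandem_repeats(s)) > 0L,
                     oracle_has_tandem(s),
                     info = substr(s, 1, 40))
  }
})

test_that("repeat screen flags repetitive variant bodies, not random ones", {
  set.seed(63)
  cfg <- run_config()
  l <- rand_dna(3000); r <- rand_dna(3000)
  cag <- substr(strrep("CAG", 34), 1, 100)       # 100 bp CAG-array deletion
  ref1 <- genome_store(c(chr1 = paste0(l, cag, r)))
  qry1 <- genome_store(c(chr1 = paste0(l, r)))
  v1 <- list(id = "d1", klass = "DEL", ref_chrom = "chr1",
             ref_start = 3000L, ref_end = 3100L, query_chrom = "chr1",
             query_start = 3000L, query_end = 3000L)
  verdict <- repeat_screen(v1, ref1, qry1, 50L, cfg)
  expect_true(verdict$is_repetitive)
  expect_identical(verdict$kind, "TANDEM")
  expect_identical(verdict$period, 3L)

  ref2 <- genome_store(c(chr1 = paste0(l, rand_dna(100), r)))
  expect_false(repeat_screen(v1, ref2, qry1, 50L, cfg)$is_repetitive)
})

test_that("repeat_find_len 0 disables flank scanning only", {
  set.seed(64)
  cfg <- run_config()
  l <- rand_dna(3000); r <- rand_dna(3000)
  arr <- strrep("CAG", 30)
  body <- rand_dna(60)
  # clean body, arrays immediately flanking it
  ref <- genome_store(c(chr1 = paste0(l, arr, body, arr, r)))
  qry <- genome_store(c(chr1 = paste0(l, arr, arr, r)))
  v <- list(id = "d2", klass = "DEL", ref_chrom = "chr1",
            ref_start = 3090L, ref_end = 3150L, query_chrom = "chr1",
            query_start = 3090L, query_end = 3090L)
  expect_true(repeat_screen(v, ref, qry, 50L, cfg)$is_repetitive)
  expect_false(repeat_screen(v, ref, qry, 0L, cfg)$is_repetitive)
})

test_that("growing the scan window never shrinks the repetitive set", {
  sim <- simulate_genomes(events = c(tmej_del = 5, repeat_embedded = 3,
                                     ssa_del = 3), seed = 65)
  cfg <- run_config()
  prev <- character(0)
  for (rfl in c(0L, 10L, 20L, 30L, 40L, 50L)) {
    flagged <- sim$vcf$id[vapply(seq_len(nrow(sim$vcf)), function(i)
      repeat_screen_raw(sim$vcf[i, ], sim$ref, rfl, cfg)$is_repetitive,
      logical(1))]
    expect_true(all(prev %in% flagged),
                info = paste("repeat_find_len", rfl))
    prev <- flagged
  }
})

test_that("second-pass screen catches intervals shifted into an array", {
  set.seed(66)
  l <- rand_dna(3000); r <- rand_dna(3000)
  ta <- strrep("TA", 60)
  ref <- genome_store(c(chr1 = paste0(l, ta, r)))
  qry <- genome_store(c(chr1 = paste0(l, substr(ta, 1, 20), r)))
  vars <- data.frame(
    id = c("clean", "shifted"), ref_chrom = "chr1",
    ref_start = c(500L, 3020L), ref_end = c(560L, 3120L),
    query_chrom = "chr1", query_start = c(500L, 3020L),
    query_end = c(500L, 3020L), klass = "DEL",
    trim_rounds_used = 0L, reason = NA_character_,
    stringsAsFactors = FALSE)
  part <- rescreen_corrected(vars, ref, qry, run_config())
  expect_identical(part$repetitive$id, "shifted")
  expect_identical(nrow(part$kept) + nrow(part$repetitive), nrow(vars))

  all_clean <- vars[1, , drop = FALSE]
  part2 <- rescreen_corrected(all_clean, ref, qry, run_config())
  expect_identical(part2$kept$id, "clean")
  expect_identical(nrow(part2$repetitive), 0L)
})

test_that("screening is deterministic", {
  sim <- simulate_genomes(events = c(repeat_embedded = 2, tmej_del = 2),
                          seed = 67)
  cfg <- run_config()
  f <- function() vapply(seq_len(nrow(sim$vcf)), function(i)
    repeat_screen_raw(sim$vcf[i, ], sim$ref, 50L, cfg)$is_repetitive,
    logical(1))
  expect_identical(f(), f())
})
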