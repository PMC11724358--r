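test_that("junction micro/homology follows the prefix/suffix contract", {
  cfg <- run_config()
  # deleted V = ACGTT, following sequence starts ACGGA -> 3 bp "ACG"
  l <- paste0(rand_dna(250), "C")
  fx <- list(v = "ACGTT", l = l, r = paste0("ACGGA", rand_dna(250)))
  g <- fixture_del_variant(fx)
  h <- junction_microhomology(g$variant, g$ref, g$query, cfg)
  expect_identical(h$hom_len, 3L)
  expect_identical(h$hom_seq, "ACG")

  # no match on either side
  fx0 <- list(v = strrep("A", 20), l = paste0(rand_dna(200), "CCCC"),
              r = paste0("TTTT", rand_dna(200)))
  g0 <- fixture_del_variant(fx0)
  expect_identical(
    junction_microhomology(g0$variant, g0$ref, g0$query, cfg)$hom_len, 0L)
})

test_that("SSA-planted homology is recovered exactly", {
  sim <- simulate_genomes(events = c(ssa_del = 4), seed = 71,
                          miscall_frac = 0)
  cfg <- run_config()
  for (i in seq_len(nrow(sim$vcf))) {
    cv <- correct_variant(sim$vcf[i, ], sim$ref, sim$query, cfg)
    tr <- sim$truth[sim$truth$event_id == cv$id, ]
    h <- junction_microhomology(cv, sim$ref, sim$query, cfg)
    expect_identical(h$hom_len, tr$planted_hom_len)
    expect_identical(h$hom_seq, tr$planted_hom_seq)
  }
})

test_that("exact-mode detection equals the brute-force oracle", {
  set.seed(72)
  cfg <- run_config()
  for (mh in c(0L, 1L, 2L, 5L, 9L, 10L, 11L, 25L, 40L, 60L)) {
    for (rep in 1:5) {
      fx <- make_mh_fixture(mh, v_len = max(mh + 5L, 30L))
      g <- fixture_del_variant(fx)
      got <- junction_microhomology(g$variant, g$ref, g$query, cfg)$hom_len
      expect_identical(got, oracle_mh(fx$v, fx$l, fx$r),
                       info = paste("planted", mh))
    }
  }
})

test_that("insertion/deletion symmetry leaves homology unchanged", {
  set.seed(73)
  cfg <- run_config()
  for (mh in c(3L, 8L, 15L)) {
    fx <- make_mh_fixture(mh, v_len = 40L)
    g <- fixture_del_variant(fx)
    del_h <- junction_microhomology(g$variant, g$ref, g$query, cfg)$hom_len
    # swap: the query now carries V as an insertion
    ins_var <- g$variant
    ins_var$klass <- "INS"
    ins_var$query_start <- g$variant$ref_start
    ins_var$query_end <- g$variant$ref_end
    ins_h <- junction_microhomology(ins_var, g$query, g$ref, cfg)$hom_len
    expect_identical(ins_h, del_h)
  }
})

test_that("mechanism classification splits at the baseline inclusively", {
  expect_identical(classify_indel(12L, 29L), "TMEJ")
  expect_identical(classify_indel(35L, 29L), "SSA")
  expect_identical(classify_indel(29L, 29L), "TMEJ")   # boundary inclusive
  expect_identical(classify_indel(30L, 29L), "SSA")
  expect_identical(classify_indel(1L, 29L), "NO_SIGNATURE")
  expect_identical(classify_indel(0L, 29L), "NO_SIGNATURE")
})

test_that("tandem duplication removal uses a strict 90% rule", {
  mk <- function(id, len, hom) data.frame(
    id = id, ref_chrom = "c", ref_start = 0L, ref_end = len,
    query_chrom = "c", query_start = 0L, query_end = 0L, klass = "DEL",
    mechanism = "NOT_DETERMINED", hom_len = hom, hom_seq = "",
    stringsAsFactors = FALSE)
  ann <- rbind(mk("a89", 100L, 89L), mk("a90", 100L, 90L),
               mk("a91", 100L, 91L), mk("zero", 20L, 0L))
  td <- remove_tandem_duplications(ann, 0.9)
  expect_identical(td$tandem_dups$id, "a91")
  expect_identical(sort(td$kept$id), sort(c("a89", "a90", "zero")))
  expect_identical(td$tandem_dups$mechanism, "TANDEM_DUP")
})

test_that("templated insertions need a local template plus two homologies", {
  sim <- simulate_genomes(events = c(templated_ins = 4), seed = 74)
  cfg <- run_config()
  for (i in seq_len(nrow(sim$vcf))) {
    cv <- correct_variant(sim$vcf[i, ], sim$ref, sim$query, cfg)
    expect_identical(cv$klass, "SUB")
    tr <- sim$truth[sim$truth$event_id == cv$id, ]
    d <- detect_templated_insertion(cv, sim$ref, sim$query, cfg)
    expect_identical(d$mechanism, "TEMPLATED_INS")
    expect_identical(d$hom_len, tr$planted_hom_len)
    expect_identical(d$second_hom_len, tr$second_hom_len)
    # the template lies upstream within the flank window
    expect_true(d$template_start >= tr$ref_start - cfg$template_window)
    expect_true(d$template_end <= tr$ref_start)
  }

  # seeded-random substituted sequence: no local template, no signature
  set.seed(75)
  l <- rand_dna(4000); r <- rand_dna(4000)
  sr <- rand_dna(40)
  sq <- paste0(substr(sr, 1, 2), rand_dna(36),
               substr(sr, 39, 40))              # MHs present, template absent
  ref <- genome_store(c(chr1 = paste0(l, sr, r)))
  qry <- genome_store(c(chr1 = paste0(l, sq, r)))
  v <- list(id = "t1", klass = "SUB", ref_chrom = "chr1", ref_start = 4000L,
            ref_end = 4040L, query_chrom = "chr1", query_start = 4000L,
            query_end = 4040L)
  expect_identical(detect_templated_insertion(v, ref, qry, cfg)$mechanism,
                   "NO_SIGNATURE")

  # local template but zero homology at one junction
  sq2 <- rand_dna(40)
  while (substr(sq2, 1, 1) == substr(sr, 1, 1) ||
         substr(sq2, 40, 40) == substr(sr, 40, 40)) sq2 <- rand_dna(40)
  refseq3 <- paste0(substr(l, 1, 3800), sq2, substr(l, 3841, 4000), sr, r)
  ref3 <- genome_store(c(chr1 = refseq3))
  qry3 <- genome_store(c(chr1 = paste0(substr(l, 1, 3800), sq2,
                                       substr(l, 3841, 4000), sq2, r)))
  expect_identical(detect_templated_insertion(v, ref3, qry3, cfg)$mechanism,
                   "NO_SIGNATURE")
})
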