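# Deterministic synthetic-genome generator. Builds a random reference at a
# given GC content, plants mechanism-labelled repair scars by editing the
# reference in place (copying planted micro/homologies, forcing boundary
# mismatches so planted lengths are exact), derives the query genome by
# applying the edits, and emits a deliberately imperfect raw VCF whose
# breakpoints can be shifted to exercise the correction machinery.

.rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# set position i (1-based) to a random base different from `avoid`
.force_diff <- function(rv, i, avoid) {
  rv[i] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  rv
}

# truncated Poisson sampler (rejection)
.rtrunc_pois <- function(n, lambda, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rpois(n, lambda)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic reference/query pair with planted repair events
#'
#' Plants TMEJ indels (2-18 bp junctional microhomology, lengths drawn from
#' a truncated Poisson(8)), SSA deletions (30-60 bp annealing homology,
#' truncated Poisson(40): one repeat copy plus the intervening spacer is
#' deleted), TMEJ templated insertions (complex substitutions whose inserted
#' sequence is copied from ~150 bp upstream with 1-8 bp microhomology at both
#' junctions), NHEJ-like indels (0-1 bp junction identity), tandem
#' duplications (60-150 bp, longer than the repeat screen's flank window so
#' they reach the annotation-stage >90% rule), and repeat-embedded deletions
#' inside planted AT/CAG arrays. A configurable fraction of emitted VCF
#' breakpoints is shifted by up to `miscall_max` bp to emulate caller error.
#'
#' @param events named integer vector of event counts; names among
#'   `tmej_del`, `tmej_ins`, `ssa_del`, `templated_ins`, `nhej`,
#'   `tandem_dup`, `repeat_embedded`
#' @param n_chroms number of chromosomes (default 2)
#' @param gc GC content of the background sequence (default 0.41)
#' @param seed random seed; identical seeds give byte-identical output
#' @param miscall_frac fraction of indel records with a shifted breakpoint
#'   (default 0.3, i.e. 70% of records are emitted at the true position)
#' @param miscall_max maximum |breakpoint shift| in bp (default 30)
#' @param spacing `c(min, max)` gap between consecutive events in bp
#' @param out_dir if non-NULL, write `ref.fa`, `query.fa`, `variants.vcf`
#'   and `truth.tsv` there
#' @return list with `ref`, `query` ([genome_store()]s), `vcf` (raw-variant
#'   data.frame as from [read_variant_vcf()]), `truth` (truth table), and
#'   `paths` when `out_dir` is given
#' @export
simulate_genomes <- function(events = c(tmej_del = 20, tmej_ins = 10,
                                        ssa_del = 10, templated_ins = 5,
                                        nhej = 10, tandem_dup = 5,
                                        repeat_embedded = 5),
                             n_chroms = 2L, gc = 0.41, seed = 1L,
                             miscall_frac = 0.3, miscall_max = 30L,
                             spacing = c(5000L, 7000L), out_dir = NULL) {
  known <- c("tmej_del", "tmej_ins", "ssa_del", "templated_ins", "nhej",
             "tandem_dup", "repeat_embedded")
  stopifnot(all(names(events) %in% known))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  mech <- rep(names(events), times = events)
  n_ev <- length(mech)
  mech <- if (n_ev) sample(mech) else character(0)
  chrom_of <- if (n_ev) sort(rep_len(seq_len(n_chroms), n_ev)) else integer(0)

  ref_seqs <- list(); query_seqs <- list()
  truth <- list(); vcf_rows <- list()
  ev_i <- 0L

  for (ci in seq_len(n_chroms)) {
    idx <- which(chrom_of == ci)
    k <- length(idx)
    gaps <- if (k) as.integer(round(stats::runif(k, spacing[1L],
                                                 spacing[2L]))) else
      integer(0)
    anchors <- 3000L + cumsum(gaps)                    # 0-based event starts
    clen <- (if (k) anchors[k] else 0L) + 4000L
    rv <- .rand_bases(clen, gc)
    evs <- vector("list", k)

    for (j in seq_len(k)) {
      ev_i <- ev_i + 1L
      a <- anchors[j]; m0 <- mech[idx[j]]
      id <- sprintf("ev%05d", ev_i)
      e <- list(id = id, mech = m0, a = a, offset = 0L)

      if (m0 == "nhej" && stats::runif(1) < 0.5) e$mech <- "nhej_ins"
      switch(e$mech,
        tmej_del = {
          m <- .rtrunc_pois(1L, 8, 2L, 18L)
          dl <- sample(seq.int(max(30L, m + 12L), 180L), 1L)
          rv <- .force_diff(rv, a + dl, rv[a])         # kill suffix-side MH
          rv[(a + dl + 1L):(a + dl + m)] <- rv[(a + 1L):(a + m)]
          rv <- .force_diff(rv, a + dl + m + 1L, rv[a + m + 1L])
          e$ref_len <- dl; e$piece <- ""
          e$hom <- m; e$hom_at <- "prefix"
        },
        ssa_del = {
          h <- .rtrunc_pois(1L, 40, 30L, 60L)
          sl <- sample(60:140, 1L)
          rv[(a + h + sl + 1L):(a + 2L * h + sl)] <- rv[(a + 1L):(a + h)]
          rv <- .force_diff(rv, a + h + 1L, rv[a + 2L * h + sl + 1L])
          rv <- .force_diff(rv, a + h + sl, rv[a])     # kill suffix-side MH
          e$ref_len <- h + sl; e$piece <- ""
          e$hom <- h; e$hom_at <- "prefix"
        },
        tmej_ins = {
          m <- .rtrunc_pois(1L, 8, 2L, 18L)
          il <- sample(seq.int(max(30L, m + 12L), 180L), 1L)
          ins <- .rand_bases(il, gc)
          ins[seq_len(m)] <- rv[(a + 1L):(a + m)]
          if (ins[m + 1L] == rv[a + m + 1L]) {
            ins[m + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                          rv[a + m + 1L]), 1L)
          }
          if (ins[il] == rv[a]) {
            ins[il] <- sample(setdiff(c("A", "C", "G", "T"), rv[a]), 1L)
          }
          e$ref_len <- 0L; e$piece <- paste(ins, collapse = "")
          e$hom <- m; e$hom_at <- "prefix"
        },
        nhej = {
          dl <- sample(10:40, 1L)
          rv <- .force_diff(rv, a + dl, rv[a])
          hom <- as.integer(stats::runif(1) < 0.5)
          if (hom == 1L) {
            rv[a + dl + 1L] <- rv[a + 1L]
            rv <- .force_diff(rv, a + dl + 2L, rv[a + 2L])
          } else {
            rv <- .force_diff(rv, a + dl + 1L, rv[a + 1L])
          }
          e$ref_len <- dl; e$piece <- ""
          e$hom <- hom; e$hom_at <- "prefix"
        },
        nhej_ins = {
          il <- sample(10:40, 1L)
          ins <- .rand_bases(il, gc)
          hom <- as.integer(stats::runif(1) < 0.5)
          if (hom == 1L) {
            ins[1L] <- rv[a + 1L]
            if (ins[2L] == rv[a + 2L]) {
              ins[2L] <- sample(setdiff(c("A", "C", "G", "T"),
                                        rv[a + 2L]), 1L)
            }
          } else if (ins[1L] == rv[a + 1L]) {
            ins[1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                      rv[a + 1L]), 1L)
          }
          if (ins[il] == rv[a]) {
            ins[il] <- sample(setdiff(c("A", "C", "G", "T"), rv[a]), 1L)
          }
          e$ref_len <- 0L; e$piece <- paste(ins, collapse = "")
          e$hom <- hom; e$hom_at <- "prefix"
        },
        templated_ins = {
          mh1 <- sample(1:8, 1L); mh2 <- sample(1:8, 1L)
          srl <- sample(seq.int(mh1 + mh2 + 12L, 60L), 1L)
          sql <- sample(seq.int(mh1 + mh2 + 12L, 60L), 1L)
          sq <- .rand_bases(sql, gc)
          sq[seq_len(mh1)] <- rv[(a + 1L):(a + mh1)]
          sq[(sql - mh2 + 1L):sql] <- rv[(a + srl - mh2 + 1L):(a + srl)]
          if (sq[mh1 + 1L] == rv[a + mh1 + 1L]) {
            sq[mh1 + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                           rv[a + mh1 + 1L]), 1L)
          }
          if (sq[sql - mh2] == rv[a + srl - mh2]) {
            sq[sql - mh2] <- sample(setdiff(c("A", "C", "G", "T"),
                                            rv[a + srl - mh2]), 1L)
          }
          t0 <- a - 150L - sql                          # template, upstream
          rv[(t0 + 1L):(t0 + sql)] <- sq
          e$ref_len <- srl; e$piece <- paste(sq, collapse = "")
          e$hom <- mh1; e$hom2 <- mh2; e$hom_at <- "prefix"
          e$template_start <- t0
        },
        tandem_dup = {
          dk <- sample(60:150, 1L)
          e$ref_len <- 0L
          e$piece <- paste(rv[(a - dk + 1L):a], collapse = "")
          e$hom <- dk; e$hom_at <- "suffix"
        },
        repeat_embedded = {
          unit <- sample(c("AT", "CAG"), 1L)
          copies <- if (unit == "AT") 150L else 100L
          arr <- strsplit(strrep(unit, copies), "")[[1L]]
          u <- sample(20:60, 1L)
          rv[(a - u + 1L):(a - u + length(arr))] <- arr
          dl <- sample(60:120, 1L)
          e$ref_len <- dl; e$piece <- ""
          e$hom <- NA_integer_; e$hom_at <- NA_character_
        })
      # breakpoint miscalls exercise the correction machinery
      if (e$mech %in% c("tmej_del", "tmej_ins", "ssa_del", "nhej",
                        "nhej_ins") &&
          stats::runif(1) < miscall_frac) {
        e$offset <- sample(c(-(1:miscall_max), 1:miscall_max), 1L)
      }
      evs[[j]] <- e
    }

    chrom <- sprintf("chr%d", ci)
    ref_str <- paste(rv, collapse = "")
    ref_seqs[[chrom]] <- ref_str

    # apply edits left to right to build the query
    pieces <- character(0); prev <- 0L; qlen <- 0L
    for (j in seq_len(k)) {
      e <- evs[[j]]
      pre <- seq_slice(ref_str, prev, e$a)
      qstart <- qlen + nchar(pre)
      pieces <- c(pieces, pre, e$piece)
      qlen <- qstart + nchar(e$piece)
      prev <- e$a + e$ref_len
      mech_out <- sub("nhej_ins", "nhej", e$mech)
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = e$id,
        mechanism = toupper(mech_out),
        ref_chrom = chrom, ref_start = e$a, ref_end = e$a + e$ref_len,
        query_chrom = chrom, query_start = qstart,
        query_end = qstart + nchar(e$piece),
        planted_hom_len = e$hom,
        planted_hom_seq = if (is.na(e$hom) || e$hom == 0L) "" else
          if (e$hom_at == "prefix") {
            if (e$ref_len > 0L && !nzchar(e$piece))
              seq_slice(ref_str, e$a, e$a + e$hom)
            else substr(e$piece, 1L, e$hom)
          } else substr(e$piece, nchar(e$piece) - e$hom + 1L,
                        nchar(e$piece)),
        second_hom_len = e$hom2 %||% NA_integer_,
        miscall_offset = e$offset,
        stringsAsFactors = FALSE)

      # emitted (possibly miscalled) VCF record
      p <- e$a + e$offset                               # 0-based call start
      anchor <- seq_slice(ref_str, p - 1L, p)
      if (e$ref_len > 0L && !nzchar(e$piece)) {         # deletion-type call
        vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
          id = e$id, chrom = chrom, pos = p,
          ref_allele = paste0(anchor, seq_slice(ref_str, p, p + e$ref_len)),
          alt_allele = anchor, caller_type = "DEL",
          stringsAsFactors = FALSE)
      } else if (e$ref_len > 0L) {                      # substitution: the
        vcf_rows[[length(vcf_rows) + 1L]] <- data.frame( # caller reports the
          id = e$id, chrom = chrom, pos = p,            # deleted side only
          ref_allele = paste0(anchor, seq_slice(ref_str, p, p + e$ref_len)),
          alt_allele = anchor, caller_type = "DEL",
          stringsAsFactors = FALSE)
      } else {                                          # insertion-type call
        vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
          id = e$id, chrom = chrom, pos = p,
          ref_allele = anchor, alt_allele = paste0(anchor, e$piece),
          caller_type = "INS", stringsAsFactors = FALSE)
      }
    }
    pieces <- c(pieces, seq_slice(ref_str, prev, nchar(ref_str)))
    query_seqs[[chrom]] <- paste(pieces, collapse = "")
  }

  ref <- genome_store(unlist(ref_seqs))
  query <- genome_store(unlist(query_seqs))
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame()
  vcf <- if (length(vcf_rows)) do.call(rbind, vcf_rows) else data.frame(
    id = character(), chrom = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(),
    caller_type = character(), stringsAsFactors = FALSE)
  out <- list(ref = ref, query = query, vcf = vcf, truth = truth)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(ref = file.path(out_dir, "ref.fa"),
               query = file.path(out_dir, "query.fa"),
               vcf = file.path(out_dir, "variants.vcf"),
               truth = file.path(out_dir, "truth.tsv"))
    write_fasta(ref, paths[["ref"]])
    write_fasta(query, paths[["query"]])
    write_variant_vcf(vcf, ref, paths[["vcf"]])
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Compare pipeline annotations against the generator truth table
#'
#' @param truth truth data.frame from [simulate_genomes()]
#' @param annotations annotation data.frame (final mechanisms assigned)
#' @param repetitive_ids ids removed by the repeat filter
#' @return list with `confusion` (planted x detected table), `recovery`
#'   (fraction of non-repeat-planted events receiving their planted label),
#'   `hom_error` (|planted - detected| homology length for matched indels)
#' @export
truth_compare <- function(truth, annotations, repetitive_ids = character()) {
  if (!all(annotations$id %in% truth$event_id)) {
    stop("annotation ids absent from truth table")
  }
  expected <- ifelse(
    truth$mechanism %in% c("TMEJ_DEL", "TMEJ_INS"), "TMEJ",
    ifelse(truth$mechanism == "SSA_DEL", "SSA",
    ifelse(truth$mechanism == "NHEJ", "NO_SIGNATURE",
    ifelse(truth$mechanism == "TEMPLATED_INS", "TEMPLATED_INS",
    ifelse(truth$mechanism == "TANDEM_DUP", "TANDEM_DUP", "REPEAT")))))
  detected <- rep("MISSING", nrow(truth))
  mi <- match(annotations$id, truth$event_id)
  detected[mi] <- annotations$mechanism
  detected[truth$event_id %in% repetitive_ids] <- "REPEAT"
  non_repeat <- expected != "REPEAT"
  hom_err <- abs(annotations$hom_len -
                   truth$planted_hom_len[match(annotations$id,
                                               truth$event_id)])
  list(confusion = table(planted = expected, detected = detected),
       recovery = mean(detected[non_repeat] == expected[non_repeat]),
       hom_error = hom_err[!is.na(hom_err)])
}
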