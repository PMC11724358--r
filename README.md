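# dsbsig

Infer the DNA double-strand-break (DSB) repair mechanism behind structural
variants, from genome assemblies.

## What it does, and for whom

Repair of a DSB by homologous-recombination-derived pathways leaves a
sequence scar at the variant junction. **TMEJ** (polymerase theta-mediated
end joining) anneals 2–18 bp microhomologies and leaves that microhomology
at the indel breakpoint; **SSA** (single-strand annealing) uses 20–60 bp
homologous repeats, deleting one copy plus the intervening sequence; TMEJ
**templated insertions** are complex substitutions whose inserted sequence
copies nearby DNA, with a microhomology at each junction. `dsbsig` is for
genome biologists who have a chromosome-level reference, a high-accuracy
query assembly, and raw ≥10 bp indel calls (VCF 4.2 with explicit
sequences), and want per-variant mechanism annotations plus a
population-level view of the micro/homology length distribution.

The pipeline: correct each call's breakpoints by re-locating its 2 kb
reference flanks in the query (plus-strand local alignment; overlapping
placements trimmed up to 3 rounds), remove repetitive variants with a
built-in tandem-repeat detector (TRF-style thresholds: match +2, mismatch
−5, identity ≥ 80%, score ≥ 50, period ≤ 500), measure junctional
micro/homology, and split the pooled length distribution at a
local-regression minimum *b*: hom ≤ *b* → TMEJ, hom > *b* → SSA (human
setting: *b* = 29 bp). Each side is then modelled as `w·Pois(λ)` with λ
boxed to [5, 20] (TMEJ) and [37, 50] (SSA); the components' tail mass across
the baseline quantifies expected misannotation.

## Worked example

The package includes a deterministic generator that plants
mechanism-labelled repair scars in a synthetic genome and emits a
deliberately imperfect VCF:

```r
library(dsbsig)
sim <- simulate_genomes(events = c(tmej_del = 8, tmej_ins = 4, ssa_del = 4,
                                   templated_ins = 3, nhej = 4,
                                   tandem_dup = 2, repeat_embedded = 3),
                        seed = 42)
res <- run_pipeline(sim$ref, sim$query, sim$vcf, run_config(),
                    out_prefix = "out/run")
res$tallies
#>       INS       DEL       SUB    REPEAT EXCEPTION
#>         7        15         3         3         0
head(res$annotations[, c("id", "klass", "mechanism", "hom_len")], 5)
#>        id klass     mechanism hom_len
#> 1 ev00001   SUB TEMPLATED_INS       7
#> 2 ev00002   DEL          TMEJ       8
#> 3 ev00003   DEL          TMEJ       7
#> 4 ev00004   INS    TANDEM_DUP     100
#> 5 ev00005   INS          TMEJ       6
res$summary
#> mechanism summary: baseline 29 bp
#>   TMEJ: lambda 7.86 weight 11.3 (1.4e-07% above baseline)
#>   SSA:  lambda 50.00 weight 5.8 (0.0917% at/below baseline)
```

Reading the output: the three planted repeat-embedded deletions were removed
(`REPEAT = 3`), the three templated insertions were recognized from their
local template plus two junction microhomologies, the 100 bp tandem
duplication was excluded by the strict >90% homology/size rule, and every
indel received its planted mechanism (`truth_compare` reports 100% label
recovery here). With only 4 SSA events the histogram has too little mass
for an interior minimum, so the baseline falls back to 29 bp with a warning
and the SSA rate pins at its box edge — both are expected on inputs this
small. `run_pipeline` also writes the TSV/BED/CSV tables, a summary JSON,
run metadata, and three summary plots.

A command-line front end wraps the same functions:

```sh
Rscript -e 'dsbsig::cli_main()' simulate --out sim --seed 42
Rscript -e 'dsbsig::cli_main()' run --ref sim/ref.fa --query sim/query.fa \
    --vcf sim/variants.vcf --out sim/res
```

## Documentation

See `vignettes/dsb-repair-signatures.Rmd` for the model, the design
decisions (local flank placement with inner-end anchoring, the
mismatch-tolerant homology extension rule, why tandem duplications survive
to the annotation stage), the synthetic world's assumptions, and known
limitations.
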