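---
title: "Inferring DSB repair mechanisms from genome assemblies"
author: "dsbsig developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring DSB repair mechanisms from genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a DNA double-strand break (DSB) is repaired by a homologous-
recombination-derived pathway, the repair leaves a sequence scar at the
breakpoint. Polymerase theta-mediated end joining (TMEJ) anneals short
microhomologies (2–18 bp) exposed by end resection and leaves that
microhomology at the junction of the resulting indel. Single-strand
annealing (SSA) uses much longer homologous repeats (20–60 bp), deleting one
repeat copy plus the intervening sequence. A third TMEJ outcome — the
templated insertion — arises when synthesis switches templates mid-repair,
producing a complex substitution whose inserted sequence copies nearby DNA
and whose two junctions each carry a microhomology. Non-homologous end
joining (NHEJ), by contrast, leaves short (~1–5 bp) random indels without a
signature and is deliberately out of scope: its randomness makes retrospective
annotation unreliable.

Given a chromosome-level reference genome, a high-accuracy query assembly,
and raw structural-variant calls (VCF 4.2 with explicit REF/ALT sequences,
≥10 bp), `dsbsig` infers which of these mechanisms most plausibly produced
each non-repetitive insertion, deletion, or complex substitution.

## Pipeline

1. **Ingestion** (`read_variant_vcf`): records whose allele-length difference
   is below `min_sv_size` (10 bp) are dropped; symbolic ALTs are skipped
   (they carry no breakpoint sequence to work with).
2. **Raw repeat screen** (`repeat_screen_raw`): the allele body plus
   `repeat_find_len` (50 bp) of flank is scanned by the internal
   tandem-repeat detector. Repetitive variants are removed: the same
   repetitive variant can be formed by replication slippage or unequal
   crossover, so no mechanism call is defensible.
3. **Breakpoint correction** (`correct_variant`): the `sv_find_len` (2 kb)
   reference flanks of each call are located in the query assembly by a
   seed-and-refine plus-strand local alignment. From the placements of the
   two flank inner ends in both genomes: separated in reference + contiguous
   in query → deletion; contiguous in reference + separated in query →
   insertion; separated in both → complex-substitution candidate. Flanks
   that *overlap* in the query (tandem-array context) are trimmed at their
   inner ends (the observed overlap + 1 bp, guaranteeing progress) and
   re-extracted at full length, up to three rounds; persistent overlap is an
   EXCEPTION.
4. **Substitution verification** (`verify_substitution`): a candidate whose
   substituted sequences are nested (prefix + suffix of the shorter covering
   it) is really an indel with a shifted breakpoint; it is reclassified,
   choosing the prefix/suffix split that makes the corrected edit
   reproduce the query exactly. Identical substituted sequences are a caller
   artifact (EXCEPTION).
5. **Second repeat screen** (`rescreen_corrected`): corrected coordinates can
   shift into an array the first pass could not see.
6. **Signature annotation** (`junction_microhomology`,
   `detect_templated_insertion`, `remove_tandem_duplications`): junctional
   micro/homology for indels, the two-microhomology + local-template test
   for substitutions, and removal of insertions whose homology exceeds 90%
   of their size (tandem duplications, strict inequality).
7. **Mechanism classification** (`find_baseline`, `fit_dual_poisson`): the
   pooled micro/homology length histogram is split at a local-regression
   minimum; lengths at or below the baseline are TMEJ, above it SSA. Each
   side is then modelled as a weighted Poisson component with the rate boxed
   to 5–20 bp (TMEJ) and 37–50 bp (SSA); the components' mass on the wrong
   side of the baseline quantifies expected misannotation.

## Key design choices

**Local, not global, flank placement.** The flank of a miscalled breakpoint
contains bases at its inner end that are absent from the other genome.
A placement forced to consume the whole flank pushes those bases into the
alignment and corrupts the inner coordinate. We therefore use a local
alignment (match +1, mismatch −2, gap open 4, gap extend 1 — constants
approximating a megablast-like regime) and carry the aligned *pattern range*:
unaligned inner overhang shrinks the flank's effective inner end in the
reference before the classification rule is applied. The inner terminus is
additionally required to sit at the end of a run of ≥ 8 consecutive exact
matches: without this anchor, a few chance matches in an unplaceable
overhang (expected every few hundred variants at 25% per-base identity)
would shift the inferred breakpoint by a handful of bases and break the
exact reference-to-query round trip. With this convention,
breakpoints shifted into flanking homology are corrected without any trim
round, and the trim loop is exercised exactly where the overlap condition
genuinely arises — variants embedded in tandem arrays. Acceptance thresholds
for a hit (identity ≥ 0.9 over ≥ 0.8 of the flank) are config-exposed; no
published value exists for them.

**Junctional micro/homology by direct string comparison.** A seed-based
aligner cannot find 1–2 bp matches (its word size is far larger), yet the
empirical microhomology distribution peaks at 2 bp. We compare the variant
sequence V directly against the sequence 3′ of the junction (prefix side)
and 5′ of it (suffix side), reporting the longer side (ties prefer the
prefix). Matches shorter than `mismatch_free_len` (10 bp) must be exact.
Longer matches may extend through mismatches, but three conditions hold:
the whole match keeps ≥ 90% running identity, the *extension beyond the
exact core* keeps ≥ 90% identity on its own, and a match ends on a matching
base. The second condition is deliberate: without it, a single chance match
two bases after an exact 10-mer would extend the reported homology (11/12 =
92%), so exactly-planted homologies would be over-reported roughly once per
few hundred junctions. Requiring nine matches per tolerated mismatch in the
extension makes chance extension vanishingly rare while still absorbing the
occasional substitution inside a genuine long SSA homology. `min_signal_len`
defaults to 2 bp: a 1 bp "match" occurs by chance with probability ~0.25.

**Tandem-repeat detector.** The detector captures the intent of the classic
TRF parameterisation 2 5 7 80 10 50 500: match +2, mismatch −5, array
identity ≥ 80%, score ≥ 50, period ≤ 500, ≥ 2 copies; indels within the
array are not modelled. For each period p it compares the sequence with
itself shifted by p, prunes periods that cannot host a qualifying array
(no window reaches the score bound — a sound necessary condition computed
from prefix sums), and otherwise enumerates windows bounded by match runs
(an optimal array always starts and ends on a match). For sequences up to a
few hundred bp this enumeration is exhaustive and provably equivalent to an
all-window oracle; for long degenerate arrays the number of runs merged into
one window is capped at 64, which cannot bind below ~320 bp at the 80%
identity floor. A variant is repetitive if any qualifying array occurs in
the scanned window (body ± `repeat_find_len`); the open question of *how
much* of a flank must be covered before a variant is discarded is thereby
resolved as "any array at all", the most conservative choice.

**Why tandem duplications survive to the annotation stage.** A duplication
of k bp shows two copies only if the scan window spans both. With the
default 50 bp flank window, duplications longer than 50 bp cannot be seen as
arrays and correctly fall through to the annotation-stage rule (homology >
90% of variant size, strict) — the same two-stage behaviour an external
TRF-then-annotate toolchain exhibits. The synthetic generator plants tandem
duplications of 60–150 bp; shorter ones are legitimately consumed by the
repeat screen.

**Baseline search.** The histogram over 10–60 bp is smoothed by local linear
regression (tricube weights, span 0.3 — both unpublished constants, exposed
as config) and the global minimum of the smoothed curve is the baseline.
If the histogram has mass on only one side of 20 bp, or the minimum sits on
the search boundary, the fixed human-genome fallback of 29 bp is used with a
warning. A breakpoint miscalled by more than the length of a small
insertion can be absorbed by the aligner as an ordinary gap, leaving both
flank pairs contiguous; such calls surface as EXCEPTION (`no_net_change`)
rather than as a guessed variant. The least-squares Poisson fits weight
each bin by its
Poisson-variance estimate (floored at 1). Overlap fractions are computed
from the fitted components' exact CDFs — the fitted-mass definition; the
empirical-count alternative is not implemented.

## The synthetic world

`simulate_genomes` builds i.i.d. background sequence at GC 0.41 (the human
genome-wide value), spaces events ≥ 5 kb apart so 2 kb flanks never
interact, and plants:

* TMEJ deletions/insertions, junction microhomology ~ Poisson(8) truncated
  to [2, 18] — the biochemical TMEJ range with its observed small-length
  mode;
* SSA deletions, annealing homology ~ Poisson(40) truncated to [30, 60]
  (the upper half of the cited 20–60 bp range, matching the ~35 bp peak of
  the empirical distribution), with a 60–140 bp spacer so homology never
  exceeds 90% of the variant;
* templated insertions: the substituted sequence is copied from ~150 bp
  upstream with independently drawn 1–8 bp microhomologies at both
  junctions, and the caller is assumed to report only the deleted side;
* NHEJ-like indels with 0–1 bp of chance junction identity;
* tandem duplications (60–150 bp) and deletions embedded in planted AT/CAG
  arrays.

Every planted boundary is forced to mismatch one base past the planted
homology, so planted lengths are exact by construction. A configurable 30%
of indel records are emitted with a breakpoint shifted uniformly by 1–30 bp
in either direction — the caller-error model the correction stage must undo.
Under breakpoint-representation ambiguity, a shift *within* a planted
homology is a legitimate alternative representation; the corrected variant
then carries a reduced junctional homology (max of the two sides), which is
a property of the genomes, not an implementation error. Chromosome count,
genome length, and GC are parameters; the genome is sized from the event
list, so an "overcrowded" configuration cannot arise by construction.

What the generator does **not** emulate: real repeat landscapes (only salted
uniform arrays), assembly or sequencing error (the query is exact), nested
or overlapping variants, minus-strand rearrangements, and ancestral/derived
polarity. A green end-to-end test therefore establishes the algorithmic
contracts — flank relocation, trim logic, signature arithmetic,
distributional separation — not performance on real pangenome data.

## Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open; VCF positions are converted
at the boundary and BED output is 0-based half-open. Only the plus strand is
ever searched. Any window containing N never matches (N is a permanent
mismatch, including N vs N). Equal-scoring flank placements resolve to the
smallest query start, then the longest alignment. Corrected variants whose
net size falls below `min_sv_size`, whose substituted sequences are
identical, or whose flanks cannot be extracted at ≥ 200 bp are EXCEPTIONs
with machine-readable reason codes. The substitution-verification
containment test is exact; a mismatch-tolerant variant (for lower-accuracy
assemblies) would be a natural extension but is intentionally absent.

## Known limitations

* NHEJ is not annotated (no reliable signature), and no attempt is made to
  assign ancestral vs derived alleles.
* Interspersed-repeat screening is an optional hook
  (`cfg$interspersed_hook`); without an external repeat library the package
  only removes tandem arrays.
* The dual-Poisson model is descriptive, not a likelihood fit; rates pinned
  at a box edge indicate a side with too little mass to constrain.
* Runtime is dominated by two ~2 kb local alignments per variant
  (~0.2 s/variant single-threaded at desk scale); `workers` parallelises
  per-variant work without changing any output byte.
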