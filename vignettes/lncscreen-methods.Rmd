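---
title: "Methods: the lncscreen identification cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lncscreen identification cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lncscreen)
```

# Scope and model

`lncscreen` implements a screen for treatment-responsive long non-coding
RNAs over a transcript catalogue: differential expression, a non-coding
filter, positional classification against gene loci, a hierarchical
small-RNA precursor taxonomy, antisense CDS pairing, and
tissue-specificity / RT-qPCR quantification. The package deliberately
starts *after* read alignment and transcript assembly: its inputs are
assembled transcript sequences, an annotation, and per-transcript read
counts. Upstream aligner/assembler choices, and external coding-potential
classifiers, are out of scope (the latter can be injected as a label
table).

# Differential expression

Expression is quantified as RPKM, `1e9 * count / (total_mapped *
length_nt)`. Two conventions matter:

* **Library sizes are full-library totals.** `total_mapped` is the
  number of mapped reads in the whole library, not the sum over the
  transcripts being analyzed. The synthetic datasets carry nominal
  totals of 10^6 per condition; when totals are omitted,
  `call_differential()` falls back to column sums, which is only
  appropriate when the table covers the full transcriptome.
* **Fold change uses a pseudocount.** One read is added to each
  condition's pooled count before the ratio, so transcripts expressed in
  only one condition (a real feature of tissue- and stress-specific
  lncRNAs) give finite fold changes. Reported RPKM columns are
  un-pseudocounted.

The count test is pluggable because screens of this kind rarely agree on
one: the default is a two-sided exact binomial test of the pooled
treatment count against the library-size proportion
(`binom.test(t, c + t, p = N_t / (N_c + N_t))`), which is exact,
dependency-free and appropriate for pooled counts without a replicate
dispersion model. Replicates are summed before testing; the interface
exposes per-replicate matrices so a dispersion-aware test can be
substituted (`test_fun`). P-values are adjusted with Benjamini–Hochberg
(`stats::p.adjust`), and a transcript is called responsive only when
*both* gates pass: |fold| beyond the 2-fold threshold *and* FDR < 0.001.

# The non-coding filter

An ORF is an `ATG` followed by an in-frame stop in one of the three
forward frames; `aa_length` counts Met and excludes the stop
(`ATGAAATAA` → 2 AA). Three conventions are deliberate:

* **Forward frames only** — assembled transcripts are
  orientation-resolved, so reverse-frame ORFs are not meaningful here.
* **A stop codon is required** — an ATG running off the 3' end is not an
  ORF. This is conservative and deterministic; the alternative (count
  open-ended ORFs) would make the screen depend on assembly truncation.
* **Codons containing `N` never match** ATG or a stop.

The retention rule is strict on both sides: length > 200 nt and longest
ORF < 80 AA. The 80 AA default follows the screen definition used
throughout the analysis (a stricter 70 AA variant appears in some
definitions of lncRNAs; the threshold is a parameter, so either is one
keystroke away).

The coding-potential stage preceding the length/ORF rule is a pluggable
stand-in for external classifiers. The built-in heuristic calls a
transcript coding iff the longest-ORF span (ATG through stop,
`3*(aa+1)` nt) exceeds half the transcript length, or the ORF reaches
100 AA. This is intentionally simple — the reproducible core of the
screen is the length/ORF rule — and an external label table, when
supplied, overrides it verbatim.

# Positional classification

Intervals are handled 0-based half-open internally (GFF3's 1-based
inclusive coordinates are converted at the I/O boundary), which removes
off-by-one ambiguity from overlap arithmetic; overlap requires at least
one shared nucleotide. Classification is against *gene spans*, not exon
models, so a transcript inside an intron counts as intragenic — the
taxonomy here describes position relative to gene loci, not splicing
structure.

The cascade is: no gene overlap → intergenic; only opposite-strand
overlap → antisense; same-strand overlap with full containment in one
gene span → intragenic; same-strand overlap crossing a boundary →
overlapping. When both same- and opposite-strand overlaps exist,
same-strand evidence wins by default (`strand_precedence = "sense"`):
the antisense class is defined against sense genes and is typically
small, so it should not absorb transcripts with direct same-strand
evidence. The precedence is configurable because the opposite convention
is defensible. The supporting gene is the maximal-overlap gene, ties
broken by smaller gene start. Candidate overlaps are found with
`GenomicRanges::findOverlaps`; the test suite cross-checks the full
cascade against a brute-force every-pair oracle.

# Alignment and the precursor hierarchy

BLAST-style search is replaced by an exact Smith–Waterman local aligner
(Rcpp) so results are bit-reproducible with no external binaries, and
zero-mismatch short-read mapping is replaced by exact substring matching
(`Biostrings::matchPDict`), which is semantics-preserving: a read maps
with zero mismatches iff it occurs as an exact substring of the target
or its reverse complement.

Aligner conventions:

* scoring defaults match +2, mismatch −3, gap open −5, gap extend −2; a
  k-column gap costs `open + (k−1)·extend` (the opening column carries
  the open penalty alone);
* `hit_len` counts all alignment columns *including* gap columns, so a
  per-side coverage `100·hit_len/length` can exceed 100 when gaps
  inflate the alignment — this matches how alignment reports in the
  field print coverage, and the package reproduces such >100% values
  exactly from printed lengths;
* traceback is deterministic: ties prefer the diagonal, then the gap
  consuming the query, then the gap consuming the subject; inside a gap,
  closing beats extending. The optimum *score* is tie-free by
  definition and is what the oracle tests compare;
* percentages are rounded to 2 decimals for reporting only;
  classification gates always use unrounded values.

The precursor taxonomy is a fixed first-match hierarchy: miRNA precursor
(alignment identity > 99% and precursor coverage > 90%), then
shRNA/siRNA precursor (distinct exact-matching reads in both libraries),
then siRNA precursor (siRNA support alone), then other. Decisions made
where the convention was genuinely open:

* **Coverage side.** The >90% coverage gate applies to the *precursor*
  (the shorter sequence): an lncRNA hosts a precursor when the precursor
  is essentially fully contained, regardless of how long the host is.
  `coverage_side = "lncrna"` selects the other reading.
* **Identity per best alignment.** The >99% identity gate is evaluated
  on the single best-scoring local alignment per (lncRNA, precursor)
  pair, both orientations searched.
* **No shRNA-only class.** The taxonomy has no class for shRNA support
  without siRNA support; such transcripts fall to `other` but carry a
  `shrna_only` flag so the anomaly is visible rather than silently
  absorbed.
* **`min_reads = 1`.** Any distinct exact read is support; the
  threshold is exposed because "numerous reads" is not a number.
* **Both strands searched** in read matching by default, since siRNA
  duplexes yield reads of both polarities.

# CDS pairing

`other`-class, non-antisense lncRNAs are aligned against the CDS set in
plus/minus orientation (query versus reverse complement of subject).
The pass gate is identity > 90% and coverage > 90%, where coverage
defaults to the *larger* of the two per-side coverages: published
examples of near-perfect antisense pairs include a 181-column alignment
of a 1258-nt lncRNA to a 183-nt CDS — 14.4% query coverage, 98.9%
subject coverage — so a both-sides or query-only reading would reject
pairs the field reports. Both alternative modes are available
(`coverage_mode = "both"` / `"query"`). The report columns satisfy
`Percent_query_aligned · Query_len = Percent_Sbject_aligned · Sbject_len
= 100 · Hit_len` up to rounding.

# Tissue specificity and qPCR

Tissue specificity uses the tau index, `Σ(1 − vᵢ/v_max)/(n−1)`: 0 for a
flat positive profile, 1 for single-tissue expression, scale-invariant,
and robust for small tissue panels. The metric is a package choice —
screens often assert specificity without defining a score — and the call
threshold (default tau ≥ 0.8) is configurable. All-zero profiles are an
error at the single-profile level and `NA` in matrix scoring.

The Pfaffl ratio is `E_target^ΔCp_target / E_ref^ΔCp_ref` with
efficiencies ≥ 1 and ΔCp taken as **control − treatment** for both
genes. Under this orientation a treatment-upregulated target (lower Cp
under treatment) gives a ratio > 1. The sign convention is the single
most error-prone spot in relative quantification, so `pfaffl_ratio()`
documents it and exposes `flip = TRUE` rather than guessing.

# The synthetic-data generator

`simulate_lnc_dataset()` emulates, with planted ground truth, exactly
the inputs the cascade consumes. Defaults (48 planted lncRNAs + 52
decoys = 100 transcripts) were chosen once to mirror the shape of a
real screen at toy scale:

* positional classes 30/10/4/4 (intergenic-dominant, few antisense and
  overlapping), precursor classes 3/6/15/24 (miRNA ≪ shRNA/siRNA <
  siRNA < other), ~5:1 up:down regulation at a planted 4-fold change;
* counts are Poisson with per-replicate means of 150–300 reads (2
  replicates per condition), so planted 4-fold changes pass FDR < 0.001
  with high margin;
* hosts embed verbatim precursor copies; siRNA hosts shed 10–50 reads
  of 21–24 nt from both strands; shRNA/siRNA hosts shed into both
  libraries; CDS partners are reverse complements of lncRNA subranges
  with 10-nt random flanks (precursor/CDS plants are verified against
  the default gates at generation time, so the planted margin is
  guaranteed, not probabilistic);
* decoys: coding (ORF ≥ 100 AA), short (< 200 nt), long-ORF (80–99 AA
  but non-coding by span fraction) and unchanged (fold 1) transcripts;
* background sequence is i.i.d. uniform over {A,C,G,T}; planted lncRNA
  backgrounds are rejection-sampled to keep their longest ORF ≤ 40 AA
  so no planted transcript sits near the 80 AA boundary by accident.

Determinism: all randomness flows from one `set.seed(seed)` call (the
caller's RNG state is restored afterwards); the same seed reproduces the
emitted files byte for byte.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic expression distributions and
overdispersion (counts are Poisson), GC bias and sequencing error,
repeat-induced multi-mapping, near-duplicate gene families (uniform
background makes spurious high-identity alignments vanishingly rare,
which real genomes do not), splicing structure (gene spans only), and
partially degraded precursor copies. The end-to-end recovery results
demonstrate correctness of the cascade's logic under clean margins, not
robustness to noisy biology.

# Problem sizes and verification

The test suite verifies each primitive against an independent oracle:
the aligner against a naive full-matrix reference on 100 random 60-nt
pairs (plus non-default scoring), the read matcher against a
sliding-window scan on 100 cases, the ORF finder against exhaustive
enumeration on 100 random 500-nt transcripts and on dense enumerations
of short {A,T,G} sequences, and BH against brute-force step-up
enumeration on random vectors of length ≤ 20. End-to-end recovery runs
on the 100-transcript default dataset, and the differential stage is
checked across 20 replicate seeds (full recovery, zero false calls
expected in ≥ 19). These sizes keep the whole suite under a couple of
minutes on one CPU while leaving each check statistically meaningful.

# Known limitations

* The default binomial count test ignores replicate dispersion; with
  real replicated data a dispersion-aware test should be plugged in.
* RPKM with external library totals is the only normalization offered;
  compositional effects (most of the transcriptome changing) are the
  user's responsibility, as in any ratio-based screen.
* The built-in coding-potential heuristic is a deliberately simple
  stand-in; for publication-grade screens inject a real classifier's
  labels.
* Positional classification uses gene spans, so exon-level
  sense/antisense fractions and bidirectional-promoter classes are not
  available.
* Hairpin-structure validation of miRNA precursor candidates (RNA
  folding) is out of scope; an alignment-level call is necessary but
  not sufficient evidence of precursor function.

# Stage-level entry points

The pipeline orchestrator (`run_pipeline()`) and the exported per-stage
functions (`call_differential()`, `filter_lncrna_candidates()`,
`classify_position()`, `classify_mirna_precursor()`,
`match_reads_exact()`, `hierarchical_classify()`, `pair_with_cds()`,
`tissue_specificity()`, `pfaffl_ratio()`) are the package's API; the
shipped `inst/scripts/lncpipe.R` wrapper exposes `generate` and `run`
from a shell with every threshold as a flag. Gates can be neutralized
individually (e.g. `fold_threshold = 1, fdr_threshold = 1` passes every
transcript through the differential stage), which is the supported way
to "disable" a stage while keeping the cascade's shape.
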