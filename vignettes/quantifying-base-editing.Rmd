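---
title: "Quantifying base-editing outcomes from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ampliconBE)
```

## The measurement problem

Cytidine base editors (nickase-Cas9 fused to a cytidine deaminase and a
uracil glycosylase inhibitor) convert C:G base pairs to T:A within a small
"activity window" of the 20-base protospacer, without a double-strand
break. The standard readout is targeted amplicon deep sequencing: PCR
amplicons spanning the protospacer are sequenced to a depth of thousands of
single-end reads, and the experimental questions are quantitative —

* what fraction of alleles carries a C→T conversion at each protospacer
  cytosine (on-target efficiency),
* how much conversion occurs at known off-target loci with partial
  protospacer homology (specificity),
* how many reads carry insertions or deletions near the nick site
  (the unwanted byproduct base editing is supposed to avoid), and
* whether any small off-target signal is real, given that sequencing
  errors, PCR errors and spontaneous deamination also produce apparent
  C→T calls.

`ampliconBE` implements this measurement pipeline end to end, together
with a synthetic read generator so every stage can be verified against
known injected truth.

## Pipeline model

### Quality masking

Each base call carries a Phred quality $Q$, with error probability
$10^{-Q/10}$. Base calls failing a threshold (default $Q = 30$,
i.e. 0.1% error) are replaced by the placeholder `N` before alignment,
so unreliable calls contribute neither to alignment scores nor to base
tallies. Two dialects are first-class because amplicon studies use both
conventions: `strict_below` masks $Q < 30$ (genomic-locus mode) and
`at_or_below` masks $Q \le 30$ (in-vitro substrate mode). The sample
sheet's mode selects the dialect; both are exposed in
`mask_low_quality()`.

### Local alignment

Masked reads are aligned to the amplicon reference with an affine-gap
Smith–Waterman aligner (compiled code, `align_reads()`). Scoring defaults
are match $+5$, mismatch $-4$, gap open $10$, gap extend $1$ (a gap of
length $L$ costs $10 + L$). These EMBOSS-water-like values make a single
two-base gap ($-12$) cheaper than three scattered mismatches, which is the
right bias when the downstream indel definition only counts contiguous
events of two or more bases. All four values are configurable. `N` scores
0 against everything, so masked bases are alignment-neutral.

Numerical determinism choices, stated once:

* Ties in the dynamic programme are broken by preferring a
  match/mismatch step over a deletion over an insertion, and by
  preferring gap extension over re-opening inside a run; this
  left-shifts gaps on the reference. The traceback starts at the maximal
  cell with the smallest reference index. Output is therefore a single
  deterministic optimum; co-optimal alignments are not enumerated.
* Reads whose best score falls below 60% of the perfect-match score for
  their length are rejected and counted (reason `low_score`). The floor
  is a package default — published analyses of this kind rarely state
  one — and is configurable in `alignment_scoring()`.
* Each read is also aligned in reverse complement and the better
  orientation kept (ties go forward). Amplicon orientation is normally
  fixed by the primers, but this prevents silent mis-tallying of
  edge-case inputs.

### Per-position tallies and editing percentages

`tally_bases()` counts A/C/G/T per reference offset over aligned reads;
`N` and gap columns are excluded, so depth at an offset can be smaller
than the number of aligned reads. `compute_editing()` converts counts into
per-cytosine percentages on the protospacer strand:

$$\%\,\mathrm{C{\to}T}_n = 100 \cdot \frac{T_n}{A_n + C_n + G_n + T_n}$$

Protospacer positions are numbered 1–20 with position 1 PAM-distal, so an
activity window of "C4–C8" means protospacer positions 4–8. For
protospacers on the minus strand of the sequenced amplicon, G→A counts on
the sequenced strand are reported as C→T on the protospacer strand (the
editor converts the C:G pair). Positions with zero depth are flagged
undefined rather than reported as 0%. Reads carrying indels stay in the
editing denominator; a gap column simply contributes no call at that
position. (Whether indel reads should be excluded from per-cytosine
percentages is a genuine dialect choice in this field; keeping them is
this package's declared behaviour.)

Reference offsets are 0-based half-open everywhere internally and 1-based
only in reports; this is stated once to prevent off-by-one drift. Locus
configs may anchor the protospacer by explicit offset or by sequence
search (which must hit exactly once over both strands).

### Windowed indel counting

`count_indels()` counts a read as indel-positive if it carries at least
one insertion or deletion of ≥ 2 bases anchored inside a 30-base window
centred on the nickase cut site. Anchoring rules (the window definition
needs a fixed convention to be deterministic):

* the nick boundary is between protospacer positions 17 and 18 (3 nt 5′
  of the PAM, the canonical SpCas9 nick), configurable per locus;
* the window is `[nick − 15, nick + 15)` — a symmetric split is the only
  non-arbitrary reading of "a 30-base window around" the site;
* a deletion is anchored at its first deleted reference base, an
  insertion at the reference base immediately 5′ of the inserted run;
* a read counts at most once.

One-base events are ignored by design: single-base indels are the
dominant sequencing/PCR artefact class at homopolymers, while
nuclease-induced indels are typically ≥ 2 bases.

### Detection limit and significance

With a $Q$ threshold of 30 the residual error probability is 0.001;
assuming errors distribute uniformly over the four bases, the lower limit
for calling a specific substitution is $0.1\%/4 = 0.025\%$
(`detection_limit()`). Observed percentages at or below this limit are
never interpreted: significance is not computed for them and they are
classified undetectable.

Above the limit, apparent editing must still be separated from
spontaneous deamination and PCR error, which is done empirically: every
treated locus requires untreated-control replicates, and
`test_vs_control()` applies the classical two-tailed Student's *t*-test
(pooled variance, not Welch) on replicate-level percentages. A position
is *detectable* only when its percentage exceeds the detection limit
**and** $P < 0.05$. Replicate aggregation always computes per-replicate
percentages first and then mean ± s.d. across replicates; reads are never
pooled across replicates. Raw p-values are reported (no multiple-testing
correction, matching practice for these small per-locus panels); an
optional Benjamini–Hochberg adjustment is available in
`aggregate_editing(p_adjust = TRUE)` but off by default.

Degenerate inputs are handled explicitly: identical constant replicate
vectors give $p = 1$; zero variance in both groups with different means
leaves the t statistic undefined, so significance is *not computed*
(flagged, and the position is not detectable) rather than forced to 0 —
with two or three replicates of sparse counts this is the case that
otherwise manufactures false positives. Fewer than two replicates in
either group also leaves $p$ undefined and flagged.

Loci whose untreated controls show more than 5% indel reads (configurable)
are flagged indel-unreliable and excluded from indel reporting;
repetitive or homopolymeric amplicons can show large artefactual deletion
rates in untreated samples.

### Specificity statistics

* `specificity_ratio()` divides on-target by off-target efficiency. When
  off-target editing is at or below the detection limit, the limit itself
  (0.025%) is substituted and the ratio flagged `lower_bound` — it is a
  "≥" statement, never a point estimate.
* `fold_change()` is a plain ratio with an integer-fold label
  ("37-fold"); a zero denominator is imputed to the limit and flagged.
* `editing_indel_ratio()` divides the window-mean C→T percentage by the
  indel-read percentage, with the same imputation rule for indel-free
  loci.
* Aggregate "specificity improvement" across cytosines is computed as the
  arithmetic mean of per-cytosine ratio quotients
  (`specificity_improvement()`); the mean-of-ratios versus
  ratio-of-means choice is genuinely open in this field, so both are
  returned and the default is labelled in the output.
* `fit_dose_response()` regresses off-target on on-target editing across
  a titration (ordinary least squares) and reports $R^2$ and the F-test
  p-value for a non-zero slope. A constant response is short-circuited to
  slope 0, $R^2 = 0$, $p = 1$ (the textbook `lm` summary is NaN there).

### In-vitro substrate mode

For biochemically edited substrates, `extract_protospacer()` scans each
quality-masked read for **exact** matches to two 14-base flanks; a read is
accepted only when both flanks match and exactly 20 bases lie between
them, otherwise it is rejected with a counted reason (`no_flank5`,
`no_flank3`, `wrong_length`). Exact matching is deliberate: the
in-vitro substrate is synthetic, so any flank mismatch indicates a
sequencing problem and the read should not vote.
`tally_protospacers()` then tallies base calls per protospacer position.

## The synthetic read generator

`simulate_sample()` emits full-length single-end amplicon reads
(amplicons in such studies are typically 100–250 bases and are sequenced
in one read) derived from the reference by, in order:

1. optionally one indel per read (probability `indel_rate`), with a
   configurable length distribution and type mix, centred on the nick
   boundary with optional jitter;
2. programmed C→T edits at profiled protospacer positions (skipped when
   the position was deleted);
3. background deamination at rate `background_ct_rate` applied as C→T
   *and* G→A on the sequenced strand, so that minus-strand protospacers
   see background too;
4. uniform substitution sequencing errors (each erroneous base goes to
   one of the 3 alternatives with equal probability);
5. per-base qualities from a constant-Q or two-component mixture model.

A truth table records exactly what was injected, and identical
(config, seed) pairs give byte-identical FASTQ output. The default
background rate of 0.05% is a *synthetic fixture value* — the real
spontaneous deamination rate of a given library prep is not a constant of
nature — and note that 0.05% sits above the 0.025% Q30 detection limit,
which is precisely why the treated-versus-control test exists.

What the generator does **not** emulate: PCR cycle-by-cycle error
compounding and chimera formation, paired-end reads, adapter read-through,
position-dependent quality decay, strand-specific error profiles, and
multi-indel alleles (at most one indel per read, which keeps truth tables
unambiguous). Passing closure tests on simulated data therefore
demonstrates that the *quantification machinery* is correct, not that any
particular biological dataset will be free of artefacts the generator
does not model.

`simulate_invitro_sample()` corrupts exactly `round(f · n)` reads
(flank mutation, truncation, or a one-base spacer deletion) so the
extractor's acceptance rate on clean input is exactly $1 - f$.

## Orchestration and reproducibility

`run_pipeline()` drives config → reads → masking → alignment → tallies →
editing/indel statistics → replicate aggregation → specificity, writing
per-sample and aggregate TSVs, a JSON run report and a run log that prints
every default the analysis depends on (scoring, floors, window anchors,
detection limit). All randomness derives from the single run seed through
deterministic per-sample substreams; reruns with the same config and seed
are byte-identical. A failing sample is reported with its stage and does
not abort the other samples. A thin command-line front end
(`inst/cli/ampliconBE`) exposes `run` (full pipeline from a YAML run
config) and `simulate`; the individual stages are the exported R
functions themselves.

## Problem sizes used in the test suite

The packaged tests run the closure checks at 10,000 reads for rate
recovery (3 binomial standard errors of a 25% editing rate at that depth
is ±1.3 percentage points; of a 2% indel rate, ±0.42), 2,500-read
triplicates for the detectability logic, 200 random pairs of length ≤ 40
against a brute-force dynamic-programming oracle for the aligner, and a
5-point titration for the dose-response regression. These sizes were
chosen so the binomial noise floor is well below the effects being
checked while the whole suite stays desk-scale.

## Known limitations

* Per-cytosine percentages are marginal frequencies; allele-level
  haplotypes and editing-purity decompositions are out of scope.
* The aligner reports one optimal alignment; indel placement within
  repeats follows the left-shift convention and may differ from other
  tools' right-shifted placements by a few bases (window membership of
  borderline events can differ accordingly).
* The t-test treats replicate percentages as approximately normal, which
  is crude for very sparse counts near the detection limit; the explicit
  detection-limit gate and the undefined-variance rule are the guardrails.
* Off-target loci must be supplied; there is no genome-wide off-target
  discovery.
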