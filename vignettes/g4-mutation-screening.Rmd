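---
title: "Screening 5' UTR mutations for RNA G-quadruplex stability effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening 5' UTR mutations for RNA G-quadruplex stability effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4screen)
```

## The problem

An intramolecular RNA G-quadruplex (G4) forms when four runs of guanines
within one strand stack into two or more planar G-tetrads, with the
intervening nucleotides looping out. In 5' UTRs these structures mostly
act as repressors of cap-dependent translation, so a somatic variant that
destabilises a 5' UTR G4 of a proto-oncogene can raise its protein
output, and one that stabilises a G4 in a pro-apoptotic gene can lower
it — both plausible driver mechanisms that coding-centric analyses never
see. `g4screen` makes that screen reproducible at desk scale: discover
candidate loci, intersect them with variants in transcript space, compare
the predicted wild-type and mutant structures, and classify the change.

## Locus model and discovery

A candidate locus is a decomposition into four G-runs and three loops.
Two search patterns are built in:

* **quadparser** (`g4_pattern("quadparser")`): runs of at least three Gs,
  loops of 1–7 nt. Used for discovery, with non-overlapping leftmost
  matching: the first eligible run starts the match, each later run is the
  earliest reachable one (with backtracking), runs are consumed maximally
  from their left end, and scanning resumes at the base after the reported
  candidate. A fixed disambiguation rule keeps output reproducible; the
  test suite checks it against a brute-force enumerator that applies the
  same rule independently.
* **relaxed** (`g4_pattern("relaxed")`): runs of 2–7 Gs, loops up to 15
  nt. Used when re-examining a locus after mutation, because a damaged G4
  can persist with two tetrads or a long loop that the discovery motif
  rejects.

`enumerate_qgrs()` lists *every* decomposition (overlapping allowed, span
capped at `max_span`, default 45 nt — comfortably above the loci this
screen targets, which run 15–30 nt) and scores each:

$$\mathrm{gscore} = 100\,\frac{t-2}{t_{\max}-2} \;-\; \frac{\bar{\ell}}{L} \;-\; \frac{\ell_{\max}-\ell_{\min}}{3L}$$

where $t$ is the tetrad count, $t_{\max}$ the largest tetrad count in the
enumeration (floored at 3 so a two-tetrad-only context scores its tetrad
term as zero rather than dividing by zero), $\ell$ the loop lengths and
$L$ the pattern's maximum loop. The score is a deterministic stability
*proxy*: it rises strictly with tetrad count and falls as loops lengthen
or become unequal — the two relationships that dominate measured G4
stability — but it does not claim any external tool's numeric scale. Ties
are broken toward smaller start, then shorter span.

## Coordinates and the transcript layer

Internally everything is 1-based closed, the IRanges convention used by
every container in the package; BED's 0-based half-open and VCF/GFF3's
1-based coordinates are converted only at file boundaries. Transcript
models carry exons and 5' UTR intervals in genomic space;
`utr5_sequence()` splices the UTR in transcript order (reverse-complement
for minus-strand transcripts, T→U) and `genome_to_transcript()` inverts
the per-base genomic map, returning a not-in-UTR value (`NA`) rather than
an error for intronic or flanking positions. The two maps are
property-tested as mutual inverses on randomly generated spliced
transcripts of both strands. Multiple transcripts per gene are screened
independently; collapsing is left to downstream reporting, with a
distinct-mutation count in the summary.

## Classification

For each overlapping variant the UTR is mutated in place and candidates
are re-enumerated in a window extending `max_span` either side of the
wild-type locus — wide enough that a quadruplex shifting onto a fifth
G-run a few nucleotides away is seen. The top-scoring wild-type and mutant
candidates are compared **structure-first**:

1. tetrad count changed → `tetrad_loss` (destabilising) or `tetrad_gain`
   (stabilising);
2. else total loop length changed → `loop_lengthening` (destabilising) or
   `loop_shortening` (stabilising);
3. else start moved → `g4_shift` (destabilising);
4. else the score difference decides, with a dead-band of `theta` (default
   5 gscore units) inside which the call is neutral.

The dead-band exists purely to absorb floating-point noise when the
decomposition is unchanged; it is deliberately *not* the primary
classifier, because structural change, not a score threshold, is what the
mechanism labels mean. A mutant with no candidate at all is `disrupted`
and always destabilising. When fold support is enabled the full wild-type
and mutant UTRs are folded and a mutant that loses the folded quadruplex
is forced to destabilising; the verdict records which rule fired.

Recurrence across samples (distinct samples per mutated position) is
reported but never used for classification — cohort-scale screens of this
kind observe essentially no recurrence, so it carries no signal here.

## Folding adapter

The adapter's contract is presence/absence of a quadruplex in the
minimum-free-energy structure, not energies. The external engine shells
out to ViennaRNA (`RNAfold --gquad`, `--noGU` unless GU pairs are allowed,
`RNALfold -L` for local mode) and parses the quadruplex marks from the
dot-bracket string; the engine version is recorded because folding
energies drift across releases. The fallback engine is pattern-based: a
quadruplex is present exactly when the relaxed enumeration finds a
candidate above a configurable gscore floor, and its pseudo-energy is the
monotone map `mfe = -gscore/10` kcal/mol, so relative stabilities order
identically to the score. Base pairing outside quadruplexes is not
modelled by the fallback, and no fidelity beyond presence/absence is
claimed for either engine. A missing external binary degrades to the
fallback with an explicit warning, never silently.

## Assay mathematics

* `smooth_spectrum()`: ten-point neighbour averaging (window truncated at
  the edges, grid unchanged). Smoothing is linear, so it commutes with
  blank subtraction — asserted in the tests.
* `to_molar_ellipticity()`: millidegrees / (10 × pathlength\[cm\] ×
  concentration\[M\]), in deg·cm²·dmol⁻¹.
* `fit_melt()`: least-squares fit of
  $y = \mathrm{lower} + (\mathrm{upper}-\mathrm{lower})/(1+e^{h(T-T_m)})$.
  The sign convention is chosen so $h > 0$ for an unfolding transition
  whose signal falls with temperature while keeping
  $\mathrm{lower} < \mathrm{upper}$ ("variable slope" fixes the family,
  not the parameterisation, so the choice is documented here).
  Levenberg–Marquardt with a deterministic multi-start grid over the
  slope; `tm` initialised at the data's mid-signal crossing. Fits are
  rejected with diagnostics — not returned as best-effort values — when
  no start converges, the fitted midpoint lies outside the data range, or
  less than 80% of the transition amplitude is covered by the data (the
  signature of a missing plateau, e.g. a species that does not fully melt
  in range).
* `pfaffl_ratio()`: $(E_t)^{\Delta CP_t} / (E_r)^{\Delta CP_r}$ with
  efficiencies constrained to (1, 2]; tested against a log-space oracle to
  1e-12 relative.
* `relative_efficiency()`: per-construct means normalised to a reference,
  SEM by the delta method for a ratio of independent means, checked
  against a bootstrap. Significance testing is intentionally out of
  scope; the tidy replicate table is passed through for any stats tool.

## What the synthetic generator emulates — and what it does not

`make_cohort()` builds one chromosome per transcript with padded flanks,
a spliced or unspliced 5' UTR on either strand, and a short CDS stub.
Each planted mutation gets its own locus whose geometry realises one
mechanism class: a four-G run whose interior G→A leaves a two-tetrad
remnant (tetrad loss); four tight runs plus a fifth run just downstream,
with a run-disrupting G→A that recruits it and lengthens a loop; a first
loop carrying two Gs and a mutable A→G that creates a new run, shifts the
last run out and shortens the loop; a U→G completing a fourth tetrad;
loop substitutions that change nothing (neutral controls); and variants
planted far from any locus (non-overlapping controls). VCF records are
always plus-strand, complemented from the RNA-space intent on
minus-strand transcripts, which is what exercises the strand logic.

Background sequence is guanine-poor by construction: ~20% G but never two
consecutive Gs outside planted loci, and never a G abutting a locus. This
makes the planted loci provably the only quadparser matches (the
generator audits this by scanning every UTR and fails generation
otherwise) and keeps re-enumeration windows free of confounding runs.
That is the deliberate trade-off to make planted truth exact, and it is
also the main way the fixtures are *unlike* real 5' UTRs, which are
GC-rich, full of near-miss G-runs, overlap each other across isoforms,
and carry mutational signatures with trinucleotide context. Passing the
recovery criteria therefore demonstrates that the machinery is correct —
coordinates, strands, windows, classification logic — not that the screen
is calibrated on real genomes; on real data the relaxed re-enumeration
window will often contain competing candidates, and verdicts there lean
on the fold-support override much more than the synthetic audit does.

Default cohort: 100 transcripts, 200 mutations split evenly over the six
classes, half the transcripts on each strand, half spliced — large enough
that every mechanism occurs on both strands in both splice states, small
enough that the full screen runs in well under a minute. Melt-curve
defaults follow the standard protocol (25–95 °C at 1 °C steps) with
noise at 2% of amplitude; the measured wild-type/mutant midpoint pairs
(78/64 °C, 68/75 °C) parameterise the simulated curves, and recovery of
the 14 °C and 7 °C gaps is the test.

## Numerical and design choices

* `theta = 5` score units: a dead-band wide enough that no floating-point
  jitter flips a call, narrow relative to the 100-unit tetrad term that
  dominates real changes.
* `max_span = 45` nt both as enumeration cap and as the re-assessment
  window pad: polynomial enumeration, and wide enough for fifth-run
  shifts.
* Degenerate inputs error loudly: non-nucleotide characters name their
  position, IUPAC codes other than N are rejected (N never matches a
  G-run and may sit in loops), reference mismatches between VCF and
  genome are flagged and excluded but never silently dropped, and the
  screen accounts for every input record (hit, non-overlapping, or
  mismatch).
* Determinism: generators and the melt fitter take explicit seeds; the
  pipeline threads one seed from its config into every stage and writes a
  manifest (version, config hash, input digests, seed, engine). The only
  volatile VCF header line (`##fileDate`) is stripped so identical seeds
  give byte-identical fixtures.

## Limitations

Only single-base substitutions are screened; indels and MNVs are filtered
with a logged reason. The gscore is ordinal, not thermodynamic, and the
fallback folder is not a substitute for a real energy model — presence or
absence of a folded G4 is the only claim either engine supports. No
driver-versus-passenger inference, burden testing or survival association
is attempted: the output of this package is the structural verdict table
that such analyses would consume.
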