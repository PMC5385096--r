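---
title: "The pentamer region-dependent hybridization model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pentamer region-dependent hybridization model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarrays that target repetitive elements — human endogenous
retroviruses (HERVs) and related retrotransposons being the canonical
case — face a failure mode that probes against ordinary genes rarely
meet: the loci of a family are phylogenetically close, so a 25-mer probe
designed for one locus can hybridize measurably with transcripts of its
paralogs that differ by a handful of mismatches or a small indel.
Designing a locus-resolved array therefore requires a quantitative
model of how mismatches and gaps degrade duplex stability, not just a
perfect-match uniqueness check.

`pehm` implements such a model, the machinery to train it on degenerate
probe sets, the three-step probe/probeset design pipeline built on it,
and the titration-based statistics used to evaluate the resulting
platform.

## The intensity model

The observed linear-scale intensity of probe $j$ on array $i$ is modeled
as the product of the abundance of the targeted transcript and a
sequence-determined affinity:

$$ I_{ij} = \theta_i \,\varphi_j + \varepsilon_{ij},
   \qquad \varepsilon_{ij} \sim N(0, \sigma^2), $$

with, for each target, the identifiability constraint
$\sum_i \theta_i^2 = N$ ($N$ = number of arrays).  The product form is
only identified up to a per-target scale, and the constraint deliberately
pins the *abundance* rather than the affinity, because the affinity is
the quantity of interest for design.  We additionally restrict
$\theta \ge 0$: abundances are physically nonnegative, and without this
restriction the decomposition retains a per-target sign freedom
$(\theta, \varphi) \to (-\theta, -\varphi)$ that the sum-of-squares
constraint cannot resolve (in noiseless experiments the alternating
optimizer does find those mirrored solutions).

The affinity is a sparse linear form over sequence features:

$$ \varphi_j = \sum_l \sum_k \beta_k^l X_{jk}^l + \sum_m \delta_m Z_{jm}. $$

$X_{jk}^l$ counts occurrences of pentamer token $k$ in sub-region $l$ of
probe $j$'s duplex; $Z_{jm}$ flags mismatch-pair interactions.  The
tokens are read off 5-column windows of the probe–target alignment:

* a window with no event emits a **PM** token — the target 5-mer
  ($4^5 = 1024$ per region and orientation);
* a window with exactly one mismatch emits an **MM** token — the target
  5-mer, the offset of the mismatch within the window, and the
  mismatching probe base ($4^5 \times 5 \times 3 = 15{,}360$);
* a window with exactly one gap emits a **GAP** token — the four paired
  target bases, the gap offset, and which strand carries the gap
  ($4^4 \times 5 \times 2 = 2{,}560$);
* windows holding two or more events emit nothing: pentamer additivity
  is not trusted across clustered lesions, whose effect is instead
  carried by duplex-wide interaction flags keyed by the distance between
  mismatch pairs (adjacent $\le 2$ nt, near 3–7 nt, far $\ge 8$ nt).

Windows are tagged by sub-region: the window start indices are split
into three equal contiguous blocks (for a 25-mer, 21 windows split
7/7/7).  This is the coarse form of position dependence: full
per-position pentamer effects would multiply the parameter count roughly
sevenfold for little gain at realistic training sizes.  With two
synthesis orientations the full vocabulary holds
$2 \times 3 \times 18{,}944 = 113{,}664$ k-mer parameters
(`enumerate_vocabulary()`), which is why estimation is penalized.

### Alignment conventions

`align_duplex()` computes the minimum-cost global alignment with
mismatch cost 1 and gap cost 1.5 — a single gap should cost more than a
single mismatch but less than two, reflecting the relative destabilizing
effect of a bulge versus a point lesion.  Cost ties are broken toward
the leftmost gap placement, making alignments (and therefore features
and affinities) deterministic.  Budget defaults of at most 3 mismatches
and 1 gap bound the search; anything beyond is treated as
non-hybridizing, signaled by a typed `no-duplex` condition rather than a
sentinel value.  Coordinates are 0-based half-open internally and in BED
output.  Antisense probes are represented on the sense-strand target
window; the orientation tag on every token keeps the two coefficient
sets separate.

## Fitting

`fit_pehm()` alternates:

1. **Coefficient step.** LASSO regression (glmnet) of all $I_{ij}$ on
   the feature counts scaled by the current $\theta_{i,g(j)}$, with no
   intercept, on the linear intensity scale — the model is
   product-plus-Gaussian, so no log transform is applied.  The penalty
   is chosen once, at the first iteration, by 10-fold cross-validation
   with folds assigned per probe and stratified by probeset, then held
   fixed (re-running CV each iteration makes the objective
   non-monotone).  We use the CV-minimum penalty followed by a
   **relaxed refit**: the LASSO selects the active token set, and the
   active set is then refit by unpenalized least squares.  The 1-SE
   rule (available via `lambda_rule = "1se"`) proved far too aggressive
   here — on sparse synthetic truths it retains roughly a fifth of the
   true support and caps the affinity correlation near 0.9, whereas the
   relaxed CV-minimum fit recovers simulated affinities with
   correlation above 0.99 at 5% noise.
2. **Abundance step.** Closed-form least squares for each
   (array, target), projected to $\theta \ge 0$, then renormalized to
   $\sum_i \theta^2 = N$.  A target with no usable signal is set to the
   constraint-satisfying constant and flagged.

Iteration stops when the relative change in residual sum of squares
falls below $10^{-6}$ (at most 100 iterations).  $\theta$ is initialized
from per-(array, target) mean intensities — positive, data-driven and
deterministic.  Every randomized step (fold assignment) derives from the
single `seed` argument.

### Hybridization threshold

`calibrate_threshold()` scans the observed affinity values and returns
the largest threshold $T$ such that at least 90% of the probes with
affinity below $T$ have median intensity (across arrays) under the
supplied background level.  The scan is non-parametric; collapsing
duplicate affinities resolves ties toward the smaller, more conservative
threshold.  If no cutoff isolates sub-background probes the function
refuses to calibrate rather than returning an arbitrary value.

Backgrounds come from `background_trpn()` (the interpolated 15th
percentile of designated control-probe intensities, R quantile type 7 —
the convention is stated because the source material does not fix one)
or `background_gcbg()` (median intensity of antigenomic probes with the
same GC count, nearest populated bin as fallback, ties toward lower GC).

## Probe and probeset design

The pipeline (`design_probes()`) follows three steps:

1. **Tiling** (`tile_region()`): 25-mer candidates at a 1–4 nt step;
   windows containing masked bases are skipped.
2. **Probe selection**: candidates whose perfect-match self-affinity is
   below $T$ are discarded (boundary *inclusive*: a probe exactly at the
   calibrated threshold is kept, since the calibration itself defined
   that affinity as usable; `inclusive = FALSE` restores the strict
   reading).  Survivors are searched against the reference libraries
   (`find_hits()`) and classified by the number of hits with affinity at
   or above $T$: one — `specific`; two or three —
   `potentially_cross_hybridizing`; four or more — `non_specific`,
   excluded.  Lowering the threshold can only move probes toward less
   specific classes (a monotonicity the tests assert).
3. **Probeset assembly** (`assemble_probesets()`): a greedy
   left-to-right scan over 400-nt windows admits probes in position
   order, enforcing a minimum start separation of 8 nt (at most 30%
   overlap for 25-mers; when two candidates are closer, the higher
   self-affinity wins, ties to the leftmost), requiring cross-hybridizing
   members to cross-react with pairwise distinct loci, and emitting a
   probeset only if 3–6 probes remain with at least one specific member.
   When a window yields a probeset the window is consumed, so emitted
   probesets never overlap.  The greedy scan and its tie-breaks are our
   algorithmic choices; the constraints themselves (size, span, overlap,
   specificity mix) are the published design rules.

The built-in hit search is an exhaustive seed-and-scan: the probe is cut
into $(\text{max\_mm} + \text{max\_gaps} + 1)$ non-overlapping seeds, so
by pigeonhole any alignment within budget contains one exact seed match,
whose position anchors the bounded alignment verification.  Alignments
of the same site that differ only by terminal-gap placement are
clustered per target (within half a probe length) and the minimum-cost
representative kept.  The backend is deliberately a pluggable contract —
at genome scale one would substitute a dedicated short-read aligner and
keep every downstream step unchanged.

## Platform evaluation

The titration design mixes two pure samples A and B into
C = 0.75 A + 0.25 B and D = 0.25 A + 0.75 B, each in technical
triplicate.  If A > B for a transcript, the replicate-mean intensities
should order A > C > D > B strictly (and conversely); exactly 2 of the
24 orderings of four exchangeable values pass, so under pure noise at
unit fold change the expected pass rate is 1/12.  `titration_curve()`
bins probesets by A/B fold change and reports the monotonic percentage
per bin; `ratio_at()` interpolates the fold change at which a target
level (default 75%) is first reached.

`estimate_mixture()` recovers the mixing fractions.  The default fits a
single no-intercept least squares of the mixture summaries on the A and
B summaries *across* probesets, without constraining
$\alpha + \beta = 1$; on noiseless data this returns the design
fractions exactly.  A per-probeset variant solves the constrained
estimate $\hat\beta = (A - \text{mix})/(A - B)$ probeset by probeset and
reports the median — the form in which per-probeset mixture estimates
are usually displayed — skipping probesets with $A \approx B$, which is
why the statistic is conventionally computed on probesets that pass the
differential-expression filter.  A per-probeset *unconstrained*
regression on scalar summaries would be underdetermined (one equation,
two unknowns), which is why the pooled form is the default.

The DE filter (`de_filter()`) uses a Welch t-test per probeset with
Benjamini–Hochberg adjustment, keeping probesets with $q \le 0.01$, fold
change $\ge 2$ in either direction, and a median replicate intensity of
at least $2^4$ in one sample so that kept probesets sit above background.
The moderated-t machinery of dedicated DE packages is intentionally not
reimplemented here; the test is a documented, pluggable placeholder with
the same thresholds.

Probe-level matrices are summarized to probeset level by median polish
(`summarize_probesets()`), the standard robust additive decomposition;
full normalization pipelines are out of scope.

## The synthetic-data generators

`make_degenerate_design()` reproduces the structure of the training
sets used for this model class: each probeset is one perfect-match
25-mer plus, per PM probe, all 75 single-mismatch variants, all single
deletion variants, and random double-mismatch variants filling the
budget (default 180 variants per PM, so 10 PM probes give 1800
degenerate probes per probeset).  Two published totals for this design
are mutually inconsistent (20 × 1810 probes is 36,200, not the printed
37,200), so the generator exposes the counts as parameters and enforces
neither total.  Deletions inside a homopolymer run yield identical
sequences; the generator deduplicates them (keeping the leftmost
position label) and tops up with extra double mismatches, so designs
never contain duplicate sequences.  "Single gap" is realized as a
single-base deletion in the probe; insertion variants can be produced by
aligning against extended targets but are not part of the default
design, as the source material does not specify which.

`sample_truth()` draws the ground truth the intensity equation
presupposes: sparse positive PM coefficients, negative MM/GAP and
interaction coefficients (mispairing must lower affinity), and positive
constraint-normalized abundances.  The default sparsity of 0.10 keeps
the nonzero support (about 110 tokens on a typical 200-probe training
design) well below the number of distinct probes — the identifiable
sparse regime that parameter-recovery experiments presuppose; a much
denser truth is unrecoverable from 200 probes by any estimator and
would test nothing about the optimizer.

`simulate_titration()` generates mixture designs at the concentration
level ($\theta$ mixes, then intensities per replicate with independent
noise), and `simulate_family()` mutates one ancestral sequence into $n$
paralogs at a stated per-site substitution rate, recording the planted
positions for oracle checks.  Divergence 0 is the worst case for
cross-hybridization: with four or more identical loci every probe is
non-specific and the design pipeline must emit nothing.

**What the generators do not emulate.** Homoscedastic Gaussian noise on
the linear scale follows the intensity equation exactly, but real
scanner noise is intensity-dependent; spatial artifacts, saturation,
labeling efficiency and RNA degradation are absent; simulated families
lack indel-rich evolution and LTR structure.  Passing tests therefore
demonstrate correctness of the algorithms under the model's own
assumptions, not platform performance on real hybridizations.

## Problem sizes and numerical conventions

The test suite and the acceptance script run, by choice, at desk scale:
parameter recovery uses 20 probesets × 10 probes on 8 arrays with noise
at 5% of the mean signal; threshold calibration uses 2,000 probes on 6
arrays with 150 spiked control probes; titration checks use 200
probesets (plus 3,000 single-probe probesets for the chance-rate check);
design conformance uses 3–4 paralogs of 150–200 nt at divergences 0 to
0.15.  Convergence tolerance $10^{-6}$ on relative RSS; constraint
conservation is asserted at $10^{-9}$; quantile type 7 and
midpoint-median conventions throughout; all generators are pure
functions of their seed.

## Known limitations

* The alternating optimizer converges to a stationary point, not a
  certified global optimum; the seed fixes the trajectory.
* Affinity is a linear proxy, not a thermodynamic free energy;
  nearest-neighbor $\Delta G$ models and RNA secondary structure are
  out of scope.
* The built-in hit scanner is complete but desk-scale; genome-scale
  design requires plugging in an external aligner behind the documented
  contract.
* The per-position ambiguity of the sub-region approximation (whole
  probes versus individual windows) is resolved here by tagging
  individual windows, which is the finer and better-determined reading.
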