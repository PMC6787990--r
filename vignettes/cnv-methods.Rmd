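---
title: "Methods: read-depth CNV discovery in exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV discovery in exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wescnv)
```

# The problem

Whole-exome sequencing (WES) captures and sequences a set of targeted
exonic intervals ("targets"). Copy-number variants — deletions and
duplications spanning one or more targets — leave a footprint in read
depth: a heterozygous deletion roughly halves coverage over its span, a
single-copy duplication raises it by about half. The difficulty is that
per-target depth is dominated by systematic technical variation (capture
efficiency, GC content, batch effects) that is far larger than the CNV
signal in any one sample. `wescnv` takes the classic cohort approach:
model the shared systematic structure across many samples, remove it,
and scan what remains with a hidden Markov model (HMM).

The pipeline is three stages, each usable on its own:

1. **Coverage** (`coverageMatrix()`): mean per-base depth of passing
   fragments for every sample × target, forming the read-depth matrix.
2. **Normalization** (`normalizeDepths()`): filter unreliable targets and
   samples, mean-centre each target, subtract the top *K* principal
   components, filter hyper-variable targets, and z-score each sample.
3. **Discovery** (`discoverCNVs()`): per-sample 3-state HMM segmentation
   of the z-scores with phred-scaled call qualities, written as `.xcnv`.

# Coverage semantics

For each target the value is the sum over target bases of per-base depth
from passing alignments, divided by target length. Records failing the
mapping-quality threshold (default 20) or flagged as duplicate,
secondary or supplementary are ignored; base qualities are not
(the protocol this matches sets no base-quality cutoff). Aligned bases
are the CIGAR reference-consuming matched positions (`M`/`=`/`X`).

Two conventions deserve explicit mention because alignment tools differ:

* **Deletions within a read** (`D`, and skips `N`) consume reference but
  are *not* counted as covered. This is a documented choice, pinned by
  tests against a brute-force per-base tally.
* **Fragment counting** (default): a base overlapped by both mates of a
  pair is counted once per fragment — per-base depth is
  `min(1, reads covering the base within the fragment)`. With
  `countUnit = "read"` every read counts independently.

# Rank selection and PCA normalization

After filtering, every target column is mean-centred and the matrix
`X` (s samples × t targets) is decomposed by SVD. With component
variances `v_i = sigma_i^2`, the removal rule keeps the *K* components
satisfying

    v_i >= 0.7 * sum(v) / n

where `n = min(s, t)` is the number of candidate components. The 0.7/n
relative-variance cutoff and all filter thresholds below are the
published protocol defaults for this class of exome CNV analysis.

Computing all `n` components only to discard `n - K` of them is
wasteful, because in practice `K << n`. `determineK()` therefore
brackets the total variance from a truncated spectrum of `k`
components:

* over-estimate: `sum(v_1..v_k) + (n - k - 1) * v_k` — the unseen tail
  is bounded by the smallest computed variance. The `n - k - 1` (rather
  than `n - k`) multiplier reflects that the centred matrix has at most
  `n - 1` informative components; note it is not a strict bound in the
  degenerate case where more than `n - k - 1` tail components equal
  `v_k` exactly, which is why certification below is always checked
  rather than assumed.
* under-estimate: `sum(v_1..v_k)` — the unseen tail taken as zero.

`K` is counted against the cutoff derived from the over-estimate. If the
first retained component `v_{K+1}` falls below the cutoff derived from
the under-estimate, no unseen component can change the count and the
result provably equals the full-spectrum `K` ("certified"). Otherwise
`k` grows geometrically (`k <- min(2k, min(s,t) - 1)`; the doubling
schedule is this package's choice — it bounds the number of expensive
re-decompositions at a logarithmic count) starting from
`k = ceil(n / 10)`; at the cap the exact full-spectrum rule is applied
directly, so the procedure can never return an uncertified answer.
Components with `v_i` exactly at the cutoff are removed (`>=`
comparison). The backing decomposition is LAPACK's deterministic dense
SVD truncated to `k` triples, so every stage of normalization is a pure
function of its input; all arithmetic is double precision.

The acceptance suite checks, on 200 random matrices with flat, steep and
mixed spectra (s in [10, 60], t in [50, 400]), that the iterative path
agrees with the full-spectrum rule exactly and never certifies a wrong
`K`.

`pcaNormalize()` subtracts the rank-`K` reconstruction, leaving (to
1e-8) zero projection on every removed component; `K = 0` is the exact
identity. Samples are then z-scored row-wise using the sample standard
deviation (denominator `t - 1`).

## Filter thresholds

| Filter | Default | Unit |
|---|---|---|
| target length | 10 – 10000 | bp |
| target mean depth | 10 – 500 | × coverage |
| target GC fraction | 0.1 – 0.9 | fraction |
| target low-complexity fraction | ≤ 0.25 | fraction |
| sample mean depth | 25 – 200 | × coverage |
| sample depth SD | ≤ 150 | × coverage |
| post-normalization target SD | ≤ 30 | normalized depth units |

GC and complexity come from a reference FASTA (complexity as the
soft-masked fraction) or a precomputed table; the rules fire only where
the annotation is present.

# The copy-number HMM

States are DEL, DIP, DUP over the filtered, ordered target list of each
sample independently. The parameterization (protocol defaults):

* `p = 1e-8` — probability a CNV starts at any given target; initial
  distribution `(p, 1 - 2p, p)`.
* mean CNV length 6 targets — exit probability `q = 1/6`.
* `D = 70000` bp — attenuation scale. The transition matrix at
  inter-target distance `d` is `T(d) = f*T0 + (1 - f)*Pi` with
  `f = exp(-d/D)`, `T0` the zero-distance matrix
  `[[1-q, q, 0], [p, 1-2p, p], [0, q, 1-q]]` and `Pi` the stationary
  rows `(p, 1-2p, p)`: distant targets forget the CNV state.
* `M = 3` — emission means `-M`, `0`, `+M` on the z-score scale, unit
  variance.
* `d` is the midpoint-to-midpoint distance of consecutive targets,
  floored at zero (a `distanceMode = "gap"` alternative is provided;
  midpoint distance makes abutting targets nearly fully coupled, which
  matches the intent of the attenuation model). A chromosome change sets
  `f = 0` exactly, so one HMM pass over the whole genome-ordered target
  list is equivalent to independent per-chromosome passes — a fact the
  enumeration tests verify.

Decoding is max-product Viterbi in natural-log space, which needs no
rescaling. Likelihoods and posteriors use the scaled forward/backward
recursions: the forward vector is renormalized to sum to one at every
target and the log scaling factors accumulate the log-likelihood. On
long informative chains the textbook probability-space recursion
underflows double precision to exact zero (demonstrable via
`hmmLogLikelihood(..., method = "naive")`); the scaled and log-sum-exp
routes remain finite and agree to better than 1e-9.

## Call qualities

A maximal non-diploid Viterbi run `[a, b]` of state `c` becomes a
candidate call. Each of the five phred-scaled qualities is an exact
likelihood ratio computed by a *constrained* scaled forward pass —
disallowed states are zeroed at specific targets — divided by the
unconstrained likelihood:

* `Q_SOME`: some target in `[a, b]` has state `c` (1 minus the pass
  forbidding `c` throughout the interval). Calls with `Q_SOME` below 30
  are suppressed by default.
* `Q_EXACT`: every target in `[a, b]` has state `c`, with non-`c`
  flanks. At the first or last target of a chromosome the nonexistent
  flank imposes no constraint — this boundary convention is pinned
  explicitly against the enumeration oracle, since edge targets are
  where implementations of this model typically diverge.
* `Q_NON_DIPLOID`: some target in `[a, b]` is non-diploid.
* `Q_START`, `Q_STOP`: the event starts exactly at `a` / stops exactly
  at `b`.

Event inclusion gives `P_EXACT <= P_SOME <= P_NON_DIPLOID` for every
call. Phred conversion `round(-10*log10(1 - P))` (half-up) happens at
the boundary only, clamped to [0, 99]; everything internal is natural
logs. Comparisons against the 3^T enumeration oracle are made to an
absolute 1e-9 on probabilities: near-certain events leave both routes
with cancellation error in `1 - P` at relative scale, and a probability
is bounded by 1, so the absolute scale is the meaningful one.

# What the synthetic cohorts emulate

`simulateCohort()` draws
`depth(s, t) = noise(base_t * scale_s * (1 + sum_r batch_r) * cnvFactor)`:

* `base_t` uniform in `meanDepthRange` (default 80–150×), emulating
  per-target capture efficiency;
* `scale_s` log-normal with 5% coefficient of variation — mild
  library-size variation;
* batch structure of chosen rank: per-sample loadings times
  orthogonalized per-target factors rescaled to unit-variance entries,
  so each component perturbs every target at the order of
  `batchStrength` (default 0.15, i.e. ±15% multiplicative bias) and the
  planted low-rank spectrum is known by construction;
* Poisson noise at read-count granularity (`lambda = depth * L / R`),
  the default because its mean–variance coupling resembles sequencing
  depth; Gaussian and noiseless options exist for controlled SVD tests;
* embedded CNVs as multiplicative factors (0.5 = heterozygous deletion,
  1.5 = duplication).

All randomness flows from the single `seed`; cohorts are bit-reproducible.

What it does *not* emulate: GC-dependent bias curves (annotations are
drawn inside passing ranges), mappability structure, correlated noise
between adjacent targets, homozygous events, common CNVs shared across
samples, or read-level artefacts. Passing recovery tests therefore
demonstrates that the pipeline removes low-rank structure and detects
multi-target shifts of the designed magnitude — not that it reproduces
performance on real cohorts, where the systematic structure is richer.

The end-to-end validation cohort is 30 samples × 500 targets with
rank-3 batch effects and twenty 5-target CNVs (factors 0.5/1.5, one per
sample). These sizes keep the full validation suite under a minute
while leaving the batch spectrum clearly separated from noise; at this
scale the recovery criterion (at least 90% of embedded CNVs
overlap-matched with breakpoint error ≤ 1 target, and PCA-normalized
detection at least matching unnormalized detection) holds with margin.
One caveat documented deliberately: with `s << t`, a cohort with *no*
planted structure has a near-flat noise spectrum whose components
cluster around the mean variance, so the 0.7/n rule removes many of
them. This mirrors the rule's behaviour on structureless input and is
why the recovery experiment always plants batch structure.

# Degenerate inputs and numeric edge cases

* An all-constant matrix centres to zero; z-scoring then fails with a
  clear error naming the sample (zero SD), rather than emitting NaNs.
* A forward pass whose masked support vanishes (constrained probability
  exactly 0) yields `-Inf` log-likelihood and probability 0, not NaN.
* Matrices are dense by contract: unparseable cells are errors with
  line numbers, never missing values.
* Matrix write precision is 2 decimals by default; `sprintf` C rounding
  of the binary double (half-even on representable ties), documented in
  `writeDepthMatrix()`.
* Unsorted target headers are rejected, not silently reordered; the
  same strictness applies to per-sample coverage tables with divergent
  target lists.

# Known limitations

* No genotyping mode: discovered intervals are not re-genotyped across
  the cohort.
* Single-machine, in-memory: cohorts must fit in RAM.
* No CRAM input; SAM/BAM only (SAM converted internally).
* The HMM's emission model is the standard shifted-normal on z-scores;
  targets with strongly non-normal residuals are only protected by the
  post-normalization SD filter.
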