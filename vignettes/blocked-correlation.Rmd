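---
title: "Blocked out-of-core computation of all pairwise Pearson correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked out-of-core computation of all pairwise Pearson correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcor)
```

## The model and its reduction

`blockcor` computes the Pearson correlation coefficient of every unordered
pair of rows of an $N \times M$ matrix — in the motivating fMRI setting, $N$
voxel time series of $M$ timepoints each. The definitional form,

$$ r_{xy} \;=\; \frac{\sum_t (x_t-\bar x)(y_t-\bar y)}
  {\sqrt{\sum_t (x_t-\bar x)^2}\,\sqrt{\sum_t (y_t-\bar y)^2}}, $$

is implemented verbatim as `pcc_direct()` and serves as the package's
correctness oracle. The engine itself never evaluates it pairwise. Instead,
each row $v$ is centered and scaled to unit Euclidean norm,
$u = (v-\bar v)/\lVert v-\bar v\rVert_2$ (`normalize_rows()`), after which
$r$ is the plain dot product $u \cdot u'$ and the entire correlation matrix
is the Gram matrix $UU^\top$ — one dense matrix product, delegated to BLAS.
A second, algebraically equivalent raw-moment form (`pcc_single_pass()`,
using only $\sum x$, $\sum x^2$, $\sum xy$) is kept as an independent
cross-check; it is numerically the weaker of the two under large means, so
it is an oracle, never the engine.

The assumptions are minimal: rows are finite real vectors with $M \ge 2$;
correlation is undefined for a constant row (zero centered norm), handled
explicitly below. Nothing is assumed about temporal structure — the
coefficient is invariant to any common reordering of timepoints.

## Condensed storage and indexing

Only the $T = N(N-1)/2$ strictly-upper-triangle coefficients are kept, as a
flat array in row-major pair order: all pairs $(0,j)$ first, then $(1,j)$,
and so on. The position of pair $i<j$ is

$$ k \;=\; iN - \tfrac{i(i+1)}{2} + j - i - 1, $$

with everything 0-based — one convention end to end, chosen because $k$ is
literally the element offset into the on-disk array. (R-side matrix rows
remain 1-based as usual; only the pair/position vocabulary is 0-based.)

The inverse map recovers $(i,j)$ from $k$ by inverting the triangular row
offsets. A closed-form inversion involves a square root whose floating-point
rounding can misplace $k$ near row boundaries once $N$ is large, so
`linear_to_pair()` uses the square root only as an initial guess and then
applies an exact integer correction of at most one row in either direction.
The authoritative specification of the map is the bijection property, which
the test suite checks exhaustively for every $N \le 500$ and by sampling at
$N = 10^6$. Counts are represented as R doubles, exact for integers up to
$2^{53}$ — ample for any feasible $N$ ($N = 10^7$ needs $\sim 5\times10^{13}$).

## The memory budget and the round recurrence

The working-buffer budget $X$ (`budget_elements`; at the CLI a byte string
such as `"512M"`, divided by the scalar width) counts the scalars available
for one round's product buffer plus its extracted condensed slice. A round
with $N'$ unfinished voxels and block size $B$ needs $BN'$ product entries
and $N'B - B(B+1)/2 < BN'$ slice entries, so $2N'B$ is a safe bound and

$$ B = \lfloor X / 2N' \rfloor. $$

The always-resident normalized matrix ($NM$ scalars) is deliberately *not*
counted against $X$, mirroring the accounting of an accelerator pipeline
where the input is parked in device memory once. `plan_blocks()` applies the
recurrence: if the first candidate $B$ exceeds $N$, one round covers the
whole triangle (the literal branch condition $B > N$ is used, not the looser
total-space criterion one could derive — the literal branch is conservative
and unambiguous); otherwise rounds consume $B$ voxels each, $N'$ shrinks,
$B$ is recomputed and clamped to $N'$ when it overshoots. Floor (rather than
round or ceiling) guarantees the bound. The plan — start voxel, $B$, $N'$,
output offset and length per round — is returned as data, logged by the CLI,
and persisted in the store sidecar, so the blocked execution is externally
observable and testable rather than an internal detail.

Two invariants pin the design down:

* **coverage** — the rounds' slices tile the condensed array exactly
  (offsets are cumulative sums of lengths; every pair falls in precisely the
  round owning its smaller index);
* **budget invariance** — the condensed array is the same for every
  feasible budget, up to floating-point summation order. The tests compare
  minimal, intermediate and unbounded budgets elementwise at
  $10^{-12}$ (f64) / $10^{-6}$ (f32).

## Numerical choices

**Precision.** The reference pipeline for this problem is single-precision
GEMM. R has no native 32-bit float arithmetic, so `precision = "f32"` is
emulated by demoting values to the nearest binary32 number (a 4-byte binary
round trip, `demote_single()`) at the module boundaries — the normalized
matrix, each block product, the stored array — while accumulation stays
double. This matches modern GEMM behaviour (32-bit operands, wider
accumulators) and makes f32 stores round-trip bitwise, since stored values
are already exactly representable. All tolerances scale with the declared
precision: $10^{-12}$/f64, $10^{-6}$/f32 for engine-vs-oracle agreement.

**Degenerate voxels.** A constant series has zero centered norm and no
defined correlation. The threshold is centered norm
$\le \varepsilon\sqrt{M}$ with $\varepsilon = 10^{-12}$ (f64) or $10^{-6}$
(f32). Policy `"nan"` (default) stores NaN for every pair touching such a
voxel — the least surprising contract, since NaN propagates; `"zero"`
stores 0 (what the zeroed normalized row produces naturally, convenient for
downstream thresholding); `"error"` aborts naming the first offending
voxel. `read_matrix(drop_degenerate = TRUE)` instead removes such voxels up
front and records their original indices.

**No clamping.** Finite-precision dot products can exceed $[-1, 1]$ by a few
ulps; outputs are *not* clamped, because clamping would mask a defective
backend. The documented bound $|r| \le 1 + 4\varepsilon M$ is asserted in
tests instead.

**Backend seam.** The block-against-remaining product is a pure function of
its inputs behind a `backend` argument. `"blas"` (R's `tcrossprod`) is the
reference; `"naive"`, a plain R loop, exists so any future accelerated
backend has an in-package independent implementation to be validated
against. Summation order inside a dot product is backend-defined, which is
why cross-budget identity is specified as tolerance-bounded, not bitwise.

## What the synthetic generators do and do not emulate

`generate_uniform()` reproduces the standard benchmark protocol for this
engine: i.i.d. intensities uniform on $[-6, 6]$, conventionally $M = 100$.
It exercises scale and numerics — uncorrelated inputs make any indexing or
blocking error visible as a misplaced coefficient — but contains no signal.

`generate_planted()` adds a ground truth for statistical recovery: voxel $v$
in community $c$ receives $\sqrt{\rho}\,g_c + \sqrt{1-\rho}\,e_v$ with
shared and private standard-normal series, so the population correlation is
exactly $\rho$ within a community and $0$ across. Default $M = 200$ keeps
the per-pair sampling noise ($\mathrm{sd} \approx (1-\rho^2)/\sqrt{M}$)
well below the $\rho \ge 0.2$ effects the recovery tests plant.

Both generators are deterministic under a seed (Mersenne-Twister, recorded
in an attribute; reproducibility is claimed per-implementation, not across
RNG implementations) and restore the caller's RNG state. Neither emulates
real BOLD data: no hemodynamic response, no temporal autocorrelation, no
spatial smoothness, no scanner drift. A green recovery test therefore
establishes that the *engine* orders and computes coefficients correctly —
not that the pipeline is robust to physiological confounds, which are a
preprocessing concern out of scope here.

## File formats

Delimited text (one voxel per line), raw little-endian binary with a JSON
sidecar, and uncompressed single-file NIfTI-1 volumes are read natively; no
R NIfTI package is a dependency, so a minimal NIfTI-1 codec (five numeric
datatypes, slope/intercept scaling, little-endian only) is included.
Volumes are flattened with the first spatial axis varying fastest — the
file's native layout and the dominant neuroimaging convention — and an
optional 3D mask keeps voxels with nonzero mask value; the ordering
provenance travels in `voxel_order_tag`. The correlation store is a bare
scalar array (directly memory-mappable) plus a JSON sidecar holding the
voxel count, precision, degenerate bookkeeping and the full round trace;
`get_correlation()` serves random pair lookups with one positioned read,
and self-correlations return 1 by definition rather than being stored.

## Known limitations

* Single-machine, single-process; no GPU backend is shipped, only the seam
  for one.
* f32 is an emulation (demoted operands, double accumulation); a true
  float32 GEMM may differ in the last one or two single-precision ulps.
* Dynamic (windowed) connectivity, covariance/eigen analysis and
  correlation-array compression are out of scope.
* NIfTI support is deliberately minimal: no `.nii.gz`, no NIfTI-2, no
  extensions, no orientation handling beyond the raw voxel grid.
* The whole condensed array is materialized in RAM before being written;
  the budget governs the compute buffers, not the output array. Streaming
  each round's slice straight to disk would lift this and is the natural
  next step.
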