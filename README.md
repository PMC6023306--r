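# blockcor

Memory-budgeted computation of **all pairwise Pearson correlations** among
the rows of a voxels-by-timepoints matrix, emitted as a single condensed
array.

## The problem

Voxel-level functional connectivity analysis of fMRI data needs the Pearson
correlation of every pair of voxel time series. With N voxels that is
N(N−1)/2 coefficients — for a whole-brain image (N ≈ 10⁵) around 5 × 10⁹
values, far more than the working memory a naive N×N correlation matrix
would demand. `blockcor` computes the full set *out of core*: it streams
the computation in blocks sized to a user-given memory budget and writes
the strictly-upper-triangle coefficients, in a fixed row-major order, to a
flat on-disk array that supports O(1) random pair lookup.

The package is aimed at anyone who needs dense all-pairs correlation
(or cosine/dot-product similarity after normalization) at a scale where the
square matrix does not fit in memory — voxel-wise brain networks being the
motivating case.

## The method

For series x, y of length M the Pearson coefficient is

    r(x, y) = Σ(xᵢ − x̄)(yᵢ − ȳ) / √(Σ(xᵢ − x̄)² · Σ(yᵢ − ȳ)²)

Center each row v and scale it to unit L2 norm,

    u = (v − v̄) / ‖v − v̄‖₂ ,

and the coefficient becomes the plain dot product u·u′, so the whole
correlation matrix is the Gram matrix U Uᵀ of the normalized data. Given a
working-buffer budget of X scalars, the engine processes the rows in
rounds: with N′ voxels still unfinished, the next block holds

    B = ⌊X / 2N′⌋

voxels (a B×N′ product buffer plus its ≤ N′B − B(B+1)/2 extracted
coefficients is bounded by 2N′B scalars). The block's rows are multiplied
against all unfinished rows by a dense BLAS product, the strictly-upper-
triangle entries of the local frame (a < b) are extracted in row-major
order, and the slice is appended to the condensed array at offset

    k(i, j) = i·N − i(i+1)/2 + j − i − 1        (0-based, i < j).

The result is bit-for-bit independent of the budget up to floating-point
summation order: every feasible budget yields the same condensed array
within precision tolerance.

## Worked example

```r
library(blockcor)

ts <- generate_uniform(n_voxels = 300, n_timepoints = 100, seed = 42)
mat <- file.path(tempdir(), "uniform.txt")
cor_path <- file.path(tempdir(), "uniform.cor")
write_matrix(ts, mat, "delimited")

st <- cmd_compute(list(input = mat, output = cor_path, budget = "64K"))
#> N=300 voxels, M=100 timepoints, precision=f64
#> budget=65536 bytes (8192 f64 elements), 13 round(s)
#>   round 1: start=0 B=13 N'=300 out=[0, +3809)
#>   round 2: start=13 B=14 N'=287 out=[3809, +3913)
#>   ...
#>   round 13: start=267 B=33 N'=33 out=[44322, +528)
#> degenerate voxels: 0 (policy nan)
#> wrote 44850 coefficients to /tmp/.../uniform.cor
```

A 64 KiB budget holds only 8192 doubles, so the 300-voxel triangle
(44,850 coefficients) is computed in 13 rounds; the trace shows the block
size B growing as the number of unfinished voxels N′ shrinks, and the
`out=[offset, +length)` slices tiling the condensed array exactly.

```r
get_correlation(st, 12, 200)   # 0-based voxel indices, order-free
#> [1] 0.0841037
get_correlation(st, 200, 12)
#> [1] 0.0841037

cmd_verify(list(input = mat, store = cor_path, sample = 200))
#> verify: 200/200 pairs checked, max deviation 1.39e-16 (tol 1e-09)
#> verify: PASS
```

Uniform noise has no real structure, so 0.084 is the sampling-level
correlation expected at M = 100 (spread ≈ 1/√M); `verify` recomputes 200
random pairs from the raw series with two independent formulas and
confirms the store reproduces them to machine precision.

The same four verbs are available from a shell via the installed
`exec/blockcor` script: `compute`, `query`, `simulate`, `verify`.

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch:
simulates a uniform 500×100 matrix, computes its condensed array under a
tight (many-round) and an effectively unbounded (single-round) budget and
checks they agree elementwise, spot-verifies the store against the
definitional correlation, recovers a planted two-community correlation
structure, and pushes a masked 4D NIfTI volume through the compute/verify
path. Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It aborts with a nonzero status if any check fails.
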