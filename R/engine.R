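#' Construct a voxel-by-timepoint time-series matrix
#'
#' Thin container around an `N x M` numeric matrix: one row per voxel, one
#' column per timepoint, plus a provenance tag recording how the row order
#' was derived (mask flattening, file order, generator seed, ...).
#'
#' @param values Numeric matrix, voxels in rows, timepoints in columns.
#'   All values must be finite.
#' @param voxel_order_tag Free-text provenance of the row ordering.
#' @return An object of class `ts_matrix` with fields `values`, `n_voxels`,
#'   `n_timepoints`, `voxel_order_tag`.
#' @export
ts_matrix <- function(values, voxel_order_tag = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("values must be a numeric matrix")
  }
  bad <- which(!apply(values, 1L, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop_data("non-finite values in voxel row(s) %s (0-based: %s)",
              paste(utils::head(bad, 5), collapse = ", "),
              paste(utils::head(bad - 1L, 5), collapse = ", "))
  }
  structure(
    list(values = unname(values),
         n_voxels = nrow(values),
         n_timepoints = ncol(values),
         voxel_order_tag = voxel_order_tag),
    class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d voxels x %d timepoints (order: %s)\n",
              x$n_voxels, x$n_timepoints, x$voxel_order_tag))
  invisible(x)
}

#' Center and scale voxel time series to unit norm
#'
#' Replaces each row v by `(v - mean(v)) / ||v - mean(v)||_2`, after which
#' the Pearson correlation of any two voxels is the plain dot product of
#' their normalized rows. Rows whose centered norm falls at or below
#' `degenerate_eps * sqrt(M)` (constant series, for which correlation is
#' undefined) are zeroed and flagged in `degenerate_mask`.
#'
#' Under `precision = "f32"` the normalized values are demoted to single
#' precision ([demote_single()]); subsequent products still accumulate in
#' double, mimicking a single-precision GEMM pipeline with full-width
#' accumulators.
#'
#' @param ts A [ts_matrix()].
#' @param precision `"f64"` (default) or `"f32"`.
#' @param degenerate_eps Relative threshold for flagging constant rows;
#'   defaults to `1e-12` (f64) or `1e-6` (f32).
#' @return An object of class `normalized_matrix`: fields `values`
#'   (N x M matrix), `degenerate_mask` (logical N), `precision_tag`.
#' @examples
#' nm <- normalize_rows(ts_matrix(rbind(c(1, 2, 3), c(3, 2, 1))))
#' nm$values %*% t(nm$values)   # 2x2 correlation matrix
#' @export
normalize_rows <- function(ts, precision = c("f64", "f32"),
                           degenerate_eps = NULL) {
  stopifnot(inherits(ts, "ts_matrix"))
  precision <- match.arg(precision)
  if (ts$n_timepoints < 2) {
    stop_invalid("need at least 2 timepoints, got %d", ts$n_timepoints)
  }
  if (is.null(degenerate_eps)) {
    degenerate_eps <- if (precision == "f32") 1e-6 else 1e-12
  }
  v <- ts$values
  m <- ncol(v)
  centered <- v - rowMeans(v)
  norms <- sqrt(rowSums(centered^2))
  degenerate <- norms <= degenerate_eps * sqrt(m)
  safe_norms <- ifelse(degenerate, 1, norms)
  u <- centered / safe_norms
  u[degenerate, ] <- 0
  if (precision == "f32") u <- demote_single(u)
  structure(
    list(values = u,
         degenerate_mask = degenerate,
         precision_tag = precision),
    class = "normalized_matrix")
}

#' Pearson correlation, definitional form
#'
#' Centered cross-product over the product of centered norms. Serves as the
#' package's primary correctness oracle; the blocked engine must reproduce
#' it pairwise. If either series is constant the coefficient is undefined
#' and `NaN` is returned.
#'
#' @param x,y Numeric vectors of equal length `M >= 2`.
#' @return Correlation in `[-1, 1]`, or `NaN` for a constant input.
#' @seealso [pcc_single_pass()] for the raw-moment form.
#' @examples
#' pcc_direct(c(1, 2, 3), c(3, 2, 1)) # -1
#' @export
pcc_direct <- function(x, y) {
  check_pair(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  if (denom == 0) return(NaN)
  sum(xc * yc) / denom
}

#' Pearson correlation, single-pass raw-moment form
#'
#' Algebraically equivalent reformulation using only raw sums
#' (`sum x`, `sum x^2`, `sum xy`), historically preferred on hardware where
#' divisions are expensive. Less numerically robust than [pcc_direct()]
#' under extreme means, so it is used here as an independent second oracle,
#' not as the engine.
#'
#' @inheritParams pcc_direct
#' @return Correlation in `[-1, 1]`, or `NaN` for a constant input.
#' @export
pcc_single_pass <- function(x, y) {
  check_pair(x, y)
  t <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- t * sum(x * y) - sx * sy
  dx <- t * sum(x^2) - sx^2
  dy <- t * sum(y^2) - sy^2
  if (dx <= 0 || dy <= 0) return(NaN)
  num / (sqrt(dx) * sqrt(dy))
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop_invalid("series lengths differ: %d vs %d", length(x), length(y))
  }
  if (length(x) < 2) stop_invalid("need at least 2 timepoints")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_data("non-finite values in input series")
  }
}

#' Plan the blocked rounds under a working-memory budget
#'
#' Given a budget of `budget_elements` working-buffer scalars, the block
#' size for a round with `N'` unfinished voxels is `B = floor(X / (2 N'))`:
#' the round needs `B x N'` product entries plus at most `N'B - B(B+1)/2`
#' condensed entries, bounded above by `2 N' B`. If the very first candidate
#' `B` exceeds `N` the whole triangle fits in one round. Otherwise rounds
#' are emitted greedily: consume `B` voxels, shrink `N'`, recompute `B`
#' (clamped to `N'` when it overshoots), until all voxels are consumed.
#' The budget covers only the per-round buffers; the `N x M` normalized
#' matrix is held for the whole run and accounted separately.
#'
#' @param n Voxel count, `n >= 2`.
#' @param m Timepoint count (recorded for provenance; not part of the
#'   working-buffer bound).
#' @param budget_elements Scalar working-buffer budget `X`, in elements of
#'   the working precision. Must be at least `2 n`, otherwise no round fits.
#' @return An object of class `block_plan`: `budget_elements`, `n_voxels`,
#'   `n_timepoints`, `single_round`, and `rounds`, a data.frame with one row
#'   per round and columns `start` (0-based first voxel of the block),
#'   `block_size` (B), `remaining` (N', unfinished voxels including the
#'   block), `out_offset` (0-based position in the condensed array) and
#'   `out_length` (`N'B - B(B+1)/2`).
#' @examples
#' plan_blocks(5, 10, budget_elements = 20) # two rounds: B = 2 then B = 3
#' @export
plan_blocks <- function(n, m, budget_elements) {
  n <- as_count(n, "n")
  x <- as_count(budget_elements, "budget_elements")
  if (n < 2) stop_invalid("need at least 2 voxels, got %d", n)
  b <- floor(x / (2 * n))
  if (b < 1) {
    stop_budget(
      "budget of %.0f elements cannot fit one row block for %.0f voxels; minimum feasible budget is %.0f elements",
      x, n, 2 * n)
  }
  if (b > n) {
    rounds <- data.frame(start = 0, block_size = n, remaining = n,
                         out_offset = 0, out_length = triangle_size(n))
    single <- TRUE
  } else {
    start <- 0
    np <- n
    starts <- blocks <- rems <- numeric(0)
    while (start < n) {
      b <- min(b, np)
      starts <- c(starts, start)
      blocks <- c(blocks, b)
      rems <- c(rems, np)
      start <- start + b
      np <- np - b
      if (np > 0) {
        b <- floor(x / (2 * np))
        if (b > np) b <- np
      }
    }
    out_len <- rems * blocks - blocks * (blocks + 1) / 2
    rounds <- data.frame(start = starts, block_size = blocks,
                         remaining = rems,
                         out_offset = cumsum(c(0, out_len[-length(out_len)])),
                         out_length = out_len)
    single <- FALSE
  }
  structure(
    list(budget_elements = x, n_voxels = n, n_timepoints = m,
         single_round = single, rounds = rounds),
    class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("<block_plan> %.0f voxels, budget %.0f elements, %d round(s)%s\n",
              x$n_voxels, x$budget_elements, nrow(x$rounds),
              if (x$single_round) " [single-round]" else ""))
  print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' Correlations of one voxel block against all unfinished voxels
#'
#' For the round starting at voxel `s` with block size `B` and `N'`
#' unfinished voxels, computes the `B x N'` sub-block of the correlation
#' matrix: entry `(a, b)` is the dot product of normalized rows `s + a` and
#' `s + b` (0-based local indices). The `"blas"` backend is the reference
#' dense product (`tcrossprod` via the linked BLAS); `"naive"` is a plain
#' R loop kept as an independent seam for backend validation.
#'
#' @param nm A [normalize_rows()] result.
#' @param round One-row slice of a [plan_blocks()] `rounds` data.frame.
#' @param backend `"blas"` (default) or `"naive"`.
#' @return A `B x N'` numeric matrix; under `f32` its entries are demoted
#'   to single precision.
#' @export
block_products <- function(nm, round, backend = c("blas", "naive")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  backend <- match.arg(backend)
  n <- nrow(nm$values)
  b <- round$block_size
  np <- round$remaining
  if (round$start + np != n || b > np) {
    stop_invalid("round (start %.0f, B %.0f, N' %.0f) inconsistent with %d-voxel matrix",
                 round$start, b, np, n)
  }
  rows <- round$start + seq_len(b)          # 1-based R rows of the block
  cols <- round$start + seq_len(np)
  s <- switch(backend,
    blas = tcrossprod(nm$values[rows, , drop = FALSE],
                      nm$values[cols, , drop = FALSE]),
    naive = {
      u <- nm$values
      out <- matrix(0, b, np)
      for (a in seq_len(b)) {
        for (bb in seq_len(np)) {
          out[a, bb] <- sum(u[rows[a], ] * u[cols[bb], ])
        }
      }
      out
    })
  if (nm$precision_tag == "f32") s <- demote_single(s)
  s
}

#' Extract the ordered strictly-upper-triangle slice of a block product
#'
#' From the `B x N'` block product keeps exactly the entries with local
#' indices `a < b` and emits them in row-major pair order (all of local row
#' 0 first, then row 1, ...), i.e. local position
#' `a*N' - a*(a+1)/2 + b - a - 1`. The slice length is `N'B - B(B+1)/2`;
#' when the round covers the whole matrix (`B = N' = N`) this is the entire
#' condensed array.
#'
#' @param s Matrix from [block_products()] for the same round.
#' @param round The round the product was computed for.
#' @return Numeric vector of length `round$out_length`.
#' @export
extract_upper_block <- function(s, round) {
  if (!is.matrix(s) || nrow(s) != round$block_size ||
      ncol(s) != round$remaining) {
    stop_invalid("block product is %dx%d but round expects %.0fx%.0f",
                 nrow(s), ncol(s), round$block_size, round$remaining)
  }
  # row-major traversal of {a < b} equals column-major traversal of the
  # transpose restricted to its strictly lower triangle
  st <- t(s)
  out <- st[row(st) > col(st)]
  stopifnot(length(out) == round$out_length)
  out
}

#' Compute the full condensed correlation array under a memory budget
#'
#' End-to-end driver: normalizes the time series, plans the rounds for the
#' given working-buffer budget, and for each round multiplies the block
#' against all unfinished voxels and appends the ordered upper-triangle
#' slice at its offset. The result is independent of the budget (up to
#' floating-point summation order): any feasible budget yields the same
#' condensed array within precision tolerance.
#'
#' Degenerate voxels (constant series; correlation undefined) are handled
#' per `degenerate_policy`: `"nan"` stores NaN for every pair touching such
#' a voxel (default), `"zero"` stores 0, `"error"` aborts naming the first
#' offending voxel.
#'
#' @param ts A [ts_matrix()] (or bare numeric matrix, voxels in rows).
#' @param budget_elements Working-buffer budget in scalars; see
#'   [plan_blocks()].
#' @param precision `"f64"` (default) or `"f32"`.
#' @param degenerate_policy `"nan"`, `"zero"` or `"error"`.
#' @param backend Product backend, see [block_products()].
#' @return An object of class `condensed_correlation`: `values` (length
#'   `triangle_size(N)` vector, row-major upper-triangle order), `n_voxels`,
#'   `order_tag` (`"upper-row-major"`), `precision_tag`, `degenerate_policy`,
#'   `degenerate_voxels` (0-based indices) and `plan` (the [plan_blocks()]
#'   object used).
#' @examples
#' ts <- ts_matrix(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)))
#' compute_condensed(ts, budget_elements = 1e6)$values # -1 1 -1
#' @export
compute_condensed <- function(ts, budget_elements,
                              precision = c("f64", "f32"),
                              degenerate_policy = c("nan", "zero", "error"),
                              backend = c("blas", "naive")) {
  if (is.matrix(ts)) ts <- ts_matrix(ts)
  stopifnot(inherits(ts, "ts_matrix"))
  precision <- match.arg(precision)
  degenerate_policy <- match.arg(degenerate_policy)
  backend <- match.arg(backend)
  n <- ts$n_voxels
  if (n < 2) stop_invalid("need at least 2 voxels, got %d", n)

  nm <- normalize_rows(ts, precision = precision)
  degenerate <- which(nm$degenerate_mask) - 1L     # 0-based
  if (degenerate_policy == "error" && length(degenerate) > 0) {
    stop_data("degenerate (constant) voxel at 0-based index %d", degenerate[1])
  }

  plan <- plan_blocks(n, ts$n_timepoints, budget_elements)
  values <- numeric(triangle_size(n))
  for (r in seq_len(nrow(plan$rounds))) {
    round <- plan$rounds[r, ]
    s <- block_products(nm, round, backend = backend)
    values[round$out_offset + seq_len(round$out_length)] <-
      extract_upper_block(s, round)
  }

  if (degenerate_policy == "nan" && length(degenerate) > 0) {
    fill <- NaN
    for (d in degenerate) {
      others <- setdiff(0:(n - 1), d)
      k <- pair_to_linear(pmin(others, d), pmax(others, d), n)
      values[k + 1] <- fill
    }
  }
  # under "zero" the zeroed normalized rows already produce exact 0 dot
  # products, so nothing to patch

  structure(
    list(values = values, n_voxels = n, order_tag = "upper-row-major",
         precision_tag = precision, degenerate_policy = degenerate_policy,
         degenerate_voxels = degenerate, plan = plan),
    class = "condensed_correlation")
}

#' @export
print.condensed_correlation <- function(x, ...) {
  cat(sprintf(
    "<condensed_correlation> %.0f coefficients for %.0f voxels (%s, %s)\n",
    length(x$values), x$n_voxels, x$order_tag, x$precision_tag))
  if (length(x$degenerate_voxels) > 0) {
    cat(sprintf("  %d degenerate voxel(s), policy '%s'\n",
                length(x$degenerate_voxels), x$degenerate_policy))
  }
  invisible(x)
}
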