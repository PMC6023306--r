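#' Number of distinct unordered pairs among n voxels
#'
#' The condensed correlation array of an `n`-voxel dataset holds the strictly
#' upper triangle of the symmetric correlation matrix, i.e. `n*(n-1)/2`
#' coefficients. Counts are returned as doubles, which represent integers
#' exactly up to 2^53 and therefore cover any realistic voxel count
#' (n up to 1e7 needs ~5e13).
#'
#' @param n Integer (scalar or vector), total voxel count, `n >= 0`.
#' @return Number of unordered pairs, `n*(n-1)/2`, as a double.
#' @examples
#' triangle_size(4)      # 6
#' triangle_size(100000) # 4999950000, exact
#' @export
triangle_size <- function(n) {
  n <- as_count(n, "n")
  if (any(n < 0)) {
    stop_invalid("n must be non-negative")
  }
  n * (n - 1) / 2
}

#' Map a voxel pair to its condensed-array position
#'
#' The condensed array stores the strictly upper triangle of the correlation
#' matrix in row-major order: all pairs `(0, j)` first, then `(1, j)`, and so
#' on. For a pair `i < j` the 0-based position is
#' `k = i*n - i*(i+1)/2 + j - i - 1`. Enumerating pairs lexicographically
#' yields `k = 0, 1, 2, ...`.
#'
#' All indices are 0-based, matching byte/element offsets in the on-disk
#' store. Callers must supply `i < j`; [get_correlation()] provides the
#' symmetric (order-free) lookup.
#'
#' @param i,j 0-based voxel indices with `0 <= i < j < n`. Vectors recycle.
#' @param n Total voxel count.
#' @return 0-based condensed position(s), as a double.
#' @seealso [linear_to_pair()] for the inverse, [get_correlation()].
#' @examples
#' pair_to_linear(0, 1, 4) # 0
#' pair_to_linear(2, 3, 4) # 5, the last of the 6 pairs
#' @export
pair_to_linear <- function(i, j, n) {
  i <- as_count(i, "i")
  j <- as_count(j, "j")
  n <- as_count(n, "n")
  if (any(i < 0) || any(i >= j) || any(j >= n)) {
    stop_invalid("pair indices must satisfy 0 <= i < j < n")
  }
  i * n - i * (i + 1) / 2 + j - i - 1
}

#' Map a condensed-array position back to its voxel pair
#'
#' Inverse of [pair_to_linear()]. The row index is located from the
#' triangular row offsets `off(i) = i*n - i*(i+1)/2`: a floating-point
#' square-root guess followed by an exact integer correction of at most one
#' step in each direction, so the mapping is exact for every valid `k` even
#' where `sqrt` alone would mis-round (large n).
#'
#' @param k 0-based condensed position(s), `0 <= k < triangle_size(n)`.
#' @param n Total voxel count.
#' @return A list with components `i` and `j` (0-based voxel indices,
#'   same length as `k`) satisfying `pair_to_linear(i, j, n) == k`.
#' @examples
#' linear_to_pair(5, 4) # i = 2, j = 3
#' @export
linear_to_pair <- function(k, n) {
  k <- as_count(k, "k")
  n <- as_count(n, "n")
  total <- n * (n - 1) / 2
  if (any(k < 0) || any(k >= total)) {
    stop_invalid("k must satisfy 0 <= k < n*(n-1)/2")
  }
  # off(i) = i*n - i*(i+1)/2 is the position of pair (i, i+1); want the
  # largest i with off(i) <= k.  Solving off(i+1) > k gives the guess below.
  i <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  i <- pmax(i, 0)
  off <- function(i) i * n - i * (i + 1) / 2
  # exact correction: the guess is off by at most 1 either way
  too_high <- off(i) > k
  i[too_high] <- i[too_high] - 1
  too_low <- off(i + 1) <= k
  i[too_low] <- i[too_low] + 1
  j <- k - off(i) + i + 1
  list(i = i, j = j)
}

# coerce index-like input to exact double counts; rejects NA and fractions
as_count <- function(x, what) {
  if (length(x) == 0 || anyNA(x) || !is.numeric(x)) {
    stop_invalid(sprintf("%s must be numeric and non-missing", what))
  }
  x <- as.double(x)
  if (any(x != floor(x))) {
    stop_invalid(sprintf("%s must be a whole number", what))
  }
  x
}
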