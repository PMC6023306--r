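#' Read a voxel-by-timepoint matrix from disk
#'
#' Three input layouts are supported:
#' \describe{
#'   \item{`delimited`}{Plain text, one voxel per line, values separated by
#'     whitespace or commas; no header unless `header = TRUE`.}
#'   \item{`raw`}{Little-endian binary scalar array with a JSON sidecar at
#'     `<path>.json` holding `n_voxels`, `n_timepoints`, `precision`
#'     (`"f32"`/`"f64"`) and `layout` (`"row-major"`).}
#'   \item{`volume4d`}{An uncompressed 4D NIfTI-1 volume. Voxels are
#'     flattened with the first spatial axis varying fastest (the file's
#'     native order); an optional 3D mask of identical spatial dimensions
#'     keeps only voxels with nonzero mask value.}
#' }
#'
#' @param path Input file.
#' @param format `"delimited"`, `"raw"` or `"volume4d"`.
#' @param mask For `volume4d`: a 3D array or path to a 3D NIfTI mask.
#' @param drop_degenerate Drop constant-series voxels before computation;
#'   their original 0-based indices are recorded in the
#'   `dropped_voxels` attribute of the result.
#' @param header For `delimited`: skip a header line.
#' @return A [ts_matrix()] whose `voxel_order_tag` records provenance.
#' @export
read_matrix <- function(path, format = c("delimited", "raw", "volume4d"),
                        mask = NULL, drop_degenerate = FALSE,
                        header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("no such file: %s", path)
  ts <- switch(format,
    delimited = read_matrix_delimited(path, header),
    raw = read_matrix_raw(path),
    volume4d = read_matrix_volume(path, mask))
  if (ts$n_voxels < 2) stop_data("need at least 2 voxels, got %d", ts$n_voxels)
  if (ts$n_timepoints < 2) {
    stop_data("need at least 2 timepoints, got %d", ts$n_timepoints)
  }
  if (drop_degenerate) {
    centered <- ts$values - rowMeans(ts$values)
    degen <- sqrt(rowSums(centered^2)) <= 1e-12 * sqrt(ts$n_timepoints)
    if (any(degen)) {
      kept <- ts_matrix(ts$values[!degen, , drop = FALSE],
                        paste0(ts$voxel_order_tag, " [degenerate dropped]"))
      attr(kept, "dropped_voxels") <- which(degen) - 1L
      return(kept)
    }
  }
  ts
}

read_matrix_delimited <- function(path, header) {
  dt <- tryCatch(
    data.table::fread(path, header = header, data.table = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop_data("cannot parse %s: %s", path, conditionMessage(e)))
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop_data("%s contains non-numeric fields", path)
  ts_matrix(m, sprintf("delimited file %s (line order)", basename(path)))
}

read_matrix_raw <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_data("missing sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("n_voxels", "n_timepoints", "precision")) {
    if (is.null(meta[[f]])) stop_data("sidecar %s lacks field '%s'", sidecar, f)
  }
  n <- as.integer(meta$n_voxels)
  m <- as.integer(meta$n_timepoints)
  width <- scalar_width(meta$precision)
  expected <- as.numeric(n) * m * width
  if (file.size(path) != expected) {
    stop_corrupt("%s: %.0f bytes on disk but sidecar implies %.0f",
                 path, file.size(path), expected)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n * m, size = width, endian = "little")
  layout <- if (is.null(meta$layout)) "row-major" else meta$layout
  mat <- if (identical(layout, "row-major")) {
    matrix(vals, nrow = n, ncol = m, byrow = TRUE)
  } else {
    matrix(vals, nrow = n, ncol = m)
  }
  ts_matrix(mat, sprintf("raw binary %s (%s, %s)", basename(path),
                         meta$precision, layout))
}

read_matrix_volume <- function(path, mask) {
  vol <- read_nifti(path)
  if (length(vol$dim) != 4) {
    stop_data("%s is %dD; the volume4d format needs a 4D image",
              path, length(vol$dim))
  }
  sp <- vol$dim[1:3]
  m <- vol$dim[4]
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- read_nifti(mask)$data
    if (!identical(as.integer(dim(mask)), as.integer(sp))) {
      stop_data("mask dimensions (%s) do not match volume grid (%s)",
                paste(dim(mask), collapse = "x"), paste(sp, collapse = "x"))
    }
    keep <- which(mask != 0)      # column-major: first axis fastest
  } else {
    keep <- seq_len(prod(sp))
  }
  flat <- vol$data
  dim(flat) <- c(prod(sp), m)
  ts <- ts_matrix(flat[keep, , drop = FALSE],
                  sprintf("volume %s flattened x-fastest%s", basename(path),
                          if (is.null(mask)) "" else
                            sprintf(", %d-voxel mask", length(keep))))
  attr(ts, "mask_indices") <- keep - 1L    # 0-based flat voxel indices
  ts
}

#' Write a time-series matrix to disk
#'
#' Counterpart of [read_matrix()]. `delimited` writes space-separated text;
#' `raw` writes little-endian binary plus the JSON sidecar; `volume4d`
#' reshapes the matrix into a `vol_dim` spatial grid (voxels must fill the
#' grid exactly, first axis fastest) and writes a NIfTI-1 volume.
#'
#' @param ts A [ts_matrix()].
#' @param path Output file.
#' @param format `"delimited"`, `"raw"` or `"volume4d"`.
#' @param precision Scalar width for `raw`/`volume4d` output.
#' @param vol_dim Length-3 spatial dimensions, required for `volume4d`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(ts, path, format = c("delimited", "raw", "volume4d"),
                         precision = c("f64", "f32"), vol_dim = NULL) {
  stopifnot(inherits(ts, "ts_matrix"))
  format <- match.arg(format)
  precision <- match.arg(precision)
  switch(format,
    delimited = {
      data.table::fwrite(as.data.frame(ts$values), path, sep = " ",
                         col.names = FALSE)
    },
    raw = {
      width <- scalar_width(precision)
      con <- file(path, "wb")
      writeBin(as.double(t(ts$values)), con, size = width, endian = "little")
      close(con)
      jsonlite::write_json(
        list(n_voxels = ts$n_voxels, n_timepoints = ts$n_timepoints,
             precision = precision, layout = "row-major",
             endian = "little", voxel_order_tag = ts$voxel_order_tag),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    },
    volume4d = {
      if (is.null(vol_dim) || length(vol_dim) != 3) {
        stop_invalid("volume4d output needs vol_dim = c(x, y, z)")
      }
      if (prod(vol_dim) != ts$n_voxels) {
        stop_invalid("vol_dim %s holds %.0f voxels but matrix has %d",
                     paste(vol_dim, collapse = "x"), prod(vol_dim),
                     ts$n_voxels)
      }
      arr <- array(ts$values, dim = c(vol_dim, ts$n_timepoints))
      write_nifti(arr, path,
                  datatype = if (precision == "f32") "float32" else "float64")
    })
  invisible(path)
}

#' Persist a condensed correlation array with random-access metadata
#'
#' Writes the coefficients as a bare little-endian scalar array (directly
#' memory-mappable; no embedded header) plus a JSON sidecar at
#' `<path>.json` recording the voxel count, precision, ordering, degenerate
#' policy and voxels, the per-round trace of the blocked execution, and an
#' input checksum when available.
#'
#' @param cond A [compute_condensed()] result.
#' @param path Output data file; the sidecar goes to `<path>.json`.
#' @param input_checksum Optional MD5 of the input matrix file.
#' @return A `correlation_store` handle (see [read_store()]), invisibly.
#' @export
write_store <- function(cond, path, input_checksum = NULL) {
  stopifnot(inherits(cond, "condensed_correlation"))
  width <- scalar_width(cond$precision_tag)
  con <- file(path, "wb")
  writeBin(as.double(cond$values), con, size = width, endian = "little")
  close(con)
  rounds <- cond$plan$rounds
  meta <- list(
    n_voxels = cond$n_voxels,
    n_timepoints = cond$plan$n_timepoints,
    n_coefficients = length(cond$values),
    precision_tag = cond$precision_tag,
    order_tag = cond$order_tag,
    degenerate_policy = cond$degenerate_policy,
    degenerate_voxels = as.integer(cond$degenerate_voxels),
    budget_elements = cond$plan$budget_elements,
    single_round = cond$plan$single_round,
    rounds = rounds,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksum = input_checksum)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(read_store(path))
}

#' Open a correlation store for random pair lookup
#'
#' Validates that the sidecar is self-consistent (round trace out-lengths
#' summing to `triangle_size(n)`) and that the data file has exactly the
#' byte length the sidecar implies, then returns a lightweight handle;
#' coefficients are read on demand by [get_correlation()].
#'
#' @param path Data file written by [write_store()].
#' @return An object of class `correlation_store`.
#' @export
read_store <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop_data("no such file: %s", path)
  if (!file.exists(sidecar)) stop_data("missing sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- as.numeric(meta$n_voxels)
  total <- triangle_size(n)
  width <- scalar_width(meta$precision_tag)
  if (!isTRUE(all.equal(sum(meta$rounds$out_length), total))) {
    stop_corrupt("%s: round trace covers %.0f coefficients, expected %.0f",
                 sidecar, sum(meta$rounds$out_length), total)
  }
  if (file.size(path) != total * width) {
    stop_corrupt("%s: %.0f bytes on disk but %.0f expected for %.0f voxels",
                 path, file.size(path), total * width, n)
  }
  structure(list(data_path = path, sidecar_path = sidecar, meta = meta,
                 n_voxels = n, width = width),
            class = "correlation_store")
}

#' @export
print.correlation_store <- function(x, ...) {
  cat(sprintf("<correlation_store> %s: %.0f voxels, %.0f coefficients (%s)\n",
              x$data_path, x$n_voxels, triangle_size(x$n_voxels),
              x$meta$precision_tag))
  invisible(x)
}

#' Look up the correlation of a voxel pair in a store
#'
#' Voxel indices are 0-based and order-free: `(i, j)` and `(j, i)` return
#' the same coefficient via a single positioned read at
#' `pair_to_linear(min(i,j), max(i,j), n)`. The self-correlation `i == j`
#' is 1 by definition and is not stored.
#'
#' @param store A [read_store()] handle.
#' @param i,j 0-based voxel indices.
#' @return The stored correlation (possibly NaN for a degenerate voxel
#'   under the `"nan"` policy), or exactly 1 when `i == j`.
#' @export
get_correlation <- function(store, i, j) {
  stopifnot(inherits(store, "correlation_store"))
  i <- as_count(i, "i"); j <- as_count(j, "j")
  n <- store$n_voxels
  if (length(i) != 1 || length(j) != 1 || i < 0 || j < 0 || i >= n || j >= n) {
    stop_invalid("voxel indices must be single values in [0, %.0f)", n)
  }
  if (i == j) return(1)
  k <- pair_to_linear(min(i, j), max(i, j), n)
  con <- file(store$data_path, "rb")
  on.exit(close(con))
  seek(con, k * store$width)
  readBin(con, "double", 1L, size = store$width, endian = "little")
}

#' Read the full condensed array back from a store
#'
#' @param store A [read_store()] handle.
#' @return Numeric vector of length `triangle_size(n_voxels)` in
#'   row-major upper-triangle order.
#' @export
store_values <- function(store) {
  stopifnot(inherits(store, "correlation_store"))
  total <- triangle_size(store$n_voxels)
  con <- file(store$data_path, "rb")
  on.exit(close(con))
  readBin(con, "double", total, size = store$width, endian = "little")
}
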