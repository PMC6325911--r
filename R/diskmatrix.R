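#' File-backed dense matrices
#'
#' A `disk_matrix` is a handle to a dense real matrix stored in a headerless
#' raw binary file: IEEE-754 values (binary32 for `"single"`, binary64 for
#' `"double"`), little-endian, row-major, no header — the dimensions travel
#' with the handle, not the file. This is the storage format used for GRMs,
#' genotype matrices, and all factorization outputs; plain-text matrices are
#' converted with [text_to_binary()] / [binary_to_text()]. All bulk access
#' goes through row tiles bounded by a tile budget, so arbitrarily large
#' matrices are processed with bounded resident memory.
#'
#' @param path Path to the binary matrix file.
#' @param n_rows,n_cols Matrix dimensions (rows usually index individuals,
#'   columns markers; `n_cols == n_rows` for a GRM).
#' @param precision `"single"` or `"double"`.
#' @return A `disk_matrix` handle (list with `path`, `n_rows`, `n_cols`,
#'   `precision`).
#' @export
#' @examples
#' p <- tempfile()
#' dm <- write_matrix(matrix(1:6, 2, 3), p, precision = "double")
#' open_matrix(p, 2, 3, "double")
#' as.matrix(dm)
open_matrix <- function(path, n_rows, n_cols, precision = c("double", "single")) {
  precision <- match.arg(precision)
  check_dims(n_rows, n_cols)
  if (!file.exists(path)) {
    ocm_io_error("matrix file '%s' does not exist", path)
  }
  expected <- as.numeric(n_rows) * n_cols * element_size(precision)
  actual <- as.numeric(file.info(path)$size)
  if (actual != expected) {
    ocm_dimension_error(
      "file '%s' holds %.0f bytes but a %d x %d %s-precision matrix needs %.0f",
      path, actual, n_rows, n_cols, precision, expected
    )
  }
  disk_matrix(path, n_rows, n_cols, precision)
}

# bare constructor (no file checks); internal
disk_matrix <- function(path, n_rows, n_cols, precision) {
  structure(
    list(path = path, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         precision = precision),
    class = "disk_matrix"
  )
}

element_size <- function(precision) {
  switch(precision, single = 4L, double = 8L,
         ocm_parameter_error("unknown precision '%s'", precision))
}

check_dims <- function(n_rows, n_cols) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1 ||
      n_rows != floor(n_rows) || n_cols != floor(n_cols)) {
    ocm_parameter_error("matrix dimensions must be positive integers")
  }
}

#' @export
dim.disk_matrix <- function(x) c(x$n_rows, x$n_cols)

#' @export
print.disk_matrix <- function(x, ...) {
  cat(sprintf("<disk_matrix %d x %d, %s precision>\n  %s\n",
              x$n_rows, x$n_cols, x$precision, x$path))
  invisible(x)
}

#' @export
as.matrix.disk_matrix <- function(x, ...) full_matrix(x)

#' Write a dense matrix (or vector) to a binary matrix file
#'
#' @param x Numeric matrix, or vector (written as a one-column matrix).
#' @inheritParams open_matrix
#' @return The `disk_matrix` handle for the written file, invisibly usable
#'   like any other handle.
#' @export
write_matrix <- function(x, path, precision = c("double", "single")) {
  precision <- match.arg(precision)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  write_block(con, x, precision)
  disk_matrix(path, nrow(x), ncol(x), precision)
}

# append one dense block (rows) to an open binary connection, row-major
write_block <- function(con, block, precision) {
  v <- if (is.matrix(block)) as.vector(t(block)) else as.double(block)
  writeBin(as.double(v), con, size = element_size(precision),
           endian = "little")
}

#' Read a contiguous block of rows from a disk matrix
#'
#' @param x A `disk_matrix`.
#' @param first 1-based index of the first row to read.
#' @param n Number of rows.
#' @param validate Reject non-finite values (`NaN`/`Inf`), the default for
#'   genotype and GRM data which are finite by construction; set `FALSE` for
#'   raw pass-through.
#' @return Dense `n` x `n_cols` matrix.
#' @export
read_rows <- function(x, first, n, validate = TRUE) {
  if (first < 1 || n < 1 || first + n - 1 > x$n_rows) {
    ocm_dimension_error("row range [%d, %d] outside 1..%d", first,
                        first + n - 1, x$n_rows)
  }
  es <- element_size(x$precision)
  con <- file(x$path, "rb")
  on.exit(close(con))
  seek(con, (as.numeric(first) - 1) * x$n_cols * es, origin = "start")
  v <- readBin(con, "double", n = n * x$n_cols, size = es, endian = "little")
  if (length(v) != n * x$n_cols) {
    ocm_io_error("short read from '%s'", x$path)
  }
  if (validate && any(!is.finite(v))) {
    ocm_format_error("non-finite value in '%s' (validated read)", x$path)
  }
  matrix(v, nrow = n, byrow = TRUE)
}

# contiguous column strip [first, first+n-1], all rows; one seek per row
read_cols <- function(x, first, n, validate = TRUE) {
  if (first < 1 || n < 1 || first + n - 1 > x$n_cols) {
    ocm_dimension_error("column range [%d, %d] outside 1..%d", first,
                        first + n - 1, x$n_cols)
  }
  es <- element_size(x$precision)
  con <- file(x$path, "rb")
  on.exit(close(con))
  out <- matrix(NA_real_, x$n_rows, n)
  for (i in seq_len(x$n_rows)) {
    seek(con, ((as.numeric(i) - 1) * x$n_cols + first - 1) * es,
         origin = "start")
    out[i, ] <- readBin(con, "double", n = n, size = es, endian = "little")
  }
  if (validate && any(!is.finite(out))) {
    ocm_format_error("non-finite value in '%s' (validated read)", x$path)
  }
  out
}

read_element <- function(x, i, j) {
  es <- element_size(x$precision)
  con <- file(x$path, "rb")
  on.exit(close(con))
  seek(con, ((as.numeric(i) - 1) * x$n_cols + j - 1) * es, origin = "start")
  readBin(con, "double", n = 1L, size = es, endian = "little")
}

#' @rdname read_rows
#' @export
full_matrix <- function(x, validate = TRUE) {
  if (inherits(x, "disk_matrix")) read_rows(x, 1L, x$n_rows, validate) else
    as.matrix(x)
}

#' Plan and stream row tiles under an element budget
#'
#' `tile_plan()` partitions the rows of a matrix into contiguous tiles of at
#' most `max_tile_elements` elements each (at least one full row per tile).
#' `map_row_tiles()` applies `f(tile, block)` to each tile in order, where
#' `tile` is a one-row data frame of the plan and `block` the dense rows.
#' Together they are the out-of-core iteration primitive: tiles cover
#' `1..n_rows` exactly once, in order, with no overlap.
#'
#' @param x A `disk_matrix` (or anything with `dim()`).
#' @param max_tile_elements Tile budget in elements; must be at least one
#'   row (`n_cols`).
#' @return `tile_plan()`: data frame with columns `first`, `last`, `n_rows`.
#'   `map_row_tiles()`: invisible list of the `f` results.
#' @export
tile_plan <- function(x, max_tile_elements = default_tile_budget()) {
  d <- dim(x)
  tile_plan_dims(d[1], d[2], max_tile_elements)
}

tile_plan_dims <- function(n_rows, n_cols,
                           max_tile_elements = default_tile_budget()) {
  if (max_tile_elements < n_cols) {
    ocm_parameter_error(
      "tile budget %.0f is below one row (%d elements)",
      max_tile_elements, n_cols
    )
  }
  per <- max(1, floor(max_tile_elements / n_cols))
  first <- seq(1L, n_rows, by = per)
  last <- pmin(first + per - 1L, n_rows)
  data.frame(first = as.integer(first), last = as.integer(last),
             n_rows = as.integer(last - first + 1L))
}

#' @rdname tile_plan
#' @param f Function of `(tile, block)`.
#' @param validate Passed to [read_rows()].
#' @export
map_row_tiles <- function(x, f, max_tile_elements = default_tile_budget(),
                          validate = TRUE) {
  plan <- tile_plan(x, max_tile_elements)
  out <- vector("list", nrow(plan))
  for (t in seq_len(nrow(plan))) {
    block <- read_rows(x, plan$first[t], plan$n_rows[t], validate = validate)
    out[[t]] <- f(plan[t, ], block)
  }
  invisible(out)
}

#' Convert a plain-text matrix to binary, and back
#'
#' Text matrices are whitespace-separated decimal numbers, one matrix row
#' per line (scientific notation accepted); binary is the raw headerless
#' format of [open_matrix()]. Conversion streams line chunks, so file size is
#' not memory-bound. Round trip preserves every value to the precision's
#' decimal guarantee (9 significant digits for single, 17 for double), which
#' is what the default `digits` of `binary_to_text()` emit.
#'
#' @param text_path Input text file.
#' @param out_path Output file.
#' @inheritParams open_matrix
#' @param validate Reject non-finite parsed values.
#' @param chunk_lines Lines read per streamed chunk.
#' @return A `disk_matrix` handle on the written binary file.
#' @export
text_to_binary <- function(text_path, out_path,
                           precision = c("double", "single"),
                           validate = TRUE, chunk_lines = 2048L) {
  precision <- match.arg(precision)
  if (!file.exists(text_path)) {
    ocm_io_error("text matrix '%s' does not exist", text_path)
  }
  tin <- file(text_path, "r")
  on.exit(close(tin), add = TRUE)
  bout <- file(out_path, "wb")
  on.exit(close(bout), add = TRUE)
  n_cols <- NULL
  n_rows <- 0L
  repeat {
    lines <- readLines(tin, n = chunk_lines)
    if (length(lines) == 0L) break
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    for (k in seq_along(toks)) {
      lineno <- n_rows + k
      tk <- toks[[k]]
      if (length(tk) == 1L && !nzchar(tk)) {
        ocm_format_error("line %d of '%s' is empty", lineno, text_path)
      }
      if (is.null(n_cols)) n_cols <- length(tk)
      if (length(tk) != n_cols) {
        ocm_format_error(
          "ragged row: line %d of '%s' has %d values, expected %d",
          lineno, text_path, length(tk), n_cols
        )
      }
      v <- suppressWarnings(as.numeric(tk))
      if (anyNA(v)) {
        bad <- tk[is.na(v)][1]
        ocm_format_error("non-numeric token '%s' at line %d of '%s'",
                         bad, lineno, text_path)
      }
      if (validate && any(!is.finite(v))) {
        ocm_format_error("non-finite value at line %d of '%s'", lineno,
                         text_path)
      }
      writeBin(v, bout, size = element_size(precision), endian = "little")
    }
    n_rows <- n_rows + length(lines)
  }
  if (n_rows == 0L) {
    ocm_format_error("text matrix '%s' has no rows", text_path)
  }
  disk_matrix(out_path, n_rows, n_cols, precision)
}

#' @rdname text_to_binary
#' @param x A `disk_matrix`.
#' @param digits Significant digits to render; default 9 for single
#'   precision, 17 for double (lossless decimal round trip).
#' @param max_tile_elements Streaming tile budget.
#' @export
binary_to_text <- function(x, out_path, digits = NULL,
                           max_tile_elements = default_tile_budget()) {
  if (is.null(digits)) digits <- if (x$precision == "single") 9L else 17L
  con <- file(out_path, "w")
  on.exit(close(con))
  map_row_tiles(x, function(tile, block) {
    txt <- formatC(block, digits = digits, format = "g", width = 1L)
    dim(txt) <- dim(block)
    writeLines(apply(txt, 1L, paste, collapse = " "), con)
  }, max_tile_elements = max_tile_elements, validate = FALSE)
  invisible(out_path)
}

# out-of-core transpose: streams column strips of x into row tiles of the
# output.  rev_cols reverses the column order of the written output (used to
# emit eigenvector matrices in descending-eigenvalue order without a second
# pass).
ooc_transpose <- function(x, out_path,
                          max_tile_elements = default_tile_budget(),
                          rev_cols = FALSE) {
  if (max_tile_elements < x$n_rows) {
    ocm_parameter_error("tile budget %.0f below one transposed row (%d)",
                        max_tile_elements, x$n_rows)
  }
  per <- max(1, floor(max_tile_elements / x$n_rows))
  con <- file(out_path, "wb")
  on.exit(close(con))
  c0 <- 1L
  while (c0 <= x$n_cols) {
    w <- min(per, x$n_cols - c0 + 1L)
    strip <- read_cols(x, c0, w, validate = FALSE)
    block <- t(strip)
    if (rev_cols) block <- block[, ncol(block):1, drop = FALSE]
    write_block(con, block, x$precision)
    c0 <- c0 + w
  }
  disk_matrix(out_path, x$n_cols, x$n_rows, x$precision)
}

# stream-convert a disk matrix to another element precision
convert_precision <- function(x, out_path, precision,
                              max_tile_elements = default_tile_budget()) {
  con <- file(out_path, "wb")
  on.exit(close(con))
  map_row_tiles(x, function(tile, block) write_block(con, block, precision),
                max_tile_elements = max_tile_elements, validate = FALSE)
  disk_matrix(out_path, x$n_rows, x$n_cols, precision)
}
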