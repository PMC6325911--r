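#' Full eigendecomposition of a symmetric matrix, in memory or out-of-core
#'
#' Factorizes a symmetric matrix (typically a genomic relationship matrix)
#' into all eigenvalues and eigenvectors with the divide-and-conquer
#' symmetric driver (`ssyevd`/`dsyevd`), through the middle-level LAPACK
#' interface in which the caller owns every large array. In `"memory"` mode
#' those arrays are ordinary allocations. In `"disk"` mode the matrix copy,
#' the eigenvector output, and the `1 + 6n + 2n^2`-element float workspace
#' are all memory-mapped files, so resident memory is governed by the
#' operating system's page cache rather than by `n^2` — the same arithmetic,
#' different storage. Single precision runs the entire factorization in
#' IEEE-754 binary32.
#'
#' @param x A [disk matrix][open_matrix] (required for disk mode) or an
#'   ordinary symmetric numeric matrix.
#' @param mode `"memory"` or `"disk"`.
#' @param precision `"double"` or `"single"`; defaults to the storage
#'   precision of `x` (double for in-memory input).
#' @param symmetrize Average `(A + t(A))/2` instead of rejecting asymmetric
#'   input. Off by default: a GRM should already be symmetric, and silent
#'   repair hides upstream bugs.
#' @param descending Order eigenvalues (and paired vectors) descending, as
#'   PCA tools expect; default ascending (solver convention).
#' @param workspace_dir Directory for disk-mode workspace and output files.
#' @param vectors_path Disk mode: final path of the eigenvector matrix file
#'   (default: a file in `workspace_dir`).
#' @param tile_budget Streaming budget, in elements, for the symmetry check,
#'   precision conversion and transpose passes.
#' @param check_symmetry Verify symmetry before factorizing (full check for
#'   in-memory input, sampled off-diagonal pairs for disk input).
#' @return An `eigen_result`: `values` (length-n vector), `vectors` (n x n
#'   matrix in memory mode, `disk_matrix` handle in disk mode; column `j`
#'   pairs with `values[j]`), plus `precision`, `mode`, `order`.
#' @export
#' @examples
#' r <- eigendecompose(matrix(c(2, 1, 1, 2), 2))
#' r$values  # 1, 3
eigendecompose <- function(x, mode = c("memory", "disk"),
                           precision = NULL,
                           symmetrize = FALSE, descending = FALSE,
                           workspace_dir = tempdir(), vectors_path = NULL,
                           tile_budget = default_tile_budget(),
                           check_symmetry = TRUE) {
  mode <- match.arg(mode)
  is_dm <- inherits(x, "disk_matrix")
  if (is.null(precision)) {
    precision <- if (is_dm) x$precision else "double"
  }
  precision <- match.arg(precision, c("double", "single"))
  d <- dim(x)
  if (d[1] != d[2]) {
    ocm_dimension_error("eigendecomposition needs a square matrix, got %d x %d",
                        d[1], d[2])
  }
  n <- d[1]

  if (mode == "disk" && !is_dm) {
    ocm_parameter_error("disk mode requires a disk_matrix input")
  }

  if (symmetrize) {
    x <- symmetrize_input(x, is_dm, workspace_dir, tile_budget)
  } else if (check_symmetry) {
    assert_symmetric(x, is_dm, precision)
  }

  if (n == 1L) {
    a11 <- if (is_dm) read_element(x, 1, 1) else x[1, 1]
    return(new_eigen_result(a11, matrix(1, 1, 1), precision, mode,
                            descending))
  }

  if (mode == "memory") {
    a <- if (is_dm) full_matrix(x) else x
    res <- cpp_syevd_mem(a, precision == "single")
    vals <- res$values
    vecs <- res$vectors
    if (descending) {
      vals <- rev(vals)
      vecs <- vecs[, n:1, drop = FALSE]
    }
    return(new_eigen_result(vals, vecs, precision, mode, descending))
  }

  ## disk mode -------------------------------------------------------------
  preflight_disk(n, precision, workspace_dir)
  stamp <- paste0("ocm-", Sys.getpid(), "-", format(as.numeric(Sys.time()) * 1000))
  scratch <- file.path(workspace_dir, paste0(stamp, "-a.bin"))
  work <- file.path(workspace_dir, paste0(stamp, "-work.bin"))
  iwork <- file.path(workspace_dir, paste0(stamp, "-iwork.bin"))
  on.exit(unlink(c(scratch, work, iwork)), add = TRUE)

  # factor a copy, never the caller's input file
  if (x$precision == precision) {
    if (!file.copy(x$path, scratch, overwrite = TRUE)) {
      ocm_io_error("cannot copy '%s' to workspace '%s'", x$path, workspace_dir)
    }
  } else {
    convert_precision(x, scratch, precision, tile_budget)
  }

  vals <- cpp_syevd_disk(scratch, n, precision == "single", work, iwork)
  unlink(c(work, iwork))

  # scratch now holds eigenvectors column-major == row-major transpose;
  # stream-transpose so the output file is row-major Q with column j paired
  # with values[j]
  if (is.null(vectors_path)) {
    vectors_path <- file.path(workspace_dir, paste0(stamp, "-Q.bin"))
  }
  qt <- disk_matrix(scratch, n, n, precision)
  vecs <- ooc_transpose(qt, vectors_path, max(tile_budget, n),
                        rev_cols = descending)
  if (descending) vals <- rev(vals)
  new_eigen_result(vals, vecs, precision, mode, descending)
}

new_eigen_result <- function(values, vectors, precision, mode, descending) {
  structure(
    list(values = as.numeric(values), vectors = vectors,
         precision = precision, mode = mode,
         order = if (descending) "descending" else "ascending"),
    class = "eigen_result"
  )
}

#' @export
print.eigen_result <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<eigen_result n = %d, %s precision, %s mode, %s>\n  eigenvalue range [%.6g, %.6g]\n",
    n, x$precision, x$mode, x$order, min(x$values), max(x$values)))
  invisible(x)
}

# symmetry tolerance: 100 * eps(working precision) * max|A|
assert_symmetric <- function(x, is_dm, precision, n_pairs = 2000L) {
  tol_of <- function(amax) 100 * precision_eps(precision) * max(amax, 1e-300)
  if (!is_dm) {
    amax <- max(abs(x))
    delta <- abs(x - t(x))
    worst <- max(delta)
    if (worst > tol_of(amax)) {
      ij <- which(delta == worst, arr.ind = TRUE)[1, ]
      ocm_symmetry_error(
        "matrix is not symmetric: |A[%d,%d] - A[%d,%d]| = %g exceeds tolerance %g",
        ij[1], ij[2], ij[2], ij[1], worst, tol_of(amax))
    }
    return(invisible(TRUE))
  }
  n <- x$n_rows
  if (n < 2) return(invisible(TRUE))
  # deterministic sample of off-diagonal pairs (full coverage for small n)
  if (n * (n - 1) / 2 <= n_pairs) {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  } else {
    r <- local({ set.seed(20260101L); cbind(sample.int(n, n_pairs, TRUE),
                                            sample.int(n, n_pairs, TRUE)) })
    r <- r[r[, 1] != r[, 2], , drop = FALSE]
    idx <- r
  }
  worst <- 0; wi <- c(1L, 1L); amax <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    aij <- read_element(x, i, j); aji <- read_element(x, j, i)
    amax <- max(amax, abs(aij), abs(aji))
    dlt <- abs(aij - aji)
    if (dlt > worst) { worst <- dlt; wi <- c(i, j) }
  }
  if (worst > tol_of(amax)) {
    ocm_symmetry_error(
      "matrix is not symmetric: |A[%d,%d] - A[%d,%d]| = %g exceeds tolerance %g (sampled check)",
      wi[1], wi[2], wi[2], wi[1], worst, tol_of(amax))
  }
  invisible(TRUE)
}

symmetrize_input <- function(x, is_dm, workspace_dir, tile_budget) {
  if (!is_dm) return((x + t(x)) / 2)
  out <- file.path(workspace_dir,
                   paste0("ocm-sym-", Sys.getpid(), "-", basename(x$path)))
  con <- file(out, "wb")
  per <- max(1, floor(tile_budget / x$n_rows))
  r0 <- 1L
  while (r0 <= x$n_rows) {
    h <- min(per, x$n_rows - r0 + 1L)
    rows <- read_rows(x, r0, h, validate = FALSE)
    cols <- read_cols(x, r0, h, validate = FALSE) # A[, r0:r1] -> t() = rows of A'
    write_block(con, (rows + t(cols)) / 2, x$precision)
    r0 <- r0 + h
  }
  close(con)
  disk_matrix(out, x$n_rows, x$n_cols, x$precision)
}

# refuse to start a disk job whose workspace cannot fit on the volume
preflight_disk <- function(n, precision, workspace_dir) {
  est <- estimate_disk(n, route = "eigen", precision = precision)
  free <- free_bytes(workspace_dir)
  if (!is.na(free) && est > free) {
    ocm_resource_error(
      "disk-mode eigendecomposition at n = %d needs about %.1f GiB on '%s' but only %.1f GiB are free",
      n, est / 2^30, workspace_dir, free / 2^30)
  }
  invisible(est)
}

free_bytes <- function(dir) {
  out <- tryCatch(
    system2("df", c("-Pk", shQuote(dir)), stdout = TRUE, stderr = FALSE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || length(out) < 2) return(NA_real_)
  fields <- strsplit(trimws(out[length(out)]), "[[:space:]]+")[[1]]
  if (length(fields) < 4) return(NA_real_)
  suppressWarnings(as.numeric(fields[4]) * 1024)
}

#' Relative reconstruction residual of an eigendecomposition
#'
#' Computes `||A Q - Q diag(lambda)||_F / ||A||_F` tile-wise, so it works
#' when either the matrix or the eigenvector factor is disk-resident. A
#' backward-stable factorization keeps this at a small multiple of machine
#' epsilon times `n`.
#'
#' @param x The factored matrix (`disk_matrix` or dense).
#' @param result An `eigen_result` for `x`.
#' @param tile_budget Streaming budget in elements.
#' @return Nonnegative scalar residual.
#' @export
check_reconstruction <- function(x, result,
                                 tile_budget = default_tile_budget()) {
  d <- dim(x)
  n <- length(result$values)
  if (d[1] != d[2] || d[1] != n) {
    ocm_dimension_error("matrix is %d x %d but result has %d eigenpairs",
                        d[1], d[2], n)
  }
  lam <- result$values
  qv <- result$vectors
  q_is_dm <- inherits(qv, "disk_matrix")
  x_is_dm <- inherits(x, "disk_matrix")
  plan <- tile_plan_dims(d[1], d[2], max(tile_budget, n))
  num2 <- 0; den2 <- 0
  qplan <- tile_plan_dims(n, n, max(tile_budget, n))
  for (t in seq_len(nrow(plan))) {
    I <- plan$first[t]:plan$last[t]
    a_rows <- if (x_is_dm) read_rows(x, plan$first[t], plan$n_rows[t]) else
      x[I, , drop = FALSE]
    den2 <- den2 + sum(a_rows^2)
    aq <- matrix(0, length(I), n)
    for (s in seq_len(nrow(qplan))) {
      J <- qplan$first[s]:qplan$last[s]
      q_rows <- if (q_is_dm) read_rows(qv, qplan$first[s], qplan$n_rows[s]) else
        qv[J, , drop = FALSE]
      aq <- aq + a_rows[, J, drop = FALSE] %*% q_rows
    }
    q_i <- if (q_is_dm) read_rows(qv, plan$first[t], plan$n_rows[t]) else
      qv[I, , drop = FALSE]
    num2 <- num2 + sum((aq - q_i * rep(lam, each = nrow(q_i)))^2)
  }
  if (den2 == 0) {
    ocm_degenerate_error("cannot form a relative residual for the zero matrix")
  }
  sqrt(num2) / sqrt(den2)
}

#' @export
dim.eigen_result <- function(x) c(length(x$values), length(x$values))
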