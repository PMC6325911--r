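#' Closed-form memory model for a full symmetric eigendecomposition
#'
#' Predicts the peak memory of an in-memory full eigendecomposition with
#' the divide-and-conquer symmetric driver:
#' the `n^2`-element matrix, the driver's documented minimum float
#' workspace of `1 + 6n + 2n^2` elements when eigenvectors are requested,
#' and its `3 + 5n` four-byte integer workspace. Floats are 4 bytes in
#' single precision and 8 in double. `total_gib_1dp` is the total in GiB
#' (2^30 bytes) rounded half-up to one decimal, the convention under which
#' the model matches published per-size figures for this solver family.
#'
#' @param n Matrix dimension (number of individuals), a positive integer.
#' @param precision `"single"` or `"double"`.
#' @return A `resource_estimate`: `matrix_bytes`, `workspace_bytes`,
#'   `integer_workspace_bytes`, `total_bytes`, `total_gib_1dp`.
#' @export
#' @examples
#' estimate_eigen_memory(10000, "single")$total_gib_1dp  # 1.1
estimate_eigen_memory <- function(n, precision = c("single", "double")) {
  precision <- match.arg(precision)
  check_positive_int(n, "n")
  s <- element_size(precision)
  n <- as.numeric(n)
  matrix_bytes <- n^2 * s
  workspace_bytes <- (1 + 6 * n + 2 * n^2) * s
  integer_workspace_bytes <- (3 + 5 * n) * 4
  total <- matrix_bytes + workspace_bytes + integer_workspace_bytes
  new_resource_estimate(matrix_bytes, workspace_bytes,
                        integer_workspace_bytes, total)
}

new_resource_estimate <- function(matrix_bytes, workspace_bytes,
                                  integer_workspace_bytes, total_bytes) {
  structure(
    list(matrix_bytes = matrix_bytes,
         workspace_bytes = workspace_bytes,
         integer_workspace_bytes = integer_workspace_bytes,
         total_bytes = total_bytes,
         total_gib_1dp = round_half_up_1(total_bytes / 2^30)),
    class = "resource_estimate"
  )
}

# half-up rounding to one decimal (round() would round half to even)
round_half_up_1 <- function(x) floor(x * 10 + 0.5) / 10

check_positive_int <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    ocm_parameter_error("%s must be a positive integer", name)
  }
}

#' @export
print.resource_estimate <- function(x, ...) {
  cat(sprintf(
    "matrix %.0f B + workspace %.0f B + integer workspace %.0f B = %.0f B (%.1f GiB)\n",
    x$matrix_bytes, x$workspace_bytes, x$integer_workspace_bytes,
    x$total_bytes, x$total_gib_1dp))
  invisible(x)
}

#' Resident-memory model for an SVD
#'
#' For the Gram route (`route = "gram"`, the package's method for tall
#' matrices) the resident footprint is independent of `N`: the `M x M` Gram
#' accumulator at the accumulation precision, the `M x k` right-vector
#' block and one `M`-vector of singular values at the working precision,
#' plus one streaming tile. The `"dense"` route models a conventional
#' in-memory thin SVD by divide and conquer: the `N x M` matrix, its
#' `N x k + M^2 + M` outputs, a `4 M^2 + 7 M` float workspace and an
#' `8 M` integer workspace.
#'
#' @param n,m Matrix dimensions (`n` individuals, `m` markers).
#' @param k Singular triplets retained, `1 <= k <= min(n, m)`.
#' @param precision Working/storage precision.
#' @param route `"gram"` or `"dense"`.
#' @param accumulation_precision Gram accumulator precision.
#' @param tile_budget Streaming tile budget in elements.
#' @return A `resource_estimate` (see [estimate_eigen_memory()]).
#' @export
estimate_svd_memory <- function(n, m, k = min(n, m),
                                precision = c("single", "double"),
                                route = c("gram", "dense"),
                                accumulation_precision = c("double", "single"),
                                tile_budget = default_tile_budget()) {
  precision <- match.arg(precision)
  route <- match.arg(route)
  accumulation_precision <- match.arg(accumulation_precision)
  check_positive_int(n, "n"); check_positive_int(m, "m")
  if (length(k) != 1L || is.na(k) || k < 1 || k > min(n, m) || k != floor(k)) {
    ocm_parameter_error("k must satisfy 1 <= k <= min(n, m)")
  }
  s <- element_size(precision)
  n <- as.numeric(n); m <- as.numeric(m); k <- as.numeric(k)
  if (route == "gram") {
    s_acc <- element_size(accumulation_precision)
    matrix_bytes <- min(tile_budget, n * m) * s      # one resident tile
    workspace_bytes <- m^2 * s_acc + m * k * s + m * s
    integer_workspace_bytes <- 0
  } else {
    matrix_bytes <- n * m * s
    workspace_bytes <- (n * k + m^2 + m) * s + (4 * m^2 + 7 * m) * s
    integer_workspace_bytes <- 8 * min(n, m) * 4
  }
  new_resource_estimate(matrix_bytes, workspace_bytes,
                        integer_workspace_bytes,
                        matrix_bytes + workspace_bytes +
                          integer_workspace_bytes)
}

#' Disk footprint of an out-of-core factorization
#'
#' Total bytes on the workspace volume: input matrix, factor outputs, and
#' any file-backed solver workspace. For `route = "eigen"` that is the
#' `n^2` input, the `n^2` eigenvector file, the `n`-element value file and
#' the `1 + 6n + 2n^2` float workspace file; for `route = "svd_gram"` the
#' `n x m` input, `n x k` left vectors, `m x k` right vectors and `k`
#' singular values (the Gram accumulator is resident, not on disk). Used as
#' the pre-flight gate before disk-mode jobs start.
#'
#' @inheritParams estimate_svd_memory
#' @param route `"eigen"` or `"svd_gram"`.
#' @return Estimated bytes (numeric scalar).
#' @export
#' @examples
#' estimate_disk(10000, route = "eigen", precision = "single") / 1e6 # ~1600 MB
estimate_disk <- function(n, m = n, k = min(n, m),
                          precision = c("single", "double"),
                          route = c("eigen", "svd_gram")) {
  precision <- match.arg(precision)
  route <- match.arg(route)
  check_positive_int(n, "n"); check_positive_int(m, "m")
  s <- element_size(precision)
  n <- as.numeric(n); m <- as.numeric(m); k <- as.numeric(k)
  if (route == "eigen") {
    n^2 * s + n^2 * s + n * s + (1 + 6 * n + 2 * n^2) * s
  } else {
    n * m * s + n * k * s + m * k * s + k * s
  }
}
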