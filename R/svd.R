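#' Streamed Gram-matrix accumulation
#'
#' Forms `G = t(A) %*% A` for a tall `N x M` matrix by streaming row tiles
#' `B` and accumulating `crossprod(B)`, so only the `M x M` Gram matrix is
#' resident; this product dominates the cost of a Gram-route SVD and is the
#' reason computing only a subset of singular values saves little time.
#' Accumulation defaults to double precision even for single-precision
#' inputs: squaring halves the effective precision, and with very many rows
#' a pure binary32 accumulation can lose small singular values entirely.
#' `accumulation_precision = "single"` rounds the accumulator through
#' binary32 after every tile for bit-faithfulness experiments.
#'
#' @param x A [disk matrix][open_matrix] or dense numeric matrix.
#' @param accumulation_precision `"double"` (default) or `"single"`.
#' @param tile_budget Row-streaming budget in elements; also the in-memory
#'   budget the `M x M` result must fit (use the eigen route on the GRM when
#'   it does not).
#' @return `M x M` symmetric positive semi-definite matrix with attribute
#'   `accumulation_precision`.
#' @export
gram_accumulate <- function(x, accumulation_precision = c("double", "single"),
                            tile_budget = default_tile_budget()) {
  accumulation_precision <- match.arg(accumulation_precision)
  d <- dim(x)
  m <- d[2]
  if (as.numeric(m)^2 > tile_budget) {
    ocm_resource_error(
      "Gram matrix would hold %.0f elements, over the %.0f-element budget; for a wide relationship matrix use eigendecompose() on the GRM instead",
      as.numeric(m)^2, tile_budget)
  }
  g <- matrix(0, m, m)
  single_acc <- accumulation_precision == "single"
  accumulate <- function(tile, block) {
    if (single_acc) {
      block <- matrix(cpp_round_float(block), nrow(block))
      g <<- matrix(cpp_round_float(g + crossprod(block)), m)
    } else {
      g <<- g + crossprod(block)
    }
    NULL
  }
  if (inherits(x, "disk_matrix")) {
    map_row_tiles(x, accumulate, tile_budget)
  } else {
    plan <- tile_plan(x, max(tile_budget, m))
    for (t in seq_len(nrow(plan))) {
      accumulate(plan[t, ], x[plan$first[t]:plan$last[t], , drop = FALSE])
    }
  }
  attr(g, "accumulation_precision") <- accumulation_precision
  g
}

#' Thin and top-k SVD of a tall matrix via the Gram route
#'
#' Decomposes a tall `N x M` matrix (individuals by markers) as
#' `A = U diag(sigma) t(V)` without holding `A` or `U` in memory: the `M x M`
#' Gram matrix `t(A) A` is accumulated by streaming row tiles
#' ([gram_accumulate()]), its eigendecomposition gives
#' `sigma = sqrt(pmax(lambda, 0))` (descending) and the right singular
#' vectors `V`, and a second streaming pass reconstructs `U` row-block by
#' row-block as `B %*% V %*% diag(1/sigma)`. Singular values below the
#' numerical-rank tolerance `max(N, M) * eps * sigma[1]` get zero-filled `U`
#' columns, reported in `$zeroed`. Each `V` column is sign-normalized so its
#' largest-magnitude entry is positive (`U` inherits), making outputs
#' deterministic.
#'
#' `svd_topk()` runs the same code path and keeps the `k` largest singular
#' values and paired vectors; `k` must satisfy `1 <= k < min(N, M)` (the full
#' decomposition is `svd_thin()`). The Gram pass is still full-`M`, so top-k
#' saves output size and the `U` pass, not the dominant product.
#'
#' The Gram route squares the condition number: relative accuracy of
#' `sigma[i]` degrades like `eps * (sigma[1] / sigma[i])^2`, a documented
#' trade-off against direct bidiagonalization that is immaterial for the
#' well-conditioned standardized-genotype matrices it targets.
#'
#' @param x A [disk matrix][open_matrix] or dense numeric matrix. If
#'   `N < M`, the matrix is transposed internally and `u`/`v` are swapped
#'   back on return (`$swapped` is set).
#' @param k Number of leading singular triplets to keep
#'   (`svd_topk()` only); strictly less than `min(N, M)`.
#' @param mode `"memory"` returns `u` as a dense matrix; `"disk"` streams
#'   `u` to a file and returns a `disk_matrix` handle.
#' @param precision Working precision of the factorization (`"single"` runs
#'   the Gram eigendecomposition in binary32); defaults to the storage
#'   precision of `x`.
#' @param accumulation_precision Passed to [gram_accumulate()].
#' @param u_path Disk mode: path for the left-singular-vector file.
#' @param workspace_dir Directory for disk-mode outputs.
#' @param tile_budget Streaming budget in elements.
#' @return An `svd_result`: `d` (singular values, descending), `u`
#'   (`N x k`), `v` (`M x k`), `k`, `rank` (numerical rank), `zeroed`
#'   (indices of zero-filled `u` columns), `precision`, `mode`, `swapped`.
#' @export
#' @examples
#' a <- rbind(diag(c(3, 2, 1)), matrix(0, 2, 3))
#' svd_thin(a)$d  # 3 2 1
svd_thin <- function(x, mode = c("memory", "disk"), precision = NULL,
                     accumulation_precision = c("double", "single"),
                     u_path = NULL, workspace_dir = tempdir(),
                     tile_budget = default_tile_budget()) {
  svd_gram_impl(x, k = NULL, mode = match.arg(mode), precision = precision,
                accumulation_precision = match.arg(accumulation_precision),
                u_path = u_path, workspace_dir = workspace_dir,
                tile_budget = tile_budget)
}

#' @rdname svd_thin
#' @export
svd_topk <- function(x, k, mode = c("memory", "disk"), precision = NULL,
                     accumulation_precision = c("double", "single"),
                     u_path = NULL, workspace_dir = tempdir(),
                     tile_budget = default_tile_budget()) {
  d <- dim(x)
  mn <- min(d)
  if (length(k) != 1L || is.na(k) || k != floor(k) || k < 1 || k >= mn) {
    ocm_parameter_error(
      "k must satisfy 1 <= k < min(N, M) = %d (use svd_thin() for the full decomposition); got %s",
      mn, paste(k, collapse = ","))
  }
  svd_gram_impl(x, k = as.integer(k), mode = match.arg(mode),
                precision = precision,
                accumulation_precision = match.arg(accumulation_precision),
                u_path = u_path, workspace_dir = workspace_dir,
                tile_budget = tile_budget)
}

svd_gram_impl <- function(x, k, mode, precision, accumulation_precision,
                          u_path, workspace_dir, tile_budget) {
  is_dm <- inherits(x, "disk_matrix")
  if (is.null(precision)) precision <- if (is_dm) x$precision else "double"
  precision <- match.arg(precision, c("double", "single"))
  d <- dim(x)
  if (any(d < 1)) ocm_dimension_error("empty matrix")
  swapped <- FALSE
  if (d[1] < d[2]) {
    # wide input: factor the transpose, swap U/V on return
    swapped <- TRUE
    if (is_dm) {
      tp <- file.path(workspace_dir,
                      paste0("ocm-t-", Sys.getpid(), "-", basename(x$path)))
      x <- ooc_transpose(x, tp, max(tile_budget, d[1]))
    } else {
      x <- t(x)
    }
    d <- dim(x)
  }
  n <- d[1]; m <- d[2]
  mn <- min(n, m)
  k_keep <- if (is.null(k)) mn else k

  g <- gram_accumulate(x, accumulation_precision, tile_budget)
  eg <- eigendecompose(g, mode = "memory", precision = precision,
                       check_symmetry = FALSE, descending = TRUE)
  lam <- eg$values[seq_len(mn)]
  sigma <- sqrt(pmax(lam, 0))
  v <- eg$vectors[, seq_len(mn), drop = FALSE]

  # deterministic sign convention: largest-|entry| of each V column positive
  sgn <- apply(v, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  v <- sweep(v, 2L, sgn, `*`)

  sigma <- sigma[seq_len(k_keep)]
  v <- v[, seq_len(k_keep), drop = FALSE]

  # Gram-route noise floor: an exactly zero singular value surfaces as
  # lambda ~ m * eps * lambda_1 in the accumulated Gram matrix, i.e. at
  # sigma ~ sqrt(max(N, M) * eps) * sigma_1 on the singular-value scale
  rank_tol <- sqrt(max(n, m) * precision_eps(precision)) *
    (if (length(sigma)) sigma[1] else 0)
  keep <- sigma > rank_tol
  zeroed <- which(!keep)

  # second streaming pass: U rows = A rows %*% V %*% diag(1/sigma)
  w <- v[, keep, drop = FALSE] *
    rep(1 / sigma[keep], each = m)
  emit_u <- function(block) {
    u_rows <- matrix(0, nrow(block), k_keep)
    if (any(keep)) u_rows[, keep] <- block %*% w
    if (precision == "single") u_rows <- matrix(cpp_round_float(u_rows),
                                                nrow(u_rows))
    u_rows
  }

  if (mode == "disk") {
    if (is.null(u_path)) {
      u_path <- file.path(workspace_dir,
                          paste0("ocm-U-", Sys.getpid(), "-",
                                 format(as.numeric(Sys.time()) * 1000), ".bin"))
    }
    con <- file(u_path, "wb")
    stream_rows(x, tile_budget, function(block) {
      write_block(con, emit_u(block), precision)
    })
    close(con)
    u <- disk_matrix(u_path, n, k_keep, precision)
  } else {
    u <- matrix(0, n, k_keep)
    r0 <- 1L
    stream_rows(x, tile_budget, function(block) {
      u[r0:(r0 + nrow(block) - 1L), ] <<- emit_u(block)
      r0 <<- r0 + nrow(block)
    })
  }

  if (swapped) { tmp <- u; u <- v; v <- tmp }
  structure(
    list(d = sigma, u = u, v = v, k = k_keep,
         rank = sum(keep), zeroed = zeroed,
         precision = precision, mode = mode, swapped = swapped),
    class = "svd_result"
  )
}

# apply f(block) to successive row tiles of a disk or dense matrix
stream_rows <- function(x, tile_budget, f) {
  if (inherits(x, "disk_matrix")) {
    map_row_tiles(x, function(tile, block) f(block), tile_budget)
  } else {
    plan <- tile_plan(x, max(tile_budget, ncol(x)))
    for (t in seq_len(nrow(plan))) {
      f(x[plan$first[t]:plan$last[t], , drop = FALSE])
    }
  }
  invisible(NULL)
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf(
    "<svd_result k = %d (rank %d), %s precision, %s mode%s>\n  sigma: %s\n",
    x$k, x$rank, x$precision, x$mode,
    if (x$swapped) ", input transposed" else "",
    paste(signif(utils::head(x$d, 5), 6), collapse = " ")))
  invisible(x)
}
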