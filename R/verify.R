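#' Relative-norm agreement between two factorizations
#'
#' `compare_vectors()` quantifies the agreement of a test vector with a
#' reference through three relative norms:
#' `||test - reference||_p / ||reference||_p` for the infinity norm
#' (`max |x_i|`), the taxicab norm (`sum |x_i|`), and the Euclidean norm
#' (`sqrt(sum x_i^2)`). The second argument is the normalizer: the report is
#' asymmetric by construction, with the reference playing the role of the
#' trusted result.
#'
#' @param test,reference Equal-length numeric vectors; `reference` must not
#'   be the zero vector.
#' @return A `norm_report`: list with `inf_norm`, `taxicab_norm`,
#'   `euclidean_norm`.
#' @export
#' @examples
#' compare_vectors(c(1, 0), c(0, 1))  # 1, 2, sqrt(2)
compare_vectors <- function(test, reference) {
  test <- as.numeric(test); reference <- as.numeric(reference)
  if (length(test) != length(reference)) {
    ocm_dimension_error("vectors differ in length (%d vs %d)",
                        length(test), length(reference))
  }
  if (all(reference == 0)) {
    ocm_degenerate_error("relative norms are undefined for a zero reference")
  }
  delta <- test - reference
  structure(
    list(inf_norm = max(abs(delta)) / max(abs(reference)),
         taxicab_norm = sum(abs(delta)) / sum(abs(reference)),
         euclidean_norm = sqrt(sum(delta^2)) / sqrt(sum(reference^2))),
    class = "norm_report"
  )
}

#' @export
print.norm_report <- function(x, ...) {
  cat(sprintf("inf: %.6e  taxicab: %.6e  euclidean: %.6e\n",
              x$inf_norm, x$taxicab_norm, x$euclidean_norm))
  invisible(x)
}

#' Align eigen/singular vector signs to a reference
#'
#' The sign of an eigenvector or singular vector is mathematically
#' arbitrary, so any column-wise comparison must first fix signs: each test
#' column is flipped when its inner product with the matching reference
#' column is negative, which minimizes `||test - reference||_2` over all
#' per-column sign choices.
#'
#' @param test,reference Numeric matrices of identical shape (columns are
#'   vectors to align).
#' @return `test` with column signs adjusted.
#' @export
align_signs <- function(test, reference) {
  test <- as.matrix(test); reference <- as.matrix(reference)
  if (!all(dim(test) == dim(reference))) {
    ocm_dimension_error("shape mismatch: %d x %d vs %d x %d",
                        nrow(test), ncol(test), nrow(reference),
                        ncol(reference))
  }
  s <- sign(colSums(test * reference))
  s[s == 0] <- 1
  sweep(test, 2L, s, `*`)
}

#' Compare two eigendecompositions or two SVDs
#'
#' Produces one [norm report][compare_vectors] for the value vector
#' (eigenvalues or singular values) and one for the vector matrices, the
#' latter flattened to a single vector after sign alignment so a single
#' scalar per norm summarizes agreement. With `per_column = TRUE` a
#' column-wise breakdown is added; columns whose values are degenerate
#' (equal within `degeneracy_tol`) are reported as subspace-ambiguous and
#' skipped, since individual vectors in a degenerate subspace are not
#' identifiable.
#'
#' @param a Test factorization (`eigen_result` or `svd_result`).
#' @param b Reference factorization of the same kind and size (the
#'   normalizer of every ratio).
#' @param per_column Also report per-column vector norms.
#' @param degeneracy_tol Values closer than this are treated as one
#'   subspace; default `10 * n * eps * max|value|` of the reference.
#' @return List with elements `values` and `vectors` (norm reports), and
#'   `per_column` (data frame) when requested.
#' @export
compare_factorizations <- function(a, b, per_column = FALSE,
                                   degeneracy_tol = NULL) {
  kind <- function(z) if (inherits(z, "eigen_result")) "eigen"
         else if (inherits(z, "svd_result")) "svd"
         else ocm_parameter_error("not a factorization result")
  if (kind(a) != kind(b)) {
    ocm_parameter_error("cannot compare an %s result with an %s result",
                        kind(a), kind(b))
  }
  va <- if (kind(a) == "eigen") a$values else a$d
  vb <- if (kind(b) == "eigen") b$values else b$d
  if (length(va) != length(vb)) {
    ocm_dimension_error("results differ in size (%d vs %d values)",
                        length(va), length(vb))
  }
  qa <- vectors_of(a); qb <- vectors_of(b)
  if (!all(dim(qa) == dim(qb))) {
    ocm_dimension_error("vector matrices differ in shape")
  }
  qa <- align_signs(qa, qb)
  out <- list(values = compare_vectors(va, vb),
              vectors = compare_vectors(as.vector(qa), as.vector(qb)))
  if (per_column) {
    n <- length(vb)
    if (is.null(degeneracy_tol)) {
      degeneracy_tol <- 10 * n * .Machine$double.eps * max(abs(vb), 1e-300)
    }
    # group adjacent (sorted-order) values within tolerance
    ambiguous <- rep(FALSE, n)
    if (n > 1) {
      near <- abs(diff(vb)) <= degeneracy_tol
      ambiguous[which(near)] <- TRUE
      ambiguous[which(near) + 1L] <- TRUE
    }
    per <- data.frame(
      column = seq_len(n),
      subspace_ambiguous = ambiguous,
      euclidean_norm = NA_real_
    )
    for (j in seq_len(n)) {
      if (!ambiguous[j]) {
        per$euclidean_norm[j] <-
          compare_vectors(qa[, j], qb[, j])$euclidean_norm
      }
    }
    out$per_column <- per
  }
  out
}

vectors_of <- function(z) {
  v <- if (inherits(z, "eigen_result")) z$vectors else {
    u <- full_matrix(z$u)
    rbind(u, full_matrix(z$v))  # stacked left and right vectors
  }
  full_matrix(v)
}
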