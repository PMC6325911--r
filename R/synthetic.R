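#' Seeded synthetic genotype matrices
#'
#' Writes an `n_individuals x n_markers` dosage matrix straight to a disk
#' matrix file: marker `j` gets an allele frequency
#' `p_j ~ Uniform(maf_low, maf_high)` and entries `(i, j) ~ Binomial(2, p_j)`
#' under Hardy-Weinberg equilibrium, independently across individuals —
#' unrelated individuals, no linkage disequilibrium or population structure.
#' Generation is tile-wise, so fixture size is bounded by disk, not memory,
#' and is a pure function of `(dimensions, MAF range, seed, tile budget)`:
#' the same call produces byte-identical files.
#'
#' @param n_individuals,n_markers Matrix dimensions.
#' @param path Output file for the binary matrix.
#' @param maf_low,maf_high Minor-allele-frequency range, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param seed Integer seed; all randomness derives from it.
#' @param precision Storage precision (single is ample for dosages in
#'   `{0, 1, 2}`).
#' @param tile_budget Elements generated per tile.
#' @return `disk_matrix` handle with attribute `allele_freq` (the generating
#'   `p_j`).
#' @export
generate_genotypes <- function(n_individuals, n_markers, path,
                               maf_low = 0.05, maf_high = 0.5,
                               seed = 1L,
                               precision = c("single", "double"),
                               tile_budget = default_tile_budget()) {
  precision <- match.arg(precision)
  check_positive_int(n_individuals, "n_individuals")
  check_positive_int(n_markers, "n_markers")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    ocm_parameter_error(
      "MAF range must satisfy 0 < maf_low <= maf_high <= 0.5, got [%g, %g]",
      maf_low, maf_high)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- runif(n_markers, maf_low, maf_high)
  con <- file(path, "wb")
  per <- max(1, floor(tile_budget / n_markers))
  r0 <- 1L
  while (r0 <= n_individuals) {
    h <- min(per, n_individuals - r0 + 1L)
    # column-major draw so each column uses its own marker frequency
    block <- matrix(rbinom(h * n_markers, 2L, rep(p, each = h)), nrow = h)
    write_block(con, block, precision)
    r0 <- r0 + h
  }
  close(con)
  out <- disk_matrix(path, n_individuals, n_markers, precision)
  attr(out, "allele_freq") <- p
  out
}

#' Build a standardized (VanRaden) GRM from a genotype matrix
#'
#' Computes the field-standard centered-and-scaled genomic relationship
#' matrix: each marker column is centered by `2 * p_hat_j` and scaled by
#' `sqrt(2 * p_hat_j * (1 - p_hat_j))` with `p_hat_j` the observed allele
#' frequency, monomorphic markers are dropped (with a message giving the
#' count), and `GRM = Z %*% t(Z) / m_retained`. Genotypes are streamed in
#' row-tile pairs; the `N x N` result is assembled in memory and written to
#' `path`, so the builder targets fixture-scale `N` (it is plumbing for the
#' factorizers, not itself an out-of-core analysis). The result is symmetric
#' positive semi-definite with diagonal mean near 1 for Hardy-Weinberg
#' genotypes.
#'
#' @param genotypes `disk_matrix` of dosages (individuals x markers), e.g.
#'   from [generate_genotypes()].
#' @param path Output file for the GRM.
#' @param precision Storage precision of the GRM file.
#' @param tile_budget Streaming budget in elements.
#' @return `disk_matrix` handle with attribute `m_retained`.
#' @export
build_grm <- function(genotypes, path, precision = c("double", "single"),
                      tile_budget = default_tile_budget()) {
  precision <- match.arg(precision)
  n <- genotypes$n_rows
  m <- genotypes$n_cols
  # pass 1: allele frequencies
  csum <- numeric(m)
  map_row_tiles(genotypes, function(tile, block) {
    csum <<- csum + colSums(block)
    NULL
  }, tile_budget)
  p_hat <- csum / (2 * n)
  keep <- p_hat > 0 & p_hat < 1
  if (!any(keep)) {
    ocm_degenerate_error("all %d markers are monomorphic; no GRM can be built", m)
  }
  if (any(!keep)) {
    message(sprintf("dropping %d monomorphic marker(s) of %d", sum(!keep), m))
  }
  center <- 2 * p_hat[keep]
  scale <- sqrt(2 * p_hat[keep] * (1 - p_hat[keep]))
  m_ret <- sum(keep)

  standardize <- function(block) {
    z <- block[, keep, drop = FALSE]
    sweep(sweep(z, 2L, center, `-`), 2L, scale, `/`)
  }

  plan <- tile_plan(genotypes, max(tile_budget, m))
  g <- matrix(0, n, n)
  for (i in seq_len(nrow(plan))) {
    zi <- standardize(read_rows(genotypes, plan$first[i], plan$n_rows[i]))
    ri <- plan$first[i]:plan$last[i]
    for (j in i:nrow(plan)) {
      zj <- if (j == i) zi else
        standardize(read_rows(genotypes, plan$first[j], plan$n_rows[j]))
      rj <- plan$first[j]:plan$last[j]
      b <- tcrossprod(zi, zj)
      g[ri, rj] <- b
      if (j > i) g[rj, ri] <- t(b)
    }
  }
  g <- g / m_ret
  g <- (g + t(g)) / 2  # exact symmetry regardless of block arithmetic
  out <- write_matrix(g, path, precision)
  attr(out, "m_retained") <- m_ret
  out
}

#' Seeded symmetric test matrices
#'
#' Families of symmetric matrices for factorization tests:
#' `"grm_like"` builds a standardized GRM from fresh binomial genotypes
#' (`m` markers, MAF in `[0.05, 0.5]`); `"wishart"` is `Z t(Z) / m` with
#' standard normal `Z` (`n x m`); `"diag_plus_noise"` is
#' `diag(1:n) + noise * (S + t(S)) / 2` with standard normal `S`, exactly
#' diagonal when `noise = 0`. All are pure functions of their arguments and
#' the seed.
#'
#' @param n Dimension.
#' @param path Output file.
#' @param kind Matrix family.
#' @param seed Integer seed.
#' @param m Markers / Wishart degrees of freedom (default `2 * n`).
#' @param noise Off-diagonal noise scale for `"diag_plus_noise"`.
#' @param precision Storage precision.
#' @return `disk_matrix` handle.
#' @export
generate_symmetric <- function(n, path,
                               kind = c("grm_like", "wishart",
                                        "diag_plus_noise"),
                               seed = 1L, m = 2L * n, noise = 0.1,
                               precision = c("double", "single")) {
  kind <- match.arg(kind)
  precision <- match.arg(precision)
  check_positive_int(n, "n")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  a <- switch(kind,
    grm_like = {
      p <- runif(m, 0.05, 0.5)
      x <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
      p_hat <- colMeans(x) / 2
      keep <- p_hat > 0 & p_hat < 1
      z <- sweep(sweep(x[, keep, drop = FALSE], 2L, 2 * p_hat[keep], `-`),
                 2L, sqrt(2 * p_hat[keep] * (1 - p_hat[keep])), `/`)
      tcrossprod(z) / sum(keep)
    },
    wishart = {
      z <- matrix(rnorm(n * m), nrow = n)
      tcrossprod(z) / m
    },
    diag_plus_noise = {
      s <- matrix(rnorm(n * n), n, n)
      diag(seq_len(n)) + noise * (s + t(s)) / 2
    })
  a <- (a + t(a)) / 2
  write_matrix(a, path, precision)
}
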