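# Fixtures are built in code, in temp files, at test time.

# write a dense matrix to a throwaway disk_matrix
tmp_dm <- function(x, precision = "double") {
  write_matrix(x, tempfile(fileext = ".bin"), precision = precision)
}

# seeded dense symmetric PSD matrix (standard-normal Wishart)
rand_psd <- function(n, m = 2L * n, seed = 1L) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * m), n)
    tcrossprod(z) / m
  })
}

# seeded dense rectangular matrix
rand_mat <- function(n, m, seed = 1L) {
  withr::with_seed(seed, matrix(rnorm(n * m), n, m))
}

# seeded standardized-genotype matrix (dense, in memory)
rand_geno_std <- function(n, m, seed = 1L) {
  withr::with_seed(seed, {
    p <- runif(m, 0.05, 0.5)
    x <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n)
    keep <- apply(x, 2L, function(col) var(col) > 0)
    x <- x[, keep, drop = FALSE]
    ph <- colMeans(x) / 2
    sweep(sweep(x, 2L, 2 * ph, `-`), 2L, sqrt(2 * ph * (1 - ph)), `/`)
  })
}

eps32 <- 2^-23
eps64 <- .Machine$double.eps
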