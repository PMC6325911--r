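test_that("closed-form cases factorize exactly", {
  r <- eigendecompose(diag(3))
  expect_equal(r$values, rep(1, 3))
  expect_equal(crossprod(r$vectors), diag(3), tolerance = 1e-14)
  expect_equal(diag(3) %*% r$vectors, r$vectors %*% diag(r$values),
               tolerance = 1e-14)

  r2 <- eigendecompose(matrix(c(2, 1, 1, 2), 2))
  expect_equal(r2$values, c(1, 3), tolerance = 1e-14)
  v <- align_signs(r2$vectors,
                   cbind(c(1, -1), c(1, 1)) / sqrt(2))
  expect_equal(v, cbind(c(1, -1), c(1, 1)) / sqrt(2), tolerance = 1e-14)

  r1 <- eigendecompose(matrix(-4.5, 1, 1))
  expect_equal(r1$values, -4.5)
  expect_equal(r1$vectors, matrix(1, 1, 1))
})

test_that("eigenvalues agree with an independent dense solver on a GRM", {
  z <- rand_geno_std(50, 120, seed = 21)
  a <- tcrossprod(z) / ncol(z)
  dm <- tmp_dm(a)
  r <- eigendecompose(dm, mode = "memory", precision = "double")
  # oracle: base eigen() goes through the dsyevr driver, a different
  # algorithm than the divide-and-conquer path under test
  o <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  nrm <- max(abs(o))
  expect_lt(max(abs(r$values - o)), 10 * 50 * eps64 * nrm)
})

test_that("trace conservation and orthonormality hold across matrix families", {
  for (kind in c("grm_like", "wishart", "diag_plus_noise")) {
    dm <- generate_symmetric(60, tempfile(), kind, seed = 9)
    a <- as.matrix(dm)
    for (precision in c("double", "single")) {
      r <- eigendecompose(dm, precision = precision)
      eps <- if (precision == "single") 2^-23 else eps64
      info <- paste(kind, precision)
      expect_lt(abs(sum(r$values) - sum(diag(a))),
                60 * eps * sum(abs(diag(a))) + 60 * eps, label = info)
      expect_lt(max(abs(crossprod(r$vectors) - diag(60))), 50 * 60 * eps,
                label = info)
      expect_false(is.unsorted(r$values), info = info)
    }
  }
})

test_that("disk mode reproduces memory mode bit-for-bit in storage terms", {
  dm <- generate_symmetric(80, tempfile(), "grm_like", seed = 31,
                           precision = "double")
  for (precision in c("double", "single")) {
    rm_ <- eigendecompose(dm, mode = "memory", precision = precision)
    rd <- eigendecompose(dm, mode = "disk", precision = precision,
                         tile_budget = 2000)
    eps <- if (precision == "single") 2^-23 else eps64
    expect_lte(compare_vectors(rd$values, rm_$values)$euclidean_norm,
               10 * eps)
    expect_s3_class(rd$vectors, "disk_matrix")
    qd <- align_signs(as.matrix(rd$vectors), rm_$vectors)
    expect_equal(qd, rm_$vectors, tolerance = 1e4 * eps)
  }
})

test_that("synthetic GRMs are numerically positive semi-definite", {
  g <- generate_genotypes(100, 500, tempfile(), seed = 17)
  grm <- build_grm(g, tempfile())
  r <- eigendecompose(grm)
  nrm <- max(abs(r$values))
  expect_gte(min(r$values), -100 * eps64 * nrm)
})

test_that("asymmetric input is rejected unless symmetrize is requested", {
  a <- rand_psd(20, seed = 4)
  a[3, 7] <- a[3, 7] + 0.01
  expect_error(eigendecompose(a), class = "ocm_symmetry_error",
               regexp = "A\\[")
  expect_error(eigendecompose(tmp_dm(a), mode = "disk"),
               class = "ocm_symmetry_error")
  r <- eigendecompose(a, symmetrize = TRUE)
  o <- eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(r$values, sort(o), tolerance = 1e-12)
  # disk-path symmetrization streams tile-wise
  rd <- eigendecompose(tmp_dm(a), mode = "disk", symmetrize = TRUE,
                       tile_budget = 100)
  expect_equal(rd$values, sort(o), tolerance = 1e-12)
})

test_that("non-square input raises a dimension error", {
  expect_error(eigendecompose(matrix(1, 2, 3)), class = "ocm_dimension_error")
})

test_that("descending order reverses pairing consistently in both modes", {
  dm <- generate_symmetric(30, tempfile(), "wishart", seed = 12)
  up <- eigendecompose(dm, mode = "memory")
  dn <- eigendecompose(dm, mode = "memory", descending = TRUE)
  expect_equal(dn$values, rev(up$values))
  expect_equal(dn$vectors, up$vectors[, 30:1])
  dnd <- eigendecompose(dm, mode = "disk", descending = TRUE,
                        tile_budget = 300)
  expect_equal(dnd$values, dn$values)
  expect_equal(align_signs(as.matrix(dnd$vectors), dn$vectors), dn$vectors,
               tolerance = 1e-12)
})

test_that("reconstruction residual is near zero when exact and grows with error", {
  r <- eigendecompose(diag(2))
  expect_lt(check_reconstruction(diag(2), r), 1e-15)

  a <- matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 4), 3)
  r3 <- eigendecompose(a)
  res <- sapply(c(0, 1e-8, 1e-6, 1e-4), function(delta) {
    rr <- r3
    rr$values[2] <- rr$values[2] + delta
    check_reconstruction(a, rr)
  })
  expect_false(is.unsorted(res))

  grm <- build_grm(generate_genotypes(100, 300, tempfile(), seed = 2),
                   tempfile())
  rg <- eigendecompose(grm, precision = "double")
  expect_lt(check_reconstruction(grm, rg), 1e-12)
  # streamed evaluation agrees with the in-memory formula
  a <- as.matrix(grm)
  direct <- norm(a %*% rg$vectors - rg$vectors %*% diag(rg$values), "F") /
    norm(a, "F")
  expect_equal(check_reconstruction(grm, rg, tile_budget = 1000), direct,
               tolerance = 1e-10)
})

test_that("disk mode refuses to start when the volume cannot hold the workspace", {
  dm <- tmp_dm(rand_psd(12, seed = 1))
  local_mocked_bindings(free_bytes = function(dir) 1024,
                        .package = "oocmatrix")
  expect_error(eigendecompose(dm, mode = "disk"),
               class = "ocm_resource_error", regexp = "free")
})
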