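test_that("gram accumulation matches the dense cross product", {
  expect_equal(gram_accumulate(matrix(1, 3, 2)), matrix(3, 2, 2),
               ignore_attr = TRUE)
  expect_equal(gram_accumulate(diag(2)), diag(2), ignore_attr = TRUE)

  x <- rand_mat(500, 20, seed = 6)
  dm <- tmp_dm(x)
  g <- gram_accumulate(dm, tile_budget = 20 * 90)  # forces >= 5 tiles
  expect_identical(g, t(g))                        # symmetric by construction
  expect_gte(min(diag(g)), 0)
  expect_lt(max(abs(g - crossprod(x))), 10 * eps64 * max(abs(x))^2 * 500)
})

test_that("gram accumulation is independent of the tile budget", {
  x <- rand_mat(200, 12, seed = 14)
  dm <- tmp_dm(x)
  ref <- gram_accumulate(dm, tile_budget = 200 * 12)
  for (budget in c(144, 12 * 37, 12 * 113, 12 * 199)) {
    g <- gram_accumulate(dm, tile_budget = budget)
    expect_lt(max(abs(g - ref)), 10 * eps64 * max(abs(x))^2 * 200)
  }
})

test_that("a Gram matrix too large for the budget is refused with advice", {
  dm <- tmp_dm(rand_mat(10, 8, seed = 1))
  expect_error(gram_accumulate(dm, tile_budget = 63),
               class = "ocm_resource_error", regexp = "eigendecompose")
})

test_that("thin SVD solves closed-form cases", {
  a <- rbind(diag(c(3, 2, 1)), matrix(0, 2, 3))
  r <- svd_thin(a)
  expect_equal(r$d, c(3, 2, 1), tolerance = 1e-12)

  col1 <- matrix(1, 4, 1)
  r1 <- svd_thin(col1)
  expect_equal(r1$d, 2, tolerance = 1e-14)
  expect_equal(abs(r1$v), matrix(1, 1, 1), tolerance = 1e-14)
  expect_equal(abs(r1$u), matrix(0.5, 4, 1), tolerance = 1e-14)
})

test_that("singular values match a direct dense SVD on a genotype fixture", {
  z <- rand_geno_std(200, 15, seed = 41)
  dm <- tmp_dm(z, precision = "single")
  r <- svd_thin(dm, precision = "single", tile_budget = 15 * 60)
  o32 <- svd(as.matrix(dm))        # oracle on the binary32-stored values
  expect_lte(compare_vectors(r$d, o32$d)$euclidean_norm, 1e-5)
  # double precision path is tighter and the vectors agree too
  rd <- svd_thin(tmp_dm(z), precision = "double")
  o <- svd(z)
  expect_lt(compare_vectors(rd$d, o$d)$euclidean_norm, 1e-9)
  expect_equal(align_signs(rd$v, o$v), o$v, tolerance = 1e-7)
  expect_equal(align_signs(rd$u, o$u), o$u, tolerance = 1e-7)
})

test_that("U and V are orthonormal and reconstruct the matrix", {
  x <- rand_mat(80, 10, seed = 51)
  r <- svd_thin(x)
  expect_lt(max(abs(crossprod(r$v) - diag(10))), 50 * 80 * eps64)
  expect_lt(max(abs(crossprod(r$u) - diag(10))), 50 * 80 * eps64)
  recon <- r$u %*% (r$d * t(r$v))
  kappa <- r$d[1] / r$d[r$rank]
  expect_lt(norm(x - recon, "F") / norm(x, "F"),
            100 * sqrt(80) * eps64 * kappa)
})

test_that("energy is conserved and Gram eigenvalues equal squared singular values", {
  x <- rand_mat(120, 9, seed = 61)
  dm <- tmp_dm(x)
  g <- gram_accumulate(dm)
  r <- svd_thin(dm)
  expect_equal(sum(r$d^2), sum(diag(g)), tolerance = 120 * eps64 * 10)
  lam <- eigendecompose(g, descending = TRUE)$values
  expect_lt(compare_vectors(r$d^2, lam)$euclidean_norm, 100 * eps64)
})

test_that("top-k enforces k < min(N, M) and returns the thin prefix", {
  a <- rbind(diag(c(3, 2, 1)), matrix(0, 2, 3))
  expect_equal(svd_topk(a, 2)$d, c(3, 2), tolerance = 1e-12)
  expect_error(svd_topk(a, 3), class = "ocm_parameter_error",
               regexp = "min\\(N, M\\)")
  expect_error(svd_topk(a, 0), class = "ocm_parameter_error")
  expect_error(svd_topk(a, 1.5), class = "ocm_parameter_error")

  x <- rand_mat(300, 25, seed = 71)
  dm <- tmp_dm(x)
  full <- svd_thin(dm)
  for (k in c(1, 5, 24)) {
    rk <- svd_topk(dm, k)
    expect_identical(rk$d, full$d[seq_len(k)])        # same code path
    expect_equal(align_signs(rk$v, full$v[, seq_len(k), drop = FALSE]),
                 full$v[, seq_len(k), drop = FALSE])
    expect_equal(align_signs(rk$u, full$u[, seq_len(k), drop = FALSE]),
                 full$u[, seq_len(k), drop = FALSE], tolerance = 1e-10)
  }
})

test_that("singular values scale linearly and vectors are scale-invariant", {
  x <- rand_mat(60, 7, seed = 81)
  r <- svd_thin(x)
  for (c_ in c(0.25, 3)) {
    rc <- svd_thin(c_ * x)
    expect_equal(rc$d, c_ * r$d, tolerance = 1e-10)
    expect_equal(align_signs(rc$v, r$v), r$v, tolerance = 1e-8)
  }
})

test_that("wide input is transposed internally and the swap is flagged", {
  x <- rand_mat(8, 30, seed = 91)
  r <- svd_thin(x)
  o <- svd(x)
  expect_true(r$swapped)
  expect_equal(r$d, o$d, tolerance = 1e-10)
  expect_equal(dim(r$u), c(8L, 8L))
  expect_equal(dim(full_matrix(r$v)), c(30L, 8L))
})

test_that("rank-deficient columns are zero-filled and flagged", {
  x <- cbind(rand_mat(40, 3, seed = 3), 0)  # an exactly zero column
  x <- cbind(x, x[, 1])                     # and a duplicate
  r <- svd_thin(x)
  expect_equal(r$rank, 3L)
  expect_equal(r$zeroed, 4:5)
  expect_true(all(r$u[, r$zeroed] == 0))
})

test_that("disk-mode U streams to a file identical to the in-memory result", {
  x <- rand_mat(150, 6, seed = 15)
  dm <- tmp_dm(x)
  rm_ <- svd_thin(dm, mode = "memory", tile_budget = 6 * 37)
  rd <- svd_thin(dm, mode = "disk", tile_budget = 6 * 37)
  expect_s3_class(rd$u, "disk_matrix")
  expect_equal(as.matrix(rd$u), rm_$u, tolerance = 1e-12)
  expect_identical(rd$d, rm_$d)
})

test_that("empty input is a dimension error", {
  dm <- tmp_dm(matrix(1, 2, 2))
  dm$n_cols <- 0L
  expect_error(svd_thin(dm), class = "ocm_dimension_error")
})
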