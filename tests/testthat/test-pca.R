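series_from_matrix <- function(mat) {
  S <- ncol(mat)
  out <- tibble::tibble(
    frame = rep(seq_len(nrow(mat)), each = S),
    class = rep(as.character(seq_len(S)), nrow(mat)),
    size = rep(seq_len(S), nrow(mat)),
    n_clusters = NA_integer_,
    component = as.numeric(t(mat)))
  attr(out, "s_max") <- S
  out
}

test_that("the covariance follows the 1/N_frames formula", {
  # constant series: zero matrix
  const <- series_from_matrix(matrix(rep(c(0.5, 0.3, 0.2, 0), 6), 6, 4,
                                     byrow = TRUE))
  expect_equal(population_covariance(const, 4), matrix(0, 4, 4),
               ignore_attr = TRUE)
  # two frames (0.6,0.4,0,0) and (0.4,0.6,0,0): hand-computed entries
  two <- series_from_matrix(rbind(c(0.6, 0.4, 0, 0), c(0.4, 0.6, 0, 0)))
  C <- population_covariance(two, 4)
  expect_equal(C[1, 1], 0.01, tolerance = 1e-15)
  expect_equal(C[2, 2], 0.01, tolerance = 1e-15)
  expect_equal(C[1, 2], -0.01, tolerance = 1e-15)
  expect_equal(C[3:4, ], matrix(0, 2, 4), ignore_attr = TRUE)
  expect_error(population_covariance(series_from_matrix(rbind(c(1, 0, 0, 0))), 4),
               "2 frames")
})

test_that("the covariance matches a naive double-loop oracle on random series", {
  withr::with_seed(102, {
    for (rep in 1:10) {
      mat <- matrix(runif(4 * 25), 25, 4)
      mat <- mat / rowSums(mat)
      C <- population_covariance(series_from_matrix(mat), 4)
      expect_equal(unclass(C), covariance_oracle(mat),
                   ignore_attr = TRUE, tolerance = 1e-12)
      # permuting frames leaves the covariance unchanged
      Cp <- population_covariance(series_from_matrix(mat[sample(25), ]), 4)
      expect_equal(C, Cp, tolerance = 1e-12)
    }
  })
})

test_that("decomposition is a faithful symmetric eigen-solve with fixed signs", {
  r <- pca_decompose(diag(c(3, 2, 1, 0)))
  expect_equal(r$eigenvalues, c(3, 2, 1, 0))
  expect_equal(abs(r$eigenvectors), diag(4), tolerance = 1e-12)
  expect_equal(r$variance_fractions, c(3, 2, 1, 0) / 6)

  # rank-1 two-frame case: leading mode (1,-1,0,0)/sqrt(2), all the variance
  two <- series_from_matrix(rbind(c(0.6, 0.4, 0, 0), c(0.4, 0.6, 0, 0)))
  r2 <- pop_pca(two, 4)
  expect_equal(r2$eigenvectors[, 1], c(1, -1, 0, 0) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(r2$variance_fractions[1], 1, tolerance = 1e-12)

  withr::with_seed(112, {
    for (rep in 1:10) {
      A <- matrix(rnorm(16), 4, 4)
      C <- crossprod(A) / 4
      r3 <- pca_decompose(C)
      # reconstruction, orthonormality, trace conservation, sign rule
      expect_lt(max(abs(C - r3$eigenvectors %*% diag(r3$eigenvalues) %*%
                          t(r3$eigenvectors))), 1e-10)
      expect_lt(max(abs(crossprod(r3$eigenvectors) - diag(4))), 1e-10)
      expect_equal(sum(r3$eigenvalues), sum(diag(C)), tolerance = 1e-12)
      for (j in 1:4) {
        v <- r3$eigenvectors[, j]
        expect_gt(v[which.max(abs(v))], 0)
      }
    }
  })
  expect_error(pca_decompose(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("overflow-free series have the zero-sum mode C 1 = 0", {
  withr::with_seed(122, {
    parts <- lapply(1:20, function(i) {
      sizes <- draw_sizes(20L, max_size = 4L)
      tibble::tibble(molecule_id = 1:20,
                     role = rep(c("cation", "anion"), 10),
                     cluster = rep(seq_along(sizes), times = sizes))
    })
    ser <- state_vector_series(parts, s_max = 4)
    C <- population_covariance(ser, 4)
    expect_lt(max(abs(C %*% rep(1, 4))), 1e-10)
    r <- pca_decompose(C)
    expect_lt(abs(r$eigenvalues[4]), 1e-10)
    expect_lt(angle_deg(r$eigenvectors[, 4], rep(1, 4)), 1e-4)
  })
})

test_that("planted two-mode series are recovered in direction and order", {
  spec <- series_spec(n_frames = 10000, amplitudes = c(0.06, 0.03),
                      noise = 0.003, seed = 33)
  ps <- plant_series(spec)
  # empirical covariance approaches the analytic one
  C <- population_covariance(ps$series, 4)
  expect_lt(max(abs(C - ps$covariance)), 0.05 * max(abs(ps$covariance)))
  r <- pca_decompose(C)
  expect_lt(angle_deg(r$eigenvectors[, 1], ps$modes[, 1]), 5)
  expect_lt(angle_deg(r$eigenvectors[, 2], ps$modes[, 2]), 5)
  expect_gt(r$eigenvalues[1], r$eigenvalues[2])
})

test_that("mode reports classify the canonical fluctuation schemes", {
  two <- series_from_matrix(rbind(c(0.6, 0.4, 0, 0), c(0.4, 0.6, 0, 0)))
  r <- pop_pca(two, 4)
  rep1 <- mode_report(r, k = 1)
  expect_equal(rep1$cumulative_variance, 1, tolerance = 1e-12)
  expect_equal(unique(rep1$loadings$pattern), "monomer-dimer anticorrelation")

  # small-vs-large redistribution pattern
  r2 <- pca_decompose(tcrossprod(c(1, 1, -1, -1) / 2))
  expect_equal(ionclust:::classify_mode(r2$eigenvectors[, 1]),
               "monomer-dimer vs trimer-tetramer anticorrelation")

  # full-rank report carries all the variance
  withr::with_seed(132, {
    mat <- matrix(runif(4 * 30), 30, 4); mat <- mat / rowSums(mat)
    rf <- pop_pca(series_from_matrix(mat), 4)
    expect_equal(mode_report(rf, k = 4)$cumulative_variance, 1,
                 tolerance = 1e-10)
  })
})

test_that("tidy and glance expose the decomposition as tibbles", {
  two <- series_from_matrix(rbind(c(0.6, 0.4, 0, 0), c(0.4, 0.6, 0, 0)))
  r <- pop_pca(two, 4)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  gl <- glance(r)
  expect_equal(gl$var_mode1, 1, tolerance = 1e-12)
  expect_equal(gl$n_frames, 2L)
  expect_s3_class(autoplot(r), "ggplot")
})
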