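test_that("the (+-1,+-2,+-3) cube gives semiaxes (6,4,2) via a_i = 2*sqrt(lambda_i)", {
  pts <- as.matrix(expand.grid(c(-1, 1), c(-2, 2), c(-3, 3)))
  e <- fit_ellipsoid(pts)
  expect_equal(e$center, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(e$semiaxes, c(6, 4, 2), tolerance = 1e-12)
})

test_that("degenerate molecules are floored to a positive-volume ellipsoid", {
  e <- fit_ellipsoid(matrix(c(5, 5, 5), 1, 3))
  expect_equal(e$center, c(5, 5, 5), ignore_attr = TRUE)
  expect_equal(e$semiaxes, rep(0.1, 3))
  # linear molecule: two degenerate directions floored, long axis kept
  line <- cbind(seq(-1, 1, length.out = 5), 0, 0)
  el <- fit_ellipsoid(line)
  expect_gt(el$semiaxes[1], 1)
  expect_equal(el$semiaxes[2:3], c(0.1, 0.1))
  expect_error(fit_ellipsoid(matrix(numeric(), 0, 3)), "non-empty")
})

test_that("random clouds match an independent eigen-solve of the explicit second-moment matrix", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      pts <- matrix(rnorm(60, sd = 0.3), 20, 3)
      e <- fit_ellipsoid(pts, semiaxis_floor = 0)
      mu <- colMeans(pts)
      M <- matrix(0, 3, 3)
      for (k in seq_len(nrow(pts))) {
        d <- pts[k, ] - mu
        M <- M + outer(d, d)
      }
      M <- M / nrow(pts)
      expect_equal(e$semiaxes, 2 * sqrt(eigen(M, symmetric = TRUE)$values),
                   tolerance = 1e-10)
      expect_equal(max(abs(crossprod(e$axes) - diag(3))), 0, tolerance = 1e-10)
    }
  })
})

test_that("the fit is translation- and rotation-equivariant and relabeling-invariant", {
  withr::with_seed(31, {
    pts <- matrix(rnorm(36, sd = 0.2), 12, 3)
    e0 <- fit_ellipsoid(pts, semiaxis_floor = 0)
    # translation
    e1 <- fit_ellipsoid(sweep(pts, 2, c(1, -2, 3), "+"), semiaxis_floor = 0)
    expect_equal(e1$semiaxes, e0$semiaxes, tolerance = 1e-8)
    expect_equal(e1$center, e0$center + c(1, -2, 3), ignore_attr = TRUE)
    # rotation
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    e2 <- fit_ellipsoid(pts %*% t(R), semiaxis_floor = 0)
    expect_equal(e2$semiaxes, e0$semiaxes, tolerance = 1e-8)
    # relabeling
    e3 <- fit_ellipsoid(pts[sample(nrow(pts)), ], semiaxis_floor = 0)
    expect_equal(e3$semiaxes, e0$semiaxes, tolerance = 1e-12)
  })
})

test_that("shell semiaxes follow a(n) = a_i + n*delta", {
  e <- fit_ellipsoid(as.matrix(expand.grid(c(-1, 1), c(-2, 2), c(-3, 3))))
  spec <- shell_spec(delta = 0.4)
  expect_equal(shell_semiaxes(e, spec, 0), c(6, 4, 2))
  expect_equal(shell_semiaxes(e, spec, 1), c(6.4, 4.4, 2.4))
  expect_equal(shell_semiaxes(e, spec, 5), c(8, 6, 4))
  expect_error(shell_semiaxes(e, spec, -1), ">= 0")
})

test_that("ellipsoid membership agrees with a principal-frame oracle and includes the boundary", {
  withr::with_seed(41, {
    box <- c(10, 10, 10)
    pts <- matrix(rnorm(30, sd = 0.3), 10, 3) + 5
    e <- fit_ellipsoid(pts)
    expect_true(ellipsoid_contains(e, e$semiaxes, e$center, box))
    # boundary point along the major axis is inside (inclusive convention)
    pb <- e$center + e$semiaxes[1] * e$axes[, 1]
    expect_true(ellipsoid_contains(e, e$semiaxes, pb, box))
    expect_false(ellipsoid_contains(e, e$semiaxes,
                                    e$center + 1.0001 * e$semiaxes[1] * e$axes[, 1],
                                    box))
    # random points: build them in the principal frame where membership is
    # the plain quadratic test, then map to world coordinates
    for (rep in 1:200) {
      q <- runif(3, -1.5, 1.5) * e$semiaxes
      inside <- sum((q / e$semiaxes)^2) <= 1
      world <- e$center + drop(e$axes %*% q)
      # shift by whole boxes: membership must be periodic
      world <- world + sample(-1:1, 3, replace = TRUE) * box
      expect_identical(ellipsoid_contains(e, e$semiaxes, world, box), inside)
    }
  })
})

test_that("shells tile space with boundaries assigned to the inner shell", {
  # reference ion at the centre; a solvent atom placed mid-shell-1
  spec <- shell_spec(delta = 0.4)
  ref <- as.matrix(expand.grid(c(-0.1, 0.1), c(-0.1, 0.1), c(-0.1, 0.1))) + 5
  e <- fit_ellipsoid(ref)
  probe <- e$center + (e$semiaxes[1] + 0.5 * spec$delta) * e$axes[, 1]
  fr <- toy_frame(rbind(ref, probe),
                  roles = c(rep("cation", 8), "solvent"),
                  molecule_id = c(rep(1L, 8), 2L))
  for (n in 0:3) {
    occ <- shell_occupants(e, spec, n, fr, reference_id = 1L)
    expect_equal(nrow(occ$solvent), as.integer(n == 1))
    expect_equal(nrow(occ$ion), 0L)
  }
  # frame with only the reference ion: every shell is empty
  fr2 <- toy_frame(ref, roles = rep("cation", 8), molecule_id = rep(1L, 8))
  for (n in 0:2) {
    occ <- shell_occupants(e, spec, n, fr2, reference_id = 1L)
    expect_equal(nrow(occ$ion) + nrow(occ$solvent), 0L)
  }
})

test_that("every atom lands in exactly one shell (brute-force cross-check)", {
  withr::with_seed(51, {
    spec <- shell_spec(delta = 0.4, n_max = 8L)
    box <- c(8, 8, 8)
    ref <- matrix(rnorm(15, sd = 0.15), 5, 3) + 4
    e <- fit_ellipsoid(ref)
    pts <- matrix(runif(300, 0, 8), 100, 3)
    idx <- ionclust:::shell_index(e, spec, pts, box, n_max = 8L)
    for (k in seq_len(nrow(pts))) {
      memberships <- vapply(0:8, function(n) {
        ellipsoid_contains(e, shell_semiaxes(e, spec, n), pts[k, ], box)
      }, logical(1))
      smallest <- if (any(memberships)) min(which(memberships)) - 1L else NA_integer_
      expect_identical(idx[k], smallest)
    }
  })
})
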