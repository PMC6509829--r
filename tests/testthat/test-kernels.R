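# Exact enumeration oracle for the shared-miRNA tail probability:
# p = 1 - sum_{x=0}^{n-1} C(K,x) C(N-K,M-x) / C(N,M). All binomials involved
# stay below 2^53 for N <= 25, so double arithmetic is exact here.
hypergeom_oracle <- function(N, K, M, n) {
  if (n == 0) return(1)
  x <- 0:(n - 1)
  1 - sum(choose(K, x) * choose(N - K, M - x)) / choose(N, M)
}

test_that("hypergeometric tail matches the enumeration oracle exhaustively", {
  for (N in 1:25) {
    for (K in 0:N) {
      for (M in 0:N) {
        n <- 0:min(K, M)
        expect_equal(hypergeom_pvalue(N, K, M, n),
                     vapply(n, hypergeom_oracle, numeric(1),
                            N = N, K = K, M = M),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("hypergeometric boundary and closed-form cases", {
  expect_identical(hypergeom_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(20, 10, 10, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  # non-increasing in n at fixed (N, K, M)
  p <- hypergeom_pvalue(25, 12, 9, 0:9)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "min")
  expect_error(hypergeom_pvalue(10, 11, 4, 2), "exceed")
})

test_that("pearson_test matches cor.test and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  v <- vectors_with_cor(0.6, n = 25)
  ct <- stats::cor.test(v$x, v$y)
  pt <- pearson_test(v$x, v$y)
  expect_equal(pt$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pt$p, ct$p.value, tolerance = 1e-9)
  expect_error(pearson_test(x, rep(1, 5)), "variance")
  expect_error(pearson_test(x, x[1:3]), "length")
})

test_that("pearson r concentrates near the population value", {
  with_seed_local(21, {
    x <- stats::rnorm(30)
    y <- 0.8 * x + sqrt(1 - 0.64) * stats::rnorm(30)
    expect_lt(abs(pearson_test(x, y)$r - 0.8), 0.15)
  })
})

test_that("partial correlation: zero-order, order-1 closed form, random sweep", {
  v <- vectors_with_cor(0.42, n = 30)
  expect_equal(partial_correlation(v$x, v$y), stats::cor(v$x, v$y))
  expect_equal(partial_correlation(v$x, v$y, NULL), stats::cor(v$x, v$y))

  # order-1 closed form on 1000 random triples
  with_seed_local(13, {
    for (i in 1:1000) {
      d <- matrix(stats::rnorm(30), 10, 3)
      R <- stats::cor(d)
      closed <- (R[1, 2] - R[1, 3] * R[2, 3]) /
        sqrt((1 - R[1, 3]^2) * (1 - R[2, 3]^2))
      expect_equal(partial_correlation(d[, 1], d[, 2], d[, 3]), closed,
                   tolerance = 1e-10)
    }
  })

  # fixed algebraic case rho_xy = 0.8, rho_xz = rho_yz = 0.5 -> 0.55/0.75
  R <- matrix(c(1, .8, .5, .8, 1, .5, .5, .5, 1), 3)
  L <- chol(R)
  with_seed_local(3, {
    raw <- matrix(stats::rnorm(600), 200, 3)
    raw <- scale(raw, scale = FALSE)
    raw <- qr.Q(qr(raw)) # centered orthonormal columns -> exact sample cor
    d <- raw %*% L
    expect_equal(partial_correlation(d[, 1], d[, 2], d[, 3]), 0.55 / 0.75,
                 tolerance = 1e-9)
  })

  # x, y driven only by shared z -> partial approximately 0
  with_seed_local(17, {
    z <- stats::rnorm(500)
    x <- z + 0.3 * stats::rnorm(500)
    y <- z + 0.3 * stats::rnorm(500)
    expect_gt(stats::cor(x, y), 0.7)
    expect_lt(abs(partial_correlation(x, y, z)), 0.1)
  })

  expect_error(partial_correlation(v$x, v$y, cbind(a = v$x, b = v$x)),
               "collinear")
})

test_that("Gaussian MI closed form and CMI behavior", {
  for (r in c(0, 0.5, 0.9)) {
    v <- vectors_with_cor(r, n = 50)
    expect_equal(mi_gaussian(v$x, v$y), -0.5 * log(1 - r^2),
                 tolerance = 1e-9)
  }
  expect_equal(-0.5 * log(1 - 0.9^2), 0.83037, tolerance = 1e-4)
  # conditioning on noise barely changes MI
  with_seed_local(31, {
    x <- stats::rnorm(300)
    y <- 0.7 * x + stats::rnorm(300)
    z <- stats::rnorm(300)
    expect_lt(abs(cmi_gaussian(x, y, z) - mi_gaussian(x, y)), 0.05)
  })
})

test_that("binning MI estimator agrees with the Gaussian one on linear data", {
  # coarse bins keep the plug-in bias ((r-1)(c-1)/2n) negligible
  with_seed_local(41, {
    x <- stats::rnorm(2000)
    y <- 0.8 * x + 0.6 * stats::rnorm(2000)
    expect_lt(abs(mi_binned(x, y, bins = 8) - mi_gaussian(x, y)), 0.1)
    expect_lt(mi_binned(x, stats::rnorm(2000), bins = 8), 0.05)
  })
})

test_that("delta statistic reflects conditioning structure", {
  with_seed_local(53, {
    mir <- stats::rnorm(400)
    rnai <- -0.8 * mir + 0.4 * stats::rnorm(400)
    noise <- stats::rnorm(400)
    # conditioning on noise: delta near 0
    expect_lt(abs(delta_statistic("hermes", mir, rnai, noise)), 0.05)
    expect_lt(abs(delta_statistic("ppc", mir, rnai, noise)), 0.05)
    # conditioning on a near-copy removes nearly all information
    copy <- rnai + 0.01 * stats::rnorm(400)
    d <- delta_statistic("hermes", mir, rnai, copy)
    expect_equal(d, -mi_gaussian(mir, rnai), tolerance = 0.1)
    # planted competition: partner absorbs dependence -> delta below null
    partner <- -0.8 * mir + 0.4 * stats::rnorm(400)
    d_obs <- delta_statistic("hermes", mir, rnai, partner)
    d_null <- replicate(50, delta_statistic("hermes", mir, rnai,
                                            sample(partner)))
    expect_lt(d_obs, stats::median(d_null))
  })
})

test_that("permutation p-value counting and boundaries", {
  expect_equal(permutation_pvalue(101, 1:100), 1 / 101)  # above every draw
  expect_equal(permutation_pvalue(0, 1:100), 1)          # below every draw
  expect_equal(permutation_pvalue(50.5, 1:99), 0.5)      # at the median
  expect_equal(permutation_pvalue(50.5, 1:100, "less"), 51 / 101)
  expect_error(permutation_pvalue(1, numeric(0)), "non-empty")
})

test_that("Fisher combination identities", {
  # single p passes through (df = 2 identity)
  for (p in c(0.9, 0.3, 0.01)) {
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-9)
  }
  # all ones
  res <- fisher_combine(c(1, 1, 1))
  expect_equal(res$x2, 0)
  expect_equal(res$p, 1)
  # closed form for df = 4: p = exp(-x/2) (1 + x/2)
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$x2, -4 * log(0.05), tolerance = 1e-9)
  expect_equal(res$x2, 11.983, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  expect_equal(res$p, exp(-res$x2 / 2) * (1 + res$x2 / 2), tolerance = 1e-9)
  expect_equal(res$p, 0.0175, tolerance = 2e-3)
  # X^2 additivity
  expect_equal(fisher_combine(c(0.1, 0.2, 0.3))$x2,
               fisher_combine(0.1)$x2 + fisher_combine(c(0.2, 0.3))$x2,
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  with_seed_local(61, {
    p <- stats::runif(50)
    a <- adjust_bh(p)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
    expect_identical(order(a[order(p)]), seq_along(p)) # order-preserving
  })
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})
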