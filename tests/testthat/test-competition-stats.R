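test_that("hypergeometric overlap test matches hand-derived values", {
  # 1/252: only the single fully-overlapping draw of C(10,5) arrangements
  expect_equal(overlap_pvalue(10, 5, 5, 5)$p_value, 1 / 252, tolerance = 1e-14)
  # 1 - C(2,0) C(2,2) / C(4,2) = 1 - 1/6
  expect_equal(overlap_pvalue(4, 2, 2, 1)$p_value, 5 / 6, tolerance = 1e-14)
  # empty sum: observing 0 or more is certain
  expect_equal(overlap_pvalue(100, 30, 40, 0)$p_value, 1)
  expect_error(overlap_pvalue(10, 11, 5, 2), "universe")
  expect_error(overlap_pvalue(10, 3, 5, 4), "overlap")
})

test_that("overlap p-value is monotone non-increasing in the overlap", {
  for (N in c(12, 25, 80)) {
    M <- floor(N / 3); K <- floor(N / 2)
    ps <- vapply(0:min(M, K), function(L)
      overlap_pvalue(N, M, K, L)$p_value, numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
  }
})

test_that("overlap p-value agrees with factorial enumeration on small universes", {
  for (N in c(5L, 11L, 18L)) {
    for (M in 0:N) for (K in seq.int(0L, N, by = 3L)) {
      tails <- hyper_tail_oracle(N, M, K)
      got <- vapply(0:min(M, K), function(L)
        overlap_pvalue(N, M, K, L)$p_value, numeric(1))
      expect_equal(got, tails[seq_along(got)], tolerance = 1e-12)
    }
  }
})

test_that("pearson_test reproduces the correlation formula and t transform", {
  # hand evaluation: deviation products sum to 8, each sum of squares 10
  r <- pearson_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$cor, 0.8, tolerance = 1e-15)
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(r$p_value, 2 * pt(tstat, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  x <- rnorm(20)
  ident <- pearson_test(x, x)
  expect_equal(ident$cor, 1)
  expect_equal(ident$p_value, 0)

  expect_error(pearson_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_test(rnorm(4), rnorm(4)), "5 samples")
})

test_that("correlation p-value equals numerical integration of the t density", {
  set.seed(31)
  for (i in 1:20) {
    s <- sample(6:60, 1)
    x <- rnorm(s); y <- rnorm(s) + 0.3 * x
    res <- pearson_test(x, y)
    tval <- res$cor * sqrt(s - 2) / sqrt(1 - res$cor^2)
    expect_equal(res$p_value, 2 * t_upper_tail_numint(tval, s - 2),
                 tolerance = 1e-10)
  }
})

test_that("independent long vectors rarely show |cor| above 0.1", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(pearson_test(rnorm(1000), rnorm(1000))$cor) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("partial correlation: base case, collinearity, and recursion agreement", {
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50) + 0.5 * x
  expect_equal(partial_correlation(x, y, NULL), cor(x, y), tolerance = 1e-15)

  z_bad <- cbind(rnorm(50), y)
  res <- partial_correlation(x, y, z_bad)
  expect_true(is.na(res))
  expect_true(isTRUE(attr(res, "degenerate")))

  # inversion vs first-order recursion across conditioning sizes
  for (trial in 1:25) {
    set.seed(100 + trial)
    n <- sample(1:8, 1)
    base <- rnorm(50)
    z <- matrix(rnorm(50 * n), 50) + base
    x <- rnorm(50) + 0.4 * base
    y <- rnorm(50) + 0.4 * base
    inv <- partial_correlation(x, y, z, method = "inversion")
    rec <- partial_correlation(x, y, z, method = "recursion")
    expect_equal(as.numeric(inv), as.numeric(rec), tolerance = 1e-8)
  }
})

test_that("duplicated conditioning columns are dropped, not fatal", {
  set.seed(12)
  x <- rnorm(60); y <- rnorm(60) + x
  z1 <- rnorm(60)
  z <- cbind(z1, z1, rnorm(60))
  res <- partial_correlation(x, y, z)
  expect_false(is.na(res))
  expect_equal(as.numeric(res),
               as.numeric(partial_correlation(x, y, z[, c(1, 3)])),
               tolerance = 1e-12)
})

test_that("sensitive correlation behaves per its construction", {
  set.seed(21)
  x <- rnorm(100); y <- rnorm(100) + 0.5 * x
  expect_equal(sensitivity(x, y, NULL)$sc, 0)

  # uncorrelated conditioners: sc centred at zero
  scs <- vapply(1:200, function(i) {
    set.seed(i)
    x <- rnorm(200); y <- 0.4 * x + rnorm(200)
    z <- matrix(rnorm(200 * 3), 200)
    sensitivity(x, y, z)$sc
  }, numeric(1))
  expect_lt(mean(abs(scs)), 0.05)

  # common driver: conditioning strips the shared signal, sc > 0
  set.seed(77)
  z <- rnorm(300)
  x <- z + rnorm(300) * 0.5
  y <- z + rnorm(300) * 0.5
  res <- sensitivity(x, y, cbind(z))
  expect_gt(res$sc, 0.3)
  expect_identical(res$sc, res$cor - res$pcor)
})
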