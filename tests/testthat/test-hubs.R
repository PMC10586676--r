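test_that("Poisson hub p-values match direct summation", {
  # K5: n = 5, m = 10 -> lambda = 2m/(n-1) = 5; every node has k = 4
  k5 <- hub_pvalues(igraph::make_full_graph(5))
  expect_true(all(k5$lambda == 5))
  direct <- 1 - exp(-5) * (1 + 5 + 25 / 2 + 125 / 6)
  expect_equal(k5$p_value, rep(direct, 5), tolerance = 1e-12)
  expect_equal(direct, 0.734974, tolerance = 1e-6)

  # lambda = 1, k = 1: p = 1 - exp(-1)
  g <- igraph::graph_from_literal(a - b, c, d) # n=4, m=1 -> lambda = 2/3
  tab <- hub_pvalues(g, pair_count = "unordered")
  lam <- 2 * 1 / (4 - 1)
  expect_equal(tab$lambda[1], lam)
  expect_equal(tab$p_value[tab$degree == 1], rep(1 - exp(-lam), 2))
  expect_equal(tab$p_value[tab$degree == 0], rep(1, 2)) # empty sum

  # arrangement reading halves lambda
  tab2 <- hub_pvalues(g, pair_count = "arrangement")
  expect_equal(tab2$lambda[1], lam / 2)
})

test_that("hub p-value is strictly decreasing in degree at fixed lambda", {
  lam <- 2.7
  ps <- ppois(0:19, lam, lower.tail = FALSE) # P(X >= k) for k = 1..20
  expect_true(all(diff(ps) < 0))
})

test_that("hub calls are calibrated on uniform random graphs", {
  frac <- vapply(1:50, function(s) {
    g <- with(list(), {set.seed(s); igraph::sample_gnm(200, 400)})
    mean(hub_pvalues(g)$is_hub)
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("overlap similarity: identities, bounds, and the hand-worked case", {
  expect_equal(overlap_similarity(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_similarity(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlap_similarity(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_true(is.na(overlap_similarity(character(0), "a")))

  # overlap coefficient dominates Jaccard
  set.seed(40)
  for (i in 1:20) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_gte(overlap_similarity(a, b), jac)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  sets <- list(T1 = c("a", "b", "c"), T2 = c("b", "c", "d", "e"),
               T3 = c("a", "x"))
  m <- similarity_matrix(sets)
  expect_identical(m, t(m))
  expect_equal(diag(m), c(T1 = 1, T2 = 1, T3 = 1))
  expect_equal(m["T1", "T2"], 2 / 3)
  expect_equal(m["T1", "T3"], 1 / 2)
  expect_equal(m["T2", "T3"], 0)

  twin <- similarity_matrix(list(A = c("e1", "e2"), B = c("e1", "e2")))
  expect_equal(unname(twin), matrix(1, 2, 2))
})

test_that("conserved/rewired labels partition all observed items", {
  sets <- list(T1 = c("a", "b"), T2 = c("b", "c"), T3 = c("c", "d"))
  rep <- conserved_rewired(sets)
  expect_setequal(rep$item, c("a", "b", "c", "d"))
  expect_identical(rep$status[rep$item == "b"], "conserved") # in 2 of 3
  expect_identical(rep$status[rep$item == "a"], "rewired")   # in exactly 1
  expect_equal(sum(rep$status == "conserved") + sum(rep$status == "rewired"),
               length(unique(unlist(sets))))
  pct <- attr(rep, "rewired_pct")
  expect_equal(unname(pct["T1"]), 50)
})
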