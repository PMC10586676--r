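test_that("characteristic path length and density have their exact small-graph values", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(char_path_length(path3), 4 / 3)
  expect_equal(graph_density(path3), 2 / 3)
  expect_equal(char_path_length(igraph::make_full_graph(6)), 1)
})

test_that("random ensembles are exactly size-matched and seed-reproducible", {
  ens <- random_ensemble(100, 200, count = 20, seed = 6)
  expect_length(ens, 20)
  expect_true(all(vapply(ens, igraph::vcount, numeric(1)) == 100))
  expect_true(all(vapply(ens, igraph::ecount, numeric(1)) == 200))
  expect_true(all(vapply(ens, graph_density, numeric(1)) == 200 / 4950))

  ens2 <- random_ensemble(100, 200, count = 20, seed = 6)
  expect_identical(lapply(ens, igraph::as_edgelist),
                   lapply(ens2, igraph::as_edgelist))
  expect_error(random_ensemble(5, 11), "exceeds")
})

test_that("preferential-attachment degrees look power-law; same-size ER degrees fit worse", {
  ks_pa <- ks_er <- numeric(10)
  p_pa <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    pa <- igraph::sample_pa(1000, m = 3, directed = FALSE)
    er <- igraph::sample_gnm(1000, igraph::ecount(pa))
    res <- powerlaw_test(pa)
    p_pa[s] <- res$p_value
    # common fixed xmin makes the tail shapes directly comparable
    ks_pa[s] <- powerlaw_test(pa, xmin = 3)$ks_statistic
    ks_er[s] <- powerlaw_test(er, xmin = 3)$ks_statistic
  }
  expect_gte(mean(p_pa >= 0.05), 0.8)
  expect_gt(median(ks_er), median(ks_pa))
})

test_that("degenerate degree shapes are handled", {
  star <- igraph::make_star(51, mode = "undirected")
  res <- powerlaw_test(star)
  expect_true(is.finite(res$exponent))

  ring <- igraph::make_ring(30) # all degrees equal -> fit undefined
  res2 <- powerlaw_test(ring)
  expect_true(is.na(res2$p_value))
})

test_that("small-world tests point the right way", {
  set.seed(2)
  ring <- igraph::make_ring(60)
  ens <- random_ensemble(60, 60, count = 50, seed = 3)
  sw <- small_world_tests(ring, ens)
  # a ring is much longer than G(n,m): observed shorter? no -> p near 1
  expect_gt(sw$path_p, 0.95)

  k10 <- igraph::make_full_graph(10)
  same <- random_ensemble(10, 45, count = 10, seed = 1) # necessarily K10
  sw2 <- small_world_tests(k10, same)
  expect_true(is.na(sw2$path_p))
  expect_true(is.na(sw2$density_p))

  # a hub-and-spoke plus shortcuts is shorter than sparse random graphs
  set.seed(9)
  g <- igraph::sample_pa(200, m = 2, directed = FALSE)
  ens3 <- random_ensemble(200, igraph::ecount(g), count = 50, seed = 5)
  sw3 <- small_world_tests(g, ens3)
  expect_lt(sw3$path_p, 0.05)
})

test_that("topology report: strict null densities are degenerate, universe nulls are not", {
  sim <- small_sim()
  nm <- small_null_model()
  ce <- infer_cerna_network(sim$dataset, sim$priors, nm, ncrna_class = "ncrna")
  syn <- infer_synergy_network(sim$dataset, ce, nm)
  rep1 <- topology_report(syn, n_random = 30, seed = 7,
                          density_null = "strict")
  expect_true(all(rep1$random_densities == rep1$density))
  expect_true(is.na(rep1$density_test_pvalue))

  rep2 <- topology_report(syn, n_random = 30, seed = 7,
                          universe_nodes = nrow(sim$dataset$ncrna))
  expect_false(is.na(rep2$density_test_pvalue))
  expect_lt(rep2$density_test_pvalue, 0.05) # planted net denser than universe null
  expect_true(rep2$density >= 0 && rep2$density <= 1)

  # deterministic under fixed seed
  rep3 <- topology_report(syn, n_random = 30, seed = 7,
                          density_null = "strict")
  expect_identical(rep1$random_path_lengths, rep3$random_path_lengths)
  expect_identical(rep1$path_test_pvalue, rep3$path_test_pvalue)
})
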