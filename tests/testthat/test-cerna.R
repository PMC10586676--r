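test_that("candidate enumeration equals brute-force prior intersection", {
  sim <- small_sim()
  cand <- candidate_cerna_pairs(sim$dataset, sim$priors, ncrna_class = "ncrna")

  # brute force over the same restricted priors
  pri_nc <- sim$priors$ncrna
  pri_m <- sim$priors$mrna
  sets_nc <- split(pri_nc$mirna, pri_nc$target)
  sets_m <- split(pri_m$mirna, pri_m$target)
  want <- 0L
  for (nc in names(sets_nc)) for (mr in names(sets_m))
    if (length(intersect(sets_nc[[nc]], sets_m[[mr]])) >= 1L)
      want <- want + 1L
  expect_equal(nrow(cand$pairs), want)

  # shared sets are genuine intersections
  i <- which.max(cand$pairs$n_shared)
  expect_setequal(cand$shared[[i]],
                  intersect(sets_nc[[cand$pairs$ncrna[i]]],
                            sets_m[[cand$pairs$mrna[i]]]))
  # universe: miRNAs that are expressed and appear in >= 1 prior
  expect_equal(cand$universe_size,
               length(unique(c(pri_nc$mirna, pri_m$mirna))))
})

test_that("simple shared/disjoint miRNA sets drive candidacy", {
  set.seed(3)
  ds <- align_samples(list(
    mirna = tiny_expr(3, 30, prefix = "mir", gene_class = "mirna"),
    ncrna = tiny_expr(2, 30, prefix = "nc", gene_class = "ncrna", seed = 2),
    mrna = tiny_expr(2, 30, prefix = "mr", gene_class = "mrna", seed = 3)))
  priors <- list(
    ncrna = prior_table(c("mir01", "mir02", "mir03"),
                        c("nc01", "nc01", "nc02"), "ncrna"),
    mrna = prior_table(c("mir02", "mir03"), c("mr01", "mr02"), "mrna"))
  cand <- candidate_cerna_pairs(ds, priors, ncrna_class = "ncrna")
  keys <- paste(cand$pairs$ncrna, cand$pairs$mrna)
  expect_setequal(keys, c("nc01 mr01", "nc02 mr02"))
  expect_identical(cand$shared[[which(keys == "nc01 mr01")]], "mir02")

  bad <- list(ncrna = prior_table("mirX", "ncX", "ncrna"),
              mrna = priors$mrna)
  expect_error(candidate_cerna_pairs(ds, bad, ncrna_class = "ncrna"),
               "no overlap")
})

test_that("planted sponge structure is recovered with high precision", {
  sim <- small_sim()
  nm <- small_null_model()
  edges <- infer_cerna_network(sim$dataset, sim$priors, nm,
                               ncrna_class = "ncrna")
  met <- recovery_metrics(edges, sim$truth$cerna)
  expect_gte(met$precision, 0.8)
  expect_gte(met$recall, 0.5)
})

test_that("edge set is monotone in alpha and deterministic", {
  sim <- small_sim()
  nm <- small_null_model()
  e1 <- infer_cerna_network(sim$dataset, sim$priors, nm, ncrna_class = "ncrna",
                            alpha = 0.01)
  e2 <- infer_cerna_network(sim$dataset, sim$priors, nm, ncrna_class = "ncrna",
                            alpha = 0.05)
  expect_true(all(edge_keys(e1) %in% edge_keys(e2)))

  e2b <- infer_cerna_network(sim$dataset, sim$priors, nm,
                             ncrna_class = "ncrna", alpha = 0.05)
  expect_identical(as.data.frame(e2), as.data.frame(e2b))

  # alpha = 1: the threshold degenerates — every candidate with defined
  # statistics strictly inside the unit interval passes (the add-one
  # empirical p-value can sit exactly at 1, which no alpha < p admits)
  e3 <- infer_cerna_network(sim$dataset, sim$priors, nm, ncrna_class = "ncrna",
                            alpha = 1.0)
  defined <- !is.na(e3$p_sensitive) & e3$cor > 0 &
    e3$p_overlap < 1 & e3$p_cor < 1 & e3$p_sensitive < 1
  expect_true(any(defined))
  expect_true(all(e3$passed[defined]))
})

test_that("independent expression fails the positive-correlation criterion", {
  nm <- small_null_model()
  fails <- vapply(1:20, function(s) {
    nd <- null_dataset(sim_config(seed = 7000 + s))
    e <- infer_cerna_network(nd$dataset, nd$priors, nm, ncrna_class = "ncrna")
    mean(!(e$cor > 0 & e$p_cor < 0.05))
  }, numeric(1))
  expect_gte(mean(fails), 0.9)
})
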