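#' Simulation configuration
#'
#' Parameters of the synthetic generator. The defaults define the reference
#' scenario used throughout the package's tests: 50 miRNAs, 60 ncRNAs, 300
#' mRNAs, 200 matched samples, 4 synergy groups of 5 ncRNAs each sharing 10
#' target mRNAs, miRNA repression strength 0.8, unit noise, seed 42.
#'
#' @param n_mirna,n_ncrna,n_mrna,n_samples matrix dimensions.
#' @param n_synergy_groups,group_size number and size of planted synergy
#'   groups (`n_synergy_groups * group_size <= n_ncrna`).
#' @param shared_targets_per_group mRNAs jointly competed for by each group.
#' @param mirnas_per_group size of each group's miRNA pool (pools are
#'   disjoint; `n_synergy_groups * mirnas_per_group <= n_mirna`).
#' @param repression_strength coefficient of the (negative) miRNA effect on
#'   its targets' expression.
#' @param latent_sd standard deviation of the shared per-group competition
#'   factor loading on a group's ncRNAs and shared target mRNAs. Pure linear
#'   miRNA mediation leaves nearly no partial correlation after conditioning,
#'   so this factor is what makes planted sensitive correlations recoverable;
#'   0 disables it.
#' @param noise_sd standard deviation of per-gene noise.
#' @param background_mirnas_per_gene sparse random prior wiring for
#'   background (non-group) genes.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_mirna = 50L, n_ncrna = 60L, n_mrna = 300L,
                       n_samples = 200L, n_synergy_groups = 4L,
                       group_size = 5L, shared_targets_per_group = 10L,
                       mirnas_per_group = 5L, repression_strength = 0.8,
                       latent_sd = 1.0, noise_sd = 1.0,
                       background_mirnas_per_gene = 2L, seed = 42L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_ncrna = as.integer(n_ncrna),
              n_mrna = as.integer(n_mrna), n_samples = as.integer(n_samples),
              n_synergy_groups = as.integer(n_synergy_groups),
              group_size = as.integer(group_size),
              shared_targets_per_group = as.integer(shared_targets_per_group),
              mirnas_per_group = as.integer(mirnas_per_group),
              repression_strength = repression_strength,
              latent_sd = latent_sd, noise_sd = noise_sd,
              background_mirnas_per_gene = as.integer(background_mirnas_per_gene),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_mirna", "n_ncrna", "n_mrna", "n_samples")])
  if (any(counts <= 0L)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_synergy_groups * cfg$group_size > cfg$n_ncrna)
    stop("synergy groups need more ncRNAs than available", call. = FALSE)
  if (cfg$n_synergy_groups * cfg$shared_targets_per_group > cfg$n_mrna)
    stop("more shared targets than mRNAs available", call. = FALSE)
  if (cfg$n_synergy_groups * cfg$mirnas_per_group > cfg$n_mirna)
    stop("more group miRNAs than miRNAs available", call. = FALSE)
  if (cfg$repression_strength < 0 || cfg$noise_sd <= 0 || cfg$latent_sd < 0)
    stop("invalid strength/noise parameters", call. = FALSE)
  structure(cfg, class = "sim_config")
}

sim_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Simulate a matched dataset with planted competition structure
#'
#' Generative model: (1) miRNA expression is independent standard normal;
#' (2) each synergy group owns a disjoint pool of miRNAs and a disjoint set
#' of shared target mRNAs, all wired into the priors (every group ncRNA and
#' every shared mRNA is targeted by the whole pool); (3) expression of a
#' group gene is `-repression_strength * mean(pool miRNAs) + group factor +
#' noise`, with the latent group factor shared between the group's ncRNAs
#' and their shared target mRNAs — the joint competition signal; (4)
#' background genes receive sparse random priors and independent noise
#' expression. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a matched dataset with classes `mirna`,
#'   `ncrna`, `mrna`), `priors` (prior tables for `ncrna` and `mrna`) and
#'   `truth` (planted `cerna` and `synergy` edge data.frames plus the group
#'   assignments).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  simulate_impl(config, planted = TRUE)
}

#' Null dataset: identical wiring, no competition structure
#'
#' Same dimensions and prior wiring as [simulate_dataset()], but every ncRNA
#' and mRNA is independent noise (no miRNA repression, no group factor), so
#' any inferred edge is a false positive. Used for type-I-error calibration.
#'
#' @inheritParams simulate_dataset
#' @return as [simulate_dataset()]; `truth` edges are retained as the
#'   (unexpressed) wiring for reference.
#' @export
null_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  simulate_impl(config, planted = FALSE)
}

simulate_impl <- function(cfg, planted) {
  with_seed(cfg$seed, {
    s <- cfg$n_samples
    mir_ids <- sim_ids("mir", cfg$n_mirna)
    nc_ids <- sim_ids("nc", cfg$n_ncrna)
    m_ids <- sim_ids("mrna", cfg$n_mrna)
    samples <- sim_ids("s", s)

    mir <- matrix(rnorm(cfg$n_mirna * s), nrow = cfg$n_mirna,
                  dimnames = list(mir_ids, samples))

    ng <- cfg$n_synergy_groups
    groups <- lapply(seq_len(ng), function(g) {
      idx <- function(k) seq.int((g - 1L) * k + 1L, g * k)
      list(ncrna = nc_ids[idx(cfg$group_size)],
           mirna_pool = mir_ids[idx(cfg$mirnas_per_group)],
           shared_mrna = m_ids[idx(cfg$shared_targets_per_group)])
    })
    group_nc <- unlist(lapply(groups, `[[`, "ncrna"))
    group_m <- unlist(lapply(groups, `[[`, "shared_mrna"))

    nc <- matrix(rnorm(cfg$n_ncrna * s, sd = cfg$noise_sd),
                 nrow = cfg$n_ncrna, dimnames = list(nc_ids, samples))
    mr <- matrix(rnorm(cfg$n_mrna * s, sd = cfg$noise_sd),
                 nrow = cfg$n_mrna, dimnames = list(m_ids, samples))

    # prior wiring is identical in planted and null data
    pri_nc <- list(); pri_m <- list()
    for (g in groups) {
      pri_nc[[length(pri_nc) + 1L]] <-
        expand.grid(mirna = g$mirna_pool, target = g$ncrna,
                    stringsAsFactors = FALSE)
      pri_m[[length(pri_m) + 1L]] <-
        expand.grid(mirna = g$mirna_pool, target = g$shared_mrna,
                    stringsAsFactors = FALSE)
    }
    # sparse background wiring (expression stays independent noise); drawn
    # before the planted signal so the wiring is identical for planted and
    # null datasets under the same seed
    bg_nc <- setdiff(nc_ids, group_nc)
    bg_m <- setdiff(m_ids, group_m)
    k <- cfg$background_mirnas_per_gene
    if (k > 0L) {
      for (id in bg_nc)
        pri_nc[[length(pri_nc) + 1L]] <-
          data.frame(mirna = sample(mir_ids, k), target = id,
                     stringsAsFactors = FALSE)
      for (id in bg_m)
        pri_m[[length(pri_m) + 1L]] <-
          data.frame(mirna = sample(mir_ids, k), target = id,
                     stringsAsFactors = FALSE)
    }
    if (planted) {
      for (g in groups) {
        pool_mean <- colMeans(mir[g$mirna_pool, , drop = FALSE])
        f <- rnorm(s, sd = cfg$latent_sd)
        signal <- -cfg$repression_strength * pool_mean + f
        for (id in g$ncrna) nc[id, ] <- nc[id, ] + signal
        for (id in g$shared_mrna) mr[id, ] <- mr[id, ] + signal
      }
    }
    pri_nc <- do.call(rbind, pri_nc)
    pri_m <- do.call(rbind, pri_m)

    truth_cerna <- do.call(rbind, lapply(groups, function(g)
      expand.grid(ncrna = g$ncrna, mrna = g$shared_mrna,
                  stringsAsFactors = FALSE)))
    truth_syn <- do.call(rbind, lapply(groups, function(g) {
      cmb <- combn(sort(g$ncrna), 2L)
      data.frame(ncrna_i = cmb[1L, ], ncrna_j = cmb[2L, ],
                 stringsAsFactors = FALSE)
    }))

    dataset <- align_samples(list(
      mirna = expression_matrix(mir, "mirna"),
      ncrna = expression_matrix(nc, "ncrna"),
      mrna = expression_matrix(mr, "mrna")), label = "synthetic")
    list(dataset = dataset,
         priors = list(ncrna = prior_table(pri_nc$mirna, pri_nc$target, "ncrna"),
                       mrna = prior_table(pri_m$mirna, pri_m$target, "mrna")),
         truth = list(cerna = truth_cerna, synergy = truth_syn,
                      groups = groups, planted = planted))
  })
}

#' Precision and recall of recovered edges against planted truth
#'
#' @param edges `"scom_edges"` table (passed edges are compared).
#' @param truth data.frame of planted pairs (two id columns).
#' @return list with `precision`, `recall`, `n_recovered`, `n_true`,
#'   `n_called`.
#' @export
recovery_metrics <- function(edges, truth) {
  called <- edge_keys(edges)
  true_keys <- unique(paste(pmin(truth[[1L]], truth[[2L]]),
                            pmax(truth[[1L]], truth[[2L]]), sep = "|"))
  hit <- intersect(called, true_keys)
  list(precision = if (length(called)) length(hit) / length(called) else NA_real_,
       recall = if (length(true_keys)) length(hit) / length(true_keys) else NA_real_,
       n_recovered = length(hit), n_true = length(true_keys),
       n_called = length(called))
}
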