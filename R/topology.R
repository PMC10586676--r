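#' Build an undirected simple network from an edge table
#'
#' @param edges an `"scom_edges"` data.frame (only `passed` rows are used
#'   unless `passed_only = FALSE`), or any data.frame whose first two columns
#'   are endpoint ids.
#' @param passed_only use only edges with `passed == TRUE` when the column is
#'   present (default `TRUE`).
#' @return an [igraph::graph] (undirected, simplified).
#' @export
as_network <- function(edges, passed_only = TRUE) {
  stopifnot(is.data.frame(edges))
  if (passed_only && "passed" %in% names(edges))
    edges <- edges[edges$passed, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, 1:2, drop = FALSE],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Asymptotic Kolmogorov survival function with the standard small-sample
# correction, as the classical igraph power-law fit reported it.
kolmogorov_p <- function(D, n) {
  if (!is.finite(D) || n < 2L) return(NA_real_)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Discrete power-law fit of the degree distribution
#'
#' Fits a discrete power law to the node degrees by maximum likelihood with
#' `xmin` chosen to minimise the Kolmogorov-Smirnov distance
#' (Clauset-Shalizi-Newman, via [igraph::fit_power_law()]), and reports the
#' KS goodness-of-fit p-value. `p >= 0.05` is read as "degree distribution
#' consistent with a power law" (scale-free). The default p-value is the
#' analytic Kolmogorov tail of the KS statistic on the `degree >= xmin` tail;
#' `p_method = "bootstrap"` instead runs a semi-parametric goodness-of-fit
#' bootstrap (data below `xmin` resampled, tail regenerated from the fit,
#' refit per resample).
#'
#' @param net an igraph network (or `"scom_edges"` table, converted).
#' @param xmin optional fixed lower cut-off; `NULL` (default) selects it by
#'   KS minimisation.
#' @param p_method `"analytic"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 100).
#' @param seed seed for the bootstrap.
#' @return list with `exponent`, `xmin`, `ks_statistic`, `p_value`,
#'   `n_tail` (nodes with degree >= xmin). Degenerate degree distributions
#'   (all degrees equal) give `NA` statistics.
#' @export
powerlaw_test <- function(net, xmin = NULL, p_method = c("analytic", "bootstrap"),
                          n_boot = 100L, seed = 1L) {
  p_method <- match.arg(p_method)
  if (is.data.frame(net)) net <- as_network(net)
  deg <- igraph::degree(net)
  deg <- deg[deg >= 1]
  if (length(deg) < 10L)
    stop("need at least 10 nodes with degree >= 1", call. = FALSE)
  if (max(deg) == min(deg))
    return(list(exponent = NA_real_, xmin = NA_real_, ks_statistic = NA_real_,
                p_value = NA_real_, n_tail = length(deg)))
  fit <- igraph::fit_power_law(deg, xmin = xmin, implementation = "plfit")
  n_tail <- sum(deg >= fit$xmin)
  p <- if (p_method == "analytic") {
    kolmogorov_p(fit$KS.stat, n_tail)
  } else {
    powerlaw_bootstrap_p(deg, fit, n_boot, seed)
  }
  list(exponent = fit$alpha, xmin = fit$xmin, ks_statistic = fit$KS.stat,
       p_value = p, n_tail = n_tail)
}

# Semi-parametric goodness-of-fit bootstrap: each resample draws degrees
# below xmin from the empirical body and tail degrees from the fitted
# discrete power law, refits with free xmin, and compares KS statistics.
powerlaw_bootstrap_p <- function(deg, fit, n_boot, seed) {
  n <- length(deg)
  body <- deg[deg < fit$xmin]
  p_tail <- 1 - length(body) / n
  # discrete power-law sampler via inverse CDF on a truncated support
  kmax <- max(deg) * 10L
  ks <- seq.int(fit$xmin, kmax)
  w <- ks^(-fit$alpha)
  cdf <- cumsum(w) / sum(w)
  with_seed(seed, {
    stats_boot <- vapply(seq_len(n_boot), function(b) {
      from_tail <- runif(n) < p_tail
      d <- integer(n)
      n_tail <- sum(from_tail)
      if (length(body)) d[!from_tail] <- sample(body, n - n_tail, replace = TRUE)
      else from_tail[] <- TRUE
      d[from_tail] <- ks[findInterval(runif(sum(from_tail)), cdf) + 1L]
      f <- igraph::fit_power_law(d[d >= 1], implementation = "plfit")
      f$KS.stat
    }, numeric(1L))
    mean(stats_boot >= fit$KS.stat)
  })
}

#' Ensemble of uniform random graphs
#'
#' `count` Erdos-Renyi G(n, m) graphs, each with exactly `n_nodes` nodes and
#' `n_edges` edges, for null comparisons of path length and density.
#'
#' @param n_nodes,n_edges graph size; `n_edges <= choose(n_nodes, 2)`.
#' @param count ensemble size (default 100).
#' @param seed integer seed; the ensemble is reproducible.
#' @return list of igraph graphs.
#' @export
random_ensemble <- function(n_nodes, n_edges, count = 100L, seed = 1L) {
  if (n_edges > choose(n_nodes, 2))
    stop("n_edges exceeds the maximum for a simple graph on n_nodes nodes",
         call. = FALSE)
  with_seed(seed, lapply(seq_len(count), function(i)
    igraph::sample_gnm(n_nodes, n_edges)))
}

#' Characteristic path length and density
#'
#' Path length is the mean shortest-path distance over connected (reachable)
#' node pairs only — the usual igraph convention, needed because inferred
#' networks are typically disconnected. Density is `|E| / choose(|V|, 2)`.
#'
#' @param net an igraph network.
#' @return a number.
#' @export
char_path_length <- function(net) {
  igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
}

#' @rdname char_path_length
#' @export
graph_density <- function(net) {
  igraph::edge_density(net, loops = FALSE)
}

#' Small-world tests against a random-graph ensemble
#'
#' One-sample, one-sided Student's t-tests of the ensemble statistics against
#' the observed network: is the observed characteristic path length smaller
#' than the random mean, and the observed density higher? Small p-values on
#' either support a small-world reading.
#'
#' Note that an exactly size-matched G(n, m) ensemble has the same density as
#' the observed network in every member (density is determined by n and m):
#' the density test is then degenerate and reported `NA`. Supplying an
#' ensemble drawn over a larger candidate-node universe (same edge count,
#' more nodes) makes the density comparison informative.
#'
#' @param net the observed igraph network.
#' @param ensemble list of igraph graphs (e.g. [random_ensemble()]).
#' @return list with `path_length`, `density`, `random_path_lengths`,
#'   `random_densities`, `path_p`, `density_p` (`NA` when the ensemble
#'   statistic has zero variance).
#' @export
small_world_tests <- function(net, ensemble) {
  if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  obs_path <- char_path_length(net)
  obs_dens <- graph_density(net)
  r_path <- vapply(ensemble, char_path_length, numeric(1L))
  r_dens <- vapply(ensemble, graph_density, numeric(1L))
  one_sided <- function(xs, mu, alternative) {
    if (length(unique(xs)) < 2L) return(NA_real_)
    t.test(xs, mu = mu, alternative = alternative)$p.value
  }
  # H1 for path: random mean > observed  (observed shorter)
  # H1 for density: random mean < observed (observed denser)
  list(path_length = obs_path, density = obs_dens,
       random_path_lengths = r_path, random_densities = r_dens,
       path_p = one_sided(r_path, obs_path, "greater"),
       density_p = one_sided(r_dens, obs_dens, "less"))
}

#' Full topology report for an inferred network
#'
#' Combines the power-law degree diagnostic with the small-world comparisons
#' against `n_random` G(n, m) random graphs. With `universe_nodes` set (the
#' number of candidate nodes the inference could have connected), the density
#' ensemble is drawn as G(universe_nodes, m) so that the density comparison
#' is non-degenerate; otherwise the strictly size-matched ensemble is used
#' for both statistics and the density test is degenerate by construction.
#'
#' @param net igraph network or `"scom_edges"` table.
#' @param n_random ensemble size (default 100).
#' @param seed integer seed.
#' @param density_null `"gnp"` (default) or `"strict"`. A strictly
#'   size-matched G(n, m) null fixes the density at `m / C(n,2)` in every
#'   member, so the density comparison is exactly degenerate and reported
#'   `NA`; the `"gnp"` null instead draws Bernoulli random graphs
#'   G(n_null, p) with `p` set to the edge density a graph with the observed
#'   edge count would have on `n_null` nodes, giving the density a sampling
#'   distribution.
#' @param universe_nodes optional candidate-universe size `n* >= n` for the
#'   density null: with it the density ensemble is drawn over all `n*`
#'   candidate nodes (isolated candidates allowed), asking whether the
#'   inferred network is denser than a random graph spending the same number
#'   of edges across the whole candidate pool.
#' @return list of class `"topology_report"`.
#' @export
topology_report <- function(net, n_random = 100L, seed = 1L,
                            density_null = c("gnp", "strict"),
                            universe_nodes = NULL) {
  density_null <- match.arg(density_null)
  if (is.data.frame(net)) net <- as_network(net)
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  pl <- tryCatch(powerlaw_test(net), error = function(e)
    list(exponent = NA_real_, xmin = NA_real_, ks_statistic = NA_real_,
         p_value = NA_real_, n_tail = NA_integer_))
  ens <- random_ensemble(n, m, count = n_random, seed = seed)
  sw <- small_world_tests(net, ens)
  if (density_null == "gnp") {
    n_null <- universe_nodes %||% n
    if (n_null < n)
      stop("'universe_nodes' must be >= the number of network nodes",
           call. = FALSE)
    p_null <- m / choose(n_null, 2)
    dens_ens <- with_seed(seed + 1L, lapply(seq_len(n_random), function(i)
      igraph::sample_gnp(n_null, p_null)))
    r_dens <- vapply(dens_ens, graph_density, numeric(1L))
    sw$random_densities <- r_dens
    sw$density_p <- if (length(unique(r_dens)) < 2L) NA_real_ else
      t.test(r_dens, mu = sw$density, alternative = "less")$p.value
  }
  structure(list(
    n_nodes = n, n_edges = m,
    powerlaw_exponent = pl$exponent, xmin = pl$xmin,
    ks_statistic = pl$ks_statistic, ks_pvalue = pl$p_value,
    char_path_length = sw$path_length, density = sw$density,
    random_path_lengths = sw$random_path_lengths,
    random_densities = sw$random_densities,
    path_test_pvalue = sw$path_p, density_test_pvalue = sw$density_p),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology report:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat(sprintf("  power law: exponent %.3f (xmin %s), KS %.4f, p = %s\n",
              x$powerlaw_exponent, format(x$xmin),
              x$ks_statistic, format.pval(x$ks_pvalue, digits = 3)))
  cat(sprintf("  char path length %.4f (random mean %.4f), p = %s\n",
              x$char_path_length, mean(x$random_path_lengths),
              format.pval(x$path_test_pvalue, digits = 3)))
  cat(sprintf("  density %.5f (random mean %.5f), p = %s\n",
              x$density, mean(x$random_densities),
              format.pval(x$density_test_pvalue, digits = 3)))
  invisible(x)
}
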