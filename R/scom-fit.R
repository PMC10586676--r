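#' Fit ceRNA and synergistic-competition networks
#'
#' The central estimator: from a matched expression dataset and miRNA-target
#' priors it (1) screens candidate ncRNA-mRNA pairs per ncRNA class with the
#' three competition criteria to obtain the ceRNA network(s), then (2) tests
#' every ncRNA pair jointly competing for mRNAs to obtain the
#' synergistic-competition network. Both stages share one empirical null
#' model for the sensitive-correlation criterion, built here (for the
#' dataset's sample count) unless supplied.
#'
#' @param dataset a matched dataset from [align_samples()] or
#'   [simulate_dataset()]; must contain `mirna`, `mrna` and at least one
#'   ncRNA class.
#' @param priors named list of [prior_table()]s covering `mrna` and each
#'   ncRNA class.
#' @param alpha per-criterion significance level (default 0.05).
#' @param null_model optional [build_null_model()]; built with `seed` and
#'   `null_draws` when `NULL`.
#' @param classes ncRNA classes to use (default: every dataset class other
#'   than `mirna`/`mrna` that has a prior table).
#' @param seed integer seed (used only for the null model).
#' @param null_draws draws per null-model cell (default 1000).
#' @param min_shared minimum shared miRNAs for a candidate ceRNA pair.
#' @param mirna_universe `"prior"` or `"all"` — miRNA universe of criterion 1
#'   in the ceRNA stage (see [candidate_cerna_pairs()]).
#' @param mrna_universe `"dataset"` or `"network"` — mRNA universe of
#'   criterion 1 in the synergy stage (see [infer_synergy_network()]).
#' @param adjust `"none"` (default) or `"BH"` multiple-testing handling.
#' @return object of class `"scom"`: list with `cerna` (named list of edge
#'   tables per ncRNA class), `synergy` (edge table), `null_model`, `alpha`,
#'   `classes`, `condition`, `call`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 60, seed = 7))
#' nm <- build_null_model(60, m_bins = c(2, 5, 10), draws_per_cell = 100,
#'                        seed = 7)
#' fit <- scom(sim$dataset, sim$priors, null_model = nm)
#' fit
#' @export
scom <- function(dataset, priors, alpha = 0.05, null_model = NULL,
                 classes = NULL, seed = 1L, null_draws = 1000L,
                 min_shared = 1L, mirna_universe = c("prior", "all"),
                 mrna_universe = c("dataset", "network"),
                 adjust = c("none", "BH")) {
  mirna_universe <- match.arg(mirna_universe)
  mrna_universe <- match.arg(mrna_universe)
  adjust <- match.arg(adjust)
  stopifnot(inherits(dataset, "matched_dataset"))
  classes <- classes %||%
    intersect(setdiff(names(dataset), c("mirna", "mrna")), names(priors))
  if (length(classes) == 0L)
    stop("no ncRNA class with both expression and priors", call. = FALSE)
  s <- ncol(dataset$mirna)
  if (is.null(null_model))
    null_model <- build_null_model(s, draws_per_cell = null_draws, seed = seed)

  cerna <- lapply(classes, function(cl)
    infer_cerna_network(dataset, priors, null_model, ncrna_class = cl,
                        alpha = alpha, min_shared = min_shared,
                        universe = mirna_universe, adjust = adjust))
  names(cerna) <- classes

  any_passed <- any(vapply(cerna, function(e) any(e$passed), logical(1L)))
  synergy <- if (any_passed) {
    infer_synergy_network(dataset, cerna, null_model, alpha = alpha,
                          universe = mrna_universe, adjust = adjust)
  } else {
    build_edge_frame(character(0L), character(0L), integer(0L), 0L,
                     numeric(0L), numeric(0L), numeric(0L), numeric(0L),
                     numeric(0L), alpha, "none", kind = "synergy",
                     condition = attr(dataset, "condition"))
  }
  structure(list(cerna = cerna, synergy = synergy, null_model = null_model,
                 alpha = alpha, classes = classes,
                 condition = attr(dataset, "condition"),
                 n_samples = s, call = match.call()),
            class = "scom")
}

#' @export
print.scom <- function(x, ...) {
  cat("Synergistic-competition fit (", x$condition, "), s = ", x$n_samples,
      " samples, alpha = ", x$alpha, "\n", sep = "")
  for (cl in x$classes) {
    e <- x$cerna[[cl]]
    cat(sprintf("  ceRNA [%s]: %d/%d candidate pairs passed\n",
                cl, sum(e$passed), nrow(e)))
  }
  cat(sprintf("  synergy: %d/%d tested ncRNA pairs passed\n",
              sum(x$synergy$passed), nrow(x$synergy)))
  invisible(x)
}

#' @export
summary.scom <- function(object, ...) {
  funnel <- function(e) {
    c(tested = nrow(e),
      pass_overlap = sum(e$p_overlap < attr(e, "alpha"), na.rm = TRUE),
      pass_cor = sum(e$cor > 0 & e$p_cor < attr(e, "alpha"), na.rm = TRUE),
      pass_sensitivity = sum(e$p_sensitive < attr(e, "alpha"), na.rm = TRUE),
      degenerate = sum(is.na(e$p_sensitive)),
      passed = sum(e$passed))
  }
  syn_net <- if (any(object$synergy$passed)) as_network(object$synergy) else NULL
  structure(list(
    condition = object$condition, alpha = object$alpha,
    n_samples = object$n_samples,
    cerna_funnel = lapply(object$cerna, funnel),
    synergy_funnel = funnel(object$synergy),
    synergy_nodes = if (is.null(syn_net)) 0L else igraph::vcount(syn_net),
    synergy_degree = if (is.null(syn_net)) NULL else
      summary(igraph::degree(syn_net))),
    class = "summary.scom")
}

#' @export
print.summary.scom <- function(x, ...) {
  cat("Criterion funnel (tested -> sharing -> positive correlation -> sensitivity):\n")
  show <- function(label, f)
    cat(sprintf("  %-18s %5d -> %5d -> %5d -> %5d passed (%d degenerate)\n",
                label, f["tested"], f["pass_overlap"], f["pass_cor"],
                f["passed"], f["degenerate"]))
  for (cl in names(x$cerna_funnel)) show(paste0("ceRNA [", cl, "]"),
                                         x$cerna_funnel[[cl]])
  show("synergy", x$synergy_funnel)
  if (x$synergy_nodes > 0L) {
    cat("Synergy network:", x$synergy_nodes, "ncRNAs; degree summary:\n")
    print(x$synergy_degree)
  }
  invisible(x)
}

#' @export
#' @importFrom graphics plot axis legend
plot.scom <- function(x, which = c("synergy", "cerna"), ...) {
  which <- match.arg(which)
  edges <- if (which == "synergy") x$synergy else do.call(rbind, x$cerna)
  if (!any(edges$passed)) {
    warning("no passed edges to plot")
    return(invisible(x))
  }
  deg <- igraph::degree(as_network(edges))
  tab <- table(deg)
  plot(as.integer(names(tab)), as.integer(tab), log = "xy",
       xlab = "degree", ylab = "number of nodes",
       main = paste(which, "network degree distribution"), pch = 19, ...)
  invisible(x)
}
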