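#' Competing-mRNA sets of each ncRNA
#'
#' From the passed edges of a ceRNA network, the set of mRNAs each ncRNA
#' competes for — the source of the set sizes and intersections in the
#' synergy sharing test.
#'
#' @param cerna_edges edge data.frame(s) from [infer_cerna_network()]; a list
#'   of edge tables (e.g. one per ncRNA class) is merged.
#' @return named list: ncRNA id -> character vector of competing mRNA ids.
#' @export
competed_mrna_sets <- function(cerna_edges) {
  if (is.data.frame(cerna_edges)) cerna_edges <- list(cerna_edges)
  src <- unlist(lapply(cerna_edges, function(e) e$source[e$passed]))
  tgt <- unlist(lapply(cerna_edges, function(e) e$target[e$passed]))
  if (length(src) == 0L) return(setNames(list(), character(0L)))
  lapply(split(tgt, src), function(v) sort(unique(v)))
}

#' Infer an ncRNA synergistic-competition network
#'
#' Tests every unordered pair of ncRNAs in the ceRNA network that jointly
#' competes for at least one mRNA, with the three criteria: (1) significant
#' overlap of their competing-mRNA sets (hypergeometric over all mRNAs in the
#' dataset), (2) significantly positive Pearson correlation of the two
#' ncRNAs, and (3) significantly positive sensitive correlation conditioning
#' on the jointly competed mRNAs' expression, judged against the empirical
#' null model. Pairs are formed within and across ncRNA classes.
#'
#' @param dataset matched dataset providing expression for `mrna` and every
#'   ncRNA class appearing in the ceRNA network.
#' @param cerna_edges passed/tested edges from [infer_cerna_network()], or a
#'   list of such tables to merge.
#' @param null_model a [build_null_model()] for this dataset's sample count.
#' @param alpha per-criterion significance level.
#' @param universe `"dataset"` (default; all mRNAs in the expression matrix)
#'   or `"network"` (only mRNAs appearing in the ceRNA network).
#' @param adjust `"none"` or `"BH"`.
#' @return `"scom_edges"` data.frame (columns as in
#'   [infer_cerna_network()]); `source < target` lexicographically.
#' @export
infer_synergy_network <- function(dataset, cerna_edges, null_model,
                                  alpha = 0.05,
                                  universe = c("dataset", "network"),
                                  adjust = c("none", "BH")) {
  universe <- match.arg(universe)
  adjust <- match.arg(adjust)
  stopifnot(inherits(null_model, "scom_null_model"))
  sets <- competed_mrna_sets(cerna_edges)
  if (length(sets) == 0L)
    stop("empty ceRNA network: no ncRNA has passed competition edges",
         call. = FALSE)
  N <- if (universe == "dataset") nrow(dataset$mrna)
       else length(unique(unlist(sets)))

  # expression lookup across all non-miRNA, non-mRNA classes
  nc_classes <- setdiff(names(dataset), c("mirna", "mrna"))
  exp_nc <- do.call(rbind, lapply(nc_classes, function(cl)
    unclass(dataset[[cl]])[rownames(dataset[[cl]]) %in% names(sets), ,
                           drop = FALSE]))
  missing_expr <- setdiff(names(sets), rownames(exp_nc))
  if (length(missing_expr))
    stop("no expression for ncRNA(s): ",
         paste(utils::head(missing_expr, 5L), collapse = ", "), call. = FALSE)
  exp_m <- dataset$mrna

  ids <- sort(names(sets))
  res_s <- res_t <- character(0L)
  res_L <- integer(0L)
  res <- matrix(numeric(0L), ncol = 5L)
  shared_sets <- list()
  if (length(ids) >= 2L) {
    cmb <- combn(ids, 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      joint <- intersect(sets[[i]], sets[[j]])
      if (length(joint) == 0L) next
      res_s <- c(res_s, i); res_t <- c(res_t, j)
      res_L <- c(res_L, length(joint))
      shared_sets[[length(res_s)]] <- joint
    }
  }
  n <- length(res_s)
  p_overlap <- cor_v <- p_cor <- sc_v <- p_sc <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- res_s[k]; j <- res_t[k]
    ov <- overlap_pvalue(N, length(sets[[i]]), length(sets[[j]]), res_L[k])
    p_overlap[k] <- ov$p_value
    x <- exp_nc[i, ]; y <- exp_nc[j, ]
    ct <- pearson_test(x, y)
    cor_v[k] <- ct$cor; p_cor[k] <- ct$p_value
    z <- t(exp_m[shared_sets[[k]], , drop = FALSE])
    sens <- sensitivity(x, y, z)
    sc_v[k] <- sens$sc
    if (!sens$degenerate)
      p_sc[k] <- null_pvalue(sens$sc, sens$conditioning_size, sens$cor,
                             null_model)
  }
  build_edge_frame(res_s, res_t, res_L, N, p_overlap, cor_v, p_cor, sc_v,
                   p_sc, alpha, adjust,
                   kind = "synergy", condition = attr(dataset, "condition"))
}

#' @export
print.scom_edges <- function(x, ...) {
  kind <- switch(attr(x, "kind") %||% "edges",
                 cerna = "ceRNA", synergy = "synergistic-competition",
                 attr(x, "kind"))
  cat(kind, " edge table: ", nrow(x), " tested pairs, ",
      sum(x$passed), " passed (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
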