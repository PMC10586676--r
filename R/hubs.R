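#' Hub calling under a Poisson degree model
#'
#' Models node degree as Poisson with rate `lambda = n p`, where
#' `p = m / C(n, 2)` is the edge probability of a uniform random graph with
#' the network's `n` nodes and `m` edges, so `lambda = 2 m / (n - 1)` equals
#' the mean degree. A node of degree `k` gets the upper-tail p-value
#' `P(X >= k) = 1 - sum_{i=0}^{k-1} lambda^i e^-lambda / i!`; hubs are nodes
#' with `p < alpha`. `pair_count = "arrangement"` instead counts ordered
#' pairs `n (n - 1)`, halving `lambda`.
#'
#' @param net igraph network or `"scom_edges"` table.
#' @param alpha hub significance cut-off (default 0.05).
#' @param pair_count `"unordered"` (default, `C(n,2)` possible edges) or
#'   `"arrangement"` (`n(n-1)`).
#' @param n_nodes optional override for `n` (e.g. all candidate ncRNAs rather
#'   than network nodes).
#' @return data.frame of class `"hub_table"`: `id`, `degree`, `lambda`,
#'   `p_value`, `is_hub`, sorted by increasing p-value.
#' @export
hub_pvalues <- function(net, alpha = 0.05,
                        pair_count = c("unordered", "arrangement"),
                        n_nodes = NULL) {
  pair_count <- match.arg(pair_count)
  if (is.data.frame(net)) net <- as_network(net)
  deg <- igraph::degree(net)
  n <- n_nodes %||% igraph::vcount(net)
  m <- igraph::ecount(net)
  if (n < 2L || m < 1L)
    stop("need a network with >= 2 nodes and >= 1 edge", call. = FALSE)
  pairs <- if (pair_count == "unordered") choose(n, 2) else n * (n - 1)
  lambda <- n * (m / pairs)
  p <- ppois(deg - 1, lambda, lower.tail = FALSE)
  ids <- names(deg) %||% as.character(seq_along(deg))
  out <- data.frame(id = ids, degree = as.integer(deg),
                    lambda = lambda, p_value = p, is_hub = p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("hub_table", "data.frame"))
}

#' Overlap-coefficient similarity
#'
#' `|A intersect B| / min(|A|, |B|)` between two sets — edge sets (as
#' canonical unordered-pair keys) or hub id sets. Equals 1 when one set
#' contains the other; always at least the Jaccard index.
#'
#' @param set_a,set_b character vectors (treated as sets); both non-empty.
#' @return similarity in `[0, 1]`, or `NA` if either set is empty.
#' @export
overlap_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Canonical unordered edge keys
#'
#' Collapses each edge to `"min|max"` of its endpoints so that edge sets from
#' different conditions are comparable regardless of orientation.
#'
#' @param edges `"scom_edges"` data.frame; only passed edges are used when
#'   the `passed` column is present.
#' @return character vector of unique keys.
#' @export
edge_keys <- function(edges) {
  if ("passed" %in% names(edges)) edges <- edges[edges$passed, , drop = FALSE]
  if (nrow(edges) == 0L) return(character(0L))
  unique(paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), sep = "|"))
}

#' Pairwise similarity matrix across conditions
#'
#' @param collections named list (one element per condition) of character
#'   sets — edge keys or hub ids.
#' @return symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(collections) {
  if (length(collections) < 2L) stop("need >= 2 conditions", call. = FALSE)
  nms <- names(collections)
  k <- length(collections)
  out <- matrix(1, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    out[i, j] <- out[j, i] <-
      overlap_similarity(collections[[i]], collections[[j]])
  }
  out
}

#' Conserved versus rewired items across conditions
#'
#' An edge or hub present in at least two conditions is conserved; one
#' present in exactly one condition is rewired. The two labels partition all
#' observed items.
#'
#' @param collections named list (one element per condition) of character
#'   sets.
#' @return data.frame `item`, `n_conditions`, `conditions`
#'   (comma-separated), `status`; attribute `rewired_pct` gives, per
#'   condition, the percentage of its items that are rewired.
#' @export
conserved_rewired <- function(collections) {
  if (length(collections) < 2L) stop("need >= 2 conditions", call. = FALSE)
  collections <- lapply(collections, unique)
  long <- data.frame(
    item = unlist(collections, use.names = FALSE),
    condition = rep(names(collections), lengths(collections)),
    stringsAsFactors = FALSE)
  by_item <- split(long$condition, long$item)
  out <- data.frame(
    item = names(by_item),
    n_conditions = lengths(by_item),
    conditions = vapply(by_item, function(v) paste(sort(v), collapse = ","),
                        character(1L)),
    stringsAsFactors = FALSE)
  out$status <- ifelse(out$n_conditions >= 2L, "conserved", "rewired")
  rewired_items <- out$item[out$status == "rewired"]
  rewired_pct <- vapply(collections, function(s)
    if (length(s)) 100 * mean(s %in% rewired_items) else NA_real_,
    numeric(1L))
  rownames(out) <- NULL
  structure(out, rewired_pct = rewired_pct,
            class = c("conservation_report", "data.frame"))
}
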