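#' Candidate ceRNA pairs from miRNA-target priors
#'
#' Enumerates all ncRNA-mRNA pairs that share at least `min_shared` putative
#' miRNA regulators, restricting prior pairs to genes present in the
#' expression matrices (the miRNA itself must be expressed). The hypergeometric
#' universe for the sharing test is, by default, the set of miRNAs that are
#' both expressed and appear in at least one retained prior pair — the pool
#' from which sharing could actually occur; `universe = "all"` uses every
#' expressed miRNA instead.
#'
#' @param dataset a [align_samples()] matched dataset containing `mirna`,
#'   `mrna` and the requested ncRNA class.
#' @param priors list with elements named after target classes (e.g.
#'   `lncrna`, `mrna`), each a [prior_table()].
#' @param ncrna_class which ncRNA class to pair against mRNAs.
#' @param min_shared minimum number of shared miRNAs (default 1).
#' @param universe `"prior"` (default) or `"all"` — see above.
#' @return list with `pairs` (data.frame `ncrna`, `mrna`, `n_shared`),
#'   `shared` (list of shared-miRNA id vectors, parallel to `pairs` rows),
#'   `mirna_sets` (per-gene miRNA regulator sets) and `universe_size`.
#' @export
candidate_cerna_pairs <- function(dataset, priors, ncrna_class = "lncrna",
                                  min_shared = 1L,
                                  universe = c("prior", "all")) {
  universe <- match.arg(universe)
  stopifnot(inherits(dataset, "matched_dataset"))
  for (need in c("mirna", "mrna", ncrna_class))
    if (is.null(dataset[[need]]))
      stop("dataset lacks an expression matrix for class '", need, "'",
           call. = FALSE)
  pri_nc <- priors[[ncrna_class]]
  pri_m <- priors[["mrna"]]
  if (is.null(pri_nc) || is.null(pri_m))
    stop("priors must cover both '", ncrna_class, "' and 'mrna'", call. = FALSE)

  mirnas <- rownames(dataset$mirna)
  nc_ids <- rownames(dataset[[ncrna_class]])
  m_ids <- rownames(dataset$mrna)

  pri_nc <- pri_nc[pri_nc$mirna %in% mirnas & pri_nc$target %in% nc_ids, ]
  pri_m <- pri_m[pri_m$mirna %in% mirnas & pri_m$target %in% m_ids, ]
  if (nrow(pri_nc) == 0L || nrow(pri_m) == 0L)
    stop("no overlap between prior ids and expression ids", call. = FALSE)

  sets_nc <- split(pri_nc$mirna, pri_nc$target)
  sets_m <- split(pri_m$mirna, pri_m$target)
  n_universe <- if (universe == "prior")
    length(unique(c(pri_nc$mirna, pri_m$mirna))) else length(mirnas)

  # invert: miRNA -> targets, then accumulate shared-miRNA lists per pair
  by_mirna_nc <- split(pri_nc$target, pri_nc$mirna)
  by_mirna_m <- split(pri_m$target, pri_m$mirna)
  common_mirnas <- intersect(names(by_mirna_nc), names(by_mirna_m))
  pair_env <- new.env(hash = TRUE, parent = emptyenv())
  for (mir in common_mirnas) {
    for (nc in by_mirna_nc[[mir]]) {
      for (mr in by_mirna_m[[mir]]) {
        key <- paste(nc, mr, sep = "\r")
        pair_env[[key]] <- c(pair_env[[key]], mir)
      }
    }
  }
  keys <- ls(pair_env)
  shared <- lapply(keys, function(k) sort(pair_env[[k]]))
  n_shared <- lengths(shared)
  keep <- n_shared >= min_shared
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  pairs <- data.frame(
    ncrna = vapply(parts, `[[`, character(1L), 1L),
    mrna = vapply(parts, `[[`, character(1L), 2L),
    n_shared = n_shared[keep],
    stringsAsFactors = FALSE)
  ord <- order(pairs$ncrna, pairs$mrna)
  list(pairs = pairs[ord, , drop = FALSE],
       shared = shared[keep][ord],
       mirna_sets = list(ncrna = sets_nc, mrna = sets_m),
       universe_size = n_universe)
}

#' Infer a ceRNA network
#'
#' Screens every candidate ncRNA-mRNA pair with the three competition
#' criteria: (1) significant sharing of miRNAs (hypergeometric upper tail
#' over the miRNA universe), (2) significantly positive Pearson correlation,
#' and (3) significantly positive sensitive correlation conditioning on the
#' shared miRNAs' expression, judged against the empirical null model. A pair
#' passes when all three p-values fall below `alpha` and the correlation is
#' positive. All tested pairs are returned with their statistics; the network
#' is the subset with `passed == TRUE`.
#'
#' Genes flagged as zero-variance are excluded from testing (their
#' correlations are undefined); affected pairs are dropped before testing.
#'
#' @inheritParams candidate_cerna_pairs
#' @param alpha per-criterion significance level (default 0.05, uncorrected;
#'   set `adjust = "BH"` for Benjamini-Hochberg within each criterion).
#' @param null_model a [build_null_model()] built for this dataset's sample
#'   count.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `"scom_edges"` with columns `source`
#'   (ncRNA), `target` (mRNA), `overlap_count`, `universe_size`, `p_overlap`,
#'   `cor`, `p_cor`, `sensitive_cor`, `p_sensitive`, `passed`.
#' @export
infer_cerna_network <- function(dataset, priors, null_model,
                                ncrna_class = "lncrna", alpha = 0.05,
                                min_shared = 1L,
                                universe = c("prior", "all"),
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- match.arg(universe)
  stopifnot(inherits(null_model, "scom_null_model"))
  if (null_model$sample_size != ncol(dataset$mirna))
    stop("null model was built for s = ", null_model$sample_size,
         " but the dataset has ", ncol(dataset$mirna), " samples", call. = FALSE)
  cand <- candidate_cerna_pairs(dataset, priors, ncrna_class = ncrna_class,
                                min_shared = min_shared, universe = universe)
  zv <- c(attr(dataset[[ncrna_class]], "zero_variance"),
          attr(dataset$mrna, "zero_variance"))
  keep <- !(cand$pairs$ncrna %in% zv | cand$pairs$mrna %in% zv)
  pairs <- cand$pairs[keep, , drop = FALSE]
  shared <- cand$shared[keep]

  sets_nc <- cand$mirna_sets$ncrna
  sets_m <- cand$mirna_sets$mrna
  N <- cand$universe_size
  exp_nc <- dataset[[ncrna_class]]
  exp_m <- dataset$mrna
  exp_mir <- dataset$mirna

  n <- nrow(pairs)
  p_overlap <- cor_v <- p_cor <- sc_v <- p_sc <- rep(NA_real_, n)
  L <- integer(n)
  for (i in seq_len(n)) {
    nc <- pairs$ncrna[i]; mr <- pairs$mrna[i]
    sh <- shared[[i]]
    L[i] <- length(sh)
    ov <- overlap_pvalue(N, length(sets_nc[[nc]]), length(sets_m[[mr]]), L[i])
    p_overlap[i] <- ov$p_value
    x <- exp_nc[nc, ]; y <- exp_m[mr, ]
    ct <- pearson_test(x, y)
    cor_v[i] <- ct$cor; p_cor[i] <- ct$p_value
    z <- t(exp_mir[sh, , drop = FALSE])
    sens <- sensitivity(x, y, z)
    sc_v[i] <- sens$sc
    if (!sens$degenerate)
      p_sc[i] <- null_pvalue(sens$sc, sens$conditioning_size, sens$cor,
                             null_model)
  }
  build_edge_frame(pairs$ncrna, pairs$mrna, L, N, p_overlap, cor_v, p_cor,
                   sc_v, p_sc, alpha, adjust,
                   kind = "cerna", condition = attr(dataset, "condition"))
}

# Shared assembly + pass rule for both inference steps.
build_edge_frame <- function(source, target, overlap, universe, p_overlap,
                             cor_v, p_cor, sc_v, p_sc, alpha, adjust,
                             kind, condition = NULL) {
  if (adjust == "BH") {
    p_overlap <- stats::p.adjust(p_overlap, "BH")
    p_cor <- stats::p.adjust(p_cor, "BH")
    ok <- !is.na(p_sc)
    p_sc[ok] <- stats::p.adjust(p_sc[ok], "BH")
  }
  passed <- !is.na(p_sc) &
    p_overlap < alpha &
    (cor_v > 0 & p_cor < alpha) &
    p_sc < alpha
  out <- data.frame(source = source, target = target,
                    overlap_count = as.integer(overlap),
                    universe_size = rep_len(as.integer(universe),
                                            length(source)),
                    p_overlap = p_overlap, cor = cor_v, p_cor = p_cor,
                    sensitive_cor = sc_v, p_sensitive = p_sc,
                    passed = passed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, kind = kind, alpha = alpha, condition = condition,
            class = c("scom_edges", "data.frame"))
}
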