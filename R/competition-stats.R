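#' Hypergeometric test for shared regulators
#'
#' Significance of the overlap between two target/regulator sets drawn from a
#' common universe. With `X ~ Hypergeometric(N, M, K)` the p-value is the
#' upper tail `P(X >= L) = 1 - sum_{x=0}^{L-1} C(M,x) C(N-M,K-x) / C(N,K)`,
#' computed exactly via [stats::phyper()] (log-space combinatorics). `L = 0`
#' gives p = 1.
#'
#' @param universe_size `N`, size of the common universe.
#' @param size_a `M`, size of the first set.
#' @param size_b `K`, size of the second set.
#' @param overlap `L`, observed intersection size.
#' @return list with the four counts and `p_value`.
#' @export
overlap_pvalue <- function(universe_size, size_a, size_b, overlap) {
  args <- c(universe_size, size_a, size_b, overlap)
  if (any(args != round(args)) || any(args < 0))
    stop("all arguments must be non-negative integers", call. = FALSE)
  if (size_a > universe_size || size_b > universe_size)
    stop("set sizes cannot exceed the universe size", call. = FALSE)
  if (overlap > min(size_a, size_b))
    stop("overlap cannot exceed the smaller set size", call. = FALSE)
  p <- phyper(overlap - 1, size_a, universe_size - size_a, size_b,
              lower.tail = FALSE)
  list(universe_size = as.integer(universe_size), size_a = as.integer(size_a),
       size_b = as.integer(size_b), overlap = as.integer(overlap),
       p_value = min(1, p))
}

#' Pearson correlation with two-sided significance
#'
#' The correlation `r` between two expression vectors and the two-sided
#' p-value `2 P(T_{s-2} >= |r sqrt(s-2) / sqrt(1 - r^2)|)` from the Student t
#' transform. A positivity requirement (`r > 0`) is applied by the network
#' inference separately, not here.
#'
#' @param x,y numeric vectors of equal length `s >= 5`, both non-constant.
#' @return list with `cor`, `p_value`, `n_samples`.
#' @export
pearson_test <- function(x, y) {
  s <- length(x)
  if (length(y) != s) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (s < 5L) stop("need at least 5 samples", call. = FALSE)
  if (max(x) - min(x) == 0 || max(y) - min(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  r <- min(1, max(-1, cor(x, y)))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(s - 2) / sqrt(1 - r^2)
    p <- min(1, 2 * pt(abs(tstat), df = s - 2, lower.tail = FALSE))
  }
  list(cor = r, p_value = p, n_samples = s)
}

# Drop conditioning columns that duplicate earlier columns (|cor| within
# 1e-10 of 1); the first-order recursion and the matrix inversion are both
# undefined under exact collinearity.
dedup_conditioners <- function(z, tol = 1e-10) {
  if (is.null(z) || ncol(z) <= 1L) return(z)
  keep <- rep(TRUE, ncol(z))
  cz <- suppressWarnings(cor(z))
  for (j in seq_len(ncol(z))[-1L]) {
    prev <- which(keep[seq_len(j - 1L)])
    if (any(abs(cz[j, prev]) >= 1 - tol, na.rm = TRUE)) keep[j] <- FALSE
  }
  z[, keep, drop = FALSE]
}

#' Partial correlation given a conditioning set
#'
#' Correlation between `x` and `y` with the linear effect of the columns of
#' `z` removed. The default computes it from the inverse of the
#' `(n+2) x (n+2)` correlation matrix of `(x, y, z)`; `method = "recursion"`
#' applies the classical first-order recursion
#' `cor(x,y|Z) = (cor(x,y|Z') - cor(x,Zn|Z') cor(y,Zn|Z')) /
#'  sqrt((1-cor(x,Zn|Z')^2)(1-cor(y,Zn|Z')^2))` one conditioner at a time.
#' The two are mathematically identical; the recursion is retained as an
#' independent cross-check.
#'
#' Degenerate inputs — a conditioner collinear with `x` or `y`, or a singular
#' correlation matrix — yield `NA` with attribute `degenerate = TRUE`; the
#' calling criterion then fails the pair rather than reporting a number.
#'
#' @param x,y numeric vectors of length `s`.
#' @param z `NULL`, or a numeric matrix with `s` rows (one conditioning
#'   variable per column). Duplicate (collinear) columns are dropped first.
#' @param method `"inversion"` (default) or `"recursion"`.
#' @return a single correlation, or `NA` flagged degenerate.
#' @export
partial_correlation <- function(x, y, z = NULL,
                                method = c("inversion", "recursion")) {
  method <- match.arg(method)
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != length(x)) stop("'z' rows must match length of 'x'", call. = FALSE)
    if (ncol(z) == 0L) z <- NULL
  }
  if (max(x) - min(x) == 0 || max(y) - min(y) == 0)
    return(degenerate_cor("constant vector"))
  if (is.null(z)) return(min(1, max(-1, cor(x, y))))
  if (any(apply(z, 2L, function(v) max(v) - min(v) == 0)))
    return(degenerate_cor("constant conditioning variable"))
  z <- dedup_conditioners(z)
  rxz <- drop(cor(x, z)); ryz <- drop(cor(y, z))
  if (any(abs(rxz) >= 1 - 1e-10) || any(abs(ryz) >= 1 - 1e-10))
    return(degenerate_cor("conditioner collinear with x or y"))
  if (method == "recursion") return(pcor_recursion(x, y, z))
  R <- cor(cbind(x, y, z))
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(P)) return(degenerate_cor("singular correlation matrix"))
  pc <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  if (!is.finite(pc)) return(degenerate_cor("singular correlation matrix"))
  min(1, max(-1, pc))
}

degenerate_cor <- function(reason) {
  structure(NA_real_, degenerate = TRUE, reason = reason)
}

# First-order recursion on the full correlation matrix of (x, y, z):
# condition on z columns one at a time. Kept simple; serves as the oracle
# for the matrix-inversion path.
pcor_recursion <- function(x, y, z) {
  R <- cor(cbind(x, y, z))
  k <- ncol(R)
  recur <- function(i, j, cond) {
    if (length(cond) == 0L) return(R[i, j])
    n <- cond[length(cond)]
    rest <- cond[-length(cond)]
    rij <- recur(i, j, rest)
    rin <- recur(i, n, rest)
    rjn <- recur(j, n, rest)
    den <- sqrt((1 - rin^2) * (1 - rjn^2))
    if (!is.finite(den) || den == 0) return(NA_real_)
    (rij - rin * rjn) / den
  }
  pc <- recur(1L, 2L, seq.int(3L, k))
  if (!is.finite(pc)) return(degenerate_cor("collinearity in recursion"))
  min(1, max(-1, pc))
}

#' Sensitive correlation
#'
#' The drop in Pearson correlation after conditioning on a mediator set:
#' `sc = cor(x, y) - cor(x, y | z)`. Large positive values indicate that the
#' association between `x` and `y` is mediated by `z` — the signature of
#' competition through a shared regulator pool.
#'
#' @inheritParams partial_correlation
#' @return list with `cor`, `pcor`, `sc`, `conditioning_size`, `degenerate`
#'   (logical) and `reason` (NA or text).
#' @export
sensitivity <- function(x, y, z = NULL) {
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (ncol(z) == 0L) z <- NULL
  }
  n_cond <- if (is.null(z)) 0L else ncol(z)
  if (max(x) - min(x) == 0 || max(y) - min(y) == 0)
    return(list(cor = NA_real_, pcor = NA_real_, sc = NA_real_,
                conditioning_size = n_cond, degenerate = TRUE,
                reason = "constant vector"))
  r <- min(1, max(-1, cor(x, y)))
  pc <- partial_correlation(x, y, z)
  if (isTRUE(attr(pc, "degenerate")))
    return(list(cor = r, pcor = NA_real_, sc = NA_real_,
                conditioning_size = n_cond, degenerate = TRUE,
                reason = attr(pc, "reason")))
  list(cor = r, pcor = as.numeric(pc), sc = r - as.numeric(pc),
       conditioning_size = n_cond, degenerate = FALSE, reason = NA_character_)
}
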