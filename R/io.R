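#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying its gene class (`"mirna"`, `"lncrna"`, `"pseudogene"`,
#' `"mrna"`, or any user label) as an attribute. Values are taken as provided
#' (assumed already normalised); an optional `log2(x + 1)` transform is
#' available at read time. Zero-variance genes are kept but flagged, because
#' correlation-based tests are undefined for them and exclude them.
#'
#' @param values numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids); all values finite.
#' @param gene_class character scalar labelling the gene class.
#' @return the matrix with attributes `gene_class` and `zero_variance`
#'   (character vector of constant-expression gene ids), class
#'   `"expression_matrix"`.
#' @export
expression_matrix <- function(values, gene_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.character(gene_class) || length(gene_class) != 1L || !nzchar(gene_class))
    stop("'gene_class' must be a non-empty string", call. = FALSE)
  zv <- rownames(values)[apply(values, 1L, function(r) max(r) - min(r) == 0)]
  structure(values,
            gene_class = gene_class,
            zero_variance = zv,
            class = c("expression_matrix", class(values)))
}

#' Read an expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns: the first column holds gene
#' ids and the header row holds sample ids. The field separator is sniffed
#' from the header (tab or comma).
#'
#' @param path path to a TSV/CSV file.
#' @param gene_class gene class label for the matrix.
#' @param log2_transform apply `log2(x + 1)` after reading (default `FALSE`;
#'   expression is otherwise taken as provided).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, gene_class, log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expected a gene-id column plus sample columns", call. = FALSE)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]), call. = FALSE)
  if (log2_transform) {
    if (any(num < -1)) stop("log2(x + 1) transform needs values >= -1", call. = FALSE)
    num <- log2(num + 1)
  }
  expression_matrix(num, gene_class)
}

#' Read a miRNA-target prior table
#'
#' Two-column delimited text (miRNA id, target id), with or without a header.
#' Duplicate pairs are dropped.
#'
#' @param path path to the file.
#' @param target_class gene class of the targets.
#' @return data.frame with columns `mirna`, `target` and attribute
#'   `target_class`.
#' @export
read_targets <- function(path, target_class) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), "[\t,]")[[1L]]
  sep <- if (grepl("\t", readLines(path, n = 1L), fixed = TRUE)) "\t" else ","
  # heuristic: header if the first row repeats as ids nowhere / non-data words
  tab <- read.delim(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("prior table needs two columns", call. = FALSE)
  if (tolower(first[1L]) %in% c("mirna", "mirna_id", "source"))
    tab <- tab[-1L, , drop = FALSE]
  prior_table(tab[[1L]], tab[[2L]], target_class)
}

#' @rdname read_targets
#' @param mirna,target character vectors of equal length.
#' @export
prior_table <- function(mirna, target, target_class) {
  mirna <- as.character(mirna); target <- as.character(target)
  if (length(mirna) != length(target))
    stop("'mirna' and 'target' must have equal length", call. = FALSE)
  if (any(!nzchar(mirna)) || any(!nzchar(target)))
    stop("empty ids in prior table", call. = FALSE)
  keep <- !duplicated(paste(mirna, target, sep = "\r"))
  structure(data.frame(mirna = mirna[keep], target = target[keep],
                       stringsAsFactors = FALSE),
            target_class = target_class)
}

#' Align samples across expression matrices
#'
#' Restricts every matrix to the intersection of sample ids, in a common
#' order, mirroring the removal of non-matching tumour samples when pairing
#' ncRNA and mRNA assays. Idempotent on already-matched input.
#'
#' @param matrices named list of [expression_matrix()] objects; names are the
#'   gene-class slots (`mirna` and `mrna` are required by the inference
#'   functions, further entries are ncRNA classes such as `lncrna`,
#'   `pseudogene`).
#' @param label condition label (e.g. tumour type), stored on the result.
#' @return a `matched_dataset`: the input list restricted to shared samples,
#'   with attributes `condition` and `dropped` (named integer vector of
#'   samples dropped per matrix).
#' @export
align_samples <- function(matrices, label = "condition") {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need at least two expression matrices", call. = FALSE)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop("'matrices' must be a named list", call. = FALSE)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  if (length(shared) == 0L)
    stop("no samples shared across all matrices", call. = FALSE)
  dropped <- vapply(matrices, function(m) ncol(m) - length(shared), integer(1L))
  out <- lapply(matrices, function(m) {
    res <- m[, shared, drop = FALSE]
    expression_matrix(unclass(res), attr(m, "gene_class") %||% "unknown")
  })
  structure(out, condition = label, dropped = dropped,
            class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat("Matched expression dataset (", attr(x, "condition"), "): ",
      ncol(x[[1L]]), " samples\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-12s %5d genes (%d constant)\n", nm, nrow(x[[nm]]),
                length(attr(x[[nm]], "zero_variance"))))
  invisible(x)
}

edge_table_columns <- c("source", "target", "overlap_count", "universe_size",
                        "p_overlap", "cor", "p_cor", "sensitive_cor",
                        "p_sensitive", "passed")

#' Write / read a competition edge table
#'
#' Tab-separated text with the fixed column order `source, target,
#' overlap_count, universe_size, p_overlap, cor, p_cor, sensitive_cor,
#' p_sensitive, passed`. Real-valued statistics are serialised in scientific
#' notation with 17 significant digits, so a read-back reproduces the written
#' doubles exactly.
#'
#' @param edges an edge data.frame as returned by [infer_cerna_network()] or
#'   [infer_synergy_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(is.data.frame(edges))
  missing_cols <- setdiff(edge_table_columns, names(edges))
  if (length(missing_cols))
    stop("edge table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- edges[, edge_table_columns, drop = FALSE]
  for (cl in c("p_overlap", "cor", "p_cor", "sensitive_cor", "p_sensitive"))
    out[[cl]] <- ifelse(is.na(out[[cl]]), "NA", sprintf("%.16e", out[[cl]]))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(edge_table_columns %in% names(tab)))
    stop("not an edge table: ", path, call. = FALSE)
  tab$passed <- as.logical(tab$passed)
  tab[, edge_table_columns, drop = FALSE]
}
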