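#' End-to-end pipeline: infer, diagnose, write
#'
#' Reads expression matrices and prior tables from disk, fits the ceRNA and
#' synergistic-competition networks with [scom()], runs the topology report
#' and hub calling on the synergy network, and writes all outputs plus a
#' manifest to `out_dir`. Rerunning with an identical config (including the
#' seed) reproduces byte-identical edge tables and manifest.
#'
#' @param config named list with elements:
#'   * `expression`: named list of file paths (`mirna`, `mrna`, plus one per
#'     ncRNA class);
#'   * `targets`: named list of prior-table paths (`mrna` plus one per ncRNA
#'     class);
#'   and optionally `alpha` (0.05), `seed` (1), `log2_transform` (FALSE),
#'   `min_shared` (1), `mirna_universe` ("prior"), `mrna_universe`
#'   ("dataset"), `adjust` ("none"), `null_draws` (1000), `n_random` (100),
#'   `condition` ("condition").
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the `scom` fit, topology report, hub table
#'   and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(alpha = 0.05, seed = 1L, log2_transform = FALSE,
                   min_shared = 1L, mirna_universe = "prior",
                   mrna_universe = "dataset", adjust = "none",
                   null_draws = 1000L, n_random = 100L,
                   condition = "condition")
  for (nm in names(defaults))
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  for (nm in c("expression", "targets")) {
    if (is.null(config[[nm]]) || is.null(names(config[[nm]])))
      stop("config needs a named '", nm, "' list of file paths", call. = FALSE)
    missing <- unlist(config[[nm]])[!file.exists(unlist(config[[nm]]))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mats <- lapply(names(config$expression), function(cl)
    read_expression(config$expression[[cl]], cl,
                    log2_transform = isTRUE(config$log2_transform)))
  names(mats) <- names(config$expression)
  dataset <- align_samples(mats, label = config$condition)
  priors <- lapply(names(config$targets), function(cl)
    read_targets(config$targets[[cl]], cl))
  names(priors) <- names(config$targets)

  fit <- scom(dataset, priors, alpha = config$alpha, seed = config$seed,
              null_draws = config$null_draws, min_shared = config$min_shared,
              mirna_universe = config$mirna_universe,
              mrna_universe = config$mrna_universe, adjust = config$adjust)

  for (cl in fit$classes)
    write_edge_table(fit$cerna[[cl]],
                     file.path(out_dir, paste0("cerna_", cl, ".tsv")))
  write_edge_table(fit$synergy, file.path(out_dir, "synergy.tsv"))

  topo <- hubs <- NULL
  if (any(fit$synergy$passed)) {
    net <- as_network(fit$synergy)
    topo <- tryCatch(
      topology_report(net, n_random = config$n_random, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(topo))
      jsonlite::write_json(unclass(topo), file.path(out_dir, "topology.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    hubs <- hub_pvalues(net, alpha = config$alpha)
    h <- hubs
    h$p_value <- sprintf("%.16e", h$p_value)
    h$lambda <- sprintf("%.16e", h$lambda)
    write.table(h, file.path(out_dir, "hubs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  manifest <- list(
    package = "spongenet",
    version = as.character(utils::packageVersion("spongenet")),
    config = config[order(names(config))],
    config_hash = config_hash(config),
    n_samples = fit$n_samples,
    edges = c(lapply(fit$cerna, function(e) sum(e$passed)),
              list(synergy = sum(fit$synergy$passed))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, topology = topo, hubs = hubs,
                 manifest = manifest))
}

# Stable hash of a config: canonical JSON (sorted names) -> md5.
config_hash <- function(config) {
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}
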