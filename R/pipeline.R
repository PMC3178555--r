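#' Pipeline configuration
#'
#' Houses every tunable of the modeling front end: the HAR calling
#' threshold, the alignment parameters, the template-filter charge and
#' top-k, the scorer choice, and the seed. Round-trips through JSON via
#' [write_config()] / [read_config()].
#'
#' @param threshold HAR calling cutoff (default 97).
#' @param params an [alignment_params()].
#' @param gamma opening-gap charge of the level statistics (default 1).
#' @param k template-filter top-k (default 5).
#' @param denominator level-statistic denominator, see [identity_level()].
#' @param scorer `"mock"` or `"table"` (z scores injected via `z_table`).
#' @param seed integer seed recorded in the run manifest.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(threshold = 97L, params = alignment_params(),
                            gamma = 1.0, k = 5L,
                            denominator = c("n_columns", "min_length"),
                            scorer = c("mock", "table"), seed = 1L) {
  stopifnot(threshold >= 0, gamma >= 0, k >= 1)
  structure(list(threshold = as.integer(threshold), params = params,
                 gamma = gamma, k = as.integer(k),
                 denominator = match.arg(denominator),
                 scorer = match.arg(scorer), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @return `write_config()`: `path` invisibly; `read_config()`: the
#'   restored `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(threshold = x$threshold,
                  params = do.call(alignment_params, x$params),
                  gamma = x$gamma, k = x$k, denominator = x$denominator,
                  scorer = x$scorer, seed = x$seed)
}

#' Run the full modeling front end over a batch of targets
#'
#' Per target: (re)flag HARs at the configured threshold, align against all
#' templates, filter to the candidate alignment set, enumerate single- and
#' double-template model candidates, score and rank them, select the best,
#' and (when `out_dir` is given) write the TSV reports and the best
#' candidate's PIR file. A target that fails is logged and skipped; the run
#' errors only if every target fails.
#'
#' @param targets named list of [annotated_seq()].
#' @param templates named list of [template_record()] (HAR flags are
#'   refreshed at the configured threshold too).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param z_table optional injected z-score table (candidate_id, z_score),
#'   used when `config$scorer == "table"`.
#' @param quiet suppress per-target progress messages.
#' @return A list of class `"pipeline_run"`: per-target results (`hars`,
#'   `alignments`, `candidates` (the filtered set), `ranked`, `best`) plus
#'   `manifest` (parameters, seed, package version, per-target status).
#' @export
run_pipeline <- function(targets, templates, config = pipeline_config(),
                         out_dir = NULL, z_table = NULL, quiet = TRUE) {
  stopifnot(length(targets) >= 1L, length(templates) >= 1L)
  if (config$scorer == "table" && is.null(z_table))
    stop("scorer = 'table' requires a z_table")
  templates <- lapply(templates, function(t) {
    t$seq <- flag_hars(t$seq, threshold = config$threshold)
    t
  })
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  status <- character(0)
  for (tgt in targets) {
    res <- tryCatch({
      tgt <- flag_hars(tgt, threshold = config$threshold)
      hars <- identify_hars(tgt, threshold = config$threshold)
      alns <- align_all(tgt, templates, config$params)
      ca <- select_candidates(alns, k = config$k, gamma = config$gamma,
                              denominator = config$denominator)
      cands <- enumerate_candidates(ca, templates)
      ranked <- rank_candidates(tgt, cands,
                                scorer = mock_surface_scorer,
                                z_table = if (config$scorer == "table")
                                  z_table else NULL)
      best <- select_best(ranked)
      if (!is.null(out_dir)) {
        tdir <- file.path(out_dir, tgt$id)
        dir.create(tdir, showWarnings = FALSE)
        write_har_tsv(hars, file.path(tdir, "hars.tsv"))
        write.table(alignment_table(alns), file.path(tdir, "alignments.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        write.table(ca$table, file.path(tdir, "candidate_alignments.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        write.table(candidate_table(ranked),
                    file.path(tdir, "candidates.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        write_pir(tgt, best$alignments, file.path(tdir, "best.pir"))
      }
      list(target_id = tgt$id, hars = hars, alignments = alns,
           candidates = ca, ranked = ranked, best = best)
    }, error = function(e) {
      warning("target '", tgt$id, "' skipped: ", conditionMessage(e))
      NULL
    })
    status[tgt$id] <- if (is.null(res)) "failed" else "ok"
    if (!is.null(res)) results[[tgt$id]] <- res
    if (!quiet)
      message("[", tgt$id, "] ", status[tgt$id])
  }
  if (!length(results)) stop("all targets failed")
  manifest <- list(
    package = "harfia",
    version = as.character(packageVersion("harfia")),
    seed = config$seed,
    threshold = config$threshold,
    k = config$k, gamma = config$gamma,
    denominator = config$denominator,
    scorer = config$scorer,
    alignment = unclass(config$params),
    n_targets = length(targets), n_templates = length(templates),
    status = as.list(status),
    selected = lapply(results, function(r) r$best$candidate_id))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(results = results, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  ok <- sum(unlist(x$manifest$status) == "ok")
  cat("<pipeline_run>", ok, "of", length(x$manifest$status),
      "targets completed\n")
  invisible(x)
}
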