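#' Pipeline configuration
#'
#' Bundles every input path and tuning parameter of the full surrogate-
#' gene discovery run: mRMR ranking, incremental feature selection with
#' jackknife validation, and (optionally) shortest-path sub-network
#' extraction over a scored interaction graph.
#'
#' @param expression path to the expression TSV (probes in rows).
#' @param labels path to the labels TSV (`sample_id`, `label`).
#' @param out_dir output directory.
#' @param class_order ordered class vector (default: label-file order).
#' @param mapping optional probe-to-gene mapping TSV; when absent, probe
#'   ids are used directly as network identifiers.
#' @param edges optional STRING-convention edge list; when absent the
#'   pipeline stops after feature selection.
#' @param method correlation method for mRMR (`"pearson"`/`"spearman"`).
#' @param max_n IFS sweep bound (truncated to the probe count).
#' @param engines prediction engines to evaluate.
#' @param select_engine engine driving the optimum rule (default `"nn1"`).
#' @param score_threshold minimum combined score for network edges.
#' @param weight_mode shortest-path weighting, `"hop"` or `"score"`.
#' @param all_shortest union all equal-weight shortest paths per pair.
#' @param seed integer seed recorded in the run report (the analysis
#'   stages are deterministic; the seed matters when inputs are simulated).
#' @param verbose print stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, labels, out_dir,
                            class_order = NULL, mapping = NULL, edges = NULL,
                            method = "pearson", max_n = 400,
                            engines = engine_ids(), select_engine = "nn1",
                            score_threshold = 400,
                            weight_mode = "hop", all_shortest = FALSE,
                            seed = 1L, verbose = FALSE) {
  structure(
    list(expression = expression, labels = labels, out_dir = out_dir,
         class_order = class_order, mapping = mapping, edges = edges,
         method = method, max_n = max_n, engines = engines,
         select_engine = select_engine, score_threshold = score_threshold,
         weight_mode = weight_mode, all_shortest = all_shortest,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "pipeline_config")
}

#' Run the full surrogate-gene discovery pipeline
#'
#' Executes, in order: expression ingest, mRMR ranking, IFS sweep with
#' jackknife validation, optimum selection, probe-to-gene mapping, and
#' shortest-path sub-network extraction (when an edge file is supplied).
#' All stage outputs are written as TSV under `config$out_dir`:
#' `ranking.tsv`, `ifs_curve.tsv`, `optimal_features.tsv`,
#' `predictions.tsv` (per-sample jackknife predictions at the optimum for
#' every engine), plus `subnetwork_edges.tsv`, `subnetwork_nodes.tsv` and
#' `paths.tsv` for the network stage, and a machine-readable
#' `report.json` (config echo, seed, versions, per-stage timings).  The
#' analysis is deterministic given the inputs; timings in the report are
#' the only run-dependent field.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `matrix`, `ranking`, `curve`,
#'   `optimal` (n, probes, genes, accuracy), `subnetwork` (or `NULL`)
#'   and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[mrmrpath] ", ...)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  say("reading expression")
  lem <- clock("ingest",
               read_expression(config$expression, config$labels,
                               config$class_order))
  n_rank <- min(config$max_n, nrow(lem$values))
  say("ranking ", n_rank, " features by mRMR")
  ranking <- clock("mrmr", mrmr_rank(lem, n_rank, method = config$method))
  write_tsv(ranking, file.path(config$out_dir, "ranking.tsv"))

  say("IFS sweep to N = ", n_rank)
  curve <- clock("ifs", run_ifs(lem, ranking, max_n = n_rank,
                                engines = config$engines,
                                select_engine = config$select_engine))
  write_tsv(curve$points, file.path(config$out_dir, "ifs_curve.tsv"))

  opt_probes <- curve$optimal_features
  genes <- opt_probes
  if (!is.null(config$mapping)) {
    map <- read_id_mapping(config$mapping)
    unmapped <- setdiff(opt_probes, names(map))
    if (length(unmapped))
      warning("optimal probes without a gene mapping dropped from the ",
              "network stage: ", paste(unmapped, collapse = ", "))
    genes <- unname(map[intersect(opt_probes, names(map))])
  }
  write_tsv(data.frame(rank = seq_along(opt_probes), probe_id = opt_probes,
                       gene_id = if (is.null(config$mapping)) opt_probes else {
                         m <- read_id_mapping(config$mapping)
                         unname(m[opt_probes])
                       }),
            file.path(config$out_dir, "optimal_features.tsv"))

  say("jackknife predictions at the optimum (N = ", curve$optimal_n, ")")
  jk <- clock("predictions",
              jackknife(lem, opt_probes, engine = config$engines))
  write_tsv(jk$predictions, file.path(config$out_dir, "predictions.tsv"))

  subnet <- NULL
  if (is.null(config$edges)) {
    say("no interaction edge file supplied; stopping after feature selection")
  } else {
    say("building shortest-path sub-network")
    subnet <- clock("network", {
      graph <- load_interactions(config$edges, config$score_threshold,
                                 config$weight_mode)
      build_subnetwork(graph, unique(genes),
                       all_shortest = config$all_shortest)
    })
    write_tsv(subnet$edges, file.path(config$out_dir, "subnetwork_edges.tsv"))
    write_tsv(subnet$nodes, file.path(config$out_dir, "subnetwork_nodes.tsv"))
    write_tsv(subnet$paths, file.path(config$out_dir, "paths.tsv"))
  }

  report <- list(
    package = "mrmrpath",
    version = as.character(utils::packageVersion("mrmrpath")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "verbose")],
    n_probes = nrow(lem$values), n_samples = ncol(lem$values),
    optimal_n = curve$optimal_n,
    optimal_accuracy = curve$optimal_accuracy,
    selecting_engine = curve$selecting_engine,
    optimal_probes = opt_probes,
    optimal_genes = unique(genes),
    bridge_genes = if (!is.null(subnet)) subnet$bridge_genes else NULL,
    network_stage_run = !is.null(subnet),
    timings_sec = timings)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  say("done; outputs in ", config$out_dir)
  invisible(list(matrix = lem, ranking = ranking, curve = curve,
                 optimal = list(n = curve$optimal_n, probes = opt_probes,
                                genes = unique(genes),
                                accuracy = curve$optimal_accuracy),
                 subnetwork = subnet, report = report))
}
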