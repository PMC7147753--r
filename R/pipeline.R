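#' Run the full cascade workflow
#'
#' Single entry point wiring all steps together: read the expression matrix
#' and the background network (or build the network from a scored
#' binding-prediction table plus PWM map), assign stage-specific
#' regulators, build the cascade, classify interaction patterns, run
#' per-stage enrichment when annotations are given, and write exports plus
#' a machine-readable run-metadata record. All input files are checked
#' before any computation, and on failure no partial output is left behind.
#'
#' @param config a named list, or the path of a YAML/JSON file holding one.
#'   Recognized keys: `expression` (path, required); `design_spec`
#'   (optional, see [read_expression()]); `network` (edge-list path) *or*
#'   `predictions` + `pwm_map` (+ optional `top_fraction`, default 0.05);
#'   `annotations` (optional path); `min_e`, `min_c`, `max_s` (defaults
#'   4 / 0.6 / 10); `alpha` (default 0.05); `restrict_to_regulators`
#'   (default `TRUE`; `FALSE` runs the ablation of
#'   [unrestricted_cascade()]); `formats` (default all four); `seed`
#'   (recorded in the metadata; the workflow itself is deterministic);
#'   `out_dir` (required).
#' @param ... individual keys overriding the config, e.g.
#'   `run_trc("cfg.yaml", max_s = 12)`.
#' @return invisibly, a list with `cascade`, `assignment`, `interactions`,
#'   `enrichment` (or `NULL`), `metadata` and `paths` (written files).
#' @export
run_trc <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_trc("config file not found: ", config, class = "trc_usage_error")
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop_trc("'config' must be a list or a YAML/JSON path",
             class = "trc_usage_error")
  overrides <- list(...)
  config[names(overrides)] <- overrides

  for (key in c("expression", "out_dir"))
    if (is.null(config[[key]]))
      stop_trc("config key '", key, "' is required",
               class = "trc_usage_error")
  use_built <- is.null(config$network)
  if (use_built && (is.null(config$predictions) || is.null(config$pwm_map)))
    stop_trc("config needs either 'network' or both 'predictions' and ",
             "'pwm_map'", class = "trc_usage_error")

  input_files <- c(expression = config$expression,
                   network = config$network,
                   predictions = config$predictions,
                   pwm_map = config$pwm_map,
                   annotations = config$annotations)
  missing <- input_files[!file.exists(input_files)]
  if (length(missing) > 0L)
    stop_trc("input file(s) not found: ",
             paste(sprintf("%s (%s)", missing, names(missing)),
                   collapse = ", "), class = "trc_usage_error")

  params <- trc_params(min_e = config$min_e %||% 4,
                       min_c = config$min_c %||% 0.6,
                       max_s = config$max_s %||% 10)
  alpha <- config$alpha %||% 0.05
  top_fraction <- config$top_fraction %||% 0.05
  restrict <- config$restrict_to_regulators %||% TRUE
  formats <- config$formats %||%
    c("edge-table", "sif", "graphml", "cytoscape-json")

  ds <- read_expression(config$expression, design_spec = config$design_spec)
  net <- if (use_built)
    build_network(read_binding_predictions(config$predictions),
                  read_pwm_map(config$pwm_map), top_fraction = top_fraction)
  else read_network(config$network)

  eligible <- if (restrict) regulator_universe(net) else rownames(ds$values)
  assignment <- assign_stages(ds, eligible, params)
  cascade <- build_cascade(assignment, net)
  interactions <- classify_interactions(cascade)

  annotations <- NULL
  enrichment <- NULL
  if (!is.null(config$annotations)) {
    annotations <- read_annotations(config$annotations)
    universe <- enrichment_universe(ds, annotations, params$min_e)
    enrichment <- enrich_all_stages(cascade, annotations, universe,
                                    alpha = alpha)
  }

  metadata <- list(
    tool = "trcascade",
    version = as.character(utils::packageVersion("trcascade")),
    parameters = list(min_e = params$min_e, min_c = params$min_c,
                      max_s = params$max_s, alpha = alpha,
                      top_fraction = if (use_built) top_fraction else NULL,
                      restrict_to_regulators = restrict),
    seed = config$seed,
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(input_files)), names(input_files))),
    filtering = assignment$log,
    cascade = list(n_nodes = nrow(cascade$nodes),
                   n_edges = nrow(cascade$edges),
                   n_stage_columns = length(cascade$stage_indices)))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    unlink(paste0(written, ".nodes.tsv"))
    stop(e)
  }
  paths <- tryCatch({
    p <- character()
    fmt_file <- c(`edge-table` = "cascade.edges.tsv", sif = "cascade.sif",
                  graphml = "cascade.graphml",
                  `cytoscape-json` = "cascade.cyjs.json")
    for (f in formats) {
      path <- file.path(out_dir, fmt_file[[f]])
      written <- c(written, path)
      export_cascade(cascade, path, format = f)
      p[f] <- path
    }
    ipath <- file.path(out_dir, "interaction_patterns.tsv")
    written <- c(written, ipath)
    utils::write.table(interactions$edges, ipath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p["interactions"] <- ipath
    if (!is.null(enrichment)) {
      epath <- file.path(out_dir, "enrichment.tsv")
      written <- c(written, epath)
      utils::write.table(enrichment, epath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p["enrichment"] <- epath
    }
    mpath <- file.path(out_dir, "run_metadata.json")
    written <- c(written, mpath)
    jsonlite::write_json(metadata, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    p["metadata"] <- mpath
    p
  }, error = on_fail)

  message(sprintf(
    paste0("cascade: %d nodes / %d edges in %d columns; %d gene(s) failed ",
           "min_e, %d constant profile(s) excluded"),
    nrow(cascade$nodes), nrow(cascade$edges), length(cascade$stage_indices),
    assignment$log$n_failing_min_e, assignment$log$n_zero_variance))

  invisible(list(cascade = cascade, assignment = assignment,
                 interactions = interactions, enrichment = enrichment,
                 metadata = metadata, paths = paths))
}
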