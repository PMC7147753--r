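#' Construct a background regulatory network
#'
#' A directed regulator -> target graph, independent of any expression
#' dataset. Cascade edges and the regulator universe are both drawn from it.
#'
#' @param edges data.frame with columns `regulator` and `target` (or any
#'   two columns in that order). Duplicate edges are collapsed; self-edges
#'   are kept.
#' @return an object of class `reg_network` with elements `edges`
#'   (data.frame `regulator`, `target`), `regulators` and `targets`
#'   (character vectors of source and sink genes).
#' @export
reg_network <- function(edges) {
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop_trc("'edges' must be a data.frame with two columns",
             class = "trc_format_error")
  edges <- data.frame(regulator = normalize_symbols(edges[[1L]]),
                      target = normalize_symbols(edges[[2L]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 regulators = unique(edges$regulator),
                 targets = unique(edges$target)),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("reg_network: %d regulators, %d targets, %d directed edges\n",
              length(x$regulators), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Read a background network from an edge-list file
#'
#' @param path two-column delimited edge list (see [read_network_edges()]).
#' @return a [reg_network()].
#' @export
read_network <- function(path) {
  reg_network(read_network_edges(path))
}

#' Write a network as a two-column edge list
#'
#' @param net a `reg_network`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  writeLines(paste(net$edges$regulator, net$edges$target, sep = "\t"), path)
  invisible(path)
}

#' Regulator universe of a network
#'
#' Only the source nodes of the background network are eligible to become
#' cascade members: the cascade is restricted to genes with known regulatory
#' capability.
#'
#' @param net a `reg_network`.
#' @return character vector of source-node gene symbols.
#' @export
regulator_universe <- function(net) {
  net$regulators
}

#' Edges between two gene sets
#'
#' All background edges whose source lies in `sources` and whose sink lies
#' in `sinks`; this is the primitive behind both within-stage and
#' consecutive-stage cascade edges.
#'
#' @param net a `reg_network`.
#' @param sources,sinks character vectors of gene symbols.
#' @return data.frame of edges (`regulator`, `target`).
#' @export
subnetwork <- function(net, sources, sinks) {
  sources <- normalize_symbols(sources)
  sinks <- normalize_symbols(sinks)
  out <- net$edges[net$edges$regulator %in% sources &
                     net$edges$target %in% sinks, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a regulatory network from scored binding-site predictions
#'
#' For each PWM independently, its predicted binding sites are ranked by
#' match score (descending) and the best `top_fraction` are retained —
#' `min(n, max(1, ceiling(top_fraction * n)))` rows for a PWM with `n`
#' predictions, so every PWM with at least one prediction contributes. Each
#' retained (PWM, target) row then yields one edge for every regulator gene
#' the PWM maps to, and duplicate edges collapse. Ties at the score cutoff
#' break deterministically by (score descending, target symbol ascending,
#' input order).
#'
#' @param predictions data.frame with columns `pwm_id`, `target`, `score`
#'   (one row per predicted binding site; a (pwm, target) pair may repeat
#'   when a promoter has several sites).
#' @param pwm_map mapping of PWM id to regulator gene symbol(s): a
#'   data.frame with columns `pwm_id` and `regulator`, or a named list of
#'   character vectors.
#' @param top_fraction fraction of best-scoring sites kept per PWM, in
#'   (0, 1]. Default 0.05.
#' @return a [reg_network()]; the number of PWMs skipped for lack of a gene
#'   mapping is reported in a message and stored in attribute
#'   `skipped_pwms`.
#' @export
build_network <- function(predictions, pwm_map, top_fraction = 0.05) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop_trc("'top_fraction' must be a single number in (0, 1]",
             class = "trc_parameter_error")
  if (!is.data.frame(predictions) ||
      !all(c("pwm_id", "target", "score") %in% names(predictions)))
    stop_trc("'predictions' needs columns pwm_id, target, score",
             class = "trc_format_error")
  if (nrow(predictions) == 0L)
    stop_trc("'predictions' is empty", class = "trc_parameter_error")
  if (!all(is.finite(predictions$score)))
    stop_trc("prediction scores must be finite", class = "trc_value_error")

  if (is.data.frame(pwm_map)) {
    if (ncol(pwm_map) < 2L)
      stop_trc("'pwm_map' needs columns pwm_id, regulator",
               class = "trc_format_error")
    pwm_map <- split(normalize_symbols(pwm_map[[2L]]),
                     as.character(pwm_map[[1L]]))
  } else {
    pwm_map <- lapply(pwm_map, normalize_symbols)
  }
  pwm_map <- lapply(pwm_map, function(g) unique(g[nzchar(g)]))
  pwm_map <- pwm_map[lengths(pwm_map) > 0L]
  if (length(pwm_map) == 0L)
    stop_trc("'pwm_map' maps no PWM to a regulator gene",
             class = "trc_parameter_error")

  pred <- data.frame(pwm_id = as.character(predictions$pwm_id),
                     target = normalize_symbols(predictions$target),
                     score = as.numeric(predictions$score),
                     stringsAsFactors = FALSE)
  pwms <- unique(pred$pwm_id)
  skipped <- setdiff(pwms, names(pwm_map))
  if (length(skipped) > 0L)
    message(length(skipped), " PWM(s) without a gene mapping skipped")
  kept_pwms <- intersect(pwms, names(pwm_map))

  edge_list <- lapply(kept_pwms, function(p) {
    rows <- pred[pred$pwm_id == p, , drop = FALSE]
    n <- nrow(rows)
    k <- min(n, max(1L, as.integer(ceiling(top_fraction * n))))
    ord <- order(-rows$score, rows$target, seq_len(n))
    top <- rows[ord[seq_len(k)], , drop = FALSE]
    regulators <- pwm_map[[p]]
    data.frame(regulator = rep(regulators, each = nrow(top)),
               target = rep(top$target, times = length(regulators)),
               stringsAsFactors = FALSE)
  })
  net <- reg_network(do.call(rbind, edge_list))
  attr(net, "skipped_pwms") <- length(skipped)
  net
}

#' Read a scored binding-prediction table
#'
#' @param path delimited text with columns `pwm_id`, `target`, `score` (a
#'   header row is detected by a non-numeric third field on line 1).
#' @return data.frame suitable for [build_network()].
#' @export
read_binding_predictions <- function(path) {
  if (!file.exists(path))
    stop_trc("prediction file not found: ", path, class = "trc_usage_error")
  sep <- detect_delimiter(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[3L])))
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, quote = "\"")
  if (ncol(tab) < 3L)
    stop_trc("prediction table needs 3 columns (pwm_id, target, score)",
             class = "trc_format_error")
  stats::setNames(tab[, 1:3], c("pwm_id", "target", "score"))
}

#' Read a PWM-to-gene mapping
#'
#' @param path two-column delimited text: `pwm_id`, regulator gene symbol.
#'   A PWM may map to several genes over several lines.
#' @return data.frame with columns `pwm_id`, `regulator`.
#' @export
read_pwm_map <- function(path) {
  if (!file.exists(path))
    stop_trc("PWM map not found: ", path, class = "trc_usage_error")
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  if (ncol(tab) < 2L)
    stop_trc("PWM map needs 2 columns (pwm_id, regulator)",
             class = "trc_format_error")
  stats::setNames(tab[, 1:2], c("pwm_id", "regulator"))
}
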