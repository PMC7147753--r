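#' TRC tuning parameters
#'
#' The three knobs of cascade construction: `min_e`, an expression floor — a
#' gene must exceed it (strictly) in at least one replicate or time point of
#' the raw matrix to enter the calculation, eliminating genes that are lowly
#' expressed even at their peak; `min_c`, the minimum correlation to a
#' stage's template peak pattern; and `max_s`, the cap on genes per stage
#' column, so the cascade never holds more than `max_s` x (number of time
#' points) nodes.
#'
#' Defaults follow common practice for differentiation time courses with
#' normalized expression units: `min_c = 0.6`, `min_e = 4`, `max_s = 10`.
#'
#' @param min_e expression threshold, same units as the matrix; >= 0.
#' @param min_c minimum Pearson correlation, in \[-1, 1\].
#' @param max_s maximum regulators per stage; positive integer.
#' @return a list of class `trc_params`.
#' @export
trc_params <- function(min_e = 4, min_c = 0.6, max_s = 10) {
  if (!is.numeric(min_e) || length(min_e) != 1L || min_e < 0)
    stop_trc("min_e must be a single number >= 0", class = "trc_parameter_error")
  if (!is.numeric(min_c) || length(min_c) != 1L || min_c < -1 || min_c > 1)
    stop_trc("min_c must lie in [-1, 1]", class = "trc_parameter_error")
  if (!is.numeric(max_s) || length(max_s) != 1L || max_s < 1)
    stop_trc("max_s must be a positive integer", class = "trc_parameter_error")
  structure(list(min_e = min_e, min_c = min_c, max_s = as.integer(max_s)),
            class = "trc_params")
}

#' Average replicates into a gene x time-point matrix
#'
#' Per gene and time point, the arithmetic mean over that time point's
#' replicates. Column order follows time order. With a single replicate per
#' time point this is the identity on the values.
#'
#' @param ds an [expr_dataset()].
#' @return numeric matrix, genes x time points (columns named by time
#'   value).
#' @export
collapse_replicates <- function(ds) {
  tt <- ds$design$time_index
  cols <- lapply(seq_along(ds$time_values), function(i) {
    rowMeans(ds$values[, tt == i, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.character(ds$time_values)
  out
}

#' Library of template peak patterns
#'
#' One template per time point: expression 100 (percent of peak) at that
#' time point and zero everywhere else. Correlating gene profiles against
#' these one-hot references attracts genes that peak at exactly one stage;
#' because Pearson correlation is invariant to positive affine transforms of
#' either argument, the 100-vs-1 encoding is purely cosmetic.
#'
#' @param n_time number of time points (>= 2; correlation is undefined for a
#'   single point).
#' @return numeric matrix, one row per stage: row `s` is the TPP of stage
#'   `s`.
#' @export
tpp_library <- function(n_time) {
  if (!is.numeric(n_time) || length(n_time) != 1L || n_time < 2L)
    stop_trc("a TPP library needs >= 2 time points",
             class = "trc_design_error")
  n_time <- as.integer(n_time)
  m <- diag(100, n_time)
  rownames(m) <- paste0("stage", seq_len(n_time))
  m
}

#' Correlation of one profile to one template peak pattern
#'
#' Pearson correlation between an expression profile and a one-hot
#' template. Profiles with zero variance have no defined correlation and
#' return `NA`; such genes are excluded from all downstream ranking.
#'
#' @param profile numeric vector, one value per time point.
#' @param tpp numeric vector, the template (same length).
#' @return correlation in \[-1, 1\], or `NA` for a constant profile.
#' @export
correlate_to_tpp <- function(profile, tpp) {
  if (length(profile) != length(tpp))
    stop_trc("profile length (", length(profile), ") != template length (",
             length(tpp), ")", class = "trc_dimension_error")
  if (stats::sd(profile) == 0) return(NA_real_)
  stats::cor(profile, tpp)
}

# Correlation of every row of a collapsed matrix to every TPP;
# genes x stages. Zero-variance rows come back NA across the board.
tpp_correlations <- function(collapsed, tpps = tpp_library(ncol(collapsed))) {
  if (ncol(collapsed) != ncol(tpps))
    stop_trc("matrix has ", ncol(collapsed), " time points but templates ",
             "have ", ncol(tpps), class = "trc_dimension_error")
  r <- suppressWarnings(stats::cor(t(collapsed), t(tpps)))
  rownames(r) <- rownames(collapsed)
  colnames(r) <- rownames(tpps)
  r
}

#' Assign regulators to stages
#'
#' The stage-identification step: (i) genes with no raw value strictly
#' above `min_e` in any replicate or time point are eliminated; (ii) only
#' genes in the regulator universe are eligible; (iii) each surviving gene
#' is correlated (on its replicate-averaged profile) against every template
#' peak pattern and assigned to its best-correlated stage, provided that
#' best correlation is at least `min_c` (ties go to the earlier stage, so a
#' gene sits in exactly one column); (iv) per stage the top `max_s` genes by
#' correlation are kept, ties broken by gene symbol.
#'
#' @param ds an [expr_dataset()] (raw values; the `min_e` test runs on the
#'   uncollapsed matrix).
#' @param regulators character vector of eligible regulator genes, normally
#'   [regulator_universe()] of the background network.
#' @param params a [trc_params()].
#' @return object of class `stage_assignment`: list with `stages` (one
#'   data.frame `gene`, `correlation` per time point, sorted by correlation
#'   descending; possibly zero rows), `time_values`, `params` and `log`
#'   (filtering counts at each step).
#' @export
assign_stages <- function(ds, regulators, params = trc_params()) {
  stopifnot(inherits(ds, "expr_dataset"))
  regulators <- unique(normalize_symbols(regulators))
  regulators <- regulators[nzchar(regulators)]
  if (length(regulators) == 0L)
    stop_trc("the regulator universe is empty; check the background ",
             "network (its source nodes define cascade eligibility)",
             class = "trc_usage_error")

  pass_min_e <- rownames(ds$values)[apply(ds$values, 1L, max) > params$min_e]
  eligible <- intersect(pass_min_e, regulators)
  log <- list(
    n_genes = nrow(ds$values),
    n_failing_min_e = nrow(ds$values) - length(pass_min_e),
    n_eligible_regulators = length(eligible))

  n_t <- length(ds$time_values)
  stages <- rep(list(data.frame(gene = character(),
                                correlation = numeric(),
                                stringsAsFactors = FALSE)), n_t)
  names(stages) <- as.character(ds$time_values)
  log$n_zero_variance <- 0L
  log$n_below_min_c <- 0L
  log$per_stage_candidates <- integer(n_t)

  if (length(eligible) > 0L) {
    collapsed <- collapse_replicates(ds)[eligible, , drop = FALSE]
    r <- tpp_correlations(collapsed)
    zero_var <- rowSums(is.na(r)) == ncol(r)
    log$n_zero_variance <- sum(zero_var)
    r <- r[!zero_var, , drop = FALSE]
    if (nrow(r) > 0L) {
      best_stage <- max.col(r, ties.method = "first")
      best_r <- r[cbind(seq_len(nrow(r)), best_stage)]
      keep <- best_r >= params$min_c
      log$n_below_min_c <- sum(!keep)
      genes <- rownames(r)[keep]
      best_stage <- best_stage[keep]
      best_r <- best_r[keep]
      for (s in seq_len(n_t)) {
        in_s <- which(best_stage == s)
        log$per_stage_candidates[s] <- length(in_s)
        if (length(in_s) == 0L) next
        ord <- in_s[order(-best_r[in_s], genes[in_s])]
        top <- ord[seq_len(min(params$max_s, length(ord)))]
        stages[[s]] <- data.frame(gene = genes[top],
                                  correlation = best_r[top],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(stages = stages, time_values = ds$time_values,
                 params = params, log = log),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  n <- vapply(x$stages, nrow, integer(1))
  cat("stage_assignment:",
      paste(sprintf("t=%s:%d", names(x$stages), n), collapse = "  "), "\n")
  invisible(x)
}

#' Build the temporal regulatory cascade
#'
#' Stage columns (time points with at least one assigned regulator) are laid
#' out in time order; all background-network edges between regulators of the
#' same column become within-stage edges, and all edges from a column to the
#' next retained column become cross-stage edges — empty stages are skipped,
#' so the cascade stays connected across a silent time point. Node indegree
#' and outdegree are computed on the cascade graph only.
#'
#' @param assignment a [assign_stages()] result.
#' @param net the background [reg_network()].
#' @return object of class `trc`: list with `nodes` (data.frame `gene`,
#'   `stage` (time-point index), `time_value`, `correlation`, `indegree`,
#'   `outdegree`), `edges` (data.frame `source`, `source_stage`, `target`,
#'   `target_stage`, `type` in within/cross), `stage_indices` (retained
#'   columns, in time order), `time_values`, `params`.
#' @export
build_cascade <- function(assignment, net) {
  stopifnot(inherits(assignment, "stage_assignment"),
            inherits(net, "reg_network"))
  n_per <- vapply(assignment$stages, nrow, integer(1))
  cols <- unname(which(n_per > 0L))

  nodes <- if (length(cols) > 0L)
    do.call(rbind, c(lapply(cols, function(s) {
      df <- assignment$stages[[s]]
      data.frame(gene = df$gene, stage = s,
                 time_value = assignment$time_values[s],
                 correlation = df$correlation, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  else data.frame(gene = character(), stage = integer(),
                  time_value = numeric(), correlation = numeric(),
                  stringsAsFactors = FALSE)

  edge_blocks <- list()
  for (i in seq_along(cols)) {
    s <- cols[i]
    genes_s <- assignment$stages[[s]]$gene
    within <- subnetwork(net, genes_s, genes_s)
    if (nrow(within) > 0L)
      edge_blocks[[length(edge_blocks) + 1L]] <- data.frame(
        source = within$regulator, source_stage = s,
        target = within$target, target_stage = s,
        type = "within", stringsAsFactors = FALSE)
    if (i < length(cols)) {
      s_next <- cols[i + 1L]
      cross <- subnetwork(net, genes_s, assignment$stages[[s_next]]$gene)
      if (nrow(cross) > 0L)
        edge_blocks[[length(edge_blocks) + 1L]] <- data.frame(
          source = cross$regulator, source_stage = s,
          target = cross$target, target_stage = s_next,
          type = "cross", stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_blocks) > 0L)
    do.call(rbind, c(edge_blocks, list(make.row.names = FALSE)))
  else data.frame(source = character(), source_stage = integer(),
                  target = character(), target_stage = integer(),
                  type = character(), stringsAsFactors = FALSE)

  nodes$indegree <- as.integer(
    table(factor(edges$target, levels = nodes$gene)))
  nodes$outdegree <- as.integer(
    table(factor(edges$source, levels = nodes$gene)))

  structure(list(nodes = nodes, edges = edges, stage_indices = cols,
                 time_values = assignment$time_values,
                 params = assignment$params),
            class = "trc")
}

#' @export
print.trc <- function(x, ...) {
  cat(sprintf(paste0("temporal regulatory cascade: %d nodes in %d stage ",
                     "columns, %d edges (%d within, %d cross)\n"),
              nrow(x$nodes), length(x$stage_indices), nrow(x$edges),
              sum(x$edges$type == "within"), sum(x$edges$type == "cross")))
  for (s in x$stage_indices) {
    in_s <- x$nodes[x$nodes$stage == s, ]
    cat(sprintf("  t=%s: %s\n", format(x$time_values[s]),
                paste(sprintf("%s(%.2f)", in_s$gene, in_s$correlation),
                      collapse = " ")))
  }
  invisible(x)
}

#' Label cascade edge patterns and score potential master regulators
#'
#' Classifies every edge by the interaction pattern it represents: a
#' within-stage edge whose reverse edge is absent is a one-way prediction
#' (causality-supporting); when both directions are present each is labeled
#' reciprocal (correlation cannot orient it); cross-stage edges are
#' time-lagged predictions to the next column. Per node, the same-stage and
#' next-stage out-fan counts are reported — a large fan marks a potential
#' master regulator of its own or of the following regulatory wave.
#'
#' @param cascade a [build_cascade()] result.
#' @return list with `edges` (cascade edges plus `pattern` in
#'   one-way/reciprocal/cross-stage) and `nodes` (per-gene `within_out_fan`
#'   and `cross_out_fan`, sorted by total fan descending).
#' @export
classify_interactions <- function(cascade) {
  stopifnot(inherits(cascade, "trc"))
  e <- cascade$edges
  pattern <- character(nrow(e))
  if (nrow(e) > 0L) {
    key <- paste(e$source, e$target, e$source_stage)
    rev_key <- paste(e$target, e$source, e$source_stage)
    within <- e$type == "within"
    pattern[within] <- ifelse(rev_key[within] %in% key[within] &
                                e$source[within] != e$target[within],
                              "reciprocal", "one-way")
    pattern[!within] <- "cross-stage"
  }
  e$pattern <- pattern

  n <- cascade$nodes
  nodes <- data.frame(
    gene = n$gene, stage = n$stage,
    within_out_fan = as.integer(table(factor(
      e$source[e$type == "within"], levels = n$gene))),
    cross_out_fan = as.integer(table(factor(
      e$source[e$type == "cross"], levels = n$gene))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(-(nodes$within_out_fan + nodes$cross_out_fan),
                       nodes$gene), ]
  rownames(nodes) <- NULL
  list(edges = e, nodes = nodes)
}
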