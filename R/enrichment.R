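#' One-sided over-representation p-value
#'
#' Probability, under the hypergeometric null, of drawing at least `k`
#' annotated genes when `n` genes are sampled without replacement from a
#' universe of `N` genes of which `K` carry the annotation — the one-sided
#' (greater) Fisher's exact test on the corresponding 2x2 table.
#'
#' @param k observed overlap between the gene set and the term.
#' @param n size of the gene set (within the universe).
#' @param K genes in the universe annotated to the term.
#' @param N universe size.
#' @return p-value(s) in (0, 1]; vectorized over its arguments.
#' @export
overrep_pvalue <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-stage GO over-representation
#'
#' For each annotation term overlapping the stage gene set, a one-sided
#' Fisher's exact test against the universe, Bonferroni correction over the
#' number of tested terms (those with overlap >= 1; terms the set never
#' touches cannot be enriched and only inflate the correction), and fold
#' enrichment `(k/n) / (K/N)`. Significant terms (`p_adj < alpha`) are
#' returned sorted by fold enrichment descending, then p ascending; the
#' unfiltered table is attached as attribute `full_table`.
#'
#' @param stage_genes character vector of gene symbols (one cascade
#'   column). Genes outside the universe are dropped with a warning.
#' @param annotations an [annotation_map()].
#' @param universe character vector of background gene symbols, e.g. all
#'   dataset genes that pass `min_e` and carry at least one annotation.
#' @param alpha significance level applied to the Bonferroni-adjusted p
#'   (default 0.05).
#' @return data.frame with columns `term`, `label`, `k`, `n`, `K`, `N`,
#'   `fold`, `p`, `p_adj`, filtered to `p_adj < alpha`; full table in
#'   `attr(, "full_table")`.
#' @export
enrich_stage <- function(stage_genes, annotations, universe, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_map"))
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0L)
    stop_trc("the annotation universe is empty", class = "trc_usage_error")
  stage_genes <- unique(normalize_symbols(stage_genes))
  outside <- setdiff(stage_genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " stage gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "))
    stage_genes <- intersect(stage_genes, universe)
  }

  empty <- data.frame(term = character(), label = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  N <- length(universe)
  n <- length(stage_genes)
  if (n == 0L) {
    attr(empty, "full_table") <- empty
    return(empty)
  }

  term_in_universe <- lapply(annotations$term_to_genes, intersect, universe)
  K <- lengths(term_in_universe)
  k <- vapply(term_in_universe, function(g)
    length(intersect(g, stage_genes)), integer(1))
  tested <- which(k >= 1L)
  if (length(tested) == 0L) {
    attr(empty, "full_table") <- empty
    return(empty)
  }
  m <- length(tested)
  p <- overrep_pvalue(k[tested], n, K[tested], N)
  full <- data.frame(
    term = names(annotations$term_to_genes)[tested],
    label = unname(annotations$term_names[tested]),
    k = unname(k[tested]), n = n, K = unname(K[tested]), N = N,
    fold = unname((k[tested] / n) / (K[tested] / N)),
    p = unname(p), p_adj = unname(pmin(1, p * m)),
    stringsAsFactors = FALSE)
  full <- full[order(-full$fold, full$p, full$term), ]
  rownames(full) <- NULL
  out <- full[full$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full_table") <- full
  out
}

#' Enrichment of every cascade column
#'
#' Runs [enrich_stage()] once per stage column and stacks the results with a
#' stage index column.
#'
#' @param cascade a [build_cascade()] result (or a `stage_assignment`).
#' @param annotations an [annotation_map()].
#' @param universe background gene set (see [enrich_stage()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame of significant terms across stages, with leading
#'   columns `stage` and `time_value`.
#' @export
enrich_all_stages <- function(cascade, annotations, universe, alpha = 0.05) {
  if (inherits(cascade, "trc")) {
    idx <- cascade$stage_indices
    genes_of <- function(s) cascade$nodes$gene[cascade$nodes$stage == s]
    tv <- cascade$time_values
  } else if (inherits(cascade, "stage_assignment")) {
    idx <- unname(which(vapply(cascade$stages, nrow, integer(1)) > 0L))
    genes_of <- function(s) cascade$stages[[s]]$gene
    tv <- cascade$time_values
  } else {
    stop_trc("expected a 'trc' or 'stage_assignment' object",
             class = "trc_usage_error")
  }
  universe <- unique(normalize_symbols(universe))
  blocks <- lapply(idx, function(s) {
    # unannotated column members fall outside the universe by construction;
    # dropping them here is the conditioning, not an anomaly worth a warning
    res <- enrich_stage(intersect(genes_of(s), universe), annotations,
                        universe, alpha)
    if (nrow(res) == 0L) return(NULL)
    cbind(data.frame(stage = s, time_value = tv[s]), res)
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L)
    return(data.frame(stage = integer(), time_value = numeric(),
                      term = character(), label = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  out
}

#' Default enrichment universe for a dataset
#'
#' All dataset genes that pass the expression floor and carry at least one
#' annotation — conditioning the background on detectability, as is standard
#' for expression-derived gene sets.
#'
#' @param ds an [expr_dataset()].
#' @param annotations an [annotation_map()].
#' @param min_e expression floor (strict, on raw replicate values).
#' @return character vector of gene symbols.
#' @export
enrichment_universe <- function(ds, annotations, min_e) {
  expressed <- rownames(ds$values)[apply(ds$values, 1L, max) > min_e]
  annotated <- unique(unlist(annotations$term_to_genes, use.names = FALSE))
  intersect(expressed, annotated)
}
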