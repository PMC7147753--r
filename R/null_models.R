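#' Shuffle the gene-to-profile assignment
#'
#' Randomly re-assigns genes to other expression profiles: a permutation of
#' the gene labels over the profile rows, either across all genes or across
#' the supplied regulator set only. Every profile row stays bit-identical to
#' some original row, so the multiset of profiles is conserved — only the
#' identity of the gene carrying each profile changes. This is the control
#' for the claim that the *identity* of the peaking genes, not merely the
#' existence of peaks, drives stage-specific enrichment.
#'
#' @param ds an [expr_dataset()].
#' @param seed integer seed; the permutation is reproducible.
#' @param scope `"all-genes"` (default) or `"regulators-only"`.
#' @param regulators character vector of regulator genes; required when
#'   `scope = "regulators-only"`.
#' @return a new `expr_dataset` with permuted rows.
#' @export
shuffle_profile_assignment <- function(ds, seed,
                                       scope = c("all-genes",
                                                 "regulators-only"),
                                       regulators = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  scope <- match.arg(scope)
  idx <- seq_len(nrow(ds$values))
  if (scope == "regulators-only") {
    if (is.null(regulators))
      stop_trc("scope 'regulators-only' needs a regulator set",
               class = "trc_usage_error")
    idx <- which(rownames(ds$values) %in% normalize_symbols(regulators))
  }
  if (length(idx) < 2L)
    stop_trc("cannot shuffle fewer than 2 profiles in scope",
             class = "trc_usage_error")
  out <- ds
  perm <- withr::with_seed(seed, sample(idx))
  v <- ds$values[perm, , drop = FALSE]
  rownames(v) <- rownames(ds$values)[idx]
  out$values[idx, ] <- v
  out
}

#' Permute every cell of the expression matrix
#'
#' A uniform random permutation of all values across rows and columns; the
#' multiset of values is conserved exactly but all profile structure is
#' destroyed. The harshest of the dataset randomizations.
#'
#' @param ds an [expr_dataset()].
#' @param seed integer seed.
#' @return a new `expr_dataset` with permuted cells.
#' @export
permute_matrix <- function(ds, seed) {
  stopifnot(inherits(ds, "expr_dataset"))
  out <- ds
  out$values[] <- withr::with_seed(
    seed, sample(as.vector(ds$values)))
  out
}

#' Random expression values on a template design
#'
#' Keeps the template's genes, samples and time-point design but replaces
#' every value by an independent draw — by default uniform on
#' \[0, max(template)\].
#'
#' @param template an [expr_dataset()] providing shape and design.
#' @param seed integer seed.
#' @param rfun sampling rule: `function(n)` returning `n` non-negative
#'   values. Default: `runif(n, 0, max(template$values))`.
#' @return a new `expr_dataset` with random values.
#' @export
random_dataset <- function(template, seed, rfun = NULL) {
  stopifnot(inherits(template, "expr_dataset"))
  if (is.null(rfun)) {
    hi <- max(template$values)
    rfun <- function(n) stats::runif(n, 0, hi)
  }
  out <- template
  vals <- withr::with_seed(seed, rfun(length(template$values)))
  if (any(!is.finite(vals) | vals < 0))
    stop_trc("random value rule produced negative or non-finite values",
             class = "trc_value_error")
  out$values[] <- vals
  out
}

#' Cascade without the regulator restriction
#'
#' Runs the identical stage-assignment and cascade pipeline but lets every
#' dataset gene compete for a column, not just the background network's
#' source nodes. The ablation control: cascades built this way tend to be
#' overwhelmed by non-regulatory genes, which dilutes per-stage enrichment.
#'
#' @param ds an [expr_dataset()].
#' @param net the background [reg_network()] (still the source of edges).
#' @param params a [trc_params()].
#' @return a `trc` cascade.
#' @export
unrestricted_cascade <- function(ds, net, params = trc_params()) {
  assignment <- assign_stages(ds, regulators = rownames(ds$values),
                              params = params)
  build_cascade(assignment, net)
}
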