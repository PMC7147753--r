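#' Design of a planted-signal synthetic benchmark
#'
#' Describes a fixture emulating a differentiation time course: a minority
#' of regulator genes with single-time-point peak profiles planted one
#' stage each, a majority of background genes with flat noisy profiles
#' (log-normal baselines so the expression floor has realistic bite), a
#' background network containing the planted within-stage and
#' stage-to-next-stage edges plus random decoys, and annotations giving
#' each stage's planted set a dedicated term plus random terms.
#'
#' @param n_time time points (default 5, sampled on an irregular day grid).
#' @param n_replicates replicates per time point (default 2).
#' @param n_planted_per_stage planted regulators per stage (default 6).
#' @param n_background background genes (default 1200).
#' @param peak_height expression at a planted gene's peak time point
#'   (default 100, arbitrary normalized units).
#' @param baseline off-peak expression of planted genes (default 5; must be
#'   below `peak_height`).
#' @param noise_sd standard deviation of additive Gaussian noise, truncated
#'   at 0 (default 5).
#' @param density_within probability of a planted regulator -> same-stage
#'   regulator edge (default 0.4).
#' @param density_cross probability of a planted regulator -> next-stage
#'   regulator edge (default 0.4).
#' @param density_background probability of a decoy edge from a decoy
#'   source to any gene (default 0.02).
#' @param n_decoy_regulators background genes that also act as network
#'   sources (default 300) — the regulator pool must dwarf the cascade's
#'   seat count (`max_s` x time points), as a genome-scale TF catalogue
#'   dwarfs a real cascade.
#' @param term_extra_genes non-regulatory background genes added to each
#'   stage's planted term (default 12) — ontology terms are dominated by
#'   non-regulatory members, so a stage term's only TF members are its
#'   planted regulators, and the term is detectable in a cascade column
#'   only through them. Drawn from background genes that are not decoy
#'   regulators.
#' @param n_random_terms random annotation terms of 10-30 genes each
#'   (default 150) — enough for dense annotation coverage, so that cascade
#'   columns keep a realistic tested-term count and the Bonferroni
#'   correction has its usual bite; sparse annotation would let a single
#'   annotated gene dominate a column's enrichment.
#' @param seed integer seed making the fixture reproducible (default 1).
#' @return a list of class `planted_design`.
#' @export
planted_design <- function(n_time = 5, n_replicates = 2,
                           n_planted_per_stage = 6, n_background = 1200,
                           peak_height = 100, baseline = 5, noise_sd = 5,
                           density_within = 0.4, density_cross = 0.4,
                           density_background = 0.02,
                           n_decoy_regulators = 300, term_extra_genes = 12,
                           n_random_terms = 150, seed = 1) {
  d <- list(n_time = as.integer(n_time),
            n_replicates = as.integer(n_replicates),
            n_planted_per_stage = as.integer(n_planted_per_stage),
            n_background = as.integer(n_background),
            peak_height = peak_height, baseline = baseline,
            noise_sd = noise_sd, density_within = density_within,
            density_cross = density_cross,
            density_background = density_background,
            n_decoy_regulators = as.integer(n_decoy_regulators),
            term_extra_genes = as.integer(term_extra_genes),
            n_random_terms = as.integer(n_random_terms),
            seed = as.integer(seed))
  if (d$n_time < 2L)
    stop_trc("need >= 2 time points", class = "trc_parameter_error")
  if (d$n_replicates < 1L || d$n_planted_per_stage < 1L ||
      d$n_background < 0L || d$n_decoy_regulators > d$n_background ||
      d$term_extra_genes < 0L ||
      d$term_extra_genes * d$n_time >
        d$n_background - d$n_decoy_regulators)
    stop_trc("inconsistent counts in planted design",
             class = "trc_parameter_error")
  if (!(d$peak_height > d$baseline) || d$baseline < 0)
    stop_trc("need peak_height > baseline >= 0",
             class = "trc_parameter_error")
  if (d$noise_sd < 0)
    stop_trc("noise_sd must be >= 0", class = "trc_parameter_error")
  for (f in c("density_within", "density_cross", "density_background"))
    if (d[[f]] < 0 || d[[f]] > 1)
      stop_trc(f, " must lie in [0, 1]", class = "trc_parameter_error")
  structure(d, class = "planted_design")
}

#' Generate a planted-signal fixture
#'
#' Draws the dataset, network, annotations and ground-truth stage
#' assignment described by a [planted_design()]. With `noise_sd = 0` every
#' planted gene's profile is an exact affine image of its stage's template
#' peak pattern (correlation exactly 1) and background genes are constant
#' (undefined correlation), so the pipeline recovers the truth perfectly;
#' rising noise degrades recovery gracefully.
#'
#' Every planted regulator is guaranteed at least one outgoing network edge
#' so that it belongs to the regulator universe.
#'
#' @param design a [planted_design()].
#' @return list with elements `dataset` ([expr_dataset()]), `network`
#'   ([reg_network()]), `annotations` ([annotation_map()]), `truth` (named
#'   list: stage index -> planted gene symbols) and `design`.
#' @export
generate_planted <- function(design = planted_design()) {
  stopifnot(inherits(design, "planted_design"))
  d <- design
  withr::with_seed(d$seed, {
    day_grid <- c(0, 1, 2, 4, 5, 11, 18, 30)
    times <- if (d$n_time <= length(day_grid)) day_grid[seq_len(d$n_time)]
             else seq(0, by = 2, length.out = d$n_time)

    planted <- lapply(seq_len(d$n_time), function(s)
      sprintf("REG%d_%02d", s, seq_len(d$n_planted_per_stage)))
    names(planted) <- as.character(seq_len(d$n_time))
    bg <- sprintf("BG%04d", seq_len(d$n_background))
    genes <- c(unlist(planted, use.names = FALSE), bg)
    decoys <- if (d$n_decoy_regulators > 0L)
      sample(bg, d$n_decoy_regulators) else character()

    n_samp <- d$n_time * d$n_replicates
    time_of_col <- rep(times, each = d$n_replicates)
    stage_of_col <- rep(seq_len(d$n_time), each = d$n_replicates)
    labels <- sprintf("d%g_r%d", time_of_col,
                      rep(seq_len(d$n_replicates), times = d$n_time))

    values <- matrix(0, nrow = length(genes), ncol = n_samp,
                     dimnames = list(genes, labels))
    for (s in seq_len(d$n_time)) {
      prof <- rep(d$baseline, n_samp)
      prof[stage_of_col == s] <- d$peak_height
      for (g in planted[[s]]) values[g, ] <- prof
    }
    if (d$n_background > 0L) {
      bg_base <- stats::rlnorm(d$n_background, meanlog = log(20), sdlog = 1)
      values[bg, ] <- matrix(rep(bg_base, n_samp), ncol = n_samp)
    }
    if (d$noise_sd > 0)
      values <- pmax(values + matrix(
        stats::rnorm(length(values), sd = d$noise_sd),
        nrow = nrow(values)), 0)

    # network: planted within-stage and stage -> next-stage edges plus
    # random decoys; each planted gene gets one guaranteed outgoing edge
    edges <- list()
    add <- function(src, tgt) {
      if (length(src) > 0L)
        edges[[length(edges) + 1L]] <<- data.frame(
          regulator = src, target = tgt, stringsAsFactors = FALSE)
    }
    for (s in seq_len(d$n_time)) {
      ps <- planted[[s]]
      pairs <- expand.grid(regulator = ps, target = ps,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
      keep <- stats::runif(nrow(pairs)) < d$density_within
      add(pairs$regulator[keep], pairs$target[keep])
      if (s < d$n_time) {
        nxt <- planted[[s + 1L]]
        pairs <- expand.grid(regulator = ps, target = nxt,
                             stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(pairs)) < d$density_cross
        add(pairs$regulator[keep], pairs$target[keep])
      }
    }
    all_planted <- unlist(planted, use.names = FALSE)
    anchor_targets <- if (d$n_background > 0L)
      sample(bg, length(all_planted), replace = TRUE)
    else sample(all_planted)
    add(all_planted, anchor_targets)
    if (length(decoys) > 0L) {
      for (g in decoys) {
        tgt <- genes[stats::runif(length(genes)) < d$density_background]
        tgt <- setdiff(tgt, g)
        if (length(tgt) == 0L) tgt <- sample(setdiff(genes, g), 1L)
        add(rep(g, length(tgt)), tgt)
      }
    }
    network <- reg_network(do.call(rbind, edges))

    terms <- stats::setNames(planted,
                             sprintf("GO:S%03d", seq_len(d$n_time)))
    if (d$term_extra_genes > 0L && d$n_background > 0L) {
      # disjoint non-regulatory members so each term stays distinguishable
      # and reaches a cascade column only through its planted regulators
      extras <- split(sample(setdiff(bg, decoys),
                             d$term_extra_genes * d$n_time),
                      rep(seq_len(d$n_time), each = d$term_extra_genes))
      for (s in seq_len(d$n_time))
        terms[[s]] <- c(terms[[s]], extras[[s]])
    }
    term_names <- stats::setNames(
      sprintf("stage %d planted program", seq_len(d$n_time)), names(terms))
    if (d$n_random_terms > 0L) {
      for (i in seq_len(d$n_random_terms)) {
        id <- sprintf("GO:R%03d", i)
        terms[[id]] <- sample(genes, min(length(genes), sample(10:30, 1L)))
        term_names[[id]] <- sprintf("random process %d", i)
      }
    }
    annotations <- annotation_map(terms, term_names)

    ds <- expr_dataset(values, time = time_of_col,
                       replicate = rep(seq_len(d$n_replicates), d$n_time))
    list(dataset = ds, network = network, annotations = annotations,
         truth = planted, design = d)
  })
}

#' Precision and recall of a cascade against a planted truth
#'
#' A retrieved (gene, stage) pair counts as correct when the truth planted
#' that gene at that stage.
#'
#' @param x a `trc` cascade or `stage_assignment`.
#' @param truth named list: stage index (as character) -> planted genes.
#' @return list with `precision`, `recall`, `n_retrieved`, `n_planted`
#'   (empty retrievals score precision 1 by convention).
#' @export
score_recovery <- function(x, truth) {
  if (inherits(x, "trc")) {
    pairs <- paste(x$nodes$stage, x$nodes$gene)
  } else if (inherits(x, "stage_assignment")) {
    pairs <- unlist(lapply(seq_along(x$stages), function(s)
      if (nrow(x$stages[[s]]) > 0L) paste(s, x$stages[[s]]$gene)),
      use.names = FALSE)
    pairs <- pairs %||% character()
  } else {
    stop_trc("expected a 'trc' or 'stage_assignment'",
             class = "trc_usage_error")
  }
  truth_pairs <- unlist(lapply(names(truth), function(s)
    paste(as.integer(s), normalize_symbols(truth[[s]]))), use.names = FALSE)
  hit <- sum(pairs %in% truth_pairs)
  list(precision = if (length(pairs) == 0L) 1 else hit / length(pairs),
       recall = if (length(truth_pairs) == 0L) 1 else hit / length(truth_pairs),
       n_retrieved = length(pairs), n_planted = length(truth_pairs))
}

#' Materialize a demo fixture on disk
#'
#' Writes the four artifacts of [generate_planted()] in the package's
#' standard text formats: `expression.csv`, `network.tsv`,
#' `annotations.gmt` and `truth.tsv` (the planted stage assignment).
#'
#' @param dir output directory (created if missing).
#' @param design a [planted_design()].
#' @return named character vector of the four file paths, invisibly.
#' @export
demo_fixture <- function(dir, design = planted_design()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_planted(design)
  paths <- c(expression = file.path(dir, "expression.csv"),
             network = file.path(dir, "network.tsv"),
             annotations = file.path(dir, "annotations.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(fx$dataset, paths[["expression"]])
  write_network(fx$network, paths[["network"]])
  write_annotations(fx$annotations, paths[["annotations"]])
  truth_lines <- unlist(lapply(names(fx$truth), function(s)
    paste(s, fx$truth[[s]], sep = "\t")), use.names = FALSE)
  writeLines(c("stage\tgene", truth_lines), paths[["truth"]])
  invisible(paths)
}
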