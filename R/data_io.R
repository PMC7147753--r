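#' Construct a time-series expression dataset
#'
#' The container for all expression input: a non-negative genes x samples
#' matrix together with a design mapping every sample to one
#' (time point, replicate) pair. Time points are ordered ascending; the
#' algorithm only ever uses their order, the numeric values are kept for
#' labelling.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample labels). All values must be
#'   finite and >= 0.
#' @param time numeric or character vector, one entry per column: the time
#'   point of that sample. Coerced to numeric when possible, otherwise
#'   ranked by first appearance.
#' @param replicate integer vector, one entry per column (default: numbered
#'   within each time point in column order).
#' @return an object of class `expr_dataset` with elements `values`
#'   (matrix, rownames normalized), `design` (data.frame with columns
#'   `sample`, `time_value`, `time_index`, `replicate`), `time_values`
#'   (sorted unique time values) and `display_names` (original gene
#'   spellings, named by normalized symbol).
#' @export
expr_dataset <- function(values, time, replicate = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_trc("'values' must be a numeric matrix", class = "trc_format_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_trc("'values' needs both row (gene) and column (sample) names",
             class = "trc_format_error")
  if (length(time) != ncol(values))
    stop_trc("'time' must have one entry per sample column",
             class = "trc_design_error")

  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_trc("non-finite or negative expression value at gene '",
             rownames(values)[bad[1L, 1L]], "', sample '",
             colnames(values)[bad[1L, 2L]], "'", class = "trc_value_error")

  display <- rownames(values)
  norm <- normalize_symbols(display)
  dup <- norm[duplicated(norm)]
  if (length(dup) > 0L)
    stop_trc("duplicated gene symbol(s) after normalization: ",
             paste(unique(dup), collapse = ", "), class = "trc_value_error")
  rownames(values) <- norm
  display_names <- stats::setNames(display, norm)

  time_num <- suppressWarnings(as.numeric(time))
  if (anyNA(time_num)) {
    # non-numeric labels: rank by first appearance (column order)
    time_num <- as.numeric(match(as.character(time), unique(as.character(time))))
  }
  time_values <- sort(unique(time_num))
  if (length(time_values) < 2L)
    stop_trc("a time-series design needs at least 2 distinct time points",
             class = "trc_design_error")
  time_index <- match(time_num, time_values)

  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(time_index), time_index, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (length(replicate) != ncol(values))
    stop_trc("'replicate' must have one entry per sample column",
             class = "trc_design_error")
  if (anyDuplicated(paste(time_index, replicate)))
    stop_trc("two samples share the same (time point, replicate) pair",
             class = "trc_design_error")

  design <- data.frame(sample = colnames(values),
                       time_value = time_num,
                       time_index = time_index,
                       replicate = replicate,
                       stringsAsFactors = FALSE)
  structure(list(values = values, design = design,
                 time_values = time_values, display_names = display_names),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d genes x %d samples, %d time points (%s)\n",
              nrow(x$values), ncol(x$values), length(x$time_values),
              paste(x$time_values, collapse = ", ")))
  invisible(x)
}

#' Number of time points of a dataset
#' @param ds an `expr_dataset`.
#' @return integer, the number of distinct time points.
#' @export
n_time_points <- function(ds) length(ds$time_values)

# Parse a vector of sample labels into (time, replicate) according to a
# design specification.
parse_design_spec <- function(labels, design_spec) {
  if (is.data.frame(design_spec)) {
    need <- c("sample", "time")
    if (!all(need %in% names(design_spec)))
      stop_trc("sidecar design table needs columns 'sample' and 'time'",
               class = "trc_design_error")
    idx <- match(labels, design_spec$sample)
    if (anyNA(idx))
      stop_trc("sample(s) missing from design table: ",
               paste(labels[is.na(idx)], collapse = ", "),
               class = "trc_design_error")
    rep <- if ("replicate" %in% names(design_spec))
      design_spec$replicate[idx] else NULL
    return(list(time = design_spec$time[idx], replicate = rep))
  }
  if (is.character(design_spec) && length(design_spec) == 1L) {
    m <- regmatches(labels, regexec(design_spec, labels))
    ok <- lengths(m) >= 2L
    if (!all(ok))
      stop_trc("design pattern did not match sample label(s): ",
               paste(labels[!ok], collapse = ", "), class = "trc_design_error")
    time <- vapply(m, `[`, character(1), 2L)
    rep <- if (all(lengths(m) >= 3L))
      as.integer(vapply(m, `[`, character(1), 3L)) else NULL
    return(list(time = time, replicate = rep))
  }
  # auto: first numeric run in the label is the time point, an optional
  # second run is the replicate ("d0_r2" -> time 0, replicate 2)
  nums <- regmatches(labels, gregexpr("[0-9]+(\\.[0-9]+)?", labels))
  if (any(lengths(nums) == 0L)) {
    # unparseable labels: one time point per column in order
    return(list(time = seq_along(labels), replicate = rep(1L, length(labels))))
  }
  time <- as.numeric(vapply(nums, `[`, character(1), 1L))
  rep <- ifelse(lengths(nums) >= 2L,
                vapply(nums, function(v) v[2L], character(1)), NA)
  rep <- suppressWarnings(as.integer(rep))
  if (anyNA(rep)) rep <- NULL
  list(time = time, replicate = rep)
}

#' Read a time-series expression matrix
#'
#' Reads a delimited text matrix (first column gene symbols, header row
#' sample labels; comma, tab or semicolon delimited — auto-detected) and
#' parses the sample labels into a (time point, replicate) design.
#'
#' @param path path to the delimited matrix.
#' @param design_spec how to obtain the design from the sample labels: `NULL`
#'   (default) extracts the first number in each label as the time point and
#'   an optional second number as the replicate; a single regular expression
#'   with one (time) or two (time, replicate) capture groups; or a
#'   data.frame with columns `sample`, `time` and optionally `replicate`.
#' @return an [expr_dataset()].
#' @export
read_expression <- function(path, design_spec = NULL) {
  if (!file.exists(path))
    stop_trc("expression file not found: ", path, class = "trc_usage_error")
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 3L)
    stop_trc("expression matrix needs a gene column and >= 2 sample columns",
             class = "trc_format_error")
  # a header whose sample fields are all plain numbers is almost certainly a
  # data row: the file is missing its header
  heads <- colnames(raw)[-1L]
  if (all(!is.na(suppressWarnings(as.numeric(heads)))))
    stop_trc("expression file appears to have no header row (all column ",
             "names are numeric)", class = "trc_format_error")

  genes <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]])) {
      i <- which(is.na(v))[1L]
      stop_trc("non-numeric expression value at gene '", genes[i],
               "', column '", colnames(vals)[j], "'",
               class = "trc_value_error")
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes

  dupn <- normalize_symbols(genes)
  if (anyDuplicated(dupn))
    stop_trc("duplicated gene row(s): ",
             paste(unique(dupn[duplicated(dupn)]), collapse = ", "),
             class = "trc_value_error")

  spec <- parse_design_spec(colnames(mat), design_spec)
  expr_dataset(mat, time = spec$time, replicate = spec$replicate)
}

#' Write an expression dataset back to delimited text
#'
#' Inverse of [read_expression()]: values are written at full double
#' precision so a write/read round trip reproduces the matrix exactly.
#'
#' @param ds an `expr_dataset`.
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, sep = ",") {
  header <- paste(c("gene", colnames(ds$values)), collapse = sep)
  disp <- ds$display_names[rownames(ds$values)]
  rows <- vapply(seq_len(nrow(ds$values)), function(i) {
    paste(c(disp[i], format_full_precision(ds$values[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a directed regulatory edge list
#'
#' Two-column delimited text, one `regulator target` edge per line.
#' Duplicate edges are collapsed; self-edges are retained (a transcription
#' factor may bind its own promoter).
#'
#' @param path path to the edge list.
#' @return data.frame with character columns `regulator` and `target`
#'   (symbols normalized), one row per unique edge.
#' @export
read_network_edges <- function(path) {
  if (!file.exists(path))
    stop_trc("network file not found: ", path, class = "trc_usage_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty network file: ", path)
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- detect_delimiter(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L)
    stop_trc("network line ", bad[1L], " has ", lengths(fields)[bad[1L]],
             " fields (expected 2)", class = "trc_format_error")
  edges <- data.frame(
    regulator = normalize_symbols(vapply(fields, `[`, character(1), 1L)),
    target = normalize_symbols(vapply(fields, `[`, character(1), 2L)),
    stringsAsFactors = FALSE)
  unique(edges)
}

#' Construct an annotation map
#'
#' @param term_to_genes named list: term id -> character vector of gene
#'   symbols. Terms with zero genes are dropped with a warning.
#' @param term_names optional named character vector of term labels.
#' @return an object of class `annotation_map`.
#' @export
annotation_map <- function(term_to_genes, term_names = NULL) {
  term_to_genes <- lapply(term_to_genes, function(g)
    unique(normalize_symbols(g[nzchar(trimws(g))])))
  empty <- lengths(term_to_genes) == 0L
  if (any(empty)) {
    warning(sum(empty), " annotation term(s) with zero genes dropped")
    term_to_genes <- term_to_genes[!empty]
  }
  if (is.null(term_names))
    term_names <- stats::setNames(names(term_to_genes), names(term_to_genes))
  structure(list(term_to_genes = term_to_genes,
                 term_names = term_names[names(term_to_genes)]),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms, %d distinct genes\n",
              length(x$term_to_genes),
              length(unique(unlist(x$term_to_genes, use.names = FALSE)))))
  invisible(x)
}

#' Read a gene/GO annotation map
#'
#' Supports two layouts: GMT (one term per line: id, description, then
#' member genes) and two-column pairs (gene, term) or (term, gene) — for the
#' two-column layout the term column is taken to be the one whose values
#' look like ontology ids (contain a colon) or, failing that, the second
#' column.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (default), `"gmt"` or `"two-column"`.
#' @return an [annotation_map()].
#' @export
read_annotations <- function(path, format = c("auto", "gmt", "two-column")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_trc("annotation file not found: ", path, class = "trc_usage_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(annotation_map(list()))
  sep <- detect_delimiter(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (format == "auto")
    format <- if (any(lengths(fields) > 2L)) "gmt" else "two-column"

  if (format == "gmt") {
    bad <- which(lengths(fields) < 3L)
    if (length(bad) > 0L)
      stop_trc("GMT line ", bad[1L], " has fewer than 3 fields",
               class = "trc_format_error")
    ids <- vapply(fields, `[`, character(1), 1L)
    labels <- stats::setNames(vapply(fields, `[`, character(1), 2L), ids)
    genes <- lapply(fields, function(f) f[-(1:2)])
    names(genes) <- ids
    return(annotation_map(genes, labels))
  }

  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L)
    stop_trc("annotation line ", bad[1L], " has ", lengths(fields)[bad[1L]],
             " fields (expected 2)", class = "trc_format_error")
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  # decide which column holds the term ids
  if (mean(grepl(":", b, fixed = TRUE)) >= mean(grepl(":", a, fixed = TRUE))) {
    term <- b; gene <- a
  } else {
    term <- a; gene <- b
  }
  annotation_map(split(gene, term))
}

#' Write an annotation map
#'
#' @param map an `annotation_map`.
#' @param path output path.
#' @param format `"gmt"` (default) or `"two-column"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(map, path, format = c("gmt", "two-column")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- vapply(names(map$term_to_genes), function(id) {
      paste(c(id, unname(map$term_names[id]), map$term_to_genes[[id]]),
            collapse = "\t")
    }, character(1))
  } else {
    lines <- unlist(lapply(names(map$term_to_genes), function(id)
      paste(map$term_to_genes[[id]], id, sep = "\t")), use.names = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}
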