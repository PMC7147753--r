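# Small in-code fixtures shared across test files.

# a 3-gene x 4-time-point single-replicate dataset
tiny_dataset <- function() {
  m <- matrix(c(0, 100, 0, 0,
                5, 5, 5, 5,
                1, 9, 2, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("PEAKY", "FLAT", "NOISY"),
                              c("T0", "T1", "T2", "T4")))
  expr_dataset(m, time = c(0, 1, 2, 4))
}

tiny_network <- function() {
  reg_network(data.frame(regulator = c("A", "B", "A"),
                         target = c("B", "C", "A"),
                         stringsAsFactors = FALSE))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# dataset with per-stage one-hot regulators on a given time grid
onehot_dataset <- function(n_time = 4, peak = 100) {
  genes <- sprintf("R%d", seq_len(n_time))
  m <- diag(peak, n_time)
  dimnames(m) <- list(genes, sprintf("t%d", seq_len(n_time)))
  expr_dataset(m, time = seq_len(n_time))
}

# a scaled-down planted design for fast structural tests
small_design <- function(...) {
  planted_design(n_background = 60, n_decoy_regulators = 12,
                 n_planted_per_stage = 4, term_extra_genes = 5, ...)
}

# brute-force hypergeometric upper tail from first principles
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
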