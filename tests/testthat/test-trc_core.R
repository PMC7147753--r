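test_that("replicate collapsing averages within time points", {
  m <- matrix(c(2, 4, 6, 8,
                1, 1, 1, 1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("d0_r1", "d0_r2", "d2_r1", "d2_r2")))
  ds <- expr_dataset(m, time = c(0, 0, 2, 2), replicate = c(1, 2, 1, 2))
  col <- collapse_replicates(ds)
  expect_equal(unname(col["G1", ]), c(3, 7))
  expect_equal(unname(col["G2", ]), c(1, 1))

  # single replicate: identity on values
  ds1 <- tiny_dataset()
  expect_equal(unname(collapse_replicates(ds1)), unname(ds1$values))
})

test_that("the TPP library is one one-hot template per time point", {
  lib <- tpp_library(4)
  expect_equal(dim(lib), c(4L, 4L))
  expect_equal(unname(lib[2, ]), c(0, 100, 0, 0))
  expect_true(all(rowSums(lib > 0) == 1))
  expect_equal(unname(tpp_library(2)), rbind(c(100, 0), c(0, 100)))
  expect_error(tpp_library(1), class = "trc_design_error")
})

test_that("profile-to-template correlation matches the expected values", {
  tpp2 <- tpp_library(4)[2, ]
  expect_equal(correlate_to_tpp(c(0, 100, 0, 0), tpp2), 1)
  expect_true(is.na(correlate_to_tpp(c(5, 5, 5, 5), tpp2)))
  # frozen oracle: r = (x_s - mean) / (sd_pop * sqrt(T-1)) = 6 / sqrt(37.5)
  expect_equal(correlate_to_tpp(c(1, 9, 2, 0), tpp2), 6 / sqrt(37.5),
               tolerance = 1e-12)
  expect_error(correlate_to_tpp(c(1, 2), tpp2),
               class = "trc_dimension_error")
})

test_that("correlations obey the closed form and the conservation law", {
  set.seed(11)
  for (T in c(3, 5, 8)) {
    x <- matrix(rexp(200 * T), ncol = T,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    r <- suppressWarnings(stats::cor(t(x), t(tpp_library(T))))
    mu <- rowMeans(x)
    sd_pop <- sqrt(rowMeans((x - mu)^2))
    closed <- (x - mu) / (sd_pop * sqrt(T - 1))
    expect_lt(max(abs(r - closed)), 1e-10)
    expect_lt(max(abs(rowSums(r^2) - T / (T - 1))), 1e-10)
  }
})

test_that("template encoding (100 vs 1) cannot change any correlation", {
  set.seed(12)
  x <- rexp(5)
  onehot <- as.numeric(seq_len(5) == 3)
  expect_equal(correlate_to_tpp(x, 100 * onehot),
               correlate_to_tpp(x, onehot))
  # and positive affine transforms of the profile preserve r too
  expect_equal(correlate_to_tpp(3 * x + 7, 100 * onehot),
               correlate_to_tpp(x, 100 * onehot))
})

test_that("stage assignment applies min_e strictly on raw replicate values", {
  m <- rbind(AT_FLOOR = c(4, 4, 4, 4),
             ABOVE = c(0, 4.5, 0, 0),
             PEAKY = c(0, 100, 0, 0))
  colnames(m) <- sprintf("t%d", 1:4)
  ds <- expr_dataset(m, time = 1:4)
  a <- assign_stages(ds, rownames(m), trc_params(min_e = 4, min_c = 0.6))
  got <- unlist(lapply(a$stages, function(s) s$gene), use.names = FALSE)
  expect_false("AT_FLOOR" %in% got)   # max value == min_e: eliminated
  expect_setequal(got, c("ABOVE", "PEAKY"))
  expect_equal(a$log$n_failing_min_e, 1L)
})

test_that("one-hot regulators each land in their own stage with r = 1", {
  ds <- onehot_dataset(4)
  a <- assign_stages(ds, sprintf("R%d", 1:4),
                     trc_params(min_e = 4, min_c = 0.6, max_s = 10))
  for (s in 1:4) {
    expect_equal(a$stages[[s]]$gene, sprintf("R%d", s))
    expect_equal(a$stages[[s]]$correlation, 1)
  }
})

test_that("max_s keeps exactly the top-correlated regulators of a stage", {
  set.seed(3)
  n <- 15
  genes <- sprintf("G%02d", seq_len(n))
  # all peak at time 2 with different sharpness -> different correlations
  m <- t(vapply(seq_len(n), function(i)
    c(runif(1, 0, 30), 100, runif(1, 0, 30), runif(1, 0, 30)),
    numeric(4)))
  dimnames(m) <- list(genes, sprintf("t%d", 1:4))
  ds <- expr_dataset(m, time = 1:4)
  a <- assign_stages(ds, genes, trc_params(min_e = 4, min_c = 0.6,
                                           max_s = 10))
  expect_equal(nrow(a$stages[[2]]), 10L)
  # brute-force ranking oracle
  r <- apply(m, 1, function(x) cor(x, c(0, 100, 0, 0)))
  expect_equal(a$stages[[2]]$gene, names(sort(r, decreasing = TRUE))[1:10])
  expect_equal(a$stages[[2]]$correlation, unname(sort(r, TRUE))[1:10])
})

test_that("a gene is assigned to one stage only and constants are dropped", {
  # at T=2 a one-hot profile has |r| = 1 to both templates (r and -r);
  # the argmax rule must place it once, at its peak
  m <- rbind(G1 = c(9, 1), CONST = c(5, 5))
  colnames(m) <- c("t1", "t2")
  ds <- expr_dataset(m, time = 1:2)
  a <- assign_stages(ds, rownames(m), trc_params(min_e = 0, min_c = 0.6))
  expect_equal(a$stages[[1]]$gene, "G1")
  expect_equal(nrow(a$stages[[2]]), 0L)
  expect_equal(a$log$n_zero_variance, 1L)
  expect_error(assign_stages(ds, character()), class = "trc_usage_error")
})

test_that("cascade edges come from the network, within and to the next column", {
  ds <- onehot_dataset(3)
  a <- assign_stages(ds, sprintf("R%d", 1:3),
                     trc_params(min_e = 4, min_c = 0.6))
  # R1 -> R2 is consecutive; R1 -> R3 skips the non-empty stage 2: excluded
  net <- reg_network(data.frame(regulator = c("R1", "R1"),
                                target = c("R2", "R3")))
  cas <- build_cascade(a, net)
  expect_equal(nrow(cas$edges), 1L)
  expect_equal(cas$edges$source, "R1")
  expect_equal(cas$edges$target, "R2")
  expect_equal(cas$edges$type, "cross")

  # empty network: columns survive, no edges
  cas0 <- build_cascade(a, reg_network(
    data.frame(regulator = character(), target = character())))
  expect_equal(nrow(cas0$nodes), 3L)
  expect_equal(nrow(cas0$edges), 0L)
})

test_that("empty stages are skipped and cross edges bridge the gap", {
  m <- rbind(R1 = c(100, 0, 0), R3 = c(0, 0, 100))
  colnames(m) <- sprintf("t%d", 1:3)
  ds <- expr_dataset(m, time = 1:3)
  a <- assign_stages(ds, c("R1", "R3"), trc_params(min_e = 4, min_c = 0.6))
  expect_equal(nrow(a$stages[[2]]), 0L)
  net <- reg_network(data.frame(regulator = "R1", target = "R3"))
  cas <- build_cascade(a, net)
  expect_equal(cas$stage_indices, c(1L, 3L))
  expect_equal(nrow(cas$edges), 1L)       # stage 1 -> stage 3 bridges day 2
  expect_equal(cas$edges$target_stage, 3L)
  expect_equal(cas$edges$type, "cross")
})

test_that("node metrics count degrees on the cascade graph only", {
  ds <- onehot_dataset(2)
  a <- assign_stages(ds, c("R1", "R2"), trc_params(min_e = 4, min_c = 0.6))
  net <- reg_network(data.frame(regulator = c("R1", "R1", "X"),
                                target = c("R2", "Z", "R2")))
  cas <- build_cascade(a, net)   # only R1 -> R2 survives
  n <- cas$nodes
  expect_equal(n$outdegree[n$gene == "R1"], 1L)
  expect_equal(n$indegree[n$gene == "R2"], 1L)
  expect_equal(n$indegree[n$gene == "R1"], 0L)
})

test_that("interaction patterns label one-way, reciprocal and cross edges", {
  m <- rbind(X = c(100, 0), Y = c(90, 5), Z = c(0, 100))
  colnames(m) <- c("t1", "t2")
  ds <- expr_dataset(m, time = 1:2)
  a <- assign_stages(ds, c("X", "Y", "Z"), trc_params(min_e = 0, min_c = 0.6))
  net <- reg_network(data.frame(regulator = c("X", "Y", "X", "X"),
                                target = c("Y", "X", "Z", "X")))
  cas <- build_cascade(a, net)
  cls <- classify_interactions(cas)
  e <- cls$edges
  expect_equal(e$pattern[e$source == "X" & e$target == "Y"], "reciprocal")
  expect_equal(e$pattern[e$source == "Y" & e$target == "X"], "reciprocal")
  expect_equal(e$pattern[e$source == "X" & e$target == "X"], "one-way")
  expect_equal(e$pattern[e$source == "X" & e$target == "Z"], "cross-stage")
  fan <- cls$nodes
  expect_equal(fan$within_out_fan[fan$gene == "X"], 2L)  # X->Y, X->X
  expect_equal(fan$cross_out_fan[fan$gene == "X"], 1L)   # X->Z
  expect_equal(fan$gene[1], "X")                         # top master score

  empty <- build_cascade(a, reg_network(
    data.frame(regulator = character(), target = character())))
  cls0 <- classify_interactions(empty)
  expect_equal(nrow(cls0$edges), 0L)
})

test_that("cascade export round-trips and SIF/JSON have the right shape", {
  ds <- onehot_dataset(2)
  a <- assign_stages(ds, c("R1", "R2"), trc_params(min_e = 4, min_c = 0.6))
  net <- reg_network(data.frame(regulator = "R1", target = "R2"))
  cas <- build_cascade(a, net)

  et <- withr::local_tempfile(fileext = ".tsv")
  export_cascade(cas, et, "edge-table")
  back <- import_cascade_edge_table(et)
  expect_equal(back$nodes, cas$nodes)
  expect_equal(back$edges, cas$edges)
  expect_equal(back$stage_indices, cas$stage_indices)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_cascade(cas, sif, "sif")
  expect_equal(readLines(sif), "R1\tregulates\tR2")

  js <- withr::local_tempfile(fileext = ".json")
  export_cascade(cas, js, "cytoscape-json")
  parsed <- jsonlite::read_json(js)
  expect_length(parsed$elements$nodes, 2L)
  expect_length(parsed$elements$edges, 1L)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_cascade(cas, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)

  expect_error(export_cascade(cas, et, "dot"))
})

test_that("an empty cascade still exports valid files", {
  ds <- onehot_dataset(2)
  a <- assign_stages(ds, "ABSENT", trc_params(min_e = 4, min_c = 0.6))
  cas <- build_cascade(a, tiny_network())
  expect_equal(nrow(cas$nodes), 0L)
  et <- withr::local_tempfile(fileext = ".tsv")
  export_cascade(cas, et, "edge-table")
  back <- import_cascade_edge_table(et)
  expect_equal(nrow(back$nodes), 0L)
  expect_equal(nrow(back$edges), 0L)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_cascade(cas, sif, "sif")
  expect_equal(length(readLines(sif)), 0L)
})
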