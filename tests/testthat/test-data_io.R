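test_that("expression matrices parse with single-replicate and replicated designs", {
  p <- write_lines_tmp(c("gene,T0,T1,T2,T4",
                         "g1,1,2,3,4",
                         "g2,0,0,5,0",
                         "g3,2,2,2,2"), ext = ".csv")
  ds <- read_expression(p)
  expect_s3_class(ds, "expr_dataset")
  expect_equal(ds$time_values, c(0, 1, 2, 4))
  expect_equal(ds$design$replicate, rep(1L, 4))
  expect_equal(unname(ds$values["G1", ]), c(1, 2, 3, 4))

  p2 <- write_lines_tmp(c("gene\td0_r1\td0_r2\td2_r1\td2_r2",
                          "g1\t1\t3\t5\t7",
                          "g2\t2\t2\t2\t2"))
  ds2 <- read_expression(p2)
  expect_equal(ds2$time_values, c(0, 2))
  expect_equal(ds2$design$time_index, c(1L, 1L, 2L, 2L))
  expect_equal(ds2$design$replicate, c(1L, 2L, 1L, 2L))
  # sample count equals the sum of replicate counts over time points
  expect_equal(ncol(ds2$values),
               sum(table(ds2$design$time_index)))
})

test_that("malformed expression input is rejected with a pointed error", {
  dup <- write_lines_tmp(c("gene,T0,T1", "g1,1,2", "G1,3,4"), ext = ".csv")
  expect_error(read_expression(dup), "G1", class = "trc_value_error")

  neg <- write_lines_tmp(c("gene,T0,T1", "g1,1,-2"), ext = ".csv")
  expect_error(read_expression(neg), "g1", class = "trc_value_error")

  txt <- write_lines_tmp(c("gene,T0,T1", "g1,1,abc"), ext = ".csv")
  expect_error(read_expression(txt), "g1", class = "trc_value_error")

  nohead <- write_lines_tmp(c("g1,1,2", "g2,3,4"), ext = ".csv")
  expect_error(read_expression(nohead), "header",
               class = "trc_format_error")

  onetime <- write_lines_tmp(c("gene,d1_r1,d1_r2", "g1,1,2"), ext = ".csv")
  expect_error(read_expression(onetime), class = "trc_design_error")
})

test_that("write_expression / read_expression round-trips values exactly", {
  ds <- tiny_dataset()
  ds$values["NOISY", 2] <- pi * 1e3  # value with no short decimal form
  p <- withr::local_tempfile(fileext = ".csv")
  write_expression(ds, p)
  back <- read_expression(p)
  expect_identical(back$values, ds$values)
  expect_equal(back$time_values, ds$time_values)
})

test_that("network edge lists deduplicate and keep self-edges", {
  p <- write_lines_tmp(c("A\tB", "A\tB", "A\tA"))
  e <- read_network_edges(p)
  expect_equal(nrow(e), 2L)
  expect_true(any(e$regulator == "A" & e$target == "A"))

  bad <- write_lines_tmp(c("A\tB", "A\tB\tC"))
  expect_error(read_network_edges(bad), "line 2",
               class = "trc_format_error")

  empty <- write_lines_tmp(character())
  expect_warning(e0 <- read_network_edges(empty), "empty")
  expect_equal(nrow(e0), 0L)
})

test_that("GMT and two-column annotations yield the same map", {
  gmt <- write_lines_tmp(c("GO:1\tdesc\tg1\tg2", "GO:2\tother\tg3"))
  two <- write_lines_tmp(c("g1\tGO:1", "g2\tGO:1", "g3\tGO:2"))
  m1 <- read_annotations(gmt)
  m2 <- read_annotations(two)
  expect_equal(lapply(m1$term_to_genes, sort),
               lapply(m2$term_to_genes, sort))
  expect_equal(unname(m1$term_names["GO:1"]), "desc")
})

test_that("annotation terms with zero genes are dropped with a warning", {
  expect_warning(m <- annotation_map(list(`GO:1` = c("g1"),
                                          `GO:2` = character())),
                 "zero genes")
  expect_equal(names(m$term_to_genes), "GO:1")
})

test_that("annotation maps survive a GMT write/read round trip", {
  m <- annotation_map(list(`GO:1` = c("g1", "g2"), `GO:2` = "g3"),
                      c(`GO:1` = "one", `GO:2` = "two"))
  p <- withr::local_tempfile(fileext = ".gmt")
  write_annotations(m, p)
  back <- read_annotations(p)
  expect_equal(back$term_to_genes, m$term_to_genes)
  expect_equal(back$term_names, m$term_names)
})
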