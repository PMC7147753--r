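test_that("per-PWM top-fraction retention keeps the best-scoring sites", {
  pred <- data.frame(pwm_id = "V$M1",
                     target = sprintf("T%03d", 1:100),
                     score = seq(1, 0.01, length.out = 100))
  map <- data.frame(pwm_id = "V$M1", regulator = "TF1")
  net <- build_network(pred, map, top_fraction = 0.05)
  expect_equal(nrow(net$edges), 5L)
  # brute force: the retained targets are exactly the 5 highest scores
  expect_setequal(net$edges$target,
                  pred$target[order(-pred$score)][1:5])

  small <- pred[1:10, ]
  expect_equal(nrow(build_network(small, map, 0.05)$edges), 1L)
  expect_equal(build_network(small, map, 0.05)$edges$target,
               small$target[which.max(small$score)])

  all_in <- build_network(pred, map, top_fraction = 1)
  expect_equal(nrow(all_in$edges), 100L)
})

test_that("one PWM fans out to all mapped regulator genes", {
  pred <- data.frame(pwm_id = "M", target = c("X", "Y"), score = c(2, 1))
  map <- data.frame(pwm_id = c("M", "M"), regulator = c("TFA", "TFB"))
  net <- build_network(pred, map, top_fraction = 1)
  expect_setequal(paste(net$edges$regulator, net$edges$target),
                  c("TFA X", "TFA Y", "TFB X", "TFB Y"))
})

test_that("unmapped PWMs are skipped and bad parameters rejected", {
  pred <- data.frame(pwm_id = c("M1", "M2"), target = c("X", "Y"),
                     score = c(1, 1))
  map <- data.frame(pwm_id = "M1", regulator = "TF1")
  expect_message(net <- build_network(pred, map, 1), "1 PWM")
  expect_equal(attr(net, "skipped_pwms"), 1L)
  expect_equal(net$edges$target, "X")

  expect_error(build_network(pred, map, 0), class = "trc_parameter_error")
  expect_error(build_network(pred, map, 1.2), class = "trc_parameter_error")
  expect_error(build_network(pred, data.frame(pwm_id = character(),
                                              regulator = character()), 0.5),
               class = "trc_parameter_error")
})

test_that("retained count per PWM equals min(n, max(1, ceiling(f*n)))", {
  set.seed(42)
  for (f in c(0.07, 0.33)) {
    for (n in c(1, 2, 3, 19, 20, 21, 50)) {
      pred <- data.frame(pwm_id = "M",
                         target = sprintf("T%03d", seq_len(n)),
                         score = sample(seq_len(n)))
      net <- build_network(pred, data.frame(pwm_id = "M", regulator = "G"),
                           top_fraction = f)
      expect_equal(nrow(net$edges), min(n, max(1, ceiling(f * n))),
                   info = sprintf("f=%g n=%d", f, n))
    }
  }
})

test_that("edge retention is monotone in top_fraction", {
  set.seed(7)
  pred <- data.frame(pwm_id = rep(c("M1", "M2", "M3"), times = c(13, 40, 7)),
                     target = sprintf("T%03d", sample(1:45, 60, TRUE)),
                     score = runif(60))
  map <- data.frame(pwm_id = c("M1", "M2", "M3"),
                    regulator = c("A", "B", "C"))
  fracs <- c(0.05, 0.1, 0.3, 0.7, 1)
  sets <- lapply(fracs, function(f) {
    e <- build_network(pred, map, f)$edges
    paste(e$regulator, e$target)
  })
  for (i in seq_len(length(fracs) - 1L))
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]),
                info = sprintf("f=%g vs f=%g", fracs[i], fracs[i + 1L]))
})

test_that("regulator universe and subnetwork are exact set operations", {
  net <- reg_network(data.frame(regulator = c("A", "B"),
                                target = c("B", "C")))
  expect_setequal(regulator_universe(net), c("A", "B"))
  expect_equal(regulator_universe(reg_network(
    data.frame(regulator = character(), target = character()))),
    character())
  self <- reg_network(data.frame(regulator = "A", target = "A"))
  expect_equal(regulator_universe(self), "A")

  net2 <- reg_network(data.frame(regulator = c("A", "B"),
                                 target = c("B", "A")))
  sub <- subnetwork(net2, "A", "B")
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$regulator, "A")
  expect_equal(nrow(subnetwork(net2, "X", "Y")), 0L)
  full <- subnetwork(net2, c("A", "B"), c("A", "B"))
  expect_equal(nrow(full), 2L)
})

test_that("prediction tables and PWM maps read from disk", {
  p <- write_lines_tmp(c("pwm\ttarget\tscore", "M1\tX\t3.5", "M1\tY\t1.0"))
  pred <- read_binding_predictions(p)
  expect_equal(names(pred), c("pwm_id", "target", "score"))
  expect_equal(pred$score, c(3.5, 1.0))

  nohead <- write_lines_tmp(c("M1\tX\t3.5", "M1\tY\t1.0"))
  expect_equal(nrow(read_binding_predictions(nohead)), 2L)

  m <- write_lines_tmp(c("M1\tTF1", "M1\tTF2"))
  map <- read_pwm_map(m)
  expect_equal(map$regulator, c("TF1", "TF2"))
})
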