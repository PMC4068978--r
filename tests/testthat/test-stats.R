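records_from <- function(eff, group = "derotation", subgroup = "attachment",
                         planned = 20, staging = 1.0) {
  data.frame(patient_id = sprintf("p%02d", seq_along(eff)), group = group,
             subgroup = subgroup, moved_tooth_id = 14L,
             primary_component = "Rz", predicted = planned,
             achieved = planned * eff / 100, efficacy_percent = eff,
             planned_total = planned, staging_per_aligner = staging,
             compliance_hours = 22, stringsAsFactors = FALSE)
}

test_that("summarize_group matches hand arithmetic and the brute-force oracle", {
  single <- summarize_group(records_from(50), "one")
  expect_identical(single$n, 1L)
  expect_identical(single$mean_accuracy, 50)
  expect_identical(single$highest, 50)
  expect_identical(single$lowest, 50)
  expect_true(is.na(single$sd))

  # {20, 40, 60}: mean 40, sample SD of fractions {0.2, 0.4, 0.6} = 0.2
  three <- summarize_group(records_from(c(20, 40, 60)))
  expect_identical(three$mean_accuracy, 40)
  expect_identical(three$lowest, 20)
  expect_identical(three$highest, 60)
  expect_equal(three$sd, 0.2, tolerance = 1e-12)

  set.seed(111)
  eff <- runif(1000, -20, 120)
  s <- summarize_group(records_from(eff))
  expect_equal(s$mean_accuracy, sum(eff) / length(eff), tolerance = 1e-12)
  expect_equal(s$sd,
               sqrt(sum((eff / 100 - mean(eff / 100))^2) / (length(eff) - 1)),
               tolerance = 1e-12)
  expect_error(summarize_group(records_from(50)[0, , drop = FALSE]),
               class = "castmove_config_error")
})

test_that("overall efficacy is the unweighted mean of subgroup means", {
  rows <- data.frame(mean_accuracy = c(37.5, 42.4, 88.4, 86.9, 49.1, 51.5))
  expect_equal(overall_efficacy(rows), 59.3, tolerance = 1e-12)
  expect_identical(overall_efficacy(data.frame(mean_accuracy = 80)), 80)
  set.seed(112)
  r <- data.frame(mean_accuracy = runif(20, 0, 100))
  expect_equal(overall_efficacy(r), mean(r$mean_accuracy))
  expect_error(overall_efficacy(data.frame(mean_accuracy = numeric(0))),
               class = "castmove_config_error")
})

test_that("paired_t matches the closed form and sign convention", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  # differences {-1, -2, -3}: t = dbar / (s / sqrt(n)) = -2 * sqrt(3)
  res <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$t, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_lt(res$t, 0)  # under-achievement gives negative t

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)),
               class = "castmove_degenerate_test_error")
  expect_error(paired_t(1, 2), class = "castmove_config_error")

  # direction agrees with a sign-permutation oracle on random data
  set.seed(113)
  for (i in 1:5) {
    a <- rnorm(20)
    b <- a - 0.8 + rnorm(20, sd = 0.5)
    res <- paired_t(a, b)
    d <- a - b
    perm <- replicate(2000, mean(d * sample(c(-1, 1), 20, replace = TRUE)))
    p_perm <- mean(abs(perm) >= abs(mean(d)))
    expect_identical(res$p < 0.05, p_perm < 0.05)
    expect_identical(sign(res$t), sign(mean(d)))
  }
})

test_that("shapiro_wilk delegates correctly and flags degenerate samples", {
  set.seed(114)
  g <- rnorm(100)
  res <- shapiro_wilk(g)
  ref <- shapiro.test(g)
  expect_equal(res$W, unname(ref$statistic))
  expect_equal(res$p, unname(ref$p.value))

  bimodal <- c(rep(0, 25), rep(1, 25)) + rnorm(50, sd = 1e-3)
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)

  expect_error(shapiro_wilk(rep(1, 10)),
               class = "castmove_degenerate_test_error")
  expect_error(shapiro_wilk(c(1, 2)), class = "castmove_config_error")
})

test_that("split_tables partitions disjointly with the closed-lower boundary", {
  rec <- records_from(c(10, 20, 30, 40), planned = c(10, 15, 20, 30),
                      staging = c(1.0, 1.5, 1.6, 2.0))
  out <- split_tables(rec)
  # exactly-at-threshold rows fall in the lower bin
  expect_identical(out$by_amount$n, c(2L, 2L))
  expect_identical(out$by_staging$n, c(2L, 2L))
  expect_identical(sum(out$by_amount$n), nrow(rec))

  all_low <- split_tables(records_from(c(10, 20), planned = c(10, 12)))
  expect_identical(all_low$by_amount$n[2], 0L)
  expect_true(is.na(all_low$by_amount$mean_accuracy[2]))

  # configured slow/fast staging efficacy ordering is recovered
  slowfast <- rbind(records_from(c(40, 45, 42), staging = 1.0),
                    records_from(c(20, 25, 22), staging = 1.8))
  sf <- split_tables(slowfast)
  expect_lt(sf$by_staging$mean_accuracy[2], sf$by_staging$mean_accuracy[1])

  expect_error(split_tables(records_from(50, group = "torque")),
               class = "castmove_config_error")
})

test_that("efficacy_report writes deterministic tables", {
  rec <- rbind(records_from(c(30, 40), subgroup = "attachment"),
               records_from(c(50, 60), subgroup = "none"),
               records_from(c(80, 90), group = "distalization",
                            subgroup = "attachment", planned = 2.5,
                            staging = 0.25))
  rec$primary_component[rec$group == "distalization"] <- "Tx"

  out <- efficacy_report(rec)
  expect_identical(nrow(out$by_subgroup), 3L)
  expect_equal(out$overall_efficacy_percent, mean(c(35, 55, 85)))

  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  r1 <- efficacy_report(rec, out_dir = d1)
  r2 <- efficacy_report(rec, out_dir = d2)
  expect_true(all(file.exists(r1$files)))
  for (i in seq_along(r1$files)) {
    expect_identical(readLines(r1$files[i]), readLines(r2$files[i]))
  }
  expect_error(efficacy_report(rec[0, ]), class = "castmove_config_error")
})
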