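test_that("replicate averaging collapses groups to their means", {
  t <- make_table(rep("img_001", 3), c(10, 11, 12),
                  replicate_index = 1:3)
  out <- average_replicates(t)
  expect_equal(nrow(out), 1L)
  expect_equal(out$value, 11)

  single <- suppressMessages(average_replicates(make_table("img_001", 42)))
  expect_equal(single$value, 42)

  # output group count equals distinct key count on a random table
  set.seed(9)
  big <- do.call(rbind, lapply(1:20, function(i)
    make_table(rep(sprintf("img_%03d", i), 3), rnorm(3),
               parameter = sample(c("anteversion", "leg_length"), 1),
               replicate_index = 1:3)))
  out <- average_replicates(big)
  keys <- unique(with(big, paste(image_id, side, program_id, reviewer_id,
                                 parameter)))
  expect_equal(nrow(out), length(keys))
})

test_that("difference summary separates signed and absolute differences", {
  t <- make_paired_table(c(20, 30, 40), c(20, 30, 40))
  ds <- difference_summary(t, "A", "B", "anteversion")
  expect_equal(ds$mean_diff, 0)
  expect_equal(ds$abs_mean_diff, 0)
  expect_equal(ds$n, 3)

  t <- make_paired_table(c(10, 10), c(11, 9))   # d = (+1, -1)
  ds <- difference_summary(t, "A", "B", "anteversion")
  expect_equal(ds$mean_diff, 0)
  expect_equal(ds$abs_mean_diff, 1)

  # d is reference minus test: positive when the reference reads higher
  t <- make_paired_table(c(10, 10), c(12, 14))
  expect_equal(difference_summary(t, "A", "B", "anteversion")$mean_diff, 3)
})

test_that("a simulated program bias is recovered by the difference summary", {
  set.seed(31)
  truths <- data.frame(image_id = sprintf("img_%03d", 1:500),
                       side = "left",
                       true_anteversion_deg = runif(500, 10, 45))
  t <- simulate_measurement_table(
    truths, rater_model(sigma2_error = 0.09,
                        program_bias = c(B = 0.5)),
    programs = c("A", "B"), reviewers = "r", replicates = 1, seed = 77)
  ds <- difference_summary(t, "A", "B", "anteversion")
  se <- sqrt(2 * 0.09 / 500)
  expect_lt(abs(ds$mean_diff - 0.5), 3 * se)
})

test_that("paired t matches the closed form and degrades gracefully", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  t <- make_paired_table(a, b)
  got <- paired_t(t, "A", "B", "anteversion")
  want <- oracle_paired_t(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)

  same <- make_paired_table(c(5, 6, 7), c(5, 6, 7))
  got <- paired_t(same, "A", "B", "anteversion")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  expect_true(got$degenerate)

  # p-values are invariant to unit rescaling
  t10 <- t; t10$value <- t10$value * 10
  expect_equal(paired_t(t10, "A", "B", "anteversion")$p_value, want$p_value,
               tolerance = 1e-12)
})

test_that("one-way ANOVA handles identical groups and reduces to t^2 for two", {
  ids <- sprintf("img_%03d", 1:4)
  t3 <- rbind(make_table(ids, c(1, 2, 3, 4), program_id = "A"),
              make_table(ids, c(1, 2, 3, 4), program_id = "B"),
              make_table(ids, c(1, 2, 3, 4), program_id = "C"))
  got <- one_way_anova(t3, c("A", "B", "C"), "anteversion")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)

  set.seed(12)
  a <- rnorm(10, 20, 2); b <- rnorm(10, 21, 2)
  t2 <- rbind(make_table(sprintf("i%02d", 1:10), a, program_id = "A"),
              make_table(sprintf("i%02d", 1:10), b, program_id = "B"))
  got <- one_way_anova(t2, c("A", "B"), "anteversion")
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("Pearson correlation hits the exact limits", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(make_paired_table(x, x), "A", "B", "anteversion")$r, 1)
  expect_equal(pearson(make_paired_table(x, -x), "A", "B", "anteversion")$r, -1)
  expect_error(pearson(make_paired_table(x, rep(2, 5)), "A", "B",
                       "anteversion"), "constant")
})

test_that("within-threshold proportions count and stay monotone", {
  t <- make_paired_table(rep(0, 4), c(0.5, 1.5, 0.9, 6))
  w1 <- within_threshold(t, "A", "B", "anteversion", 1)
  expect_equal(w1$proportion, 0.5)
  expect_equal(w1$n_within, 2L)
  expect_equal(w1$n_total, 4L)
  w5 <- within_threshold(t, "A", "B", "anteversion", 5)
  expect_equal(w5$proportion, 0.75)

  ident <- make_paired_table(1:5, 1:5)
  expect_equal(within_threshold(ident, "A", "B", "anteversion", 0.1)$proportion, 1)

  set.seed(21)
  for (i in 1:10) {
    tr <- make_paired_table(rnorm(30), rnorm(30, sd = 3))
    p1 <- within_threshold(tr, "A", "B", "anteversion", 1)$proportion
    p5 <- within_threshold(tr, "A", "B", "anteversion", 5)$proportion
    expect_gte(p5, p1)
  }
})

test_that("proportion_test switches between chi-square and Fisher correctly", {
  bal <- matrix(c(50, 50, 50, 50), 2, byrow = TRUE)
  got <- proportion_test(bal)
  expect_equal(got$test_used, "chi_square")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)

  small <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  got <- proportion_test(small)
  expect_equal(got$test_used, "fisher_exact")
  expect_equal(got$p_value, oracle_fisher_enum(small), tolerance = 1e-12)
  expect_equal(got$p_value, fisher.test(small)$p.value, tolerance = 1e-9)

  big <- matrix(c(90, 10, 85, 15), 2, byrow = TRUE)
  got <- proportion_test(big)
  expect_equal(got$test_used, "chi_square")
  want <- oracle_chisq_2x2(big)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)

  expect_error(proportion_test(matrix(0, 2, 2)), "all-zero")

  # random small tables: Fisher branch agrees with stats::fisher.test
  set.seed(14)
  for (i in 1:25) {
    m <- matrix(rpois(4, 4), 2, 2)
    if (sum(m) == 0) next
    got <- proportion_test(m)
    if (got$test_used == "fisher_exact") {
      expect_equal(got$p_value, fisher.test(m)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("ICC reflects the variance decomposition", {
  # replicates identical within subjects, subjects differ -> ICC 1
  perfect <- matrix(rep(c(10, 20, 30, 40), 3), ncol = 3)
  expect_equal(icc(perfect)$icc_value, 1)

  flat <- matrix(5, 10, 3)
  got <- icc(flat)
  expect_true(got$degenerate)
  expect_true(is.na(got$icc_value))

  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "missing")

  # two-way data with sigma2_s = 99, sigma2_e = 1 -> ICC near 0.99
  set.seed(55)
  est <- replicate(40, {
    s <- rnorm(135, 0, sqrt(99))
    m <- matrix(s, 135, 3) + matrix(rnorm(135 * 3), 135, 3)
    icc(m)$icc_value
  })
  expect_lt(abs(mean(est) - 0.99), 0.005)
})

test_that("pooled ICC is a fixed point on equal reviewers and handles 1", {
  mk <- function(rev, vals) {
    do.call(rbind, lapply(1:3, function(rep_i)
      make_table(sprintf("img_%02d", seq_len(nrow(vals))), vals[, rep_i],
                 reviewer_id = rev, replicate_index = rep_i)))
  }
  set.seed(66)
  vals <- matrix(rnorm(20 * 3, rep(rnorm(20, 0, 5), 3)), 20, 3)
  t <- rbind(mk("r1", vals), mk("r2", vals))
  single <- icc(vals)$icc_value
  pooled <- pooled_icc(t, "p", "anteversion")
  expect_equal(pooled$icc_value, single, tolerance = 1e-12)
  expect_equal(unname(pooled$component_iccs), rep(single, 2))

  perfect <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  tp <- rbind(mk("r1", perfect), mk("r2", perfect))
  expect_equal(pooled_icc(tp, "p", "anteversion")$icc_value, 1)
})

test_that("build_report mirrors the study protocol structure", {
  set.seed(88)
  truths <- data.frame(image_id = sprintf("img_%03d", 1:60), side = "left",
                       true_anteversion_deg = runif(60, 10, 45),
                       true_inclination_deg = runif(60, 30, 55),
                       true_leg_length_mm = runif(60, -15, 35))
  t <- simulate_measurement_table(
    truths, rater_model(sigma2_error = 0.04),
    programs = c("NS", "PRV", "SRV"), reviewers = c("r1", "r2"),
    replicates = 3, seed = 5)
  # the secondary reference has no ellipse tool: no anteversion records
  t <- t[!(t$program_id == "SRV" & t$parameter == "anteversion"), ]

  rep <- build_report(t, reference_programs = c("PRV", "SRV"),
                      test_program = "NS")
  av <- rep$parameters$anteversion
  expect_setequal(names(av$comparisons), "PRV")
  expect_equal(av$omnibus$test, "paired_t")
  inc <- rep$parameters$inclination
  expect_setequal(names(inc$comparisons), c("PRV", "SRV"))
  expect_equal(inc$omnibus$test, "one_way_anova")

  # no configured bias: mean differences near zero
  for (pp in rep$parameters) {
    for (cmp in pp$comparisons) {
      expect_lt(abs(cmp$mean_diff), 3 * sqrt(2 * 0.04 / 3 / 2 / 60))
      expect_equal(cmp$prop_within$within_5$proportion, 1)
    }
  }
  # ICCs from sigma2_s >> sigma2_e data are near 1
  expect_gt(rep$parameters$anteversion$iccs$NS$icc_value, 0.99)

  df <- as.data.frame(rep)
  expect_true(all(c("parameter", "program_test", "program_ref", "n",
                    "mean_diff", "sd_diff", "abs_mean_diff", "abs_sd_diff",
                    "pearson_r", "paired_t_p", "omnibus_p",
                    "prop_within_1", "prop_within_5") %in% names(df)))
  expect_equal(nrow(df), 5L)  # 1 anteversion + 2 inclination + 2 leg length

  # deterministic: same table in, identical report out
  expect_identical(as.data.frame(build_report(t, c("PRV", "SRV"), "NS")), df)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  report_to_json(rep, json)
  report_to_csv(rep, csv)
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "\n")))
  expect_equal(nrow(read.csv(csv)), 5L)
})
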