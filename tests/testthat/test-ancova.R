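# simulated 2x2 cohort-style data for the ANCOVA battery
sim_design <- function(n_per_cell, effect_apoe4 = 0, effect_prog = 0,
                       effect_ix = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(apoe4 = c("carrier", "noncarrier"),
                   progression = c("converter", "nonconverter"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  n <- nrow(d)
  d$age <- rnorm(n, 75, 7)
  d$sex <- sample(c("male", "female"), n, replace = TRUE)
  d$gm_volume <- rnorm(n, 590, 70)
  d$y <- rnorm(n) + 0.01 * (d$age - 75) +
    effect_apoe4 * (d$apoe4 == "carrier") +
    effect_prog * (d$progression == "converter") +
    effect_ix * (d$apoe4 == "carrier") * (d$progression == "converter")
  d
}

test_that("ANCOVA reports the three design effects with valid statistics", {
  d <- sim_design(30, effect_apoe4 = 1, seed = 2)
  res <- ancova(d, "y", covariates = c("age", "sex", "gm_volume"))
  expect_identical(res$effect, c("apoe4", "progression", "interaction"))
  expect_true(all(res$F >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$df1 == 1))
  expect_lt(res$p[res$effect == "apoe4"], 0.001)
  expect_true(all(res$omega_sq >= 0 & res$omega_sq < 1))
})

test_that("ANCOVA matches car's type-III F statistics on unbalanced data", {
  d <- sim_design(25, effect_prog = 0.6, seed = 3)
  d <- d[-(1:7), ]  # unbalance the cells
  res <- ancova(d, "y", covariates = "age", transform = "none")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ age + apoe4 * progression, data = d)
  a3 <- car::Anova(fit, type = 3)
  expect_equal(res$F[1], a3["apoe4", "F value"], tolerance = 1e-12)
  expect_equal(res$F[2], a3["progression", "F value"], tolerance = 1e-12)
  expect_equal(res$F[3], a3["apoe4:progression", "F value"], tolerance = 1e-12)
  # omega^2 from the printed formula
  ms_err <- a3["Residuals", "Sum Sq"] / a3["Residuals", "Df"]
  ss_tot <- sum((d$y - mean(d$y))^2)
  om <- (a3["progression", "Sum Sq"] - 1 * ms_err) / (ss_tot + ms_err)
  expect_equal(res$omega_sq[2], max(0, om), tolerance = 1e-12)
})

test_that("an outcome equal to a covariate leaves nothing for the factors", {
  d <- sim_design(20, seed = 4)
  d$y <- d$age
  res <- ancova(d, "y", covariates = "age", transform = "none")
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$omega_sq == 0))
})

test_that("ANCOVA type-I error is nominal under the null", {
  reps <- 400
  rej <- matrix(FALSE, reps, 3)
  for (r in seq_len(reps)) {
    d <- sim_design(12, seed = 5000 + r)
    res <- ancova(d, "y", covariates = "age", transform = "none")
    rej[r, ] <- res$p < 0.05
  }
  rate <- colMeans(rej)
  se2 <- 2 * sqrt(0.05 * 0.95 / reps)
  expect_true(all(abs(rate - 0.05) <= se2 + 1e-9),
              info = paste("rates:", paste(round(rate, 3), collapse = " ")))
})

test_that("error handling: empty cells and rank deficiency are rejected", {
  d <- sim_design(10, seed = 5)
  d_empty <- d[!(d$apoe4 == "carrier" & d$progression == "converter"), ]
  expect_error(ancova(d_empty, "y", covariates = "age"), "empty design cell")
  d$age2 <- d$age * 2
  expect_error(ancova(d, "y", covariates = c("age", "age2"),
                      transform = "none"), "rank-deficient")
})

test_that("post hoc comparisons behave across methods", {
  set.seed(6)
  g <- factor(rep(c("a", "b", "c"), each = 20))
  x <- rnorm(60)
  # identical cells -> corrected p near 1
  x_eq <- rep(rnorm(20), 3)
  for (m in c("tukey", "bonferroni", "games_howell")) {
    res <- posthoc(x_eq, g, method = m)
    expect_true(all(res$p > 0.99), info = m)
    expect_equal(nrow(res), 3L)
  }

  # bonferroni is min(1, raw * m) on the pooled t
  res_b <- posthoc(x, g, method = "bonferroni")
  df <- 60 - 3
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / df
  m12 <- mean(x[g == "b"]) - mean(x[g == "a"])
  t12 <- m12 / sqrt(mse * (1 / 20 + 1 / 20))
  expect_equal(res_b$p[1], min(1, 2 * pt(-abs(t12), df) * 3), tolerance = 1e-12)

  # tukey agrees with the studentized-range computation on a balanced design
  res_t <- posthoc(x, g, method = "tukey")
  p_hand <- ptukey(abs(t12) * sqrt(2), 3, df, lower.tail = FALSE)
  expect_equal(res_t$p[1], p_hand, tolerance = 1e-8)

  expect_error(posthoc(x, g, method = "scheffe"))
})

test_that("group analysis runs end to end on a small synthetic cohort", {
  sim <- generate_cohort(8, effect_spec(zero = TRUE, seed = 31),
                         shape = c(12, 12, 12), volumes = FALSE)
  co <- sim$cohort
  # metric tables with a known structure (no network extraction needed here)
  set.seed(32)
  mk_metrics <- function(visit) {
    data.frame(subject_id = co$subject_id, visit = visit,
               clux = rnorm(nrow(co), 0.4, 0.05),
               charpath = rnorm(nrow(co), 1.8, 0.1),
               eglobal = rnorm(nrow(co), 0.6, 0.05),
               gconnect = rnorm(nrow(co), 0.3, 0.05),
               gamma = rnorm(nrow(co), 1.3, 0.1),
               lambda = rnorm(nrow(co), 1.05, 0.02),
               sigma = rnorm(nrow(co), 1.25, 0.1),
               sparsity = rnorm(nrow(co), 30, 5),
               size = round(rnorm(nrow(co), 960, 10)),
               mean_degree = rnorm(nrow(co), 300, 30))
  }
  metrics <- rbind(mk_metrics(1L), mk_metrics(2L))
  regional <- expand.grid(subject_id = co$subject_id, visit = 1:2,
                          region = 1:4, stringsAsFactors = FALSE)
  regional$value <- rnorm(nrow(regional), 1.3, 0.15)
  regional$region_gm_volume <- rnorm(nrow(regional), 0.5, 0.05)
  regional$nodal_degree <- rnorm(nrow(regional), 300, 25)

  res <- run_group_analysis(co, metrics, regional = regional)
  expect_s3_class(res$baseline, "data.frame")
  expect_true(all(c("apoe4", "progression", "interaction") %in% res$baseline$effect))
  expect_s3_class(res$roc, "data.frame")
  expect_equal(sort(unique(res$regional$region)), 1:4)
  expect_true(all(c("p_fdr", "rejected") %in% names(res$regional)))
  expect_s3_class(res$associations, "data.frame")
  expect_s3_class(res$comparisons, "data.frame")
  expect_true(nzchar(res$manifest$config_hash))

  # deterministic: same inputs give identical tables
  res2 <- run_group_analysis(co, metrics, regional = regional)
  expect_identical(res$baseline, res2$baseline)
  expect_identical(res$associations, res2$associations)
})
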