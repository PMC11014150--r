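test_that("BMI categories cut at 25 and 30 with the mid band inclusive", {
  cohort <- data.frame(sex = "female", vo2max = 35,
                       bmi = c(24.9, 25.0, 29.9, 30.0, 30.1))
  g <- assign_groups(cohort)
  expect_equal(as.character(g$bmi_category),
               c("low", "mid", "mid", "mid", "high"))
})

test_that("CRF tertiles are sex-specific and split exact thirds", {
  cohort <- data.frame(sex = rep("female", 9), bmi = 22,
                       vo2max = c(25, 27, 29, 33, 34, 35, 39, 41, 43))
  g <- assign_groups(cohort)
  expect_equal(as.integer(table(g$crf_third)), c(3L, 3L, 3L))
  expect_equal(as.character(g$crf_third[c(1, 4, 9)]), c("low", "mid", "high"))

  # a cohort built to have the published quantiles reproduces its cuts
  v_w <- c(seq(20, 31.2, length.out = 34), seq(31.2, 36.3, length.out = 34)[-1],
           seq(36.3, 48, length.out = 34)[-1])
  v_m <- c(seq(22, 34.4, length.out = 34), seq(34.4, 40.4, length.out = 34)[-1],
           seq(40.4, 52, length.out = 34)[-1])
  cohort2 <- data.frame(sex = rep(c("female", "male"), each = 100),
                        bmi = 25, vo2max = c(v_w, v_m))
  cuts <- crf_tertile_cuts(cohort2)
  expect_equal(cuts$tertile_1[cuts$sex == "female"], 31.2, tolerance = 0.01)
  expect_equal(cuts$tertile_2[cuts$sex == "female"], 36.3, tolerance = 0.01)
  expect_equal(cuts$tertile_1[cuts$sex == "male"], 34.4, tolerance = 0.01)

  # missing covariate: flagged NA, others unaffected
  cohort$vo2max[5] <- NA
  g2 <- assign_groups(cohort)
  expect_true(is.na(g2$crf_third[5]))
  expect_false(anyNA(g2$crf_third[-5]))
})

test_that("age-sex weights equalize cell shares", {
  # two cells with counts 10 and 30 and equal targets: weights 2 and 2/3
  cohort <- data.frame(age = 25, sex = rep(c("female", "male"), c(10, 30)))
  expect_warning(w <- compute_weights(cohort), "empty")
  expect_equal(unique(w[cohort$sex == "female"]), 2)
  expect_equal(unique(w[cohort$sex == "male"]), 2 / 3, tolerance = 1e-9)

  # perfectly balanced cohort: all weights 1
  bal <- data.frame(age = rep(c(25, 35, 45, 55, 65), times = 2),
                    sex = rep(c("female", "male"), each = 5))
  expect_equal(compute_weights(bal), rep(1, 10))

  # defining property: weighted cell shares all equal
  set.seed(31)
  big <- data.frame(age = runif(400, 20, 69.9),
                    sex = sample(c("female", "male"), 400, TRUE))
  w <- compute_weights(big)
  grp <- interaction(big$sex, cut(big$age, c(20, 30, 40, 50, 60, 71),
                                  right = FALSE))
  shares <- tapply(w, grp, sum) / sum(w)
  expect_equal(as.numeric(shares), rep(1 / 10, 10), tolerance = 1e-9)
})

test_that("partial Spearman matches the brute-force rank-residual oracle", {
  set.seed(41)
  n <- 6
  x <- rnorm(n); y <- rnorm(n); age <- runif(n, 20, 69)
  sex <- rep(c("female", "male"), 3)
  ps <- partial_spearman(x, y, age, sex)
  expect_equal(ps$estimate, oracle_partial_spearman(x, y, age, sex),
               tolerance = 1e-10)

  # y = x with orthogonal covariates gives 1
  x2 <- 1:20
  expect_equal(partial_spearman(x2, x2, rep(c(30, 50), 10),
                                rep(c("f", "m"), 10))$estimate, 1,
               tolerance = 1e-9)

  # independence given covariates: near-zero at n = 5000
  n <- 5000
  age <- runif(n, 20, 69); sex <- sample(c("f", "m"), n, TRUE)
  x <- rnorm(n) + 0.05 * age
  y <- rnorm(n) + 0.05 * age
  expect_lt(abs(partial_spearman(x, y, age, sex)$estimate), 0.05)

  expect_warning(r0 <- partial_spearman(rep(1, 12), rnorm(12), runif(12, 20, 60),
                                        rep(c("f", "m"), 6)),
                 "constant")
  expect_true(is.na(r0$estimate))
})

test_that("partial Spearman is invariant to monotone transforms", {
  set.seed(51)
  n <- 60
  x <- rexp(n); y <- x + rnorm(n); age <- runif(n, 20, 69)
  sex <- rep(c("f", "m"), n / 2)
  base <- partial_spearman(x, y, age, sex)$estimate
  expect_equal(partial_spearman(exp(x), y, age, sex)$estimate, base)
  expect_equal(partial_spearman(x, y^3 + 5 * y, age, sex)$estimate, base)
  expect_equal(partial_spearman(log(x), sign(y) * abs(y)^1.7, age, sex)$estimate,
               base)
})

test_that("Kruskal-Wallis and Dunn-Bonferroni behave on known inputs", {
  # two groups of three with ranks 1..6: textbook H = 3.857
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("a", "b"), each = 3)
  gc <- group_compare(vals, grp)
  expect_equal(gc$statistic, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2) ,
               tolerance = 1e-9)
  # Dunn z by hand: (2 - 5) / sqrt((6*7/12) * (1/3 + 1/3))
  expect_equal(gc$pairwise$z, (2 - 5) / sqrt(3.5 * 2 / 3), tolerance = 1e-9)

  # three identical groups: H ~ 0, nothing significant
  same <- group_compare(rep(c(5, 6, 7, 8), 3), rep(c("a", "b", "c"), each = 4))
  expect_lt(same$statistic, 1e-9)
  expect_true(all(same$pairwise$p_adj > 0.9))

  # planted location shift is detected at moderate n
  set.seed(61)
  vals2 <- c(rnorm(60), rnorm(60) + 1, rnorm(60) + 2)
  grp2 <- rep(c("low", "mid", "high"), each = 60)
  gc2 <- group_compare(vals2, grp2)
  expect_lt(gc2$p.value, 0.05)
  expect_true(all(gc2$pairwise$p_adj <= 1))

  expect_error(group_compare(1:5, rep("a", 5)), "config error")
  expect_error(group_compare(1:3, c("a", "a", "b")), "config error")
})
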