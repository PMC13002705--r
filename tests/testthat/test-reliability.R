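# exhaustive pair-counting oracle for observed agreement: among the
# n*(n-1) ordered rater pairs per item, the fraction assigning the item
# to the same category
pbar_oracle <- function(tab) {
  n <- rowSums(tab)[1]
  mean(apply(tab, 1, function(row) {
    sum(row * (row - 1)) / (n * (n - 1))
  }))
}

test_that("Fleiss' kappa matches hand evaluation and its fixed points", {
  # 2 items x 2 raters: one unanimous item, one split item
  # Pbar = (1 + 0)/2, Pe = (3/4)^2 + (1/4)^2 = 5/8 -> kappa = -1/3
  tab <- matrix(c(2, 0, 1, 1), 2, byrow = TRUE)
  expect_equal(fleiss_kappa(tab), -1 / 3)

  # unanimity over 90 items x 13 raters x 6 categories
  unan <- matrix(0, 90, 6)
  unan[cbind(1:90, sample(1:6, 90, replace = TRUE))] <- 13
  expect_equal(fleiss_kappa(unan), 1)

  # formula agreement with the pair-counting oracle on random tables
  set.seed(300)
  for (i in 1:20) {
    tab <- t(rmultinom(30, 13, runif(6)))
    p_cat <- colSums(tab) / sum(tab)
    p_e <- sum(p_cat^2)
    expect_equal(fleiss_kappa(tab),
                 (pbar_oracle(tab) - p_e) / (1 - p_e), tolerance = 1e-12)
  }

  expect_error(fleiss_kappa(matrix(c(2, 0, 1, 0), 2, byrow = TRUE)),
               "same number of raters")
  expect_warning(k <- fleiss_kappa(matrix(c(3, 0, 3, 0), 2, byrow = TRUE)),
                 "one category")
  expect_true(is.na(k))
})

test_that("kappa is near zero when raters guess independently of the items", {
  set.seed(301)
  n_sim <- 40
  kappas <- replicate(n_sim, {
    fleiss_kappa(t(rmultinom(90, 13, rep(1 / 6, 6))))
  })
  expect_lt(abs(mean(kappas)), 3 * sd(kappas) / sqrt(n_sim))
})

test_that("two-way ICC matches its ANOVA definition and fixed points", {
  # raters identical to each other, items varying: perfect reliability
  items <- seq(1, 10, length.out = 12)
  perfect <- matrix(rep(items, 5), ncol = 5)
  res <- icc_two_way(perfect)
  expect_equal(res$icc_2_1, 1)
  expect_equal(res$icc_2_k, 1)

  # no item variance at all: estimates hover around zero
  set.seed(302)
  n_sim <- 40
  noise <- replicate(n_sim, icc_two_way(matrix(rnorm(60 * 13), 60))$icc_2_1)
  expect_lt(abs(mean(noise)), 3 * sd(noise) / sqrt(n_sim))

  # simulated two-way data: ICC(2,1) approaches the variance ratio
  # sigma_item^2 / (sigma_item^2 + sigma_noise^2)
  target <- 1 / (1 + 1.12^2)
  est <- replicate(n_sim, {
    item <- rnorm(90, 0, 1)
    m <- outer(item, rep(1, 13)) + matrix(rnorm(90 * 13, 0, 1.12), 90)
    r <- icc_two_way(m)
    c(r$icc_2_1, r$icc_2_k)
  })
  expect_lt(abs(mean(est[1, ]) - target), 3 * sd(est[1, ]) / sqrt(n_sim))
  expect_gt(mean(est[2, ]), 0.9) # averaging 13 raters boosts reliability

  expect_warning(flat <- icc_two_way(matrix(2, 4, 4)), "Zero total variance")
  expect_true(is.na(flat$icc_2_1))
})

test_that("ICC agrees with a two-way mixed-model variance decomposition", {
  # REML variance components give an independent route to the same
  # estimand on balanced complete data
  set.seed(303)
  n_items <- 40
  k <- 8
  m <- outer(rnorm(n_items, 5, 1.2), rep(1, k)) +
    outer(rep(1, n_items), rnorm(k, 0, 0.6)) +
    matrix(rnorm(n_items * k, 0, 0.9), n_items)
  anova_est <- icc_two_way(m)

  df <- data.frame(y = as.vector(m),
                   item = factor(rep(seq_len(n_items), k)),
                   rater = factor(rep(seq_len(k), each = n_items)))
  fit <- lme4::lmer(y ~ (1 | item) + (1 | rater), data = df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  icc21_reml <- v[["item"]] / (v[["item"]] + v[["rater"]] + v[["Residual"]])
  icc2k_reml <- v[["item"]] /
    (v[["item"]] + (v[["rater"]] + v[["Residual"]]) / k)

  expect_equal(anova_est$icc_2_1, unname(icc21_reml), tolerance = 0.05)
  expect_equal(anova_est$icc_2_k, unname(icc2k_reml), tolerance = 0.05)
})

test_that("ICC invariances hold on random matrices", {
  set.seed(304)
  for (i in 1:10) {
    m <- outer(rnorm(20, 0, runif(1, 0.5, 2)), rep(1, 6)) +
      matrix(rnorm(120), 20)
    r <- icc_two_way(m)
    if (r$icc_2_1 > 0) expect_gte(r$icc_2_k, r$icc_2_1)
    shifted <- icc_two_way(m + 7)
    expect_equal(shifted$icc_2_1, r$icc_2_1, tolerance = 1e-9)
    expect_equal(shifted$icc_2_k, r$icc_2_k, tolerance = 1e-9)
  }
})

test_that("reliability summary aggregates per list and pools kappa", {
  plan <- build_design(n_expressors = 10, raters_per_list = 4, seed = 6)
  ratings <- simulate_ratings(plan, seed = 40)
  out <- reliability_summary(ratings)

  lists <- sort(unique(ratings$list_id))
  expect_equal(sum(out$list_id == "mean"), 5)
  expect_equal(sum(out$list_id == "pooled"), 1)
  expect_equal(nrow(out), length(lists) * 5 + 6)

  per_list_kappa <- out$value[out$statistic == "fleiss_kappa" &
                                !out$list_id %in% c("mean", "pooled")]
  expect_equal(out$value[out$list_id == "mean" &
                           out$statistic == "fleiss_kappa"],
               mean(per_list_kappa))
  # group means of many raters are more reliable than single raters
  m21 <- out$value[out$list_id == "mean" & out$statistic == "icc_2_1_arousal"]
  m2k <- out$value[out$list_id == "mean" & out$statistic == "icc_2_k_arousal"]
  expect_gt(m2k, m21)
})
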