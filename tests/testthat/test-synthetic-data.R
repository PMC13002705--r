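test_that("default confusion model encodes the documented recognition pattern", {
  cmod <- default_confusion_model()
  m <- cmod$matrix

  expect_equal(m["reward", "reward"], 0.921)
  expect_equal(m["neutral", "neutral"], 0.926)
  expect_equal(m["disgust", "disgust"], 0.915)
  expect_equal(m["affiliative", "affiliative"], 0.692)
  expect_equal(m["dominance", "dominance"], 0.660)
  expect_equal(m["affiliative", "reward"], 0.177)
  expect_equal(m["affiliative", "neutral"], 0.075)
  expect_equal(m["dominance", "affiliative"], 0.109)
  expect_equal(m["dominance", "disgust"], 0.078)
  expect_equal(m["dominance", "other"], 0.098)
  expect_equal(m["reward", "affiliative"], 0.059)

  expect_true(all(m >= 0))
  expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
})

test_that("malformed confusion models are rejected before sampling", {
  m <- default_confusion_model()$matrix
  m[1, 1] <- m[1, 1] + 0.2
  expect_error(confusion_model(m), "sum to 1")
  m2 <- default_confusion_model()$matrix
  m2[2, 1] <- -0.01
  expect_error(confusion_model(m2))
  expect_error(confusion_model(default_confusion_model()$matrix,
                               concentration = -2))
})

test_that("identity confusion reproduces the intended labels and seeds reproduce tables", {
  plan <- small_plan()
  r1 <- simulate_ratings(plan, confusion = identity_confusion(), seed = 4)
  expect_true(all(r1$chosen_category == r1$expression_intended))

  r2 <- simulate_ratings(plan, confusion = identity_confusion(), seed = 4)
  expect_identical(r1, r2)
  r3 <- simulate_ratings(plan, confusion = identity_confusion(), seed = 5)
  expect_false(identical(r1$arousal, r3$arousal))

  # scale bounds and completeness
  expect_true(all(r1$arousal %in% 1:9))
  expect_true(all(r1$plausibility %in% 1:7))
  expect_false(anyNA(r1))
  expect_error(simulate_ratings(plan), "seed")
})

test_that("sampled confusion frequencies converge to the configured rows", {
  plan <- build_design(seed = 9)
  ratings <- simulate_ratings(plan, seed = 20)

  aff <- ratings[ratings$expression_intended == "affiliative", ]
  expect_equal(nrow(aff), 2340)
  p_hat <- mean(aff$chosen_category == "reward")
  se <- sqrt(0.177 * (1 - 0.177) / 2340)
  expect_lt(abs(p_hat - 0.177), 3 * se)

  # at 10x raters every diagonal cell matches within 3 binomial SE
  plan10 <- build_design(raters_per_list = 130, seed = 9)
  big <- simulate_ratings(plan10, seed = 21)
  m <- default_confusion_model()$matrix
  for (e in expression_names()) {
    sub <- big[big$expression_intended == e, ]
    p <- m[e, e]
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$chosen_category == e) - p), 3 * se)
  }
})

test_that("threshold calibration moment-matches the discrete mean", {
  # symmetric case: mean at the scale midpoint stays exactly there
  th <- calibrate_thresholds(5, 1.3, 9)
  expect_equal(length(th), 8)
  expect_true(all(diff(th) > 0))
  discrete_mean <- function(th, mu, sd) {
    1 + sum(1 - pnorm(th, mu, sd))
  }
  expect_equal(discrete_mean(th, 5, 1.3), 5, tolerance = 1e-6)

  # asymmetric case, checked by Monte Carlo draws rather than the
  # calibration identity itself
  th2 <- calibrate_thresholds(6.72, 1.39, 9)
  set.seed(42)
  x <- findInterval(rnorm(2e5, 6.72, 1.39), th2) + 1
  expect_true(all(x %in% 1:9))
  expect_gt(mean(x), 6.67)
  expect_lt(mean(x), 6.77)

  expect_error(calibrate_thresholds(0.5, 1, 7), "within")
  expect_error(calibrate_thresholds(8, -1, 7))
})

test_that("discrete rating means recover the configured latent means", {
  plan <- build_design(seed = 1)
  ar <- flat_ordinal(default_arousal_model())
  pl <- flat_ordinal(default_plausibility_model())
  ratings <- simulate_ratings(plan, arousal = ar, plausibility = pl, seed = 31)
  for (e in expression_names()) {
    sub <- ratings[ratings$expression_intended == e, ]
    expect_equal(mean(sub$arousal), ar$means[[e]], tolerance = 0.1)
    expect_equal(mean(sub$plausibility), pl$means[[e]], tolerance = 0.1)
  }
})

test_that("structural effects shift ratings in the configured direction", {
  plan <- build_design(seed = 1)
  ratings <- simulate_ratings(plan, seed = 32)

  # male expressors: lower arousal, higher plausibility
  by_gender <- tapply(ratings$arousal, ratings$expressor_gender, mean)
  expect_lt(by_gender[["male"]], by_gender[["female"]])
  by_gender_p <- tapply(ratings$plausibility, ratings$expressor_gender, mean)
  expect_gt(by_gender_p[["male"]], by_gender_p[["female"]])

  # mirrored versions slightly less plausible, arousal untouched in design
  by_ver <- tapply(ratings$plausibility, ratings$version, mean)
  expect_lt(by_ver[["R"]], by_ver[["L"]])
})
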