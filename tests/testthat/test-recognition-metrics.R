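# brute-force UHR: probability correct given presented times probability
# correct given used, evaluated cell-wise without the closed-form shortcut
uhr_oracle <- function(cm) {
  sapply(rownames(cm), function(e) {
    p_correct_given_presented <- cm[e, e] / sum(cm[e, ])
    p_correct_given_used <- cm[e, e] / sum(cm[, e])
    p_correct_given_presented * p_correct_given_used
  })
}

test_that("confusion tallies partition the ratings at every scope", {
  plan <- small_plan()
  ratings <- simulate_ratings(plan, seed = 14)
  cm <- tally_confusion(ratings)

  expect_equal(sum(cm), nrow(ratings))
  expect_equal(dim(cm), c(5L, 6L))

  by_rater <- tally_confusion(ratings, scope = "rater")
  expect_equal(Reduce(`+`, lapply(by_rater, unclass)), unclass(cm),
               ignore_attr = TRUE)
  # each rater judged 2 expressors per expression in this reduced plan
  expect_true(all(vapply(by_rater, function(m) all(rowSums(m) == 2),
                         logical(1))))
  by_expr <- tally_confusion(ratings, scope = "expressor")
  expect_equal(Reduce(`+`, lapply(by_expr, unclass)), unclass(cm),
               ignore_attr = TRUE)

  ident <- simulate_ratings(plan, confusion = identity_confusion(), seed = 14)
  mi <- tally_confusion(ident)
  expect_equal(sum(mi[cbind(expression_names(), expression_names())]), sum(mi))

  bad <- ratings
  bad$chosen_category[3] <- "smug"
  expect_error(tally_confusion(bad), "row\\(s\\) 3")
})

test_that("hit-rate statistics match direct formula evaluation", {
  # two-category toy matrix: first-category UHR = 3^2 / (4 * 5) = 0.45
  toy <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(unbiased_hit_rate(toy)["a"]), 0.45)
  expect_equal(unname(simple_hit_rate(toy)), c(75, 200 / 3))

  # balanced matrix: row and column marginals 18, N = 90 -> chance 0.04
  bal <- matrix(0, 5, 6, dimnames = list(expression_names(),
                                         response_categories()))
  bal[cbind(expression_names(), expression_names())] <- 18
  expect_equal(unname(chance_uhr(bal)), rep(0.04, 5))
  expect_equal(unname(simple_hit_rate(bal)), rep(100, 5))
  expect_equal(unname(unbiased_hit_rate(bal)), rep(1, 5))

  # random matrices: closed form vs cell-wise oracle, and UHR <= SHR/100
  set.seed(100)
  for (i in 1:25) {
    cm <- random_cm()
    uhr <- unbiased_hit_rate(cm)
    expect_equal(unname(uhr), unname(uhr_oracle(cm)), tolerance = 1e-12)
    expect_true(all(uhr <= simple_hit_rate(cm) / 100 + 1e-12))
    expect_true(all(uhr >= 0 & uhr <= 1))
  }
})

test_that("statistics are invariant to consistent relabeling", {
  set.seed(7)
  cm <- random_cm()
  perm <- sample(5)
  cm2 <- cm[perm, c(perm, 6)]
  expect_equal(unbiased_hit_rate(cm2)[rownames(cm)],
               unbiased_hit_rate(cm)[rownames(cm)], ignore_attr = TRUE)
  expect_equal(chance_uhr(cm2)[rownames(cm)], chance_uhr(cm)[rownames(cm)])
  expect_equal(simple_hit_rate(cm2)[rownames(cm)],
               simple_hit_rate(cm)[rownames(cm)])
})

test_that("a stimulus-independent responder scores at Wagner's chance level", {
  # responses drawn independently of the stimulus: E[UHR] ~ chance UHR
  set.seed(200)
  n_sim <- 200
  diff <- replicate(n_sim, {
    p <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1) # biased but stimulus-independent
    cm <- t(sapply(1:5, function(i) as.vector(rmultinom(1, 90, p))))
    dimnames(cm) <- list(expression_names(), response_categories())
    mean(unbiased_hit_rate(cm) - chance_uhr(cm))
  })
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(n_sim))
})

test_that("degenerate matrices are flagged rather than silently zeroed", {
  cm <- random_cm()
  cm[, "reward"] <- 0 # response never used
  cm["reward", "neutral"] <- 5 # keep the row presented
  uhr <- unbiased_hit_rate(cm)
  expect_equal(unname(uhr["reward"]), 0)
  expect_equal(attr(uhr, "zero_use"), "reward")
  expect_equal(unname(chance_uhr(cm)["reward"]), 0)

  cm2 <- random_cm()
  cm2["disgust", ] <- 0
  expect_warning(shr <- simple_hit_rate(cm2), "disgust")
  expect_true(is.na(shr["disgust"]))
  expect_error(unbiased_hit_rate(cm2), "zero presentations")
})

test_that("the arcsine square-root transform behaves as the closed form", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(round(arcsine_transform(1), 2), 1.57)
  expect_equal(arcsine_transform(0.5), pi / 4)
  expect_equal(arcsine_transform(0.25, variant = "asin"), asin(0.25))
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]")
})

test_that("per-rater metrics are tidy and consistent with pooled tallies", {
  plan <- small_plan()
  ratings <- simulate_ratings(plan, seed = 15)
  tidy <- rater_metrics(ratings)
  expect_named(tidy, c("rater_id", "expression", "shr", "uhr",
                       "arcsine_uhr", "chance_uhr"))
  expect_equal(nrow(tidy), length(unique(ratings$rater_id)) * 5)
  expect_equal(tidy$arcsine_uhr, asin(sqrt(tidy$uhr)))
  expect_true(all(tidy$uhr >= 0 & tidy$uhr <= 1))
})
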