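#' Confusion model for forced-choice category responses
#'
#' A confusion model holds, for each intended expression, the probability
#' distribution of the six response categories a rater may choose. An
#' optional Dirichlet `concentration` governs rater-level heterogeneity:
#' each rater's personal row is drawn from
#' `Dirichlet(concentration * row)`, so larger values mean raters closer
#' to the population row and `NULL` disables perturbation entirely.
#'
#' @param matrix Numeric matrix, intended expressions as rows (named by
#'   [expression_names()]), response categories as columns (named by
#'   [response_categories()]); rows must sum to 1.
#' @param concentration Positive scalar or `NULL`.
#' @return A `confusion_model`.
#' @export
confusion_model <- function(matrix, concentration = 50) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) rownames(matrix) <- expression_names()
  if (is.null(colnames(matrix))) colnames(matrix) <- response_categories()
  if (!setequal(rownames(matrix), expression_names()) ||
      !setequal(colnames(matrix), response_categories())) {
    stop("Confusion matrix must have the 5 intended expressions as rows ",
         "and the 6 response categories as columns.", call. = FALSE)
  }
  matrix <- matrix[expression_names(), response_categories()]
  if (any(matrix < 0)) {
    stop("Confusion probabilities must be non-negative.", call. = FALSE)
  }
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("Each confusion row must sum to 1 (tolerance 1e-9).", call. = FALSE)
  }
  if (!is.null(concentration)) {
    stopifnot(is.numeric(concentration), length(concentration) == 1L,
              concentration > 0)
  }
  structure(list(matrix = matrix, concentration = concentration),
            class = "confusion_model")
}

#' Default confusion model calibrated to the observed recognition pattern
#'
#' Diagonal entries are the observed mean simple hit rates of the
#' validation ratings (neutral 92.6%, reward 92.1%, disgust 91.5%,
#' affiliative 69.2%, dominance 66.0%, as proportions). The documented
#' off-diagonal confusions are set explicitly: affiliative mistaken for
#' reward (17.7%) and neutral (7.5%); dominance mistaken for affiliative
#' (10.9%), disgust (7.8%) and "other" (9.8%); reward mistaken for
#' affiliative (5.9%). The residual mass of each row is spread uniformly
#' over its remaining cells and rows are renormalised to sum to 1.
#'
#' @param concentration Dirichlet concentration for rater-level
#'   perturbation (see [confusion_model()]).
#' @return A `confusion_model`.
#' @export
#' @examples
#' round(default_confusion_model()$matrix, 3)
default_confusion_model <- function(concentration = 50) {
  expr <- expression_names()
  resp <- response_categories()
  m <- matrix(NA_real_, nrow = 5, ncol = 6, dimnames = list(expr, resp))
  diag_shr <- c(reward = 0.921, affiliative = 0.692, dominance = 0.660,
                disgust = 0.915, neutral = 0.926)
  for (e in expr) m[e, e] <- diag_shr[[e]]
  m["affiliative", "reward"] <- 0.177
  m["affiliative", "neutral"] <- 0.075
  m["dominance", "affiliative"] <- 0.109
  m["dominance", "disgust"] <- 0.078
  m["dominance", "other"] <- 0.098
  m["reward", "affiliative"] <- 0.059
  for (e in expr) {
    free <- is.na(m[e, ])
    m[e, free] <- max(0, 1 - sum(m[e, !free])) / sum(free)
    m[e, ] <- m[e, ] / sum(m[e, ])
  }
  confusion_model(m, concentration = concentration)
}

#' Latent-normal model for an ordinal rating scale
#'
#' Discrete ratings on a `scale_points`-point scale are generated by
#' thresholding a latent normal variable whose mean is the per-expression
#' latent mean plus a rater random intercept and fixed shifts for male
#' expressors and mirrored (R-version) images. Thresholds are
#' moment-matched per expression (see [calibrate_thresholds()]) so the
#' discrete mean reproduces the latent mean.
#'
#' @param scale_points Number of scale points (>= 2).
#' @param means,sds Named numeric vectors (one entry per expression) of
#'   latent means and SDs.
#' @param rater_intercept_sd SD of the rater random intercept, latent units.
#' @param male_effect Latent shift applied to male-expressor trials.
#' @param mirror_effect Latent shift applied to R-version trials.
#' @return An `ordinal_rating_model`.
#' @export
ordinal_rating_model <- function(scale_points, means, sds,
                                 rater_intercept_sd = 0.5,
                                 male_effect = 0, mirror_effect = 0) {
  stopifnot(scale_points >= 2, all(sds > 0), rater_intercept_sd >= 0)
  if (!setequal(names(means), expression_names()) ||
      !setequal(names(sds), expression_names())) {
    stop("means and sds must be named by the five expressions.", call. = FALSE)
  }
  if (any(means < 1 | means > scale_points)) {
    stop("Latent means must lie within [1, scale_points].", call. = FALSE)
  }
  structure(
    list(scale_points = as.integer(scale_points),
         means = means[expression_names()], sds = sds[expression_names()],
         rater_intercept_sd = rater_intercept_sd,
         male_effect = male_effect, mirror_effect = mirror_effect),
    class = "ordinal_rating_model"
  )
}

#' Default ordinal models for arousal and plausibility
#'
#' Arousal uses a 9-point pictorial (SAM-style) scale; per-expression
#' latent means/SDs are the observed rating means/SDs (neutral 2.63/1.66,
#' affiliative 4.50/1.60, disgust 5.44/1.66, dominance 5.29/1.59, reward
#' 6.72/1.39) with a male-expressor shift of -0.145. Plausibility uses a
#' 7-point scale (neutral 5.21/1.26, affiliative 4.66/1.39, disgust
#' 4.23/1.41, dominance 4.06/1.43, reward 5.02/1.33) with a
#' male-expressor shift of +0.248 and a mirrored-version shift of -0.169.
#' Rater intercept SD defaults to 0.5 latent units.
#'
#' @param rater_intercept_sd SD of the rater random intercept.
#' @param male_effect,mirror_effect Fixed latent shifts; see
#'   [ordinal_rating_model()].
#' @param scale_points Number of scale points.
#' @return An `ordinal_rating_model`.
#' @export
default_arousal_model <- function(scale_points = 9,
                                  rater_intercept_sd = 0.5,
                                  male_effect = -0.145,
                                  mirror_effect = 0) {
  ordinal_rating_model(
    scale_points = scale_points,
    means = c(reward = 6.72, affiliative = 4.50, dominance = 5.29,
              disgust = 5.44, neutral = 2.63),
    sds = c(reward = 1.39, affiliative = 1.60, dominance = 1.59,
            disgust = 1.66, neutral = 1.66),
    rater_intercept_sd = rater_intercept_sd,
    male_effect = male_effect, mirror_effect = mirror_effect
  )
}

#' @rdname default_arousal_model
#' @export
default_plausibility_model <- function(scale_points = 7,
                                       rater_intercept_sd = 0.5,
                                       male_effect = 0.248,
                                       mirror_effect = -0.169) {
  ordinal_rating_model(
    scale_points = scale_points,
    means = c(reward = 5.02, affiliative = 4.66, dominance = 4.06,
              disgust = 4.23, neutral = 5.21),
    sds = c(reward = 1.33, affiliative = 1.39, dominance = 1.43,
            disgust = 1.41, neutral = 1.26),
    rater_intercept_sd = rater_intercept_sd,
    male_effect = male_effect, mirror_effect = mirror_effect
  )
}

#' Moment-matched thresholds for discretising a latent normal
#'
#' Returns `scale_points - 1` strictly increasing cut points such that a
#' `N(latent_mean, latent_sd^2)` variable, discretised to the value
#' `1 + #\{cut points below it\}`, has expectation equal to `latent_mean`
#' (within 0.05). Cut points are equally spaced at half-integer
#' boundaries, shifted by a common offset found by root-finding; extreme
#' bins absorb the tails so discrete values always lie in
#' `1..scale_points`.
#'
#' @param latent_mean Target mean, in `[1, scale_points]`.
#' @param latent_sd Latent SD (> 0).
#' @param scale_points Number of scale points (>= 2).
#' @return Numeric vector of `scale_points - 1` thresholds.
#' @export
#' @examples
#' th <- calibrate_thresholds(6.72, 1.39, 9)
#' x <- seq(-2, 14, by = 0.001)
#' discrete_mean <- sum(
#'   (findInterval(x, th) + 1) * dnorm(x, 6.72, 1.39) * 0.001
#' )
calibrate_thresholds <- function(latent_mean, latent_sd, scale_points) {
  stopifnot(scale_points >= 2, latent_sd > 0)
  if (latent_mean < 1 || latent_mean > scale_points) {
    stop("latent_mean (", latent_mean, ") must lie within [1, ",
         scale_points, "].", call. = FALSE)
  }
  base <- seq_len(scale_points - 1L) + 0.5
  # E[discrete] = 1 + sum_j P(X > t_j); decreasing in the common offset
  discrete_mean <- function(offset) {
    1 + sum(1 - pnorm(base + offset, mean = latent_mean, sd = latent_sd))
  }
  span <- scale_points + 6 * latent_sd
  offset <- uniroot(function(o) discrete_mean(o) - latent_mean,
                    lower = -span, upper = span, tol = 1e-10)$root
  base + offset
}

# draw one Dirichlet(alpha) vector via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha # degenerate guard for tiny concentrations
  g / sum(g)
}

#' Simulate rating records for a design plan
#'
#' Expands the plan into trials and draws, for every trial, a chosen
#' category from the (optionally rater-perturbed) confusion row of the
#' intended expression, plus arousal and plausibility ratings from the
#' latent-normal ordinal models. Rater gender is assigned independently
#' (balanced Bernoulli); it has no generative effect, mirroring the
#' absence of rater-gender effects in validation ratings of this kind.
#' Output is fully reproducible given `seed`.
#'
#' @param plan A `design_plan`.
#' @param confusion A `confusion_model`.
#' @param arousal,plausibility `ordinal_rating_model`s; the mirror effect
#'   is applied to plausibility-style models whenever nonzero.
#' @param seed Integer seed (mandatory).
#' @return A tibble: the trial table plus `rater_gender`,
#'   `chosen_category`, `arousal`, `plausibility`.
#' @export
#' @examples
#' plan <- build_design()
#' ratings <- simulate_ratings(plan, seed = 7)
#' head(ratings)
simulate_ratings <- function(plan,
                             confusion = default_confusion_model(),
                             arousal = default_arousal_model(),
                             plausibility = default_plausibility_model(),
                             seed) {
  stopifnot(inherits(plan, "design_plan"),
            inherits(confusion, "confusion_model"),
            inherits(arousal, "ordinal_rating_model"),
            inherits(plausibility, "ordinal_rating_model"))
  if (missing(seed)) stop("A seed is required for simulation.", call. = FALSE)

  trials <- enumerate_trials(plan)
  n <- nrow(trials)
  raters <- sort(unique(trials$rater_id))
  expr <- expression_names()
  resp <- response_categories()

  set.seed(seed)

  # per-rater confusion rows (Dirichlet perturbation, optional)
  conc <- confusion$concentration
  rater_rows <- lapply(seq_along(raters), function(i) {
    if (is.null(conc)) return(confusion$matrix)
    t(apply(confusion$matrix, 1, function(row) {
      rdirichlet1(conc * pmax(row, 1e-12))
    }))
  })
  names(rater_rows) <- raters

  # rater gender: balanced assignment, shuffled
  rg <- sample(rep_len(c("female", "male"), length(raters)))
  names(rg) <- raters

  rater_idx <- match(trials$rater_id, raters)
  expr_idx <- match(trials$expression_intended, expr)

  draw_category <- function() {
    u <- runif(n)
    out <- character(n)
    by_rater <- split(seq_len(n), rater_idx)
    for (r in names(by_rater)) {
      rows <- rater_rows[[as.integer(r)]]
      for (e in seq_along(expr)) {
        s <- by_rater[[r]][expr_idx[by_rater[[r]]] == e]
        if (!length(s)) next
        out[s] <- resp[findInterval(u[s], cumsum(rows[e, ]),
                                    left.open = TRUE) + 1L]
      }
    }
    out
  }
  chosen <- draw_category()

  draw_ordinal <- function(model) {
    thresholds <- lapply(expr, function(e) {
      calibrate_thresholds(model$means[[e]], model$sds[[e]], model$scale_points)
    })
    intercepts <- rnorm(length(raters), 0, model$rater_intercept_sd)
    mu <- unname(model$means[expr_idx]) +
      intercepts[rater_idx] +
      model$male_effect * (trials$expressor_gender == "male") +
      model$mirror_effect * (trials$version == "R")
    latent <- rnorm(n, mu, unname(model$sds[expr_idx]))
    out <- integer(n)
    for (e in seq_along(expr)) {
      s <- which(expr_idx == e)
      out[s] <- findInterval(latent[s], thresholds[[e]]) + 1L
    }
    out
  }

  trials$rater_gender <- unname(rg[trials$rater_id])
  trials$chosen_category <- chosen
  trials$arousal <- draw_ordinal(arousal)
  trials$plausibility <- draw_ordinal(plausibility)
  trials
}
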