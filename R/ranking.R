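#' Per-expressor quality inputs from rating records
#'
#' For each expressor, tallies their own confusion matrix (pooled over
#' raters and versions), computes arcsine-transformed UHR per expression
#' and averages it over the five expressions, and averages the raw
#' plausibility ratings over all of the expressor's trials. These are the
#' two ingredients of the composite quality score.
#'
#' @param ratings A rating tibble.
#' @param variant Arcsine variant, see [arcsine_transform()].
#' @return A list of two tibbles: `uhr` (`expressor_id`, `gender`,
#'   `mean_arcsine_uhr`) and `plausibility` (`expressor_id`,
#'   `mean_plausibility`).
#' @export
expressor_inputs <- function(ratings, variant = c("asin_sqrt", "asin")) {
  variant <- match.arg(variant)
  cms <- tally_confusion(ratings, scope = "expressor")
  uhr <- dplyr::bind_rows(lapply(names(cms), function(id) {
    tibble::tibble(
      expressor_id = id,
      mean_arcsine_uhr = mean(
        arcsine_transform(unbiased_hit_rate(cms[[id]]), variant)
      )
    )
  }))
  gender <- dplyr::distinct(ratings, .data$expressor_id,
                            gender = .data$expressor_gender)
  uhr <- dplyr::inner_join(gender, uhr, by = "expressor_id")
  plaus <- dplyr::summarise(
    dplyr::group_by(ratings, .data$expressor_id),
    mean_plausibility = mean(.data$plausibility), .groups = "drop"
  )
  list(uhr = uhr, plausibility = plaus)
}

zscore <- function(x, sd_type) {
  denom <- switch(sd_type,
                  sample = sd(x),
                  population = sqrt(mean((x - mean(x))^2)))
  if (!is.finite(denom) || denom == 0) {
    warning("Constant scores; z-scores set to 0.", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / denom
}

#' Composite expressor quality scores
#'
#' Standardises each expressor's mean arcsine-transformed UHR and mean
#' plausibility across expressors (z-scores) and averages the two
#' z-scores into a composite quality score, so recognition accuracy and
#' apparent naturalness weigh equally.
#'
#' @param uhr Tibble with `expressor_id`, `gender`, `mean_arcsine_uhr`.
#' @param plausibility Tibble with `expressor_id`, `mean_plausibility`.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A tibble with the input columns plus `z_uhr`, `z_plaus` and
#'   `composite`.
#' @export
composite_scores <- function(uhr, plausibility,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!setequal(uhr$expressor_id, plausibility$expressor_id)) {
    only_u <- setdiff(uhr$expressor_id, plausibility$expressor_id)
    only_p <- setdiff(plausibility$expressor_id, uhr$expressor_id)
    stop("Expressor sets differ between the two inputs. ",
         "Only in UHR table: ", paste(only_u, collapse = ", "),
         "; only in plausibility table: ", paste(only_p, collapse = ", "),
         ".", call. = FALSE)
  }
  if (nrow(uhr) < 2) {
    stop("Need at least 2 expressors to standardise scores.", call. = FALSE)
  }
  scores <- dplyr::inner_join(uhr, plausibility, by = "expressor_id")
  scores$z_uhr <- zscore(scores$mean_arcsine_uhr, sd_type)
  scores$z_plaus <- zscore(scores$mean_plausibility, sd_type)
  scores$composite <- (scores$z_uhr + scores$z_plaus) / 2
  scores
}

#' Rank expressors and split them into quality subgroups
#'
#' Sorts expressors by composite score (descending; ties broken by
#' expressor id so the ranking is deterministic), assigns ranks 1..n, and
#' partitions the ranking into `n_subgroups` contiguous blocks of equal
#' size. Also reports the gender distribution within each subgroup, which
#' reveals whether one gender's stimuli systematically outrank the
#' other's.
#'
#' @param scores Output of [composite_scores()].
#' @param n_subgroups Number of equal-size subgroups; must divide the
#'   number of expressors.
#' @return A list with `ranked` (the scores plus `rank` and `subgroup`)
#'   and `gender_distribution` (`subgroup`, `male`, `female`).
#' @export
#' @examples
#' plan <- build_design()
#' ratings <- simulate_ratings(plan, seed = 3)
#' inputs <- expressor_inputs(ratings)
#' ranked <- rank_and_group(composite_scores(inputs$uhr, inputs$plausibility))
#' ranked$gender_distribution
rank_and_group <- function(scores, n_subgroups = 10) {
  n <- nrow(scores)
  if (n %% n_subgroups != 0) {
    stop("Number of expressors (", n, ") is not divisible into ",
         n_subgroups, " equal subgroups.", call. = FALSE)
  }
  size <- n %/% n_subgroups
  ranked <- scores[order(-scores$composite, scores$expressor_id), ]
  ranked$rank <- seq_len(n)
  ranked$subgroup <- (ranked$rank - 1L) %/% size + 1L
  dist <- dplyr::summarise(
    dplyr::group_by(ranked, .data$subgroup),
    male = sum(.data$gender == "male"),
    female = sum(.data$gender == "female"),
    .groups = "drop"
  )
  list(ranked = tibble::as_tibble(ranked), gender_distribution = dist)
}
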