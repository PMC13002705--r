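#' Item-by-category agreement table for nominal ratings
#'
#' Builds the input for Fleiss' kappa from rating records: one row per
#' item (image), one column per response category, counting how many
#' raters assigned the item to the category. All items must be rated by
#' the same number of raters, which the counterbalanced design guarantees
#' within a list.
#'
#' @param ratings Rating records for one list (or any balanced item set).
#' @return An integer matrix, items x categories, with constant row sums.
#' @export
agreement_table <- function(ratings) {
  item <- interaction(ratings$expressor_id, ratings$expression_intended,
                      ratings$version, drop = TRUE)
  tab <- table(item, factor(ratings$chosen_category,
                            levels = response_categories()))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Fleiss' kappa for multiple raters and nominal categories
#'
#' Chance-corrected agreement among n raters each assigning N items to
#' one of k nominal categories: `kappa = (Pbar - Pe) / (1 - Pe)`, where
#' `Pbar` is the mean per-item observed agreement (proportion of
#' concordant rater pairs) and `Pe` the sum of squared overall category
#' proportions. Equals 1 under unanimity on every item and is
#' approximately 0 when raters guess independently of the items.
#'
#' @param table Items x categories count matrix with constant row sums
#'   (>= 2 raters).
#' @return The kappa estimate; `NA` with a warning when every rating
#'   falls in a single category (expected agreement 1, kappa undefined).
#' @export
#' @examples
#' # two raters, one unanimous item and one split item
#' fleiss_kappa(matrix(c(2, 0, 1, 1), 2, byrow = TRUE)) # -1/3
fleiss_kappa <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  n <- unique(rowSums(table))
  if (length(n) != 1L) {
    stop("All items must be rated by the same number of raters; row sums ",
         "range over ", paste(range(rowSums(table)), collapse = "-"), ".",
         call. = FALSE)
  }
  if (n < 2) stop("Fleiss' kappa needs at least 2 raters.", call. = FALSE)
  p_item <- (rowSums(table^2) - n) / (n * (n - 1))
  p_bar <- mean(p_item)
  p_cat <- colSums(table) / sum(table)
  p_e <- sum(p_cat^2)
  if (abs(1 - p_e) < 1e-12) {
    warning("All ratings in one category; kappa undefined.", call. = FALSE)
    return(NA_real_)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Two-way random-effects intraclass correlations
#'
#' ICC(2,1) and ICC(2,k) for absolute agreement, from the two-way ANOVA
#' mean squares of a complete items-by-raters matrix: with `MSR` (items),
#' `MSC` (raters) and `MSE` (residual),
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` and
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`. The single-rater
#' form describes the reliability of one rater's scores; the average-score
#' form describes the reliability of the k-rater mean. For balanced
#' complete data this ANOVA estimator coincides with the two-way
#' cross-classified multilevel estimate. Negative estimates are reported
#' unclipped, with a flag.
#'
#' @param ratings_matrix Numeric matrix, items (images) as rows, raters as
#'   columns, no missing cells; >= 2 of each.
#' @return A list with `icc_2_1`, `icc_2_k`, the mean squares, and
#'   `flags` (character vector; `"negative_estimate"` and/or
#'   `"zero_variance"`).
#' @export
icc_two_way <- function(ratings_matrix) {
  m <- as.matrix(ratings_matrix)
  stopifnot(is.numeric(m), nrow(m) >= 2, ncol(m) >= 2, !anyNA(m))
  n <- nrow(m) # items
  k <- ncol(m) # raters
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  flags <- character()
  denom1 <- msr + (k - 1) * mse + k * (msc - mse) / n
  denomk <- msr + (msc - mse) / n
  if (denom1 <= 0 || denomk <= 0) {
    warning("Zero total variance; ICC undefined.", call. = FALSE)
    return(list(icc_2_1 = NA_real_, icc_2_k = NA_real_,
                msr = msr, msc = msc, mse = mse, flags = "zero_variance"))
  }
  icc1 <- (msr - mse) / denom1
  icck <- (msr - mse) / denomk
  if (icc1 < 0 || icck < 0) flags <- c(flags, "negative_estimate")
  list(icc_2_1 = icc1, icc_2_k = icck,
       msr = msr, msc = msc, mse = mse, flags = flags)
}

#' Interrater reliability summary across lists
#'
#' Computes Fleiss' kappa for the categorical choices and ICC(2,1)/(2,k)
#' for arousal and plausibility, per stimulus list (each list is a
#' complete items-by-raters block), then averages across lists. A pooled
#' kappa treating all lists' images as one item set is also reported.
#'
#' @param ratings A rating tibble covering one or more lists.
#' @return A tibble with columns `list_id` (`"mean"` and `"pooled"` for
#'   the aggregates), `statistic`, `value`.
#' @export
#' @examples
#' plan <- build_design(n_expressors = 10, raters_per_list = 4)
#' ratings <- simulate_ratings(plan, seed = 2)
#' reliability_summary(ratings)
reliability_summary <- function(ratings) {
  lists <- split(ratings, ratings$list_id)
  per_list <- dplyr::bind_rows(lapply(names(lists), function(lid) {
    df <- lists[[lid]]
    kap <- fleiss_kappa(agreement_table(df))
    wide <- function(col) {
      w <- tidyr::pivot_wider(
        df[, c("expressor_id", "expression_intended", "rater_id", col)],
        names_from = "rater_id", values_from = dplyr::all_of(col)
      )
      as.matrix(w[, -(1:2)])
    }
    icc_a <- icc_two_way(wide("arousal"))
    icc_p <- icc_two_way(wide("plausibility"))
    tibble::tibble(
      list_id = lid,
      statistic = c("fleiss_kappa",
                    "icc_2_1_arousal", "icc_2_k_arousal",
                    "icc_2_1_plausibility", "icc_2_k_plausibility"),
      value = c(kap, icc_a$icc_2_1, icc_a$icc_2_k,
                icc_p$icc_2_1, icc_p$icc_2_k)
    )
  }))
  means <- dplyr::summarise(
    dplyr::group_by(per_list, .data$statistic),
    value = mean(.data$value), .groups = "drop"
  )
  means$list_id <- "mean"
  pooled <- tibble::tibble(
    list_id = "pooled",
    statistic = "fleiss_kappa",
    value = fleiss_kappa(agreement_table(ratings))
  )
  dplyr::bind_rows(per_list, means[, c("list_id", "statistic", "value")],
                   pooled)
}
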