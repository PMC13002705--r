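#' Tally confusion matrices from rating records
#'
#' Cross-tabulates intended expression (rows) against chosen category
#' (columns), either pooled over all ratings or split by rater or by
#' expressor. Rows are the five intended expressions, columns the six
#' response categories; counts partition the input exactly.
#'
#' @param ratings A rating tibble as produced by [simulate_ratings()] or
#'   [read_ratings()].
#' @param scope `"overall"` for one pooled matrix, `"rater"` or
#'   `"expressor"` for one matrix per scope unit.
#' @return For `"overall"`, a `confusion_matrix` (an integer matrix with
#'   attributes `scope` and `scope_id`); otherwise a named list of them.
#' @export
#' @examples
#' plan <- build_design()
#' ratings <- simulate_ratings(plan, seed = 1)
#' tally_confusion(ratings)
tally_confusion <- function(ratings, scope = c("overall", "rater", "expressor")) {
  scope <- match.arg(scope)
  stopifnot(nrow(ratings) > 0)
  bad_cat <- !ratings$chosen_category %in% response_categories()
  if (any(bad_cat)) {
    stop("Unknown chosen_category at row(s) ",
         paste(head(which(bad_cat), 5), collapse = ", "),
         ": '", ratings$chosen_category[which(bad_cat)[1]], "'.",
         call. = FALSE)
  }
  bad_expr <- !ratings$expression_intended %in% expression_names()
  if (any(bad_expr)) {
    stop("Unknown expression_intended at row(s) ",
         paste(head(which(bad_expr), 5), collapse = ", "), ".", call. = FALSE)
  }

  one <- function(df, id = NA_character_) {
    counts <- table(
      factor(df$expression_intended, levels = expression_names()),
      factor(df$chosen_category, levels = response_categories())
    )
    m <- matrix(as.integer(counts), nrow = 5,
                dimnames = list(expression_names(), response_categories()))
    structure(m, class = c("confusion_matrix", class(m)),
              scope = scope, scope_id = id)
  }

  if (scope == "overall") return(one(ratings))
  key <- if (scope == "rater") ratings$rater_id else ratings$expressor_id
  groups <- split(ratings, key)
  mapply(one, groups, names(groups), SIMPLIFY = FALSE)
}

check_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") ||
              (is.matrix(cm) && is.numeric(cm)))
  if (any(cm < 0)) stop("Confusion counts must be non-negative.", call. = FALSE)
  invisible(cm)
}

#' Simple hit rate
#'
#' The percentage of presentations of each intended expression that were
#' answered with the matching category: `100 * diagonal / row total`.
#' With six response alternatives the theoretical chance level is 16.7%.
#'
#' @param cm A confusion matrix (intended expressions as rows, chosen
#'   categories as columns; the diagonal is taken over the shared labels).
#' @return Named numeric vector of percentages in `[0, 100]`; `NA` with a
#'   warning for any expression never presented.
#' @export
simple_hit_rate <- function(cm) {
  check_cm(cm)
  rows <- rownames(cm)
  totals <- rowSums(cm)
  hits <- cm[cbind(rows, rows)]
  if (any(totals == 0)) {
    warning("Zero presentations for: ",
            paste(rows[totals == 0], collapse = ", "),
            "; SHR undefined (NA).", call. = FALSE)
  }
  out <- ifelse(totals > 0, 100 * hits / totals, NA_real_)
  names(out) <- rows
  out
}

#' Unbiased hit rate (Wagner)
#'
#' Chance- and bias-corrected recognition accuracy: the squared diagonal
#' count divided by the product of the row marginal (presentations of the
#' intended expression) and the column marginal (uses of the matching
#' response). This is the joint probability that a stimulus is correctly
#' identified given that it is presented and that the response is
#' correctly used given that it is used. Defined only for the intended
#' expressions, never for the residual "other" response column.
#'
#' @param cm A confusion matrix.
#' @return Named numeric vector of proportions in `[0, 1]`, with attribute
#'   `zero_use` flagging expressions whose response category was never
#'   used (their UHR is reported as 0).
#' @export
#' @examples
#' m <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' unbiased_hit_rate(m) # a: 9 / (4 * 5) = 0.45
unbiased_hit_rate <- function(cm) {
  check_cm(cm)
  rows <- rownames(cm)
  row_m <- rowSums(cm)
  col_m <- colSums(cm)[rows]
  if (any(row_m == 0)) {
    stop("UHR undefined: zero presentations for ",
         paste(rows[row_m == 0], collapse = ", "), ".", call. = FALSE)
  }
  hits <- cm[cbind(rows, rows)]
  out <- ifelse(col_m > 0, hits^2 / (row_m * col_m), 0)
  names(out) <- rows
  if (any(col_m == 0)) attr(out, "zero_use") <- rows[col_m == 0]
  out
}

#' Chance-level unbiased hit rate
#'
#' The UHR expected from a responder whose choices are statistically
#' independent of the stimulus, computed from the matrix marginals:
#' `(row marginal / N) * (column marginal / N)` (Wagner's chance
#' performance). Observed UHR is compared against this value per
#' expression.
#'
#' @param cm A confusion matrix.
#' @return Named numeric vector of chance proportions.
#' @export
chance_uhr <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  if (n == 0) stop("Empty confusion matrix.", call. = FALSE)
  rows <- rownames(cm)
  out <- (rowSums(cm) / n) * (colSums(cm)[rows] / n)
  names(out) <- rows
  out
}

#' Arcsine square-root transform for proportions
#'
#' The variance-stabilising transform `asin(sqrt(p))`, mapping `[0, 1]`
#' onto `[0, pi/2 ~ 1.5708]`; used on UHR values before averaging and
#' modelling. The plain `asin(p)` variant is available for comparison.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param variant `"asin_sqrt"` (default) or `"asin"`.
#' @return Transformed value(s).
#' @export
#' @examples
#' arcsine_transform(c(0, 0.5, 1))
arcsine_transform <- function(p, variant = c("asin_sqrt", "asin")) {
  variant <- match.arg(variant)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("Proportions must lie in [0, 1].", call. = FALSE)
  }
  switch(variant, asin_sqrt = asin(sqrt(p)), asin = asin(p))
}

#' Per-rater recognition metrics in tidy form
#'
#' Computes SHR, UHR, arcsine-transformed UHR and chance UHR per rater and
#' expression (each rater contributes one confusion matrix over their own
#' ratings; 18 presentations per expression under the default design).
#'
#' @param ratings A rating tibble.
#' @param variant Arcsine variant, see [arcsine_transform()].
#' @return A tibble with columns `rater_id`, `expression`, `shr`, `uhr`,
#'   `arcsine_uhr`, `chance_uhr`.
#' @export
rater_metrics <- function(ratings, variant = c("asin_sqrt", "asin")) {
  variant <- match.arg(variant)
  cms <- tally_confusion(ratings, scope = "rater")
  dplyr::bind_rows(lapply(names(cms), function(r) {
    cm <- cms[[r]]
    uhr <- unbiased_hit_rate(cm)
    tibble::tibble(
      rater_id = r,
      expression = rownames(cm),
      shr = unname(simple_hit_rate(cm)),
      uhr = unname(uhr),
      arcsine_uhr = unname(arcsine_transform(uhr, variant)),
      chance_uhr = unname(chance_uhr(cm))
    )
  }))
}
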