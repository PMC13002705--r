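#' Build the Latin-square counterbalanced rating design
#'
#' Constructs the full assignment of expressors, expressions, mirror
#' versions, stimulus lists and raters used by the validation study design.
#' Expressors are split into `n_groups` gender-balanced groups; a cyclic
#' Latin square pairs each group with each expression exactly once across
#' the `n_groups` lists of a version, and the whole square is duplicated
#' for the mirrored (R) version. Each list is rated by its own group of
#' `raters_per_list` raters, so every image receives `raters_per_list`
#' ratings and every expressor-by-expression combination accrues
#' `2 * raters_per_list` ratings across the two versions, while no rater
#' ever sees two expressions of the same expressor.
#'
#' Under the defaults (90 expressors, 5 groups, 13 raters per list) the
#' plan has 10 lists of 90 images, 130 rater slots and 11,700 trials.
#'
#' @param n_expressors Number of expressors; must be divisible by
#'   `2 * n_groups` so each group can hold equal numbers of male and female
#'   expressors.
#' @param n_groups Number of expressor groups (= lists per version).
#' @param expressions Expression labels in Latin-square base order: the
#'   row of the square read by group for the first list. The default is the
#'   canonical rotation (reward, neutral, disgust, dominance, affiliative).
#' @param versions Version labels; `"L"` is the original orientation,
#'   `"R"` the horizontal mirror.
#' @param raters_per_list Raters assigned to each list.
#' @param seed Integer seed; rater identifiers and list membership are
#'   generated deterministically from it.
#' @return A `design_plan`: a list with tibbles `expressors`
#'   (`expressor_id`, `gender`, `group`), `lists` (`list_id`, `version`,
#'   `group`, `expression`), `raters` (`rater_id`, `list_id`) and a
#'   `params` list.
#' @export
#' @examples
#' plan <- build_design()
#' subset(plan$lists, list_id == 1)
build_design <- function(n_expressors = 90,
                         n_groups = 5,
                         expressions = c("reward", "neutral", "disgust",
                                         "dominance", "affiliative"),
                         versions = c("L", "R"),
                         raters_per_list = 13,
                         seed = 1L) {
  if (n_expressors %% (2L * n_groups) != 0L) {
    stop("n_expressors (", n_expressors, ") must be divisible by 2 * n_groups (",
         2L * n_groups, ") to keep groups gender-balanced.", call. = FALSE)
  }
  if (length(expressions) != n_groups) {
    stop("Need exactly one expression per group: got ", length(expressions),
         " expressions for ", n_groups, " groups.", call. = FALSE)
  }
  stopifnot(length(versions) >= 1L, raters_per_list >= 1L)

  per_gender <- n_expressors %/% 2L
  pad <- function(i) formatC(i, width = 2, flag = "0")
  expressors <- tibble::tibble(
    expressor_id = c(paste0("M", pad(seq_len(per_gender))),
                     paste0("F", pad(seq_len(per_gender)))),
    gender = rep(c("male", "female"), each = per_gender),
    # sorted id within gender, dealt cyclically across groups
    group = rep((seq_len(per_gender) - 1L) %% n_groups + 1L, times = 2L)
  )

  n_lists <- length(versions) * n_groups
  lists <- tidyr::expand_grid(
    version = versions,
    rotation = seq_len(n_groups),
    group = seq_len(n_groups)
  )
  lists$list_id <- (match(lists$version, versions) - 1L) * n_groups +
    lists$rotation
  # cyclic Latin square: list k assigns group g the expression at
  # position ((g - 1) + (k - 1)) mod n_groups in the base order
  lists$expression <- expressions[
    ((lists$group - 1L) + (lists$rotation - 1L)) %% n_groups + 1L
  ]
  lists <- lists[, c("list_id", "version", "group", "expression")]

  n_raters <- n_lists * raters_per_list
  set.seed(seed)
  rater_ids <- paste0("R", formatC(sample(n_raters), width = 3, flag = "0"))
  raters <- tibble::tibble(
    rater_id = rater_ids,
    list_id = rep(seq_len(n_lists), each = raters_per_list)
  )

  structure(
    list(
      expressors = expressors,
      lists = lists,
      raters = raters,
      params = list(
        n_expressors = n_expressors, n_groups = n_groups,
        expressions = expressions, versions = versions,
        raters_per_list = raters_per_list, seed = seed
      )
    ),
    class = "design_plan"
  )
}

#' @export
print.design_plan <- function(x, ...) {
  p <- x$params
  cat("<design_plan> ", p$n_expressors, " expressors in ", p$n_groups,
      " groups; ", nrow(x$lists) / p$n_groups, " lists (",
      paste(p$versions, collapse = "/"), "); ", p$raters_per_list,
      " raters per list (", nrow(x$raters), " total)\n", sep = "")
  invisible(x)
}

#' Validate a design plan
#'
#' Checks the counterbalancing guarantees: every list contains all
#' expressors exactly once; the group-by-list expression matrix of each
#' version is a Latin square; every image is rated by exactly
#' `raters_per_list` raters; every expressor-by-expression combination
#' accrues `versions * raters_per_list` ratings; no rater is assigned to
#' more than one list.
#'
#' @param plan A `design_plan`.
#' @return A tibble of violations (`rule`, `detail`); zero rows when the
#'   plan is valid.
#' @export
validate_design <- function(plan) {
  stopifnot(inherits(plan, "design_plan"))
  p <- plan$params
  bad <- list()
  note <- function(rule, detail) {
    tibble::tibble(rule = rule, detail = detail)
  }

  # each list covers every group exactly once -> every expressor once
  cover <- dplyr::count(plan$lists, .data$list_id)
  if (any(cover$n != p$n_groups) ||
      !all(tapply(plan$lists$group, plan$lists$list_id,
                  function(g) setequal(g, seq_len(p$n_groups))))) {
    bad <- c(bad, list(note("list_coverage",
                            "some list does not cover every group exactly once")))
  }

  # Latin-square rows/columns per version
  for (v in p$versions) {
    sq <- plan$lists[plan$lists$version == v, ]
    m <- tapply(sq$expression, list(sq$list_id, sq$group), identity)
    row_ok <- apply(m, 1, function(r) setequal(r, p$expressions))
    col_ok <- apply(m, 2, function(r) setequal(r, p$expressions))
    if (!all(row_ok) || !all(col_ok)) {
      off <- c(rownames(m)[!row_ok], colnames(m)[!col_ok])
      bad <- c(bad, list(note(
        "latin_square",
        paste0("version ", v, ": expression repeated within list/group (",
               paste(off, collapse = ", "), ")")
      )))
    }
  }

  # rater assignment: balanced, one list each
  rl <- dplyr::count(plan$raters, .data$list_id)
  if (nrow(rl) != nrow(unique(plan$lists["list_id"])) ||
      any(rl$n != p$raters_per_list)) {
    bad <- c(bad, list(note("raters_per_list",
                            "lists do not all have raters_per_list raters")))
  }
  if (anyDuplicated(plan$raters$rater_id)) {
    bad <- c(bad, list(note("rater_reuse",
                            "a rater is assigned to more than one list")))
  }

  # per-image and per-expressor-by-expression rating counts follow from the
  # above, but verify them directly on the enumerated trials
  if (length(bad) == 0L) {
    trials <- enumerate_trials(plan)
    per_image <- dplyr::count(trials, .data$expressor_id, .data$expression_intended,
                              .data$version)
    if (any(per_image$n != p$raters_per_list)) {
      bad <- c(bad, list(note("ratings_per_image",
                              "unequal ratings per image")))
    }
    per_combo <- dplyr::count(trials, .data$expressor_id, .data$expression_intended)
    if (any(per_combo$n != length(p$versions) * p$raters_per_list)) {
      bad <- c(bad, list(note("ratings_per_expressor_expression",
                              "unequal ratings per expressor x expression")))
    }
    seen <- dplyr::distinct(trials, .data$rater_id, .data$expressor_id,
                            .data$expression_intended)
    per_rater_expressor <- dplyr::count(seen, .data$rater_id, .data$expressor_id)
    if (any(per_rater_expressor$n != 1L)) {
      bad <- c(bad, list(note("rater_expressor_overlap",
                              "a rater sees two expressions of one expressor")))
    }
  }

  if (length(bad)) dplyr::bind_rows(bad) else note(character(), character())
}

#' Enumerate all rating trials of a plan
#'
#' Expands a design plan into its trial table: one row per rater-by-image
#' pairing, carrying the design metadata needed downstream. Under the
#' default plan this is 10 lists x 13 raters x 90 images = 11,700 rows.
#'
#' @param plan A `design_plan`.
#' @return A tibble with columns `rater_id`, `list_id`, `version`,
#'   `expressor_id`, `expressor_gender`, `expression_intended`.
#' @export
enumerate_trials <- function(plan) {
  stopifnot(inherits(plan, "design_plan"))
  images <- dplyr::inner_join(plan$lists, plan$expressors,
                              by = "group", relationship = "many-to-many")
  trials <- dplyr::inner_join(plan$raters, images,
                              by = "list_id", relationship = "many-to-many")
  trials <- dplyr::select(
    trials,
    "rater_id", "list_id", "version", "expressor_id",
    expressor_gender = "gender", expression_intended = "expression"
  )
  dplyr::arrange(tibble::as_tibble(trials),
                 .data$list_id, .data$rater_id, .data$expressor_id)
}
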