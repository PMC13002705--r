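#' Expression category labels
#'
#' The five intended expression categories used throughout the package, in
#' canonical order, and the six response categories offered to raters
#' (the five expressions plus `"other"`).
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' expression_names()
#' response_categories()
expression_names <- function() {
  c("reward", "affiliative", "dominance", "disgust", "neutral")
}

#' @rdname expression_names
#' @export
response_categories <- function() {
  c(expression_names(), "other")
}

# single AU row; tibble layout shared by every recipe
au_spec <- function(au, intensity = 50, essential = FALSE,
                    unilateral = FALSE, side = "none") {
  stopifnot(is.character(au), length(au) == 1L)
  tibble::tibble(
    au = au,
    intensity = as.numeric(intensity),
    essential = isTRUE(essential),
    unilateral = isTRUE(unilateral),
    side = side
  )
}

new_recipe <- function(expression, aus, note = NA_character_) {
  structure(
    list(expression = expression, aus = aus, note = note),
    class = "expression_recipe"
  )
}

#' @export
print.expression_recipe <- function(x, ...) {
  cat("<expression_recipe> ", x$expression, "\n", sep = "")
  if (nrow(x$aus) == 0L) {
    cat("  (no AU activation)\n")
  } else {
    print(x$aus, n = Inf)
  }
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Action-unit prototype registry for the five expressions
#'
#' Builds the registry of FACS action-unit configurations defining each
#' expression prototype: the three functional smile types (reward,
#' affiliative, dominance), disgust, and neutral. Essential AUs are those
#' required for the expression to read as its category; optional AUs may be
#' activated at any intensity. AU12 (Lip Corner Puller), shared by all three
#' smiles, is fixed at 80% intensity; every other AU defaults to a midpoint
#' 50% and can be overridden after construction. Composite synthesis tokens
#' (e.g. `"ahh"`, `"i"`, `"k"`, parenthesised AU groups) are kept as opaque
#' labels. The neutral prototype activates no AUs at all: neutral stimuli
#' are the unmodified base portraits.
#'
#' The dominance smile carries a unilateral Dimpler (`AU14_Unilateral`);
#' FACS synthesis software typically lacks asymmetric AU12, so the
#' asymmetric mouth-corner appearance is approximated by the unilateral
#' dimpler plus a manual mouth-corner adjustment, recorded in the recipe's
#' `note` field.
#'
#' @param dominance_side Side (`"left"` or `"right"`) for the unilateral
#'   dominance AUs. The choice of side is a study configuration decision.
#' @return A named list of `expression_recipe` objects, one per expression,
#'   with class `au_registry`.
#' @export
#' @examples
#' reg <- au_registry()
#' reg$reward$aus
au_registry <- function(dominance_side = c("left", "right")) {
  dominance_side <- match.arg(dominance_side)

  smile_au12 <- au_spec("AU12", intensity = 80, essential = TRUE)

  reward <- dplyr::bind_rows(
    au_spec("AU1", essential = TRUE),
    au_spec("AU2", essential = TRUE),
    au_spec("AU6"),
    au_spec("AU7"),
    smile_au12,
    au_spec("AU13", essential = TRUE),
    au_spec("AU14", essential = TRUE),
    au_spec("AU20"),
    au_spec("AU26"),
    au_spec("ahh"),
    au_spec("i"),
    au_spec("k")
  )

  affiliative <- dplyr::bind_rows(
    au_spec("AU6"),
    au_spec("AU7"),
    smile_au12,
    au_spec("AU13"),
    au_spec("AU14", essential = TRUE),
    au_spec("AU20"),
    au_spec("AU24", essential = TRUE)
  )

  dominance <- dplyr::bind_rows(
    au_spec("AU2"),
    au_spec("AU4"),
    au_spec("(AU1+2+4)"),
    au_spec("AU5", essential = TRUE),
    au_spec("AU6", essential = TRUE),
    au_spec("AU7"),
    au_spec("AU9", essential = TRUE),
    au_spec("AU10", essential = TRUE),
    smile_au12,
    au_spec("AU14_Unilateral", unilateral = TRUE, side = dominance_side),
    au_spec("AU25"),
    au_spec("AU17")
  )

  disgust <- dplyr::bind_rows(
    au_spec("AU4"),
    au_spec("(AU1+4)"),
    au_spec("AU6", essential = TRUE),
    au_spec("AU7"),
    au_spec("AU9"),
    au_spec("AU10", essential = TRUE),
    au_spec("AU11"),
    au_spec("AU16"),
    au_spec("AU15"),
    au_spec("AU17"),
    au_spec("AU20"),
    au_spec("AU24")
  )

  neutral <- au_spec("drop")[0, ] # empty tibble with the AU columns

  registry <- list(
    reward = new_recipe("reward", reward),
    affiliative = new_recipe("affiliative", affiliative),
    dominance = new_recipe(
      "dominance", dominance,
      note = paste(
        "Asymmetric AU12 is approximated by AU14_Unilateral plus a manual",
        "mouth-corner drag on the base head model."
      )
    ),
    disgust = new_recipe("disgust", disgust),
    neutral = new_recipe("neutral", neutral)
  )
  structure(registry, class = "au_registry")
}

#' Look up one expression prototype
#'
#' @param expression One of `expression_names()`.
#' @param registry Registry to look in; defaults to [au_registry()].
#' @return An `expression_recipe`.
#' @export
#' @examples
#' get_recipe("reward")
get_recipe <- function(expression, registry = au_registry()) {
  if (!is.character(expression) || length(expression) != 1L ||
      !expression %in% names(registry)) {
    stop(
      "Unknown expression ", deparse(substitute(expression)), ": '",
      paste(expression, collapse = ", "),
      "'. Valid options: ", paste(names(registry), collapse = ", "), ".",
      call. = FALSE
    )
  }
  registry[[expression]]
}

#' Validate an expression recipe
#'
#' Checks a recipe against the prototype semantics: intensities within
#' \[0, 100\], essential AUs actually activated, no duplicate AU labels,
#' unilateral AUs carrying a side. Violations are reported, not thrown, so
#' a recipe edited by hand can be screened before use.
#'
#' @param recipe An `expression_recipe`.
#' @param reference Optional reference recipe whose essential AUs must all
#'   be present; defaults to the registry entry for the same expression
#'   (set to `NULL` to skip the completeness check).
#' @return A tibble with columns `rule` and `detail`, one row per
#'   violation; zero rows when the recipe is valid.
#' @export
validate_recipe <- function(recipe,
                            reference = get_recipe(recipe$expression)) {
  stopifnot(inherits(recipe, "expression_recipe"))
  aus <- recipe$aus
  bad <- list()
  report <- function(rule, detail) {
    tibble::tibble(rule = rule, detail = detail)
  }

  out_of_range <- aus$au[aus$intensity < 0 | aus$intensity > 100]
  if (length(out_of_range)) {
    bad <- c(bad, list(report(
      "intensity_range",
      paste0("intensity outside [0, 100] for: ",
             paste(out_of_range, collapse = ", "))
    )))
  }
  inactive_essential <- aus$au[aus$essential & aus$intensity <= 0]
  if (length(inactive_essential)) {
    bad <- c(bad, list(report(
      "essential_inactive",
      paste0("essential AU with zero intensity: ",
             paste(inactive_essential, collapse = ", "))
    )))
  }
  dup <- unique(aus$au[duplicated(aus$au)])
  if (length(dup)) {
    bad <- c(bad, list(report(
      "duplicate_au", paste0("duplicated AU: ", paste(dup, collapse = ", "))
    )))
  }
  sideless <- aus$au[aus$unilateral & !aus$side %in% c("left", "right")]
  if (length(sideless)) {
    bad <- c(bad, list(report(
      "unilateral_without_side",
      paste0("unilateral AU with no side: ", paste(sideless, collapse = ", "))
    )))
  }
  if (!is.null(reference)) {
    missing <- setdiff(reference$aus$au[reference$aus$essential], aus$au)
    if (length(missing)) {
      bad <- c(bad, list(report(
        "missing_essential",
        paste0("essential AU absent: ", paste(missing, collapse = ", "))
      )))
    }
  }
  if (length(bad)) dplyr::bind_rows(bad) else report(character(), character())
}

#' Export and import the recipe registry as JSON
#'
#' The on-disk format is a top-level map from expression name to a list of
#' `{au, intensity, essential, unilateral, side}` records (plus an optional
#' `note`). The round trip `import_recipes(export_recipes(reg, f))`
#' reproduces the registry exactly.
#'
#' @param registry An `au_registry`.
#' @param path Destination (for export) or source (for import) file path.
#' @return `export_recipes()` returns `path` invisibly; `import_recipes()`
#'   returns an `au_registry`.
#' @export
export_recipes <- function(registry, path) {
  stopifnot(inherits(registry, "au_registry"))
  payload <- lapply(registry, function(r) {
    entry <- list(aus = r$aus)
    if (!is.na(r$note)) entry$note <- r$note
    entry
  })
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("Failed to write recipe registry to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' @rdname export_recipes
#' @export
import_recipes <- function(path) {
  if (!file.exists(path)) {
    stop("Recipe file not found: '", path, "'.", call. = FALSE)
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  registry <- lapply(names(payload), function(nm) {
    entry <- payload[[nm]]
    aus <- entry$aus
    if (is.null(aus) || (is.data.frame(aus) && nrow(aus) == 0L) ||
        length(aus) == 0L) {
      aus <- au_spec("drop")[0, ]
    } else {
      aus <- tibble::as_tibble(aus)
      aus$intensity <- as.numeric(aus$intensity)
    }
    new_recipe(nm, aus, note = entry$note %||% NA_character_)
  })
  names(registry) <- names(payload)
  structure(registry, class = "au_registry")
}
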