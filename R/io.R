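rating_columns <- function() {
  c("rater_id", "list_id", "version", "expressor_id", "expressor_gender",
    "expression_intended", "rater_gender", "chosen_category",
    "arousal", "plausibility")
}

#' Read and validate a rating table
#'
#' Reads a long-format CSV of rating records (one row per rater x image)
#' and validates it: required columns present, category labels known,
#' ordinal values within their scale bounds. Errors name the first
#' offending rows so malformed exports are easy to locate.
#'
#' @param path CSV file path.
#' @param arousal_points,plausibility_points Scale bounds used for
#'   validation.
#' @return A rating tibble.
#' @export
read_ratings <- function(path, arousal_points = 9, plausibility_points = 7) {
  if (!file.exists(path)) {
    stop("Ratings file not found: '", path, "'.", call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) stop("No records in '", path, "'.", call. = FALSE)
  missing <- setdiff(rating_columns(), names(df))
  if (length(missing)) {
    stop("Missing column(s) in '", path, "': ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  complain <- function(bad, what) {
    if (any(bad)) {
      stop("Invalid ", what, " at row(s) ",
           paste(head(which(bad), 5), collapse = ", "), " of '", path, "'.",
           call. = FALSE)
    }
  }
  complain(!df$expression_intended %in% expression_names(),
           "expression_intended")
  complain(!df$chosen_category %in% response_categories(), "chosen_category")
  complain(!df$version %in% c("L", "R"), "version")
  complain(is.na(df$arousal) | df$arousal < 1 | df$arousal > arousal_points |
             df$arousal != round(df$arousal), "arousal value")
  complain(is.na(df$plausibility) | df$plausibility < 1 |
             df$plausibility > plausibility_points |
             df$plausibility != round(df$plausibility), "plausibility value")
  df$list_id <- as.integer(df$list_id)
  df$arousal <- as.integer(df$arousal)
  df$plausibility <- as.integer(df$plausibility)
  tibble::as_tibble(df[, rating_columns()])
}

#' @rdname read_ratings
#' @param ratings A rating tibble.
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(ratings[, rating_columns()], path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: design parameters, simulator
#' models (or an external ratings CSV to ingest instead of simulating),
#' analysis switches and the output directory. `read_config()` loads the
#' same structure from a JSON or YAML file; any field omitted there keeps
#' its default.
#'
#' @param seed Integer seed (mandatory when simulating).
#' @param out_dir Output directory for the run.
#' @param n_expressors,n_groups,raters_per_list Design parameters, see
#'   [build_design()].
#' @param ratings_csv Optional path to an existing rating table; when set,
#'   simulation is skipped and the file is ingested.
#' @param confusion,arousal,plausibility Simulator models.
#' @param arcsine_variant,sd_type,n_subgroups Analysis switches.
#' @return A `run_config` list.
#' @export
run_config <- function(seed,
                       out_dir = "smileval-run",
                       n_expressors = 90, n_groups = 5, raters_per_list = 13,
                       ratings_csv = NULL,
                       confusion = default_confusion_model(),
                       arousal = default_arousal_model(),
                       plausibility = default_plausibility_model(),
                       arcsine_variant = "asin_sqrt",
                       sd_type = "sample",
                       n_subgroups = 10) {
  if (missing(seed) && is.null(ratings_csv)) {
    stop("A seed is required for simulation runs.", call. = FALSE)
  }
  structure(
    list(seed = if (missing(seed)) NA_integer_ else as.integer(seed),
         out_dir = out_dir,
         n_expressors = n_expressors, n_groups = n_groups,
         raters_per_list = raters_per_list,
         ratings_csv = if (is.null(ratings_csv)) NULL
                       else normalizePath(ratings_csv, mustWork = TRUE),
         confusion = confusion, arousal = arousal,
         plausibility = plausibility,
         arcsine_variant = arcsine_variant, sd_type = sd_type,
         n_subgroups = n_subgroups),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON or YAML configuration file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("Config file not found: '", path, "'.", call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- setdiff(names(formals(run_config)), "seed")
  unknown <- setdiff(names(raw), c(allowed, "seed"))
  if (length(unknown)) {
    stop("Unknown config field(s): ", paste(unknown, collapse = ", "), ".",
         call. = FALSE)
  }
  do.call(run_config, raw)
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message("[smileval] ", stage, ": ", ...)
}

#' Run the full validation pipeline
#'
#' Executes design -> simulate (or ingest) -> recognition metrics ->
#' reliability -> ranking, writing every stage output as CSV plus a JSON
#' manifest recording the parameters, seed and package version, so any
#' output can be re-derived from the manifest alone. Identical
#' configuration and seed yield identical outputs.
#'
#' @param config A [run_config()].
#' @param verbose Emit one log line per stage.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 1, out_dir = tempfile("run"))
#' res <- run_pipeline(cfg, verbose = FALSE)
#' names(res$files)
#' }
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  files <- list()
  fail <- function(stage, e) {
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, code) {
    stage_log(verbose, stage, "running")
    tryCatch(code, error = function(e) fail(stage, e))
  }

  plan <- run_stage("design", {
    p <- build_design(n_expressors = config$n_expressors,
                      n_groups = config$n_groups,
                      raters_per_list = config$raters_per_list,
                      seed = if (is.na(config$seed)) 1L else config$seed)
    problems <- validate_design(p)
    if (nrow(problems) > 0) {
      stop("invalid design: ", paste(problems$rule, collapse = ", "))
    }
    readr::write_csv(enumerate_trials(p), path("trials.csv"))
    files$trials <- path("trials.csv")
    p
  })

  ratings <- run_stage("ratings", {
    r <- if (!is.null(config$ratings_csv)) {
      read_ratings(config$ratings_csv,
                   arousal_points = config$arousal$scale_points,
                   plausibility_points = config$plausibility$scale_points)
    } else {
      simulate_ratings(plan, confusion = config$confusion,
                       arousal = config$arousal,
                       plausibility = config$plausibility,
                       seed = config$seed)
    }
    write_ratings(r, path("ratings.csv"))
    files$ratings <- path("ratings.csv")
    r
  })

  metrics <- run_stage("metrics", {
    per_rater <- rater_metrics(ratings, variant = config$arcsine_variant)
    readr::write_csv(per_rater, path("rater_metrics.csv"))
    files$rater_metrics <- path("rater_metrics.csv")
    cm <- tally_confusion(ratings)
    cm_tbl <- tibble::as_tibble(as.data.frame.matrix(unclass(cm)),
                                rownames = "expression_intended")
    readr::write_csv(cm_tbl, path("confusion_counts.csv"))
    files$confusion <- path("confusion_counts.csv")
    list(per_rater = per_rater, confusion = cm)
  })

  relia <- run_stage("reliability", {
    out <- reliability_summary(ratings)
    readr::write_csv(out, path("reliability.csv"))
    files$reliability <- path("reliability.csv")
    out
  })

  ranking <- run_stage("ranking", {
    inputs <- expressor_inputs(ratings, variant = config$arcsine_variant)
    scores <- composite_scores(inputs$uhr, inputs$plausibility,
                               sd_type = config$sd_type)
    out <- rank_and_group(scores, n_subgroups = config$n_subgroups)
    readr::write_csv(out$ranked, path("expressor_ranking.csv"))
    files$ranking <- path("expressor_ranking.csv")
    out
  })

  manifest <- list(
    package = "smileval",
    version = as.character(utils::packageVersion("smileval")),
    seed = config$seed,
    parameters = list(
      n_expressors = config$n_expressors, n_groups = config$n_groups,
      raters_per_list = config$raters_per_list,
      ratings_csv = config$ratings_csv,
      arcsine_variant = config$arcsine_variant, sd_type = config$sd_type,
      n_subgroups = config$n_subgroups
    ),
    outputs = files
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(verbose, "done", length(files), " stage outputs in ",
            config$out_dir)
  invisible(list(plan = plan, ratings = ratings, metrics = metrics,
                 reliability = relia, ranking = ranking,
                 manifest = manifest, files = files))
}
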