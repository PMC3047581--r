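# The project store: one versioned, human-readable JSON file holding the
# three collections (experiment profiles, calibration profiles + OCF, amplicon
# registry) together with parameters and flat analysis/quantification results.
# Heavy derived objects (per-cycle fits, expansion traces) are recomputable
# deterministically and are not persisted.

PROJECT_SCHEMA_VERSION <- 1L

# Column type schema used to restore exact types after a JSON round-trip.
PROJECT_COL_TYPES <- list(
  integer = c(
    "cycle", "amplicon_size", "start_cycle", "window_start", "window_size",
    "n_replicates", "n_valid", "n", "realized_molecules", "seed"
  ),
  double = c(
    "fluorescence", "known_ng", "baseline", "emax", "delta_e", "fmax", "r2",
    "avg_f0", "c_half", "drift_score", "arc_score", "molecules",
    "avg_profile_molecules", "f0_cv", "c_half_range", "no_molecules",
    "n_molecules", "f0", "ocf", "noise_sd", "strength", "size"
  ),
  logical = c("is_calibration", "valid"),
  character = c(
    "profile_id", "run_id", "well", "sample_name", "amplicon_name",
    "strandedness", "flag", "stop_reason", "classification", "path",
    "notes", "name", "distortion"
  )
)

cast_cols <- function(df) {
  if (is.null(df)) {
    return(NULL)
  }
  df <- as_tibble(df)
  for (col in names(df)) {
    if (col %in% PROJECT_COL_TYPES$integer) {
      df[[col]] <- as.integer(df[[col]])
    } else if (col %in% PROJECT_COL_TYPES$double) {
      df[[col]] <- as.double(df[[col]])
    } else if (col %in% PROJECT_COL_TYPES$logical) {
      df[[col]] <- as.logical(df[[col]])
    } else if (col %in% PROJECT_COL_TYPES$character) {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Create a project
#'
#' A project bundles the three collections — experiment profiles, calibration
#' profiles (with their OCF once computed), and the amplicon registry that
#' supplies amplicon sizes at import — plus analysis parameters and flat
#' results tables. Amplicon names referenced by profiles that do not resolve
#' in the registry trigger a warning (their size must then be annotated
#' inline, as it is in the template format).
#'
#' @param profiles Long-format sample profiles (or `NULL`).
#' @param calibration Long-format calibration profiles (or `NULL`).
#' @param amplicons Amplicon registry tibble (`name`, `size`, optional
#'   `notes`); built from the profiles when omitted.
#' @param params An [lre_params()] object.
#' @param analyses,quantities Flat results tables (list-columns are dropped).
#' @param ocf An [compute_ocf()] result.
#' @param truth Optional ground-truth table (synthetic projects).
#' @return An object of class `lre_project`.
#' @export
lre_project <- function(profiles = NULL, calibration = NULL, amplicons = NULL,
                        params = lre_params(), analyses = NULL,
                        quantities = NULL, ocf = NULL, truth = NULL) {
  if (!is.null(profiles)) profiles <- validate_profiles(profiles)
  if (!is.null(calibration)) calibration <- validate_profiles(calibration)
  all_prof <- dplyr::bind_rows(profiles, calibration)
  if (is.null(amplicons) && !is.null(all_prof) && nrow(all_prof) &&
    all(c("amplicon_name", "amplicon_size") %in% names(all_prof))) {
    amplicons <- dplyr::distinct(
      tibble(name = all_prof$amplicon_name, size = as.double(all_prof$amplicon_size))
    )
  }
  if (!is.null(all_prof) && nrow(all_prof) && !is.null(amplicons)) {
    unresolved <- setdiff(unique(all_prof$amplicon_name), amplicons$name)
    if (length(unresolved)) {
      warn(paste0(
        "Amplicon(s) not in the registry (inline sizes used): ",
        paste(unresolved, collapse = ", ")
      ))
    }
  }
  drop_list_cols <- function(df) {
    if (is.null(df)) {
      return(NULL)
    }
    as_tibble(df)[, !vapply(df, is.list, TRUE), drop = FALSE]
  }
  structure(
    list(
      schema_version = PROJECT_SCHEMA_VERSION,
      params = params,
      profiles = profiles,
      calibration = calibration,
      amplicons = amplicons,
      analyses = drop_list_cols(analyses),
      quantities = drop_list_cols(quantities),
      ocf = ocf,
      truth = truth
    ),
    class = "lre_project"
  )
}

#' @export
print.lre_project <- function(x, ...) {
  np <- if (is.null(x$profiles)) 0L else dplyr::n_distinct(x$profiles$profile_id)
  nc <- if (is.null(x$calibration)) 0L else dplyr::n_distinct(x$calibration$profile_id)
  cat(sprintf(
    "<lre_project> schema v%d | %d sample profile(s), %d calibration profile(s), %d amplicon(s)\n",
    x$schema_version, np, nc, if (is.null(x$amplicons)) 0L else nrow(x$amplicons)
  ))
  if (!is.null(x$ocf)) cat(sprintf("  OCF: %.6g units/ng\n", x$ocf$value))
  if (!is.null(x$quantities)) cat(sprintf("  %d quantified replicate set(s)\n", nrow(x$quantities)))
  invisible(x)
}

#' Save and load a project
#'
#' The project is stored as a single versioned JSON file (UTF-8,
#' full-precision numbers). `load_project(save_project(p))` reproduces the
#' project exactly, including parameters, analysis results and the OCF. A
#' schema-version mismatch raises an explicit migration error; a truncated or
#' malformed file raises a parse error naming the file.
#'
#' @param project An [lre_project()].
#' @param path File path (`.json`).
#' @return `save_project` returns `path` invisibly; `load_project` returns the
#'   restored `lre_project`.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "lre_project"))
  payload <- list(
    schema_version = project$schema_version,
    params = unclass(project$params),
    profiles = project$profiles,
    calibration = project$calibration,
    amplicons = project$amplicons,
    analyses = project$analyses,
    quantities = project$quantities,
    ocf = if (is.null(project$ocf)) NULL else unclass(project$ocf),
    truth = project$truth
  )
  json <- jsonlite::toJSON(payload,
    dataframe = "columns", digits = NA, na = "null", null = "null",
    auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) abort(sprintf("Project file not found: %s", path))
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      abort(sprintf("Cannot parse project file '%s': %s", path, conditionMessage(e)))
    }
  )
  ver <- payload$schema_version
  if (is.null(ver) || !identical(as.integer(ver), PROJECT_SCHEMA_VERSION)) {
    abort(sprintf(
      "Project schema version %s does not match supported version %d; explicit migration required.",
      ver %||% "<missing>", PROJECT_SCHEMA_VERSION
    ))
  }
  params <- payload$params
  prm <- lre_params(
    min_fc = params$min_fc,
    f0_threshold = params$f0_threshold,
    initial_window_size = params$initial_window_size,
    baseline_cycles = params$baseline_cycles,
    baseline = params$baseline,
    drift_threshold = params$drift_threshold,
    r2_threshold = params$r2_threshold,
    arc_threshold = params$arc_threshold,
    low_copy_threshold = params$low_copy_threshold,
    c_half_warn_range = params$c_half_warn_range,
    conv = params$conv
  )
  ocf <- if (is.null(payload$ocf)) {
    NULL
  } else {
    structure(
      list(
        value = payload$ocf$value, sd = payload$ocf$sd %||% NA_real_,
        n = as.integer(payload$ocf$n),
        per_profile = cast_cols(payload$ocf$per_profile),
        known_ng = payload$ocf$known_ng
      ),
      class = "lre_ocf"
    )
  }
  structure(
    list(
      schema_version = as.integer(ver),
      params = prm,
      profiles = cast_cols(payload$profiles),
      calibration = cast_cols(payload$calibration),
      amplicons = cast_cols(payload$amplicons),
      analyses = cast_cols(payload$analyses),
      quantities = cast_cols(payload$quantities),
      ocf = ocf,
      truth = cast_cols(payload$truth)
    ),
    class = "lre_project"
  )
}
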