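# Import/export tables. The canonical template layout (CSV, or XLSX sheet 1
# with the identical logical layout) is one column per profile:
#
#   field,<profile_id>,<profile_id>,...
#   well,A1,A2,...
#   run_id,run1,run1,...
#   sample_name,COL1,COL1,...
#   amplicon_name,g12240,g12240,...
#   amplicon_size,150,150,...
#   strandedness,single,single,...
#   quantity_ng,,            (calibration templates only)
#   1,52041,51913,...        (cycle-numbered fluorescence rows)
#   2,...
#
# UTF-8, period decimal separator, RFC 4180 quoting. Numeric cells round-trip
# at IEEE double precision.

TEMPLATE_HEADER_FIELDS <- c(
  "well", "run_id", "sample_name", "amplicon_name",
  "amplicon_size", "strandedness"
)

#' Read a profile import template
#'
#' Reads the documented template layout from CSV or XLSX (first sheet): one
#' column per replicate profile, header rows carrying the annotations, then
#' cycle-numbered fluorescence rows. Columns with a defect (non-numeric
#' reading, missing annotation, bad strandedness) are rejected individually
#' with a warning giving the row/column coordinates; remaining columns import
#' normally. Counts are conserved and reported — nothing is dropped silently.
#'
#' @param path Path to a `.csv` or `.xlsx` template.
#' @param kind `"sample"` or `"calibration"`; calibration templates must carry
#'   a `quantity_ng` header row (the known DNA mass per reaction, ng) and set
#'   `is_calibration`.
#' @return Long-format profile tibble (see [validate_profiles()]).
#' @export
read_profile_table <- function(path, kind = c("sample", "calibration")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path, col_types = "text", col_names = TRUE))
  } else {
    as.data.frame(readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    ))
  }
  if (ncol(raw) < 2L) abort(sprintf("%s: template needs a field column plus at least one profile column.", path))
  keys <- raw[[1]]
  need <- c("sample_name", "amplicon_name", "amplicon_size", "strandedness")
  if (kind == "calibration") need <- c(need, "quantity_ng")
  missing <- setdiff(need, keys)
  if (length(missing)) {
    abort(sprintf(
      "%s: missing header row(s): %s.", path,
      paste(missing, collapse = ", ")
    ))
  }
  cycle_rows <- grepl("^[0-9]+$", keys)
  cycles <- as.integer(keys[cycle_rows])
  if (length(cycles) < 10L || cycles[1] != 1L || any(diff(cycles) != 1L)) {
    abort(sprintf("%s: cycle rows must be numbered 1..n consecutively with n >= 10.", path))
  }

  hdr <- function(col, field) {
    i <- match(field, keys)
    if (is.na(i)) NA_character_ else raw[i, col]
  }
  profiles <- list()
  rejected <- character()
  for (col in 2:ncol(raw)) {
    id <- names(raw)[col]
    reject <- function(msg) {
      warn(sprintf("%s: column %d ('%s') rejected: %s", path, col, id, msg))
      rejected <<- c(rejected, id)
    }
    ann <- vapply(TEMPLATE_HEADER_FIELDS, hdr, "", col = col)
    if (is.na(ann[["sample_name"]]) || is.na(ann[["amplicon_name"]])) {
      reject("missing sample_name or amplicon_name")
      next
    }
    size <- suppressWarnings(as.numeric(ann[["amplicon_size"]]))
    if (!is.finite(size) || size < 1) {
      reject(sprintf("bad amplicon_size '%s' (row %d)", ann[["amplicon_size"]], match("amplicon_size", keys)))
      next
    }
    if (!ann[["strandedness"]] %in% c("double", "single")) {
      reject(sprintf("bad strandedness '%s' (row %d)", ann[["strandedness"]], match("strandedness", keys)))
      next
    }
    readings_chr <- raw[cycle_rows, col]
    readings <- suppressWarnings(as.numeric(readings_chr))
    bad <- which(!is.finite(readings))
    if (length(bad)) {
      reject(sprintf(
        "non-numeric fluorescence '%s' at cycle %d (row %d)",
        readings_chr[bad[1]], cycles[bad[1]], which(cycle_rows)[bad[1]]
      ))
      next
    }
    known_ng <- if (kind == "calibration") {
      q <- suppressWarnings(as.numeric(hdr(col, "quantity_ng")))
      if (!is.finite(q) || q <= 0) {
        reject("calibration column without a positive quantity_ng")
        next
      }
      q
    } else {
      NA_real_
    }
    profiles[[id]] <- tibble(
      profile_id = id,
      run_id = ann[["run_id"]] %|NA|% "run1",
      well = ann[["well"]] %|NA|% id,
      sample_name = ann[["sample_name"]],
      amplicon_name = ann[["amplicon_name"]],
      amplicon_size = as.integer(size),
      strandedness = ann[["strandedness"]],
      is_calibration = kind == "calibration",
      known_ng = known_ng,
      cycle = cycles,
      fluorescence = readings
    )
  }
  if (!length(profiles)) {
    abort(sprintf("%s: no importable profile columns (all %d rejected).", path, length(rejected)))
  }
  inform(sprintf(
    "%s: imported %d profile(s), rejected %d.", path, length(profiles), length(rejected)
  ))
  validate_profiles(dplyr::bind_rows(profiles))
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Write a profile import template
#'
#' Writes a long-format profile table in the canonical template layout (CSV;
#' see [read_profile_table()]). The writer is the exact inverse of the reader:
#' numeric cells round-trip at IEEE double precision.
#'
#' @param profiles Long-format profile tibble.
#' @param path Output path (`.csv`).
#' @param kind `"sample"` or `"calibration"` (adds the `quantity_ng` row).
#' @return `path`, invisibly.
#' @export
write_profile_template <- function(profiles, path, kind = c("sample", "calibration")) {
  kind <- match.arg(kind)
  profiles <- validate_profiles(profiles)
  ids <- unique(profiles$profile_id)
  per <- split(profiles, factor(profiles$profile_id, levels = ids))
  cycles <- sort(unique(profiles$cycle))
  fields <- TEMPLATE_HEADER_FIELDS
  if (kind == "calibration") fields <- c(fields, "quantity_ng")

  header_value <- function(df, field) {
    if (field == "quantity_ng") {
      return(format_cell(df$known_ng[1]))
    }
    if (!field %in% names(df)) {
      return("")
    }
    v <- df[[field]][1]
    if (is.na(v)) "" else as.character(v)
  }
  rows <- lapply(fields, function(f) {
    c(f, vapply(per, header_value, "", field = f))
  })
  for (cy in cycles) {
    rows[[length(rows) + 1L]] <- c(
      as.character(cy),
      vapply(per, function(df) {
        v <- df$fluorescence[match(cy, df$cycle)]
        format_cell(v)
      }, "")
    )
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("field", ids)
  readr::write_csv(as_tibble(as.data.frame(mat, check.names = FALSE)), path, progress = FALSE)
  invisible(path)
}

# Full-precision numeric cell (17 significant digits round-trips any double).
format_cell <- function(x) {
  if (!length(x) || is.na(x)) {
    return("")
  }
  formatC(x, digits = 17, format = "g")
}

#' Export quantification results, sorted into groups
#'
#' Writes one CSV file per group (run, sample or amplicon) into a directory —
#' the worksheet-per-group export layout. Columns: run, sample, amplicon,
#' `no_molecules` (the molecule count), `c_half`, `emax`, `delta_e`, `fmax`,
#' `avg_f0`, window position, quantification path and flags. Numbers are
#' written at full precision; unquantified sets appear with empty quantity
#' cells and their flag.
#'
#' @param quantified Result of [quantify_replicates()].
#' @param dir Output directory (created if needed).
#' @param sort_by `"run"`, `"sample"` or `"amplicon"`.
#' @return Tibble of written files (`group`, `path`, `n_sets`), invisibly.
#' @export
write_export <- function(quantified, dir, sort_by = c("run", "sample", "amplicon")) {
  sort_by <- match.arg(sort_by)
  flat <- export_table(quantified)
  key <- switch(sort_by,
    run = flat$run_id,
    sample = flat$sample_name,
    amplicon = flat$amplicon_name
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- split(flat, factor(key, levels = unique(key)))
  out <- lapply(names(groups), function(g) {
    p <- file.path(dir, sprintf("by_%s_%s.csv", sort_by, gsub("[^A-Za-z0-9_.-]", "_", g)))
    readr::write_csv(groups[[g]], p, progress = FALSE, na = "")
    tibble(group = g, path = p, n_sets = nrow(groups[[g]]))
  })
  invisible(dplyr::bind_rows(out))
}

#' Flatten quantification results for export
#'
#' One row per replicate set with the exported columns only (no list-columns):
#' the kinetic parameters come from the set's average-profile analysis.
#'
#' @param quantified Result of [quantify_replicates()].
#' @return A flat tibble.
#' @export
export_table <- function(quantified) {
  pull_avg <- function(a, col) {
    if (is.null(a) || !nrow(a)) NA_real_ else a[[col]][1]
  }
  tibble(
    run_id = quantified$run_id,
    sample_name = quantified$sample_name,
    amplicon_name = quantified$amplicon_name,
    amplicon_size = quantified$amplicon_size,
    strandedness = quantified$strandedness,
    no_molecules = quantified$molecules,
    c_half = quantified$c_half,
    emax = vapply(quantified$avg_analysis, pull_avg, 1.0, col = "emax"),
    delta_e = vapply(quantified$avg_analysis, pull_avg, 1.0, col = "delta_e"),
    fmax = vapply(quantified$avg_analysis, pull_avg, 1.0, col = "fmax"),
    avg_f0 = vapply(quantified$avg_analysis, pull_avg, 1.0, col = "avg_f0"),
    window_start = vapply(quantified$avg_analysis, function(a) {
      if (is.null(a) || !nrow(a)) NA_integer_ else a$window_start[1]
    }, 1L),
    window_size = vapply(quantified$avg_analysis, function(a) {
      if (is.null(a) || !nrow(a)) NA_integer_ else a$window_size[1]
    }, 1L),
    n_replicates = quantified$n_replicates,
    n_valid = quantified$n_valid,
    f0_cv = quantified$f0_cv,
    path = quantified$path,
    flag = quantified$flag
  )
}

#' Profile label in the standard display template
#'
#' `"<amplicon> @ <sample> (<E_max>) <molecules>"` — the label format used for
#' profiles in logs and exports.
#'
#' @param amplicon,sample Character annotations.
#' @param emax Fitted maximal efficiency.
#' @param molecules Molecule count (may be `NA` for flagged profiles).
#' @return Character vector of labels.
#' @export
profile_label <- function(amplicon, sample, emax, molecules) {
  sprintf(
    "%s @ %s (%.3f) %s", amplicon, sample, emax,
    ifelse(is.na(molecules), "-", format(round(molecules), big.mark = ",", trim = TRUE))
  )
}
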