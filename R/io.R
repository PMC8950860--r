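axis_suffixes <- c("_X", "_Y", "_Z")

# render numeric columns as shortest-guaranteed-round-trip decimal text
# (17 significant digits), so a written trial reloads bit-for-bit
format_full_precision <- function(df) {
  out <- df
  for (nm in names(out)) {
    x <- out[[nm]]
    if (is.double(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      out[[nm]] <- s
    }
  }
  out
}

# read a CSV of doubles exactly: parse fields as text, convert with R's
# correctly-rounded strtod (vroom's fast parser can be off by one ulp)
read_numeric_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  out <- tibble(.rows = nrow(raw))
  for (nm in names(raw)) out[[nm]] <- as.numeric(raw[[nm]])
  out
}

marker_col_names <- function() {
  nodes <- grid_layout()$node
  as.vector(t(outer(nodes, axis_suffixes, paste0)))
}

#' Save a trial to disk
#'
#' Writes three files into `out_dir`: the marker trajectories
#' (`<id>_r<rep>_markers.csv` or `.trc`), the IMU streams
#' (`<id>_r<rep>_imus.csv`, 54 signal columns + time) and a JSON metadata
#' record. The CSV dialects are one row per frame/sample with full-precision
#' (round-trippable) numbers, so [load_trial()] inverts this exactly.
#'
#' @param trial A `resp_trial`.
#' @param out_dir Output directory (created if absent).
#' @param format Marker format: `"csv"` (default) or `"trc"`.
#' @return Invisibly, the named character vector of written paths
#'   (`markers`, `imus`, `meta`).
#' @export
save_trial <- function(trial, out_dir, format = c("csv", "trc")) {
  format <- match.arg(format)
  if (nrow(trial$markers) == 0 || nrow(trial$imus) == 0) {
    abort("Refusing to write an empty trial (0 frames).")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, sprintf("%s_r%d", trial$subject_id, trial$repetition))
  mpath <- paste0(stem, "_markers.", format)
  ipath <- paste0(stem, "_imus.csv")
  jpath <- paste0(stem, "_meta.json")
  if (format == "csv") {
    readr::write_csv(format_full_precision(trial$markers), mpath,
                     progress = FALSE, na = "")
  } else {
    write_trc(trial$markers, mpath, rate = attr(trial$markers, "rate") %||% trial$marker_rate)
  }
  readr::write_csv(format_full_precision(trial$imus), ipath,
                   progress = FALSE, na = "")
  # flat JSON written by hand so numeric fields keep full (17-digit)
  # precision; jsonlite caps doubles at 15 significant digits
  jnum <- function(x) if (is.na(x)) "null" else sprintf("%.17g", x)
  jstr <- function(x) if (is.na(x)) "null" else paste0('"', x, '"')
  writeLines(paste0(
    "{\n",
    '  "subject_id": ', jstr(trial$subject_id), ",\n",
    '  "repetition": ', trial$repetition, ",\n",
    '  "sex": ', jstr(trial$sex), ",\n",
    '  "body_mass": ', jnum(trial$body_mass), ",\n",
    '  "height": ', jnum(trial$height), ",\n",
    '  "marker_rate": ', jnum(attr(trial$markers, "rate") %||% trial$marker_rate), ",\n",
    '  "imu_rate": ', jnum(trial$imu_rate), ",\n",
    '  "aligned": ', if (isTRUE(trial$aligned)) "true" else "false", "\n",
    "}"
  ), jpath)
  invisible(c(markers = mpath, imus = ipath, meta = jpath))
}

check_uniform_time <- function(time, rate, what, tol = 1e-6) {
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(abs(dt - 1 / rate)) > tol) {
      abort(sprintf("%s timestamps are not uniform at %g Hz (max deviation %.3g s).",
                    what, rate, max(abs(dt - 1 / rate))))
    }
  }
  invisible(TRUE)
}

#' Load a trial from disk
#'
#' Reads a marker file (CSV dialect `time, <NODE>_X, <NODE>_Y, <NODE>_Z` in
#' mm, or TRC) plus the single-file IMU CSV (`time, imu1_ax ... imu9_gz` in
#' SI units) and a metadata record, validating the type invariants: all 45
#' grid nodes present (a missing node is named in the error), 9 x 6 IMU
#' channels, and uniform timestamps at the declared rates.
#'
#' @param marker_path Marker CSV or TRC path.
#' @param imu_path IMU CSV path.
#' @param meta Metadata: a JSON path or a named list with at least
#'   `subject_id`, `repetition` and `body_mass`.
#' @return A `resp_trial`.
#' @export
load_trial <- function(marker_path, imu_path, meta) {
  if (is.character(meta)) meta <- jsonlite::fromJSON(meta)
  for (f in c(marker_path, imu_path)) {
    if (!file.exists(f)) abort(paste0("File not found: ", f))
  }
  if (grepl("\\.trc$", marker_path, ignore.case = TRUE)) {
    markers <- read_trc(marker_path)
  } else {
    markers <- read_numeric_csv(marker_path)
  }
  missing_cols <- setdiff(c("time", marker_col_names()), names(markers))
  if (length(missing_cols)) {
    nodes <- unique(sub("_[XYZ]$", "", setdiff(missing_cols, "time")))
    abort(paste0("Marker file lacks node(s): ",
                 paste(nodes, collapse = ", ")))
  }
  imus <- read_numeric_csv(imu_path)
  miss_imu <- setdiff(c("time", imu_channel_names()), names(imus))
  if (length(miss_imu)) {
    abort(paste0("IMU file lacks channel(s): ", paste(miss_imu, collapse = ", "),
                 " (expected 9 IMUs x 6 channels)."))
  }
  marker_rate <- meta$marker_rate %||% 50
  imu_rate <- meta$imu_rate %||% 100
  check_uniform_time(markers$time, marker_rate, "Marker")
  check_uniform_time(imus$time, imu_rate, "IMU")
  attr(markers, "rate") <- marker_rate
  attr(imus, "rate") <- imu_rate
  tr <- new_trial(
    subject_id = meta$subject_id, repetition = as.integer(meta$repetition),
    sex = meta$sex %||% NA_character_, body_mass = meta$body_mass,
    height = meta$height %||% NA_real_,
    markers = markers, imus = imus,
    marker_rate = marker_rate, imu_rate = imu_rate
  )
  tr$aligned <- isTRUE(meta$aligned)
  tr
}

#' Write marker trajectories as TRC
#'
#' Minimal TRC (Track Row Column) writer: the standard 5-line header
#' followed by tab-separated frames in mm. Missing samples are written as
#' empty fields.
#'
#' @param markers Marker tibble (`time` + `<NODE>_X/_Y/_Z` in mm).
#' @param path Output path.
#' @param rate Sampling rate (Hz).
#' @export
write_trc <- function(markers, path, rate = 50) {
  nodes <- unique(sub("_[XYZ]$", "", setdiff(names(markers), "time")))
  n <- nrow(markers)
  hdr <- c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", rate, rate, n, length(nodes), rate, n),
    paste(c("Frame#", "Time", as.vector(rbind(nodes, "", ""))), collapse = "\t"),
    paste(c("", "", as.vector(t(outer(c("X", "Y", "Z"), seq_along(nodes),
                                      paste0)))), collapse = "\t")
  )
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  body <- vapply(seq_len(n), function(i) {
    vals <- unlist(lapply(nodes, function(nd) {
      fmt(c(markers[[paste0(nd, "_X")]][i], markers[[paste0(nd, "_Y")]][i],
            markers[[paste0(nd, "_Z")]][i]))
    }))
    paste(c(sprintf("%d", i), sprintf("%.8f", markers$time[i]), vals),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, "", body), path)
}

#' Read a TRC marker file
#'
#' @param path TRC path.
#' @return Marker tibble (`time` + `<NODE>_X/_Y/_Z`), with a `rate`
#'   attribute from the header. Empty fields become NA (flagged missing).
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) abort("Not a valid TRC file (truncated header).")
  hdr3 <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(hdr3[1])
  names_row <- strsplit(lines[4], "\t")[[1]]
  nodes <- names_row[-(1:2)]
  nodes <- nodes[nzchar(nodes)]
  first_data <- 6L
  while (first_data <= length(lines) && !nzchar(trimws(lines[first_data]))) {
    first_data <- first_data + 1L
  }
  rows <- strsplit(lines[first_data:length(lines)], "\t")
  rows <- rows[vapply(rows, length, 0L) >= 2]
  parse_num <- function(s) ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)
  mat <- t(vapply(rows, function(r) {
    r <- c(r, rep("", 2 + 3 * length(nodes) - length(r)))
    parse_num(r[2:(2 + 3 * length(nodes))])
  }, numeric(1 + 3 * length(nodes))))
  out <- tibble(time = mat[, 1])
  for (k in seq_along(nodes)) {
    out[[paste0(nodes[k], "_X")]] <- mat[, 3 * k - 1]
    out[[paste0(nodes[k], "_Y")]] <- mat[, 3 * k]
    out[[paste0(nodes[k], "_Z")]] <- mat[, 3 * k + 1]
  }
  attr(out, "rate") <- rate
  out
}

#' Save / load a cohort directory
#'
#' `save_cohort()` writes `subjects.csv` plus the three per-trial files for
#' every trial; `load_cohort()` re-reads them. Ground truth is not
#' serialised (it belongs to the generator, not the measurement record).
#'
#' @param cohort A `resp_cohort`.
#' @param out_dir Directory.
#' @param format Marker format passed to [save_trial()].
#' @return `save_cohort()`: invisibly, `out_dir`. `load_cohort()`: a
#'   `resp_cohort` (without truths).
#' @export
save_cohort <- function(cohort, out_dir, format = "csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
                   progress = FALSE)
  for (tr in cohort$trials) save_trial(tr, out_dir, format = format)
  invisible(out_dir)
}

#' @rdname save_cohort
#' @param dir Directory written by `save_cohort()`.
#' @param config Configuration attached to the loaded cohort.
#' @export
load_cohort <- function(dir, config = resp_config()) {
  subj_path <- file.path(dir, "subjects.csv")
  if (!file.exists(subj_path)) abort(paste0("No subjects.csv in ", dir))
  subjects <- readr::read_csv(subj_path, show_col_types = FALSE, progress = FALSE)
  metas <- sort(list.files(dir, pattern = "_meta\\.json$", full.names = TRUE))
  trials <- list()
  for (jp in metas) {
    stem <- sub("_meta\\.json$", "", jp)
    mpath <- if (file.exists(paste0(stem, "_markers.csv"))) {
      paste0(stem, "_markers.csv")
    } else paste0(stem, "_markers.trc")
    tr <- load_trial(mpath, paste0(stem, "_imus.csv"), jp)
    trials[[paste0(tr$subject_id, "_r", tr$repetition)]] <- tr
  }
  structure(list(subjects = subjects, trials = trials, truths = NULL,
                 config = config),
            class = "resp_cohort")
}

#' Serialise trained coefficients to JSON
#'
#' @param fits Named list of `resp_fit` objects (one per compartment), or a
#'   `resp_loocv` fold entry.
#' @param path Output JSON path.
#' @param model Model id recorded in the file.
#' @export
write_coefficients <- function(fits, path, model = fits[[1]]$model) {
  payload <- list(
    model = model,
    compartments = lapply(fits, function(f) {
      list(compartment = f$compartment,
           coefficients = as.list(f$coefficients),
           objective = f$objective, n_trials = f$n_trials)
    })
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
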