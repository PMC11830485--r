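#' Read and validate an SMBG log CSV
#'
#' Strict schema: columns `participant_id`, `datetime` (ISO-8601, UTC),
#' `slot` (`prebreakfast`/`predinner`), `glucose_mmol_l`, `assisted` (0/1).
#' Missing columns are a hard error. Malformed rows (unknown slot label,
#' non-numeric or non-physiological glucose, unparseable datetime) are
#' collected in the `rejected` attribute and dropped; if they make up 5% or
#' more of the file the read fails. Duplicate (participant, day, slot)
#' readings keep the earliest, the rest are logged in the `duplicates`
#' attribute.
#'
#' @param path Path to the CSV file.
#' @return A tibble `participant_id`, `time` (POSIXct UTC), `slot`, `glucose`
#'   (mmol/L), `assisted` (logical), with attributes `rejected` (tibble: row,
#'   reason) and `duplicates` (dropped duplicate rows).
#' @export
readSmbg <- function(path) {
  cols <- c("participant_id", "datetime", "slot", "glucose_mmol_l", "assisted")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("SMBG log is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tm <- parse_iso_datetime(raw$datetime)
  glucose <- suppressWarnings(as.numeric(raw$glucose_mmol_l))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(tm)] <- "malformed datetime"
  reason[is.na(glucose) | glucose <= 0 | glucose >= 50] <- "invalid glucose"
  reason[!(raw$slot %in% SMBG_SLOTS)] <- "unknown slot label"
  bad <- !is.na(reason)
  rejected <- tibble::tibble(row = which(bad), reason = reason[bad])
  if (nrow(raw) > 0 && mean(bad) >= 0.05) {
    stop(sprintf("%d of %d SMBG rows are invalid (>= 5%%); aborting. First problems: %s",
                 sum(bad), nrow(raw),
                 paste(utils::head(unique(reason[bad]), 3), collapse = "; ")))
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id[!bad],
    time = tm[!bad],
    slot = raw$slot[!bad],
    glucose = glucose[!bad],
    assisted = raw$assisted[!bad] %in% c("1", "TRUE", "true")
  )
  out <- out[order(out$participant_id, out$time), ]
  dup <- duplicated(paste(out$participant_id, as.Date(out$time, tz = "UTC"), out$slot))
  duplicates <- out[dup, ]
  out <- out[!dup, ]
  attr(out, "rejected") <- rejected
  attr(out, "duplicates") <- duplicates
  out
}

parse_iso_datetime <- function(x) {
  tm <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  alt <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  tm[is.na(tm)] <- alt[is.na(tm)]
  tm
}

#' Write an SMBG log CSV
#' @param readings Tibble as returned by [readSmbg()] (or `runTrial()$smbg`,
#'   whose `glucose` column maps to `glucose_mmol_l`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeSmbg <- function(readings, path) {
  df <- data.frame(
    participant_id = readings$participant_id,
    datetime = format(readings$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    slot = readings$slot,
    glucose_mmol_l = readings$glucose,
    assisted = as.integer(readings$assisted %in% c(TRUE, 1L, "1"))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a regimen history CSV
#'
#' Columns: `participant_id`, `effective_date` (ISO date) or `day` (0-based
#' study day), `morning_dose_units`, `evening_dose_units`, `weight_kg`.
#'
#' @param path Path to the CSV file.
#' @param study_start Date of study day 1, used to convert `effective_date`
#'   to study days when `day` is absent.
#' @return A tibble `participant_id`, `day`, `morning_dose`, `evening_dose`,
#'   `weight_kg` suitable for [summarizeTrial()].
#' @export
readRegimen <- function(path, study_start = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("participant_id", "morning_dose_units", "evening_dose_units", "weight_kg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("regimen file is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if ("day" %in% names(raw)) {
    day <- as.integer(raw$day)
  } else if ("effective_date" %in% names(raw)) {
    if (is.null(study_start)) stop("study_start is required to interpret effective_date")
    day <- as.integer(as.Date(raw$effective_date) - as.Date(study_start))
  } else {
    stop("regimen file needs a `day` or `effective_date` column")
  }
  tibble::tibble(
    participant_id = as.character(raw$participant_id), day = day,
    morning_dose = as.integer(raw$morning_dose_units),
    evening_dose = as.integer(raw$evening_dose_units),
    weight_kg = as.numeric(raw$weight_kg)
  )
}

#' Read a laboratory results CSV
#'
#' Columns: `participant_id`, `week` (0/12/24), `hba1c_pct`, `fpg_mmol_l`,
#' `bmi`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with those columns, typed.
#' @export
readLabs <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("participant_id", "week", "hba1c_pct", "fpg_mmol_l", "bmi")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("labs file is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    week = as.integer(raw$week),
    hba1c_pct = as.numeric(raw$hba1c_pct),
    fpg_mmol_l = as.numeric(raw$fpg_mmol_l),
    bmi = as.numeric(raw$bmi)
  )
}

#' Read a simulation/titration configuration from YAML
#'
#' Top-level keys map to [simConfig()] arguments; the optional `rules` block
#' maps to [titrationConfig()].
#'
#' @param path Path to a YAML file.
#' @return A [simConfig()].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$rules)) y$rules <- do.call(titrationConfig, y$rules)
  do.call(simConfig, y)
}

#' Write the trial summary report files
#'
#' Writes `timepoints.csv`, `changes.csv`, `adherence.csv`, `incidence.csv`
#' and a human-readable `report.txt` mirroring the outcome-table layout, with
#' deterministic column order and formatting: identical inputs give identical
#' bytes.
#'
#' @param summary A [summarizeTrial()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeReport <- function(summary, out_dir) {
  stopifnot(inherits(summary, "trial_summary"))
  if (summary$n_participants < 1) stop("empty cohort: nothing to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- c()
  wr <- function(df, name) {
    f <- file.path(out_dir, name)
    df <- as.data.frame(df)
    for (cl in names(df)) if (is.factor(df[[cl]])) df[[cl]] <- as.character(df[[cl]])
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE, eol = "\n")
    files[[name]] <<- f
  }
  wr(summary$timepoints, "timepoints.csv")
  wr(summary$changes, "changes.csv")
  if (!is.null(summary$adherence)) wr(summary$adherence, "adherence.csv")
  if (!is.null(summary$incidence)) wr(summary$incidence, "incidence.csv")
  txt <- file.path(out_dir, "report.txt")
  writeLines(utils::capture.output(print(summary)), txt)
  files[["report.txt"]] <- txt
  invisible(unlist(files))
}

#' Read report CSVs back
#' @param out_dir Directory written by [writeReport()].
#' @return List of tibbles keyed by file stem.
#' @export
readReport <- function(out_dir) {
  out <- list()
  for (stem in c("timepoints", "changes", "adherence", "incidence")) {
    f <- file.path(out_dir, paste0(stem, ".csv"))
    if (file.exists(f)) out[[stem]] <- tibble::as_tibble(utils::read.csv(f))
  }
  out
}

#' Run manifest for reproducibility
#'
#' Records the configuration hash, seed, package version and input-file
#' checksums that uniquely identify a run; re-running with the same manifest
#' inputs reproduces the outputs byte-for-byte.
#'
#' @param config A [simConfig()] (or any serialisable configuration object).
#' @param seed The seed in force.
#' @param inputs Character vector of input file paths to checksum.
#' @return An object of class `run_manifest`.
#' @export
runManifest <- function(config, seed, inputs = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config, tf)
  structure(
    list(
      config_hash = unname(tools::md5sum(tf)),
      seed = seed,
      package_version = as.character(utils::packageVersion("glucotitr")),
      input_checksums = if (length(inputs)) tools::md5sum(inputs) else character(),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest\n")
  cat("  config md5 :", x$config_hash, "\n")
  cat("  seed       :", x$seed, "\n")
  cat("  glucotitr  :", x$package_version, "\n")
  for (f in names(x$input_checksums)) {
    cat(sprintf("  input %s : %s\n", f, x$input_checksums[[f]]))
  }
  invisible(x)
}
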