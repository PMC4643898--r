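# Spectrum and cohort input/output: two-column delimited text, a JCAMP-DX
# AFFN subset, cohort metadata CSV, and the pipeline configuration file.

#' Construct a spectrum object
#'
#' A spectrum is a frequency-domain, phased, baseline-corrected 1D trace:
#' a strictly increasing ppm axis with one intensity per point.
#'
#' @param ppm Numeric ppm axis.
#' @param intensity Numeric intensities, same length as `ppm`.
#' @param sample_id Identifier.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "sample") {
  if (length(ppm) != length(intensity)) {
    stop_sepsimet("sepsimet_format_error",
                  "ppm and intensity lengths differ (%d vs %d)",
                  length(ppm), length(intensity))
  }
  if (any(!is.finite(ppm)) || any(!is.finite(intensity))) {
    stop_sepsimet("sepsimet_format_error",
                  "spectrum contains non-finite values")
  }
  if (is.unsorted(ppm, strictly = TRUE)) {
    if (is.unsorted(rev(ppm), strictly = TRUE)) {
      stop_sepsimet("sepsimet_format_error",
                    "ppm axis is not strictly monotone")
    }
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %.3f to %.3f ppm>\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Supports plain two-column delimited text (ppm, intensity; comma, tab or
#' whitespace separated, `#` comments allowed) and a JCAMP-DX subset with an
#' AFFN `##XYDATA=(X++(Y..Y))` block. Descending-ppm storage is reordered to
#' ascending on load.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension/content), `"two-column"` or
#'   `"jcamp-dx"`.
#' @param sample_id Identifier; defaults to the file name without extension.
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path, dialect = c("auto", "two-column", "jcamp-dx"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_sepsimet("sepsimet_format_error", "file not found: %s", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^##", lines[seq_len(min(5, length(lines)))])))
      "jcamp-dx" else "two-column"
  }
  s <- if (dialect == "jcamp-dx") parse_jcamp(lines, path)
       else parse_two_column(lines, path)
  new_spectrum(s$ppm, s$intensity, sample_id)
}

parse_two_column <- function(lines, path) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    stop_sepsimet("sepsimet_format_error", "%s: no data rows", path)
  }
  ppm <- numeric(length(keep)); intensity <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(lines[i]), "[,;\t ]+")[[1]]
    if (length(fields) != 2L) {
      stop_sepsimet("sepsimet_format_error",
                    "%s line %d: expected 2 columns, found %d",
                    path, i, length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_sepsimet("sepsimet_format_error",
                    "%s line %d: non-numeric value '%s'",
                    path, i, fields[which(is.na(vals))[1]])
    }
    ppm[j] <- vals[1]; intensity[j] <- vals[2]
  }
  list(ppm = ppm, intensity = intensity)
}

jcamp_field <- function(lines, key) {
  hit <- grep(sprintf("^##%s\\s*=", key), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub("^[^=]*=", "", hit[1]))
}

parse_jcamp <- function(lines, path) {
  start <- grep("^##XYDATA\\s*=", lines)
  if (!length(start)) {
    stop_sepsimet("sepsimet_format_error",
                  "%s: no ##XYDATA block", path)
  }
  npoints <- as.integer(jcamp_field(lines, "NPOINTS"))
  firstx <- as.numeric(jcamp_field(lines, "FIRSTX"))
  lastx <- as.numeric(jcamp_field(lines, "LASTX"))
  xfac <- as.numeric(jcamp_field(lines, "XFACTOR")); if (is.na(xfac)) xfac <- 1
  yfac <- as.numeric(jcamp_field(lines, "YFACTOR")); if (is.na(yfac)) yfac <- 1
  if (is.na(npoints) || is.na(firstx) || is.na(lastx)) {
    stop_sepsimet("sepsimet_format_error",
                  "%s: missing NPOINTS/FIRSTX/LASTX", path)
  }
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  y <- numeric(0)
  for (i in seq_along(body)) {
    fields <- strsplit(trimws(body[i]), "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)) || length(vals) < 2L) {
      stop_sepsimet("sepsimet_format_error",
                    "%s ##XYDATA line %d: unparseable", path, i)
    }
    y <- c(y, vals[-1] * yfac)  # first value on each line is the X check value
  }
  if (length(y) != npoints) {
    stop_sepsimet("sepsimet_format_error",
                  "%s: NPOINTS=%d but %d ordinates read",
                  path, npoints, length(y))
  }
  # FIRSTX/LASTX are in actual units; XFACTOR scales only the per-line checks
  x <- seq(firstx, lastx, length.out = npoints)
  list(ppm = x, intensity = y)
}

#' Write a spectrum to disk
#'
#' @param s A `spectrum`.
#' @param path Output path.
#' @param dialect `"two-column"` (tab-separated ppm/intensity) or
#'   `"jcamp-dx"` (AFFN `(X++(Y..Y))` block).
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(s, path, dialect = c("two-column", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (dialect == "two-column") {
    writeLines(sprintf("%.12g\t%.12g", s$ppm, s$intensity), path)
  } else {
    n <- length(s$ppm)
    per_line <- 6L
    idx <- split(seq_len(n), ceiling(seq_len(n) / per_line))
    body <- vapply(idx, function(ii) {
      paste(c(sprintf("%.12g", s$ppm[ii[1]]),
              sprintf("%.12g", s$intensity[ii])), collapse = " ")
    }, character(1))
    writeLines(c(
      sprintf("##TITLE=%s", s$sample_id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=NMR SPECTRUM",
      "##XUNITS=PPM",
      "##YUNITS=ARBITRARY",
      "##XFACTOR=1",
      "##YFACTOR=1",
      sprintf("##FIRSTX=%.12g", s$ppm[1]),
      sprintf("##LASTX=%.12g", s$ppm[n]),
      sprintf("##NPOINTS=%d", n),
      "##XYDATA=(X++(Y..Y))",
      body,
      "##END="), path)
  }
  invisible(path)
}

cohort_required_cols <- c("sample_id", "subject_id", "timepoint", "outcome",
                          "SOFA_0h", "SOFA_24h", "SOFA_72h", "age", "sex")
cohort_outcomes <- c("survivor", "non-survivor")
cohort_timepoints <- c("0h", "24h")

#' Validate a cohort metadata table
#'
#' @param cohort A data.frame with the cohort schema.
#' @return The validated table, classed `cohort_table`.
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing)) {
    stop_sepsimet("sepsimet_format_error",
                  "cohort table lacks columns: %s",
                  paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(cohort$outcome), cohort_outcomes)
  if (length(bad)) {
    stop_sepsimet("sepsimet_format_error",
                  "unknown outcome label(s) %s; allowed: %s",
                  paste(sQuote(bad), collapse = ", "),
                  paste(cohort_outcomes, collapse = ", "))
  }
  bad <- setdiff(unique(cohort$timepoint), cohort_timepoints)
  if (length(bad)) {
    stop_sepsimet("sepsimet_format_error",
                  "unknown timepoint label(s) %s; allowed: %s",
                  paste(sQuote(bad), collapse = ", "),
                  paste(cohort_timepoints, collapse = ", "))
  }
  key <- paste(cohort$subject_id, cohort$timepoint)
  if (anyDuplicated(key)) {
    stop_sepsimet("sepsimet_format_error",
                  "duplicate (subject, timepoint) pair: %s",
                  key[anyDuplicated(key)])
  }
  sofa <- as.matrix(cohort[, c("SOFA_0h", "SOFA_24h", "SOFA_72h")])
  if (any(sofa < 0 | sofa > 24, na.rm = TRUE)) {
    stop_sepsimet("sepsimet_format_error", "SOFA scores must lie in [0, 24]")
  }
  per_subj <- tapply(cohort$outcome, cohort$subject_id,
                     function(o) length(unique(o)))
  if (any(per_subj > 1)) {
    stop_sepsimet("sepsimet_format_error",
                  "outcome must be constant within subject")
  }
  if (!inherits(cohort, "cohort_table")) {
    class(cohort) <- c("cohort_table", "data.frame")
  }
  cohort
}

#' Read a cohort metadata CSV
#'
#' @param path CSV path (comma-separated, UTF-8, header row mandatory).
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  log_msg("INFO", "read cohort: ", nrow(cohort), " rows from ", path)
  validate_cohort(cohort)
}

#' Write a cohort metadata CSV
#'
#' Ground-truth concentration columns (`conc.*`) are dropped: the analysis
#' pipeline never sees them. Use [write_cohort_truth()] to persist them
#' separately.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  keep <- !grepl("^conc\\.", names(cohort))
  utils::write.csv(as.data.frame(cohort)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth concentrations (synthetic cohorts only)
#'
#' @param cohort A `cohort_table` carrying `conc.*` columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_truth <- function(cohort, path) {
  cols <- c("sample_id", grep("^conc\\.", names(cohort), value = TRUE))
  utils::write.csv(as.data.frame(cohort)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits one two-column spectrum file per sample, `cohort.csv` (metadata,
#' no ground truth), `truth.csv` (ground-truth concentrations) and
#' `manifest.csv` mapping sample ids to spectrum files.
#'
#' @param cohort A `cohort_table`.
#' @param spectra Named list of `spectrum` objects (names = sample ids).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data.frame.
#' @export
write_dataset <- function(cohort, spectra, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, paste0(names(spectra), ".tsv"))
  for (i in seq_along(spectra)) write_spectrum(spectra[[i]], files[i])
  manifest <- data.frame(sample_id = names(spectra),
                         file = basename(files), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  if (any(grepl("^conc\\.", names(cohort)))) {
    write_cohort_truth(cohort, file.path(dir, "truth.csv"))
  }
  log_msg("INFO", "wrote dataset to ", dir, " (", length(spectra),
          " spectra)")
  invisible(manifest)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the workflow in one structured list; written
#' verbatim (YAML) into every output directory for provenance.
#'
#' @return A named list of sections.
#' @export
default_config <- function() {
  list(
    binning = list(low_ppm = 0.5, high_ppm = 10, width_ppm = 0.005),
    normalization = list(region_low_ppm = 0.5, region_high_ppm = 4.4),
    exclusion = list(water_region = NULL),  # e.g. c(4.5, 5.0); off by default
    referencing = list(tsp_window = c(-0.2, 0.2)),
    outliers = list(alpha = 0.95, cum_var = 0.95),
    pls = list(max_components = 5, cv_repeats = 10, cv_folds = 7),
    permutation = list(n_perm = 200, statistic = "Q2_press"),
    prognosis = list(ridge = 0.1, predictors = "both-timepoints",
                     n_boot = 2000, conf_level = 0.95)
  )
}

#' Read / write the pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns the configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
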