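# Readers and writers for plate-reader time series, layouts, standards and
# result reports. Long format (time_s, well, signal) is canonical on disk;
# wide time-by-well matrices are supported read-only since plate readers
# export both. Times on disk are seconds; hours are accepted with an
# explicit flag.

delim_of <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a plate time series
#'
#' @param path Delimited text file (`.csv` comma, `.tsv`/`.txt` tab). Long
#'   format requires columns `time_s` (or `time`), `well`, `signal`; wide
#'   format has a first time column followed by one column per well.
#' @param format `"long"` (canonical) or `"wide"`.
#' @param time_unit `"s"` (default) or `"h"`; hours are converted to
#'   seconds on read.
#' @return Long tibble: `well`, `time_s`, `signal`, sorted by well and
#'   time. Duplicate (well, time) pairs and non-numeric cells are errors.
#' @export
read_timeseries <- function(path, format = c("long", "wide"),
                            time_unit = c("s", "h")) {
  format <- match.arg(format)
  time_unit <- match.arg(time_unit)
  raw <- read_delim_quiet(path, delim_of(path))
  if (format == "wide") {
    names(raw)[1] <- "time_s"
    raw <- tidyr::pivot_longer(raw, -"time_s", names_to = "well",
                               values_to = "signal")
  } else {
    if ("time" %in% names(raw) && !"time_s" %in% names(raw)) {
      names(raw)[names(raw) == "time"] <- "time_s"
    }
    need <- c("time_s", "well", "signal")
    if (!all(need %in% names(raw))) {
      stop("time series must have columns time_s (or time), well, signal; ",
           "found: ", paste(names(raw), collapse = ", "), call. = FALSE)
    }
  }
  raw$time_s <- suppressWarnings(as.numeric(raw$time_s))
  raw$signal <- suppressWarnings(as.numeric(raw$signal))
  if (any(is.na(raw$time_s)) || any(is.na(raw$signal))) {
    stop("non-numeric time or signal cells in ", path, call. = FALSE)
  }
  if (time_unit == "h") raw$time_s <- raw$time_s * 3600
  dup <- duplicated(raw[, c("well", "time_s")])
  if (any(dup)) {
    d <- raw[dup, ][1, ]
    stop(sprintf("duplicated time point: well %s at t = %g s",
                 d$well, d$time_s), call. = FALSE)
  }
  out <- raw[order(raw$well, raw$time_s), c("well", "time_s", "signal")]
  tibble::as_tibble(out)
}

#' Write a plate time series (long format)
#'
#' @param timeseries Tibble with `well`, `time_s`, `signal`.
#' @param path Output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(timeseries, path) {
  readr::write_delim(timeseries[, c("well", "time_s", "signal")], path,
                     delim = delim_of(path))
  invisible(path)
}

#' Read a plate layout
#'
#' @param path Delimited text with columns `well`, `role`, `construct`,
#'   `substrate_conc`, `enzyme_conc`, and optionally `conc_unit`.
#' @return A [plate_layout()] tibble (wells validated unique, roles
#'   validated against the role enum).
#' @export
read_layout <- function(path) {
  raw <- read_delim_quiet(path, delim_of(path))
  need <- c("well", "role", "construct", "substrate_conc", "enzyme_conc")
  if (!all(need %in% names(raw))) {
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  plate_layout(
    well = raw$well, role = raw$role, construct = raw$construct,
    substrate_conc = raw$substrate_conc, enzyme_conc = raw$enzyme_conc,
    conc_unit = if ("conc_unit" %in% names(raw)) raw$conc_unit else "uM")
}

#' Write a plate layout
#'
#' @param layout A [plate_layout()].
#' @param path Output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_delim(layout, path, delim = delim_of(path))
  invisible(path)
}

#' Write an assay report (parameter table, JSON mirror, run manifest)
#'
#' Writes `<prefix>_table.tsv` and `<prefix>_table.json` (the per-construct
#' parameter table at full numeric precision), `<prefix>_rates.tsv`
#' (per-well rate diagnostics) and `<prefix>_manifest.json` (configuration,
#' seed, package and R versions, timestamp).
#'
#' @param result An [run_assay()] result.
#' @param prefix Output path prefix.
#' @param seed Seed recorded in the manifest (optional).
#' @return Named list of the files written, invisibly.
#' @export
write_report <- function(result, prefix, seed = NA_integer_) {
  stopifnot(inherits(result, "assay_result"))
  if (nrow(result$table) < 1) stop("empty result table", call. = FALSE)
  files <- list(
    table_tsv = paste0(prefix, "_table.tsv"),
    table_json = paste0(prefix, "_table.json"),
    rates_tsv = paste0(prefix, "_rates.tsv"),
    manifest = paste0(prefix, "_manifest.json")
  )
  readr::write_tsv(result$table, files$table_tsv)
  jsonlite::write_json(result$table, files$table_json, dataframe = "rows",
                       digits = NA, na = "null")
  readr::write_tsv(result$rates, files$rates_tsv)
  manifest <- list(
    assay = result$config$assay,
    config = unclass(result$config),
    standard_curve = unclass(result$standard_curve),
    seed = seed,
    n_constructs = nrow(result$table),
    n_wells = nrow(result$rates),
    package_version = as.character(utils::packageVersion("chitkin")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(files)
}

#' Read a parameter table back from its JSON mirror
#'
#' Round-trip companion of [write_report()]: numeric fields are preserved
#' at full precision.
#'
#' @param path A `*_table.json` file.
#' @return Tibble.
#' @export
read_report_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
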