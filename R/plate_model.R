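# Domain types and canonical tidy CSV I/O for plate-reader experiments.
#
# A plate dataset couples, for every well, an optical-density time course
# (absorbance at 595 nm) with fluorescence at two emission wavelengths
# (excitation 485 nm; emission 525 nm and 585 nm), plus a layout that assigns
# each well a role: media blank, untagged wild-type, or GFP-tagged strain.

VALID_ROLES <- c("media", "wildtype", "tagged")

#' Construct and validate a plate dataset
#'
#' Builds the package's central container from a long data frame of readings
#' and a layout table. All downstream operations consume this object; no other
#' module re-parses files.
#'
#' Wells must share a common time grid: time stamps are allowed to jitter by
#' at most 1% of the median sampling interval between wells (plate readers
#' read wells sequentially) and are snapped to the per-time-point median.
#' Incomplete series (a well missing a time point) are rejected rather than
#' imputed, because every downstream estimator assumes complete series.
#'
#' @param data Data frame with columns `well`, `time_h`, `od`, `f525`, `f585`
#'   (one row per well and time point).
#' @param layout Data frame with columns `well`, `role`, `strain`,
#'   `condition`, `replicate_group`; `role` is one of `media`, `wildtype`,
#'   `tagged`, and media wells must have an empty strain.
#' @param meta Optional named list of free-form metadata (gain, bandwidths,
#'   temperature, absolute cell-density anchor, ...).
#' @return An object of class `plate_dataset` with elements `times` (common
#'   grid, hours), matrices `od`, `f525`, `f585` (time by well), `layout`,
#'   and `meta`.
#' @export
plate_dataset <- function(data, layout, meta = list()) {
  need_data <- c("well", "time_h", "od", "f525", "f585")
  miss <- setdiff(need_data, names(data))
  if (length(miss) > 0) {
    stop_platemix(paste("data is missing column(s):", paste(miss, collapse = ", ")),
                  "platemix_schema_error")
  }
  need_layout <- c("well", "role", "strain", "condition", "replicate_group")
  miss <- setdiff(need_layout, names(layout))
  if (length(miss) > 0) {
    stop_platemix(paste("layout is missing column(s):", paste(miss, collapse = ", ")),
                  "platemix_schema_error")
  }
  layout <- as.data.frame(lapply(layout[need_layout], as.character),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(layout$well)) {
    stop_platemix("duplicate well ids in layout", "platemix_layout_error")
  }
  bad_role <- setdiff(unique(layout$role), VALID_ROLES)
  if (length(bad_role) > 0) {
    stop_platemix(paste("unknown role(s):", paste(bad_role, collapse = ", ")),
                  "platemix_layout_error")
  }
  media_strain <- layout$strain[layout$role == "media"]
  if (any(!is.na(media_strain) & nzchar(media_strain))) {
    stop_platemix("media wells must have an empty strain", "platemix_layout_error")
  }

  data <- data[need_data]
  data$well <- as.character(data$well)
  for (col in c("time_h", "od", "f525", "f585")) {
    assert_numeric(data[[col]], col)
  }
  wells <- unique(data$well)
  unknown <- setdiff(wells, layout$well)
  if (length(unknown) > 0) {
    stop_platemix(paste("well(s) present in data but not in layout:",
                        paste(unknown, collapse = ", ")),
                  "platemix_layout_error")
  }
  data <- data[order(match(data$well, wells), data$time_h), ]

  series <- split(data, factor(data$well, levels = wells))
  lens <- vapply(series, nrow, integer(1))
  if (any(lens < 2)) {
    stop_platemix("every well needs at least 2 time points", "platemix_data_error")
  }
  if (length(unique(lens)) != 1) {
    stop_platemix("wells have differing numbers of time points; incomplete series are not imputed",
                  "platemix_data_error")
  }
  tmat <- vapply(series, function(s) s$time_h, numeric(lens[1]))
  if (any(diff(tmat[, 1]) <= 0) ||
      any(apply(tmat, 2, function(tt) any(diff(tt) <= 0)))) {
    stop_platemix("times within a well must be strictly increasing",
                  "platemix_data_error")
  }
  times <- apply(tmat, 1, stats::median)
  tol <- 0.01 * stats::median(diff(times))
  if (any(abs(tmat - times) > tol)) {
    stop_platemix("wells do not share a common time grid (jitter exceeds 1% of the sampling interval)",
                  "platemix_data_error")
  }

  grab <- function(col) {
    m <- vapply(series, function(s) s[[col]], numeric(lens[1]))
    colnames(m) <- wells
    m
  }
  structure(list(
    times = times,
    od = grab("od"), f525 = grab("f525"), f585 = grab("f585"),
    layout = layout[match(wells, layout$well), , drop = FALSE],
    meta = meta
  ), class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  tab <- table(x$layout$role)
  cat(sprintf("<plate_dataset> %d wells x %d time points (%.2f-%.2f h)\n",
              ncol(x$od), length(x$times), min(x$times), max(x$times)))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Well ids with a given role
#'
#' @param dataset A `plate_dataset`.
#' @param role One of `"media"`, `"wildtype"`, `"tagged"`.
#' @return Character vector of well ids.
#' @export
wells_by_role <- function(dataset, role) {
  role <- match.arg(role, VALID_ROLES)
  dataset$layout$well[dataset$layout$role == role]
}

#' Read a plate experiment from canonical tidy CSV files
#'
#' The data CSV has exactly the columns `well, time_h, od, f525, f585` (one
#' row per well and time point); the layout CSV has
#' `well, role, strain, condition, replicate_group`. Vendor exports (e.g.
#' Tecan Excel sheets) must be reshaped to this layout first; the format is
#' deliberately plain so that a few lines of spreadsheet work or R suffice.
#'
#' @param path Path to the data CSV.
#' @param layout_path Path to the layout CSV.
#' @param meta Optional metadata list attached to the dataset.
#' @return A validated [plate_dataset()].
#' @export
read_plate_csv <- function(path, layout_path, meta = list()) {
  for (p in c(path, layout_path)) {
    if (!file.exists(p)) {
      stop_platemix(paste("file not found:", p), "platemix_io_error")
    }
  }
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(well = "character"))
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  plate_dataset(data, layout, meta = meta)
}

#' Write a plate dataset to canonical tidy CSV
#'
#' Numbers are written with 17 significant digits so that
#' `read_plate_csv(write_plate_csv(d))` reproduces `d` exactly.
#'
#' @param dataset A `plate_dataset`.
#' @param path Output path for the data CSV.
#' @param layout_path Optional output path for the layout CSV.
#' @return Invisibly, `path`.
#' @export
write_plate_csv <- function(dataset, path, layout_path = NULL) {
  stopifnot(inherits(dataset, "plate_dataset"))
  if (ncol(dataset$od) == 0) {
    stop_platemix("dataset has no wells to write", "platemix_domain_error")
  }
  wells <- colnames(dataset$od)
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(
    well = rep(wells, each = length(dataset$times)),
    time_h = num(rep(dataset$times, times = length(wells))),
    od = num(as.vector(dataset$od)),
    f525 = num(as.vector(dataset$f525)),
    f585 = num(as.vector(dataset$f585)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(layout_path)) {
    utils::write.csv(dataset$layout, layout_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Emission ratio of a fluorophore between two wavelengths
#'
#' Ratio of (normalized) emission at the higher, mostly-autofluorescence
#' wavelength to emission at the reporter wavelength. For enhanced GFP excited
#' at 485 nm, the normalized emission is 0.570 at 525 nm and 0.065 at 585 nm,
#' giving a spectral constant of about 0.114.
#'
#' @param em_high Emission at the higher wavelength (>= 0).
#' @param em_low Emission at the reporter wavelength (> 0).
#' @return `em_high / em_low` at full precision; round with `signif(x, 3)`
#'   for display.
#' @examples
#' signif(emission_ratio(0.065, 0.570), 3)  # EGFP: 0.114
#' @export
emission_ratio <- function(em_high, em_low) {
  assert_numeric(em_high, "em_high"); assert_numeric(em_low, "em_low")
  if (any(em_low <= 0)) {
    stop_platemix("em_low must be strictly positive", "platemix_domain_error")
  }
  if (any(em_high < 0)) {
    stop_platemix("em_high must be non-negative", "platemix_domain_error")
  }
  em_high / em_low
}

#' Spectral constants for unmixing
#'
#' @param rg Ratio of reporter emission at 585 nm to 525 nm. The default is
#'   the EGFP value 0.114; override for other fluorophores (see
#'   [emission_ratio()]).
#' @return An object of class `unmixing_constants`.
#' @export
unmixing_constants <- function(rg = 0.114) {
  assert_numeric(rg, "rg")
  if (rg < 0 || rg >= 1) {
    stop_platemix("rg must satisfy 0 <= rg < 1", "platemix_domain_error")
  }
  structure(list(rg = rg), class = "unmixing_constants")
}
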