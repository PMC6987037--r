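# CSV interchange schemas and study configuration files.
#
# CSV is the interchange format throughout: no domain standard exists for
# summarised ddPCR well records or enumeration tables. Column names are
# fixed; readers validate and reject rather than coerce.

measurement_cols <- function() {
  readr::cols(
    batch_id = readr::col_character(),
    strain = readr::col_character(),
    method = readr::col_character(),
    replicate = readr::col_integer(),
    count_per_g = readr::col_double()
  )
}

droplet_cols <- function() {
  readr::cols(
    batch_id = readr::col_character(),
    well_id = readr::col_character(),
    arm = readr::col_character(),
    accepted_droplets = readr::col_integer(),
    positive_droplets = readr::col_integer(),
    dilution_factor = readr::col_double(),
    droplet_volume = readr::col_double()
  )
}

plate_cols <- function() {
  readr::cols(
    batch_id = readr::col_character(),
    dilution_level = readr::col_double(),
    plated_volume = readr::col_double(),
    plate_index = readr::col_integer(),
    colonies = readr::col_integer()
  )
}

flow_cols <- function() {
  readr::cols(
    batch_id = readr::col_character(),
    replicate = readr::col_integer(),
    live_events = readr::col_double(),
    dead_events = readr::col_double(),
    total_events = readr::col_double(),
    analyzed_volume = readr::col_double(),
    dilution_factor = readr::col_double()
  )
}

read_checked <- function(path, spec, label) {
  if (!file.exists(path)) abort(paste0(label, " file not found: ", path))
  # parsing problems are escalated to errors below; silence readr's warning
  out <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE)
  )
  expected <- names(spec$cols)
  missing_cols <- setdiff(expected, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0(label, " file ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0(label, " file ", path, " has ", nrow(probs),
                 " malformed value(s); refusing to coerce."))
  }
  out
}

#' Read and write the CSV interchange files
#'
#' Fixed-schema CSV readers and writers for the four table shapes the
#' pipeline exchanges: the long measurement table
#' (`batch_id, strain, method, replicate, count_per_g`), droplet well
#' records, plate series and flow records. Readers validate the schema
#' and fail on malformed values instead of coercing.
#'
#' @param path File path.
#' @param data Tibble to write.
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name dropcount-io
NULL

#' @rdname dropcount-io
#' @export
read_measurement_table <- function(path) {
  out <- read_checked(path, measurement_cols(), "Measurement table")
  validate_measurement_table(out)
  out
}

#' @rdname dropcount-io
#' @export
write_measurement_table <- function(data, path) {
  validate_measurement_table(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname dropcount-io
#' @export
read_droplet_wells <- function(path) {
  read_checked(path, droplet_cols(), "Droplet well")
}

#' @rdname dropcount-io
#' @export
write_droplet_wells <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname dropcount-io
#' @export
read_plate_series <- function(path) {
  read_checked(path, plate_cols(), "Plate series")
}

#' @rdname dropcount-io
#' @export
write_plate_series <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname dropcount-io
#' @export
read_flow_records <- function(path) {
  read_checked(path, flow_cols(), "Flow record")
}

#' @rdname dropcount-io
#' @export
write_flow_records <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read or write a pipeline configuration as YAML
#'
#' Serialises a [pipeline_config()] (including its study design and noise
#' model) to a flat YAML file and back.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- unclass(config)
  ser$design <- unclass(ser$design)
  ser$design$n_batches_per_strain <- as.list(ser$design$n_batches_per_strain)
  ser$noise <- unclass(ser$noise)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  design <- do.call(study_design, c(
    list(n_batches_per_strain = unlist(raw$design$n_batches_per_strain)),
    raw$design[setdiff(names(raw$design), "n_batches_per_strain")]
  ))
  noise <- do.call(noise_model, raw$noise)
  rest <- raw[setdiff(names(raw), c("design", "noise"))]
  do.call(pipeline_config, c(list(design = design, noise = noise), rest))
}
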