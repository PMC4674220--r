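#' Reading and writing the survey CSV schemas
#'
#' Three plain CSV tables encode a survey: `parks.csv` (park_id,
#' area_km2), `density.csv` (park_id, year, density_per_km2, se) and
#' `classification.csv` (park_id, year, n_juvenile, n_female, n_male and
#' optionally n_unknown, which never enters the likelihood). Missing
#' park-years are simply absent rows, not errors.
#'
#' @name io
NULL

#' Load a survey dataset from its three CSV files
#'
#' Validation errors name the offending table, row and column. If the
#' classification table carries a redundant total column (`y_N`), it must
#' equal the sum of the class counts.
#'
#' @param density_csv,classification_csv,parks_csv File paths.
#' @return A validated [survey_dataset()].
#' @export
load_survey_data <- function(density_csv, classification_csv, parks_csv) {
  for (f in c(density_csv, classification_csv, parks_csv))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  parks <- utils::read.csv(parks_csv)
  density <- utils::read.csv(density_csv)
  classification <- utils::read.csv(classification_csv)
  if ("y_N" %in% names(classification)) {
    tot <- classification$n_juvenile + classification$n_female +
      classification$n_male
    bad <- which(classification$y_N != tot)
    if (length(bad))
      stop("classification y_N does not equal the sum of class counts, row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  survey_dataset(parks, density, classification)
}

#' Write a survey dataset to a directory of CSV files
#'
#' @param data A [survey_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_survey_data <- function(data, dir) {
  stopifnot(inherits(data, "survey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$parks, file.path(dir, "parks.csv"), row.names = FALSE)
  utils::write.csv(data$density, file.path(dir, "density.csv"),
                   row.names = FALSE)
  utils::write.csv(data$classification, file.path(dir, "classification.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write the truth record of a synthetic dataset as JSON
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Persist posterior scalar draws to CSV
#'
#' Long-format columns: chain, iteration, then one column per scalar
#' parameter. Latent states are omitted (they are large; refit or use the
#' in-memory object for state-dependent quantities).
#'
#' @param draws A `posterior_draws` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- dim(draws$scalars)
  out <- data.frame(chain = rep(seq_len(d[2]), each = d[1]),
                    iteration = rep(seq_len(d[1]), d[2]))
  for (p in dimnames(draws$scalars)[[3]])
    out[[p]] <- as.numeric(draws$scalars[, , p])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
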