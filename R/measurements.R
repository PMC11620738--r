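#' @name measurement-tables
#' @title Cell-pair measurement tables
#'
#' @description
#' A measurement table holds one row per scored cell pair: the two daughter
#' nuclear intensities (arbitrary fluorescence units), the signed
#' focal-plane distance between them (proximal minus distal, micrometres),
#' and grouping metadata.  The required columns are
#'
#' \preformatted{
#'   animal_id, genotype, temperature_c, cell, reporter,
#'   intensity_proximal, intensity_distal, z_distance_um
#' }
#'
#' `cell` must be `"Z1"` or `"Z4"`; `reporter` must be `"control_nls"`
#' (symmetric calibration reporter), `"pop1"`, or `"sys1"`.  Both
#' intensities must be strictly positive so the log ratio exists.  The
#' proximal daughter is Z1.p for Z1 and Z4.a for Z4, so the ratio is
#' oriented proximal/distal for both cells and a positive residual means
#' normal polarity orientation in both lineages.
#'
#' Files are plain delimited text (comma by default, tab accepted) with a
#' mandatory header, UTF-8, and `#` comment lines.
NULL

.measurement_cols <- c("animal_id", "genotype", "temperature_c", "cell",
                       "reporter", "intensity_proximal", "intensity_distal",
                       "z_distance_um")
.phenotype_cols <- c("genotype", "region", "pct_missing", "n")

#' Validate a cell-pair measurement table
#'
#' Checks the schema and row-level invariants of a measurement
#' `data.frame`.  Invalid rows are dropped with a warning naming the
#' offending row numbers; a missing column is an error.
#'
#' @param df a `data.frame` with the measurement schema columns.
#' @param action `"error"` to fail on any invalid row, `"drop"` (default)
#'   to drop invalid rows with a warning.
#' @return the validated `data.frame`, with enum columns as character and
#'   numeric columns as double; row order preserved.
#' @export
validate_measurements <- function(df, action = c("drop", "error")) {
  action <- match.arg(action)
  missing_cols <- setdiff(.measurement_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .measurement_cols, drop = FALSE]
  df$animal_id <- as.character(df$animal_id)
  df$genotype <- as.character(df$genotype)
  df$cell <- as.character(df$cell)
  df$reporter <- as.character(df$reporter)
  for (col in c("temperature_c", "intensity_proximal", "intensity_distal",
                "z_distance_um")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  problems <- character(0)
  note <- function(rows, what) {
    if (any(rows)) sprintf("row %s: %s", which(rows), what) else character(0)
  }
  bad_cell <- !(df$cell %in% .pola_cells)
  bad_rep <- !(df$reporter %in% .pola_reporters)
  bad_prox <- !is.finite(df$intensity_proximal) | df$intensity_proximal <= 0
  bad_dist <- !is.finite(df$intensity_distal) | df$intensity_distal <= 0
  bad_z <- !is.finite(df$z_distance_um)
  problems <- c(note(bad_cell, "unknown cell label"),
                note(bad_rep, "unknown reporter label"),
                note(bad_prox, "non-positive proximal intensity"),
                note(bad_dist, "non-positive distal intensity"),
                note(bad_z, "non-finite z_distance_um"))
  bad <- bad_cell | bad_rep | bad_prox | bad_dist | bad_z
  if (any(bad)) {
    msg <- paste0("invalid measurement row(s):\n  ",
                  paste(problems, collapse = "\n  "))
    if (action == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a cell-pair measurement table
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; `","` (default) or `"\t"`.
#' @param action how to treat invalid rows; see [validate_measurements()].
#' @return a validated measurement `data.frame`, input order preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' m <- simulate_control(3, genotype_profile("N2"), seed = 1)
#' write_measurements(m, f)
#' read_measurements(f)
#' @export
read_measurements <- function(path, sep = ",", action = c("drop", "error")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "\"",
                   fileEncoding = "UTF-8")
  validate_measurements(df, action = match.arg(action))
}

#' Write a cell-pair measurement table
#'
#' @param df a measurement `data.frame` (validated on the way out).
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path, sep = ",") {
  df <- validate_measurements(df, action = "error")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Log intensity ratio of a cell pair
#'
#' The classification statistic starts from the proximal/distal intensity
#' ratio on a logarithmic scale: `log_base(intensity_proximal /
#' intensity_distal)`.  The base (default 10) is a convention; every stage
#' of the pipeline (calibration, scoring, simulation) must use the same
#' one, and classification outcomes are invariant to the choice because
#' the confidence band is estimated on the same scale.
#'
#' @param m a measurement `data.frame` (or any list with
#'   `intensity_proximal` and `intensity_distal` components).
#' @param base logarithm base, default 10.
#' @return numeric vector of log ratios, one per row.
#' @examples
#' log_ratio(data.frame(intensity_proximal = 200, intensity_distal = 100))
#' @export
log_ratio <- function(m, base = 10) {
  log(m$intensity_proximal / m$intensity_distal, base = base)
}

#' Read or write a phenotype penetrance table
#'
#' Penetrance tables mirror published missing-phenotype tables: one row per
#' (genotype, region) with the printed percentage and the number of animals
#' scored, plus an optional `count_missing` column carrying the true
#' integer count when known.  Columns: `genotype, region, pct_missing, n`
#' and optionally `count_missing`; `region` is `"anterior"` or
#' `"posterior"`.
#'
#' @param path file path; delimited text with header, `#` comments.
#' @param sep field delimiter.
#' @return `read_phenotype_table`: a validated `data.frame`.
#' @export
read_phenotype_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_phenotype_table(df)
}

#' @rdname read_phenotype_table
#' @param df a phenotype `data.frame`.
#' @export
write_phenotype_table <- function(df, path, sep = ",") {
  df <- validate_phenotype_table(df)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_phenotype_table
#' @export
validate_phenotype_table <- function(df) {
  missing_cols <- setdiff(.phenotype_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$genotype <- as.character(df$genotype)
  df$region <- as.character(df$region)
  df$pct_missing <- as.numeric(df$pct_missing)
  df$n <- as.integer(df$n)
  if (!all(df$region %in% .pola_regions)) {
    stop("region must be one of: ", paste(.pola_regions, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$pct_missing < 0 | df$pct_missing > 100)) {
    stop("pct_missing must lie in [0, 100]", call. = FALSE)
  }
  if (any(df$n < 1L)) stop("n must be a positive integer", call. = FALSE)
  if ("count_missing" %in% names(df)) {
    cm <- df$count_missing
    ok <- is.na(cm) | (cm >= 0L & cm <= df$n)
    if (!all(ok)) stop("count_missing must lie in [0, n]", call. = FALSE)
    df$count_missing <- as.integer(cm)
  }
  rownames(df) <- NULL
  df
}
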