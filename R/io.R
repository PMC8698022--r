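#' Construct a validated solubility dataset
#'
#' Tidy record container for isothermal solid-solubility measurements:
#' one row per (T, P, y2) point, optionally with the CO2 density. Units
#' are carried in the column names (`temperature_K`, `pressure_bar`, `y2`,
#' `density_kg_m3`); pressures are converted to Pa only inside
#' computations.
#'
#' @param data Data frame with the columns above.
#' @return The data frame with class `solubility_dataset` prepended.
#' @export
solubility_dataset <- function(data) {
  req <- c("temperature_K", "pressure_bar", "y2")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cn in intersect(c(req, "density_kg_m3"), names(data))) {
    bad <- which(!is.finite(data[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing %s in row %d", cn, bad[1]),
           call. = FALSE)
  }
  bad <- which(data$temperature_K <= 0 | data$pressure_bar <= 0)
  if (length(bad))
    stop(sprintf("non-positive temperature or pressure in row %d", bad[1]),
         call. = FALSE)
  bad <- which(data$y2 <= 0 | data$y2 >= 1)
  if (length(bad))
    stop(sprintf("y2 outside (0, 1) in row %d", bad[1]), call. = FALSE)
  class(data) <- unique(c("solubility_dataset", class(data)))
  rownames(data) <- NULL
  data
}

#' Read a solubility dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns
#' `temperature_K`, `pressure_bar`, `y2` and optionally `density_kg_m3`
#' ('.' decimal separator). Validation errors name the offending row.
#'
#' @param path CSV path.
#' @param density_source `"column"` (use `density_kg_m3` if present) or
#'   `"eos"` (compute densities from the chosen EoS when absent).
#' @param eos EoS for `density_source = "eos"`.
#' @return A [solubility_dataset()].
#' @export
read_dataset <- function(path, density_source = c("column", "eos"),
                         eos = eos_form("pr")) {
  density_source <- match.arg(density_source)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  ds <- solubility_dataset(raw)
  if (density_source == "eos" && !"density_kg_m3" %in% names(ds))
    ds <- add_co2_density(ds, eos = eos)
  ds
}

#' Write a solubility dataset to CSV
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(x, f))` is
#' value-identical.
#'
#' @param data A [solubility_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach EoS-derived CO2 densities to a dataset
#'
#' Fills (or replaces) the `density_kg_m3` column from [co2_density()]
#' at each record's (T, P).
#'
#' @param data A solubility dataset.
#' @param eos EoS used for the density (default Peng-Robinson).
#' @return The dataset with `density_kg_m3` set.
#' @export
add_co2_density <- function(data, eos = eos_form("pr")) {
  data$density_kg_m3 <- co2_density(data$temperature_K,
                                    data$pressure_bar * 1e5, eos = eos)
  if (!inherits(data, "solubility_dataset"))
    data <- solubility_dataset(data)
  data
}
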