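#' Built-in radionuclide registry
#'
#' Half-lives for the two gamma emitters identified in the pond sediments.
#' Co-60 and Cs-137 are treated as independent single nuclides; the short-lived
#' Ba-137m progeny of Cs-137 is folded into the dose-rate coefficient data, as
#' is conventional for external-exposure coefficient tables.
#'
#' @return A data.frame with columns `name` and `half_life_years`.
#' @export
nuclide_registry <- function() {
  data.frame(
    name = c("Co-60", "Cs-137"),
    half_life_years = c(5.2711, 30.05),
    stringsAsFactors = FALSE
  )
}

#' Read a nuclide registry from CSV
#'
#' Expected columns: `name,half_life_years`.
#'
#' @param path Path to a CSV file.
#' @return A validated nuclide registry data.frame.
#' @export
read_nuclide_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_nuclides(df)
}

#' @keywords internal
validate_nuclides <- function(df) {
  required <- c("name", "half_life_years")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("nuclide registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) stop("duplicate nuclide names in registry")
  if (any(!is.finite(df$half_life_years)) || any(df$half_life_years <= 0)) {
    stop("half_life_years must be finite and > 0")
  }
  df
}

#' Decay constants for named nuclides
#'
#' Returns lambda = ln(2)/T_half in 1/years for each requested nuclide.
#'
#' @param names Character vector of nuclide names.
#' @param nuclides Registry data.frame (see [nuclide_registry()]).
#' @return Numeric vector of decay constants, named by nuclide.
#' @export
decay_constants <- function(names, nuclides = nuclide_registry()) {
  i <- match(names, nuclides$name)
  if (anyNA(i)) {
    stop("unknown nuclide(s): ", paste(unique(names[is.na(i)]), collapse = ", "))
  }
  stats::setNames(log(2) / nuclides$half_life_years[i], names)
}

# Calendar difference in (Julian) years; decay operates on this scale.
years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / 365.25
}
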