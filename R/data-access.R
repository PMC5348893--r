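#' Compiled minor ampullate silk properties by species
#'
#' Published mean tensile properties of minor ampullate silk fibers and
#' the mean GPG motif percentage of the species' described minor ampullate
#' spidroins, compiled across cobweb- and orb-web-weaving species. Some
#' species carry rows from more than one literature source (`source`
#' column); cells a source did not report are `NA`.
#'
#' @return A tibble with columns `species`, `source`, `diameter_um`,
#'   `modulus_GPa`, `strength_MPa`, `extensibility` (ln mm/mm),
#'   `toughness_J_cm3`, `gpg_percent`.
#' @export
minor_silk_species <- function() {
  readr::read_tsv(system.file("extdata", "minor_silk_species.tsv",
                              package = "misilk", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Species table for the GPG-extensibility regression
#'
#' One row per species with both a GPG percentage and an extensibility
#' value; where a species has rows from multiple sources the first-listed
#' source is used. The selection is deliberately exposed (rather than
#' hard-coded) because the choice among multiple published rows is a
#' documented analysis decision.
#'
#' @param data The compiled table (default [minor_silk_species()]); pass a
#'   modified table to make a different source selection.
#' @return A tibble with columns `id` (abbreviated species), `species`,
#'   `gpg_percent`, `extensibility`.
#' @export
species_regression_data <- function(data = minor_silk_species()) {
  data |>
    dplyr::filter(!is.na(.data$gpg_percent), !is.na(.data$extensibility)) |>
    dplyr::distinct(.data$species, .keep_all = TRUE) |>
    dplyr::mutate(id = abbreviate_species(.data$species)) |>
    dplyr::select("id", "species", "gpg_percent", "extensibility")
}

abbreviate_species <- function(x) {
  vapply(strsplit(x, "\\s+"), function(w) {
    paste0(substr(w[1], 1, 1), "_", w[length(w)])
  }, character(1))
}
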