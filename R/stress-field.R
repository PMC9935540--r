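#' Per-element von Mises stress field
#'
#' A `stress_field` is a tibble with one row per finite element, columns
#' `element` (id), `vm_mpa` (von Mises stress, MPa) and `volume_mm3`
#' (element volume). The load scenario and specimen id travel as attributes
#' so fields can be concatenated into batches for the intervals method.
#'
#' @param vm_mpa non-negative per-element von Mises stress (MPa).
#' @param volume_mm3 strictly positive per-element volumes (mm^3).
#' @param scenario one of `"scratch_digging"`, `"hook_and_pull"`,
#'   `"piercing"`, or `NA` for scenario-less fields.
#' @param specimen_id identifier of the specimen the field belongs to.
#' @param element optional element ids (default sequential).
#'
#' @return a tibble of class `stress_field`.
#' @export
stress_field <- function(vm_mpa, volume_mm3, scenario = NA_character_,
                         specimen_id = NA_character_, element = NULL) {
  vm_mpa <- as.numeric(vm_mpa)
  volume_mm3 <- as.numeric(volume_mm3)
  if (length(vm_mpa) != length(volume_mm3))
    stop("`vm_mpa` and `volume_mm3` must have the same length")
  if (any(volume_mm3 <= 0)) stop("element volumes must be strictly positive")
  if (any(vm_mpa < -1e-12)) stop("von Mises stress cannot be negative")
  vm_mpa <- pmax(vm_mpa, 0)
  if (is.null(element)) element <- seq_along(vm_mpa)
  out <- tibble::tibble(element = element, vm_mpa = vm_mpa,
                        volume_mm3 = volume_mm3)
  attr(out, "scenario") <- scenario
  attr(out, "specimen_id") <- specimen_id
  attr(out, "trimmed_volume_mm3") <- 0
  attr(out, "original_volume_mm3") <- sum(volume_mm3)
  class(out) <- c("stress_field", class(out))
  out
}

field_scenario <- function(field) attr(field, "scenario") %||% NA_character_
field_specimen <- function(field) attr(field, "specimen_id") %||% NA_character_

#' Volume-weighted mean von Mises stress of a field
#'
#' The scalar used to rank simulations as sitting in a "higher" or "lower"
#' stress field: the arithmetic mean of element stress weighted by element
#' volume. Trimmed-away elements (see [trim_upper_tail()]) do not
#' contribute.
#'
#' @param field a [stress_field()].
#' @return mean stress in MPa.
#' @export
mean_stress_summary <- function(field) {
  if (nrow(field) == 0L) stop("empty stress field")
  sum(field$vm_mpa * field$volume_mm3) / sum(field$volume_mm3)
}

#' Read a per-element stress export
#'
#' Reads the CSV dialect used to exchange stress fields with external FEA
#' programs: header columns `element_id`, `von_mises_mpa`, `volume_mm3`.
#' Rows with non-positive volume are dropped with a message giving the
#' count.
#'
#' @param path CSV file path.
#' @param scenario,specimen_id metadata to attach (read from optional
#'   `scenario`/`specimen_id` columns when present).
#' @return a [stress_field()].
#' @export
read_stress_export <- function(path, scenario = NULL, specimen_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element_id", "von_mises_mpa", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("stress export is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- df$volume_mm3 <= 0 | !is.finite(df$volume_mm3)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with non-positive volume")
    df <- df[!bad, , drop = FALSE]
  }
  scenario <- scenario %||%
    (if ("scenario" %in% names(df)) as.character(df$scenario[1L]) else NA_character_)
  specimen_id <- specimen_id %||%
    (if ("specimen_id" %in% names(df)) as.character(df$specimen_id[1L]) else NA_character_)
  stress_field(df$von_mises_mpa, df$volume_mm3, scenario = scenario,
               specimen_id = specimen_id, element = df$element_id)
}

#' Write a stress field to the exchange CSV dialect
#'
#' @param field a [stress_field()].
#' @param path output path.
#' @param digits significant digits to print (default 12).
#' @return `path`, invisibly.
#' @export
write_stress_export <- function(field, path, digits = 12) {
  df <- data.frame(
    element_id = field$element,
    von_mises_mpa = signif(field$vm_mpa, digits),
    volume_mm3 = signif(field$volume_mm3, digits),
    scenario = field_scenario(field),
    specimen_id = field_specimen(field))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
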