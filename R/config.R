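#' Load a run configuration from YAML
#'
#' Reads material, load and intervals settings from a YAML file and
#' returns validated parameter objects with package defaults filling any
#' omissions. Recognised top-level keys: `material`
#' (`youngs_modulus_gpa`, `poisson_ratio`), `load` (`total_force_n`,
#' `tip_fraction`), `intervals` (`n_intervals`, `trim_fraction`,
#' `lower_bound_mpa`, `upper_bound_mpa`, `log_offset`).
#'
#' @param path YAML file path.
#' @return list with elements `material` ([material_spec()]),
#'   `load` (list), `intervals` ([interval_config()]).
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations")
  cfg <- yaml::read_yaml(path) %||% list()
  mat <- cfg$material %||% list()
  lod <- cfg$load %||% list()
  itv <- cfg$intervals %||% list()
  list(
    material = material_spec(
      youngs_modulus_gpa = mat$youngs_modulus_gpa %||% 20.49,
      poisson_ratio = mat$poisson_ratio %||% 0.40),
    load = list(total_force_n = lod$total_force_n %||% 200,
                tip_fraction = lod$tip_fraction %||% 0.05),
    intervals = interval_config(
      n_intervals = itv$n_intervals %||% 50,
      trim_fraction = itv$trim_fraction %||% 0.02,
      lower_bound_mpa = itv$lower_bound_mpa %||% 0,
      upper_bound_mpa = itv$upper_bound_mpa,
      log_offset = itv$log_offset %||% 0.01))
}
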