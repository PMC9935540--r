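#' Configuration of the intervals method
#'
#' The intervals method summarises a von Mises stress field as the vector
#' of model sub-volume percentages falling into fixed stress ranges. Fifty
#' intervals is the standard balance between resolution and stability
#' (more intervals do not materially change downstream ordinations); the
#' upper tail is trimmed before binning to avoid extreme-value effects
#' from constraint anchor points, by default 2% of the model volume
#' (the accepted range being 1-5%).
#'
#' @param n_intervals number of stress intervals (>= 2, default 50).
#' @param trim_fraction volume fraction trimmed from the upper stress tail
#'   (0 to 0.05, default 0.02).
#' @param lower_bound_mpa lower edge of the first interval (default 0).
#' @param upper_bound_mpa shared upper edge; `NULL` (default) uses the
#'   pooled post-trim maximum across the batch being binned.
#' @param log_offset constant added (in percentage points) before the log
#'   transform in [ordinate()], because empty intervals are common
#'   (default 0.01).
#' @return an `interval_config` list.
#' @export
interval_config <- function(n_intervals = 50, trim_fraction = 0.02,
                            lower_bound_mpa = 0, upper_bound_mpa = NULL,
                            log_offset = 0.01) {
  if (n_intervals < 2) stop("`n_intervals` must be >= 2")
  if (trim_fraction < 0 || trim_fraction > 0.05)
    stop("`trim_fraction` must lie in [0, 0.05]")
  if (!is.null(upper_bound_mpa) && upper_bound_mpa <= lower_bound_mpa)
    stop("`upper_bound_mpa` must exceed `lower_bound_mpa`")
  if (log_offset <= 0) stop("`log_offset` must be positive")
  structure(list(n_intervals = as.integer(n_intervals),
                 trim_fraction = trim_fraction,
                 lower_bound_mpa = lower_bound_mpa,
                 upper_bound_mpa = upper_bound_mpa,
                 log_offset = log_offset),
            class = "interval_config")
}

#' Trim the upper stress tail of a field by volume
#'
#' Removes whole elements in descending stress order, greedily, while the
#' cumulative removed volume stays at or below `fraction` of the total
#' volume (never exceeding it). The removed volume is recorded on the
#' result so interval percentages can still be expressed relative to the
#' original model volume.
#'
#' @param field a [stress_field()].
#' @param fraction volume fraction to trim, in \[0, 1).
#' @return the trimmed [stress_field()].
#' @export
trim_upper_tail <- function(field, fraction) {
  if (fraction < 0 || fraction >= 1) stop("`fraction` must lie in [0, 1)")
  if (fraction == 0 || nrow(field) == 0L) return(field)
  ord <- order(field$vm_mpa, decreasing = TRUE)
  total <- sum(field$volume_mm3)
  cum <- cumsum(field$volume_mm3[ord])
  n_remove <- sum(cum <= fraction * total + 1e-15 * total)
  if (n_remove == 0L) return(field)
  drop <- ord[seq_len(n_remove)]
  removed <- sum(field$volume_mm3[drop])
  out <- field[-drop, , drop = FALSE]
  attr(out, "scenario") <- attr(field, "scenario")
  attr(out, "specimen_id") <- attr(field, "specimen_id")
  attr(out, "original_volume_mm3") <- attr(field, "original_volume_mm3")
  attr(out, "trimmed_volume_mm3") <-
    (attr(field, "trimmed_volume_mm3") %||% 0) + removed
  class(out) <- class(field)
  out
}

#' Bin a stress field into an interval vector
#'
#' Linear stress intervals over \[lower, upper\]; interval i accumulates
#' the volume of elements with stress in `[edge_i, edge_{i+1})` (the last
#' interval is closed above). Percentages are relative to the ORIGINAL
#' (pre-trim) model volume, so the vector plus the trimmed volume always
#' accounts for 100% of the model.
#'
#' @param field a [stress_field()] (usually post-[trim_upper_tail()]).
#' @param config an [interval_config()]; when `upper_bound_mpa` is `NULL`
#'   the field's own maximum is used (for batches, use
#'   [compute_interval_vectors()] which pools the bound).
#' @return a tibble of class `interval_vector` with columns `interval`,
#'   `lower_mpa`, `upper_mpa`, `pct`, and attributes `edges`,
#'   `specimen_id`, `scenario`, `trimmed_volume_pct`, `mean_stress_mpa`.
#' @export
compute_interval_vector <- function(field, config = interval_config()) {
  if (nrow(field) == 0L) stop("empty stress field")
  upper <- config$upper_bound_mpa %||% max(field$vm_mpa)
  lower <- config$lower_bound_mpa
  if (upper <= lower) upper <- lower + 1e-9
  n <- config$n_intervals
  edges <- seq(lower, upper, length.out = n + 1L)
  idx <- findInterval(field$vm_mpa, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  over <- field$vm_mpa > upper
  if (any(over)) {
    warning(sum(over), " element(s) above the shared upper bound ",
            "accumulated into the last interval")
    idx[over] <- n
  }
  idx[idx < 1L] <- 1L
  vol <- numeric(n)
  agg <- rowsum(field$volume_mm3, idx, reorder = TRUE)
  vol[as.integer(rownames(agg))] <- agg[, 1L]
  orig <- attr(field, "original_volume_mm3") %||% sum(field$volume_mm3)
  trimmed <- attr(field, "trimmed_volume_mm3") %||% 0
  out <- tibble::tibble(interval = seq_len(n),
                        lower_mpa = edges[-(n + 1L)],
                        upper_mpa = edges[-1L],
                        pct = 100 * vol / orig)
  attr(out, "edges") <- edges
  attr(out, "specimen_id") <- field_specimen(field)
  attr(out, "scenario") <- field_scenario(field)
  attr(out, "trimmed_volume_pct") <- 100 * trimmed / orig
  attr(out, "mean_stress_mpa") <- mean_stress_summary(field)
  class(out) <- c("interval_vector", class(out))
  out
}

#' Trim and bin a batch of stress fields with a shared upper bound
#'
#' Applies [trim_upper_tail()] to every field, pools the post-trim maximum
#' stress across the batch as the shared upper interval edge (unless the
#' config fixes one), and bins each field. A shared bound is what makes
#' interval vectors comparable across specimens and scenarios.
#'
#' @param fields list of [stress_field()]s.
#' @param config an [interval_config()].
#' @return list of `interval_vector`s, one per field.
#' @export
compute_interval_vectors <- function(fields, config = interval_config()) {
  stopifnot(is.list(fields), length(fields) >= 1L)
  trimmed <- lapply(fields, trim_upper_tail, fraction = config$trim_fraction)
  if (is.null(config$upper_bound_mpa))
    config$upper_bound_mpa <- max(vapply(trimmed, function(f) max(f$vm_mpa),
                                         numeric(1L)))
  lapply(trimmed, compute_interval_vector, config = config)
}
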