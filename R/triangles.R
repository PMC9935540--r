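#' Build a functional triangle for one specimen
#'
#' The specimen's three load-scenario simulations form a triangle in the
#' (PC1, PC2) functional space. Its geometry quantifies function: the
#' area measures functional divergence (how differently the claw performs
#' across the three functions), the centroid the average performance, and
#' the three signed sides the pairwise divergences. A side's sign follows
#' the mean-stress rule: +1 when the terminal scenario sits in a higher
#' volume-weighted mean stress field than the initial scenario, -1 when
#' lower, 0 when equal within `tol` (the terminal function being the less
#' well-suited of the pair when positive).
#'
#' @param scores a data frame with exactly three rows (one per scenario)
#'   and columns `scenario`, `pc1`, `pc2`, `mean_stress_mpa`; typically a
#'   per-specimen slice of `ordinate()$scores`.
#' @param specimen_id identifier; defaults to the `specimen_id` column.
#' @param tol mean-stress tolerance (MPa) below which a side's sign is 0.
#' @return a `functional_triangle` object with elements `specimen_id`,
#'   `vertices` (3 x 2 matrix, rows named by scenario),
#'   `vertex_mean_stress`, `centroid`, `area`, `sides` (tibble with
#'   `name`, `from`, `to`, `length`, `sign`, `signed_value`).
#' @export
build_functional_triangle <- function(scores, specimen_id = NULL,
                                      tol = 1e-9) {
  scen <- c("scratch_digging", "hook_and_pull", "piercing")
  if (!all(c("scenario", "pc1", "pc2", "mean_stress_mpa") %in% names(scores)))
    stop("`scores` needs columns scenario, pc1, pc2, mean_stress_mpa")
  if (anyDuplicated(scores$scenario))
    stop("duplicated scenario: ",
         scores$scenario[duplicated(scores$scenario)][1L])
  missing_scen <- setdiff(scen, scores$scenario)
  if (length(missing_scen))
    stop("missing scenario: ", paste(missing_scen, collapse = ", "))
  if (nrow(scores) != 3L) stop("`scores` must have exactly three rows")
  specimen_id <- specimen_id %||%
    (if ("specimen_id" %in% names(scores)) scores$specimen_id[1L] else NA)

  ord <- match(scen, scores$scenario)
  V <- as.matrix(scores[ord, c("pc1", "pc2")])
  rownames(V) <- scen
  ms <- scores$mean_stress_mpa[ord]
  names(ms) <- scen

  centroid <- colMeans(V)
  area <- abs((V[2L, 1L] - V[1L, 1L]) * (V[3L, 2L] - V[1L, 2L]) -
                (V[3L, 1L] - V[1L, 1L]) * (V[2L, 2L] - V[1L, 2L])) / 2

  side_def <- tibble::tibble(
    name = c("hook-and-pull to piercing", "scratch-digging to piercing",
             "scratch-digging to hook-and-pull"),
    from = c("hook_and_pull", "scratch_digging", "scratch_digging"),
    to = c("piercing", "piercing", "hook_and_pull"))
  sides <- dplyr::mutate(
    side_def,
    length = unname(sqrt(rowSums((V[.data$to, , drop = FALSE] -
                                    V[.data$from, , drop = FALSE])^2))),
    sign = unname(ifelse(abs(ms[.data$to] - ms[.data$from]) <= tol, 0L,
                         ifelse(ms[.data$to] > ms[.data$from], 1L, -1L))),
    signed_value = .data$sign * .data$length)

  structure(list(specimen_id = specimen_id, vertices = V,
                 vertex_mean_stress = ms, centroid = centroid,
                 area = area, sides = sides),
            class = "functional_triangle")
}

#' Build functional triangles for every specimen in an ordination
#'
#' @param space a `functional_space` from [ordinate()].
#' @param tol mean-stress sign tolerance (MPa).
#' @return named list of [build_functional_triangle()] results.
#' @export
functional_triangles <- function(space, tol = 1e-9) {
  stopifnot(inherits(space, "functional_space"))
  split(space$scores, space$scores$specimen_id) |>
    lapply(build_functional_triangle, tol = tol)
}

#' Classify a point of the functional space into a quadrant
#'
#' Quadrant semantics follow the oriented ordination: simulations with the
#' lowest stress fields fall in quadrant II (PC1 negative, PC2 positive)
#' and the highest in quadrant I (both positive). Points on an axis take
#' the adjacent quadrant by the half-open rule (0 counts as positive).
#'
#' @param pc1,pc2 coordinates (vectorised).
#' @return character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_quadrant <- function(pc1, pc2) {
  stopifnot(length(pc1) == length(pc2), all(is.finite(pc1)),
            all(is.finite(pc2)))
  ifelse(pc1 >= 0,
         ifelse(pc2 >= 0, "I", "IV"),
         ifelse(pc2 >= 0, "II", "III"))
}

#' Tabular summary of functional triangles
#'
#' One row per specimen with the quantified functional indicators: area,
#' centroid coordinates and quadrant, the three signed side values, and
#' the mean of the vertex mean stresses. Rows are ordered by specimen id.
#'
#' @param triangles a list of `functional_triangle`s (or a single one).
#' @return a tibble with columns `specimen_id`, `area`, `centroid_pc1`,
#'   `centroid_pc2`, `quadrant`, `side_pullpierce`, `side_digpierce`,
#'   `side_digpull`, `mean_stress_mpa`.
#' @export
triangle_report <- function(triangles) {
  if (inherits(triangles, "functional_triangle")) triangles <- list(triangles)
  stopifnot(length(triangles) >= 1L)
  rows <- lapply(triangles, function(tr) {
    sv <- stats::setNames(tr$sides$signed_value, tr$sides$name)
    tibble::tibble(
      specimen_id = as.character(tr$specimen_id),
      area = tr$area,
      centroid_pc1 = tr$centroid[1L],
      centroid_pc2 = tr$centroid[2L],
      quadrant = classify_quadrant(tr$centroid[1L], tr$centroid[2L]),
      side_pullpierce = sv[["hook-and-pull to piercing"]],
      side_digpierce = sv[["scratch-digging to piercing"]],
      side_digpull = sv[["scratch-digging to hook-and-pull"]],
      mean_stress_mpa = mean(tr$vertex_mean_stress))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$specimen_id)
}
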