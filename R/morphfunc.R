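#' Ordinary least-squares regression with optional log transforms
#'
#' The regression engine of the total-evidence assessment (function vs.
#' morphology vs. size): simple OLS of `y` on `x`, with optional
#' log-transformation of either axis (base 10 by default, as is usual for
#' size variables such as ungual volume or body mass). R-squared is the
#' squared Pearson correlation; the p-value is the two-sided slope t-test
#' on n - 2 degrees of freedom. Missing pairs are dropped.
#'
#' @param data a data frame.
#' @param x,y column names (strings) of predictor and response.
#' @param log_x,log_y log-transform the axis first (requires positive
#'   values).
#' @param log_base base of the log transform (default 10).
#' @return a one-row tibble of class `regression_result`: `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `x_label`, `y_label`.
#' @export
regress_ols <- function(data, x, y, log_x = FALSE, log_y = FALSE,
                        log_base = 10) {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  xv <- as.numeric(data[[x]]); yv <- as.numeric(data[[y]])
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 2L) stop("need at least 2 complete (x, y) pairs")
  x_label <- x; y_label <- y
  if (log_x) {
    if (any(xv <= 0)) stop("log_x requires strictly positive x values")
    xv <- log(xv, base = log_base); x_label <- paste0("log", log_base, "(", x, ")")
  }
  if (log_y) {
    if (any(yv <= 0)) stop("log_y requires strictly positive y values")
    yv <- log(yv, base = log_base); y_label <- paste0("log", log_base, "(", y, ")")
  }
  if (stats::sd(xv) == 0) stop("zero variance in x; slope undefined")
  fit <- stats::lm(yv ~ xv)
  co <- stats::coef(fit)
  n <- length(xv)
  if (n == 2L) {
    r2 <- 1; p <- NA_real_
  } else {
    r2 <- stats::cor(xv, yv)^2
    # a perfect fit triggers lm's precision caveat; the p-value is ~0 there
    p <- suppressWarnings(summary(fit))$coefficients["xv", "Pr(>|t|)"]
  }
  out <- tibble::tibble(slope = unname(co[2L]), intercept = unname(co[1L]),
                        r_squared = r2, p_value = p, n = n,
                        x_label = x_label, y_label = y_label)
  attr(out, "model_frame") <- tibble::tibble(x = xv, y = yv)
  class(out) <- c("regression_result", class(out))
  out
}

#' Project study claws into a reference ratio morphospace
#'
#' Fits a PCA (covariance, on log-transformed ratios) to a published
#' reference table of claw shape ratios (columns `ratio_LW`, `ratio_LD`,
#' `ratio_DW`; one row per reference animal), then projects the study
#' records as supplementary points: reference scores are unchanged by the
#' projection, and study claws land where their ratios place them among
#' the reference animals. Component signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param records data frame of study claws with the three ratio columns
#'   (strictly positive) and a `specimen_id` column.
#' @param reference data frame with the three ratio columns (>= 3 rows).
#' @param log_base base of the log transform (default 10).
#' @return a `morphospace` object: `record_scores` and `reference_scores`
#'   tibbles (`mpc1`, `mpc2`, ...), `explained_variance`, `rotation`,
#'   `center`.
#' @export
morphospace_project <- function(records, reference, log_base = 10) {
  ratio_cols <- c("ratio_LW", "ratio_LD", "ratio_DW")
  miss <- setdiff(ratio_cols, names(reference))
  if (length(miss))
    stop("reference table is missing ratio column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(ratio_cols, names(records))
  if (length(miss))
    stop("records are missing ratio column(s): ", paste(miss, collapse = ", "))
  if (nrow(reference) < 3L) stop("need at least 3 reference rows")
  Rf <- as.matrix(reference[, ratio_cols])
  Rc <- as.matrix(records[, ratio_cols])
  if (any(!is.finite(Rf)) || any(Rf <= 0))
    stop("reference ratios must be finite and strictly positive")
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    stop("record ratios must be finite and strictly positive")
  Lf <- log(Rf, base = log_base)
  Lc <- log(Rc, base = log_base)
  pca <- stats::prcomp(Lf, center = TRUE, scale. = FALSE)
  rot <- pca$rotation
  for (k in seq_len(ncol(rot))) {       # deterministic signs
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  score <- function(L) sweep(L, 2L, pca$center) %*% rot
  name_scores <- function(S, ids) {
    out <- tibble::as_tibble(S, .name_repair = "minimal")
    names(out) <- paste0("mpc", seq_len(ncol(S)))
    dplyr::bind_cols(tibble::tibble(specimen_id = ids), out)
  }
  ref_ids <- if ("specimen_id" %in% names(reference))
    as.character(reference$specimen_id) else paste0("ref_", seq_len(nrow(Rf)))
  rec_ids <- if ("specimen_id" %in% names(records))
    as.character(records$specimen_id) else paste0("rec_", seq_len(nrow(Rc)))
  structure(list(
    record_scores = name_scores(score(Lc), rec_ids),
    reference_scores = name_scores(score(Lf), ref_ids),
    explained_variance = pca$sdev^2 / sum(pca$sdev^2),
    rotation = rot, center = pca$center, log_base = log_base),
    class = "morphospace")
}

#' Morphological and functional divergence from a baseline specimen
#'
#' Morphological divergence is the Euclidean distance from the baseline
#' record in the first two morphospace components; functional divergence
#' is reported both as the triangle area and as a named signed side, with
#' `functional_metric` selecting which of the two fills the
#' `functional_divergence` column.
#'
#' @param records data frame holding per-specimen morphospace coordinates
#'   (`mpc1`, `mpc2`) and triangle summaries (columns of
#'   [triangle_report()]), joined by `specimen_id`.
#' @param baseline_id specimen id of the divergence origin.
#' @param functional_metric `"area"` (default) or one of
#'   `"side_pullpierce"`, `"side_digpierce"`, `"side_digpull"`.
#' @return `records` with columns `morphological_divergence`,
#'   `functional_divergence` (selected metric) appended.
#' @export
divergence_metrics <- function(records, baseline_id,
                               functional_metric = c("area",
                                                     "side_pullpierce",
                                                     "side_digpierce",
                                                     "side_digpull")) {
  functional_metric <- match.arg(functional_metric)
  need <- c("specimen_id", "mpc1", "mpc2", "area")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  base <- records[records$specimen_id == baseline_id, , drop = FALSE]
  if (nrow(base) != 1L)
    stop("unknown (or ambiguous) baseline specimen: ", baseline_id)
  dplyr::mutate(
    tibble::as_tibble(records),
    morphological_divergence = sqrt((.data$mpc1 - base$mpc1)^2 +
                                      (.data$mpc2 - base$mpc2)^2),
    functional_divergence = .data[[functional_metric]])
}
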