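#' Ordinate interval vectors into the functional space
#'
#' Joint principal component analysis of a batch of interval vectors (all
#' simulations from all specimens together). Pipeline:
#' `log(pct + log_offset)` per cell, drop zero-variance columns,
#' standardise the remaining columns to zero mean and unit variance
#' (correlation PCA), then PCA. Component signs are fixed
#' deterministically: PC1 is oriented so it correlates non-negatively with
#' each simulation's volume-weighted mean stress (so "high stress" is
#' always to the right, and the low-stress region is quadrant II), and
#' PC2 onward have their largest-magnitude loading set positive.
#'
#' @param vectors list of `interval_vector`s from
#'   [compute_interval_vectors()] (>= 3, sharing identical edges).
#' @param log_offset constant (percentage points) added before the log;
#'   defaults to the binning config's 0.01.
#' @return a `functional_space` object: `scores` tibble (`specimen_id`,
#'   `scenario`, `mean_stress_mpa`, `pc1`, `pc2`, ...),
#'   `explained_variance` (proportions), `loadings`, `center`, `scale`,
#'   `kept_columns`, `edges`, `log_offset`.
#' @export
ordinate <- function(vectors, log_offset = 0.01) {
  stopifnot(is.list(vectors))
  if (length(vectors) < 3L)
    stop("need at least 3 interval vectors to ordinate ",
         "(no functional triangle is constructible from fewer)")
  edges <- attr(vectors[[1L]], "edges")
  same <- vapply(vectors, function(v) {
    e <- attr(v, "edges")
    length(e) == length(edges) && all(abs(e - edges) < 1e-9 * (1 + abs(edges)))
  }, logical(1L))
  if (!all(same))
    stop("interval vectors have mismatched edges; re-bin the batch with a ",
         "shared upper bound (see compute_interval_vectors())")
  P <- do.call(rbind, lapply(vectors, function(v) v$pct))
  ms <- vapply(vectors, function(v) attr(v, "mean_stress_mpa"), numeric(1L))
  ids <- vapply(vectors, function(v) as.character(attr(v, "specimen_id")),
                character(1L))
  scn <- vapply(vectors, function(v) as.character(attr(v, "scenario")),
                character(1L))

  X <- log(P + log_offset)
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 1e-12)
  if (length(keep) < 2L)
    stop("fewer than two informative interval columns; fields are too uniform")
  Xk <- X[, keep, drop = FALSE]
  pca <- stats::prcomp(Xk, center = TRUE, scale. = TRUE)
  scores <- pca$x
  load <- pca$rotation

  # deterministic sign conventions
  if (ncol(scores) >= 1L) {
    r <- suppressWarnings(stats::cor(scores[, 1L], ms))
    if (!is.na(r) && r < 0) {
      scores[, 1L] <- -scores[, 1L]; load[, 1L] <- -load[, 1L]
    }
  }
  if (ncol(scores) >= 2L) for (k in 2L:ncol(scores)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      scores[, k] <- -scores[, k]; load[, k] <- -load[, k]
    }
  }

  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0("pc", seq_len(ncol(scores)))
  sc <- dplyr::bind_cols(
    tibble::tibble(specimen_id = ids, scenario = scn, mean_stress_mpa = ms),
    sc)
  structure(list(
    scores = sc,
    explained_variance = pca$sdev^2 / sum(pca$sdev^2),
    loadings = load,
    center = pca$center, scale = pca$scale,
    kept_columns = keep, edges = edges, log_offset = log_offset),
    class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat("<functional_space> ", nrow(x$scores), " simulations, ",
      length(x$kept_columns), " informative intervals\n", sep = "")
  ev <- round(100 * x$explained_variance[seq_len(min(3L,
        length(x$explained_variance)))], 1)
  cat("  variance explained: ", paste0("PC", seq_along(ev), " ", ev, "%",
      collapse = ", "), "\n", sep = "")
  invisible(x)
}
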