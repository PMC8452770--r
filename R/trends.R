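#' Affinity-diffusion imputation of features
#'
#' Denoises a feature matrix by diffusing it over the single-cell KNN graph:
#' `X_imputed = T^t X` with `T` the row-normalized affinity matrix. Constant
#' columns are fixed points; `t_steps = 0` is the identity. Rows of isolated
#' cells are left unchanged with a warning.
#'
#' @param X Cells x features matrix.
#' @param g An `sc_knn_graph` over the same cells.
#' @param t_steps Nonnegative number of diffusion steps (default 3).
#' @return Imputed matrix of the same shape.
#' @export
impute_features <- function(X, g, t_steps = 3L) {
  if (t_steps < 0L) stop("t_steps must be >= 0")
  X <- as.matrix(X)
  if (nrow(X) != g$n) stop("matrix and graph have different cell counts")
  if (t_steps == 0L) return(X)
  rs <- Matrix::rowSums(g$adj)
  iso <- rs == 0
  if (any(iso)) warning(sum(iso), " isolated cell(s) left unimputed")
  Tm <- g$adj / ifelse(rs > 0, rs, 1)
  out <- X
  for (i in seq_len(t_steps)) {
    nxt <- as.matrix(Tm %*% out)
    nxt[iso, ] <- out[iso, , drop = FALSE]
    out <- nxt
  }
  dimnames(out) <- dimnames(X)
  out
}

#' Lineage-weighted expression trend along pseudotime
#'
#' Fits a weighted penalized B-spline (cubic basis, `knots` basis functions,
#' GCV-selected penalty via [mgcv::gam()]) of a feature against per-cell
#' pseudotime, with lineage probabilities as prior weights so cells likely to
#' belong to the lineage dominate the fit. The curve is evaluated on a
#' uniform grid spanning the pseudotime range of positively weighted cells;
#' no extrapolation.
#'
#' @param feature Per-cell feature values.
#' @param t_cells Per-cell pseudotime.
#' @param w_cells Per-cell lineage probabilities (nonnegative, not all zero).
#' @param grid_size Number of grid points (default 100).
#' @param knots Spline basis dimension (default 10).
#' @param lineage Optional lineage id recorded in the result.
#' @return Object of class `trend_curve`: data frame with columns `grid`,
#'   `fitted`, plus attributes `lineage` and `edf`.
#' @export
lineage_trend <- function(feature, t_cells, w_cells = NULL, grid_size = 100L,
                          knots = 10L, lineage = NA_character_) {
  n <- length(feature)
  if (length(t_cells) != n) stop("feature and pseudotime lengths differ")
  if (is.null(w_cells)) w_cells <- rep(1, n)
  if (length(w_cells) != n) stop("weights length differs")
  if (any(w_cells < 0)) stop("negative lineage weights")
  if (all(w_cells == 0))
    stop("all-zero lineage weights for lineage ", lineage)
  keep <- w_cells > 0
  df <- data.frame(y = feature[keep], t = t_cells[keep], w = w_cells[keep])
  rng <- range(df$t)
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  if (stats::var(df$y) == 0) {            # constant feature: flat curve
    fit <- rep(df$y[1], grid_size)
    edf <- 1
  } else {
    k <- min(knots, max(3L, length(unique(df$t)) - 1L))
    gm <- mgcv::gam(y ~ s(t, k = k, bs = "bs"), data = df, weights = df$w,
                    method = "GCV.Cp")
    fit <- as.numeric(stats::predict(gm, newdata = data.frame(t = grid)))
    edf <- sum(gm$edf)
  }
  structure(data.frame(grid = grid, fitted = fit),
            class = c("trend_curve", "data.frame"),
            lineage = lineage, edf = edf)
}

#' Trend curves for every lineage of a fitted trajectory
#'
#' Convenience wrapper running [lineage_trend()] for one feature against each
#' terminal state's cell-level lineage probabilities.
#'
#' @param fit A `trajwalk` fit.
#' @param feature Per-cell feature values (e.g. one imputed gene).
#' @param ... Passed to [lineage_trend()].
#' @return Named list of `trend_curve` objects, one per terminal state.
#' @export
lineage_trends <- function(fit, feature, ...) {
  terms <- colnames(fit$lineage_cells)
  out <- lapply(terms, function(j)
    lineage_trend(feature, fit$pseudotime_cells, fit$lineage_cells[, j],
                  lineage = j, ...))
  stats::setNames(out, terms)
}
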