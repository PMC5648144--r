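#' Build a principal-component predictor set from a stack
#'
#' Variables are standardized (mean 0, SD 1 over the jointly valid cells)
#' and the correlation matrix is eigendecomposed (PCA via [stats::prcomp]
#' with scaling). The minimal number of leading components whose cumulative
#' variance proportion strictly exceeds `threshold` is retained, and their
#' score layers become the new, mutually uncorrelated predictors. Component
#' signs are pinned by making each component's largest-magnitude loading
#' positive, so results are reproducible across platforms.
#'
#' @param stack a `grid_stack` of raw variables (>= 2 layers).
#' @param threshold cumulative-variance cutoff in `(0, 1]`; components are
#'   retained until the cumulative proportion exceeds it (strict).
#' @param label predictor-set label (`"C"`, `"E"`, `"CE"`, ...).
#' @return an object of class `predictor_set`: `label`, `k`, `loadings`
#'   (variables x k), `eigenvalues` (all), `cum_var`, `center`, `scale`,
#'   and `scores`, a `grid_stack` of the retained score layers.
#' @export
fit_pca_predictors <- function(stack, threshold = 0.95, label = "PC") {
  stopifnot(inherits(stack, "grid_stack"))
  if (n_layers(stack) < 2L) stop("need at least 2 layers for PCA")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  jv <- stack$joint_valid
  X <- vapply(stack$layers, function(l) l$values[jv], numeric(sum(jv)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant layer(s): ",
         paste(names(stack$layers)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  cum_var <- cumsum(ev) / sum(ev)
  k <- which(cum_var > threshold)[1L]
  if (is.na(k)) k <- length(ev)     # threshold = 1: keep every component
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(c)
    sign(rot[which.max(abs(rot[, c])), c]), numeric(1))
  rot <- sweep(rot, 2L, flip, `*`)
  g <- stack_geometry(stack)
  scores_valid <- scale(X, center = pc$center, scale = pc$scale) %*%
    rot[, seq_len(k), drop = FALSE]
  score_layers <- lapply(seq_len(k), function(c) {
    m <- matrix(NA_real_, g$nrow, g$ncol)
    m[jv] <- scores_valid[, c]
    grid_layer(m, g$origin_x, g$origin_y, g$cell_size,
               name = paste0(label, "_PC", c))
  })
  structure(
    list(label = label, k = k, loadings = rot, eigenvalues = ev,
         cum_var = cum_var, center = pc$center, scale = pc$scale,
         variables = names(stack$layers), threshold = threshold,
         scores = grid_stack(score_layers)),
    class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %s: %d of %d components (cum. var %.1f%% > %.0f%%)\n",
              x$label, x$k, length(x$eigenvalues),
              100 * x$cum_var[x$k], 100 * x$threshold))
  invisible(x)
}

#' Project a co-registered stack onto stored components
#'
#' Applies the fitted standardization and loadings to any stack carrying the
#' variables the PCA was fitted on; cells invalid in the new stack stay
#' invalid.
#'
#' @param ps a `predictor_set`.
#' @param stack a `grid_stack` with (at least) the fitted variables.
#' @return a `grid_stack` of `ps$k` score layers.
#' @export
project_scores <- function(ps, stack) {
  stopifnot(inherits(ps, "predictor_set"), inherits(stack, "grid_stack"))
  missing <- setdiff(ps$variables, names(stack$layers))
  if (length(missing))
    stop("stack lacks variable(s): ", paste(missing, collapse = ", "))
  jv <- Reduce(`&`, lapply(stack$layers[ps$variables], `[[`, "valid"))
  X <- vapply(stack$layers[ps$variables], function(l) l$values[jv],
              numeric(sum(jv)))
  S <- scale(X, center = ps$center, scale = ps$scale) %*%
    ps$loadings[, seq_len(ps$k), drop = FALSE]
  g <- stack_geometry(stack)
  grid_stack(lapply(seq_len(ps$k), function(c) {
    m <- matrix(NA_real_, g$nrow, g$ncol)
    m[jv] <- S[, c]
    grid_layer(m, g$origin_x, g$origin_y, g$cell_size,
               name = paste0(ps$label, "_PC", c))
  }))
}

#' Build the C / E / CE predictor sets
#'
#' Three independent PCAs: climate-only (C), edaphic-only (E), and the
#' concatenation of both families (CE). The CE joint mask is the
#' intersection of the two family masks.
#'
#' @param climate,edaphic co-registered `grid_stack`s.
#' @param threshold cumulative-variance cutoff (see [fit_pca_predictors()]).
#' @return named list of `predictor_set`s: `C`, `E`, `CE`.
#' @export
build_predictor_sets <- function(climate, edaphic, threshold = 0.95) {
  gc <- stack_geometry(climate); ge <- stack_geometry(edaphic)
  if (!isTRUE(all.equal(gc, ge)))
    stop("climate and edaphic stacks are not co-registered")
  ce <- grid_stack(c(climate$layers, edaphic$layers))
  list(C = fit_pca_predictors(climate, threshold, label = "C"),
       E = fit_pca_predictors(edaphic, threshold, label = "E"),
       CE = fit_pca_predictors(ce, threshold, label = "CE"))
}

#' Write a predictor set's bookkeeping tables
#'
#' Loadings and an eigenvalue/variance table as CSV; score layers as ASCII
#' grids.
#'
#' @param ps a `predictor_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_predictor_set <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- file.path(dir, paste0(ps$label, "_loadings.csv"))
  utils::write.csv(data.frame(variable = ps$variables, ps$loadings), lp,
                   row.names = FALSE)
  vp <- file.path(dir, paste0(ps$label, "_variance.csv"))
  utils::write.csv(data.frame(component = seq_along(ps$eigenvalues),
                              eigenvalue = ps$eigenvalues,
                              cum_var = ps$cum_var,
                              retained = seq_along(ps$eigenvalues) <= ps$k),
                   vp, row.names = FALSE)
  sp <- vapply(seq_len(ps$k), function(c)
    write_asc(ps$scores$layers[[c]],
              file.path(dir, paste0(ps$label, "_PC", c, ".asc"))),
    character(1))
  invisible(c(lp, vp, sp))
}
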