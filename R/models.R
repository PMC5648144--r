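#' Algorithm adapters with one shared contract
#'
#' Every `fit_*()` returns an `enm_model`; [predict_points()] maps a
#' predictor matrix to suitabilities in `[0, 1]`, and [predict_raster()]
#' maps a score stack to a suitability layer. The factorial runner is
#' algorithm-agnostic through this contract.
#'
#' @param model an `enm_model`.
#' @param X numeric matrix, columns named as at fit time.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_points <- function(model, X) UseMethod("predict_points")

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("<enm_model> %s (%d predictors)\n", x$algorithm,
              length(x$feature_names)))
  invisible(x)
}

as_model_frame <- function(X, feature_names) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- feature_names
  missing <- setdiff(feature_names, colnames(X))
  if (length(missing))
    stop("predictor-set mismatch; missing: ", paste(missing, collapse = ", "))
  as.data.frame(X[, feature_names, drop = FALSE])
}

## GAM -----------------------------------------------------------------------

#' Fit a binomial GAM with one smooth per predictor
#'
#' Additive model on the logit scale with a univariate thin-plate smooth for
#' every predictor (no interactions, no term selection); the smoothing
#' parameters are optimized by mgcv's outer Newton iteration. The basis
#' dimension is capped at `k = 10` per smooth and, jointly, so that the
#' model never carries more coefficients than training points: with p
#' predictors and n points each smooth gets at most `floor((n-1)/p) + 1`
#' basis functions. A smooth that cannot get a basis of at least 3 -- and
#' any predictor with under 4 distinct values -- enters linearly instead.
#' Small spatial folds with many principal-component predictors would
#' otherwise be wildly over-parameterized.
#'
#' @param X predictor matrix (rows = points).
#' @param y 0/1 labels; both classes required.
#' @param k basis dimension cap per smooth.
#' @return an `enm_model`.
#' @export
fit_gam <- function(X, y, k = 10) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("need both classes to fit a GAM")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  d <- data.frame(y = y, X, check.names = FALSE)
  n <- nrow(X); p <- ncol(X)
  k_budget <- floor((n - 1) / p) + 1L      # total coefficients <= n
  terms <- vapply(colnames(X), function(v) {
    nu <- length(unique(X[, v]))
    kv <- min(k, nu - 1L, k_budget)
    if (nu < 4L || kv < 3L) sprintf("`%s`", v)
    else sprintf("s(`%s`, k = %d)", v, kv)
  }, character(1))
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    mgcv::gam(f, family = stats::binomial(), data = d,
              optimizer = c("outer", "newton")),
    warning = function(w) {
      # perfect separation yields fitted probabilities of 0/1; keep the
      # capped fit and demote the condition to a message-level warning
      warning(conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  structure(list(algorithm = "GAM", fit = fit,
                 feature_names = colnames(X)),
            class = c("enm_gam", "enm_model"))
}

#' @export
predict_points.enm_gam <- function(model, X) {
  d <- as_model_frame(X, model$feature_names)
  p <- as.numeric(stats::predict(model$fit, newdata = d, type = "response"))
  pmin(pmax(p, 0), 1)
}

## MaxEnt, linear + quadratic features ---------------------------------------

# default L1 bound per feature: the published default schedule for
# linear+quadratic feature sets, interpolated on presence count m, scaled by
# the feature's presence-sample SD / sqrt(m)
maxent_default_beta <- function(m, s, reg_multiplier = 1) {
  mm <- c(10, 17, 30, 100)
  bb <- c(0.22, 0.18, 0.14, 0.10)
  b_cat <- stats::approx(mm, bb, xout = m, rule = 2)$y
  reg_multiplier * b_cat * pmax(s, 1e-3) / sqrt(m)
}

#' Fit a maximum-entropy model with linear and quadratic features
#'
#' The model is a Gibbs density over the background cells,
#' `q(x) = exp(lambda . f(x)) / Z`, with features `f` equal to each
#' predictor and its square, affinely rescaled to `[0, 1]` over the
#' background (new points are clamped to that range). The weights minimize
#' the L1-regularized negative mean presence log-likelihood
#' `-(1/m) sum log q(x_i) + sum_j beta_j |lambda_j|`, a convex problem
#' solved by monotone proximal-gradient descent with backtracking, so the
#' objective never increases across iterations. The fitted entropy
#' `H = -sum q log q` drives the logistic output
#' `p(x) = exp(H) q(x) / (1 + exp(H) q(x))`, which is 0.5 everywhere for
#' the uniform (all-zero-weight) model.
#'
#' @param presences_X matrix of predictor values at presences.
#' @param background_X matrix of predictor values at background cells
#'   (callers should cap at 10000 points; see [sample_background()]).
#' @param beta per-feature L1 bounds; default the interpolated schedule.
#' @param reg_multiplier scales the default bounds.
#' @param max_iter iteration cap (default 1000).
#' @param tol relative objective-change convergence tolerance.
#' @return an `enm_model` with weights `lambda`, entropy `H`, and the
#'   per-iteration `objective` trace.
#' @export
fit_maxent_lq <- function(presences_X, background_X, beta = NULL,
                          reg_multiplier = 1, max_iter = 1000, tol = 1e-8) {
  P <- as.matrix(presences_X); B <- as.matrix(background_X)
  if (is.null(colnames(P))) colnames(P) <- paste0("x", seq_len(ncol(P)))
  if (is.null(colnames(B))) colnames(B) <- colnames(P)
  if (!all(is.finite(P)) || !all(is.finite(B)))
    stop("non-finite predictor values")
  vars <- colnames(P)
  raw_feats <- function(M) {
    M <- M[, vars, drop = FALSE]
    F <- cbind(M, M^2)
    colnames(F) <- c(vars, paste0(vars, "^2"))
    F
  }
  Fb_raw <- raw_feats(B)
  lo <- apply(Fb_raw, 2L, min); hi <- apply(Fb_raw, 2L, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  scale_feats <- function(Fr) {
    Fr <- sweep(sweep(Fr, 2L, lo), 2L, rng, `/`)
    pmin(pmax(Fr, 0), 1)   # clamp to the background range
  }
  Fb <- scale_feats(Fb_raw)
  Fp <- scale_feats(raw_feats(P))
  m <- nrow(Fp); nf <- ncol(Fb)
  if (is.null(beta))
    beta <- maxent_default_beta(m, apply(Fp, 2L, stats::sd), reg_multiplier)
  beta <- rep_len(beta, nf)
  p_mean <- colMeans(Fp)
  # objective: log Z(lambda) - lambda . p_mean + sum beta |lambda|
  logZ_q <- function(eta) {            # eta = Fb %*% lambda
    mx <- max(eta)
    w <- exp(eta - mx)
    Z <- sum(w)
    list(logZ = mx + log(Z), q = w / Z)
  }
  lambda <- rep(0, nf)
  eta <- as.vector(Fb %*% lambda)
  zq <- logZ_q(eta)
  smooth_val <- zq$logZ - sum(lambda * p_mean)
  obj <- smooth_val + sum(beta * abs(lambda))
  trace <- obj
  step <- 1
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    grad <- as.vector(crossprod(Fb, zq$q)) - p_mean
    repeat {  # backtracking on the proximal step
      cand <- lambda - step * grad
      cand <- sign(cand) * pmax(abs(cand) - step * beta, 0)  # soft threshold
      eta_c <- as.vector(Fb %*% cand)
      zq_c <- logZ_q(eta_c)
      sv_c <- zq_c$logZ - sum(cand * p_mean)
      d <- cand - lambda
      if (sv_c <= smooth_val + sum(grad * d) + sum(d^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) { cand <- lambda; zq_c <- zq; sv_c <- smooth_val; break }
    }
    new_obj <- sv_c + sum(beta * abs(cand))
    if (new_obj > obj) { converged <- TRUE; break }  # numerically stalled
    lambda <- cand; zq <- zq_c; smooth_val <- sv_c
    converged <- (obj - new_obj) < tol * max(1, abs(obj))
    obj <- new_obj
    trace <- c(trace, obj)
    step <- min(step * 2, 1e3)         # allow the step to grow back
    if (converged) break
  }
  if (max_iter > 0L && !converged)
    warning(sprintf("maxent reached the iteration cap (objective %.6g)", obj))
  q <- zq$q
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  lambda <- stats::setNames(as.vector(lambda), colnames(Fb))
  structure(list(algorithm = "MElq", lambda = lambda, H = H,
                 logZ = zq$logZ, beta = beta, objective = trace,
                 feature_lo = lo, feature_rng = rng,
                 feature_names = vars, n_background = nrow(Fb),
                 scale_feats = NULL),
            class = c("enm_maxent", "enm_model"))
}

maxent_q <- function(model, X) {
  X <- as_model_frame(X, model$feature_names)
  F <- cbind(as.matrix(X), as.matrix(X)^2)
  F <- sweep(sweep(F, 2L, model$feature_lo), 2L, model$feature_rng, `/`)
  F <- pmin(pmax(F, 0), 1)
  exp(as.vector(F %*% model$lambda) - model$logZ)
}

#' @export
predict_points.enm_maxent <- function(model, X) {
  q <- maxent_q(model, X)
  eh <- exp(model$H)
  p <- eh * q / (1 + eh * q)
  pmin(pmax(p, 0), 1)
}

#' Sample background points for the maximum-entropy model
#'
#' All jointly valid cell centers when there are at most `max_points`
#' (the conventional cap of 10000), otherwise a seeded uniform sample of
#' `max_points` cells.
#'
#' @param scores `grid_stack` of predictor layers.
#' @param seed integer.
#' @param max_points background cap.
#' @return list with `X` (matrix of predictor values) and `lon`/`lat`.
#' @export
sample_background <- function(scores, seed, max_points = 10000) {
  g <- stack_geometry(scores)
  cells <- which(scores$joint_valid)
  if (length(cells) > max_points)
    cells <- local_seed(seed, sort(sample(cells, max_points)))
  i <- ((cells - 1L) %% g$nrow) + 1L
  j <- ((cells - 1L) %/% g$nrow) + 1L
  X <- vapply(scores$layers, function(l) l$values[cells],
              numeric(length(cells)))
  cc <- cell_center(g, i, j)
  list(X = X, lon = cc$lon, lat = cc$lat)
}

## Random forest -------------------------------------------------------------

#' Fit a tuned classification random forest
#'
#' Sweeps `mtry` from the classification default (`floor(sqrt(p))`) by the
#' standard step factor 2 in both directions, fits a 500-tree forest per
#' candidate, and keeps the candidate with the minimum out-of-bag error
#' (ties to the smaller `mtry`); the final model is refit at that `mtry`.
#' Suitability is the fraction of tree votes for presence.
#'
#' @param X predictor matrix.
#' @param y 0/1 labels.
#' @param seed integer (forests are seeded per candidate).
#' @param n_trees trees per forest (tuning and final).
#' @param step_factor multiplicative `mtry` step.
#' @return an `enm_model` with `mtry`, `oob_table`.
#' @export
fit_rf <- function(X, y, seed, n_trees = 500, step_factor = 2) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("need both classes to fit a random forest")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  yf <- factor(y, levels = c(0, 1))
  p <- ncol(X)
  m0 <- max(1L, floor(sqrt(p)))
  cand <- m0
  m <- m0; while ((m <- max(1L, floor(m / step_factor))) < min(cand)) cand <- c(m, cand)
  m <- m0; while ((m <- min(p, ceiling(m * step_factor))) > max(cand)) cand <- c(cand, m)
  cand <- sort(unique(pmin(pmax(cand, 1L), p)))
  oob <- vapply(seq_along(cand), function(k) {
    local_seed(seed + k, {
      f <- randomForest::randomForest(X, yf, ntree = n_trees, mtry = cand[k])
      f$err.rate[n_trees, "OOB"]
    })
  }, numeric(1))
  best <- cand[which.min(oob)]
  fit <- local_seed(seed, randomForest::randomForest(X, yf, ntree = n_trees,
                                                     mtry = best))
  structure(list(algorithm = "RF", fit = fit, mtry = best,
                 oob_table = data.frame(mtry = cand, oob = oob),
                 feature_names = colnames(X)),
            class = c("enm_rf", "enm_model"))
}

#' @export
predict_points.enm_rf <- function(model, X) {
  d <- as_model_frame(X, model$feature_names)
  p <- stats::predict(model$fit, newdata = d, type = "prob")[, "1"]
  as.numeric(pmin(pmax(p, 0), 1))
}

## SVM -----------------------------------------------------------------------

#' Fit an RBF support vector machine (C = 1) with probability outputs
#'
#' Radial-basis-kernel C-classification with cost fixed at 1. The kernel
#' width defaults to the inverse median squared pairwise distance between
#' training points (recorded in the model metadata). Class probabilities
#' come from the fitted Platt sigmoid on the decision values. Zero-variance
#' predictors are dropped with a warning.
#'
#' @param X predictor matrix.
#' @param y 0/1 labels.
#' @param seed integer (the Platt fit cross-validates internally).
#' @param cost soft-margin cost.
#' @param gamma kernel width; `NULL` for the median heuristic.
#' @return an `enm_model` with `gamma`.
#' @export
fit_svm <- function(X, y, seed = 1, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("need both classes to fit an SVM")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (is.null(gamma)) {
    n <- nrow(X)
    sub <- if (n > 500) X[round(seq(1, n, length.out = 500)), , drop = FALSE] else X
    med <- stats::median(stats::dist(sub)^2)
    gamma <- if (is.finite(med) && med > 0) 1 / med else 1 / ncol(X)
  }
  yf <- factor(y, levels = c(0, 1))
  fit <- local_seed(seed,
    e1071::svm(X, yf, kernel = "radial", cost = cost, gamma = gamma,
               probability = TRUE))
  structure(list(algorithm = "SVM", fit = fit, gamma = gamma,
                 feature_names = colnames(X)),
            class = c("enm_svm", "enm_model"))
}

#' @export
predict_points.enm_svm <- function(model, X) {
  M <- as.matrix(as_model_frame(X, model$feature_names))
  pr <- stats::predict(model$fit, M, probability = TRUE)
  p <- attr(pr, "probabilities")[, "1"]
  as.numeric(pmin(pmax(p, 0), 1))
}

## shared raster prediction and thresholding ---------------------------------

#' Project a fitted model onto a score stack
#'
#' Predicts suitability for every jointly valid cell; invalid cells stay
#' invalid. The raster prediction at a cell equals the point prediction at
#' that cell's center.
#'
#' @param model an `enm_model`.
#' @param scores `grid_stack` of the predictor set the model was trained on.
#' @return a `grid_layer` of suitabilities in `[0, 1]`.
#' @export
predict_raster <- function(model, scores) {
  stopifnot(inherits(model, "enm_model"), inherits(scores, "grid_stack"))
  if (!all(model$feature_names %in% names(scores$layers)))
    stop("predictor-set mismatch between model and stack")
  g <- stack_geometry(scores)
  cells <- which(scores$joint_valid)
  X <- vapply(scores$layers[model$feature_names],
              function(l) l$values[cells], numeric(length(cells)))
  colnames(X) <- model$feature_names
  p <- predict_points(model, X)
  m <- matrix(NA_real_, g$nrow, g$ncol)
  m[cells] <- p
  grid_layer(m, g$origin_x, g$origin_y, g$cell_size,
             name = paste0(model$algorithm, "_suitability"))
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans the unique predicted values as candidate thresholds under the rule
#' `pred >= threshold -> presence` and returns the candidate maximizing
#' sensitivity + specificity; ties go to the smallest candidate.
#'
#' @param obs 0/1 observed labels (both classes required).
#' @param pred predicted suitabilities.
#' @return the selected threshold (a single number).
#' @export
select_threshold <- function(obs, pred) {
  if (length(unique(obs)) < 2L)
    stop("threshold selection needs both classes")
  cand <- sort(unique(pred))
  np <- sum(obs == 1); nn <- sum(obs == 0)
  ss <- vapply(cand, function(t) {
    sum(pred >= t & obs == 1) / np + sum(pred < t & obs == 0) / nn
  }, numeric(1))
  cand[which.max(ss)]   # which.max returns the first (= smallest) maximizer
}
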