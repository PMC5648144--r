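sep_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- as.integer(X[, 1] > 0)
  list(X = X, y = y)
}

test_that("GAM: separable data give training AUC 1; null labels give ~0.5", {
  d <- sep_data(80, 2)
  m <- suppressWarnings(fit_gam(d$X, d$y))
  expect_equal(auc_rank(d$y, predict_points(m, d$X)), 1)
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400), 200, 2); y <- rbinom(200, 1, 0.5)
    g <- suppressWarnings(fit_gam(X, y))
    auc_rank(y, predict_points(g, X))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(fit_gam(d$X, rep(1, 80)), "both classes")
})

test_that("maxent: zero-iteration model is uniform with logistic output 0.5", {
  set.seed(5)
  bg <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  pr <- bg[1:30, ] + 0.5
  m0 <- fit_maxent_lq(pr, bg, max_iter = 0)
  expect_equal(m0$lambda, rep(0, 4), ignore_attr = TRUE)
  expect_equal(m0$H, log(300))
  p <- predict_points(m0, bg)
  expect_true(all(abs(p - 0.5) < 1e-12))
  q <- nichefactor:::maxent_q(m0, bg)
  expect_equal(sum(q), 1)
})

test_that("maxent: unregularized fit matches the 1-D moment constraint", {
  bg <- matrix(rep(c(0, 1), times = c(500, 500)), ncol = 1,
               dimnames = list(NULL, "x"))
  pr <- matrix(rep(c(1, 0), times = c(80, 20)), ncol = 1,
               dimnames = list(NULL, "x"))
  m <- fit_maxent_lq(pr, bg, beta = 0)
  q <- nichefactor:::maxent_q(m, bg)
  expect_equal(sum(q), 1, tolerance = 1e-10)
  expect_equal(sum(q * bg[, 1]), 0.8, tolerance = 1e-4)
  # independent 1-D bisection oracle: E_q[x] = 0.8 with q ~ exp(theta x)
  # over a 50/50 binary background  =>  e^theta/(e^theta + 1) = 0.8
  f <- function(th) exp(th) / (exp(th) + 1) - 0.8
  lo <- 0; hi <- 10
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) > 0) hi <- mid else lo <- mid }
  theta_hat <- sum(m$lambda)   # both features equal x on this toy
  expect_equal(theta_hat, (lo + hi) / 2, tolerance = 1e-3)
  # objective trace is non-increasing (convex descent contract)
  expect_true(all(diff(m$objective) <= 1e-10))
})

test_that("maxent: strong regularization shrinks all weights to zero", {
  set.seed(6)
  bg <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  pr <- bg[1:40, , drop = FALSE] + 1
  m_big <- fit_maxent_lq(pr, bg, beta = 1e3)
  expect_equal(m_big$lambda, rep(0, 4), ignore_attr = TRUE)
  m_fit <- fit_maxent_lq(pr, bg)
  expect_gt(max(abs(m_fit$lambda)), 0)
  expect_error(fit_maxent_lq(pr * NA, bg), "non-finite")
})

test_that("random forest: OOB-tuned mtry within bounds, seeded determinism", {
  set.seed(7)
  X <- matrix(rnorm(150 * 6), 150, 6)
  X[, 4:6] <- X[, 1:3] + matrix(rnorm(450, sd = 0.1), 150, 3)  # duplicated info
  y <- as.integer(X[, 1] + X[, 2] > 0)
  m <- fit_rf(X, y, seed = 3)
  expect_true(m$mtry >= 1 && m$mtry <= ncol(X))
  oob <- m$oob_table
  expect_lte(oob$oob[oob$mtry == m$mtry][1],
             oob$oob[oob$mtry == max(1, floor(sqrt(ncol(X))))][1])
  m2 <- fit_rf(X, y, seed = 3)
  expect_identical(predict_points(m, X), predict_points(m2, X))
  expect_error(fit_rf(X, rep(0, 150), seed = 1), "both classes")
})

test_that("SVM: radial separability, calibrated null, recorded kernel width", {
  # class = inside/outside a circle; linearly inseparable, RBF-separable
  set.seed(8)
  X <- matrix(runif(400, -1, 1), 200, 2)
  y <- as.integer(rowSums(X^2) < 0.4)
  m <- fit_svm(X, y, seed = 1)
  acc <- mean((predict_points(m, X) >= 0.5) == y)
  expect_gt(acc, 0.95)
  expect_true(is.finite(m$gamma) && m$gamma > 0)
  # probabilities bounded and centered on permuted labels
  ps <- sapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(200), 100, 2); yn <- rbinom(100, 1, 0.5)
    p <- predict_points(fit_svm(Xn, yn, seed = s), Xn)
    expect_true(all(p >= 0 & p <= 1))
    mean(p)
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_warning(fit_svm(cbind(X, 0 * X[, 1]), y, seed = 1), "zero-variance")
})

test_that("raster prediction equals point prediction and respects the mask", {
  env <- toy_world(20, 20, seed = 13)
  env$climate$layers[[1]]$values[2, 2] <- NA
  env$climate$layers[[1]]$valid[2, 2] <- FALSE
  st <- grid_stack(env$climate$layers[1:2])
  d <- sep_data(60, 3)
  colnames(d$X) <- names(st$layers)
  m <- suppressWarnings(fit_gam(d$X, d$y))
  r <- predict_raster(m, st)
  expect_false(r$valid[2, 2])
  expect_true(all(r$values[r$valid] >= 0 & r$values[r$valid] <= 1))
  g <- nichefactor:::stack_geometry(st)
  cc <- cell_center(g, 5, 7)
  ex <- extract_values(st, cc$lon, cc$lat)
  expect_equal(r$values[5, 7], predict_points(m, ex$values))
  # constant model (uniform maxent) -> constant raster
  bg <- sample_background(st, seed = 1)
  m0 <- fit_maxent_lq(bg$X[1:10, ], bg$X, max_iter = 0)
  r0 <- predict_raster(m0, st)
  expect_true(all(abs(r0$values[r0$valid] - 0.5) < 1e-12))
  expect_error(predict_raster(m, grid_stack(list(toy_layer(matrix(1:4, 2))))),
               "mismatch")
})

test_that("threshold selection maximizes sensitivity + specificity exactly", {
  obs <- c(0, 0, 1, 1); pred <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(select_threshold(obs, pred), 0.8)
  cm <- confusion_metrics(obs, pred >= 0.8)
  expect_equal(cm$TPR + cm$TNR, 2)
  # all predictions equal: single candidate, sens + spec = 1, TSS = 0
  obs2 <- c(0, 1, 0, 1); pred2 <- rep(0.4, 4)
  thr2 <- select_threshold(obs2, pred2)
  expect_equal(thr2, 0.4)
  cm2 <- confusion_metrics(obs2, pred2 >= thr2)
  expect_equal(cm2$TSS, 0)
  # randomized vectors against the exhaustive-scan oracle
  for (s in 1:10) {
    set.seed(s)
    obs3 <- rbinom(20, 1, 0.5); if (length(unique(obs3)) < 2) next
    pred3 <- round(runif(20), 2)
    expect_equal(select_threshold(obs3, pred3), bf_threshold(obs3, pred3))
  }
  expect_error(select_threshold(rep(1, 5), runif(5)), "both classes")
})

test_that("every algorithm clears the sanity floor on a strong niche", {
  tss <- sapply(1:10, function(s) {
    env <- toy_world(30, 30, seed = 300 + s)
    st <- grid_stack(c(env$climate$layers, env$edaphic$layers))
    vs <- make_virtual_species(st, data.frame(layer = "clim1", optimum = 0,
                                              breadth = 0.6), "sp")
    occ <- sample_occurrences(vs, 100, seed = s)
    sets <- build_predictor_sets(env$climate, env$edaphic, 0.95)
    ts <- build_training_set("sp", occ[c("lon", "lat")], sets$CE$scores,
                             env$edaphic$layers[[1]], seed = s,
                             r_min = 2, r_max = 15, step = 1)
    sapply(c("GAM", "MElq", "RF", "SVM"), function(al)
      suppressWarnings(
        evaluate_treatment(ts, al, sets$CE$scores, seed = s)$record$TSS))
  })
  expect_true(all(rowMeans(tss) > 0))
})
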