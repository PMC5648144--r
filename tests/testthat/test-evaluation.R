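test_that("confusion metrics follow their definitions", {
  obs <- rep(c(1, 0), c(50, 50))
  expect_equal(confusion_metrics(obs, obs)$TSS, 1)
  expect_equal(confusion_metrics(obs, 1 - obs)$TSS, -1)
  # TP=40 FN=10 TN=30 FP=20
  pred <- c(rep(1, 40), rep(0, 10), rep(0, 30), rep(1, 20))
  cm <- confusion_metrics(obs, pred)
  expect_equal(cm$TPR, 0.8)
  expect_equal(cm$TNR, 0.6)
  expect_equal(cm$TSS, 0.4, tolerance = 1e-12)
  expect_error(confusion_metrics(rep(1, 10), rep(1, 10)), "both classes")
})

test_that("rank AUC matches exhaustive pair counting and is rank-invariant", {
  obs <- rep(c(1, 0), c(4, 4))
  expect_equal(auc_rank(obs, c(5, 6, 7, 8, 1, 2, 3, 4)), 1)
  expect_equal(auc_rank(obs, rep(2, 8)), 0.5)
  # 12-point vectors with heavy ties vs the O(n^2) oracle
  for (s in 1:10) {
    set.seed(s)
    o <- rbinom(12, 1, 0.5); if (length(unique(o)) < 2) next
    sc <- sample(seq(0, 1, 0.25), 12, replace = TRUE)
    expect_equal(auc_rank(o, sc), bf_auc(o, sc))
    # invariance under strictly increasing transforms
    expect_equal(auc_rank(o, sc), auc_rank(o, exp(3 * sc)))
  }
})

test_that("patch labelling counts areas and boundary edges", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1                       # single cell
  p1 <- label_patches(toy_layer(m))
  expect_equal(p1$area, 1L); expect_equal(p1$perimeter, 4L)
  m[4:5, 4:5] <- 1                   # plus a 2x2 block
  p2 <- label_patches(toy_layer(m))
  expect_equal(sort(p2$area), c(1L, 4L))
  expect_equal(sort(p2$perimeter), c(4L, 8L))
  # L-tromino
  m3 <- matrix(0, 4, 4); m3[2, 2] <- 1; m3[3, 2] <- 1; m3[3, 3] <- 1
  p3 <- label_patches(toy_layer(m3))
  expect_equal(p3$area, 3L); expect_equal(p3$perimeter, 8L)
  # perimeters are even and at least 4; invalid cells count as background
  m4 <- matrix(1, 3, 3); m4[2, 2] <- NA
  p4 <- label_patches(toy_layer(m4))
  expect_equal(p4$area, 8L)
  expect_equal(p4$perimeter %% 2, 0L)
  expect_equal(p4$perimeter, 12L + 4L)   # outer ring: outside + hole edges
  # diagonal cells: separate under rook, joined under queen
  m5 <- matrix(0, 3, 3); m5[1, 1] <- 1; m5[2, 2] <- 1
  expect_equal(nrow(label_patches(toy_layer(m5), 4)), 2L)
  expect_equal(nrow(label_patches(toy_layer(m5), 8)), 1L)
  expect_equal(nrow(label_patches(toy_layer(matrix(0, 3, 3)))), 0L)
})

test_that("shape index: squares score 1, bars and fragments score more", {
  sq <- function(k) { m <- matrix(0, k + 2, k + 2); m[2:(k + 1), 2:(k + 1)] <- 1; m }
  for (k in 1:4)
    expect_equal(shape_index(toy_layer(sq(k))), 1)
  bar <- matrix(0, 3, 6); bar[2, 2:5] <- 1
  expect_equal(shape_index(toy_layer(bar)), 1.25)
  l3 <- matrix(0, 4, 4); l3[2, 2] <- 1; l3[3, 2] <- 1; l3[3, 3] <- 1
  expect_equal(shape_index(toy_layer(l3)), 0.25 * 8 / sqrt(3))
  two <- matrix(0, 4, 4); two[1, 1] <- 1; two[3, 3] <- 1
  expect_equal(shape_index(toy_layer(two)), 2)
  expect_equal(shape_index(toy_layer(matrix(0, 3, 3))), 0)
})

test_that("shape index invariances: translation, rotation, isolated cells, merging", {
  set.seed(14)
  m <- matrix(rbinom(100, 1, 0.35), 10, 10)
  si <- shape_index(toy_layer(m))
  # translation (padding shifts) and 90-degree rotation
  pad <- matrix(0, 14, 14); pad[3:12, 2:11] <- m
  expect_equal(shape_index(toy_layer(pad)), si)
  expect_equal(shape_index(toy_layer(t(m[nrow(m):1, ]))), si)
  # adding an isolated suitable cell adds exactly 1
  pad2 <- pad; pad2[14, 14] <- 1
  expect_equal(shape_index(toy_layer(pad2)), si + 1)
  # merging two adjacent singles into a domino lowers SI (2 -> ~1.06)
  dm <- matrix(0, 3, 4); dm[2, 2] <- 1; dm[2, 3] <- 1
  expect_equal(shape_index(toy_layer(dm)), 0.25 * 6 / sqrt(2))
  expect_lt(shape_index(toy_layer(dm)), 2)
})

test_that("map tau-b matches the brute-force pair count and handles ties", {
  set.seed(15)
  m1 <- matrix(sample(1:6, 50, TRUE), 5, 10)
  m2 <- matrix(sample(1:6, 50, TRUE), 5, 10)
  a <- toy_layer(m1); b <- toy_layer(m2)
  expect_equal(kendall_map_tau(a, a), 1)
  neg <- a; neg$values <- -a$values
  expect_equal(kendall_map_tau(a, neg), -1)
  expect_equal(kendall_map_tau(a, b),
               bf_tau_b(as.vector(m1), as.vector(m2)))
  for (s in 1:10) {
    set.seed(100 + s)
    x <- sample(1:5, 50, TRUE); y <- sample(1:7, 50, TRUE)
    expect_equal(nichefactor:::kendall_tau_b_cpp(x, y), bf_tau_b(x, y))
  }
  # only jointly valid cells are compared
  av <- a; av$values[1, 1] <- NA; av$valid[1, 1] <- FALSE
  jv <- which(av$valid)
  expect_equal(kendall_map_tau(av, b),
               bf_tau_b(av$values[jv], b$values[jv]))
  cst <- a; cst$values[] <- 1
  expect_error(kendall_map_tau(a, cst), "constant")
})

test_that("fold evaluation averages symmetric folds and rewards the true model", {
  env <- toy_world(25, 25, seed = 31)
  st <- grid_stack(c(env$climate$layers, env$edaphic$layers))
  sets <- build_predictor_sets(env$climate, env$edaphic, 0.95)
  vs <- make_virtual_species(st, data.frame(layer = "soil1", optimum = 0,
                                            breadth = 0.7), "sp")
  occ <- sample_occurrences(vs, 80, seed = 4)
  ts <- build_training_set("sp", occ[c("lon", "lat")], sets$E$scores,
                           env$edaphic$layers[[1]], seed = 6,
                           r_min = 2, r_max = 15, step = 1)
  res <- evaluate_treatment(ts, "GAM", sets$E$scores, seed = 2)
  r <- res$record
  expect_true(r$TSS >= -1 && r$TSS <= 1)
  expect_true(r$AUC >= 0 && r$AUC <= 1)
  expect_gte(r$SI, 0)
  # swapping the fold roles leaves the averaged record unchanged
  ts_sw <- ts; ts_sw$points$bin <- 3L - ts$points$bin
  r_sw <- evaluate_treatment(ts_sw, "GAM", sets$E$scores, seed = 2)$record
  expect_equal(r_sw$TSS, r$TSS)
  expect_equal(r_sw$AUC, r$AUC)
  expect_equal(r_sw$SI, r$SI)
  # an oracle scoring the true suitability beats a misspecified competitor
  # (here: the same map with its suitability ordering inverted)
  g <- nichefactor:::stack_geometry(sets$E$scores)
  inverted <- vs$true_suitability
  inverted$values <- 1 - inverted$values
  score_with <- function(suit) {
    idx <- cell_index(g, ts$points$lon, ts$points$lat)
    pr <- suit$values[cbind(idx$i, idx$j)]
    te <- ts$points$bin == 2
    auc_rank(ts$points$label[te], pr[te])
  }
  expect_gte(score_with(vs$true_suitability), score_with(inverted))
})
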