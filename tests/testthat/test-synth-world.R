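lag1_cor <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))

test_that("field generation is seeded, standardized and autocorrelation-controlled", {
  f1 <- gen_gaussian_field(50, 50, autocorr_range = 5, seed = 11)
  f2 <- gen_gaussian_field(50, 50, autocorr_range = 5, seed = 11)
  expect_identical(f1$values, f2$values)
  expect_false(identical(
    f1$values, gen_gaussian_field(50, 50, 5, seed = 12)$values))
  # standardized marginal
  expect_lt(abs(mean(f1$values)), 1e-6)
  expect_lt(abs(sd(f1$values) - 1), 1e-6)
  # range 0 -> white noise: lag-1 spatial correlation near zero
  rhos <- sapply(1:20, function(s)
    lag1_cor(gen_gaussian_field(200, 200, 0, seed = s)$values))
  expect_lt(max(abs(rhos)), 0.05)
  # smoothing increases lag-1 correlation monotonically in range
  r_small <- lag1_cor(gen_gaussian_field(100, 100, 2, seed = 3)$values)
  r_big <- lag1_cor(gen_gaussian_field(100, 100, 10, seed = 3)$values)
  expect_gt(r_small, 0.5)
  expect_gt(r_big, r_small)
  expect_error(gen_gaussian_field(0, 10, 1, seed = 1), "positive")
})

test_that("environment generator controls within-family correlation and holes", {
  # strong within-family correlation: first PC of the family > 50% variance
  cfg <- world_config(nrow = 80, ncol = 80, n_climate = 6, n_edaphic = 3,
                      cor_climate = 0.9, cor_edaphic = 0,
                      mask_hole_frac = 0, seed = 5)
  env <- gen_environment(cfg)
  X <- sapply(env$climate$layers, function(l) as.vector(l$values))
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / sum(ev), 0.5)
  # zero correlation: mean absolute pairwise correlation small (200x200)
  cfg0 <- world_config(nrow = 200, ncol = 200, n_climate = 4, n_edaphic = 3,
                       cor_climate = 0, range_climate = 3,
                       mask_hole_frac = 0, seed = 6)
  X0 <- sapply(gen_environment(cfg0)$climate$layers,
               function(l) as.vector(l$values))
  C0 <- cor(X0)
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.05)
  # mask holes: ~10% of the edaphic (and hence joint) cells invalid
  cfgh <- world_config(nrow = 60, ncol = 60, mask_hole_frac = 0.1, seed = 7)
  envh <- gen_environment(cfgh)
  frac <- 1 - mean(envh$edaphic$joint_valid)
  expect_equal(frac, 0.1, tolerance = 0.01)
  expect_true(all(envh$climate$joint_valid))
})

test_that("virtual species have a unimodal product-Gaussian niche", {
  env <- toy_world(20, 20, seed = 2)
  st <- grid_stack(c(env$climate$layers, env$edaphic$layers))
  resp <- data.frame(layer = c("clim1", "soil1"), optimum = c(0.2, -0.4),
                     breadth = c(0.8, 0.5))
  vs <- make_virtual_species(st, resp, "sp_test")
  s <- vs$true_suitability$values
  x1 <- st$layers$clim1$values; x2 <- st$layers$soil1$values
  # closed form at every cell
  expect_equal(s, exp(-(x1 - 0.2)^2 / (2 * 0.8^2)) *
                    exp(-(x2 + 0.4)^2 / (2 * 0.5^2)))
  # at the joint optimum the product is 1; one variable at optimum +/- breadth
  # contributes exp(-1/2), symmetrically
  g1 <- exp(-(0.2 + 0.8 - 0.2)^2 / (2 * 0.8^2))
  expect_equal(g1, exp(-0.5))
  expect_error(make_virtual_species(st, data.frame(layer = "nope",
    optimum = 0, breadth = 1)), "unknown")
  expect_error(make_virtual_species(st, data.frame(layer = "clim1",
    optimum = 0, breadth = 0)), "breadth")
})

test_that("breadth controls range size monotonically", {
  env <- toy_world(30, 30, seed = 4)
  st <- grid_stack(c(env$climate$layers, env$edaphic$layers))
  sizes <- sapply(c(0.3, 0.6, 1.2, 2.4), function(b) {
    vs <- make_virtual_species(st, data.frame(layer = "soil2", optimum = 0.5,
                                              breadth = b))
    sum(vs$true_suitability$values > 0.5, na.rm = TRUE)
  })
  expect_true(all(diff(sizes) > 0))
})

test_that("occurrence sampling follows suitability weights", {
  env <- toy_world(20, 20, seed = 9)
  st <- grid_stack(c(env$climate$layers, env$edaphic$layers))
  vs <- make_virtual_species(st, data.frame(layer = "clim1", optimum = 0,
                                            breadth = 1), "sp")
  occ <- sample_occurrences(vs, 20, seed = 1)
  expect_equal(nrow(occ), 20L)
  expect_true(all(occ$year >= 1979 & occ$year <= 2013))
  expect_identical(occ, sample_occurrences(vs, 20, seed = 1))
  # zero-suitability region is never sampled: zero out all but a quadrant
  vs2 <- vs
  vs2$true_suitability$values[, 11:20] <- 0
  vs2$true_suitability$values[11:20, ] <- 0
  occ2 <- sample_occurrences(vs2, 500, seed = 2)
  g <- nichefactor:::grid_geometry(vs$true_suitability)
  idx <- cell_index(g, occ2$lon, occ2$lat)
  expect_true(all(idx$i <= 10 & idx$j <= 10))
  # exact multinomial frequencies on a 3-cell toy
  toy <- structure(list(species_id = "toy", true_suitability =
    grid_layer(matrix(c(0.5, 0.3, 0.2), 1, 3), 0, 1, 1)),
    class = "virtual_species")
  occ3 <- sample_occurrences(toy, 10000, seed = 3, year_range = NULL)
  cellj <- cell_index(nichefactor:::grid_geometry(toy$true_suitability),
                      occ3$lon, occ3$lat)$j
  tab <- tabulate(cellj, 3)
  expect_gt(chisq.test(tab, p = c(0.5, 0.3, 0.2))$p.value, 0.001)
  # all-zero weights error
  toy$true_suitability$values[] <- 0
  expect_error(sample_occurrences(toy, 5, seed = 1), "zero")
})
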