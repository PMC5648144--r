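mk_occ <- function(lon, lat, year = NA_integer_, sp = "sp1") {
  data.frame(species = sp, lon = lon, lat = lat, year = year)
}

test_that("occurrence CSV round trips and validates coordinates", {
  occ <- mk_occ(lon = c(-60.25, -59.5), lat = c(-10, 3.5),
                year = c(1990L, NA))
  p <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, p)
  back <- read_occurrences(p)
  expect_equal(back, occ)
  # missing column and out-of-range coordinates are rejected
  writeLines(c("species,x,y", "sp,1,2"), p)
  expect_error(read_occurrences(p), "columns")
  writeLines(c("species,lon,lat", "sp,200,10"), p)
  expect_error(read_occurrences(p), "lon")
})

test_that("cleaning drops out-of-area, duplicate and out-of-window records", {
  occ <- mk_occ(lon = c(1, 1, 2, 50, 3, 4, 5),
                lat = c(1, 1, 2, 2, 3, 4, 5),
                year = c(1990, 1990, 1960, 1990, NA, 2000, 2010))
  bbox <- c(0, 10, 0, 10)
  # duplicates collapse, out-of-bbox removed
  cl <- clean_records(occ, bbox)
  expect_equal(nrow(cl), 5L)
  expect_false(any(duplicated(cl[c("lon", "lat")])))
  # year window removes dated records outside it; undated kept by default
  cl2 <- clean_records(occ, bbox, year_range = c(1979, 2013))
  expect_equal(nrow(cl2), 4L)
  expect_true(any(is.na(cl2$year)))
  # strict mode drops undated records too
  cl3 <- clean_records(occ, bbox, year_range = c(1979, 2013),
                       strict_year = TRUE)
  expect_equal(nrow(cl3), 3L)
  expect_error(clean_records(mk_occ(50, 50), bbox), "sp1")
})

test_that("systematic thinning keeps one random record per cell", {
  # 3 records in one 1-degree cell, 2 in another
  occ <- mk_occ(lon = c(0.1, 0.5, 0.9, 2.2, 2.8), lat = c(0.5, 0.2, 0.8, 0.5, 0.4))
  th <- thin_systematic(occ, 1, seed = 5, anchor = c(0, 1))
  expect_equal(nrow(th), 2L)
  expect_identical(th, thin_systematic(occ, 1, seed = 5, anchor = c(0, 1)))
  # all-distinct cells: identity
  occ2 <- mk_occ(lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 0.5))
  expect_identical(thin_systematic(occ2, 1, seed = 1, anchor = c(0, 1)), occ2)
})

test_that("thinning matches brute-force cell assignment and is idempotent", {
  set.seed(33)
  occ <- mk_occ(lon = runif(100, 0, 2), lat = runif(100, 0, 2))
  th <- thin_systematic(occ, 1, seed = 9, anchor = c(0, 2))
  expect_lte(nrow(th), 4L)
  # every retained record is in a distinct brute-force cell, and every
  # occupied cell is represented
  cid <- function(d) paste(floor((2 - d$lat) / 1), floor((d$lon - 0) / 1))
  expect_false(any(duplicated(cid(th))))
  expect_setequal(unique(cid(occ)), cid(th))
  # idempotent at the same resolution and seed
  expect_identical(thin_systematic(th, 1, seed = 9, anchor = c(0, 2)), th)
})

test_that("geographic profiles: hull cell count, floor rule, density", {
  geom <- list(origin_x = 0, origin_y = 5, cell_size = 1, nrow = 5, ncol = 5)
  # 4 records at the corner cell centers of a 3x3 block -> 9 cells
  occ <- mk_occ(lon = c(1.5, 3.5, 1.5, 3.5), lat = c(1.5, 1.5, 3.5, 3.5))
  prof <- geo_profile(occ, NULL, geom)
  expect_equal(prof$GE, 9)
  expect_equal(prof$NR, 4)
  expect_equal(prof$DR, 4 / 9)
  # single record: floor rule GE = 1, DR = 1
  p1 <- geo_profile(mk_occ(0.5, 0.5), NULL, geom)
  expect_equal(p1$GE, 1); expect_equal(p1$DR, 1)
  # collinear records fall back to occupied cells
  pc <- geo_profile(mk_occ(c(0.5, 1.5, 2.5), c(4.5, 4.5, 4.5)), NULL, geom)
  expect_equal(pc$GE, 3)
  # permutation invariance; interior record leaves GE fixed, raises DR
  perm <- occ[c(3, 1, 4, 2), ]
  expect_equal(geo_profile(perm, NULL, geom)$GE, 9)
  occ5 <- rbind(occ, mk_occ(2.5, 2.5))
  p5 <- geo_profile(occ5, NULL, geom)
  expect_equal(p5$GE, 9)
  expect_gt(p5$DR, prof$DR)
})

test_that("hull cell count agrees with ray-casting on random configurations", {
  geom <- list(origin_x = 0, origin_y = 10, cell_size = 1, nrow = 10, ncol = 10)
  for (s in 1:10) {
    set.seed(s)
    lon <- runif(8, 0.3, 9.7) + 0.011; lat <- runif(8, 0.3, 9.7) + 0.013
    got <- nichefactor:::convex_hull_cell_count(lon, lat, geom)
    pts <- unique(cbind(lon, lat)); h <- grDevices::chull(pts)
    vx <- pts[h, 1]; vy <- pts[h, 2]
    centers <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
    want <- sum(mapply(bf_point_in_poly, centers$x, centers$y,
                       MoreArgs = list(vx = vx, vy = vy)))
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("profile correlations and VIF match their definitions", {
  profiles <- data.frame(GE = c(10, 20, 30, 40, 50),
                         NR = c(10, 20, 30, 40, 50),
                         DR = c(1, 0.9, 1.1, 0.95, 1.05))
  r <- suppressWarnings(correlate_profiles(profiles))  # perfect-fit VIF
  expect_equal(r$r["GE", "NR"], 1)
  # orthogonalized (and centered) triple: VIF all 1
  set.seed(41)
  X <- qr.Q(qr(scale(matrix(rnorm(30), 10, 3), center = TRUE, scale = FALSE)))
  p2 <- data.frame(GE = X[, 1], NR = X[, 2], DR = X[, 3])
  expect_equal(unname(correlate_profiles(p2)$vif), rep(1, 3), tolerance = 1e-10)
  # 10-row toy vs definitional brute force
  set.seed(12)
  p3 <- data.frame(GE = rnorm(10), NR = rnorm(10), DR = rnorm(10))
  r3 <- correlate_profiles(p3)
  expect_equal(r3$r["GE", "DR"], cor(p3$GE, p3$DR))
  fit <- lm(GE ~ NR + DR, data = p3)
  expect_equal(unname(r3$vif["GE"]), 1 / (1 - summary(fit)$r.squared))
  expect_error(correlate_profiles(data.frame(GE = rep(1, 5), NR = 1:5,
                                             DR = rnorm(5))), "zero-variance")
})
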