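#' Read / write occurrence tables
#'
#' CSV with header `species,lon,lat` and optional `year`.
#'
#' @param path file path.
#' @return data.frame with columns `species, lon, lat, year`.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns species,lon,lat[,year]")
  if (is.null(occ$year)) occ$year <- NA_integer_
  if (any(!is.finite(occ$lon) | !is.finite(occ$lat)))
    stop("non-finite coordinates in ", path)
  if (any(abs(occ$lon) > 180 | abs(occ$lat) > 90))
    stop("coordinates outside lon [-180,180] / lat [-90,90] in ", path)
  occ[c("species", "lon", "lat", "year")]
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Clean occurrence records
#'
#' Drops records outside the study-area bounding box, collapses exact
#' duplicate coordinate pairs to a single record, and (when `year_range` is
#' given) drops records dated outside the range. Undated records are kept by
#' default -- set `strict_year = TRUE` to drop them too.
#'
#' @param occ occurrence data.frame (`species, lon, lat[, year]`).
#' @param bbox `c(xmin, xmax, ymin, ymax)`, degrees.
#' @param year_range optional inclusive `c(first, last)`.
#' @param strict_year drop records with missing year when filtering by year.
#' @return cleaned data.frame, original order preserved.
#' @export
clean_records <- function(occ, bbox, year_range = NULL, strict_year = FALSE) {
  stopifnot(length(bbox) == 4L)
  keep <- occ$lon >= bbox[1] & occ$lon <= bbox[2] &
          occ$lat >= bbox[3] & occ$lat <= bbox[4]
  if (!is.null(year_range)) {
    yr <- if (is.null(occ$year)) rep(NA_integer_, nrow(occ)) else occ$year
    in_years <- !is.na(yr) & yr >= year_range[1] & yr <= year_range[2]
    keep <- keep & ifelse(is.na(yr), !strict_year, in_years)
  }
  out <- occ[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("lon", "lat")]), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no records left after cleaning for species ",
         paste(unique(occ$species), collapse = ","))
  rownames(out) <- NULL
  out
}

#' Systematic spatial thinning
#'
#' Overlays a square grid of the given resolution (anchored at the
#' study-extent top-left corner) and keeps one record per occupied cell,
#' chosen uniformly at random under `seed`. Output preserves the input
#' order of the retained records, so the operation is deterministic and
#' idempotent at a fixed seed.
#'
#' @param occ occurrence data.frame.
#' @param resolution thinning cell size, degrees (`> 0`).
#' @param seed integer.
#' @param anchor `c(x, y)` top-left corner of the thinning grid.
#' @return thinned data.frame.
#' @export
thin_systematic <- function(occ, resolution, seed, anchor = c(-180, 90)) {
  if (resolution <= 0) stop("resolution must be > 0")
  bi <- floor((anchor[2] - occ$lat) / resolution)
  bj <- floor((occ$lon - anchor[1]) / resolution)
  cellid <- paste(bi, bj)
  keep <- local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(occ)), cellid), function(ix)
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]))
  })
  out <- occ[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-species geographic characteristics
#'
#' Computes, on a given grid geometry: `GE`, the number of grid cells whose
#' centers lie inside or on the minimum convex polygon of the records
#' (fewer than 3 distinct or collinear records fall back to the count of
#' occupied cells, as does a hull containing no cell center); `NR`, the
#' record count; `DR = NR / GE`, the record density; and, per predictor
#' set, the standard deviation of first-principal-component scores at the
#' record cells.
#'
#' @param occ occurrence data.frame for one species.
#' @param predictor_sets optional named list of `predictor_set` objects
#'   (see [fit_pca_predictors()]); may be `NULL`.
#' @param geom grid geometry (from a layer of the modeling grid).
#' @return one-row data.frame `species, GE, NR, DR[, sd_pc1_<label>...]`.
#' @export
geo_profile <- function(occ, predictor_sets = NULL, geom) {
  stopifnot(nrow(occ) >= 1L)
  idx <- cell_index(geom, occ$lon, occ$lat)
  occupied <- unique(stats::na.omit(paste(idx$i, idx$j)))
  GE <- convex_hull_cell_count(occ$lon, occ$lat, geom)
  if (is.na(GE) || GE < 1L) GE <- length(occupied)
  NR <- nrow(occ)
  prof <- data.frame(species = occ$species[1], GE = GE, NR = NR, DR = NR / GE)
  for (lab in names(predictor_sets)) {
    ps <- predictor_sets[[lab]]
    ex <- extract_values(ps$scores, occ$lon, occ$lat)
    prof[[paste0("sd_pc1_", lab)]] <- stats::sd(ex$values[ex$valid, 1L])
  }
  prof
}

# count of cell centers inside/on the convex hull; NA for degenerate hulls
convex_hull_cell_count <- function(lon, lat, geom) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3L) return(NA_integer_)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(NA_integer_)    # collinear
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # force clockwise orientation (signed shoelace area > 0 means CCW)
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 > 0) { hx <- rev(hx); hy <- rev(hy) }
  # candidate centers restricted to the hull's bounding box
  xc <- geom$origin_x + (seq_len(geom$ncol) - 0.5) * geom$cell_size
  yc <- geom$origin_y - (seq_len(geom$nrow) - 0.5) * geom$cell_size
  xc <- xc[xc >= min(hx) - geom$cell_size & xc <= max(hx) + geom$cell_size]
  yc <- yc[yc >= min(hy) - geom$cell_size & yc <= max(hy) + geom$cell_size]
  if (!length(xc) || !length(yc)) return(0L)
  px <- rep(xc, times = length(yc)); py <- rep(yc, each = length(xc))
  inside <- rep(TRUE, length(px))
  n <- length(hx)
  eps <- 1e-12 * max(1, max(abs(hx)), max(abs(hy)))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    # cross product; clockwise hull => interior has cross <= 0
    cr <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    inside <- inside & (cr <= eps)
  }
  sum(inside)
}

#' Correlations and collinearity among geographic characteristics
#'
#' Pairwise Pearson correlations (with two-sided p-values) and variance
#' inflation factors, `VIF_j = 1 / (1 - R2_j)` from regressing each
#' characteristic on the others.
#'
#' @param profiles data.frame of per-species profiles (rows = species).
#' @param vars columns to analyze; default `GE`, `NR`, `DR`.
#' @return list with `r` (correlation matrix), `p` (p-value matrix), `vif`
#'   (named vector).
#' @export
correlate_profiles <- function(profiles, vars = c("GE", "NR", "DR")) {
  X <- as.matrix(profiles[vars])
  if (nrow(X) < 3L) stop("need at least 3 species")
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("zero-variance characteristic: ",
         paste(vars[apply(X, 2L, stats::sd) == 0], collapse = ", "))
  p <- r <- diag(1, length(vars))
  dimnames(r) <- dimnames(p) <- list(vars, vars)
  diag(p) <- NA_real_
  for (a in seq_along(vars)) for (b in seq_along(vars)) if (a < b) {
    ct <- stats::cor.test(X[, a], X[, b])
    r[a, b] <- r[b, a] <- unname(ct$estimate)
    p[a, b] <- p[b, a] <- ct$p.value
  }
  vif <- vapply(seq_along(vars), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
  names(vif) <- vars
  list(r = r, p = p, vif = vif)
}
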