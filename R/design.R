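#' Sample pseudo-absences at prevalence 1
#'
#' Draws one pseudo-absence per presence (prevalence 1) at the centers of
#' cells sampled without replacement from the eligible cells of the mask
#' layer: valid cells that contain no presence. The mask plays the role of
#' the soil layer used to keep pseudo-absences out of "empty cells".
#'
#' @param presences data.frame with `lon`, `lat`.
#' @param mask_layer a `grid_layer`; its valid cells define the sampling
#'   domain.
#' @param seed integer.
#' @param n number of pseudo-absences; defaults to `nrow(presences)`.
#' @return data.frame `lon, lat` of cell centers, one row per pseudo-absence.
#' @export
sample_pseudoabsences <- function(presences, mask_layer, seed,
                                  n = nrow(presences)) {
  stopifnot(inherits(mask_layer, "grid_layer"))
  g <- grid_geometry(mask_layer)
  idx <- cell_index(g, presences$lon, presences$lat)
  pres_lin <- unique(stats::na.omit(idx$i + (idx$j - 1L) * g$nrow))
  eligible <- which(mask_layer$valid)
  eligible <- setdiff(eligible, pres_lin)
  if (length(eligible) < n)
    stop(sprintf("only %d eligible cells for %d pseudo-absences",
                 length(eligible), n))
  cells <- local_seed(seed, eligible[sample.int(length(eligible), n)])
  i <- ((cells - 1L) %% g$nrow) + 1L
  j <- ((cells - 1L) %/% g$nrow) + 1L
  cell_center(g, i, j)
}

#' Checkerboard bin assignment
#'
#' Points are binned by the parity of their checkerboard block: a point in
#' block `(bi, bj)` (blocks of edge `resolution`, anchored at `anchor`,
#' half-open) gets bin `1 + ((bi + bj) mod 2)`, so horizontally or
#' vertically adjacent blocks alternate bins and diagonal blocks share one.
#'
#' @param lon,lat point coordinates, degrees.
#' @param resolution block edge, degrees (`> 0`).
#' @param anchor `c(x, y)` top-left corner of the block grid (the study
#'   extent's top-left by convention).
#' @return integer vector of bins in `{1, 2}`.
#' @export
checkerboard_assign <- function(lon, lat, resolution, anchor) {
  if (resolution <= 0) stop("resolution must be > 0")
  bi <- floor((anchor[2] - lat) / resolution)
  bj <- floor((lon - anchor[1]) / resolution)
  as.integer(1L + (bi + bj) %% 2L)
}

#' Select the checkerboard resolution that balances the two folds
#'
#' Enumerates candidate resolutions `r_min, r_min + step, ..., r_max` (the
#' default sweep 0.5 to 15 by 0.5 gives 30 candidates). A candidate is
#' feasible when both bins hold at least one presence; among feasible
#' candidates the one minimizing the presence imbalance
#' `|n_bin1 - n_bin2|` wins, ties going to the smallest resolution (finest
#' blocks, hence the most conservative spatial separation).
#'
#' @param presences data.frame with `lon`, `lat` (>= 2 rows).
#' @param r_min,r_max,step candidate sweep, degrees.
#' @param anchor block-grid anchor `c(x, y)`.
#' @return object of class `partition_search`: `candidates` data.frame
#'   (`resolution, n_bin1, n_bin2, feasible, imbalance`),
#'   `chosen_resolution`, `imbalance`.
#' @export
select_checkerboard_resolution <- function(presences, r_min = 0.5, r_max = 15,
                                           step = 0.5, anchor) {
  if (nrow(presences) < 2L) stop("need at least 2 presences")
  res <- seq(r_min, r_max, by = step)
  tab <- do.call(rbind, lapply(res, function(r) {
    b <- checkerboard_assign(presences$lon, presences$lat, r, anchor)
    data.frame(resolution = r, n_bin1 = sum(b == 1L), n_bin2 = sum(b == 2L))
  }))
  tab$feasible <- tab$n_bin1 > 0L & tab$n_bin2 > 0L
  tab$imbalance <- abs(tab$n_bin1 - tab$n_bin2)
  if (!any(tab$feasible))
    stop("no feasible checkerboard resolution: some bin is always empty")
  feas <- tab[tab$feasible, ]
  best <- feas[which.min(feas$imbalance), ]  # which.min takes the first = smallest r
  structure(list(candidates = tab,
                 chosen_resolution = best$resolution,
                 imbalance = best$imbalance),
            class = "partition_search")
}

#' @export
print.partition_search <- function(x, ...) {
  cat(sprintf("<partition_search> chosen resolution %.2g deg (imbalance %d, %d/%d candidates feasible)\n",
              x$chosen_resolution, x$imbalance,
              sum(x$candidates$feasible), nrow(x$candidates)))
  invisible(x)
}

#' Allocate pseudo-absences to partition bins at per-bin prevalence 1
#'
#' Spatial-first rule (default): each pseudo-absence starts in the bin of
#' its own checkerboard block; if the resulting per-bin counts differ from
#' the presence counts, surplus pseudo-absences from the over-represented
#' bin are re-sampled onto eligible cells lying in blocks of the deficient
#' bin until each bin holds exactly as many pseudo-absences as presences.
#' The `"relabel"` method ignores location and randomly assigns bin labels
#' with the right counts.
#'
#' @param pa data.frame of pseudo-absences (`lon`, `lat`).
#' @param presence_bins integer vector of presence bins (defines the
#'   per-bin quotas).
#' @param resolution,anchor checkerboard geometry.
#' @param mask_layer `grid_layer` restricting re-sampled cells.
#' @param presences presence data.frame (their cells stay off-limits).
#' @param seed integer.
#' @param method `"spatial"` (default) or `"relabel"`.
#' @return list with `pa` (possibly with re-sampled coordinates) and `bin`
#'   (integer vector).
#' @export
allocate_pa_to_bins <- function(pa, presence_bins, resolution, anchor,
                                mask_layer, presences, seed,
                                method = c("spatial", "relabel")) {
  method <- match.arg(method)
  if (nrow(pa) != length(presence_bins))
    stop("pseudo-absence count must equal presence count")
  quota <- tabulate(presence_bins, nbins = 2L)
  if (method == "relabel") {
    bin <- local_seed(seed, sample(rep(1:2, quota)))
    return(list(pa = pa, bin = bin))
  }
  bin <- checkerboard_assign(pa$lon, pa$lat, resolution, anchor)
  g <- grid_geometry(mask_layer)
  pres_idx <- cell_index(g, presences$lon, presences$lat)
  pres_lin <- unique(stats::na.omit(pres_idx$i + (pres_idx$j - 1L) * g$nrow))
  local_seed(seed, {
    have <- tabulate(bin, nbins = 2L)
    if (any(have != quota)) {
      over <- which.max(have - quota); under <- 3L - over
      n_move <- have[over] - quota[over]
      # eligible cells in the deficient bin's blocks, excluding presence
      # cells and cells already used by pseudo-absences
      pa_idx <- cell_index(g, pa$lon, pa$lat)
      pa_lin <- pa_idx$i + (pa_idx$j - 1L) * g$nrow
      cand <- which(mask_layer$valid)
      cand <- setdiff(cand, c(pres_lin, pa_lin))
      ci <- ((cand - 1L) %% g$nrow) + 1L
      cj <- ((cand - 1L) %/% g$nrow) + 1L
      cc <- cell_center(g, ci, cj)
      cand_bin <- checkerboard_assign(cc$lon, cc$lat, resolution, anchor)
      pool <- which(cand_bin == under)
      if (length(pool) < n_move)
        stop(sprintf("bin %d lacks eligible cells to restore prevalence 1", under))
      movers <- which(bin == over)
      movers <- movers[sample.int(length(movers), n_move)]
      dest <- pool[sample.int(length(pool), n_move)]
      pa$lon[movers] <- cc$lon[dest]
      pa$lat[movers] <- cc$lat[dest]
      bin[movers] <- under
    }
    list(pa = pa, bin = bin)
  })
}

#' Assemble a species' training set
#'
#' Runs the spatial design end to end for one species and one predictor
#' set: drops presences over invalid predictor cells, selects the
#' checkerboard resolution on the presences, samples prevalence-1
#' pseudo-absences under the mask, allocates them to bins at per-bin
#' prevalence 1, and extracts predictor values for every point.
#'
#' @param species_id text id.
#' @param presences data.frame `lon, lat`.
#' @param scores `grid_stack` of predictor (score) layers.
#' @param mask_layer `grid_layer` for pseudo-absence eligibility.
#' @param seed integer.
#' @param r_min,r_max,step candidate resolutions (degrees).
#' @param anchor checkerboard anchor; defaults to the score grid's top-left
#'   corner.
#' @param pa_method passed to [allocate_pa_to_bins()].
#' @return object of class `training_set`: `points` data.frame
#'   (`lon, lat, label, bin`), `X` predictor matrix, `chosen_resolution`,
#'   `search` (the `partition_search`), `species_id`.
#' @export
build_training_set <- function(species_id, presences, scores, mask_layer,
                               seed, r_min = 0.5, r_max = 15, step = 0.5,
                               anchor = NULL, pa_method = "spatial") {
  g <- stack_geometry(scores)
  if (is.null(anchor)) anchor <- c(g$origin_x, g$origin_y)
  # pseudo-absences must carry valid predictor values too: restrict the
  # mask to cells that are also valid under the score stack
  mv <- mask_layer$values
  mv[!scores$joint_valid] <- NA_real_
  mask_layer <- grid_layer(mv, g$origin_x, g$origin_y, g$cell_size,
                           name = mask_layer$name)
  ex <- extract_values(scores, presences$lon, presences$lat)
  if (any(!ex$valid)) {
    presences <- presences[ex$valid, , drop = FALSE]
    if (nrow(presences) < 2L)
      stop("species ", species_id, ": fewer than 2 presences on valid cells")
  }
  search <- select_checkerboard_resolution(presences, r_min, r_max, step,
                                           anchor = anchor)
  r <- search$chosen_resolution
  pres_bin <- checkerboard_assign(presences$lon, presences$lat, r, anchor)
  pa0 <- sample_pseudoabsences(presences, mask_layer, seed = seed)
  al <- allocate_pa_to_bins(pa0, pres_bin, r, anchor, mask_layer, presences,
                            seed = seed + 1L, method = pa_method)
  pts <- rbind(
    data.frame(lon = presences$lon, lat = presences$lat, label = 1L,
               bin = pres_bin),
    data.frame(lon = al$pa$lon, lat = al$pa$lat, label = 0L, bin = al$bin))
  ex_all <- extract_values(scores, pts$lon, pts$lat)
  if (any(!ex_all$valid))
    stop("species ", species_id, ": point without valid predictor values")
  structure(list(species_id = species_id, points = pts, X = ex_all$values,
                 chosen_resolution = r, search = search, anchor = anchor),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s: %d presences + %d pseudo-absences, bins %d/%d, resolution %.2g deg\n",
              x$species_id, sum(x$points$label == 1L), sum(x$points$label == 0L),
              sum(x$points$bin == 1L), sum(x$points$bin == 2L),
              x$chosen_resolution))
  invisible(x)
}
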