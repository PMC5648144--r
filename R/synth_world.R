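#' Generate a Gaussian random field layer
#'
#' White noise is filtered with an isotropic Gaussian kernel of scale
#' `autocorr_range` (in cells) by circular (FFT) convolution, then
#' standardized to mean 0, SD 1 over valid cells. Circular convolution keeps
#' the field stationary right up to the edges. `autocorr_range = 0` returns
#' standardized white noise. The result is a pure function of
#' `(nrow, ncol, spec)`.
#'
#' @param nrow,ncol grid shape in cells (positive).
#' @param autocorr_range Gaussian kernel SD in cells; `>= 0`. Large values
#'   give smooth, climate-like fields; small values give rough, soil-like
#'   fields.
#' @param seed integer seed; generation does not disturb the caller's RNG.
#' @param origin_x,origin_y,cell_size,name geometry and name passed to
#'   [grid_layer()].
#' @return a standardized `grid_layer`.
#' @export
gen_gaussian_field <- function(nrow, ncol, autocorr_range, seed,
                               origin_x = 0, origin_y = 0, cell_size = 1,
                               name = "field") {
  if (nrow < 1 || ncol < 1) stop("field shape must be positive")
  if (autocorr_range < 0) stop("autocorr_range must be >= 0")
  noise <- local_seed(seed, matrix(stats::rnorm(nrow * ncol), nrow, ncol))
  f <- if (autocorr_range > 0) {
    # circular convolution with a periodic Gaussian kernel
    di <- c(0:(nrow %/% 2), -((nrow - nrow %/% 2 - 1):1))
    dj <- c(0:(ncol %/% 2), -((ncol - ncol %/% 2 - 1):1))
    if (nrow == 1) di <- 0
    if (ncol == 1) dj <- 0
    k <- exp(-outer(di^2, dj^2, `+`) / (2 * autocorr_range^2))
    Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
      (nrow * ncol)
  } else noise
  f <- (f - mean(f)) / stats::sd(f)
  grid_layer(f, origin_x, origin_y, cell_size, name = name)
}

# evaluate expr under a temporary RNG state; seeds folded into 31 bits
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  expr
}

# derive a 31-bit stream seed from a base seed and a stage offset
offset_seed <- function(seed, offset) {
  (as.numeric(seed) %% 2146483) * 1000 + offset
}

#' Default synthetic-world configuration
#'
#' The defaults mirror the contrast the analysis depends on: few smooth,
#' strongly intercorrelated climate-like fields (long autocorrelation range)
#' versus more numerous, rough, spatially complex edaphic-like fields (short
#' range), on one shared lon/lat geometry covering a Neotropical-scale
#' window (-120 to -30 longitude, -55 to 35 latitude). A small fraction of
#' edaphic cells is punched out to emulate grid cells where climate exists
#' but soil data do not ("empty cells").
#'
#' @param nrow,ncol world shape in cells.
#' @param cell_size cell edge, degrees.
#' @param origin_x,origin_y top-left corner, degrees.
#' @param n_climate,n_edaphic layer counts per family.
#' @param range_climate,range_edaphic autocorrelation ranges, cells.
#' @param cor_climate,cor_edaphic within-family correlation (share of a
#'   common latent field), in `[0, 1)`; mimics the collinearity that lets a
#'   couple of principal components carry most of the variance.
#' @param mask_hole_frac fraction of cells set invalid in the edaphic family.
#' @param seed integer.
#' @return a named list understood by [gen_environment()].
#' @export
world_config <- function(nrow = 150, ncol = 150, cell_size = 0.6,
                         origin_x = -120, origin_y = 35,
                         n_climate = 6, n_edaphic = 8,
                         range_climate = 40, range_edaphic = 4,
                         cor_climate = 0.6, cor_edaphic = 0.6,
                         mask_hole_frac = 0.02, seed = 1) {
  as.list(environment())
}

#' Generate the paired climate-like and edaphic-like stacks
#'
#' Each family mixes a shared latent field with independent fields:
#' `layer = sqrt(rho) * shared + sqrt(1 - rho) * independent`, restandardized,
#' giving expected pairwise within-family correlation `rho`. Mask holes are
#' applied to the edaphic family only, so the joint mask of the combined
#' world loses about `mask_hole_frac` of its cells.
#'
#' @param config list from [world_config()].
#' @return list with `climate` and `edaphic` grid stacks on one geometry.
#' @export
gen_environment <- function(config = world_config()) {
  cfg <- config
  gen_family <- function(prefix, n, rng, rho, seed0) {
    shared <- gen_gaussian_field(cfg$nrow, cfg$ncol, rng, seed = seed0,
                                 origin_x = cfg$origin_x, origin_y = cfg$origin_y,
                                 cell_size = cfg$cell_size, name = "shared")
    lapply(seq_len(n), function(k) {
      ind <- gen_gaussian_field(cfg$nrow, cfg$ncol, rng, seed = seed0 + k,
                                origin_x = cfg$origin_x, origin_y = cfg$origin_y,
                                cell_size = cfg$cell_size,
                                name = paste0(prefix, k))
      v <- sqrt(rho) * shared$values + sqrt(1 - rho) * ind$values
      v <- (v - mean(v)) / stats::sd(v)
      grid_layer(v, cfg$origin_x, cfg$origin_y, cfg$cell_size,
                 name = paste0(prefix, k))
    })
  }
  clim <- gen_family("clim", cfg$n_climate, cfg$range_climate,
                     cfg$cor_climate, seed0 = offset_seed(cfg$seed, 0))
  edap <- gen_family("soil", cfg$n_edaphic, cfg$range_edaphic,
                     cfg$cor_edaphic, seed0 = offset_seed(cfg$seed, 500))
  if (cfg$mask_hole_frac > 0) {
    ncell <- cfg$nrow * cfg$ncol
    holes <- local_seed(offset_seed(cfg$seed, 999),
                        sample.int(ncell, round(cfg$mask_hole_frac * ncell)))
    edap <- lapply(edap, function(l) { l$values[holes] <- NA_real_
                                       l$valid[holes] <- FALSE; l })
  }
  list(climate = grid_stack(clim), edaphic = grid_stack(edap))
}

#' Define a virtual species with a known Gaussian niche
#'
#' True suitability is a product of Gaussian responses,
#' `prod(exp(-(x - optimum)^2 / (2 breadth^2)))`, so it equals 1 at the joint
#' optimum, decreases monotonically as any variable departs from its
#' optimum, and stays in `[0, 1]`. Suitability is undefined (invalid) where
#' the stack's joint mask is false.
#'
#' @param stack a `grid_stack` holding the response layers (typically the
#'   combined raw climate + edaphic world).
#' @param responses data.frame with columns `layer`, `optimum`, `breadth`
#'   (`breadth > 0`).
#' @param species_id text id.
#' @param seed stored for provenance (sampling uses it downstream).
#' @return an object of class `virtual_species` with a `true_suitability`
#'   grid layer.
#' @export
make_virtual_species <- function(stack, responses, species_id = "vsp", seed = 1) {
  stopifnot(inherits(stack, "grid_stack"), is.data.frame(responses))
  missing <- setdiff(responses$layer, names(stack$layers))
  if (length(missing))
    stop("unknown response layer(s): ", paste(missing, collapse = ", "))
  if (any(responses$breadth <= 0)) stop("breadth must be > 0")
  g <- stack_geometry(stack)
  s <- matrix(1, g$nrow, g$ncol)
  for (r in seq_len(nrow(responses))) {
    x <- stack$layers[[responses$layer[r]]]$values
    s <- s * exp(-(x - responses$optimum[r])^2 / (2 * responses$breadth[r]^2))
  }
  s[!stack$joint_valid] <- NA_real_
  structure(list(species_id = species_id, responses = responses,
                 true_suitability = grid_layer(
                   s, g$origin_x, g$origin_y, g$cell_size,
                   name = paste0(species_id, "_suitability")),
                 seed = seed),
            class = "virtual_species")
}

#' Sample occurrence records from a virtual species
#'
#' Cells are drawn (with replacement) with probability proportional to
#' `true_suitability * bias` over valid cells; each record is then placed
#' uniformly within its cell. Years are drawn uniformly from `year_range`
#' (the collection window of the climate normals) so the temporal cleaning
#' stage has something to act on.
#'
#' @param vs a `virtual_species`.
#' @param n number of records, `>= 1`.
#' @param seed integer.
#' @param bias optional `grid_layer` of non-negative sampling weights
#'   (default uniform).
#' @param year_range integer length-2, inclusive; `NULL` for no years.
#' @return data.frame `species, lon, lat, year` (an occurrence table).
#' @export
sample_occurrences <- function(vs, n, seed, bias = NULL,
                               year_range = c(1979, 2013)) {
  stopifnot(inherits(vs, "virtual_species"), n >= 1)
  suit <- vs$true_suitability
  w <- suit$values
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "grid_layer"))
    w <- w * bias$values
  }
  w[!is.finite(w)] <- 0
  if (all(w == 0)) stop("all sampling weights are zero for ", vs$species_id)
  g <- grid_geometry(suit)
  local_seed(seed, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    i <- ((cells - 1L) %% g$nrow) + 1L
    j <- ((cells - 1L) %/% g$nrow) + 1L
    lon <- g$origin_x + (j - 1L + stats::runif(n)) * g$cell_size
    lat <- g$origin_y - (i - 1L + stats::runif(n)) * g$cell_size
    year <- if (is.null(year_range)) NA_integer_ else
      sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
    data.frame(species = vs$species_id, lon = lon, lat = lat, year = year)
  })
}

#' Build a roster of virtual species
#'
#' Each species responds to `n_responses` layers drawn from the requested
#' family; optima are taken from random quantiles (0.1-0.9) of the layer's
#' valid values so the niche sits inside the realized environment, and
#' breadths are drawn uniformly from `breadth_range` (in SD units of the
#' standardized layers -- larger breadth means larger range size). Record
#' counts are log-uniform between `n_records_range` bounds, matching the
#' spread of cleaned-record counts (20 to 1227) the design anticipates.
#'
#' @param stack combined raw-environment `grid_stack`.
#' @param n_species number of species.
#' @param niche `"edaphic"`, `"climate"` or `"mixed"` -- which family the
#'   response layers come from (`"mixed"` draws from both).
#' @param climate_layers,edaphic_layers layer-name character vectors.
#' @param n_responses responses per species.
#' @param breadth_range,n_records_range numeric length-2.
#' @param seed integer.
#' @return list of `virtual_species`, each with an `n_records` attribute.
#' @export
make_species_roster <- function(stack, n_species, niche = "mixed",
                                climate_layers, edaphic_layers,
                                n_responses = 2,
                                breadth_range = c(0.5, 1.25),
                                n_records_range = c(20, 1227),
                                seed = 1) {
  pool <- switch(niche,
                 edaphic = edaphic_layers,
                 climate = climate_layers,
                 mixed = c(climate_layers, edaphic_layers),
                 stop("niche must be edaphic, climate or mixed"))
  local_seed(seed, {
    lapply(seq_len(n_species), function(s) {
      lys <- sample(pool, min(n_responses, length(pool)))
      resp <- data.frame(
        layer = lys,
        optimum = vapply(lys, function(nm)
          stats::quantile(stack$layers[[nm]]$values[stack$joint_valid],
                          stats::runif(1, 0.1, 0.9), names = FALSE),
          numeric(1)),
        breadth = stats::runif(length(lys), breadth_range[1], breadth_range[2]))
      vs <- make_virtual_species(stack, resp,
                                 species_id = sprintf("vsp%02d", s),
                                 seed = seed + s)
      attr(vs, "n_records") <- round(exp(stats::runif(
        1, log(n_records_range[1]), log(n_records_range[2]))))
      vs
    })
  })
}
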