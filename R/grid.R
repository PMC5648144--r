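#' Construct a gridded environmental layer
#'
#' A `grid_layer` is a north-up, square-celled raster in geographic
#' coordinates (lon/lat degrees). Cell `(i, j)` (row `i` from the top, column
#' `j` from the left) covers the half-open box
#' `[origin_x + (j-1) s, origin_x + j s) x (origin_y - i s, origin_y - (i-1) s]`,
#' so a point on a shared edge belongs to exactly one cell (left/top
#' inclusive). Invalid (nodata) cells are `NA` in `values` and `FALSE` in
#' `valid`; all statistics in the package ignore them.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param origin_x,origin_y longitude/latitude of the top-left corner, degrees.
#' @param cell_size cell edge in degrees; must be positive.
#' @param name layer name.
#' @param crs_label free-text CRS tag; geographic lon/lat is assumed.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, origin_x, origin_y, cell_size,
                       name = "layer", crs_label = "lonlat-degrees") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (any(is.infinite(values)))
    stop("values must be finite or NA")
  structure(
    list(name = as.character(name), values = values,
         valid = is.finite(values),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), crs_label = crs_label),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %s: %d x %d cells, %.6g deg, origin (%.6g, %.6g), %d valid\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y, sum(x$valid)))
  invisible(x)
}

#' Stack co-registered layers
#'
#' All layers must share shape, origin, cell size and CRS label. The stack's
#' `joint_valid` mask is the conjunction of the member masks: a cell missing
#' in any layer is unusable for fitting or prediction (the "empty cells"
#' rule used when soil and climate grids disagree on coverage).
#'
#' @param layers list of [grid_layer] objects.
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(layers) {
  if (length(layers) == 0L) stop("empty stack")
  if (inherits(layers, "grid_layer")) layers <- list(layers)
  ref <- layers[[1L]]
  for (l in layers) {
    stopifnot(inherits(l, "grid_layer"))
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(c(l$origin_x, l$origin_y, l$cell_size),
                          c(ref$origin_x, ref$origin_y, ref$cell_size))) ||
        !identical(l$crs_label, ref$crs_label))
      stop("layers are not co-registered (shape/origin/cell_size/crs differ)")
  }
  jv <- Reduce(`&`, lapply(layers, `[[`, "valid"))
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, joint_valid = jv), class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d layers (%s), %d x %d cells, %d jointly valid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$joint_valid), ncol(x$joint_valid), sum(x$joint_valid)))
  invisible(x)
}

#' @rdname grid_stack
#' @param x a `grid_stack`.
#' @export
n_layers <- function(x) length(x$layers)

## shared geometry helpers ---------------------------------------------------

grid_geometry <- function(layer) {
  list(origin_x = layer$origin_x, origin_y = layer$origin_y,
       cell_size = layer$cell_size,
       nrow = nrow(layer$values), ncol = ncol(layer$values))
}

stack_geometry <- function(stack) grid_geometry(stack$layers[[1L]])

#' Map lon/lat points to cell row/column indices
#'
#' Uses the half-open convention: `j = floor((lon - origin_x)/s) + 1`,
#' `i = floor((origin_y - lat)/s) + 1`. Points outside the grid get `NA`.
#'
#' @param geom geometry list from a layer (origin, cell size, dims).
#' @param lon,lat numeric vectors, degrees.
#' @return data.frame with columns `i`, `j` (NA when outside the extent).
#' @export
cell_index <- function(geom, lon, lat) {
  j <- floor((lon - geom$origin_x) / geom$cell_size) + 1
  i <- floor((geom$origin_y - lat) / geom$cell_size) + 1
  out <- i < 1 | i > geom$nrow | j < 1 | j > geom$ncol |
    !is.finite(lon) | !is.finite(lat)
  i[out] <- NA_integer_; j[out] <- NA_integer_
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Cell-center coordinates
#'
#' @param geom geometry list (see [cell_index()]).
#' @param i,j row/column indices.
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(geom, i, j) {
  data.frame(lon = geom$origin_x + (j - 0.5) * geom$cell_size,
             lat = geom$origin_y - (i - 0.5) * geom$cell_size)
}

## I/O -----------------------------------------------------------------------

#' Read or write a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange. The header carries `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and `NODATA_value`; values follow in
#' row-major order from the top row. Cells are square by construction of the
#' format; files declaring `dx`/`dy` (non-square variant) are rejected, as
#' are multi-layer concatenations. A write/read round trip preserves values,
#' mask and geotransform exactly (values are printed with full precision).
#'
#' @param path file path (conventionally `.asc`).
#' @param nodata nodata sentinel written to the file.
#' @return [read_asc()] returns a `grid_layer`; [write_asc()] returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ASCII grid: too short: ", path)
  hdr <- list(); n_hdr <- 0L
  for (k in seq_len(min(7L, length(lines)))) {
    tok <- strsplit(trimws(lines[[k]]), "\\s+")[[1]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- tok[2]; n_hdr <- k
    } else break
  }
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square cells (dx/dy header) are not supported: ", path)
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(req %in% names(hdr)))
    stop("ASCII grid header incomplete (need ",
         paste(setdiff(req, names(hdr)), collapse = ", "), "): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize)
  nodata <- as.numeric(hdr$nodata_value)
  body <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d values, found %d (multi-layer files are not supported): %s",
                 nr * nc, length(body), path))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_layer(m,
             origin_x = as.numeric(hdr$xllcorner),
             origin_y = as.numeric(hdr$yllcorner) + nr * cs,
             cell_size = cs,
             name = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_asc
#' @param layer a `grid_layer` to write.
#' @export
write_asc <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "grid_layer"))
  if (any(layer$values[layer$valid] == nodata, na.rm = TRUE))
    stop("a valid cell equals the nodata sentinel; choose another nodata value")
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", layer$origin_x),
    sprintf("yllcorner %.17g", layer$origin_y - nr * layer$cell_size),
    sprintf("cellsize %.17g", layer$cell_size),
    sprintf("NODATA_value %.17g", nodata))
  m <- layer$values
  m[!layer$valid] <- nodata
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## operations ----------------------------------------------------------------

#' Mean-aggregate a layer to a coarser resolution
#'
#' Each coarse cell is the mean of the valid fine cells in its
#' `factor x factor` block (the upscaling rule used to take 30 arc-second
#' grids to 5 arc-minutes). Blocks with no valid fine cell become invalid.
#' Trailing partial blocks are averaged over the cells present rather than
#' dropped, so the study area never shrinks.
#'
#' @param layer a `grid_layer`.
#' @param factor integer aggregation factor, `>= 1`.
#' @return a `grid_layer` with `cell_size * factor`.
#' @export
aggregate_mean <- function(layer, factor) {
  stopifnot(inherits(layer, "grid_layer"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(layer)
  v <- layer$values
  nr <- nrow(v); nc <- ncol(v)
  ri <- ceiling(seq_len(nr) / factor)
  ci <- ceiling(seq_len(nc) / factor)
  grp <- ri[row(v)] + (ci[col(v)] - 1L) * max(ri)  # block id, column-major in blocks
  ok <- is.finite(v)
  sums <- rowsum(as.vector(ifelse(ok, v, 0)), as.vector(grp), reorder = TRUE)
  cnts <- rowsum(as.vector(ok * 1), as.vector(grp), reorder = TRUE)
  out <- as.vector(sums) / as.vector(cnts)   # NaN where count 0
  out[!is.finite(out)] <- NA_real_
  m <- matrix(out, nrow = max(ri), ncol = max(ci))
  grid_layer(m, layer$origin_x, layer$origin_y, layer$cell_size * factor,
             name = layer$name, crs_label = layer$crs_label)
}

#' Crop a layer to a bounding box
#'
#' Keeps exactly the cells whose centers fall inside `bbox` (inclusive
#' bounds) and updates the geotransform accordingly.
#'
#' @param layer a `grid_layer`.
#' @param bbox numeric vector `c(xmin, xmax, ymin, ymax)` in degrees.
#' @return cropped `grid_layer`.
#' @export
crop_extent <- function(layer, bbox) {
  stopifnot(inherits(layer, "grid_layer"), length(bbox) == 4L)
  g <- grid_geometry(layer)
  xc <- g$origin_x + (seq_len(g$ncol) - 0.5) * g$cell_size
  yc <- g$origin_y - (seq_len(g$nrow) - 0.5) * g$cell_size
  jj <- which(xc >= bbox[1] & xc <= bbox[2])
  ii <- which(yc >= bbox[3] & yc <= bbox[4])
  if (length(ii) == 0L || length(jj) == 0L)
    stop("bbox does not intersect the layer extent")
  grid_layer(layer$values[ii, jj, drop = FALSE],
             origin_x = g$origin_x + (min(jj) - 1L) * g$cell_size,
             origin_y = g$origin_y - (min(ii) - 1L) * g$cell_size,
             cell_size = g$cell_size, name = layer$name,
             crs_label = layer$crs_label)
}

#' Extract stack values at points
#'
#' Returns the value of the containing cell for every layer. Points outside
#' the extent or over a jointly invalid cell are flagged, never silently
#' dropped.
#'
#' @param stack a `grid_stack`.
#' @param lon,lat point coordinates in degrees.
#' @return list with `values` (points x layers matrix), `valid` (logical),
#'   and `cell` (data.frame of row/col indices, NA outside the extent).
#' @export
extract_values <- function(stack, lon, lat) {
  stopifnot(inherits(stack, "grid_stack"))
  g <- stack_geometry(stack)
  idx <- cell_index(g, lon, lat)
  inside <- !is.na(idx$i)
  lin <- ifelse(inside, idx$i + (idx$j - 1L) * g$nrow, NA_integer_)
  vals <- vapply(stack$layers,
                 function(l) ifelse(inside, l$values[lin], NA_real_),
                 numeric(length(lon)))
  if (length(lon) == 1L) vals <- matrix(vals, nrow = 1L,
                                        dimnames = list(NULL, names(stack$layers)))
  ok <- inside & ifelse(inside, stack$joint_valid[lin], FALSE)
  list(values = vals, valid = as.logical(ok), cell = idx)
}
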