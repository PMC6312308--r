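#' Define a north-up geographic raster grid
#'
#' A grid of square cells in WGS84 decimal degrees with its origin at the
#' upper-left corner. Row 1 is the northernmost row. Cell `(r, c)` owns the
#' half-open box `[x_min + (c-1)*res, x_min + c*res)` in longitude and
#' `(y_max - r*res, y_max - (r-1)*res]` in latitude, so every in-bounds point
#' maps to exactly one cell.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min Western edge (degrees longitude).
#' @param y_max Northern edge (degrees latitude).
#' @param resolution Cell size in degrees (square cells).
#' @param nodata Sentinel value used when writing rasters to disk.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(n_rows, n_cols, x_min, y_max, resolution,
                        nodata = -9999) {
  if (n_rows < 1 || n_cols < 1) stop("grid must have at least one row and column")
  if (resolution <= 0) stop("resolution must be positive")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_min = x_min, y_max = y_max, resolution = resolution,
         nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d rows x %d cols @ %g deg, x [%g, %g], y [%g, %g]\n",
              x$n_rows, x$n_cols, x$resolution,
              x$x_min, x$x_min + x$n_cols * x$resolution,
              x$y_max - x$n_rows * x$resolution, x$y_max))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_max - b$y_max) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Map points to grid cells
#'
#' Assigns each point to the unique cell owning it under the half-open
#' convention (western and northern edges closed, eastern and southern open at
#' cell level; the grid's top edge is closed, its bottom edge open).
#'
#' @param grid A [raster_grid()].
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return A data.frame with integer columns `row`, `col` (1-based; `NA` for
#'   points outside the grid bounding box).
#' @export
cell_of <- function(grid, lon, lat) {
  cc <- floor((lon - grid$x_min) / grid$resolution)
  # a horizontal boundary is the (closed) top edge of the cell below it, so
  # plain floor implements the convention; lat == y_max lands in row 1
  rr <- floor((grid$y_max - lat) / grid$resolution)
  ok <- !is.na(cc) & !is.na(rr) &
    cc >= 0 & cc < grid$n_cols & rr >= 0 & rr < grid$n_rows
  data.frame(row = ifelse(ok, as.integer(rr) + 1L, NA_integer_),
             col = ifelse(ok, as.integer(cc) + 1L, NA_integer_))
}

# linear (column-major, R-native) index into a values matrix; NA when off-grid
cell_index <- function(grid, lon, lat) {
  rc <- cell_of(grid, lon, lat)
  (rc$col - 1L) * grid$n_rows + rc$row
}

#' Coordinates of cell centers
#'
#' @param grid A [raster_grid()].
#' @param row,col 1-based cell indices.
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(lon = grid$x_min + (col - 0.5) * grid$resolution,
             lat = grid$y_max - (row - 0.5) * grid$resolution)
}

# matrix (n_rows x n_cols) of cell-center latitudes / longitudes
center_lat_matrix <- function(grid) {
  matrix(rep(grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$resolution,
             grid$n_cols), grid$n_rows, grid$n_cols)
}
center_lon_matrix <- function(grid) {
  matrix(rep(grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution,
             each = grid$n_rows), grid$n_rows, grid$n_cols)
}

#' Create a single environmental layer
#'
#' @param values Numeric matrix of shape `(n_rows, n_cols)`; `NA` marks nodata.
#' @param grid The [raster_grid()] the values live on.
#' @param name Layer label.
#' @return An object of class `env_layer`.
#' @export
env_layer <- function(values, grid, name = "layer") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape must be (n_rows, n_cols)")
  structure(list(grid = grid, name = name, values = values),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("env_layer '%s': %d x %d, %d valid cells, range [%g, %g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Bundle aligned layers into an environmental stack
#'
#' All layers must share one grid and one nodata mask; layer names must be
#' unique. `scenario_tag` is `"present"` or a `(gcm, rcp, period)` label such
#' as `"gcm3_rcp85_2070"`.
#'
#' @param layers Named list of numeric matrices, or a list of [env_layer()]s.
#' @param grid A [raster_grid()] (ignored when `layers` are `env_layer`s).
#' @param scenario_tag Scenario label.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, grid = NULL, scenario_tag = "present") {
  if (length(layers) && inherits(layers[[1]], "env_layer")) {
    grid <- layers[[1]]$grid
    nm <- vapply(layers, function(l) l$name, character(1))
    layers <- lapply(layers, function(l) l$values)
    names(layers) <- nm
  }
  if (is.null(grid)) stop("grid required when layers are plain matrices")
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layer names must be present and unique")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", nm, "' shape mismatch")
  }
  mask0 <- is.na(layers[[1]])
  for (nm in names(layers)[-1])
    if (!identical(unname(is.na(layers[[nm]])), unname(mask0)))
      stop("nodata mask of layer '", nm, "' differs from first layer")
  structure(list(grid = grid, layers = layers, scenario_tag = scenario_tag),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack [%s]: %d layers on %d x %d grid (%s)\n",
              paste(unlist(x$scenario_tag), collapse = "_"),
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(utils::head(names(x$layers), 5), collapse = ", ")))
  invisible(x)
}

#' Layer names of a stack
#' @param stack An [env_stack()].
#' @return Character vector of layer names.
#' @export
stack_names <- function(stack) names(stack$layers)

# logical matrix: TRUE where all layers carry data
valid_mask <- function(stack) !is.na(stack$layers[[1]])

# cells-by-layers matrix of values at the given linear cell indices
stack_values_at <- function(stack, idx) {
  out <- vapply(stack$layers, function(m) m[idx], numeric(length(idx)))
  if (length(idx) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

#' Define a latitude-band (optionally longitude-bounded) calibration region
#'
#' The accessible-area hypothesis `M`: the region background points are drawn
#' from and models are calibrated in, expressed as a latitude band with
#' optional longitude bounds.
#'
#' @param lat_max,lat_min Northern and southern bounds (degrees).
#' @param lon_min,lon_max Optional western/eastern bounds (default unbounded).
#' @return An object of class `calibration_region`.
#' @export
calibration_region <- function(lat_max, lat_min, lon_min = -Inf, lon_max = Inf) {
  if (lat_min >= lat_max) stop("lat_min must be below lat_max")
  structure(list(lat_max = lat_max, lat_min = lat_min,
                 lon_min = lon_min, lon_max = lon_max),
            class = "calibration_region")
}

# logical matrix over grid cells whose centers fall inside the region
region_mask <- function(grid, region) {
  if (is.null(region)) return(matrix(TRUE, grid$n_rows, grid$n_cols))
  lat <- center_lat_matrix(grid); lon <- center_lon_matrix(grid)
  lat <= region$lat_max & lat >= region$lat_min &
    lon >= region$lon_min & lon <= region$lon_max
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
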