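#' Write a layer to an ESRI ASCII grid file
#'
#' Values are written at full double precision (`%.17g`) so a write/read
#' round-trip is value-exact; integer category codes round-trip as integers.
#' `NA` cells are written as the grid's nodata sentinel.
#'
#' @param layer An [env_layer()].
#' @param path Output path (conventionally `.asc`); parent directory must
#'   exist. An existing file is overwritten.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(layer, path) {
  g <- layer$grid
  v <- layer$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$x_min),
    sprintf("yllcorner %.17g", g$y_max - g$n_rows * g$resolution),
    sprintf("cellsize %.17g", g$resolution),
    sprintf("NODATA_value %.17g", g$nodata)
  )
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path Path to an `.asc` file with a square-cell, north-up header.
#' @return An [env_layer()]; the grid is parsed from the header and the nodata
#'   sentinel converted to `NA`. Files declaring rectangular (non-square)
#'   cells via `dx`/`dy` headers are rejected.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value", "dx", "dy")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("format error: file declares rectangular cells (dx/dy); ",
         "only square cells are supported")
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("format error: missing header field '", k, "'")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("format error: expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  grid <- raster_grid(nr, nc,
                      x_min = hdr$xllcorner,
                      y_max = hdr$yllcorner + nr * hdr$cellsize,
                      resolution = hdr$cellsize,
                      nodata = nodata)
  env_layer(m, grid, name = sub("\\.[^.]*$", "", basename(path)))
}

# ---- occurrence records -----------------------------------------------------

new_occurrence_set <- function(df, stage, counts_log = NULL) {
  rownames(df) <- NULL
  if (is.null(counts_log)) counts_log <- c()
  counts_log[stage] <- nrow(df)
  structure(df, class = c("occurrence_set", "data.frame"),
            stage = stage, counts_log = counts_log)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set [%s]: %d records, %d species\n",
              attr(x, "stage"), nrow(x), length(unique(x$species))))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Record-count log of the cleaning cascade
#' @param occ An occurrence set.
#' @return Named integer vector of record counts per stage passed so far.
#' @export
counts_log <- function(occ) attr(occ, "counts_log")

#' Stage tag of an occurrence set
#' @param occ An occurrence set.
#' @return The stage label (`"raw"`, `"precise"`, `"unique"`, `"thinned"`, ...).
#' @export
occ_stage <- function(occ) attr(occ, "stage")

count_decimals <- function(s) {
  s <- sub("^[^.]*\\.?", "", trimws(s))
  s <- sub("[eE].*$", "", s)
  nchar(s)
}

#' Read occurrence records from CSV
#'
#' Requires columns `species`, `longitude`, `latitude`; an optional `precision`
#' column gives the decimal places of the source coordinates. Without it,
#' precision is inferred from the coordinate text: a record whose coordinates
#' both have at most one decimal place is flagged low-precision (positional
#' uncertainty larger than a 2.5-arcmin pixel). Longitudes are wrapped into
#' `[-180, 180)`. Rows with unparseable or out-of-range coordinates are
#' dropped, counted, and reported via a warning and the `parse_log` attribute.
#'
#' @param path CSV path.
#' @return An occurrence set at stage `"raw"` with columns `species`,
#'   `longitude`, `latitude`, `precision_flag`, `source_id`.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  for (col in c("species", "longitude", "latitude"))
    if (!col %in% names(raw))
      stop("schema error: missing mandatory column '", col, "'")
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  bad_parse <- is.na(lon) | is.na(lat)
  bad_range <- !bad_parse & abs(lat) > 90
  keep <- !bad_parse & !bad_range
  lon <- ((lon + 180) %% 360) - 180
  if ("precision" %in% names(raw)) {
    dec <- suppressWarnings(as.numeric(raw$precision))
    low <- !is.na(dec) & dec <= 1
  } else {
    low <- count_decimals(raw$longitude) <= 1 & count_decimals(raw$latitude) <= 1
  }
  df <- data.frame(
    species = raw$species[keep],
    longitude = lon[keep],
    latitude = lat[keep],
    precision_flag = ifelse(low[keep], "low", "exact"),
    source_id = sprintf("row%05d", which(keep)),
    stringsAsFactors = FALSE
  )
  n_bad <- sum(bad_parse) + sum(bad_range)
  if (n_bad > 0)
    warning(sum(bad_parse), " unparseable and ", sum(bad_range),
            " out-of-range coordinate rows dropped from ", basename(path))
  occ <- new_occurrence_set(df, "raw")
  attr(occ, "parse_log") <- c(n_rows = nrow(raw),
                              n_unparseable = sum(bad_parse),
                              n_out_of_range = sum(bad_range))
  occ
}

#' Write an occurrence set to CSV
#'
#' @param occ An occurrence set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occurrences <- function(occ, path) {
  df <- as.data.frame(occ)
  df$longitude <- sprintf("%.17g", df$longitude)
  df$latitude <- sprintf("%.17g", df$latitude)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
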