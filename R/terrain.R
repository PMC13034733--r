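#' Digital elevation model grid
#'
#' A minimal north-up DEM container over projected planar coordinates in
#' metres: an elevation matrix (row 1 = northernmost row), the lower-left
#' corner of the grid, and a square cell size. Cell centres sit at
#' `origin + (index - 0.5) * cell_size`. Geographic (lat/lon) input is not
#' supported; reproject to a metric CRS first.
#'
#' @param elevations Numeric matrix of elevations (metres), row-major
#'   north-up.
#' @param origin_x,origin_y Lower-left corner coordinates (metres).
#' @param cell_size Cell edge length in metres (> 0).
#' @param nodata Value marking missing cells (converted to `NA`).
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(elevations, origin_x = 0, origin_y = 0,
                     cell_size = 30, nodata = NULL) {
  stopifnot(is.matrix(elevations), cell_size > 0)
  if (cell_size < 1e-2) {  # degree-sized cells: almost surely lat/lon
    abort("coordinates look geographic (degrees); reproject to metres",
          class = "behavsyn_validation_error")
  }
  if (!is.null(nodata)) elevations[elevations == nodata] <- NA_real_
  structure(list(elevations = elevations, origin_x = origin_x,
                 origin_y = origin_y, cell_size = cell_size,
                 n_rows = nrow(elevations), n_cols = ncol(elevations)),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat("DEM grid:", x$n_rows, "x", x$n_cols, "cells of", x$cell_size,
      "m; origin (", x$origin_x, ",", x$origin_y, ")\n")
  invisible(x)
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text DEM exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by rows of elevations, north first.
#'
#' @param path File path.
#' @return `read_ascii_grid()`: a [dem_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  repeat {
    i <- i + 1
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (suppressWarnings(is.na(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else break
  }
  for (need in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[need]])) {
      abort(paste0("ASCII grid header lacks ", need),
            class = "behavsyn_format_error")
    }
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort("ASCII grid body does not match ncols * nrows",
          class = "behavsyn_format_error")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  dem_grid(m, xll, yll, hdr$cellsize, nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param dem A [dem_grid()].
#' @param nodata Value written for `NA` cells.
#' @export
write_ascii_grid <- function(dem, path, nodata = -9999) {
  m <- dem$elevations
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", dem$n_cols), paste("nrows", dem$n_rows),
    paste("xllcorner", format(dem$origin_x, scientific = FALSE)),
    paste("yllcorner", format(dem$origin_y, scientific = FALSE)),
    paste("cellsize", format(dem$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bilinearly interpolated elevation at arbitrary points
#'
#' Interpolates between the four surrounding cell centres; points beyond
#' the outermost centres clamp to the edge row/column (constant
#' extrapolation over the outer half-cell). Points outside the grid extent
#' are an error.
#'
#' @param dem A [dem_grid()].
#' @param x,y Coordinate vectors (metres).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Elevation vector (metres); `NA` where a contributing cell is
#'   nodata.
#' @export
dem_elevation <- function(dem, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  cs <- dem$cell_size
  xmax <- dem$origin_x + dem$n_cols * cs
  ymax <- dem$origin_y + dem$n_rows * cs
  out_of_extent <- x < dem$origin_x | x > xmax | y < dem$origin_y | y > ymax
  if (any(out_of_extent)) {
    abort(paste0("point(s) outside DEM extent at index ",
                 paste(which(out_of_extent), collapse = ", ")),
          class = "behavsyn_validation_error")
  }
  # fractional column/row in cell-centre coordinates
  fc <- (x - dem$origin_x) / cs + 0.5
  fr <- (ymax - y) / cs + 0.5          # row 1 is northernmost
  if (method == "nearest") {
    r <- pmin(pmax(round(fr), 1), dem$n_rows)
    c <- pmin(pmax(round(fc), 1), dem$n_cols)
    return(dem$elevations[cbind(r, c)])
  }
  c0 <- pmin(pmax(floor(fc), 1), dem$n_cols)
  r0 <- pmin(pmax(floor(fr), 1), dem$n_rows)
  c1 <- pmin(c0 + 1, dem$n_cols)
  r1 <- pmin(r0 + 1, dem$n_rows)
  wx <- pmin(pmax(fc - c0, 0), 1)
  wy <- pmin(pmax(fr - r0, 0), 1)
  e <- dem$elevations
  (1 - wy) * ((1 - wx) * e[cbind(r0, c0)] + wx * e[cbind(r0, c1)]) +
    wy * ((1 - wx) * e[cbind(r1, c0)] + wx * e[cbind(r1, c1)])
}

#' Terrain-profile distance between two points
#'
#' Ground distance along the terrain profile over the straight planimetric
#' segment from `a` to `b`: elevations are sampled by bilinear
#' interpolation at uniform chainages (the segment is split into
#' `ceiling(L / step)` equal pieces, so the actual step never exceeds
#' `step` and the sampling is symmetric in `a` and `b`), and the profile
#' length is the sum of `sqrt(dd^2 + dz^2)` over consecutive samples.
#' Always at least the planimetric distance, with equality on flat
#' profiles.
#'
#' @param dem A [dem_grid()].
#' @param a,b Numeric `c(x, y)` points inside the DEM extent.
#' @param step Nominal chainage step in metres (default 30, the native
#'   resolution of typical global DEMs).
#' @param method Elevation interpolation, see [dem_elevation()].
#' @return Distance in metres.
#' @examples
#' flat <- dem_grid(matrix(100, 10, 10), cell_size = 30)
#' profile_distance(flat, c(10, 10), c(100, 100)) # == planimetric
#' @export
profile_distance <- function(dem, a, b, step = 30,
                             method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  L <- sqrt(sum((b - a)^2))
  if (L == 0) return(0)
  n <- max(1, ceiling(L / step))
  tt <- seq(0, 1, length.out = n + 1)
  xs <- a[1] + tt * (b[1] - a[1])
  ys <- a[2] + tt * (b[2] - a[2])
  zs <- dem_elevation(dem, xs, ys, method = method)
  if (anyNA(zs)) {
    abort(paste0("nodata under profile at chainage ",
                 format(tt[which(is.na(zs))[1]] * L, digits = 6), " m"),
          class = "behavsyn_validation_error")
  }
  dd <- L / n
  sum(sqrt(dd^2 + diff(zs)^2))
}

#' Disturbance point matrix from a mask or point list
#'
#' Converts a disturbance raster mask (roads, agricultural land) into one
#' point per masked cell centre at the stated spacing, or passes through an
#' existing point table.
#'
#' @param mask Either a logical matrix (north-up, same convention as
#'   [dem_grid()]) or a data frame with `x`, `y` columns.
#' @param origin_x,origin_y,spacing Grid geometry when `mask` is a matrix
#'   (spacing default 30 m).
#' @return Tibble of disturbance points `x`, `y`.
#' @export
disturbance_points <- function(mask, origin_x = 0, origin_y = 0,
                               spacing = 30) {
  if (is.data.frame(mask)) {
    if (nrow(mask) == 0) abort("empty disturbance point list",
                               class = "behavsyn_empty_data_error")
    return(tibble::tibble(x = mask$x, y = mask$y))
  }
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("empty disturbance mask",
                            class = "behavsyn_empty_data_error")
  tibble::tibble(
    x = origin_x + (idx[, "col"] - 0.5) * spacing,
    y = origin_y + (nrow(mask) - idx[, "row"] + 0.5) * spacing
  )
}

#' Shortest surface distance to disturbance
#'
#' For each sample point, the minimum [profile_distance()] to any
#' disturbance point. Because a profile distance can never be shorter than
#' its planimetric distance, candidates whose planimetric distance already
#' exceeds the best surface distance found so far are pruned without
#' evaluation (candidates are visited in increasing planimetric order, so
#' the first exceedance stops the search). Ties between candidates are
#' broken by lexicographic `(x, y)`.
#'
#' @param dem A [dem_grid()].
#' @param samples Data frame with `sample_id`, `x`, `y`.
#' @param disturbance Data frame of disturbance points `x`, `y` (see
#'   [disturbance_points()]).
#' @param step,method Passed to [profile_distance()].
#' @param prune Disable to force evaluation of every candidate (used for
#'   verification; the result is identical).
#' @return Tibble: `sample_id`, `nearest_x`, `nearest_y`, `ssd_m`,
#'   `ssd_km`, `n_candidates_pruned`.
#' @export
ssd <- function(dem, samples, disturbance, step = 30,
                method = c("bilinear", "nearest"), prune = TRUE) {
  method <- match.arg(method)
  if (nrow(disturbance) == 0) abort("empty disturbance set",
                                    class = "behavsyn_empty_data_error")
  purrr::pmap(samples[c("sample_id", "x", "y")],
              function(sample_id, x, y) {
    a <- c(x, y)
    plan <- sqrt((disturbance$x - x)^2 + (disturbance$y - y)^2)
    ord <- order(plan, disturbance$x, disturbance$y)
    best <- Inf
    best_pt <- c(NA_real_, NA_real_)
    pruned <- 0L
    for (k in seq_along(ord)) {
      i <- ord[k]
      if (prune && plan[i] > best) {
        pruned <- pruned + (length(ord) - k + 1L)
        break
      }
      d <- profile_distance(dem, a, c(disturbance$x[i], disturbance$y[i]),
                            step = step, method = method)
      better <- d < best - 1e-9 ||
        (abs(d - best) <= 1e-9 &&
           (disturbance$x[i] < best_pt[1] ||
              (disturbance$x[i] == best_pt[1] &&
                 disturbance$y[i] < best_pt[2])))
      if (better) {
        best <- d
        best_pt <- c(disturbance$x[i], disturbance$y[i])
      }
    }
    tibble::tibble(sample_id = sample_id, nearest_x = best_pt[1],
                   nearest_y = best_pt[2], ssd_m = best,
                   ssd_km = best / 1000, n_candidates_pruned = pruned)
  }) |> purrr::list_rbind()
}
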