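#' Prediction grid specification
#'
#' Defines a regular grid of square cells in the working CRS. The origin
#' (lower-left corner) is snapped to multiples of `cell_size` so the same
#' point set always yields the same grid. The grid covers the bounding
#' envelope of the points plus `padding` on every side.
#'
#' @param points Data frame with `x`/`y` columns (metres), or `NULL` when
#'   `xlim`/`ylim` are given.
#' @param cell_size Cell edge, metres (default 10 km).
#' @param padding Extra margin around the point envelope, metres.
#' @param xlim,ylim Explicit envelope, overriding `points`.
#' @param crs CRS label stored with the grid.
#' @return An object of class `grid_spec`: `crs`, `cell_size`, `origin_x`,
#'   `origin_y` (lower-left corner), `n_cols`, `n_rows`.
#' @export
grid_spec <- function(points = NULL, cell_size = 10000, padding = 0,
                      xlim = NULL, ylim = NULL, crs = "ESRI:102008") {
  stopifnot(cell_size > 0, padding >= 0)
  if (is.null(xlim) || is.null(ylim)) {
    stopifnot(!is.null(points), nrow(points) >= 1L)
    xlim <- range(points$x)
    ylim <- range(points$y)
  }
  ox <- floor((xlim[1] - padding) / cell_size) * cell_size
  oy <- floor((ylim[1] - padding) / cell_size) * cell_size
  n_cols <- max(1L, ceiling((xlim[2] + padding - ox) / cell_size))
  n_rows <- max(1L, ceiling((ylim[2] + padding - oy) / cell_size))
  structure(list(crs = crs, cell_size = cell_size,
                 origin_x = ox, origin_y = oy,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g), %s\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' Centres are ordered row-major from the top (north) row down, matching
#' the raster layout used throughout the package (row 1 = maximum y).
#'
#' @param grid A [grid_spec()].
#' @return Data frame with `x`, `y`, `row`, `col`.
#' @export
build_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cs <- grid$cell_size
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * cs
  ys_top_down <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs
  data.frame(
    x = rep(xs, times = grid$n_rows),
    y = rep(ys_top_down, each = grid$n_cols),
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows)
  )
}

#' Read polygons from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries (plain geometries,
#' `Feature`s, or a `FeatureCollection`). Rings are returned as a list of
#' two-column matrices; with even-odd membership semantics, hole rings are
#' handled naturally by [mask_raster()].
#'
#' @param path Path to a GeoJSON file.
#' @param crs CRS label to attach; GeoJSON is conventionally geographic
#'   (`"EPSG:4326"`).
#' @return An object of class `poly_set`: list with `rings` and `crs`.
#' @export
read_polygons_geojson <- function(path, crs = "EPSG:4326") {
  g <- jsonlite::read_json(path)
  rings <- list()
  add_poly <- function(coords) {
    for (ring in coords) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      rings[[length(rings) + 1L]] <<- m
    }
  }
  walk <- function(obj) {
    type <- obj$type %||% ""
    switch(type,
      FeatureCollection = lapply(obj$features, walk),
      Feature = walk(obj$geometry),
      Polygon = add_poly(obj$coordinates),
      MultiPolygon = lapply(obj$coordinates, add_poly),
      stop("unsupported GeoJSON type: ", type, call. = FALSE)
    )
    invisible(NULL)
  }
  walk(g)
  poly_set(rings, crs = crs)
}

#' Construct a polygon set
#'
#' @param rings List of two-column coordinate matrices (closed or open
#'   rings; closure is not required).
#' @param crs CRS label the coordinates are expressed in.
#' @return An object of class `poly_set`.
#' @export
poly_set <- function(rings, crs = "ESRI:102008") {
  stopifnot(is.list(rings), all(vapply(rings, is.matrix, logical(1))))
  structure(list(rings = rings, crs = crs), class = "poly_set")
}

#' Project a geographic polygon set into the working CRS
#'
#' @param polys A `poly_set` in geographic coordinates (`EPSG:4326`).
#' @return A `poly_set` in `ESRI:102008`.
#' @export
project_polygons <- function(polys) {
  stopifnot(inherits(polys, "poly_set"))
  rings <- lapply(polys$rings, function(m) {
    xy <- albers_forward(m[, 1], m[, 2])
    cbind(xy$x, xy$y)
  })
  poly_set(rings, crs = "ESRI:102008")
}

# even-odd point-in-polygon over all rings, via mgcv::in.out
points_in_polys <- function(px, py, polys) {
  bnd <- do.call(rbind, lapply(polys$rings, function(m)
    rbind(m, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(px, py))
}

#' Mask a raster field with territory outlines
#'
#' Cells whose centre falls outside every polygon are set to missing;
#' retained cells are unchanged (bit-identical). Both prediction and
#' variance layers are masked.
#'
#' @param field An `interp_field` (see [interpolate_grid()]).
#' @param polys A [poly_set()] in the field's CRS.
#' @return The masked `interp_field`.
#' @export
mask_raster <- function(field, polys) {
  stopifnot(inherits(field, "interp_field"), inherits(polys, "poly_set"))
  if (!identical(polys$crs, field$grid$crs)) {
    stop(sprintf("CRS mismatch: polygons are %s, raster is %s",
                 polys$crs, field$grid$crs), call. = FALSE)
  }
  centres <- build_grid(field$grid)
  keep <- if (length(polys$rings) == 0L) {
    rep(FALSE, nrow(centres))
  } else {
    points_in_polys(centres$x, centres$y, polys)
  }
  keep_m <- matrix(keep, nrow = field$grid$n_rows,
                   ncol = field$grid$n_cols, byrow = TRUE)
  field$values[!keep_m] <- NA_real_
  if (!is.null(field$variance)) field$variance[!keep_m] <- NA_real_
  field$masked <- TRUE
  field
}
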