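# Seeded country-scale habitat grid: a smoothed synthetic elevation field
# over a rectangle, an elevation-band habitat mask per species, and per-cell
# climate generated with paired seeds so reference and scenario periods are
# comparable cell by cell.

#' Generate a synthetic habitat grid
#'
#' The elevation field is a coarse Gaussian random field bilinearly
#' interpolated to the target resolution and rescaled to the requested
#' range; habitat is an elevation band per species. Per-cell climate seeds
#' are drawn once so that reference and scenario series for the same cell
#' are paired.
#'
#' @param n_cells Approximate number of grid cells (>= 10).
#' @param elevation_range Range of the elevation field, m a.s.l.
#' @param habitat_range Elevation band the species occupies, m a.s.l.
#' @param aspect Ratio of grid columns to rows (default 1.6).
#' @param coarse Number of coarse-field knots per axis (default 6).
#' @param latitude Grid latitude, degrees.
#' @param asw_max,fertility_rating Site constants applied to every cell.
#' @param seed Integer seed.
#' @return Data frame: `cell_id`, `x`, `y`, `elevation`, `habitat`
#'   (logical), `climate_seed`, plus attributes `latitude`, `asw_max`,
#'   `fertility_rating`.
#' @export
generate_country_grid <- function(n_cells, elevation_range = c(200, 2600),
                                  habitat_range = c(400, 2000),
                                  aspect = 1.6, coarse = 6, latitude = 46.8,
                                  asw_max = 150, fertility_rating = 0.5,
                                  seed = NULL) {
  if (n_cells < 10) stop("n_cells must be >= 10")
  ny <- max(2, round(sqrt(n_cells / aspect)))
  nx <- max(2, ceiling(n_cells / ny))
  with_seed(seed, {
    field <- matrix(rnorm(coarse * coarse), coarse, coarse)
    # bilinear interpolation of the coarse field to the full grid
    gx <- seq(1, coarse, length.out = nx)
    gy <- seq(1, coarse, length.out = ny)
    interp <- outer(gy, gx, Vectorize(function(yy, xx) {
      x0 <- floor(xx); x1 <- min(x0 + 1, coarse)
      y0 <- floor(yy); y1 <- min(y0 + 1, coarse)
      fx <- xx - x0; fy <- yy - y0
      field[y0, x0] * (1 - fx) * (1 - fy) + field[y0, x1] * fx * (1 - fy) +
        field[y1, x0] * (1 - fx) * fy + field[y1, x1] * fx * fy
    }))
    z <- as.vector(interp)
    z <- (z - min(z)) / (max(z) - min(z))
    elevation <- elevation_range[1] + z * diff(elevation_range)
    grid <- data.frame(
      cell_id = seq_len(nx * ny),
      x = rep(seq_len(nx), each = ny),
      y = rep(seq_len(ny), nx),
      elevation = elevation,
      habitat = elevation >= habitat_range[1] &
        elevation <= habitat_range[2],
      climate_seed = sample.int(2^31 - 2, nx * ny)
    )
    attr(grid, "latitude") <- latitude
    attr(grid, "asw_max") <- asw_max
    attr(grid, "fertility_rating") <- fertility_rating
    grid
  })
}

#' Site description for one grid cell
#'
#' @param grid Output of [generate_country_grid()].
#' @param cell_id Cell identifier.
#' @return Site list usable by [run_simulation()].
#' @export
grid_cell_site <- function(grid, cell_id) {
  row <- grid[grid$cell_id == cell_id, ]
  asw_max <- attr(grid, "asw_max")
  list(
    latitude = attr(grid, "latitude"),
    elevation = row$elevation,
    asw_max = asw_max,
    asw_init = 0.75 * asw_max,
    fertility_rating = attr(grid, "fertility_rating")
  )
}
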