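#' Build a cubic lattice for spheroid simulation
#'
#' Sites are cubes of edge `dx` with `dx^3 = 2 * mean_cell_volume`, so
#' an occupied site is half cell and half extracellular space (cell
#' volume fraction 0.5). The grid is sized to contain a sphere of
#' `max_radius` around its center plus one vacant boundary shell, which
#' is where the lattice couples to the bulk medium.
#'
#' @param mean_cell_volume mean cell volume (um^3); must be > 0.
#' @param max_radius largest spheroid radius the grid must hold (um);
#'   `0` gives the degenerate single-site grid plus its vacant shell.
#' @return object of class `hap_grid`: list with `dx`, `dims`,
#'   `n_sites`, `site_volume`, `center` (um coordinates of the grid
#'   center), `occupancy` (integer site -> cell row, 0 = vacant),
#'   `nbr` (n_sites x 6 face-neighbor index matrix, NA at boundaries),
#'   `r` (site center distance to grid center, um), `boundary`
#'   (logical, outermost shell).
#' @examples
#' g <- build_lattice(2500, 100)
#' g$dx                       # 17.1 um
#' g$site_volume / 2500       # exactly 2
#' @export
build_lattice <- function(mean_cell_volume = 2500, max_radius) {
  if (!is.numeric(mean_cell_volume) || mean_cell_volume <= 0) {
    stop("mean_cell_volume must be > 0", call. = FALSE)
  }
  stopifnot(max_radius >= 0)
  dx <- (2 * mean_cell_volume)^(1 / 3)
  n_half <- ceiling(max_radius / dx)
  n1 <- 2L * (n_half + 1L) + 1L   # sphere + one vacant boundary shell
  dims <- c(n1, n1, n1)
  n <- n1^3
  # 0-based integer indices; site centers at (i + 1/2) dx
  i <- rep.int(seq_len(n1) - 1L, n1 * n1)
  j <- rep.int(rep(seq_len(n1) - 1L, each = n1), n1)
  k <- rep(seq_len(n1) - 1L, each = n1 * n1)
  c0 <- (n1 - 1) / 2              # array index of the grid center
  r <- dx * sqrt((i - c0)^2 + (j - c0)^2 + (k - c0)^2)
  boundary <- i == 0L | i == n1 - 1L | j == 0L | j == n1 - 1L |
    k == 0L | k == n1 - 1L
  grid <- structure(
    list(dx = dx, dims = dims, n_sites = n, site_volume = dx^3,
         mean_cell_volume = mean_cell_volume,
         center = rep((c0 + 0.5) * dx, 3), c0 = c0,
         ijk = cbind(i = i, j = j, k = k), r = r, boundary = boundary,
         occupancy = integer(n), nbr = NULL),
    class = "hap_grid")
  grid$nbr <- .face_neighbors(grid)
  grid
}

# n x 6 matrix of face-adjacent linear indices (NA outside the grid),
# column order -x +x -y +y -z +z
.face_neighbors <- function(grid) {
  n1 <- grid$dims[1]; n <- grid$n_sites
  i <- grid$ijk[, 1]; j <- grid$ijk[, 2]; k <- grid$ijk[, 3]
  lin <- function(i, j, k, ok) {
    out <- i + n1 * j + n1 * n1 * k + 1L
    out[!ok] <- NA_integer_
    out
  }
  cbind(lin(i - 1L, j, k, i > 0L),      lin(i + 1L, j, k, i < n1 - 1L),
        lin(i, j - 1L, k, j > 0L),      lin(i, j + 1L, k, j < n1 - 1L),
        lin(i, j, k - 1L, k > 0L),      lin(i, j, k + 1L, k < n1 - 1L))
}

#' Face-adjacent neighbors of a lattice site
#'
#' @param grid a `hap_grid`.
#' @param site linear site index.
#' @return integer vector of the (up to 6) face-adjacent sites, clipped
#'   at grid boundaries.
#' @export
neighbors <- function(grid, site) {
  if (!is.numeric(site) || length(site) != 1L || is.na(site) ||
      site < 1 || site > grid$n_sites) {
    stop("site out of grid", call. = FALSE)
  }
  nb <- grid$nbr[site, ]
  nb[!is.na(nb)]
}

# all 26 neighbors (face+edge+corner) of one site, clipped
.moore_neighbors <- function(grid, site) {
  n1 <- grid$dims[1]
  ijk <- grid$ijk[site, ]
  di <- rep(-1:1, 9); dj <- rep(rep(-1:1, each = 3), 3)
  dk <- rep(-1:1, each = 9)
  keep <- !(di == 0 & dj == 0 & dk == 0)
  i <- ijk[1] + di[keep]; j <- ijk[2] + dj[keep]; k <- ijk[3] + dk[keep]
  ok <- i >= 0L & i < n1 & j >= 0L & j < n1 & k >= 0L & k < n1
  (i + n1 * j + n1 * n1 * k + 1L)[ok]
}

# linear index from 0-based ijk (no bounds check)
.lin_idx <- function(grid, i, j, k) {
  n1 <- grid$dims[1]
  i + n1 * j + n1 * n1 * k + 1L
}

#' Trim a spheroid's lattice to a tight bounding grid
#'
#' Rebuilds the lattice just large enough to hold the occupied sites
#' plus `margin` vacant shells (and the mandatory boundary shell),
#' remapping cells; the grid may shrink or grow to fit. Growth grids
#' are sized for worst-case expansion; refitting before a drug exposure
#' keeps the transport solves on the smallest adequate grid (a larger
#' margin is adequate when the medium O2 boundary layer matters).
#'
#' @param sph spheroid state (`grid`, `cells`, ...).
#' @param margin vacant shells to keep around the occupied hull.
#' @return the spheroid state on the trimmed grid.
#' @export
trim_lattice <- function(sph, margin = 3) {
  grid <- sph$grid
  occ <- which(grid$occupancy > 0L)
  if (!length(occ)) return(sph)
  r_hull <- max(grid$r[occ])
  new_grid <- build_lattice(grid$mean_cell_volume, r_hull + margin * grid$dx)
  if (new_grid$dims[1] == grid$dims[1]) return(sph)
  # map ijk offsets between the two centered grids
  shift <- as.integer(round(grid$c0 - new_grid$c0))
  cells <- sph$cells
  old_ijk <- grid$ijk[cells$site, , drop = FALSE]
  new_ijk <- old_ijk - shift
  n1 <- new_grid$dims[1]
  stopifnot(all(new_ijk >= 1L), all(new_ijk <= n1 - 2L))
  cells$site <- .lin_idx(new_grid, new_ijk[, 1], new_ijk[, 2], new_ijk[, 3])
  new_grid$occupancy[cells$site] <- seq_along(cells$site)
  sph$grid <- new_grid
  sph$cells <- cells
  sph
}

#' Equivalent-sphere diameter of the occupied lattice region
#'
#' `(6 V / pi)^(1/3)` where `V` is the total volume of occupied sites.
#'
#' @param grid a `hap_grid`.
#' @return diameter (um).
#' @export
lattice_diameter <- function(grid) {
  v <- sum(grid$occupancy > 0L) * grid$site_volume
  (6 * v / pi)^(1 / 3)
}
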