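#' Two-sphere cell model
#'
#' The cell is modelled as two homogeneous concentric spheres of unit-density
#' water: a 10 um-radius cell containing a 5 um-radius nucleus, centred in a
#' water cube of side 30 um that acts as the world volume (particles reaching
#' its boundary are terminated).  Radionuclide sources are placed in one of
#' four sub-volumes: a 0.01 um layer on the outer cell wall, the cytoplasm
#' volume, a 0.01 um layer on the nucleus wall, or the nucleus volume.
#'
#' @param r_cell Cell radius, um.
#' @param r_nucleus Nucleus radius, um.
#' @param shell_thickness Thickness of the membrane/wall source layers, um.
#' @param box_half_side Half side length of the bounding water cube, um.
#' @param density Medium density, g/cm^3.
#' @return Object of class \code{cell_model}; includes the nucleus mass in kg.
#' @export
#' @examples
#' cell <- cell_model()
#' cell$nucleus_mass_kg  # 5.236e-13 kg for the default 5 um nucleus
cell_model <- function(r_cell = 10, r_nucleus = 5, shell_thickness = 0.01,
                       box_half_side = 15, density = 1.0) {
  stopifnot(r_nucleus > 0, r_cell > r_nucleus, box_half_side > r_cell,
            shell_thickness > 0, density > 0)
  mass_kg <- 4 / 3 * pi * (r_nucleus * 1e-6)^3 * density * 1000  # m^3 * kg/m^3
  structure(list(r_cell = r_cell, r_nucleus = r_nucleus,
                 shell_thickness = shell_thickness,
                 box_half_side = box_half_side, density = density,
                 nucleus_mass_kg = mass_kg),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "Two-sphere cell model: cell r = %g um, nucleus r = %g um,\n  %g um source layers, %g um water box, density %g g/cm^3\n",
    x$r_cell, x$r_nucleus, x$shell_thickness, 2 * x$box_half_side, x$density))
  invisible(x)
}

SOURCE_LOCATIONS <- c("cell_membrane", "cytoplasm", "nucleus_wall",
                      "nucleus_volume")

#' Sample source positions uniformly in a subcellular compartment
#'
#' Positions are uniform in the named sub-volume.  Volume compartments
#' (cytoplasm, nucleus) sample the radius by the inverse CDF of the shell
#' volume (r^3 uniform); the membrane and nucleus-wall layers are thin radial
#' shells of thickness \code{cell$shell_thickness} placed immediately
#' \emph{outside} the respective sphere surface (a carrier docking at the
#' nuclear envelope has not internalised, so nucleus-wall sources sit in the
#' cytoplasm side of the boundary; set \code{wall_inside = TRUE} for the
#' alternative convention).
#'
#' @param n Number of positions.
#' @param location One of \code{"cell_membrane"}, \code{"cytoplasm"},
#'   \code{"nucleus_wall"}, \code{"nucleus_volume"}.
#' @param cell A \code{\link{cell_model}}.
#' @param wall_inside Place the nucleus-wall layer just inside (rather than
#'   outside) the nucleus surface.
#' @return \code{n x 3} matrix of Cartesian positions in um, cell centred at
#'   the origin.
#' @export
sample_source_position <- function(n, location, cell = cell_model(),
                                   wall_inside = FALSE) {
  location <- match.arg(location, SOURCE_LOCATIONS)
  t <- cell$shell_thickness
  lim <- switch(location,
    cell_membrane  = c(cell$r_cell, cell$r_cell + t),
    cytoplasm      = c(cell$r_nucleus, cell$r_cell),
    nucleus_wall   = if (wall_inside) c(cell$r_nucleus - t, cell$r_nucleus)
                     else c(cell$r_nucleus, cell$r_nucleus + t),
    nucleus_volume = c(0, cell$r_nucleus))
  u <- stats::runif(n)
  r <- (lim[1]^3 + u * (lim[2]^3 - lim[1]^3))^(1 / 3)
  r * random_directions(n)
}

#' Isotropic unit vectors
#'
#' Marsaglia's method for points uniform on the unit sphere.
#'
#' @param n Number of directions.
#' @return \code{n x 3} matrix of unit vectors.
#' @export
random_directions <- function(n) {
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  while (length(need)) {
    u <- stats::runif(length(need), -1, 1)
    v <- stats::runif(length(need), -1, 1)
    s <- u * u + v * v
    ok <- s < 1
    if (any(ok)) {
      root <- sqrt(1 - s[ok])
      out[need[ok], ] <- cbind(2 * u[ok] * root, 2 * v[ok] * root,
                               1 - 2 * s[ok])
      need <- need[!ok]
    }
  }
  out
}

# Positive-t intersections of ray origin + t*dir with a centred sphere.
.sphere_roots <- function(origin, direction, radius) {
  b <- sum(origin * direction)
  c0 <- sum(origin * origin) - radius^2
  disc <- b * b - c0
  if (disc <= 0) return(numeric())
  s <- sqrt(disc)
  sort(c(-b - s, -b + s))
}

# Distance at which the ray leaves the bounding cube (origin assumed inside).
.box_exit <- function(origin, direction, half) {
  tt <- rep(Inf, 3)
  for (k in 1:3) {
    d <- direction[k]
    if (d > 1e-12) tt[k] <- (half - origin[k]) / d
    else if (d < -1e-12) tt[k] <- (-half - origin[k]) / d
  }
  min(tt)
}

#' Decompose a ray into per-region path segments
#'
#' Intersects the ray from \code{origin} along \code{direction} with the
#' nucleus and cell spheres and the bounding cube, returning the ordered,
#' contiguous forward segments with their region labels.  This is the
#' geometric backbone of the straight-track transport.
#'
#' @param origin Numeric length-3 position, um.
#' @param direction Unit vector.
#' @param cell A \code{\link{cell_model}}.
#' @return Data frame with columns \code{region} (\code{"nucleus"},
#'   \code{"cytoplasm"}, \code{"outside_cell"}), \code{entry} and \code{exit}
#'   (distances along the ray, um).
#' @export
#' @examples
#' sphere_segments(c(0, 0, 0), c(0, 0, 1))   # nucleus [0,5], cytoplasm [5,10]
sphere_segments <- function(origin, direction, cell = cell_model()) {
  stopifnot(abs(sqrt(sum(direction^2)) - 1) < 1e-9)
  t_end <- .box_exit(origin, direction, cell$box_half_side)
  cuts <- c(.sphere_roots(origin, direction, cell$r_nucleus),
            .sphere_roots(origin, direction, cell$r_cell))
  cuts <- sort(unique(c(0, cuts[cuts > 0 & cuts < t_end], t_end)))
  entry <- cuts[-length(cuts)]
  exit <- cuts[-1]
  mid <- (entry + exit) / 2
  pm <- outer(mid, direction)
  r_mid <- sqrt(rowSums((matrix(origin, length(mid), 3, byrow = TRUE) + pm)^2))
  region <- ifelse(r_mid < cell$r_nucleus, "nucleus",
                   ifelse(r_mid < cell$r_cell, "cytoplasm", "outside_cell"))
  keep <- exit - entry > 1e-12
  data.frame(region = region, entry = entry, exit = exit,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Solid-angle fraction subtended by the nucleus
#'
#' Fraction of isotropic emission directions from \code{origin} whose rays
#' intersect the nucleus sphere: \eqn{(1 - \sqrt{1 - (r_n/d)^2})/2} for a
#' point at distance \eqn{d > r_n}; 1 for points inside the nucleus.
#' Analytic oracle for Monte-Carlo hit rates.
#'
#' @param origin Length-3 position (um), or a distance scalar.
#' @param cell A \code{\link{cell_model}}.
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' nucleus_solid_angle_fraction(c(10, 0, 0))  # 0.06699 for the default cell
nucleus_solid_angle_fraction <- function(origin, cell = cell_model()) {
  d <- if (length(origin) == 3L) sqrt(sum(origin^2)) else origin
  if (d <= cell$r_nucleus) return(1.0)
  (1 - sqrt(1 - (cell$r_nucleus / d)^2)) / 2
}

# Region containing a point; used for local energy deposits.
.region_of_point <- function(p, cell) {
  r <- sqrt(sum(p^2))
  if (r < cell$r_nucleus) "nucleus"
  else if (r < cell$r_cell) "cytoplasm"
  else "outside_cell"
}
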