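#' Load an alpha stopping-power table for liquid water
#'
#' Reads the packaged electronic stopping-power nodes (MeV, MeV/um) and builds
#' a dense log-log interpolated grid with the cumulative CSDA range
#' \eqn{R(E) = \int_0^E dE'/S(E')}, used for range-inversion transport.
#' Energy below the first node is treated as locally deposited (the residual
#' range there, under 1 um, is credited to the current region).
#'
#' @param path Path to a stopping-power table; defaults to the packaged one.
#' @param n_grid Number of dense grid points for the range integral.
#' @return Object of class \code{stopping_table} with elements
#'   \code{energy} (node energies), \code{sp} (node stopping powers),
#'   \code{grid_e}, \code{grid_sp}, \code{grid_range} (dense grids).
#' @export
load_stopping_table <- function(path = system.file(
                                  "extdata", "alpha_stopping_power_water.tsv",
                                  package = "alphacell"),
                                n_grid = 4000L) {
  tab <- utils::read.delim(path, comment.char = "#")
  e <- tab$energy_mev
  s <- tab$stopping_power_mev_per_um
  stopifnot(all(diff(e) > 0), all(s > 0))
  grid_e <- exp(seq(log(min(e)), log(max(e)), length.out = n_grid))
  grid_sp <- exp(stats::approx(log(e), log(s), log(grid_e), rule = 2)$y)
  # Trapezoid integral of 1/S dE; anchor R(E_min) = E_min / S(E_min), i.e.
  # constant stopping power extrapolation below the grid.
  inv <- 1 / grid_sp
  seg <- diff(grid_e) * (inv[-1] + inv[-length(inv)]) / 2
  grid_range <- cumsum(c(grid_e[1] / grid_sp[1], seg))
  structure(list(energy = e, sp = s, grid_e = grid_e, grid_sp = grid_sp,
                 grid_range = grid_range),
            class = "stopping_table")
}

default_stopping_table <- function() {
  if (is.null(.alphacell_env$sp_table))
    .alphacell_env$sp_table <- load_stopping_table()
  .alphacell_env$sp_table
}

#' Stopping power at given energies
#'
#' Log-log interpolation of the table nodes; constant extrapolation outside.
#'
#' @param energy Energies, MeV (vectorised).
#' @param table A \code{\link{load_stopping_table}} object.
#' @return Stopping power, MeV/um.
#' @export
stopping_power <- function(energy, table = default_stopping_table()) {
  exp(stats::approx(log(table$grid_e), log(table$grid_sp),
                    log(pmax(energy, table$grid_e[1])), rule = 2)$y)
}

#' CSDA range of an alpha of given energy
#'
#' @inheritParams stopping_power
#' @return Range in um (vectorised).
#' @export
csda_range <- function(energy, table = default_stopping_table()) {
  stats::approx(table$grid_e, table$grid_range,
                pmin(pmax(energy, table$grid_e[1]), max(table$grid_e)),
                rule = 2)$y *
    ifelse(energy < table$grid_e[1], energy / table$grid_e[1], 1)
}

# Inverse: energy whose range equals r (0 below the grid).
.energy_of_range <- function(r, table) {
  r0 <- table$grid_range[1]
  out <- stats::approx(table$grid_range, table$grid_e, pmax(r, r0),
                       rule = 2)$y
  ifelse(r < r0, 0, out)
}

#' Residual energy after a path length, by range inversion
#'
#' Continuous-slowing-down transport primitive: the energy remaining after an
#' alpha of energy \code{E0} travels \code{path} um of water is the energy
#' whose CSDA range equals \eqn{R(E_0) - path}; zero once the path meets or
#' exceeds the full range.
#'
#' @param E0 Initial energy, MeV.
#' @param path Path length, um (vectorised, >= 0).
#' @param table A \code{\link{load_stopping_table}} object.
#' @return Residual energy, MeV.
#' @export
#' @examples
#' residual_energy(6, 0)        # 6: identity at zero path
#' residual_energy(6, 1e4)      # 0: beyond the full range
residual_energy <- function(E0, path, table = default_stopping_table()) {
  if (any(path < 0)) stop("path must be non-negative")
  .energy_of_range(csda_range(E0, table) - path, table)
}

load_electron_range_table <- function(path = system.file(
                                        "extdata", "electron_range_water.tsv",
                                        package = "alphacell")) {
  utils::read.delim(path, comment.char = "#")
}

default_electron_ranges <- function() {
  if (is.null(.alphacell_env$e_range))
    .alphacell_env$e_range <- load_electron_range_table()
  .alphacell_env$e_range
}

#' CSDA range of an electron in water
#'
#' Log-log interpolation of the packaged ESTAR-consistent range table; used
#' by the light-particle deposition policy.
#'
#' @param energy Electron energies, MeV (vectorised).
#' @return Range in um.
#' @export
electron_range <- function(energy) {
  tab <- default_electron_ranges()
  exp(stats::approx(log(tab$energy_mev), log(tab$csda_range_um),
                    log(pmax(energy, min(tab$energy_mev))), rule = 2)$y)
}
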