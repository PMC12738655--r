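#' Transport one alpha particle along a straight track
#'
#' Composes the ray--sphere decomposition of \code{\link{sphere_segments}}
#' with range-inversion energy loss (\code{\link{residual_energy}}): the
#' track deposits energy region by region until it stops or reaches the
#' bounding box, where it is terminated.  Straight tracks (no lateral
#' scattering) and no straggling: transport is deterministic given
#' (origin, direction, energy).
#'
#' @param origin Length-3 position, um.
#' @param direction Unit vector.
#' @param energy Initial alpha energy, MeV.
#' @param cell A \code{\link{cell_model}}.
#' @param table Stopping-power table.
#' @return Data frame of per-segment deposits: \code{region}, \code{entry},
#'   \code{exit} (um along the track), \code{path} (um actually travelled in
#'   the segment), \code{edep} (MeV), \code{e_entry} (energy entering the
#'   segment), plus attributes \code{residual} (MeV escaping at the box) and
#'   \code{entered_nucleus}.
#' @export
#' @examples
#' dep <- transport_alpha(c(0, 0, 0), c(0, 0, 1), 6.787)
#' sum(dep$edep[dep$region == "nucleus"])  # several hundred keV over 5 um
transport_alpha <- function(origin, direction, energy,
                            cell = cell_model(),
                            table = default_stopping_table()) {
  stopifnot(energy > 0)
  seg <- sphere_segments(origin, direction, cell)
  n <- nrow(seg)
  edep <- numeric(n)
  path <- numeric(n)
  e_entry <- numeric(n)
  E <- energy
  range_left <- csda_range(E, table)
  for (i in seq_len(n)) {
    e_entry[i] <- E
    if (E <= 0) break
    len <- seg$exit[i] - seg$entry[i]
    travelled <- min(len, range_left)
    E_next <- residual_energy(E, travelled, table)
    edep[i] <- E - E_next
    path[i] <- travelled
    range_left <- range_left - travelled
    E <- E_next
    if (E <= 0 || range_left <= 0) {
      # stopped inside this segment: credit any interpolation remainder here
      edep[i] <- edep[i] + E
      E <- 0
    }
  }
  seg$path <- path
  seg$edep <- edep
  seg$e_entry <- e_entry
  nuc <- seg$region == "nucleus" & seg$path > 0
  attr(seg, "residual") <- E
  attr(seg, "entered_nucleus") <- any(nuc)
  seg
}

#' Convert deposits of short-ranged secondaries into local energy deposits
#'
#' Policy for the non-alpha, non-gamma decay products.  Electrons (betas,
#' conversion and Auger electrons) whose CSDA range is below
#' \code{range_cut} deposit their full energy at the emission point, in the
#' region containing it; longer-ranged electrons and all gammas are dropped
#' (they overwhelmingly escape the 30 um world volume).  Recoil nuclei
#' (sub-MeV, range well under a micron) deposit locally unless
#' \code{recoil_policy = "drop"}, which imitates transport codes that cannot
#' ionise with heavy ions.
#'
#' @param emissions Emission data frame from \code{\link{sample_decay_chain}}
#'   (rows of kinds other than \code{"alpha"} are considered).
#' @param position Length-3 emission point, um.
#' @param cell A \code{\link{cell_model}}.
#' @param policy \code{"local_below_range_cut"} (default) or \code{"ignore"}
#'   (drop all light particles).
#' @param range_cut Electron range cut in um.
#' @param recoil_policy \code{"local"} (default) or \code{"drop"}.
#' @return Data frame with columns \code{region}, \code{edep} (MeV),
#'   \code{kind}; zero rows if nothing deposits.
#' @export
deposit_light_particles <- function(emissions, position, cell = cell_model(),
                                    policy = c("local_below_range_cut",
                                               "ignore"),
                                    range_cut = 1.0,
                                    recoil_policy = c("local", "drop")) {
  policy <- match.arg(policy)
  recoil_policy <- match.arg(recoil_policy)
  out <- data.frame(region = character(), edep = numeric(),
                    kind = character(), stringsAsFactors = FALSE)
  if (policy == "ignore" || nrow(emissions) == 0L) return(out)
  region <- .region_of_point(position, cell)
  keep_e <- emissions$kind %in% c("beta", "electron") &
    electron_range(emissions$energy) < range_cut
  keep_r <- emissions$kind == "recoil" & recoil_policy == "local"
  keep <- keep_e | keep_r
  if (!any(keep)) return(out)
  data.frame(region = region, edep = emissions$energy[keep],
             kind = ifelse(emissions$kind[keep] == "recoil",
                           "recoil", "electron"),
             stringsAsFactors = FALSE)
}

#' Generate discrete ionization events along a nucleus chord
#'
#' Converts a continuous energy deposit along a nucleus segment into a cloud
#' of point ionization events for the damage scorer.  The event count is
#' Poisson with mean \code{edep / w_bar}; longitudinal positions are uniform
#' on the traversed chord; lateral displacements are isotropic Gaussian with
#' standard deviation \code{sigma_r} per transverse axis (a compact surrogate
#' for the sub-clustering-radius track penumbra); per-event energies are
#' exponential with mean \code{w_bar}, rescaled so that their sum equals the
#' deposited energy exactly.
#'
#' @param p_entry,p_exit Length-3 chord end points, um (nucleus frame,
#'   i.e. relative to the nucleus centre).
#' @param edep Deposited energy along the chord, MeV.
#' @param w_bar Mean energy per ionization event, eV.
#' @param sigma_r Lateral spread, nm.
#' @param track_id,decay_id,kind Labels attached to every event.
#' @param cell A \code{\link{cell_model}} (events are kept inside the nucleus
#'   sphere by radial clamping of the rare boundary spill-over).
#' @return Event data frame: \code{x}, \code{y}, \code{z} (nm),
#'   \code{edep_ev}, \code{track_id}, \code{decay_id}, \code{kind}.
#' @export
generate_ionization_events <- function(p_entry, p_exit, edep,
                                       w_bar = 37.5, sigma_r = 3,
                                       track_id = 1L, decay_id = 1L,
                                       kind = "alpha",
                                       cell = cell_model()) {
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      edep_ev = numeric(), track_id = integer(),
                      decay_id = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (edep <= 0) return(empty)
  n <- stats::rpois(1L, edep * 1e6 / w_bar)
  if (n == 0L) return(empty)
  a <- p_entry * 1000   # nm
  b <- p_exit * 1000
  u <- stats::runif(n)
  pos <- cbind(a[1] + u * (b[1] - a[1]),
               a[2] + u * (b[2] - a[2]),
               a[3] + u * (b[3] - a[3])) +
    matrix(stats::rnorm(3L * n, sd = sigma_r), n, 3)
  r <- sqrt(rowSums(pos^2))
  r_max <- cell$r_nucleus * 1000
  over <- r > r_max
  if (any(over)) pos[over, ] <- pos[over, , drop = FALSE] * (r_max / r[over])
  e <- stats::rexp(n, rate = 1 / w_bar)
  e <- e * (edep * 1e6) / sum(e)
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], edep_ev = e,
             track_id = track_id, decay_id = decay_id, kind = kind,
             stringsAsFactors = FALSE)
}
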