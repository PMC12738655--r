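#' Synthetic ionization-event cloud with known damage ground truth
#'
#' Builds an event cloud whose clustering outcome under the default damage
#' parameters is known by construction: \code{n_clusters} compact clusters
#' (every pairwise within-cluster distance below \code{eps}) plus isolated
#' background singletons (every cross distance above \code{eps}).  All event
#' energies are set to \code{params$e_max} and the events carry explicit
#' strand labels, so with \code{dna_fraction = 1} every event becomes a
#' break with the intended strand and the SSB/sDSB/cDSB counts are exact.
#'
#' Cluster centres are laid out on a coarse lattice with spacing well above
#' \code{2 * eps}; within-cluster spread must stay below \code{eps / 2} so
#' that intended co-clustering is guaranteed.
#'
#' @param n_clusters Number of clusters.
#' @param breaks_per_cluster Breaks in each cluster (scalar or vector).
#' @param strand_pattern List (per cluster) of strand labels, recycled to the
#'   cluster size; e.g. \code{c(1, 2)} gives opposite-strand pairs.  Default
#'   alternates strands, so every cluster spans both strands.
#' @param n_singletons Isolated single breaks.
#' @param spread Within-cluster half-extent, nm; must be < eps / 2.
#' @param params A \code{\link{damage_params}} (its \code{eps} drives the
#'   layout; \code{e_max} sets the event energies).
#' @return List with \code{events} (interchange-format data frame with an
#'   extra \code{strand} column) and \code{truth} (list: n_ssb, n_sdsb,
#'   n_cdsb computed from the construction).
#' @export
#' @examples
#' fx <- make_event_cloud(3, 2, n_singletons = 5)
#' fx$truth  # 5 SSB, 3 sDSB, 0 cDSB
make_event_cloud <- function(n_clusters, breaks_per_cluster = 2L,
                             strand_pattern = NULL, n_singletons = 0L,
                             spread = 0.5, params = damage_params()) {
  eps <- params$eps
  if (spread >= eps / 2)
    stop("spread must be below eps/2 = ", eps / 2,
         " nm to guarantee co-clustering")
  sizes <- rep_len(as.integer(breaks_per_cluster), n_clusters)
  if (is.null(strand_pattern))
    strand_pattern <- rep(list(c(1L, 2L)), n_clusters)
  if (n_clusters > 0 && length(strand_pattern) != n_clusters)
    strand_pattern <- rep_len(strand_pattern, n_clusters)

  # lattice of well-separated sites for clusters and singletons
  n_sites <- n_clusters + n_singletons
  pitch <- 4 * eps + 2 * spread   # > 2*eps margin between hulls
  side <- ceiling(n_sites^(1 / 3))
  idx <- seq_len(n_sites) - 1L
  centres <- cbind(idx %% side, (idx %/% side) %% side,
                   idx %/% (side * side)) * pitch

  rows <- list()
  n_ssb <- n_singletons
  n_sdsb <- 0L
  n_cdsb <- 0L
  for (k in seq_len(n_clusters)) {
    sz <- sizes[k]
    strands <- rep_len(as.integer(strand_pattern[[k]]), sz)
    # points inside a ball of radius `spread`: diameter < eps guarantees
    # mutual adjacency
    p <- matrix(stats::runif(3 * sz, -spread, spread) / sqrt(3), sz, 3)
    p <- sweep(p, 2, centres[k, ], "+")
    rows[[length(rows) + 1L]] <- data.frame(
      x = p[, 1], y = p[, 2], z = p[, 3], edep_ev = params$e_max,
      track_id = k, decay_id = 1L, kind = "alpha", strand = strands,
      stringsAsFactors = FALSE)
    both <- params$strandless || length(unique(strands)) == 2L
    if (sz == 1L) n_ssb <- n_ssb + 1L
    else if (both && sz == 2L) n_sdsb <- n_sdsb + 1L
    else if (both) n_cdsb <- n_cdsb + 1L
    else n_ssb <- n_ssb + sz
  }
  if (n_singletons > 0) {
    cs <- centres[n_clusters + seq_len(n_singletons), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      x = cs[, 1], y = cs[, 2], z = cs[, 3], edep_ev = params$e_max,
      track_id = n_clusters + seq_len(n_singletons), decay_id = 1L,
      kind = "alpha",
      strand = rep_len(c(1L, 2L), n_singletons), stringsAsFactors = FALSE)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               edep_ev = numeric(), track_id = integer(),
               decay_id = integer(), kind = character(), strand = integer())
  list(events = events,
       truth = list(n_ssb = n_ssb, n_sdsb = n_sdsb, n_cdsb = n_cdsb))
}

#' Build an in-memory toy nuclide chain
#'
#' Constructs a validated decay database from a branch table, for testing
#' the chain sampler against exactly known yields without the packaged data.
#' Daughters not listed as parents are added as stable nuclides.
#'
#' @param branches Data frame with columns \code{nuclide},
#'   \code{probability}, \code{mode}, \code{daughter}, \code{emissions}
#'   (emission spec string such as \code{"alpha:5.0"} or \code{"-"}), and
#'   optionally \code{half_life_s} (default 1).
#' @return A \code{decay_db} containing the toy chain.
#' @export
#' @examples
#' db <- make_toy_nuclide(data.frame(
#'   nuclide = "X-100", probability = c(0.3, 0.7),
#'   mode = c("alpha", "beta"), daughter = "Y-96",
#'   emissions = c("alpha:5.0", "beta:0.5")))
#' expected_alpha_yield("X-100", db)  # 0.3
make_toy_nuclide <- function(branches) {
  needed <- c("nuclide", "probability", "mode", "daughter", "emissions")
  if (!all(needed %in% names(branches)))
    stop("branch table must have columns: ", paste(needed, collapse = ", "))
  hl <- branches$half_life_s %||% rep(1, nrow(branches))
  db <- list()
  for (nm in unique(branches$nuclide)) {
    rows <- which(branches$nuclide == nm)
    db[[nm]] <- list(name = nm, half_life = hl[rows[1]], stable = FALSE,
                     branches = lapply(rows, function(i) list(
                       probability = branches$probability[i],
                       mode = branches$mode[i],
                       daughter = branches$daughter[i],
                       emissions = .parse_emissions(branches$emissions[i],
                                                    parent = nm))))
  }
  for (d in setdiff(unique(branches$daughter), names(db)))
    db[[d]] <- list(name = d, half_life = Inf, stable = TRUE,
                    branches = list())
  class(db) <- "decay_db"
  validate_decay_db(db)
  db
}

#' Ionization events on a free-standing line segment
#'
#' Runs the same event sampler as the transport stage on a straight line of
#' given length and deposited energy, detached from any cell geometry, so
#' the Poisson count statistics and exact energy conservation can be checked
#' in isolation.
#'
#' @param edep Deposited energy, MeV.
#' @param length Line length, um.
#' @param w_bar,sigma_r See \code{\link{generate_ionization_events}}.
#' @return Event data frame (positions in nm along the z axis).
#' @export
make_line_track_events <- function(edep, length, w_bar = 37.5, sigma_r = 3) {
  stopifnot(edep >= 0, length > 0)
  big <- cell_model(r_nucleus = max(2 * length, 1),
                    r_cell = max(4 * length, 2),
                    box_half_side = max(8 * length, 4))
  generate_ionization_events(c(0, 0, -length / 2), c(0, 0, length / 2),
                             edep, w_bar, sigma_r, cell = big)
}
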