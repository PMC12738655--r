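#' Damage-scoring parameters
#'
#' Parameters of the clustered-damage scorer.  An ionization event damages
#' DNA with a probability that rises linearly from 0 at \code{e_min} (5 eV)
#' to 1 at \code{e_max} (37.5 eV), multiplied by the fraction of the nucleus
#' volume occupied by DNA (\code{dna_fraction}, 16%).  Accepted breaks are
#' clustered with a density-based search of radius \code{eps} (3.2 nm, about
#' ten base pairs) and core threshold \code{min_points} = 2.
#'
#' @param e_min,e_max Damage-probability ramp knots, eV.
#' @param dna_fraction Fraction of the nucleus volume occupied by DNA.
#' @param eps Clustering neighbourhood radius, nm (strict inequality:
#'   breaks separated by exactly \code{eps} are not neighbours).
#' @param min_points Minimum neighbourhood size (itself included) for a core
#'   point; 2 makes every mutually-close pair a cluster.
#' @param strandless If \code{TRUE}, ignore strand labels and score any
#'   cluster of two or more breaks as a DSB (pure proximity definition, for
#'   sensitivity analysis).  Default \code{FALSE}: a DSB requires breaks on
#'   both strands.
#' @return Object of class \code{damage_params}.
#' @export
damage_params <- function(e_min = 5, e_max = 37.5, dna_fraction = 0.16,
                          eps = 3.2, min_points = 2L, strandless = FALSE) {
  stopifnot(0 < e_min, e_min < e_max, 0 < dna_fraction, dna_fraction <= 1,
            eps > 0, min_points >= 1)
  structure(list(e_min = e_min, e_max = e_max, dna_fraction = dna_fraction,
                 eps = eps, min_points = as.integer(min_points),
                 strandless = isTRUE(strandless)),
            class = "damage_params")
}

#' Probability that an ionization event damages DNA
#'
#' Piecewise-linear ramp: 0 below \code{e_min}, rising linearly to 1 at
#' \code{e_max}, constant 1 above.
#'
#' @param edep Deposited energy per event, eV (vectorised).
#' @param params A \code{\link{damage_params}}.
#' @return Probabilities in [0, 1].
#' @export
#' @examples
#' damage_probability(c(5, 21.25, 37.5))  # 0, 0.5, 1
damage_probability <- function(edep, params = damage_params()) {
  stopifnot(all(edep >= 0))
  pmin(pmax((edep - params$e_min) / (params$e_max - params$e_min), 0), 1)
}

#' Select strand breaks from ionization events
#'
#' Each event is independently retained with probability
#' \code{damage_probability(edep) * dna_fraction} (the damage ramp and the
#' 16% DNA-volume sampling applied as one multiplicative Bernoulli, which is
#' order-independent), and each retained break is assigned to strand 1 or 2
#' with probability 1/2.  If the events carry a \code{strand} column (as the
#' synthetic fixtures do), those labels are honoured instead of being drawn.
#'
#' @param events Event data frame (\code{x}, \code{y}, \code{z} in nm,
#'   \code{edep_ev}; optionally \code{decay_id}, \code{kind},
#'   \code{strand}).
#' @param params A \code{\link{damage_params}}.
#' @return Break data frame: \code{x}, \code{y}, \code{z}, \code{strand},
#'   \code{event_id}, plus \code{decay_id}/\code{kind} if present.
#' @export
select_breaks <- function(events, params = damage_params()) {
  n <- nrow(events)
  if (n == 0L)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      strand = integer(), event_id = integer()))
  p <- damage_probability(events$edep_ev, params) * params$dna_fraction
  keep <- stats::runif(n) < p
  out <- events[keep, intersect(c("x", "y", "z", "decay_id", "kind", "strand"),
                                names(events)), drop = FALSE]
  out$event_id <- which(keep)
  if (is.null(out$strand))
    out$strand <- sample(c(1L, 2L), nrow(out), replace = TRUE)
  rownames(out) <- NULL
  out
}

# Density clustering with neighbourhood radius eps (strict) and core
# threshold min_points.  Returns an integer cluster label per break
# (0 = noise/singleton).  Classic queue-based DBSCAN region expansion over a
# cell-hash neighbour index.
.dbscan_labels <- function(xyz, eps, min_points) {
  n <- nrow(xyz)
  if (n == 0L) return(integer())
  cellkey <- function(p) paste(floor(p[, 1] / eps), floor(p[, 2] / eps),
                               floor(p[, 3] / eps), sep = ",")
  keys <- cellkey(xyz)
  index <- split(seq_len(n), keys)
  grid <- floor(xyz / eps)
  neighbours <- function(i) {
    g <- grid[i, ]
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(g[1] + dx, g[2] + dy, g[3] + dz, sep = ",")
      cand <- c(cand, index[[k]])
    }
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < eps^2]   # strict; includes i itself
  }
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_points) next   # provisional noise
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_points)
          queue <- c(queue, nbj[labels[nbj] == 0L])
      }
    }
  }
  labels
}

#' Cluster strand breaks into SSB / sDSB / cDSB counts
#'
#' Density-based clustering (radius \code{eps}, core threshold
#' \code{min_points}, density-reachable chaining) of accepted strand breaks.
#' A cluster containing breaks on both strands is a double-strand break:
#' exactly two breaks make a simple DSB, three or more a complex DSB.
#' Clusters confined to a single strand (tandem SSBs) and unclustered
#' singletons count their breaks as SSBs.  The histogram records the sizes of
#' all clusters of two or more breaks.
#'
#' @param breaks Break data frame from \code{\link{select_breaks}}.
#' @param params A \code{\link{damage_params}}.
#' @return Object of class \code{damage_summary}: list with counts
#'   \code{n_ssb}, \code{n_sdsb}, \code{n_cdsb}, \code{n_breaks}, the
#'   DSB-cluster \code{sizes}, and \code{histogram} (table of all cluster
#'   sizes >= 2).
#' @export
cluster_breaks <- function(breaks, params = damage_params()) {
  n <- nrow(breaks)
  if (n == 0L) return(.damage_summary(0L, 0L, 0L, integer(), integer(), 0L))
  labels <- .dbscan_labels(as.matrix(breaks[, c("x", "y", "z")]),
                           params$eps, params$min_points)
  n_ssb <- sum(labels == 0L)
  sdsb <- 0L
  cdsb <- 0L
  dsb_sizes <- integer()
  all_sizes <- integer()
  for (cl in unique(labels[labels > 0L])) {
    idx <- labels == cl
    size <- sum(idx)
    all_sizes <- c(all_sizes, size)
    both <- params$strandless || length(unique(breaks$strand[idx])) == 2L
    if (both && size == 2L) {
      sdsb <- sdsb + 1L
      dsb_sizes <- c(dsb_sizes, size)
    } else if (both && size >= 3L) {
      cdsb <- cdsb + 1L
      dsb_sizes <- c(dsb_sizes, size)
    } else {
      n_ssb <- n_ssb + size   # single-strand cluster: tandem SSBs
    }
  }
  .damage_summary(n_ssb, sdsb, cdsb, dsb_sizes, all_sizes, n)
}

.damage_summary <- function(n_ssb, n_sdsb, n_cdsb, dsb_sizes, all_sizes,
                            n_breaks) {
  structure(list(n_ssb = as.integer(n_ssb), n_sdsb = as.integer(n_sdsb),
                 n_cdsb = as.integer(n_cdsb),
                 n_breaks = as.integer(n_breaks),
                 sizes = as.integer(dsb_sizes),
                 histogram = table(factor(all_sizes))),
            class = "damage_summary")
}

#' @export
print.damage_summary <- function(x, ...) {
  cat(sprintf("Damage summary: %d breaks -> %d SSB, %d sDSB, %d cDSB\n",
              x$n_breaks, x$n_ssb, x$n_sdsb, x$n_cdsb))
  invisible(x)
}

#' Score DNA damage for events grouped by parent decay
#'
#' Applies break selection and clustering independently within each parent
#' decay's event set (ionizations from different decays never co-cluster)
#' and reports both per-decay summaries and per-decay means.
#'
#' @param events Event data frame with a \code{decay_id} column.
#' @param params A \code{\link{damage_params}}.
#' @param n_decays Number of parent decays to normalise by; defaults to the
#'   number of distinct \code{decay_id} values present (pass the true decay
#'   count when some decays produced no events).
#' @return List with \code{per_decay} (data frame: decay_id, n_breaks, n_ssb,
#'   n_sdsb, n_cdsb), \code{mean_per_decay} (named numeric), and
#'   \code{n_decays}.
#' @export
score_damage <- function(events, params = damage_params(),
                         n_decays = NULL) {
  ids <- if (nrow(events)) unique(events$decay_id) else integer()
  if (is.null(n_decays)) n_decays <- length(ids)
  rows <- lapply(ids, function(id) {
    ev <- events[events$decay_id == id, , drop = FALSE]
    s <- cluster_breaks(select_breaks(ev, params), params)
    data.frame(decay_id = id, n_breaks = s$n_breaks, n_ssb = s$n_ssb,
               n_sdsb = s$n_sdsb, n_cdsb = s$n_cdsb)
  })
  per_decay <- if (length(rows)) do.call(rbind, rows)
    else data.frame(decay_id = integer(), n_breaks = integer(),
                    n_ssb = integer(), n_sdsb = integer(),
                    n_cdsb = integer())
  totals <- colSums(per_decay[, c("n_breaks", "n_ssb", "n_sdsb", "n_cdsb"),
                              drop = FALSE])
  mean_per_decay <- if (n_decays > 0) totals / n_decays else totals * 0
  list(per_decay = per_decay, mean_per_decay = mean_per_decay,
       n_decays = n_decays)
}

#' Write / read the delimited-text ionization-event interchange format
#'
#' Tab-separated columns \code{x}, \code{y}, \code{z} (nm), \code{edep_ev},
#' \code{track_id}, \code{decay_id}, \code{kind}; this is the boundary
#' between the transport and damage stages, so externally produced
#' phase-space exports can be converted in.
#'
#' @param events Event data frame.
#' @param path File path.
#' @return \code{read_events} returns the event data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
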