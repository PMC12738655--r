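#' Sample one complete decay cascade
#'
#' Walks the decay-branch graph from a parent nuclide to stability, choosing a
#' branch at each step according to its branching probability, and collects
#' every particle emitted along the way.  Each alpha emission is paired with a
#' recoil emission of the daughter nucleus carrying
#' \eqn{E_{recoil} = E_\alpha \, m_\alpha / m_{daughter}}.  All chain members
#' decay at the parent's position instantly: half-lives play no role in
#' sampling (no temporal effects), except through \code{stop_half_life},
#' which truncates the chain at very long-lived intermediates (for example
#' Bi-207, half-life about 32 years, in the At-211 chain) when set.
#'
#' Beta branches carry a mean beta energy in the decay table; a single
#' electron energy is drawn from an exponential distribution with that mean
#' (a surrogate for the Fermi spectrum).  Uses the R global random number
#' generator; seed with \code{set.seed()} for reproducibility.
#'
#' @param parent Nuclide name, e.g. \code{"At-211"}.
#' @param db Decay database; defaults to the packaged four-chain table.
#' @param stop_half_life Half-life threshold in seconds above which a
#'   daughter is treated as effectively stable (chain truncation).
#'   \code{Inf} (default) disables truncation.
#' @return Data frame of emissions in chain order with columns \code{kind}
#'   (\code{alpha}, \code{beta}, \code{gamma}, \code{recoil}), \code{energy}
#'   (MeV) and \code{parent} (the emitting nuclide).
#' @seealso \code{\link{discrete_alpha_spectrum}}, \code{\link{mean_alpha_yield}}
#' @export
#' @examples
#' set.seed(1)
#' sample_decay_chain("At-211")
sample_decay_chain <- function(parent, db = default_decay_db(),
                               stop_half_life = Inf) {
  nuc <- .get_nuclide(parent, db)
  out <- vector("list", 32L)
  n_out <- 0L
  steps <- 0L
  while (!nuc$stable && nuc$half_life <= stop_half_life) {
    steps <- steps + 1L
    if (steps > 1000L) stop("decay chain failed to terminate from '",
                            parent, "'")
    br <- .draw_branch(nuc$branches)
    em <- br$emissions
    if (nrow(em) > 0) {
      is_beta <- em$kind == "beta"
      if (any(is_beta))
        em$energy[is_beta] <- stats::rexp(sum(is_beta),
                                          rate = 1 / em$energy[is_beta])
      is_alpha <- em$kind == "alpha"
      if (any(is_alpha)) {
        rec <- em[is_alpha, , drop = FALSE]
        rec$kind <- "recoil"
        rec$energy <- rec$energy * ALPHA_MASS_AMU / .mass_number(br$daughter)
        em <- rbind(em, rec)
      }
      n_out <- n_out + 1L
      out[[n_out]] <- em
    }
    nuc <- db[[br$daughter]]
  }
  if (n_out == 0L)
    return(data.frame(kind = character(), energy = numeric(),
                      parent = character(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(n_out)])
}

.draw_branch <- function(branches) {
  if (length(branches) == 1L) return(branches[[1L]])
  p <- vapply(branches, `[[`, 0, "probability")
  branches[[sample.int(length(branches), 1L, prob = p)]]
}

#' Expected per-decay frequency of every branch in a chain
#'
#' Propagates expected visit counts through the (acyclic) branch graph:
#' the parent is visited once per decay, and each branch is taken its
#' probability times the expected visits of its nuclide.  This is the exact
#' enumeration underlying both the discrete alpha spectrum weights and the
#' exact alpha yield.
#'
#' @return Data frame with one row per (nuclide, branch) pair:
#'   \code{nuclide}, \code{branch}, \code{frequency} (expected traversals per
#'   parent decay).
#' @noRd
.branch_frequencies <- function(parent, db, stop_half_life = Inf) {
  visits <- c(stats::setNames(1, parent))
  rows <- list()
  # The graph may reconverge (e.g. Bi-213 -> Po-213/Tl-209 -> Pb-209), so a
  # nuclide's total inflow is only known once all its parents are expanded:
  # process nuclides in topological order.
  topo <- .topo_order(parent, db)
  for (nm in topo) {
    v <- visits[nm]
    if (is.na(v) || v == 0) next
    nuc <- db[[nm]]
    if (nuc$stable || nuc$half_life > stop_half_life) next
    for (i in seq_along(nuc$branches)) {
      br <- nuc$branches[[i]]
      f <- v * br$probability
      rows[[length(rows) + 1L]] <-
        data.frame(nuclide = nm, branch = i, frequency = f,
                   stringsAsFactors = FALSE)
      visits[br$daughter] <- ifelse(is.na(visits[br$daughter]), f,
                                    visits[br$daughter] + f)
    }
  }
  do.call(rbind, rows)
}

.topo_order <- function(parent, db) {
  order <- character()
  seen <- new.env(parent = emptyenv())
  visit <- function(nm) {
    if (!is.null(seen[[nm]])) return()
    seen[[nm]] <- TRUE
    for (br in db[[nm]]$branches) visit(br$daughter)
    order <<- c(nm, order)
  }
  visit(parent)
  order
}

#' Discrete alpha spectrum of a decay chain
#'
#' Collects every alpha line emitted anywhere in the chain of \code{parent}
#' with weights proportional to the expected per-parent-decay emission
#' frequency (computed by exact enumeration of the branch graph),
#' renormalised to sum to one.  This is the source description for the
#' "alpha-only" source model: one alpha per decay, drawn from these lines.
#'
#' @inheritParams sample_decay_chain
#' @return Object of class \code{alpha_spectrum}: list with \code{energies}
#'   (MeV), \code{weights} (sum to 1) and \code{parent}.
#' @export
#' @examples
#' discrete_alpha_spectrum("At-211")  # lines near 5.87 and 7.45 MeV
discrete_alpha_spectrum <- function(parent, db = default_decay_db(),
                                    stop_half_life = Inf) {
  .get_nuclide(parent, db)
  freq <- .branch_frequencies(parent, db, stop_half_life)
  energies <- numeric()
  weights <- numeric()
  if (!is.null(freq)) {
    for (i in seq_len(nrow(freq))) {
      br <- db[[freq$nuclide[i]]]$branches[[freq$branch[i]]]
      a <- br$emissions$energy[br$emissions$kind == "alpha"]
      if (length(a)) {
        energies <- c(energies, a)
        weights <- c(weights, rep(freq$frequency[i], length(a)))
      }
    }
  }
  if (length(energies) == 0L)
    stop("chain of '", parent, "' emits no alpha particles")
  o <- order(energies)
  structure(list(energies = energies[o],
                 weights = weights[o] / sum(weights),
                 parent = parent),
            class = "alpha_spectrum")
}

#' @export
print.alpha_spectrum <- function(x, ...) {
  cat("Discrete alpha spectrum of", x$parent, "chain\n")
  print(data.frame(energy_mev = x$energies, weight = round(x$weights, 5)))
  invisible(x)
}

#' Mean number of alpha particles per parent decay
#'
#' Monte-Carlo estimate over \code{n_samples} sampled cascades.  For the
#' packaged chains every branch path emits the same number of alphas
#' (4 for Ac-225 and Ra-223, 1 for Pb-212 and At-211), so the estimate is
#' exact for any \code{n_samples}.
#'
#' @inheritParams sample_decay_chain
#' @param n_samples Number of cascades to sample (>= 1).
#' @return Mean alphas per decay.
#' @export
mean_alpha_yield <- function(parent, n_samples = 100L,
                             db = default_decay_db(), stop_half_life = Inf) {
  stopifnot(n_samples >= 1)
  counts <- vapply(seq_len(n_samples), function(i) {
    em <- sample_decay_chain(parent, db, stop_half_life)
    sum(em$kind == "alpha")
  }, numeric(1))
  mean(counts)
}

#' Exact expected alpha yield by branch-graph enumeration
#'
#' Deterministic counterpart of \code{\link{mean_alpha_yield}}: sums alpha
#' multiplicities over all branches weighted by their expected traversal
#' frequency.
#'
#' @inheritParams sample_decay_chain
#' @return Expected alphas per parent decay.
#' @export
expected_alpha_yield <- function(parent, db = default_decay_db(),
                                 stop_half_life = Inf) {
  .get_nuclide(parent, db)
  freq <- .branch_frequencies(parent, db, stop_half_life)
  if (is.null(freq)) return(0)
  total <- 0
  for (i in seq_len(nrow(freq))) {
    br <- db[[freq$nuclide[i]]]$branches[[freq$branch[i]]]
    total <- total + freq$frequency[i] * sum(br$emissions$kind == "alpha")
  }
  total
}
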