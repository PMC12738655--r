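#' @keywords internal
"_PACKAGE"

# Atomic mass ratio used for alpha-recoil kinematics: m_alpha / m_daughter,
# with the daughter mass number parsed from names like "Bi-207".
ALPHA_MASS_AMU <- 4.002602

.alphacell_env <- new.env(parent = emptyenv())

#' Read and validate a decay-chain table
#'
#' Parses the structured-text decay-chain format shipped with the package
#' (one row per decay branch; see \code{inst/extdata/decay_chains.tsv} for the
#' schema) into a decay database: a named list of nuclides, each holding its
#' half-life and branch list.  Validation enforces that per-nuclide branch
#' probabilities sum to one, that every daughter resolves within the table,
#' that the branch graph is acyclic (chains reach stability), and that all
#' alpha line energies are physically plausible (4--10 MeV).
#'
#' @param path Path to a decay-chain table. Defaults to the packaged table
#'   covering the Ac-225, Ra-223, Pb-212 and At-211 chains.
#' @return An object of class \code{decay_db}: a named list of nuclides.
#'   Each nuclide is a list with elements \code{name}, \code{half_life}
#'   (seconds), \code{stable} (flag) and \code{branches} (list of branches,
#'   each with \code{probability}, \code{mode}, \code{daughter} and an
#'   \code{emissions} data frame with columns \code{kind}, \code{energy},
#'   \code{parent}).
#' @export
load_decay_data <- function(path = system.file("extdata", "decay_chains.tsv",
                                               package = "alphacell")) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("nuclide", "half_life_s", "probability", "mode", "daughter",
              "emissions")
  if (!all(needed %in% names(raw)))
    stop("decay table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))

  db <- list()
  for (nm in unique(raw$nuclide)) {
    rows <- raw[raw$nuclide == nm, , drop = FALSE]
    stable <- identical(rows$mode[1], "stable")
    branches <- list()
    if (!stable) {
      for (i in seq_len(nrow(rows))) {
        branches[[i]] <- list(
          probability = rows$probability[i],
          mode = rows$mode[i],
          daughter = rows$daughter[i],
          emissions = .parse_emissions(rows$emissions[i], parent = nm)
        )
      }
    }
    db[[nm]] <- list(name = nm, half_life = rows$half_life_s[1],
                     stable = stable, branches = branches)
  }
  class(db) <- "decay_db"
  validate_decay_db(db)
  db
}

.parse_emissions <- function(spec, parent) {
  empty <- data.frame(kind = character(), energy = numeric(),
                      parent = character(), stringsAsFactors = FALSE)
  if (is.na(spec) || spec == "-" || spec == "") return(empty)
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed emission spec '", spec, "' for ", parent)
  data.frame(kind = vapply(parts, `[`, "", 1L),
             energy = as.numeric(vapply(parts, `[`, "", 2L)),
             parent = parent, stringsAsFactors = FALSE)
}

#' Validate a decay database
#'
#' Checks the structural invariants a decay database must satisfy before it
#' can be sampled: branch probabilities sum to 1 (within 1e-9), daughters
#' resolve, no cycles, positive emission energies, alpha lines within
#' 4--10 MeV.  Called automatically by \code{\link{load_decay_data}} and
#' \code{\link{make_toy_nuclide}}.
#'
#' @param db A \code{decay_db} object.
#' @param alpha_window Allowed alpha energy window in MeV.
#' @return \code{db}, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_decay_db <- function(db, alpha_window = c(4, 10)) {
  for (nuc in db) {
    if (nuc$stable) {
      if (length(nuc$branches) > 0L)
        stop(nuc$name, ": stable nuclide must have no branches")
      next
    }
    if (length(nuc$branches) == 0L)
      stop(nuc$name, ": unstable nuclide has no branches")
    p <- vapply(nuc$branches, `[[`, 0, "probability")
    if (abs(sum(p) - 1) > 1e-9)
      stop(nuc$name, ": branch probabilities sum to ", sum(p), ", not 1")
    if (any(p < 0 | p > 1))
      stop(nuc$name, ": branch probabilities outside [0, 1]")
    for (br in nuc$branches) {
      if (!br$daughter %in% names(db))
        stop(nuc$name, ": daughter '", br$daughter, "' not in table")
      em <- br$emissions
      if (nrow(em) > 0) {
        if (any(em$energy <= 0))
          stop(nuc$name, ": emission energies must be positive")
        a <- em$energy[em$kind == "alpha"]
        if (any(a < alpha_window[1] | a > alpha_window[2]))
          stop(nuc$name, ": alpha energy outside [",
               alpha_window[1], ", ", alpha_window[2], "] MeV")
      }
    }
  }
  .check_acyclic(db)
  invisible(db)
}

.check_acyclic <- function(db) {
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  visit <- function(nm) {
    s <- state[[nm]]
    if (identical(s, 2L)) return()
    if (identical(s, 1L)) stop("cycle in decay chain at ", nm)
    state[[nm]] <- 1L
    for (br in db[[nm]]$branches) visit(br$daughter)
    state[[nm]] <- 2L
  }
  for (nm in names(db)) visit(nm)
  invisible(TRUE)
}

# Packaged database, loaded once per session.
default_decay_db <- function() {
  if (is.null(.alphacell_env$decay_db))
    .alphacell_env$decay_db <- load_decay_data()
  .alphacell_env$decay_db
}

# Mass number from a name like "Bi-207"; used for recoil kinematics.
.mass_number <- function(name) {
  a <- suppressWarnings(as.numeric(sub("^[A-Za-z]+-", "", name)))
  if (is.na(a)) stop("cannot parse mass number from nuclide name '", name, "'")
  a
}

.get_nuclide <- function(parent, db) {
  if (!parent %in% names(db))
    stop("unknown nuclide '", parent, "'; known: ",
         paste(names(db), collapse = ", "))
  db[[parent]]
}
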