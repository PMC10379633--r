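#' Electronic state property tables
#'
#' A `state_table` holds everything a sum-over-states calculation needs for
#' one molecule: the excitation energies of `n` electronic states and the
#' full symmetric `n x n` matrix of dipole 3-vectors
#' \eqn{\mu_{pq} = \langle\psi_p|\mu|\psi_q\rangle}. Diagonal entries are
#' permanent dipole moments, off-diagonal entries transition moments.
#' Energies are stored ground-relative in Hartree (state 1 is the ground
#' state S0 with energy 0) and dipoles in atomic units.
#'
#' @param energies numeric vector of state energies in Hartree. They are
#'   shifted to be ground-relative and must be non-decreasing.
#' @param dipoles numeric array of dimension `c(n, n, 3)`, symmetric in its
#'   first two indices (real wavefunctions), in atomic units.
#' @param labels optional character vector of state names; defaults to
#'   `"S0"`, `"S1"`, ...
#' @param provenance free-form list of metadata (method, basis, source).
#' @return An object of class `state_table`.
#' @seealso [from_two_level()], [builtin_fixture()], [random_state_table()],
#'   [load_state_table()]
#' @export
state_table <- function(energies, dipoles, labels = NULL, provenance = list()) {
  energies <- as.numeric(energies)
  n <- length(energies)
  if (n < 2) stop("a state table needs at least 2 states", call. = FALSE)
  if (any(!is.finite(energies))) stop("energies must be finite", call. = FALSE)
  dipoles <- array(as.numeric(dipoles), dim = dim(dipoles))
  if (!identical(dim(dipoles), c(n, n, 3L)) && !identical(dim(dipoles), as.integer(c(n, n, 3))))
    stop("dipoles must be an n x n x 3 array with n = ", n, call. = FALSE)
  if (any(!is.finite(dipoles))) stop("dipole components must be finite", call. = FALSE)
  if (is.null(labels)) labels <- paste0("S", seq_len(n) - 1L)
  x <- structure(
    list(energies = energies - energies[1L], dipoles = dipoles,
         labels = as.character(labels), provenance = provenance),
    class = "state_table"
  )
  validate_state_table(x)
}

#' Validate a state table
#'
#' Checks the invariants every `state_table` must satisfy: ground-relative,
#' non-decreasing energies and a dipole matrix symmetric to within `tol`
#' componentwise. On a symmetry violation, the error names the worst
#' offending state pair.
#'
#' @param x a `state_table`.
#' @param tol absolute symmetry tolerance in atomic units.
#' @return `x`, invisibly usable, on success; otherwise an error.
#' @export
validate_state_table <- function(x, tol = 1e-8) {
  stopifnot(inherits(x, "state_table"))
  e <- x$energies
  if (e[1L] != 0) stop("energies must be ground-relative (E[1] = 0)", call. = FALSE)
  if (any(diff(e) < 0)) stop("energies must be non-decreasing", call. = FALSE)
  d <- x$dipoles
  asym <- abs(d - aperm(d, c(2L, 1L, 3L)))
  if (max(asym) > tol) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    pq <- sort(c(worst[["dim1"]], worst[["dim2"]])) - 1L
    stop(sprintf(
      "dipole matrix not symmetric: |mu(%d,%d) - mu(%d,%d)| = %.3g a.u. exceeds %g",
      pq[1L], pq[2L], pq[2L], pq[1L], max(asym), tol), call. = FALSE)
  }
  x
}

#' @export
print.state_table <- function(x, ...) {
  n <- n_states(x)
  cat(sprintf("state_table: %d electronic states\n", n))
  ev <- x$energies * tpa_constants$hartree_in_ev
  mu <- vapply(seq_len(n), function(i) sqrt(sum(x$dipoles[i, 1L, ]^2)), 0)
  df <- data.frame(state = x$labels, energy_ev = round(ev, 4),
                   mu_to_ground_D = round(au_to_debye(mu), 3))
  print(df, row.names = FALSE)
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance), unlist(x$provenance),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname state_table
#' @param x a `state_table`.
#' @export
n_states <- function(x) length(x$energies)

#' Dipole vector accessors
#'
#' `state_dipole()` extracts one dipole 3-vector
#' \eqn{\langle\psi_p|\mu|\psi_q\rangle} (a.u.); `delta_dipole()` returns the
#' permanent-dipole difference between a final state and the ground state,
#' the quantity that drives the two-level TPA strength.
#'
#' @param x a `state_table`.
#' @param p,q 1-based state indices (state 1 = S0).
#' @param final 1-based final-state index (default 2 = S1).
#' @return a numeric 3-vector in atomic units.
#' @export
state_dipole <- function(x, p, q) {
  stopifnot(inherits(x, "state_table"))
  x$dipoles[p, q, ]
}

#' @rdname state_dipole
#' @export
delta_dipole <- function(x, final = 2L) {
  state_dipole(x, final, final) - state_dipole(x, 1L, 1L)
}

#' Magnitude of a dipole vector
#'
#' @param v numeric 3-vector.
#' @return Euclidean norm.
#' @export
dipole_magnitude <- function(v) sqrt(sum(v^2))

# ---- two-level construction ------------------------------------------------

#' Two-level model specification
#'
#' Bundles the four scalars that determine a two-level TPA calculation:
#' the transition dipole magnitude, the permanent-dipole-difference
#' magnitude, the angle between the two vectors, and the vertical
#' excitation energy.
#'
#' @param mu10 transition dipole magnitude |mu10| in Debye (>= 0).
#' @param dmu10 permanent-dipole-difference magnitude |dmu10| in Debye (>= 0).
#' @param vee vertical excitation energy in eV (> 0).
#' @param theta angle between dmu10 and mu10 in degrees, in [0, 180].
#' @return An object of class `two_level_spec`.
#' @export
two_level_spec <- function(mu10, dmu10, vee, theta = 0) {
  .assert_finite(c(mu10, dmu10, vee, theta), "two-level parameters")
  if (mu10 < 0 || dmu10 < 0) stop("dipole magnitudes must be >= 0", call. = FALSE)
  if (vee <= 0) stop("vertical excitation energy must be positive", call. = FALSE)
  if (theta < 0 || theta > 180) stop("theta must lie in [0, 180] degrees", call. = FALSE)
  structure(list(mu10 = mu10, dmu10 = dmu10, vee = vee, theta = theta),
            class = "two_level_spec")
}

#' Build a two-state table from two-level parameters
#'
#' Constructs the minimal `state_table` realizing a two-level model: the
#' transition dipole lies along x with magnitude `mu10`; the ground-state
#' permanent dipole is the zero vector and the excited-state permanent
#' dipole is placed in the xy-plane at angle `theta` to the transition
#' dipole with magnitude `dmu10`. Only the difference of permanent dipoles
#' enters the two-level strength, so this gauge choice is immaterial.
#'
#' @param spec a [two_level_spec()], or the `mu10` magnitude in Debye if the
#'   remaining scalars are given separately.
#' @inheritParams two_level_spec
#' @param labels,provenance passed to [state_table()].
#' @return A 2-state `state_table` (energies in Hartree, dipoles in a.u.).
#' @examples
#' egfp <- from_two_level(mu10 = 10.5, dmu10 = 4.4, vee = 2.52)
#' @export
from_two_level <- function(spec, dmu10 = NULL, vee = NULL, theta = 0,
                           labels = NULL, provenance = list()) {
  if (!inherits(spec, "two_level_spec"))
    spec <- two_level_spec(spec, dmu10, vee, theta)
  mu <- c(debye_to_au(spec$mu10), 0, 0)
  th <- spec$theta * pi / 180
  dmu <- debye_to_au(spec$dmu10) * c(cos(th), sin(th), 0)
  d <- array(0, dim = c(2L, 2L, 3L))
  d[1L, 2L, ] <- d[2L, 1L, ] <- mu
  d[2L, 2L, ] <- dmu                       # mu00 = 0, so dmu sits on mu11
  state_table(c(0, energy_convert(spec$vee, "ev", "hartree")), d,
              labels = labels, provenance = provenance)
}

# Table of the three built-in chromophore systems: magnitudes in Debye,
# vertical excitation energies in eV.
.fixture_params <- list(
  hbdi       = list(mu10 = 10.5, dmu10 = 2.9, vee = 2.62),
  egfp_t203i = list(mu10 = 10.9, dmu10 = 2.5, vee = 2.43),
  egfp       = list(mu10 = 10.5, dmu10 = 4.4, vee = 2.52)
)

#' Built-in chromophore state tables
#'
#' Two-state tables for the three systems whose excited-state properties the
#' package ships as fixtures: the isolated HBDI anion (the GFP chromophore),
#' EGFP and its T203I mutant. Only the magnitudes |mu10| and |dmu10| are
#' known, so by default the two vectors are assumed collinear (`theta = 0`),
#' an overridable approximation.
#'
#' @param name one of `"hbdi"`, `"egfp"`, `"egfp_t203i"`.
#' @param theta assumed angle between dmu10 and mu10, degrees.
#' @return A 2-state `state_table`.
#' @examples
#' builtin_fixture("egfp")
#' @export
builtin_fixture <- function(name = c("hbdi", "egfp", "egfp_t203i"), theta = 0) {
  name <- match.arg(name)
  p <- .fixture_params[[name]]
  from_two_level(p$mu10, p$dmu10, p$vee, theta = theta,
                 provenance = list(system = name, source = "built-in fixture"))
}

#' @rdname builtin_fixture
#' @export
fixture_names <- function() names(.fixture_params)

# Run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random electronic-state tables
#'
#' Generates a reproducible synthetic `state_table` with `n_states` states:
#' energies ascending in (0, `energy_span`] eV with a minimum gap of
#' 0.05 eV, and a symmetric dipole matrix with zero-mean Gaussian
#' components of scale `dipole_scale` (Debye). Intended for property tests
#' and oracle comparisons of the sum-over-states machinery on tables larger
#' than two states.
#'
#' @param n_states number of states (>= 2).
#' @param seed integer seed; the same seed reproduces the table bit-for-bit.
#' @param energy_span upper bound of the excitation energies, eV.
#' @param dipole_scale standard deviation of dipole components, Debye.
#' @return A `state_table`.
#' @export
random_state_table <- function(n_states, seed, energy_span = 6, dipole_scale = 5) {
  if (n_states < 2) stop("n_states must be >= 2", call. = FALSE)
  n <- as.integer(n_states)
  .with_seed(seed, {
    gap_min <- 0.05
    slack <- (energy_span - gap_min * (n - 1L)) / (n - 1L)
    if (slack < 0) stop("energy_span too small for the 0.05 eV minimum gap", call. = FALSE)
    gaps <- gap_min + stats::runif(n - 1L) * slack
    e_ev <- c(0, cumsum(gaps))
    raw <- array(stats::rnorm(n * n * 3L, sd = debye_to_au(dipole_scale)),
                 dim = c(n, n, 3L))
    d <- (raw + aperm(raw, c(2L, 1L, 3L))) / 2
    state_table(energy_convert(e_ev, "ev", "hartree"), d,
                provenance = list(source = "random_state_table", seed = seed))
  })
}

#' Synthetic table dominated by the two-level channel
#'
#' Extends a two-state table with extra higher-lying states whose couplings
#' to the ground and final states are scaled to a small fraction of the
#' transition dipole, emulating a charge-transfer transition for which the
#' two-level model captures nearly all of the TPA strength. Intermediate
#' permanent dipoles are set to zero (they do not enter the truncated sum).
#'
#' @param base a 2-state `state_table`; defaults to the EGFP fixture.
#' @param n_states total number of states in the output table.
#' @param coupling_scale magnitude of the intermediate couplings relative to
#'   |mu10| (default 0.05, i.e. 5 percent).
#' @param energy_span upper bound for the added state energies, eV.
#' @param seed integer seed for the random coupling directions.
#' @return A `state_table` with `n_states` states.
#' @export
tlm_dominant_table <- function(base = builtin_fixture("egfp"), n_states = 7,
                               coupling_scale = 0.05, energy_span = 6, seed = 1) {
  stopifnot(inherits(base, "state_table"), n_states(base) == 2L)
  n <- as.integer(n_states)
  if (n < 3L) stop("n_states must be >= 3 to add intermediates", call. = FALSE)
  e1_ev <- energy_convert(base$energies[2L], "hartree", "ev")
  mu_scale <- coupling_scale * dipole_magnitude(state_dipole(base, 1L, 2L))
  .with_seed(seed, {
    extra <- sort(stats::runif(n - 2L, e1_ev + 0.2, energy_span))
    d <- array(0, dim = c(n, n, 3L))
    d[1:2, 1:2, ] <- base$dipoles
    for (i in 3:n) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      d[1L, i, ] <- d[i, 1L, ] <- mu_scale * u
      d[2L, i, ] <- d[i, 2L, ] <- mu_scale * v
    }
    state_table(energy_convert(c(0, e1_ev, extra), "ev", "hartree"), d,
                provenance = list(source = "tlm_dominant_table", seed = seed))
  })
}

# ---- JSON file format ------------------------------------------------------

.st_format <- "tpa-state-table/1"

#' Read and write state-table files
#'
#' The canonical file format is a small JSON document:
#' ```
#' { "format": "tpa-state-table/1",
#'   "units": {"energy": "eV|hartree|cm-1", "dipole": "debye|au"},
#'   "energy_reference": "ground|absolute",
#'   "states": [{"index": 0, "label": "S0"}, ...],
#'   "energies": [ ... n values ... ],
#'   "dipoles": [[ [x,y,z] x n ] x n ] }
#' ```
#' On load, energies are normalized to ground-relative Hartree and dipoles
#' to atomic units according to the declared units, and all `state_table`
#' invariants are enforced. `write_state_table()` emits exactly this schema
#' (in Hartree/a.u.) at full precision, so a save/load round trip
#' reproduces the table to machine precision.
#'
#' @param path file path.
#' @param x a `state_table`.
#' @return `load_state_table()` returns a `state_table`;
#'   `write_state_table()` returns `path` invisibly.
#' @export
load_state_table <- function(path) {
  if (!file.exists(path)) stop("state-table file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse ", path, " as JSON: ",
                                           conditionMessage(e), call. = FALSE))
  .field <- function(name) {
    if (is.null(doc[[name]]))
      stop("state-table file ", path, ": missing field \"", name, "\"", call. = FALSE)
    doc[[name]]
  }
  if (!identical(.field("format"), .st_format))
    stop("state-table file ", path, ": field \"format\" must be \"", .st_format, "\"",
         call. = FALSE)
  units <- .field("units")
  eu <- tolower(units$energy %||% stop("missing units.energy", call. = FALSE))
  du <- tolower(units$dipole %||% stop("missing units.dipole", call. = FALSE))
  if (!eu %in% c("ev", "hartree", "cm-1"))
    stop("units.energy must be one of eV, hartree, cm-1; got \"", eu, "\"", call. = FALSE)
  if (!du %in% c("debye", "au"))
    stop("units.dipole must be \"debye\" or \"au\"; got \"", du, "\"", call. = FALSE)
  ref <- .field("energy_reference")
  if (!ref %in% c("ground", "absolute"))
    stop("energy_reference must be \"ground\" or \"absolute\"; got \"", ref, "\"",
         call. = FALSE)
  energies <- as.numeric(.field("energies"))
  n <- length(energies)
  dip <- .field("dipoles")
  if (is.list(dip)) dip <- simplify2array(dip)
  dip <- array(as.numeric(dip), dim = dim(dip))
  if (length(dip) != n * n * 3L)
    stop("field \"dipoles\" must hold n x n dipole 3-vectors with n = ", n, call. = FALSE)
  # fromJSON reads [[ [x,y,z] x n ] x n ] as an n x n x 3 array (row, col, component)
  dim(dip) <- c(n, n, 3L)
  labels <- NULL
  states <- doc$states
  if (!is.null(states) && !is.null(states$label)) labels <- states$label
  e_ha <- energy_convert(energies - if (ref == "absolute") energies[1L] else 0,
                         eu, "hartree")
  d_au <- if (du == "debye") debye_to_au(dip) else dip
  prov <- doc$provenance
  state_table(e_ha, d_au, labels = labels,
              provenance = if (is.null(prov)) list(file = path) else as.list(prov))
}

#' @rdname load_state_table
#' @export
write_state_table <- function(x, path) {
  stopifnot(inherits(x, "state_table"))
  n <- n_states(x)
  dip <- lapply(seq_len(n), function(p)
    lapply(seq_len(n), function(q) x$dipoles[p, q, ]))
  doc <- list(
    format = .st_format,
    units = list(energy = "hartree", dipole = "au"),
    energy_reference = "ground",
    states = data.frame(index = seq_len(n) - 1L, label = x$labels),
    energies = x$energies,
    dipoles = dip
  )
  if (length(x$provenance)) doc$provenance <- x$provenance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
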