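#' Physical constants for two-photon absorption calculations
#'
#' A read-only list of CODATA 2018 constants and derived conversion factors
#' used throughout the package. All cross-section formulas are evaluated in
#' Hartree atomic units internally; these constants define the boundaries to
#' laboratory units (eV, nm, cm-1, Debye, Goeppert-Mayer).
#'
#' @format A named list:
#' \describe{
#'   \item{bohr_radius_cm}{Bohr radius \eqn{a_0} in cm.}
#'   \item{fine_structure_constant}{Fine structure constant \eqn{\alpha}
#'     (dimensionless); in atomic units the speed of light is \eqn{1/\alpha}.}
#'   \item{hartree_in_ev}{1 Hartree in eV.}
#'   \item{debye_in_au}{1 Debye in atomic units of dipole moment.}
#'   \item{atomic_time_s}{Atomic unit of time \eqn{t_0} in seconds.}
#'   \item{ev_nm_product}{\eqn{hc} in eV nm, fixed at 1239.842 so that
#'     nm round trips are bit-reproducible.}
#'   \item{ev_in_wavenumbers}{Wavenumbers (cm-1) per eV.}
#'   \item{tpa_au_in_gm}{The atomic unit of TPA cross-section,
#'     \eqn{a_0^4 t_0}, expressed in GM (1 GM = 1e-50 cm^4 s/photon);
#'     approximately 1.897.}
#' }
#' @examples
#' tpa_constants$tpa_au_in_gm
#' @export
tpa_constants <- local({
  a0 <- 5.29177210903e-9    # cm
  t0 <- 2.4188843265857e-17 # s
  list(
    bohr_radius_cm          = a0,
    fine_structure_constant = 7.2973525693e-3,
    hartree_in_ev           = 27.211386245988,
    debye_in_au             = 0.3934303,
    atomic_time_s           = t0,
    ev_nm_product           = 1239.842,
    ev_in_wavenumbers       = 8065.544,
    tpa_au_in_gm            = a0^4 * t0 / 1e-50
  )
})

.assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Convert dipole moments between Debye and atomic units
#'
#' @param value numeric vector of dipole moments.
#' @return The converted dipole moment(s).
#' @examples
#' debye_to_au(10.5)  # 4.131 a.u., the EGFP transition dipole
#' au_to_debye(debye_to_au(1))
#' @export
debye_to_au <- function(value) {
  .assert_finite(value, "dipole value")
  value * tpa_constants$debye_in_au
}

#' @rdname debye_to_au
#' @export
au_to_debye <- function(value) {
  .assert_finite(value, "dipole value")
  value / tpa_constants$debye_in_au
}

.energy_units <- c("ev", "hartree", "nm", "cm-1")

.normalize_energy_unit <- function(unit) {
  u <- tolower(unit)
  u[u %in% c("cm^-1", "wavenumber", "1/cm")] <- "cm-1"
  if (!all(u %in% .energy_units))
    stop("unknown energy unit: ", paste(setdiff(u, .energy_units), collapse = ", "),
         " (known: ", paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  u
}

#' Convert energies between eV, Hartree, nm and wavenumbers
#'
#' Conversions route through eV, so any composition of conversions is
#' path-independent. Wavelengths relate to energy reciprocally via
#' hc = 1239.842 eV nm; nm values must be strictly positive.
#'
#' @param value numeric vector of energies (or wavelengths for `from = "nm"`).
#' @param from,to unit tokens, one of `"ev"`, `"hartree"`, `"nm"`, `"cm-1"`.
#' @return numeric vector in the `to` unit.
#' @examples
#' energy_convert(2.52, "ev", "nm")   # EGFP vertical excitation: 492 nm
#' energy_convert(2.43, "ev", "nm")   # EGFP T203I: 510 nm
#' @export
energy_convert <- function(value, from, to) {
  .assert_finite(value, "energy value")
  from <- .normalize_energy_unit(from)
  to <- .normalize_energy_unit(to)
  if (from == "nm" && any(value <= 0))
    stop("wavelength must be positive", call. = FALSE)
  ev <- switch(from,
    ev = value,
    hartree = value * tpa_constants$hartree_in_ev,
    nm = tpa_constants$ev_nm_product / value,
    `cm-1` = value / tpa_constants$ev_in_wavenumbers
  )
  if (to == "nm" && any(ev <= 0))
    stop("energy must be positive to convert to a wavelength", call. = FALSE)
  switch(to,
    ev = ev,
    hartree = ev / tpa_constants$hartree_in_ev,
    nm = tpa_constants$ev_nm_product / ev,
    `cm-1` = ev * tpa_constants$ev_in_wavenumbers
  )
}

#' Spectral shift between two wavelengths, in wavenumbers
#'
#' Returns `1e7/lambda_a - 1e7/lambda_b` (cm-1), positive when `lambda_a`
#' is the bluer of the two. Used e.g. for the calculated EGFP (492 nm) vs
#' EGFP T203I (510 nm) red shift of about 720 cm-1.
#'
#' @param lambda_a,lambda_b wavelengths in nm, both positive.
#' @return shift in cm-1.
#' @examples
#' wavenumber_shift(492, 510)  # ~717 cm-1
#' wavenumber_shift(488, 507)  # ~768 cm-1 (experimental absorption maxima)
#' @export
wavenumber_shift <- function(lambda_a, lambda_b) {
  .assert_finite(lambda_a, "lambda_a"); .assert_finite(lambda_b, "lambda_b")
  if (any(lambda_a <= 0) || any(lambda_b <= 0))
    stop("wavelengths must be positive", call. = FALSE)
  1e7 / lambda_a - 1e7 / lambda_b
}

#' Convert a TPA cross-section from atomic units to GM
#'
#' The atomic unit of the two-photon cross-section is \eqn{a_0^4 t_0};
#' 1 GM is 1e-50 cm^4 s/photon, so 1 a.u. is about 1.897 GM.
#'
#' @param value cross-section(s) in atomic units.
#' @return cross-section(s) in GM.
#' @export
sigma_au_to_gm <- function(value) {
  .assert_finite(value, "cross-section")
  value * tpa_constants$tpa_au_in_gm
}

#' @rdname sigma_au_to_gm
#' @export
sigma_gm_to_au <- function(value) {
  .assert_finite(value, "cross-section")
  value / tpa_constants$tpa_au_in_gm
}
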