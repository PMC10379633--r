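#' Lineshape functions for cross-section conversion
#'
#' The phenomenological lineshape `g` turns a rotationally averaged TPA
#' strength into a peak cross-section. `gamma_ev` is the half-width at
#' half-maximum (HWHM) in eV — not the FWHM, a common source of factor-of-2
#' confusion. Both kinds are area-normalized over energy, so `g` has units
#' of inverse energy; the Lorentzian peak value is `1/(pi * Gamma)`.
#'
#' @param kind `"lorentzian"` (default, the conventional choice for
#'   homogeneous electronic broadening) or `"gaussian"`.
#' @param gamma_ev HWHM in eV, positive. Default 0.1 eV.
#' @return An object of class `lineshape`.
#' @export
lineshape <- function(kind = c("lorentzian", "gaussian"), gamma_ev = 0.1) {
  kind <- match.arg(kind)
  .assert_finite(gamma_ev, "gamma_ev")
  if (gamma_ev <= 0) stop("gamma_ev (HWHM) must be positive", call. = FALSE)
  structure(list(kind = kind, gamma_ev = gamma_ev), class = "lineshape")
}

#' @rdname lineshape
#' @param shape a `lineshape`.
#' @param energy,center energies in eV at which the normalized lineshape is
#'   evaluated and centered.
#' @return `lineshape_value()`: the lineshape value in 1/eV.
#' @export
lineshape_value <- function(shape, energy, center) {
  stopifnot(inherits(shape, "lineshape"))
  g <- shape$gamma_ev
  switch(shape$kind,
    lorentzian = (g / pi) / ((energy - center)^2 + g^2),
    gaussian = stats::dnorm(energy, mean = center, sd = g / sqrt(2 * log(2)))
  )
}

#' Linear-parallel polarization setting
#'
#' Coefficients of the isotropic rotational average for two identical
#' linearly polarized photons: F = G = H = 2. This is the only built-in
#' polarization case.
#'
#' @return An object of class `polarization` with elements `F`, `G`, `H`.
#' @export
linear_polarization <- function() {
  structure(list(F = 2, G = 2, H = 2), class = "polarization")
}

.new_tpa_tensor <- function(s, photon_energy, final_state, model) {
  dimnames(s) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(list(s = s, photon_energy = photon_energy,
                 final_state = final_state, model = model),
            class = "tpa_tensor")
}

#' @export
print.tpa_tensor <- function(x, ...) {
  cat(sprintf("tpa_tensor (%s, final state S%d, photon energy %.4f eV)\n",
              x$model, x$final_state - 1L,
              energy_convert(x$photon_energy, "hartree", "ev")))
  print(round(x$s, 4))
  invisible(x)
}

#' Two-level TPA transition tensor
#'
#' The two-level model keeps only the initial and final states in the
#' sum over states; at the resonant condition the tensor reduces to
#' \deqn{S^{\alpha\beta} = (\Delta\mu^\alpha \mu^\beta +
#'       \Delta\mu^\beta \mu^\alpha)/\hbar\omega,}
#' where \eqn{\mu} is the transition dipole, \eqn{\Delta\mu} the
#' permanent-dipole difference and \eqn{\hbar\omega} the photon energy.
#'
#' @param dmu permanent-dipole-difference 3-vector, a.u.
#' @param mu transition-dipole 3-vector, a.u.
#' @param photon_energy photon energy in Hartree, positive.
#' @param final_state metadata: 1-based index of the final state.
#' @return A `tpa_tensor` (3x3 symmetric matrix in a.u., plus metadata).
#' @export
tpa_tensor_tlm <- function(dmu, mu, photon_energy, final_state = 2L) {
  .assert_finite(dmu, "dmu"); .assert_finite(mu, "mu")
  stopifnot(length(dmu) == 3L, length(mu) == 3L)
  if (!is.finite(photon_energy) || photon_energy <= 0)
    stop("photon energy must be positive", call. = FALSE)
  s <- (outer(dmu, mu) + outer(mu, dmu)) / photon_energy
  .new_tpa_tensor(s, photon_energy, final_state, "tlm")
}

#' N-level TPA transition tensor
#'
#' Truncated sum-over-states tensor for the transition to `final`. The
#' initial- and final-state terms are always included (at the resonant
#' condition they combine into the two-level term
#' \eqn{(\Delta\mu^\alpha\mu^\beta + \Delta\mu^\beta\mu^\alpha)/\hbar\omega});
#' the `N - 2` lowest-energy remaining states enter as intermediates with
#' energy denominators \eqn{E_i - E_0 - \hbar\omega}. An intermediate whose
#' denominator vanishes (a one-photon resonance) raises an error rather
#' than returning a misleadingly divergent tensor.
#'
#' @param states a [state_table()].
#' @param final 1-based final state index (default 2, the S0 -> S1
#'   transition).
#' @param N number of states in the truncation, `2 <= N <= n_states`;
#'   default all states.
#' @param photon_energy photon energy in Hartree; default the resonant
#'   value `(E_final - E_0)/2`.
#' @return A `tpa_tensor`.
#' @export
tpa_tensor_nlm <- function(states, final = 2L, N = NULL,
                           photon_energy = NULL) {
  stopifnot(inherits(states, "state_table"))
  n <- n_states(states)
  if (is.null(N)) N <- n
  if (N < 2L || N > n) stop("N must satisfy 2 <= N <= n_states", call. = FALSE)
  if (final < 2L || final > n) stop("final state index out of range", call. = FALSE)
  e <- states$energies
  if (is.null(photon_energy)) photon_energy <- (e[final] - e[1L]) / 2
  if (!is.finite(photon_energy) || photon_energy <= 0)
    stop("photon energy must be positive", call. = FALSE)
  dmu <- delta_dipole(states, final)
  mu <- state_dipole(states, final, 1L)
  s <- (outer(dmu, mu) + outer(mu, dmu)) / photon_energy
  intermediates <- utils::head(setdiff(seq_len(n), c(1L, final)), N - 2L)
  for (i in intermediates) {
    denom <- e[i] - e[1L] - photon_energy
    if (abs(denom) < 1e-8)
      stop(sprintf("one-photon resonance with intermediate state S%d (|E_i - E_0 - hw| = %.2g Hartree)",
                   i - 1L, abs(denom)), call. = FALSE)
    mni <- state_dipole(states, final, i)
    mi0 <- state_dipole(states, i, 1L)
    s <- s + (outer(mni, mi0) + outer(mi0, mni)) / denom
  }
  model <- if (N == 2L) "tlm" else sprintf("nlm(%d)", N)
  .new_tpa_tensor(s, photon_energy, final, model)
}

#' Rotationally averaged TPA strength from a tensor
#'
#' Contracts a TPA tensor into the three invariant combinations
#' \eqn{\delta_F = (\sum_\alpha S^{\alpha\alpha})^2},
#' \eqn{\delta_G = \sum_{\alpha\beta} (S^{\alpha\beta})^2},
#' \eqn{\delta_H = \sum_{\alpha\beta} S^{\alpha\beta} S^{\beta\alpha}}
#' and forms the isotropic average
#' \eqn{\langle\delta\rangle = (F\delta_F + G\delta_G + H\delta_H)/30}.
#' For real symmetric tensors \eqn{\delta_G = \delta_H} identically and
#' the linear-parallel average is non-negative.
#'
#' @param tensor a `tpa_tensor`.
#' @param polarization a polarization setting; only [linear_polarization()]
#'   is built in.
#' @return An object of class `tpa_strength` with elements `delta_f`,
#'   `delta_g`, `delta_h`, `delta_avg` (all a.u.) and `polarization`.
#' @export
rotational_average <- function(tensor, polarization = linear_polarization()) {
  stopifnot(inherits(tensor, "tpa_tensor"))
  s <- tensor$s
  delta_f <- sum(diag(s))^2
  delta_g <- sum(s * s)
  delta_h <- sum(s * t(s))
  delta_avg <- (polarization$F * delta_f + polarization$G * delta_g +
                polarization$H * delta_h) / 30
  structure(list(delta_f = delta_f, delta_g = delta_g, delta_h = delta_h,
                 delta_avg = delta_avg, polarization = polarization),
            class = "tpa_strength")
}

#' @export
print.tpa_strength <- function(x, ...) {
  cat(sprintf("tpa_strength: <delta> = %.6g a.u. (dF = %.6g, dG = %.6g, dH = %.6g; F=G=H=%g)\n",
              x$delta_avg, x$delta_f, x$delta_g, x$delta_h, x$polarization$F))
  invisible(x)
}

#' Closed-form two-level TPA strength
#'
#' For two identical linearly polarized photons the two-level strength has
#' the closed form
#' \deqn{\langle\delta\rangle = \frac{8}{30}\,
#'   |\Delta\mu|^2 |\mu|^2 (2\cos^2\theta + 1)/\omega^2}
#' (atomic units), with the photon energy at resonance,
#' \eqn{\omega = VEE/2}. The 1/30 isotropic-averaging normalization is
#' included so that the closed form agrees with the tensor route
#' ([tpa_tensor_tlm()] followed by [rotational_average()]) to machine
#' precision.
#'
#' @param mu10 transition dipole magnitude, Debye.
#' @param dmu10 permanent-dipole-difference magnitude, Debye.
#' @param theta angle between the two vectors, degrees.
#' @param vee vertical excitation energy, eV.
#' @return The strength in atomic units.
#' @examples
#' tlm_strength_closed_form(10.5, 4.4, 0, 2.52)  # EGFP: ~1.91e4 a.u.
#' @export
tlm_strength_closed_form <- function(mu10, dmu10, theta = 0, vee) {
  spec <- two_level_spec(mu10, dmu10, vee, theta)
  omega <- energy_convert(spec$vee / 2, "ev", "hartree")
  mu <- debye_to_au(spec$mu10)
  dmu <- debye_to_au(spec$dmu10)
  cth <- cos(spec$theta * pi / 180)
  (8 / 30) * dmu^2 * mu^2 * (2 * cth^2 + 1) / omega^2
}

#' Macroscopic TPA cross-section in GM
#'
#' Converts a rotationally averaged strength into a cross-section,
#' \deqn{\sigma = 4\pi^3 \alpha^2 \omega^2\, g\, \langle\delta\rangle}
#' in atomic units (the \eqn{a_0^5 \alpha / c} prefactor collapses to
#' \eqn{\alpha^2} because \eqn{c = 1/\alpha} in a.u.), then to GM. By
#' default the lineshape is evaluated at its peak, i.e. at the resonant
#' condition where the two photon energies sum to the transition energy;
#' supplying `transition_energy_ev` instead evaluates `g` at the detuned
#' position `2 * photon_energy_ev`.
#'
#' @param delta_avg rotationally averaged strength, a.u., non-negative.
#' @param photon_energy_ev photon energy in eV, positive.
#' @param shape a [lineshape()]; default Lorentzian with HWHM 0.1 eV.
#' @param transition_energy_ev optional transition energy `E_n - E_0` in eV
#'   for off-resonance evaluation; `NULL` (default) means resonant.
#' @return Cross-section in GM.
#' @examples
#' cross_section(19262, 1.26)  # EGFP two-level strength -> ~44.8 GM
#' @export
cross_section <- function(delta_avg, photon_energy_ev, shape = lineshape(),
                          transition_energy_ev = NULL) {
  .assert_finite(delta_avg, "delta_avg")
  if (delta_avg < 0) stop("delta_avg must be non-negative", call. = FALSE)
  if (!is.finite(photon_energy_ev) || photon_energy_ev <= 0)
    stop("photon energy must be positive", call. = FALSE)
  g_ev <- if (is.null(transition_energy_ev)) {
    lineshape_value(shape, 0, 0)           # peak value
  } else {
    lineshape_value(shape, 2 * photon_energy_ev, transition_energy_ev)
  }
  g_au <- g_ev * tpa_constants$hartree_in_ev
  omega <- energy_convert(photon_energy_ev, "ev", "hartree")
  alpha <- tpa_constants$fine_structure_constant
  sigma_au <- 4 * pi^3 * alpha^2 * omega^2 * g_au * delta_avg
  sigma_au_to_gm(sigma_au)
}

#' Full TPA calculation on a state table
#'
#' Convenience front end combining tensor construction, rotational
#' averaging and unit conversion into one `tpa_result`.
#'
#' @inheritParams tpa_tensor_nlm
#' @param model `"nlm"` (default; `N` states, all by default) or `"tlm"`.
#' @param shape a [lineshape()].
#' @param photon_energy_ev photon energy in eV; default resonant,
#'   `(E_final - E_0)/2`.
#' @param polarization a polarization setting.
#' @return An object of class `tpa_result`: the strength, `sigma_gm`, the
#'   photon energy in eV, the lineshape and model metadata.
#' @examples
#' compute_tpa(builtin_fixture("egfp"), model = "tlm")
#' @export
compute_tpa <- function(states, final = 2L, model = c("nlm", "tlm"), N = NULL,
                        photon_energy_ev = NULL, shape = lineshape(),
                        polarization = linear_polarization()) {
  model <- match.arg(model)
  if (model == "tlm") N <- 2L
  pe <- if (is.null(photon_energy_ev)) NULL
        else energy_convert(photon_energy_ev, "ev", "hartree")
  tensor <- tpa_tensor_nlm(states, final = final, N = N, photon_energy = pe)
  strength <- rotational_average(tensor, polarization)
  pe_ev <- energy_convert(tensor$photon_energy, "hartree", "ev")
  e_trans <- energy_convert(states$energies[final] - states$energies[1L],
                            "hartree", "ev")
  resonant <- abs(2 * pe_ev - e_trans) < 1e-9
  sigma <- cross_section(strength$delta_avg, pe_ev, shape,
                         transition_energy_ev = if (resonant) NULL else e_trans)
  structure(list(strength = strength, sigma_gm = sigma,
                 photon_energy_ev = pe_ev, lineshape = shape,
                 model = tensor$model, final_state = final,
                 resonant = resonant),
            class = "tpa_result")
}

#' @export
print.tpa_result <- function(x, ...) {
  cat(sprintf("tpa_result (%s, final state S%d)\n", x$model, x$final_state - 1L))
  cat(sprintf("  photon energy : %.4f eV%s\n", x$photon_energy_ev,
              if (x$resonant) " (resonant)" else " (off-resonance)"))
  cat(sprintf("  <delta>       : %.4g a.u.\n", x$strength$delta_avg))
  cat(sprintf("  sigma         : %.4g GM  (%s, HWHM %.3g eV)\n",
              x$sigma_gm, x$lineshape$kind, x$lineshape$gamma_ev))
  invisible(x)
}

#' Serialize a TPA result to JSON
#'
#' Writes (or returns) the machine-readable form of a [compute_tpa()]
#' result. The `final_state` field uses the spectroscopic 0-based
#' numbering (S0 = 0), matching the state-table file format.
#'
#' @param x a `tpa_result`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
tpa_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "tpa_result"))
  N <- if (grepl("^nlm", x$model)) as.integer(sub("nlm\\((\\d+)\\)", "\\1", x$model)) else 2L
  doc <- list(
    model = if (x$model == "tlm") "tlm" else "nlm",
    N = N,
    final_state = x$final_state - 1L,
    photon_energy_ev = x$photon_energy_ev,
    delta_f = x$strength$delta_f,
    delta_g = x$strength$delta_g,
    delta_h = x$strength$delta_h,
    delta_avg_au = x$strength$delta_avg,
    sigma_gm = x$sigma_gm,
    lineshape = list(kind = x$lineshape$kind, gamma_ev = x$lineshape$gamma_ev)
  )
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convergence of the N-level truncation
#'
#' Evaluates the truncated sum-over-states cross-section for every
#' `N = 2 .. n_max` at the resonant photon energy, mirroring the usual
#' convergence table of few-state models. The `N = 2` row equals the
#' two-level route exactly.
#'
#' @inheritParams tpa_tensor_nlm
#' @param n_max largest truncation, `<= n_states`; default all states.
#' @param shape a [lineshape()].
#' @return A data frame of class `convergence_table` with columns `N`,
#'   `delta_avg_au`, `sigma_gm`; the photon energy (eV) is attached as the
#'   attribute `photon_energy_ev`.
#' @export
convergence_scan <- function(states, final = 2L, n_max = NULL,
                             shape = lineshape()) {
  stopifnot(inherits(states, "state_table"))
  if (is.null(n_max)) n_max <- n_states(states)
  if (n_max > n_states(states)) stop("n_max exceeds n_states", call. = FALSE)
  rows <- lapply(2:n_max, function(N) {
    r <- compute_tpa(states, final = final, model = "nlm", N = N, shape = shape)
    data.frame(N = N, delta_avg_au = r$strength$delta_avg, sigma_gm = r$sigma_gm)
  })
  out <- do.call(rbind, rows)
  attr(out, "photon_energy_ev") <-
    energy_convert((states$energies[final] - states$energies[1L]) / 2,
                   "hartree", "ev")
  class(out) <- c("convergence_table", "data.frame")
  out
}

#' @rdname convergence_scan
#' @param x a `convergence_table`.
#' @param path output CSV path (header `N,delta_avg_au,sigma_gm`).
#' @export
write_convergence_csv <- function(x, path) {
  stopifnot(inherits(x, "convergence_table"))
  utils::write.csv(as.data.frame(x)[c("N", "delta_avg_au", "sigma_gm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.convergence_table <- function(x, ...) {
  cat(sprintf("N-level convergence (photon energy %.4f eV)\n",
              attr(x, "photon_energy_ev")))
  cat("  N  sigma_GM (delta, a.u.)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %d  %d (%s)\n", x$N[i], round(x$sigma_gm[i]),
                format(signif(x$delta_avg_au[i], 4), big.mark = ",")))
  invisible(x)
}

#' Monte-Carlo orientation average of a TPA tensor
#'
#' Independent numerical check of the analytic isotropic average: for two
#' identical linearly polarized photons the averaged strength equals
#' \eqn{\langle (\lambda^T S \lambda)^2 \rangle} over uniformly random unit
#' polarization directions \eqn{\lambda}. Seeded and reproducible; the
#' standard error of the estimate is reported.
#'
#' @param tensor a `tpa_tensor`.
#' @param n_orientations number of random orientations (>= 1000).
#' @param seed integer seed.
#' @return A list with `estimate`, `se` (standard error) and `n`.
#' @export
numeric_rotational_average <- function(tensor, n_orientations = 1e5, seed = 1) {
  stopifnot(inherits(tensor, "tpa_tensor"))
  if (n_orientations < 1000) stop("use at least 1000 orientations", call. = FALSE)
  n <- as.integer(n_orientations)
  .with_seed(seed, {
    l <- matrix(stats::rnorm(3L * n), ncol = 3L)
    l <- l / sqrt(rowSums(l^2))
    q <- rowSums((l %*% tensor$s) * l)^2   # (lambda^T S lambda)^2 per row
    list(estimate = mean(q), se = stats::sd(q) / sqrt(n), n = n)
  })
}
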