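omega_ha <- function(vee_ev) energy_convert(vee_ev / 2, "ev", "hartree")

test_that("the two-level tensor reduces correctly in closed-form cases", {
  w <- omega_ha(2.52)
  z <- tpa_tensor_tlm(c(0, 0, 0), c(1, 2, 3), w)
  expect_identical(unname(z$s), matrix(0, 3, 3))

  dmu <- c(1.7, 0, 0); mu <- c(4.1, 0, 0)
  t1 <- tpa_tensor_tlm(dmu, mu, w)
  expect_equal(t1$s[["x", "x"]], 2 * 1.7 * 4.1 / w, tolerance = 1e-14)
  expect_equal(sum(abs(t1$s)) - abs(t1$s[["x", "x"]]), 0)

  t2 <- tpa_tensor_tlm(c(1, 2, -1), c(0.5, -3, 2), w)
  expect_identical(unname(t2$s), unname(t(t2$s)))
  expect_error(tpa_tensor_tlm(dmu, mu, -0.1), "positive")
})

test_that("the N-level tensor with N = 2 equals the two-level route", {
  for (s in c(4, 13)) {
    st <- random_state_table(6, seed = s)
    tn <- tpa_tensor_nlm(st, N = 2)
    tt <- tpa_tensor_tlm(delta_dipole(st), state_dipole(st, 2, 1),
                         (st$energies[2] - st$energies[1]) / 2)
    expect_equal(tn$s, tt$s, tolerance = 1e-15)
  }
})

test_that("the full truncation matches a brute-force sum-over-states oracle", {
  for (s in 1:20) {
    n <- c(5, 6, 7)[1 + (s %% 3)]
    st <- random_state_table(n, seed = s)
    w <- (st$energies[2] - st$energies[1]) / 2
    impl <- tpa_tensor_nlm(st, final = 2, N = n, photon_energy = w)
    oracle <- brute_force_sos_tensor(st, final = 2, omega = w)
    expect_equal(unname(impl$s), oracle, tolerance = 1e-12)
  }
})

test_that("vanishing intermediate couplings make the tensor N-independent", {
  st <- tlm_dominant_table(n_states = 5, coupling_scale = 0, seed = 1)
  tensors <- lapply(2:5, function(N) tpa_tensor_nlm(st, N = N)$s)
  for (k in 2:4) expect_identical(tensors[[k]], tensors[[1]])
})

test_that("a one-photon resonance with an intermediate state is refused", {
  st <- from_two_level(5, 2, 2.0)
  e_fin <- st$energies[2]
  d <- array(0, dim = c(3, 3, 3))
  d[1, 3, ] <- d[3, 1, ] <- st$dipoles[1, 2, ]   # transition dipole to final
  d[3, 3, ] <- st$dipoles[2, 2, ]                # final-state permanent dipole
  d[1, 2, ] <- d[2, 1, ] <- c(0.1, 0, 0)
  d[2, 3, ] <- d[3, 2, ] <- c(0.1, 0, 0)
  # intermediate exactly at half the transition energy = the photon energy
  bad <- state_table(c(0, e_fin / 2, e_fin), d)
  expect_error(tpa_tensor_nlm(bad, final = 3, N = 3),
               "one-photon resonance with intermediate state S1")
  expect_error(tpa_tensor_nlm(st, N = 5), "N must satisfy")
})

test_that("rotational averaging matches closed-form and Monte-Carlo oracles", {
  iso <- tpa_tensor_tlm(c(1, 0, 0), c(1, 0, 0), 1)  # container only
  iso$s <- diag(3)
  expect_equal(rotational_average(iso)$delta_avg,
               sphere_average_closed_form(diag(3)), tolerance = 1e-14)

  zero <- iso; zero$s <- matrix(0, 3, 3)
  r0 <- rotational_average(zero)
  expect_identical(c(r0$delta_f, r0$delta_g, r0$delta_h, r0$delta_avg),
                   rep(0, 4))
  expect_identical(numeric_rotational_average(zero, 1e3, seed = 1)$estimate, 0)

  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(9), 3)
    sym <- iso; sym$s <- (m + t(m)) / 2
    r <- rotational_average(sym)
    expect_identical(r$delta_g, r$delta_h)
    expect_gte(r$delta_avg, 0)
    expect_equal(r$delta_avg, sphere_average_closed_form(sym$s),
                 tolerance = 1e-12)
    mc <- numeric_rotational_average(sym, 1e5, seed = rep)
    expect_lt(abs(mc$estimate - r$delta_avg), 3 * mc$se)
  }
})

test_that("the closed-form two-level strength equals the tensor route", {
  cases <- rbind(c(10.5, 4.4, 0, 2.52), c(10.9, 2.5, 0, 2.43),
                 c(10.5, 2.9, 0, 2.62), c(3.3, 1.2, 57, 4.1),
                 c(8, 8, 120, 1.5))
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, ]
    closed <- tlm_strength_closed_form(p[1], p[2], p[3], p[4])
    st <- from_two_level(p[1], p[2], p[4], theta = p[3])
    route <- rotational_average(tpa_tensor_nlm(st, N = 2))$delta_avg
    expect_equal(closed, route, tolerance = 1e-12)
  }
})

test_that("orthogonal and parallel dipole-difference geometries differ by 3x", {
  r <- tlm_strength_closed_form(6, 2, 0, 3) / tlm_strength_closed_form(6, 2, 90, 3)
  expect_equal(r, 3, tolerance = 1e-12)
})

test_that("lineshapes are normalized with the stated peak and half-maximum", {
  lor <- lineshape("lorentzian", 0.1)
  peak <- lineshape_value(lor, 2.52, 2.52)
  expect_equal(peak, 1 / (0.1 * pi), tolerance = 1e-14)
  expect_equal(lineshape_value(lor, 2.52 + 0.1, 2.52), peak / 2, tolerance = 1e-12)
  expect_equal(lineshape_value(lor, 2.52 - 0.1, 2.52), peak / 2, tolerance = 1e-12)

  gau <- lineshape("gaussian", 0.1)
  expect_equal(lineshape_value(gau, 0.1, 0), lineshape_value(gau, 0, 0) / 2,
               tolerance = 1e-12)
  for (shape in list(lor, gau)) {
    area <- stats::integrate(function(e) lineshape_value(shape, e, 0),
                             -Inf, Inf)$value
    expect_equal(area, 1, tolerance = 1e-6)
  }
  # truncated quadrature of the Lorentzian agrees with its closed form
  trunc <- stats::integrate(function(e) lineshape_value(lor, e, 0),
                            -50 * 0.1, 50 * 0.1)$value
  expect_equal(trunc, (2 / pi) * atan(50), tolerance = 1e-6)
  expect_error(lineshape("lorentzian", 0), "positive")
})

test_that("the cross-section is linear in strength and lineshape peak", {
  sh <- lineshape("lorentzian", 0.1)
  expect_identical(cross_section(0, 1.26, sh), 0)
  s1 <- cross_section(1000, 1.26, sh)
  expect_equal(cross_section(2000, 1.26, sh), 2 * s1, tolerance = 1e-14)
  # halving the HWHM doubles the resonant Lorentzian cross-section
  expect_equal(cross_section(1000, 1.26, lineshape("lorentzian", 0.05)),
               2 * s1, tolerance = 1e-14)
  expect_lt(cross_section(1000, 1.26, sh, transition_energy_ev = 2.8), s1)
  expect_error(cross_section(-1, 1.26, sh), "non-negative")
})

test_that("the convergence scan starts at the two-level row and hits the oracle", {
  # degenerate scan on a two-state system: a single row, equal to the TLM route
  egfp <- builtin_fixture("egfp")
  tab <- convergence_scan(egfp)
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$delta_avg_au[1],
                   rotational_average(tpa_tensor_nlm(egfp, N = 2))$delta_avg)

  st <- random_state_table(7, seed = 1)
  tab <- convergence_scan(st)
  expect_identical(tab$N, 2:7)
  w <- (st$energies[2] - st$energies[1]) / 2
  oracle <- brute_force_sos_tensor(st, final = 2, omega = w)
  t7 <- tpa_tensor_nlm(st, N = 7)
  expect_equal(unname(t7$s), oracle, tolerance = 1e-12)
  expect_identical(tab$delta_avg_au[6], rotational_average(t7)$delta_avg)
})

test_that("a TLM-dominant system converges flat across truncation orders", {
  tab <- convergence_scan(tlm_dominant_table(n_states = 7, seed = 3))
  spread <- (max(tab$sigma_gm) - min(tab$sigma_gm)) / min(tab$sigma_gm)
  expect_lte(spread, 0.05)
})

test_that("strengths and cross-sections are invariant under rigid rotation", {
  set.seed(21)
  for (s in c(2, 9)) {
    st <- random_state_table(5, seed = s)
    rot <- random_rotation()
    st_r <- rotate_state_table(st, rot)
    a <- compute_tpa(st, model = "nlm")
    b <- compute_tpa(st_r, model = "nlm")
    for (f in c("delta_f", "delta_g", "delta_h", "delta_avg"))
      expect_equal(b$strength[[f]], a$strength[[f]], tolerance = 1e-10)
    expect_equal(b$sigma_gm, a$sigma_gm, tolerance = 1e-10)
  }
})

test_that("two-level strength scales as the fourth power of the dipoles", {
  base <- tlm_strength_closed_form(4, 2, 25, 3)
  for (k in c(0.5, 2, 3))
    expect_equal(tlm_strength_closed_form(4 * k, 2 * k, 25, 3), k^4 * base,
                 tolerance = 1e-12)
})

test_that("only the permanent-dipole difference enters the two-level result", {
  st <- from_two_level(7, 3, 2.8, theta = 40)
  shifted <- st
  shift <- c(0.3, -1.1, 0.7)
  shifted$dipoles[1, 1, ] <- shifted$dipoles[1, 1, ] + shift
  shifted$dipoles[2, 2, ] <- shifted$dipoles[2, 2, ] + shift
  a <- rotational_average(tpa_tensor_nlm(st, N = 2))$delta_avg
  b <- rotational_average(tpa_tensor_nlm(shifted, N = 2))$delta_avg
  expect_equal(b, a, tolerance = 1e-12)
})

test_that("results serialize to the documented JSON layout", {
  r <- compute_tpa(builtin_fixture("egfp"), model = "tlm")
  path <- withr::local_tempfile(fileext = ".json")
  tpa_result_json(r, path)
  doc <- jsonlite::fromJSON(path)
  expect_identical(doc$model, "tlm")
  expect_identical(doc$N, 2L)
  expect_identical(doc$final_state, 1L)
  expect_equal(doc$sigma_gm, r$sigma_gm, tolerance = 1e-12)
  expect_identical(doc$lineshape$kind, "lorentzian")
  expect_equal(doc$lineshape$gamma_ev, 0.1)

  tab <- convergence_scan(random_state_table(4, seed = 8))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_convergence_csv(tab, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("N", "delta_avg_au", "sigma_gm"))
  expect_equal(back$sigma_gm, tab$sigma_gm, tolerance = 1e-12)
})
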