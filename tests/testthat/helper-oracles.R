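# Independent oracles, deliberately written as plain term-by-term loops so
# they share no code path with the package implementation.

# Full sum-over-states TPA tensor: every state enters as an "intermediate",
# including the ground state (denominator -omega) and the final state
# (denominator E_n - E_0 - omega). Agrees with the package's truncated form
# only at the resonant photon energy omega = (E_n - E_0)/2.
brute_force_sos_tensor <- function(st, final, omega) {
  n <- length(st$energies)
  s <- matrix(0, 3L, 3L)
  for (i in seq_len(n)) {
    mni <- st$dipoles[final, i, ]
    mi0 <- st$dipoles[i, 1L, ]
    denom <- st$energies[i] - st$energies[1L] - omega
    for (a in 1:3) {
      for (b in 1:3) {
        s[a, b] <- s[a, b] + (mni[a] * mi0[b] + mni[b] * mi0[a]) / denom
      }
    }
  }
  s
}

# Closed-form isotropic average of (lambda^T S lambda)^2 for a symmetric
# tensor, from <l_a l_b l_c l_d> = (d_ab d_cd + d_ac d_bd + d_ad d_bc)/15.
sphere_average_closed_form <- function(s) {
  (sum(diag(s))^2 + 2 * sum(s * s)) / 15
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Apply one common rotation to every dipole vector of a state table.
rotate_state_table <- function(st, rot) {
  n <- length(st$energies)
  d <- st$dipoles
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      d[p, q, ] <- as.numeric(rot %*% st$dipoles[p, q, ])
    }
  }
  state_table(st$energies, d)
}
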