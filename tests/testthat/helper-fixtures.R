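# shared fixtures built in code

# instantaneous-activation parameters for closed-form oracles: with
# tau_act = 0 the current at step onset equals gmax (V - vrev) m_inf h0
oracle_params <- function(...) {
  gating_params(tau_act = 0, slow_frac = 0, ...)
}

# steep-inactivation parameters so holding sits at ~full availability and
# the pulse voltage at ~zero: the recovery ratio follows 1 - exp(-dt/tau)
recovery_oracle_params <- function(recovery_tau = 10) {
  gating_params(inact_vhalf = -35, inact_k = 2, slow_frac = 0,
                tau_inact_fast = 1.5, tau_inact_slow = 8,
                recovery_tau = recovery_tau)
}

# random two-chain atom cloud for contact tests
random_complex <- function(n_a = 60, n_b = 50, sep = 5, seed = 1) {
  set.seed(seed)
  mk <- function(n, chain, cx, serial0) tibble::tibble(
    serial = serial0 + seq_len(n),
    atom = sample(c("CA", "CB", "N", "O", "CG", "SD"), n, TRUE),
    altloc = "",
    resname = sample(c("ALA", "LEU", "SER", "MET"), n, TRUE),
    chain = chain,
    resno = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    insert = "",
    x = stats::rnorm(n, cx, 4), y = stats::rnorm(n, 0, 4),
    z = stats::rnorm(n, 0, 4),
    element = NA_character_
  )
  a <- mk(n_a, "A", 0, 0)
  b <- mk(n_b, "B", sep, n_a)
  a$element <- substr(a$atom, 1, 1)
  b$element <- substr(b$atom, 1, 1)
  list(receptor = a, ligand = b)
}

# single atom-row helper for geometric fixtures
atom_row <- function(serial, atom, resname, chain, resno, x, y, z,
                     element = substr(atom, 1, 1)) {
  tibble::tibble(serial = serial, atom = atom, altloc = "",
                 resname = resname, chain = chain, resno = resno,
                 insert = "", x = x, y = y, z = z, element = element)
}

# rigid rotation + translation of an atom table
rigid_move <- function(atoms, angles = c(0.3, -0.5, 1.1),
                       shift = c(5, -3, 2)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                             -sin(a), 0, cos(a)), 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, byrow = TRUE)
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
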