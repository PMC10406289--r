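# Independent oracles used by the simulator and metric tests.

# iterated two-pulse recursion for the alternating-phase short-TR steady
# state: hard pulses of the given flip, full relaxation over TR, run to
# convergence; returns |m_xy| at TE after the final pulse.
bssfp_steady_state_oracle <- function(flip = 90, tr = 8, te = 4,
                                      t1 = 1000, t2 = 100, m0 = 1,
                                      iters = 5000) {
  rot <- function(a, p) {
    a <- a * pi / 180; p <- p * pi / 180
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                 3, 3, byrow = TRUE)
    Rz(p) %*% Rx %*% Rz(-p)
  }
  relax <- function(m, dt) c(m[1] * exp(-dt / t2), m[2] * exp(-dt / t2),
                             m0 + (m[3] - m0) * exp(-dt / t1))
  m <- c(0, 0, m0); phase_i <- 0
  for (i in seq_len(iters)) {
    m <- rot(flip, 180 * (phase_i %% 2)) %*% m
    phase_i <- phase_i + 1
    m <- relax(m, tr)
  }
  m <- rot(flip, 180 * (phase_i %% 2)) %*% m
  m <- relax(m, te)
  sqrt(m[1]^2 + m[2]^2)
}

# textbook Pearson correlation over a mask, written out longhand
pcc_oracle <- function(a, b, mask) {
  x <- a[mask]; y <- b[mask]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# brute-force PE shift scan (independent of the package implementation)
shift_scan_oracle <- function(moving, reference, mask) {
  n <- nrow(moving)
  sapply(seq_len(n) - 1L, function(d) {
    idx <- ((seq_len(n) - 1L + d) %% n) + 1L   # rows shifted back by d
    pcc_oracle(moving[idx, , drop = FALSE], reference, mask)
  })
}
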