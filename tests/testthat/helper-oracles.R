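# Independent fixed-step RK4 oracle for dC/dt = A C, written as a plain
# loop so it shares no code path with the package's solvers.
rk4_linear_oracle <- function(A, c0, t_end, dt) {
  n_steps <- round(t_end / dt)
  out <- matrix(NA_real_, n_steps + 1L, length(c0))
  s <- c0
  out[1, ] <- s
  for (i in seq_len(n_steps)) {
    k1 <- A %*% s
    k2 <- A %*% (s + dt / 2 * k1)
    k3 <- A %*% (s + dt / 2 * k2)
    k4 <- A %*% (s + dt * k3)
    s <- s + dt / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- s
  }
  list(times = dt * (0:n_steps), states = out)
}
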