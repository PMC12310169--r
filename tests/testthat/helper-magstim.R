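# Shared oracles for the test suite.

# Direct Biot-Savart quadrature around a single circular filament (1 A),
# independent of the elliptic-integral implementation. Loop of radius a in
# the z = 0 plane; field point at (x = r, y = 0, z).
bs_loop_field <- function(a, r, z, n_seg = 2e4) {
  mu0 <- 4e-7 * pi
  th <- (seq_len(n_seg) - 0.5) / n_seg * 2 * pi
  dth <- 2 * pi / n_seg
  px <- a * cos(th); py <- a * sin(th)
  dlx <- -a * sin(th) * dth; dly <- a * cos(th) * dth
  rx <- r - px; ry <- -py; rz <- z
  rr2 <- rx^2 + ry^2 + rz^2
  f <- mu0 / (4 * pi) / (rr2 * sqrt(rr2))
  c(Br = sum(f * dly * rz),   # Bx at y = 0 is the radial component
    Bz = sum(f * (dlx * ry - dly * rx)))
}

# Ramped-sinusoid current model used to synthesise traces for fitting tests
ramped_sine <- function(t, I0, tau, f, phi = 0) {
  I0 * (1 - exp(-t / tau)) * sin(2 * pi * f * t + phi)
}

make_trace <- function(times, values, kind = "current") {
  structure(list(times = times, values = values, kind = kind),
            class = "waveform_trace")
}

# Binomial log-likelihood of a sigmoid parameter pair, written independently
# of the package's internal likelihood
sigmoid_loglik <- function(amp, y, B_th, B_width) {
  p <- magstim::sigmoid_probability(amp, B_th, B_width)
  sum(stats::dbinom(y, 1, p, log = TRUE))
}
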