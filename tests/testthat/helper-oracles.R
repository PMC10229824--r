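# Independent oracles and small utilities shared across the suite.

nrmse <- function(x, ref) sqrt(mean((x - ref)^2)) / stats::sd(as.vector(ref))

# closed-form alpha kernel, written out independently of the package
alpha_kernel_oracle <- function(t, H, tau, A = 1) A * H / tau * t * exp(-t / tau)

# exact response of one channel to a unit-area Gaussian pulse: fine-grid
# discrete convolution of the analytic kernel with the analytic pulse
gauss_kernel_conv_oracle <- function(t_out, t0, sg, H, tau, dt = 0.002) {
  tt <- seq(0, max(t_out) + 6 * sg, by = dt)
  g <- exp(-(tt - t0)^2 / (2 * sg^2)) / (sg * sqrt(2 * pi))
  k <- alpha_kernel_oracle(tt, H, tau)
  z <- stats::convolve(g, rev(k), type = "open")[seq_along(tt)] * dt
  stats::approx(tt, z, xout = t_out)$y
}

# Independent linearized simulator for the two-source M1 network: Euler
# integration of the channel ODEs with the sigmoid replaced by its slope at
# zero (r / 4). The wiring is hand-coded here from the documented default
# architecture; only the numerical constants are shared with the package.
linear_m1_oracle <- function(amp_scale = 1e-3, dt = 0.02, t_end = 200,
                             out_ms = 1:200) {
  r <- 0.56; slope <- r / 4
  He <- 4; Hi <- 32; te <- 8; ti <- 16
  ext <- 0.05
  # populations: 1 MCN out, 2 MCN ei, 3 MCN ii, 4 PAG out, 5 PAG ei, 6 PAG ii
  conn <- rbind(
    c(2, 1, +1, 0.15, 2), c(1, 2, +1, 0.15, 2), c(1, 3, +1, 0.15, 2),
    c(3, 1, -1, 0.05, 2),
    c(5, 4, +1, 0.15, 2), c(4, 5, +1, 0.15, 2), c(4, 6, +1, 0.15, 2),
    c(6, 4, -1, 0.05, 2),
    c(1, 4, +1, ext * 1, 16),   # MCN -> vlPAG, glutamatergic output target
    c(4, 2, +1, ext * 1, 16))   # vlPAG -> MCN, IO-type onto the relay
  n_steps <- round(t_end / dt)
  # states per population: excitatory channel (v, z), inhibitory channel (v, z)
  ve <- ze <- vi <- zi <- matrix(0, 6, 1)
  comp_hist <- matrix(0, 6, n_steps + 1)
  u_exo <- function(t) amp_scale * 0.25 *
    (exp(-(t - 10)^2 / 128) + exp(-(t - 40)^2 / 128))
  out <- matrix(0, 2, length(out_ms))
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    ue <- numeric(6); ui <- numeric(6)
    for (j in seq_len(nrow(conn))) {
      kd <- k - round(conn[j, 5] / dt)
      vd <- if (kd < 1) 0 else comp_hist[conn[j, 1], kd]
      drive <- conn[j, 4] * slope * vd
      if (conn[j, 3] > 0) ue[conn[j, 2]] <- ue[conn[j, 2]] + drive
      else ui[conn[j, 2]] <- ui[conn[j, 2]] + drive
    }
    ue[2] <- ue[2] + u_exo(t); ue[5] <- ue[5] + u_exo(t)
    ae <- He / te * ue - 2 / te * ze - ve / te^2
    ai <- Hi / ti * ui - 2 / ti * zi - vi / ti^2
    ve <- ve + dt * ze; ze <- ze + dt * ae
    vi <- vi + dt * zi; zi <- zi + dt * ai
    comp_hist[, k + 1] <- ve - vi
  }
  idx <- round(out_ms / dt) + 1
  rbind(MCN = comp_hist[1, idx], vlPAG = comp_hist[4, idx])
}

# helper to build block-averaged noisy datasets the way the cohort does
averaged_dataset <- function(clean, n_trials = 7, snr_db = 10) {
  tr <- make_noisy_trials(clean, n_trials, snr_db)
  erp_pair(clean$time_ms, apply(tr, c(1, 2), mean), n_trials = n_trials)
}

# independent ideal band-limiting of an ERP embedded in a long silent trace
# (mirrors the recording embedding incl. the terminal cosine taper), used as
# the pipeline-fidelity reference
bandlimit_oracle <- function(amp_long, time_ms_long, out_ms, low = 1,
                             high = 32, order = 4, rate = 1000,
                             taper_ms = 50) {
  n <- 20000L
  x <- numeric(n)
  mx <- max(time_ms_long)
  taper <- rep(1, length(time_ms_long))
  sel <- time_ms_long > mx - taper_ms
  taper[sel] <- 0.5 * (1 + cos(pi * (time_ms_long[sel] - (mx - taper_ms)) /
                                 taper_ms))
  x[5000L + time_ms_long] <- amp_long * taper
  f <- (0:(n - 1)) / n * rate
  f <- pmin(f, rate - f)
  om <- ifelse(f > 0, (f^2 - low * high) / (f * (high - low)), Inf)
  y <- Re(stats::fft(stats::fft(x) * (1 / (1 + om^(2 * order))),
                     inverse = TRUE)) / n
  y[5000L + out_ms]
}

# independent log-evidence of the linear-Gaussian second level at fixed g,
# computed directly from the marginal density (user units; for fits built
# with prior_sd = Inf, i.e. no first-level shrinkage removal)
peb_logev_oracle <- function(design, fits, g, prior_var_user,
                             selector = c("A_MCN_to_vlPAG", "A_vlPAG_to_MCN")) {
  X <- design$X
  p <- length(selector)
  M <- t(vapply(fits, function(f) unname(f$posterior$mean[selector]),
                numeric(p)))
  m <- as.vector(t(M))
  W <- kronecker(X, diag(p))
  D <- matrix(0, length(m), length(m))
  for (i in seq_along(fits)) {
    ix <- (i - 1) * p + seq_len(p)
    D[ix, ix] <- as.matrix(fits[[i]]$posterior$cov)[seq_len(p), seq_len(p)] +
      diag(exp(-g), p)
  }
  Sig <- W %*% (prior_var_user * t(W)) + D
  as.numeric(-0.5 * (length(m) * log(2 * pi) +
                       determinant(Sig, logarithm = TRUE)$modulus +
                       t(m) %*% solve(Sig, m)))
}

# minimal stand-in for a dcm_fit, for second-level unit tests
fake_fit <- function(mean, cov, names = names(mean), prior_sd = Inf) {
  structure(list(posterior = list(
    mean = stats::setNames(mean, names),
    cov = as.matrix(cov), names = names,
    prior_sd = stats::setNames(rep(prior_sd, length(mean)), names))),
    class = "dcm_fit")
}
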