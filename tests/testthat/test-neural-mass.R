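# Forward model: sigmoid, alpha kernel, exogenous input, model space,
# network simulation.

test_that("sigmoid_rate matches the closed form and its structural properties", {
  expect_identical(sigmoid_rate(0), 0)
  expect_gt(sigmoid_rate(100), 0.499)
  expect_equal(sigmoid_rate(1), 0.1364525, tolerance = 1e-5)
  v <- seq(-20, 20, by = 0.37)
  expect_equal(sigmoid_rate(-v), -sigmoid_rate(v))          # odd
  expect_true(all(diff(sigmoid_rate(v)) > 0))               # strictly increasing
  expect_true(all(abs(sigmoid_rate(v)) < 0.5))              # bounded
})

test_that("kernel_value is the alpha form: zero at 0, peak at tau, integral A*H*tau", {
  k <- synaptic_kernel(H = 4, tau = 8)
  expect_identical(kernel_value(0, k), 0)
  expect_error(kernel_value(-1, k), "t >= 0")
  tt <- seq(0, 100, by = 1e-3)
  expect_equal(tt[which.max(kernel_value(tt, k))], 8, tolerance = 1e-2)
  for (pars in list(c(4, 8, 1), c(32, 16, 0.5), c(1.7, 3.2, 2.5))) {
    kk <- synaptic_kernel(pars[1], pars[2])
    ii <- stats::integrate(kernel_value, 0, Inf, kernel = kk, A = pars[3],
                           rel.tol = 1e-10)$value
    expect_equal(ii, pars[3] * pars[1] * pars[2], tolerance = 1e-6)
    expect_equal(kernel_value(5, kk, A = pars[3]),
                 alpha_kernel_oracle(5, pars[1], pars[2], pars[3]))
  }
})

test_that("exogenous input is a sum of Gaussian bumps with the stated geometry", {
  spec <- input_spec()   # onsets (10, 40) ms, dispersions (8, 8) ms
  tt <- seq(0, 200, by = 0.01)
  u <- exogenous_input(tt, spec)
  pk <- tt[which(diff(sign(diff(u))) == -2) + 1]
  expect_equal(pk, c(10, 40), tolerance = 0.05)
  expect_lt(exogenous_input(200, spec), 1e-6 * max(u))
  # single component: value at onset +/- dispersion is exp(-1/2) * peak
  s1 <- input_spec(onsets = 10, dispersions = 8, amplitudes = 1)
  expect_equal(exogenous_input(c(2, 18), s1),
               rep(exp(-0.5) * exogenous_input(10, s1), 2))
})

test_that("channel impulse response matches the closed-form kernel", {
  # an isolated channel driven by a unit-area pulse reduces to the kernel;
  # zero all intrinsic gains and realize the pulse as a narrow Gaussian
  # (sigma 0.3 ms, area 1)
  zg <- c(ei_to_out = 0, out_to_ei = 0, out_to_ii = 0, ii_to_out = 0)
  v <- model_variant("probe",
                     data.frame(from = character(), to = character(),
                                target = character(), rate = numeric()),
                     list(MCN = source_architecture("MCN", gains = zg),
                          vlPAG = source_architecture("vlPAG", gains = zg)))
  t0 <- 3; sg <- 0.3
  inp <- input_spec(onsets = t0, dispersions = sg,
                    amplitudes = 1 / (sg * sqrt(2 * pi)))
  grid <- simulation_grid(window = c(1, 200), dt = 0.1)
  e <- simulate_erp(v, grid = grid, input = inp, return_states = TRUE)
  # the excitatory-interneuron population receives the drive directly; its
  # composite potential is the excitatory channel's response: the kernel
  # convolved with the (narrow, unit-area) pulse, computed independently
  v_ei <- e$states[, 2]
  ker <- gauss_kernel_conv_oracle(grid$time_ms, t0, sg, H = 4, tau = 8)
  pk <- max(abs(ker))
  expect_lt(max(abs(v_ei - ker)) / pk, 0.01)
  # step-halving convergence: dt 0.1 vs 0.05 agree to < 0.5% of peak
  g2 <- simulation_grid(window = c(1, 200), dt = 0.05)
  e2 <- simulate_erp(v, grid = g2, input = inp, return_states = TRUE)
  expect_lt(max(abs(e$states[, 2] - e2$states[, 2])) / pk, 0.005)
})

test_that("build_model_space reproduces the five stated hypotheses", {
  ms <- build_model_space()
  expect_length(ms, 5)
  expect_identical(names(ms), paste0("M", 1:5))
  empty <- vapply(ms, function(m) nrow(m$extrinsic) == 0, logical(1))
  expect_identical(sum(empty), 1L)
  expect_true(empty[["M5"]])
  fwd <- function(m) m$extrinsic[m$extrinsic$from == "MCN", ]
  bwd <- function(m) m$extrinsic[m$extrinsic$from == "vlPAG", ]
  expect_identical(fwd(ms$M1)$target, "output")
  expect_identical(fwd(ms$M1)$rate, 1)
  expect_identical(bwd(ms$M1)$rate, 1)
  expect_setequal(fwd(ms$M2)$target, c("output", "inhibitory_interneuron"))
  expect_identical(fwd(ms$M2)$rate, c(1 / 2, 1 / 2))
  expect_identical(sort(fwd(ms$M3)$target),
                   sort(c("output", "excitatory_interneuron",
                          "inhibitory_interneuron")))
  expect_identical(fwd(ms$M3)$rate, rep(1 / 8, 3))
  expect_identical(bwd(ms$M3)$rate, 1)          # IO-type, rate 1
  expect_identical(nrow(bwd(ms$M4)), 3L)        # "all" in both directions
  expect_identical(bwd(ms$M4)$rate, rep(1 / 8, 3))
})

test_that("null model has no extrinsic parameters and ignores the coupling scale", {
  ms <- build_model_space()
  expect_false(any(grepl("^A_", pack_parameters(ms$M5)$name)))
  expect_error(simulate_erp(ms$M5, c(A_MCN_to_vlPAG = 1)), "unknown parameter")
  # M1 and M5 differ: the extrinsic connections shape the waveforms
  e1 <- simulate_erp(ms$M1); e5 <- simulate_erp(ms$M5)
  expect_gt(nrmse(e1$amplitude, e5$amplitude), 0.05)
})

test_that("observation gain is a linear output stage", {
  ms <- build_model_space()
  base <- simulate_erp(ms$M1)
  double <- simulate_erp(ms$M1, c(L_MCN = log(2)))
  expect_equal(double$amplitude["MCN", ], 2 * base$amplitude["MCN", ])
  expect_identical(double$amplitude["vlPAG", ], base$amplitude["vlPAG", ])
})

test_that("small-signal simulation matches the independent linearized oracle", {
  ms <- build_model_space()
  eps <- 1e-3
  inp <- input_spec(amplitudes = rep(0.25 * eps, 2))
  e <- simulate_erp(ms$M1, c(L_MCN = 0, L_vlPAG = 0), input = inp)
  ref <- linear_m1_oracle(amp_scale = eps)
  expect_lt(nrmse(e$amplitude, ref), 0.01)
})

test_that("shifting an extrinsic delay shifts the cross-source footprint", {
  ms <- build_model_space()
  shift_variant <- function(extra) {
    v <- ms$M1; v$extrinsic_delay <- v$extrinsic_delay + extra; v
  }
  foot <- function(v) {
    on <- simulate_erp(v, c(A_vlPAG_to_MCN = log(2)))
    off <- simulate_erp(v)
    on$amplitude["MCN", ] - off$amplitude["MCN", ]
  }
  d0 <- foot(ms$M1); d4 <- foot(shift_variant(4))
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    i <- seq_len(200 - abs(l))
    if (l >= 0) stats::cor(d4[i + l], d0[i]) else stats::cor(d4[i], d0[i - l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 4, tolerance = 1)
})

test_that("waveforms stay finite for parameters within 3 prior SD", {
  ms <- build_model_space(ii_to_ii = TRUE)   # include the self-connection too
  pp <- pack_parameters(ms$M1)
  set.seed(7)
  for (i in 1:15) {
    th <- stats::setNames(stats::rnorm(nrow(pp), 0, pp$prior_sd), pp$name)
    th <- pmax(pmin(th, 3 * pp$prior_sd), -3 * pp$prior_sd)
    e <- simulate_erp(ms$M1, th)
    expect_true(all(is.finite(e$amplitude)))
  }
  # corner case: every parameter at +3 SD simultaneously
  th3 <- stats::setNames(3 * pp$prior_sd, pp$name)
  expect_true(all(is.finite(simulate_erp(ms$M1, th3)$amplitude)))
})

test_that("architecture validation enforces the structural invariants", {
  expect_error(source_architecture("MCN", gains = c(bogus = 1)), "unknown names")
  expect_error(source_architecture("MCN", H = c(e = -1, i = 32)), "positive")
  a <- source_architecture("MCN", ii_self = TRUE)
  expect_identical(nrow(a$intrinsic_connections), 5L)
  expect_true(all(a$intrinsic_connections$from[
    a$intrinsic_connections$polarity == "inhibitory"] ==
      "inhibitory_interneuron"))
  expect_error(
    model_variant("X", data.frame(from = "MCN", to = "vlPAG",
                                  target = "nonexistent", rate = 1),
                  list(MCN = source_architecture("MCN"),
                       vlPAG = source_architecture("vlPAG"))),
    "target population")
})
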