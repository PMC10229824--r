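## Variational-Laplace inversion of one ERP pair under one model variant:
## Gaussian priors over latent log-scaling parameters, Gauss-Newton/EM ascent
## on a free-energy objective with Levenberg-style step regularization.

## prior standard deviations on the latent (log) scale, by parameter class:
## wide on the quantities of interest (extrinsic coupling, input amplitude,
## lead-field gain), tight on biophysical constants.
.prior_sd_class <- c(A = sqrt(1 / 2), G = sqrt(1 / 16), H = sqrt(1 / 16),
                     U = sqrt(1 / 2), L = sqrt(1 / 2))

#' Latent parameterization of a model variant
#'
#' Enumerates the free parameters of a variant in a deterministic order with
#' their latent prior moments. Every physical parameter is prior mean times
#' `exp(theta)`, so the latent prior mean is 0 for all parameters. Pinned
#' parameters (the null model's extrinsic couplings, which have zero prior
#' mean and zero prior variance) are excluded from the free set.
#'
#' Order: extrinsic couplings (one per direction), intrinsic gains (MCN then
#' vlPAG), maximum PSPs, input amplitudes, lead-field gains.
#'
#' @param variant A [model_variant()].
#' @return A data frame with columns `name`, `class`, `prior_mean`
#'   (latent, all 0), `prior_sd` (latent), and `phys_mean` (the physical
#'   prior mean the parameter scales; for extrinsic couplings this is the
#'   Table-style prior rate shared by the direction's targets).
#' @export
pack_parameters <- function(variant) {
  stopifnot(inherits(variant, "model_variant"))
  rows <- list()
  add <- function(name, class, phys) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, prior_mean = 0,
      prior_sd = unname(.prior_sd_class[class]), phys_mean = phys,
      stringsAsFactors = FALSE)
  }
  ext <- variant$extrinsic
  if (nrow(ext)) {
    dirs <- unique(ext[, c("from", "to")])
    for (i in seq_len(nrow(dirs))) {
      sel <- ext$from == dirs$from[i] & ext$to == dirs$to[i]
      add(paste0("A_", dirs$from[i], "_to_", dirs$to[i]), "A",
          ext$rate[sel][1])
    }
  }
  for (s in .source_order) {
    cc <- variant$architectures[[s]]$intrinsic_connections
    for (i in seq_len(nrow(cc)))
      add(.gain_param_name(s, cc$from[i], cc$to[i]), "G", cc$gain[i])
  }
  for (s in .source_order) {
    add(paste0("H_e_", s), "H", variant$architectures[[s]]$H[["e"]])
    add(paste0("H_i_", s), "H", variant$architectures[[s]]$H[["i"]])
  }
  add("U_amp1", "U", NA_real_)
  add("U_amp2", "U", NA_real_)
  for (s in .source_order) add(paste0("L_", s), "L", 1)
  do.call(rbind, rows)
}

#' Map latent parameters to physical values
#'
#' @param variant A [model_variant()].
#' @param theta Named latent vector (missing entries default to 0).
#' @return Named numeric vector of physical parameter values
#'   (`phys_mean * exp(theta)`); input amplitudes are reported as the
#'   multiplier `exp(theta)` applied to the input specification.
#' @export
unpack_parameters <- function(variant, theta = numeric(0)) {
  pp <- pack_parameters(variant)
  th <- stats::setNames(rep(0, nrow(pp)), pp$name)
  if (length(theta)) th[names(theta)] <- theta
  phys <- ifelse(is.na(pp$phys_mean), exp(th), pp$phys_mean * exp(th))
  stats::setNames(phys, pp$name)
}

#' Fit options for [fit_dcm()]
#'
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Free-energy improvement (nats) below which an iteration counts
#'   as stalled.
#' @param patience Number of consecutive stalled iterations that triggers
#'   convergence.
#' @param fd_step Central finite-difference step on the latent scale.
#' @param lambda_prior_var Prior variance of the log noise-precision.
#' @param max_retry Levenberg step-halving attempts per iteration.
#' @return A list of options.
#' @export
fit_options <- function(max_iter = 64, tol = 1e-2, patience = 4,
                        fd_step = 1e-3, lambda_prior_var = 1,
                        max_retry = 8) {
  list(max_iter = max_iter, tol = tol, patience = patience,
       fd_step = fd_step, lambda_prior_var = lambda_prior_var,
       max_retry = max_retry)
}

## free-energy terms under the Laplace assumption; residuals evaluated at the
## posterior mean. Returns the total and its named components.
.free_energy_terms <- function(resid, lambda, mu, Cq, prior_sd,
                               lambda0, vlambda) {
  N <- length(resid)
  ee <- sum(resid^2)
  accuracy_quad <- -0.5 * exp(lambda) * ee
  accuracy_norm <- 0.5 * N * lambda - 0.5 * N * log(2 * pi)
  iSp <- 1 / prior_sd^2
  ldCq <- determinant(Cq, logarithm = TRUE)$modulus
  if (!is.finite(ldCq)) stop("singular posterior covariance")
  kl_theta <- 0.5 * (sum(diag(Cq) * iSp) + sum(mu^2 * iSp) -
                     length(mu) + 2 * sum(log(prior_sd)) - as.numeric(ldCq))
  kl_lambda <- 0.5 * (lambda - lambda0)^2 / vlambda
  F <- accuracy_quad + accuracy_norm - kl_theta - kl_lambda
  list(F = F, accuracy_quad = accuracy_quad, accuracy_norm = accuracy_norm,
       complexity_theta = kl_theta, complexity_lambda = kl_lambda)
}

#' Variational free energy of an approximate posterior
#'
#' Computes the Laplace free energy of a Gaussian posterior `q` for a given
#' ERP pair under a model variant: Gaussian log-likelihood of the residuals
#' at the posterior mean under noise precision `exp(lambda)`, minus the KL
#' divergence from the prior to `q`, minus the hyperparameter penalty.
#'
#' @param data An [erp_pair()] on the model grid.
#' @param variant A [model_variant()].
#' @param q Posterior density: list with `mean` (named latent vector), `cov`
#'   (matrix), `lambda` (log noise-precision) and `lambda0`
#'   (its prior mean; defaults to `lambda`).
#' @param grid,input Forward-model settings.
#' @param lambda_prior_var Prior variance of `lambda`.
#' @return The free energy (nats), with the individual terms as attribute
#'   `"terms"`.
#' @export
free_energy <- function(data, variant, q, grid = simulation_grid(),
                        input = input_spec(), lambda_prior_var = 1) {
  pp <- pack_parameters(variant)
  mu <- stats::setNames(rep(0, nrow(pp)), pp$name)
  mu[names(q$mean)] <- q$mean
  pred <- simulate_erp(variant, mu, grid, input)
  resid <- as.vector(t(data$amplitude)) - as.vector(t(pred$amplitude))
  lambda0 <- if (is.null(q$lambda0)) q$lambda else q$lambda0
  terms <- .free_energy_terms(resid, q$lambda, unname(mu), q$cov,
                              pp$prior_sd, lambda0, lambda_prior_var)
  structure(terms$F, terms = terms)
}

## 1-D Newton maximization of F in lambda given the residual sum of squares
.opt_lambda <- function(ee, N, lambda0, v, floor_ee) {
  ee <- max(ee, floor_ee)
  lam <- min(log(N / ee), lambda0 + 10)
  for (i in 1:50) {
    g <- N / 2 - exp(lam) * ee / 2 - (lam - lambda0) / v
    h <- -exp(lam) * ee / 2 - 1 / v
    step <- g / h
    step <- max(min(step, 4), -4)
    lam <- lam - step
    if (abs(step) < 1e-10) break
  }
  lam
}

#' Invert a dynamic causal model for one ERP pair
#'
#' Gauss-Newton / EM ascent on the variational free energy: the E-step
#' updates the latent parameters using a central finite-difference Jacobian
#' of the forward simulation, with Levenberg-style damping so that only
#' free-energy-increasing steps are accepted; the M-step updates the log
#' noise-precision under its Gaussian prior. The recorded free-energy trace
#' contains accepted steps only and is non-decreasing by construction; the
#' best-so-far posterior is returned.
#'
#' @param data An [erp_pair()] sampled on the model grid (1 kHz, (1, 200) ms
#'   by default).
#' @param variant A [model_variant()] from the model space.
#' @param options See [fit_options()].
#' @param grid,input Forward-model settings (must match the data grid).
#' @return An object of class `dcm_fit`: posterior mean/covariance over the
#'   latent parameters, `lambda` (log noise-precision), `free_energy`,
#'   `trace`, fitted waveforms, residuals, `converged`, `iterations`.
#' @export
fit_dcm <- function(data, variant, options = fit_options(),
                    grid = simulation_grid(), input = input_spec()) {
  stopifnot(inherits(data, "erp_pair"))
  if (length(data$time_ms) != length(grid$time_ms) ||
      max(abs(data$time_ms - grid$time_ms)) > 1e-6)
    stop("data grid does not match the model grid")
  pp <- pack_parameters(variant)
  d <- nrow(pp)
  prior_sd <- pp$prior_sd
  iSp <- diag(1 / prior_sd^2, d)
  cm <- .compile_variant(variant, grid, input)
  sim <- function(th) as.vector(t(.sim_compiled(cm, stats::setNames(th, pp$name))))

  y <- as.vector(t(data$amplitude))
  N <- length(y)
  vy <- stats::var(y)
  lambda0 <- log(4 / max(vy, .Machine$double.eps))  # prior: noise var ~ var(y)/4
  vlambda <- options$lambda_prior_var
  floor_ee <- N * vy * 1e-10 + .Machine$double.xmin

  theta <- rep(0, d)
  f <- sim(theta)
  if (any(!is.finite(f))) stop("non-finite prediction at the prior mean")
  resid <- y - f
  lambda <- .opt_lambda(sum(resid^2), N, lambda0, vlambda, floor_ee)

  jac <- function(th) {
    J <- matrix(0, N, d)
    h <- options$fd_step
    for (j in seq_len(d)) {
      ej <- rep(0, d); ej[j] <- h
      J[, j] <- (sim(th + ej) - sim(th - ej)) / (2 * h)
    }
    J
  }

  post_cov <- function(J, lam) {
    Hm <- exp(lam) * crossprod(J) + iSp
    Cq <- tryCatch(chol2inv(chol(Hm)), error = function(e) NULL)
    if (is.null(Cq)) Cq <- solve(Hm + diag(1e-8 * max(diag(Hm)), d))
    Cq
  }

  J <- jac(theta)
  Cq <- post_cov(J, lambda)
  Fbest <- .free_energy_terms(resid, lambda, theta, Cq, prior_sd,
                              lambda0, vlambda)$F
  best <- list(theta = theta, Cq = Cq, lambda = lambda, resid = resid, f = f)
  trace <- Fbest
  nu <- 1e-4 * mean(diag(iSp))   # Levenberg damping
  stall <- 0L
  converged <- FALSE
  iter <- 0L

  while (iter < options$max_iter) {
    iter <- iter + 1L
    JtJ <- crossprod(J)
    g <- exp(lambda) * crossprod(J, resid) - iSp %*% theta
    accepted <- FALSE
    for (try in seq_len(options$max_retry)) {
      Hm <- exp(lambda) * JtJ + iSp + diag(nu, d)
      step <- tryCatch(solve(Hm, g), error = function(e) NULL)
      if (is.null(step)) { nu <- nu * 8; next }
      th_new <- theta + as.vector(step)
      f_new <- tryCatch(sim(th_new), error = function(e) NULL)
      if (is.null(f_new) || any(!is.finite(f_new))) { nu <- nu * 8; next }
      r_new <- y - f_new
      lam_new <- .opt_lambda(sum(r_new^2), N, lambda0, vlambda, floor_ee)
      Cq_new <- post_cov(J, lam_new)
      F_new <- .free_energy_terms(r_new, lam_new, th_new, Cq_new, prior_sd,
                                  lambda0, vlambda)$F
      if (is.finite(F_new) && F_new > Fbest) {
        theta <- th_new; resid <- r_new; f <- f_new
        lambda <- lam_new; Cq <- Cq_new
        improvement <- F_new - Fbest
        Fbest <- F_new
        best <- list(theta = theta, Cq = Cq, lambda = lambda,
                     resid = resid, f = f)
        trace <- c(trace, Fbest)
        nu <- nu / 2
        accepted <- TRUE
        break
      }
      nu <- nu * 8
    }
    if (accepted && improvement >= options$tol) stall <- 0L
    else stall <- stall + 1L
    if (stall >= options$patience) { converged <- TRUE; break }
    if (accepted) J <- jac(theta)
  }

  ## refresh posterior covariance at the accepted optimum
  Jb <- jac(best$theta)
  Cq <- post_cov(Jb, best$lambda)
  Fb <- .free_energy_terms(best$resid, best$lambda, best$theta, Cq, prior_sd,
                           lambda0, vlambda)$F
  if (Fb > Fbest) { Fbest <- Fb; trace <- c(trace, Fb) }
  else Cq <- best$Cq

  fitted <- erp_pair(grid$time_ms,
                     matrix(best$f, nrow = 2, byrow = TRUE,
                            dimnames = list(.source_order, NULL)),
                     meta = list(variant = variant$id))
  structure(list(
    posterior = list(mean = stats::setNames(best$theta, pp$name), cov = Cq,
                     names = pp$name,
                     prior_sd = stats::setNames(prior_sd, pp$name)),
    lambda = list(mean = best$lambda, prior_mean = lambda0,
                  prior_var = vlambda),
    free_energy = Fbest,
    trace = trace,
    fitted = fitted,
    residuals = matrix(best$resid, nrow = 2, byrow = TRUE,
                       dimnames = list(.source_order, NULL)),
    converged = converged,
    iterations = iter,
    variant_id = variant$id,
    options = options
  ), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> variant %s: F = %.2f nats, %d iterations, %s\n",
              x$variant_id, x$free_energy, x$iterations,
              if (x$converged) "converged" else "not converged"))
  ext <- grep("^A_", x$posterior$names, value = TRUE)
  if (length(ext)) {
    sd <- sqrt(diag(x$posterior$cov))[match(ext, x$posterior$names)]
    for (i in seq_along(ext))
      cat(sprintf("  %s: %.3f (sd %.3f)\n", ext[i],
                  x$posterior$mean[[ext[i]]], sd[i]))
  }
  invisible(x)
}

#' Forward prediction at the posterior mean
#'
#' @param fit A `dcm_fit`.
#' @param variant The [model_variant()] it was fitted under.
#' @param grid,input Forward-model settings used in the fit.
#' @return An [erp_pair()]: the model's predicted response.
#' @export
predicted_response <- function(fit, variant, grid = simulation_grid(),
                               input = input_spec()) {
  stopifnot(inherits(fit, "dcm_fit"), variant$id == fit$variant_id)
  simulate_erp(variant, fit$posterior$mean, grid, input)
}
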