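## Parametric empirical Bayes second level: a hierarchical Gaussian model
## regressing first-level (per subject x block) posterior connection
## strengths on a between-subject design matrix [mean, trial, freezing],
## with Bayesian model reduction to prune covariate effects.

#' Build the second-level design matrix
#'
#' One row per first-level fit (subject-major, block-minor order): a constant
#' column ("mean", the group-mean effective connectivity after
#' mean-centering), a centred trial (block index) column, and a centred
#' freezing column.
#'
#' @param covariates Data frame with columns `subject`, `block`,
#'   `freezing_pct`, one row per subject x block cell; every subject must
#'   have every block (missing cells are an error).
#' @return An object of class `group_design`: `$X` (n x 3 matrix with
#'   columns `mean`, `trial`, `freezing`) and `$rows` (the reordered
#'   covariate table).
#' @export
build_design <- function(covariates) {
  stopifnot(is.data.frame(covariates),
            all(c("subject", "block", "freezing_pct") %in% names(covariates)))
  subjects <- sort(unique(covariates$subject))
  blocks <- sort(unique(covariates$block))
  want <- expand.grid(block = blocks, subject = subjects)[, c("subject", "block")]
  key <- function(d) paste(d$subject, d$block, sep = "_")
  missing <- setdiff(key(want), key(covariates))
  if (length(missing))
    stop("missing covariate cells (subject_block): ",
         paste(missing, collapse = ", "))
  ord <- order(covariates$subject, covariates$block)
  cov_s <- covariates[ord, , drop = FALSE]
  X <- cbind(mean = 1,
             trial = cov_s$block - mean(cov_s$block),
             freezing = cov_s$freezing_pct - mean(cov_s$freezing_pct))
  structure(list(X = X, rows = cov_s), class = "group_design")
}

#' Options for [fit_peb()]
#'
#' @param prior_var_beta Prior variance of every second-level coefficient.
#' @param g0,vg Gaussian hyperprior (mean, variance) on the log random-effect
#'   precision; the default expects between-row variance about 1/16 of the
#'   first-level prior variance.
#' @param fix_g Optional fixed value for the log random-effect precision
#'   (used mainly by oracle tests); `NULL` estimates it.
#' @return A list of options.
#' @export
peb_options <- function(prior_var_beta = 1 / 2, g0 = log(32), vg = 1,
                        fix_g = NULL) {
  list(prior_var_beta = prior_var_beta, g0 = g0, vg = vg, fix_g = fix_g)
}

#' Fit the second-level hierarchical model
#'
#' Hierarchical Gaussian model over the selected first-level parameters:
#' `theta_i = (x_i' (x) I_p) beta + eps_i`, with `eps_i ~ N(0, exp(-g) I_p)`
#' and each first-level posterior entering through its full Gaussian density
#' `N(m_i, S_i)` (posterior means AND covariances, not point estimates).
#' `beta` carries a zero-mean Gaussian prior; the scalar log random-effect
#' precision `g` has a Gaussian hyperprior and is optimized by maximizing
#' the (exact, linear-Gaussian) log evidence.
#'
#' @param fits List of `dcm_fit` objects, one per design row, in design
#'   order (subject-major, block-minor).
#' @param design A [build_design()] result.
#' @param selector Names of first-level parameters to model at the second
#'   level; default: the two extrinsic connection strengths.
#' @param options See [peb_options()].
#' @return An object of class `peb_result`: `$beta` (coefficient data frame
#'   with posterior mean, sd and the probability of a non-zero effect),
#'   `$mu` and `$cov` (posterior over the stacked coefficients,
#'   parameter-fastest within design column), `$free_energy`, `$g`,
#'   `$prior_var` and bookkeeping fields.
#' @export
fit_peb <- function(fits, design,
                    selector = c("A_MCN_to_vlPAG", "A_vlPAG_to_MCN"),
                    options = peb_options()) {
  stopifnot(inherits(design, "group_design"))
  X <- design$X
  n <- nrow(X); cdim <- ncol(X); p <- length(selector)
  if (length(fits) != n) stop("number of fits must equal the design rows")
  M <- matrix(0, n, p)
  S <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fits[[i]]
    idx <- match(selector, f$posterior$names)
    if (any(is.na(idx)))
      stop("fit ", i, " does not expose parameter(s): ",
           paste(selector[is.na(idx)], collapse = ", "))
    mi <- f$posterior$mean[idx]
    Si <- as.matrix(f$posterior$cov)[idx, idx, drop = FALSE]
    ## the first-level posterior is shrunk toward the first-level prior;
    ## the second level supplies its own (empirical) prior in its place, so
    ## the first-level prior is divided out of each row's likelihood
    ## (fits without recorded prior sds are treated as unshrunk)
    psd <- f$posterior$prior_sd
    v0 <- if (is.null(psd)) rep(Inf, p) else unname(psd[idx])
    iSi <- chol2inv(chol(Si))
    Li <- iSi - diag(1 / v0^2, p)
    eg <- eigen(Li, symmetric = TRUE)
    eg$values <- pmax(eg$values, 1e-4)
    M[i, ] <- as.vector(eg$vectors %*% ((t(eg$vectors) %*% (iSi %*% mi)) /
                                          eg$values))
    S[[i]] <- eg$vectors %*% ((1 / eg$values) * t(eg$vectors))
  }
  ## standardize covariate columns to unit SD for the prior, so that
  ## prior_var_beta refers to the effect of a 1-SD covariate change and the
  ## evidence is invariant to covariate units; coefficients are transformed
  ## back to user units below.
  col_scale <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  col_scale[col_scale == 0] <- 1
  Xs <- sweep(X, 2, col_scale, "/")
  m <- as.vector(t(M))                 # stacked fit-major, param-fastest
  W <- kronecker(Xs, diag(p))          # (n p) x (p c)
  Vb <- rep(options$prior_var_beta, p * cdim)

  neg_ev <- function(g) -.peb_evidence(m, W, S, Vb, g, n, p)$log_ev
  if (is.null(options$fix_g)) {
    opt <- stats::optimize(function(g)
      neg_ev(g) + 0.5 * (g - options$g0)^2 / options$vg +
        0.5 * log(2 * pi * options$vg),
      interval = options$g0 + c(-8, 8))
    g_hat <- opt$minimum
    Fpeb <- -opt$objective
  } else {
    g_hat <- options$fix_g
    Fpeb <- .peb_evidence(m, W, S, Vb, g_hat, n, p)$log_ev
  }
  ev <- .peb_evidence(m, W, S, Vb, g_hat, n, p)

  cn <- colnames(X)
  coef_names <- as.vector(outer(selector, cn, paste, sep = ":"))
  ## back to user units (posterior and prior transform together, so model
  ## evidence and all BMR quantities are unaffected by the standardization)
  sc <- rep(col_scale, each = p)
  mu <- stats::setNames(ev$mu / sc, coef_names)
  C_user <- ev$C / tcrossprod(sc)
  Vb_user <- Vb / sc^2
  sdv <- sqrt(pmax(diag(C_user), 0))
  beta <- data.frame(
    parameter = rep(selector, cdim),
    covariate = rep(cn, each = p),
    mean = unname(mu), sd = sdv,
    p_nonzero = stats::pnorm(abs(mu) / pmax(sdv, .Machine$double.eps)),
    row.names = coef_names)
  structure(list(beta = beta, mu = mu, cov = C_user, free_energy = Fpeb,
                 g = g_hat, prior_var = stats::setNames(Vb_user, coef_names),
                 design = design, selector = selector, n = n,
                 options = options),
            class = "peb_result")
}

## exact evidence and posterior of the linear-Gaussian second level at a
## given log random-effect precision g
.peb_evidence <- function(m, W, S, Vb, g, n, p) {
  D <- matrix(0, n * p, n * p)
  for (i in seq_len(n)) {
    ix <- (i - 1) * p + seq_len(p)
    D[ix, ix] <- S[[i]] + diag(exp(-g), p)
  }
  Sig <- W %*% (Vb * t(W)) + D
  ch <- tryCatch(chol(Sig), error = function(e)
    stop("non-positive-definite second-level covariance"))
  quad <- sum(backsolve(ch, m, transpose = TRUE)^2)
  log_ev <- -0.5 * (length(m) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  Pi <- chol2inv(chol(D))
  A <- t(W) %*% Pi %*% W + diag(1 / Vb)
  C <- chol2inv(chol(A))
  mu <- as.vector(C %*% t(W) %*% Pi %*% m)
  list(log_ev = log_ev, mu = mu, C = C)
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("<peb_result> %d rows, F = %.2f, log RE precision = %.2f\n",
              x$n, x$free_energy, x$g))
  print(cbind(round(x$beta[, c("mean", "sd", "p_nonzero")], 4)))
  invisible(x)
}

#' Bayesian model reduction of a second-level model
#'
#' Analytically re-evaluates evidence and posterior when the prior of
#' masked-off coefficients is replaced by a point mass at zero (realized as
#' a negligible prior variance); no refitting.
#'
#' @param full A `peb_result`.
#' @param mask Logical vector over the stacked coefficients, or a logical
#'   `p x c` matrix (parameters x design columns); `TRUE` = keep ("on").
#' @param off_var Prior variance assigned to pruned coefficients.
#' @return An object of class `reduced_model`: `$mask`, `$dF` (reduced minus
#'   full free energy), `$free_energy`, `$mu`, `$cov`.
#' @export
bmr <- function(full, mask, off_var = 1e-8) {
  stopifnot(inherits(full, "peb_result"))
  mask <- as.vector(mask)
  d <- length(full$mu)
  if (length(mask) != d) stop("mask dimension must match the coefficients")
  V <- full$prior_var
  Vr <- ifelse(mask, V, off_var)
  P <- chol2inv(chol(full$cov))
  Pr <- P + diag(1 / Vr - 1 / V, d)
  chPr <- tryCatch(chol(Pr), error = function(e)
    stop("non-positive-definite reduced precision"))
  Cr <- chol2inv(chPr)
  mur <- as.vector(Cr %*% (P %*% full$mu))
  ldP <- determinant(P, logarithm = TRUE)$modulus
  dF <- 0.5 * (as.numeric(ldP) - 2 * sum(log(diag(chPr))) +
               sum(log(V)) - sum(log(Vr)) +
               sum(mur * (Pr %*% mur)) - sum(full$mu * (P %*% full$mu)))
  structure(list(mask = mask, dF = dF, free_energy = full$free_energy + dF,
                 mu = stats::setNames(mur, names(full$mu)), cov = Cr),
            class = "reduced_model")
}

.default_masks <- function(full) {
  p <- length(full$selector)
  cn <- colnames(full$design$X)
  covs <- cn[-1]
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(covs)))
  names(combos) <- covs
  combos <- combos[order(-rowSums(combos)), , drop = FALSE]
  masks <- lapply(seq_len(nrow(combos)), function(i) {
    keep_col <- c(TRUE, as.logical(combos[i, ]))
    matrix(rep(keep_col, each = p), p, length(cn))
  })
  names(masks) <- apply(combos, 1, function(z) {
    on <- covs[as.logical(z)]
    if (!length(on)) "mean only" else paste(c("mean", on), collapse = " + ")
  })
  masks
}

#' Compare reduced second-level models
#'
#' Scores a set of reduced models (default: every on/off combination of the
#' covariate columns, with the mean column always on) by their reduced free
#' energies and returns softmax model probabilities. The full model (all
#' coefficients on) is part of the default set.
#'
#' @param full A `peb_result`.
#' @param masks Named list of masks (see [bmr()]); `NULL` for the default
#'   covariate on/off space.
#' @return An object of class `peb_model_comparison`: `$probability`,
#'   `$free_energy`, `$reduced` (the `reduced_model` objects), and `$bma`
#'   (Bayesian model average over the set: mixture mean/cov).
#' @export
compare_reduced_models <- function(full, masks = NULL) {
  stopifnot(inherits(full, "peb_result"))
  if (is.null(masks)) masks <- .default_masks(full)
  if (!length(masks)) stop("empty mask list")
  red <- lapply(masks, function(mk) bmr(full, mk))
  Fr <- vapply(red, function(r) r$free_energy, numeric(1))
  pr <- exp(Fr - max(Fr)); pr <- pr / sum(pr)
  d <- length(full$mu)
  mu_bar <- rep(0, d); M2 <- matrix(0, d, d)
  for (i in seq_along(red)) {
    mu_bar <- mu_bar + pr[i] * red[[i]]$mu
    M2 <- M2 + pr[i] * (red[[i]]$cov + tcrossprod(red[[i]]$mu))
  }
  C_bar <- M2 - tcrossprod(mu_bar)
  structure(list(probability = pr, free_energy = Fr, reduced = red,
                 bma = list(mu = stats::setNames(mu_bar, names(full$mu)),
                            cov = C_bar)),
            class = "peb_model_comparison")
}

#' @export
print.peb_model_comparison <- function(x, ...) {
  cat("<peb_model_comparison>\n")
  print(round(x$probability, 4))
  invisible(x)
}

#' Posterior probability of a non-zero effect
#'
#' The posterior mass, under the Gaussian marginal of a coefficient (from a
#' `peb_result`, a `reduced_model`, a model comparison's Bayesian model
#' average, or an explicit `(mean, sd)`), of the sign region containing its
#' mean. The conventional 0.95 reporting threshold is applied downstream,
#' never inside this computation.
#'
#' @param result A `peb_result`, `reduced_model` or `peb_model_comparison`.
#' @param coefficient Coefficient name (`"parameter:covariate"`).
#' @return Probability in `[0.5, 1]`.
#' @export
posterior_prob_nonzero <- function(result, coefficient) {
  if (inherits(result, "peb_model_comparison")) {
    mu <- result$bma$mu; C <- result$bma$cov
  } else if (inherits(result, c("peb_result", "reduced_model"))) {
    mu <- result$mu; C <- result$cov
  } else stop("unsupported result object")
  if (!coefficient %in% names(mu)) stop("unknown coefficient: ", coefficient)
  i <- match(coefficient, names(mu))
  sdv <- sqrt(max(C[i, i], 0))
  if (sdv == 0) return(if (mu[[i]] == 0) 0.5 else 1)
  unname(stats::pnorm(abs(mu[[i]]) / sdv))
}
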