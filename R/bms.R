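## Group-level Bayesian model selection over fitted free energies:
## fixed-effects pooling and the random-effects variational-Dirichlet scheme
## with Monte-Carlo exceedance probabilities.

#' Assemble an evidence matrix
#'
#' @param fits_by_model Either a numeric subjects x models matrix of free
#'   energies, or a list (one element per model) of lists of `dcm_fit`
#'   objects in a common subject order.
#' @return A numeric matrix (subjects x models) with dimnames.
#' @export
evidence_matrix <- function(fits_by_model) {
  if (is.matrix(fits_by_model)) {
    E <- fits_by_model
  } else {
    E <- vapply(fits_by_model,
                function(fl) vapply(fl, function(f) f$free_energy, numeric(1)),
                numeric(length(fits_by_model[[1]])))
    E <- matrix(E, ncol = length(fits_by_model),
                dimnames = list(NULL, names(fits_by_model)))
  }
  if (!all(is.finite(E))) stop("free energies must be finite")
  if (is.null(colnames(E))) colnames(E) <- paste0("M", seq_len(ncol(E)))
  if (is.null(rownames(E))) rownames(E) <- paste0("subject", seq_len(nrow(E)))
  E
}

.check_evidence <- function(E) {
  E <- evidence_matrix(E)
  if (nrow(E) < 1L) stop("at least one subject required")
  if (ncol(E) < 2L) stop("at least two models required")
  E
}

#' Fixed-effects Bayesian model selection
#'
#' Pools log evidence across subjects and returns posterior model
#' probabilities proportional to `exp(colSums(E))` (computed with a
#' max-subtraction for numerical stability). Invariant to adding a constant
#' to every entry.
#'
#' @param E Evidence matrix (subjects x models, nats); see
#'   [evidence_matrix()].
#' @return An object of class `bms_result` with `method = "ffx"` and
#'   `$probability`.
#' @export
ffx_bms <- function(E) {
  E <- .check_evidence(E)
  s <- colSums(E)
  p <- exp(s - max(s))
  p <- p / sum(p)
  structure(list(method = "ffx", probability = p, evidence = E),
            class = "bms_result")
}

#' Random-effects Bayesian model selection
#'
#' Variational update of Dirichlet concentrations over population model
#' frequencies (uniform Dirichlet(1) prior; subject-wise responsibilities
#' iterated to convergence), followed by Monte-Carlo estimation of each
#' model's exceedance probability -- the probability that it is the most
#' frequent model in the population.
#'
#' @param E Evidence matrix (subjects x models, nats).
#' @param n_samples Monte-Carlo samples for the exceedance estimate
#'   (default 1e5, minimum 1e4).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return An object of class `bms_result` with `method = "rfx"`:
#'   `$alpha` (Dirichlet concentrations), `$expected_frequency`,
#'   `$exceedance`, `$n_samples`, `$seed`.
#' @export
rfx_bms <- function(E, n_samples = 1e5, seed = 1L) {
  E <- .check_evidence(E)
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  K <- ncol(E)
  alpha0 <- rep(1, K)
  alpha <- alpha0 + nrow(E) / K
  for (it in 1:500) {
    lg <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(E, 2, lg, "+")
    u <- exp(u - apply(u, 1, max))
    g <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-4) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(E)
  ef <- alpha / sum(alpha)
  ## exceedance by Dirichlet sampling (gamma representation)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  counts <- integer(K)
  chunk <- 1e5
  left <- n_samples
  while (left > 0) {
    m <- min(chunk, left)
    G <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    win <- max.col(G, ties.method = "first")
    counts <- counts + tabulate(win, K)
    left <- left - m
  }
  xp <- counts / n_samples
  names(xp) <- colnames(E)
  structure(list(method = "rfx", alpha = alpha, expected_frequency = ef,
                 exceedance = xp, n_samples = n_samples, seed = seed,
                 evidence = E),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", toupper(x$method), "\n")
  if (x$method == "ffx") {
    print(round(x$probability, 4))
  } else {
    cat("  expected frequencies:\n"); print(round(x$expected_frequency, 4))
    cat("  exceedance probabilities:\n"); print(round(x$exceedance, 4))
  }
  invisible(x)
}
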