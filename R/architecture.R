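## Source architectures and the model space of extrinsic connectivity
## hypotheses for the two-region (MCN <-> vlPAG) evoked-response model.

#' Population roles within one source
#'
#' Every source is a three-population network: one output (projection)
#' population, one excitatory interneuron (relay) population and one
#' inhibitory interneuron population.
#' @keywords internal
.pop_roles <- c("output", "excitatory_interneuron", "inhibitory_interneuron")

#' Default architecture constants
#'
#' Intrinsic coupling gains, maximum post-synaptic potentials and receptor
#' time constants of the canonical three-population evoked-response source.
#' The gains are not published for this circuit; the defaults were fixed once
#' from a small-signal loop-gain analysis so that the resting state is stable
#' under the prior and moderately perturbed parameters (see the methods
#' vignette).
#' @keywords internal
.arch_defaults <- list(
  gains = c(ei_to_out = 0.15, out_to_ei = 0.15, out_to_ii = 0.15,
            ii_to_out = 0.05, ii_to_ii = 0.05),
  H     = c(e = 4, i = 32),     # mV, maximum PSP (excitatory, inhibitory)
  tau   = c(e = 8, i = 16),     # ms, AMPA / GABA-A receptor time constants
  intrinsic_delay = 2,          # ms, within-region conduction delay
  extrinsic_delay = 16,         # ms, between-region conduction delay
  sigmoid_r = 0.56,             # curvature of the firing-rate sigmoid
  ext_scale = 0.05              # fixed physical scale of extrinsic coupling
)

#' Construct a source architecture
#'
#' Builds the population list and intrinsic wiring of one neural-mass source:
#' the excitatory interneuron drives the output population, the output
#' population drives both interneuron classes, and the inhibitory interneuron
#' inhibits the output population. An optional inhibitory self-connection on
#' the inhibitory interneurons (`ii_self`, the "ii-to-ii" variant) can be
#' toggled; the default is off, matching the architecture favoured by model
#' selection on this circuit.
#'
#' @param name Source label, e.g. `"MCN"` or `"vlPAG"`.
#' @param ii_self Logical; include the inhibitory-interneuron self-connection.
#' @param gains Named numeric vector of intrinsic gains (see
#'   `.arch_defaults$gains` for names and defaults).
#' @param H Named numeric `c(e=, i=)`: maximum post-synaptic potentials (mV).
#' @param tau Named numeric `c(e=, i=)`: receptor time constants (ms);
#'   defaults 8 ms (excitatory/AMPA) and 16 ms (inhibitory/GABA-A).
#' @param intrinsic_delay Within-source conduction delay (ms).
#' @return An object of class `source_architecture`.
#' @export
source_architecture <- function(name, ii_self = FALSE,
                                gains = .arch_defaults$gains,
                                H = .arch_defaults$H,
                                tau = .arch_defaults$tau,
                                intrinsic_delay = .arch_defaults$intrinsic_delay) {
  stopifnot(is.character(name), length(name) == 1L)
  gains <- .merge_named(.arch_defaults$gains, gains)
  H <- .merge_named(.arch_defaults$H, H)
  tau <- .merge_named(.arch_defaults$tau, tau)
  if (any(H <= 0) || any(tau <= 0)) stop("H and tau must be positive")

  conn <- data.frame(
    from = c("excitatory_interneuron", "output", "output",
             "inhibitory_interneuron"),
    to   = c("output", "excitatory_interneuron", "inhibitory_interneuron",
             "output"),
    polarity = c("excitatory", "excitatory", "excitatory", "inhibitory"),
    gain = unname(gains[c("ei_to_out", "out_to_ei", "out_to_ii", "ii_to_out")]),
    delay = intrinsic_delay,
    stringsAsFactors = FALSE
  )
  if (ii_self) {
    conn <- rbind(conn, data.frame(
      from = "inhibitory_interneuron", to = "inhibitory_interneuron",
      polarity = "inhibitory", gain = unname(gains["ii_to_ii"]),
      delay = intrinsic_delay, stringsAsFactors = FALSE))
  }
  arch <- structure(list(
    name = name,
    populations = data.frame(label = .pop_roles, role = .pop_roles,
                             stringsAsFactors = FALSE),
    intrinsic_connections = conn,
    ii_self = ii_self,
    H = H, tau = tau,
    intrinsic_delay = intrinsic_delay
  ), class = "source_architecture")
  .validate_architecture(arch)
  arch
}

.merge_named <- function(defaults, x) {
  if (is.null(names(x)) && length(x) == length(defaults)) names(x) <- names(defaults)
  out <- defaults
  bad <- setdiff(names(x), names(defaults))
  if (length(bad)) stop("unknown names: ", paste(bad, collapse = ", "))
  out[names(x)] <- x
  out
}

.validate_architecture <- function(arch) {
  pops <- arch$populations$label
  if (sum(arch$populations$role == "output") != 1L)
    stop("architecture must have exactly one output population")
  cc <- arch$intrinsic_connections
  if (!all(cc$from %in% pops) || !all(cc$to %in% pops))
    stop("intrinsic connection references undeclared population")
  inh_src <- cc$from[cc$polarity == "inhibitory"]
  if (length(inh_src) && !all(inh_src == "inhibitory_interneuron"))
    stop("inhibitory connections must originate from inhibitory populations")
  invisible(arch)
}

#' Construct a model variant
#'
#' A model variant couples the two shared source architectures through a set
#' of delayed extrinsic (between-region) glutamatergic connections. Each
#' direction of coupling carries one free log-scaling parameter; its
#' per-target prior rate is the `rate` column.
#'
#' @param id Variant identifier (`"M1"` .. `"M5"`).
#' @param extrinsic Data frame with columns `from`, `to` (source names),
#'   `target` (population label in the receiving source) and `rate`
#'   (prior rate of the connection). Zero rows encode the null model.
#' @param architectures Named list with elements `MCN` and `vlPAG`
#'   (class `source_architecture`).
#' @param extrinsic_delay Between-region conduction delay (ms), default 16.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(id, extrinsic, architectures,
                          extrinsic_delay = .arch_defaults$extrinsic_delay) {
  stopifnot(is.data.frame(extrinsic),
            all(c("from", "to", "target", "rate") %in% names(extrinsic)))
  stopifnot(all(c("MCN", "vlPAG") %in% names(architectures)))
  if (nrow(extrinsic)) {
    if (any(extrinsic$rate < 0)) stop("extrinsic prior rates must be >= 0")
    for (i in seq_len(nrow(extrinsic))) {
      to <- extrinsic$to[i]
      if (!extrinsic$target[i] %in% architectures[[to]]$populations$label)
        stop("extrinsic target population not declared in receiving source")
    }
  }
  structure(list(id = id, extrinsic = extrinsic,
                 architectures = architectures,
                 extrinsic_delay = extrinsic_delay),
            class = "model_variant")
}

#' Build the five-model extrinsic connectivity space
#'
#' Constructs the competing hypotheses about MCN <-> vlPAG coupling:
#' \describe{
#'   \item{M1}{vlPAG -> MCN via the inferior-olive-type ("IO") projection plus
#'     MCN -> vlPAG onto the glutamatergic output population; prior rate 1.}
#'   \item{M2}{as M1 but MCN -> vlPAG reaches the glutamatergic output and the
#'     GABAergic inhibitory population; prior rate 1/2 per target.}
#'   \item{M3}{MCN -> vlPAG onto all three vlPAG populations (prior rate 1/8
#'     each) with the IO-type vlPAG -> MCN projection (rate 1).}
#'   \item{M4}{"all" targeting in both directions (rate 1/8 per target).}
#'   \item{M5}{the null hypothesis: no extrinsic connections; the coupling
#'     parameters are pinned (zero prior mean and variance) and are therefore
#'     excluded from the free parameter set.}
#' }
#' All extrinsic projections are glutamatergic and enter the excitatory
#' receptor channel of their target populations. The vlPAG -> MCN projection
#' terminates on the MCN excitatory-interneuron (relay) population.
#'
#' @param ii_to_ii Logical; use the architecture variant with the inhibitory
#'   self-connection in both sources.
#' @param m4_bidirectional_all Logical; if `TRUE` (default) M4 differs from M3
#'   by applying "all"-population targeting in both directions.
#' @return A list of five `model_variant` objects named `M1` .. `M5`.
#' @export
build_model_space <- function(ii_to_ii = FALSE, m4_bidirectional_all = TRUE) {
  arch <- list(MCN = source_architecture("MCN", ii_self = ii_to_ii),
               vlPAG = source_architecture("vlPAG", ii_self = ii_to_ii))
  all_pops <- .pop_roles
  fwd <- function(targets, rate)
    data.frame(from = "MCN", to = "vlPAG", target = targets, rate = rate,
               stringsAsFactors = FALSE)
  bwd_io <- data.frame(from = "vlPAG", to = "MCN",
                       target = "excitatory_interneuron", rate = 1,
                       stringsAsFactors = FALSE)
  bwd_all <- data.frame(from = "vlPAG", to = "MCN", target = all_pops,
                        rate = 1 / 8, stringsAsFactors = FALSE)
  m4_bwd <- if (m4_bidirectional_all) bwd_all else bwd_io
  ext <- list(
    M1 = rbind(fwd("output", 1), bwd_io),
    M2 = rbind(fwd(c("output", "inhibitory_interneuron"), 1 / 2), bwd_io),
    M3 = rbind(fwd(all_pops, 1 / 8), bwd_io),
    M4 = rbind(fwd(all_pops, 1 / 8), m4_bwd),
    M5 = data.frame(from = character(), to = character(),
                    target = character(), rate = numeric(),
                    stringsAsFactors = FALSE)
  )
  lapply(names(ext), function(id) model_variant(id, ext[[id]], arch)) |>
    stats::setNames(names(ext))
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant>", x$id, "\n")
  if (nrow(x$extrinsic)) {
    cat("  extrinsic connections:\n")
    for (i in seq_len(nrow(x$extrinsic)))
      cat(sprintf("    %s -> %s [%s], prior rate %s\n",
                  x$extrinsic$from[i], x$extrinsic$to[i],
                  x$extrinsic$target[i], format(x$extrinsic$rate[i])))
  } else cat("  null model (no extrinsic connections)\n")
  invisible(x)
}
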