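#' Build a simulation-ready network
#'
#' Wires the architecture (via [build_architecture()]) and compiles the
#' edge lists into the internal state used by the stepping engine: one
#' compressed-sparse-column store for all plastic excitatory-to-excitatory
#' synapses (local and between-area), one for the static
#' excitatory-to-inhibitory weights, plus dense per-unit state arrays.
#' All excitatory units across areas share a single global index space
#' (area blocks of 625 in the order of `arch$areas`).
#'
#' @param params A [model_parameters()] object selecting the backend.
#' @param pparams A [plasticity_parameters()] object.
#' @param arch An [architecture()].
#' @param seed Master wiring seed.
#' @param exclude_self Exclude autapses in local excitatory wiring.
#' @return An environment of class `hebbnet_network`.
#' @export
build_network <- function(params = model_parameters("felix"),
                          pparams = plasticity_parameters(params$preset),
                          arch = architecture(), seed = 1L,
                          exclude_self = TRUE) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(pparams, "plasticity_parameters"))
  built <- build_architecture(arch, seed = seed, exclude_self = exclude_self)
  areas <- arch$areas$area
  n_areas <- length(areas)
  ne <- arch$n_exc
  n_tot <- n_areas * ne
  offsets <- setNames((seq_len(n_areas) - 1L) * ne, areas)

  gather <- function(classes) {
    keep <- vapply(built$projections,
                   function(pr) pr$spec$synapse_class %in% classes,
                   logical(1))
    prs <- built$projections[keep]
    pre <- post <- integer(0); w <- numeric(0)
    pre <- unlist(lapply(prs, function(pr)
      pr$edges$pre + offsets[[pr$spec$source_area]]), use.names = FALSE)
    post <- unlist(lapply(prs, function(pr)
      pr$edges$post + offsets[[pr$spec$target_area]]), use.names = FALSE)
    w <- unlist(lapply(prs, function(pr) pr$edges$weight), use.names = FALSE)
    compile_csc(pre, post, w, n_tot)
  }

  net <- new.env(parent = emptyenv())
  net$arch <- arch
  net$params <- params
  net$pparams <- pparams
  net$seed <- seed
  net$areas <- areas
  net$offsets <- offsets
  net$n_tot <- n_tot
  net$area_of <- rep(seq_len(n_areas), each = ne)
  net$decay <- decay_factors(params)
  net$ee <- gather(c("EE_local", "EE_between"))
  net$ei <- gather("EI")
  # dense state
  net$V_e <- numeric(n_tot)
  net$omega_adapt <- numeric(n_tot)
  net$omega_rate <- numeric(n_tot)
  net$phi <- integer(n_tot)
  net$V_i <- numeric(n_tot)
  net$G <- numeric(n_areas)
  net$step_count <- 0L
  class(net) <- "hebbnet_network"
  net
}

# Compile 0-based (pre, post, weight) triplets into CSC by presynaptic
# column: p has length n_col + 1, i holds 0-based post indices.
compile_csc <- function(pre, post, w, n_col) {
  ord <- order(pre, method = "radix")
  counts <- tabulate(pre + 1L, nbins = n_col)
  list(p = c(0L, cumsum(counts)),
       i = as.integer(post[ord]),
       x = as.numeric(w[ord]))
}

#' @export
print.hebbnet_network <- function(x, ...) {
  cat(sprintf(
    "hebbnet_network: %d areas, %d excitatory units, %d plastic EE edges\n",
    length(x$areas), x$n_tot, length(x$ee$x)))
  cat(sprintf("  backend: %s (dt=%g, %s), step %d\n", x$params$mode,
              x$params$dt, x$params$scheme, x$step_count))
  invisible(x)
}

#' Advance the network by one excitatory step
#'
#' One full excitatory time step, in the model's update order: inhibitory
#' and global-inhibitory units integrate the excitatory spikes of the
#' previous step, then the excitatory units integrate the freshly computed
#' inhibition together with delayed (previous-step) excitatory input and
#' any external drive, spike, and drive adaptation, firing-rate and
#' plasticity updates.  In felix mode this is the synchronous scheme with
#' same-step inhibition; in delay mode the identical schedule arises from
#' the staggered half-step grid, where inhibitory/global units live on
#' half-integer ticks (0.5-step synaptic delays in and out) and excitatory
#' units on integer ticks (1-step excitatory-to-excitatory delay), each
#' integrating exactly over its 1-step interval.
#'
#' @param net A [build_network()] environment.
#' @param drive Numeric external drive current per excitatory unit
#'   (length `net$n_tot`), or `NULL`.
#' @param noise_amplitude Amplitude of the area-level noise drive: each
#'   excitatory unit receives an additional uniform `[-0.5, 0.5] *
#'   noise_amplitude` current each step.  The per-neuron noise of the
#'   membrane equation (`k2` path) is always applied when `k2_exc > 0`.
#' @param plastic Apply the ABS rule to the excitatory-to-excitatory
#'   weights this step?
#' @return The binary spike vector of this step, invisibly.
#' @export
step_network <- function(net, drive = NULL, noise_amplitude = 0,
                         plastic = TRUE) {
  p <- net$params
  d <- net$decay
  pp <- net$pparams
  n <- net$n_tot
  spiking <- which(net$phi == 1L) - 1L   # 0-based presynaptic indices

  # inhibitory units: input from previous-step excitatory spikes
  inh_in <- p$strength_ei *
    csc_spike_input(net$ei$p, net$ei$i, net$ei$x, spiking, n)
  net$V_i <- d$inh * net$V_i + (1 - d$inh) * (p$k1_inh * inh_in)
  out_inh <- pmax(net$V_i, 0)

  # global inhibition: leaky integral of the area spike count
  cnt <- tabulate(net$area_of[spiking + 1L], nbins = length(net$G))
  net$G <- d$glob * net$G + (1 - d$glob) * (p$k1_glob * cnt)

  # excitatory input: delayed EE spikes, same-step inhibition, drive, noise
  I_e <- p$strength_ee *
    csc_spike_input(net$ee$p, net$ee$i, net$ee$x, spiking, n) -
    p$k_G * net$G[net$area_of] - p$strength_ie * out_inh
  if (!is.null(drive)) I_e <- I_e + drive
  if (noise_amplitude > 0)
    I_e <- I_e + stats::runif(n, -0.5, 0.5) * noise_amplitude
  eta <- if (p$k2_exc > 0) stats::runif(n, -0.5, 0.5) else 0
  net$V_e <- d$exc * net$V_e + (1 - d$exc) *
    (p$k1_exc * (I_e + p$k2_exc * eta))

  phi <- as.integer(net$V_e - p$psi * p$alpha * net$omega_adapt > p$thresh)

  # adaptation and rate estimate advance with the same-step output
  net$omega_adapt <- d$adapt * net$omega_adapt + (1 - d$adapt) * phi
  net$omega_rate <- d$favg * net$omega_rate + (1 - d$favg) * phi

  # ABS update over all plastic EE edges, on the pre-reset potential;
  # skipped when no postsynaptic unit can satisfy any branch
  if (plastic && max(net$V_e) >= pp$theta_minus) {
    abs_plasticity_csc(net$ee$p, net$ee$i, net$ee$x,
                       net$omega_rate >= pp$theta_pre, net$V_e,
                       pp$theta_plus, pp$theta_minus, pp$delta,
                       pp$w_min, pp$w_max)
  }

  if (isTRUE(p$spike_reset)) net$V_e[phi == 1L] <- 0
  net$phi <- phi
  net$step_count <- net$step_count + 1L
  if (net$step_count %% 100L == 0L) check_state(net)
  invisible(phi)
}

# numerical guard: name the first area whose state went non-finite
check_state <- function(net) {
  bad <- !is.finite(net$V_e)
  if (any(bad))
    stop("numerical instability: non-finite membrane potential in area ",
         net$areas[net$area_of[which(bad)[1]]])
  if (any(!is.finite(net$G)))
    stop("numerical instability: non-finite global inhibition in area ",
         net$areas[which(!is.finite(net$G))[1]])
  invisible(TRUE)
}

#' Run several steps, optionally recording spikes
#'
#' @inheritParams step_network
#' @param n_steps Number of excitatory steps.
#' @param record Return the binary spike raster?
#' @return If `record`, an integer raster of dimension
#'   `n_steps x n_tot` with class `spike_raster` (areas in the attribute
#'   `areas`, block size in `n_exc`); otherwise the network, invisibly.
#' @export
run_steps <- function(net, n_steps, drive = NULL, noise_amplitude = 0,
                      plastic = TRUE, record = FALSE) {
  raster <- if (record)
    matrix(0L, nrow = n_steps, ncol = net$n_tot)
  for (s in seq_len(n_steps)) {
    phi <- step_network(net, drive = drive,
                        noise_amplitude = noise_amplitude, plastic = plastic)
    if (record) raster[s, ] <- phi
  }
  if (record) {
    structure(raster, class = c("spike_raster", "matrix"),
              areas = net$areas, n_exc = net$arch$n_exc)
  } else {
    invisible(net)
  }
}

#' Build the external drive vector for a set of target cells
#'
#' @param net Network.
#' @param cells Named list mapping area name to 0-based excitatory cell
#'   indices within that area.
#' @param amplitude Drive current added to each targeted cell.
#' @return Numeric vector of length `net$n_tot`.
#' @export
drive_vector <- function(net, cells, amplitude) {
  v <- numeric(net$n_tot)
  for (a in names(cells)) {
    if (!a %in% net$areas) stop("drive_vector: unknown area '", a, "'")
    v[net$offsets[[a]] + cells[[a]] + 1L] <- amplitude
  }
  v
}

#' Edge table of the plastic excitatory-to-excitatory synapses
#'
#' @param net Network.
#' @return Data frame with 0-based global `pre`, `post` and current
#'   `weight` for every plastic edge.
#' @export
network_weights <- function(net) {
  ee <- net$ee
  ncol_ <- length(ee$p) - 1L
  # the weight store is mutated in place by the stepping engine; hand out
  # a detached copy so snapshots stay immutable
  data.frame(pre = rep.int(0:(ncol_ - 1L), diff(ee$p)),
             post = ee$i + 0L, weight = ee$x + 0)
}
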