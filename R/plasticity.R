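#' Discretised ABS Hebbian weight change
#'
#' The Artola-Broecher-Singer rule with two postsynaptic thresholds,
#' discretised to fixed steps of size `delta`:
#' * LTP (`+delta`) when the presynaptic rate estimate is at least
#'   `theta_pre` and the postsynaptic potential is at least `theta_plus`;
#' * homosynaptic LTD (`-delta`) when the presynaptic rate is at least
#'   `theta_pre` and the postsynaptic potential lies in
#'   `[theta_minus, theta_plus)`;
#' * heterosynaptic LTD (`-delta`) when the presynaptic rate is below
#'   `theta_pre` but the postsynaptic potential is at least `theta_plus`;
#' * no change otherwise.
#'
#' All threshold comparisons are inclusive (`>=`).  At the boundary
#' `V = theta_plus` both the LTP and homosynaptic-LTD conditions hold as
#' printed; the branches are evaluated in the order above, so LTP wins.
#'
#' @param omega_e_pre Presynaptic firing-rate estimate(s).
#' @param v_post Postsynaptic membrane potential(s).
#' @param p A [plasticity_parameters()] object.
#' @return Weight change(s): `+delta`, `-delta` or `0` (vectorised).
#' @export
#' @examples
#' p <- plasticity_parameters("nest")
#' hebbian_delta(0.06, 0.16, p)   # LTP:  +2e-4
#' hebbian_delta(0.06, 0.13, p)   # homosynaptic LTD: -2e-4
#' hebbian_delta(0.02, 0.16, p)   # heterosynaptic LTD: -2e-4
#' hebbian_delta(0.02, 0.05, p)   # no change
hebbian_delta <- function(omega_e_pre, v_post, p) {
  stopifnot(inherits(p, "plasticity_parameters"))
  n <- max(length(omega_e_pre), length(v_post))
  omega_e_pre <- rep_len(omega_e_pre, n)
  v_post <- rep_len(v_post, n)
  pre_active <- omega_e_pre >= p$theta_pre
  post_high <- v_post >= p$theta_plus
  post_mid <- v_post >= p$theta_minus & !post_high
  dw <- numeric(n)
  dw[pre_active & post_high] <- p$delta
  dw[pre_active & post_mid] <- -p$delta
  dw[!pre_active & post_high] <- -p$delta
  dw
}

#' Apply the ABS rule to every edge of a plastic projection
#'
#' Each edge weight is updated by [hebbian_delta()] evaluated at its
#' presynaptic rate estimate and postsynaptic potential, then clipped to
#' `[w_min, w_max]`.  Calling this on a non-plastic projection is a
#' contract violation.
#'
#' @param projection A plastic [wire_projection()] result.
#' @param pre_rates Firing-rate estimates of the source grid (indexed by
#'   0-based `pre`).
#' @param post_potentials Membrane potentials of the target grid (indexed
#'   by 0-based `post`).
#' @param p A [plasticity_parameters()] object.
#' @return The projection with updated edge weights.
#' @export
apply_plasticity <- function(projection, pre_rates, post_potentials, p) {
  stopifnot(inherits(projection, "projection"))
  if (!isTRUE(projection$spec$plastic))
    stop("apply_plasticity: projection is not plastic (synapse class ",
         projection$spec$synapse_class, ")")
  e <- projection$edges
  dw <- hebbian_delta(pre_rates[e$pre + 1L], post_potentials[e$post + 1L], p)
  projection$edges$weight <- pmin(p$w_max, pmax(p$w_min, e$weight + dw))
  projection
}
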