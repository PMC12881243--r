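#' Gaussian connection kernel specification
#'
#' A kernel describes the distance-dependent connection probability (or, for
#' excitatory-to-inhibitory synapses, the weight profile) between two 25x25
#' toroidal grids.  The probability of an edge at grid offset `(dx, dy)` from
#' the source cell follows a bivariate Gaussian,
#' \deqn{p(dx, dy) = k_C \exp\!\left(-\frac{(dx-\bar x)^2/\sigma_x^2 +
#'   (dy-\bar y)^2/\sigma_y^2 + 2q(dx-\bar x)(dy-\bar y)/(\sigma_x\sigma_y)}
#'   {2(1-q^2)}\right),}
#' truncated to a square window of half-width `half_width` cells.  The model
#' uses the isotropic special case (`mean_x = mean_y = 0`, `q = 0`)
#' throughout; the anisotropic form is retained for flexibility.
#'
#' @param sigma_x,sigma_y Standard deviations in grid-cell units (both > 0).
#'   `sigma_y` defaults to `sigma_x`.
#' @param k_c Amplitude (peak probability) in `[0, 1]`.
#' @param half_width Integer window radius in cells: 9 gives the 19x19
#'   window used for excitatory-to-excitatory links, 2 the 5x5 window of
#'   excitatory-to-inhibitory links.
#' @param mean_x,mean_y Offsets of the kernel centre (grid cells).
#' @param q Anisotropy coefficient, `|q| < 1`.
#' @return An object of class `kernel_spec`.
#' @seealso [kernel_probability()], [expected_out_degree()]
#' @export
#' @examples
#' k <- kernel_spec(sigma_x = 3.2, k_c = 0.15, half_width = 9)
#' kernel_probability(k, 0, 0)   # equals k_c at the centre
kernel_spec <- function(sigma_x, sigma_y = sigma_x, k_c, half_width,
                        mean_x = 0, mean_y = 0, q = 0) {
  stopifnot(is.numeric(sigma_x), is.numeric(sigma_y), is.numeric(k_c))
  if (sigma_x <= 0 || sigma_y <= 0)
    stop("kernel_spec: sigma_x and sigma_y must be positive")
  if (abs(q) >= 1)
    stop("kernel_spec: invalid kernel, |q| must be < 1")
  if (k_c < 0 || k_c > 1)
    stop("kernel_spec: k_c must lie in [0, 1]")
  half_width <- as.integer(half_width)
  if (length(half_width) != 1L || is.na(half_width) || half_width < 0L)
    stop("kernel_spec: half_width must be a non-negative integer")
  structure(
    list(sigma_x = sigma_x, sigma_y = sigma_y, k_c = k_c,
         half_width = half_width, mean_x = mean_x, mean_y = mean_y, q = q),
    class = "kernel_spec")
}

#' Evaluate a Gaussian connection kernel at grid offsets
#'
#' Returns the connection probability (bounded by the kernel amplitude
#' `k_c`) at signed toroidal offsets `(dx, dy)` from the source cell.
#' Offsets outside the kernel window evaluate to zero by convention.
#'
#' @param kernel A [kernel_spec()].
#' @param dx,dy Signed offsets in grid cells (vectorised, recycled).
#' @return Numeric vector of probabilities in `[0, k_c]`.
#' @export
kernel_probability <- function(kernel, dx, dy) {
  stopifnot(inherits(kernel, "kernel_spec"))
  ux <- dx - kernel$mean_x
  uy <- dy - kernel$mean_y
  expo <- (ux^2 / kernel$sigma_x^2 + uy^2 / kernel$sigma_y^2 +
             2 * kernel$q * ux * uy / (kernel$sigma_x * kernel$sigma_y)) /
    (2 * (1 - kernel$q^2))
  p <- kernel$k_c * exp(-expo)
  p[abs(dx) > kernel$half_width | abs(dy) > kernel$half_width] <- 0
  p
}

#' Analytic expected out-degree of a kernel-wired projection
#'
#' Sums the kernel probability over every offset in the window.  Because
#' wiring performs one independent Bernoulli trial per source-target pair,
#' this sum is the exact expectation of the number of connections a source
#' neuron forms, and serves as the analytic oracle for the stochastic
#' wiring routine.  With the local excitatory kernel (`sigma = 3.2`,
#' `k_c = 0.15`, 19x19 window) it evaluates to 9.60 including the
#' self-offset and 9.45 excluding it.
#'
#' @param kernel A [kernel_spec()].
#' @param exclude_self Drop the centre term (`dx = dy = 0`)?  Relevant for
#'   within-area wiring where the centre is the source neuron itself.
#' @return Expected number of connections per source neuron.
#' @export
expected_out_degree <- function(kernel, exclude_self = FALSE) {
  hw <- kernel$half_width
  off <- expand.grid(dx = -hw:hw, dy = -hw:hw)
  total <- sum(kernel_probability(kernel, off$dx, off$dy))
  if (exclude_self)
    total <- total - kernel_probability(kernel, 0, 0)
  total
}

#' Signed minimal toroidal offset between grid coordinates
#'
#' Both arguments are 0-based scalar coordinates (row or column) on a ring
#' of `n` cells; the result is the signed difference `to - from` wrapped
#' into `(-n/2, n/2]`.
#'
#' @param from,to 0-based coordinates (vectorised).
#' @param n Ring length (grid side, default 25).
#' @return Signed offsets.
#' @export
toroidal_offset <- function(from, to, n = 25L) {
  d <- (to - from) %% n
  ifelse(d > n / 2, d - n, d)
}

#' @rdname toroidal_offset
#' @param index 0-based linear cell index in `[0, n^2 - 1]` (row-major).
#' @export
grid_coords <- function(index, n = 25L) {
  cbind(row = index %/% n, col = index %% n)
}

#' @rdname toroidal_offset
#' @param row,col 0-based grid coordinates.
#' @export
grid_index <- function(row, col, n = 25L) {
  (row %% n) * n + (col %% n)
}
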