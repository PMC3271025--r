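# Toy bistable network of Rhodopsin production.
#
# Rhodopsin protein P induces its own production machinery through a
# sigmoidal positive-feedback loop (by analogy with classic bistable
# networks such as the lac operon); degradation is linear.  The mRNA level
# m is the control parameter: for low or high m the system is monostable,
# in an intermediate window it is bistable.  The repressor Dve keeps m low,
# holding the system in the monostable-low regime — it controls the
# stability of the network, not its state.

#' Toy network parameters
#'
#' @param m Rhodopsin mRNA level (dimensionless control parameter, > 0).
#' @param v_max Maximal induced production rate (> 0).
#' @param P_star Production threshold: protein level at half-activation.
#' @param h Hill steepness of the activation (>= 1).
#' @param basal Basal production rate (> 0); default 5% of `v_max`.
#' @param delta Linear degradation rate constant (> 0).
#' @return An object of class `toy_network_params`.
#' @export
toy_network_params <- function(m = 1, v_max = 1, P_star = 1, h = 4,
                               basal = 0.05 * v_max, delta = 0.45) {
  vals <- c(m, v_max, P_star, h, basal, delta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("toy_network_params: all parameters must be positive")
  }
  if (h < 1) stop("toy_network_params: h must be >= 1")
  structure(list(m = m, v_max = v_max, P_star = P_star, h = h,
                 basal = basal, delta = delta),
            class = "toy_network_params")
}

#' Protein production rate of the toy network
#'
#' `m * (basal + v_max * P^h / (P_star^h + P^h))`.
#'
#' @param P Protein level(s), >= 0.
#' @param params A `toy_network_params` object.
#' @return Production rate(s).
#' @export
production_rate <- function(P, params) {
  stopifnot(inherits(params, "toy_network_params"))
  if (any(P < 0)) stop("P must be >= 0")
  hill <- P^params$h / (params$P_star^params$h + P^params$h)
  hill[P == 0] <- 0  # guard 0^h/0^h at h tiny
  params$m * (params$basal + params$v_max * hill)
}

#' Locate fixed points of the toy network
#'
#' Roots of `production(P) - delta * P` on `[0, P_max]` by sign-change
#' bracketing on a dense grid followed by bisection (`uniroot`); stability
#' from the sign of the derivative of the net rate at each root.
#'
#' @param params A `toy_network_params` object.
#' @param P_max Upper end of the search bracket; default comfortably above
#'   the saturated production balance `m (basal + v_max) / delta`.
#' @param n_grid Grid resolution for bracketing.
#' @return A data.frame with columns `P` (steady-state level) and `stable`.
#' @export
find_fixed_points <- function(params, P_max = NULL, n_grid = 4000) {
  stopifnot(inherits(params, "toy_network_params"))
  if (is.null(P_max)) {
    P_max <- 2 * params$m * (params$basal + params$v_max) / params$delta
  }
  net <- function(P) production_rate(P, params) - params$delta * P
  grid <- seq(0, P_max, length.out = n_grid)
  v <- net(grid)
  roots <- numeric(0)
  if (v[1] == 0) roots <- c(roots, grid[1])
  sgn <- sign(v)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(net, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    roots <- c(roots, r)
  }
  # grid points that are exact zeros (rare)
  roots <- sort(unique(c(roots, grid[-1][v[-1] == 0])))
  eps <- max(P_max * 1e-7, 1e-10)
  stable <- vapply(roots, function(r) {
    (net(r + eps) - net(max(r - eps, 0))) < 0
  }, logical(1))
  data.frame(P = roots, stable = stable)
}

#' Classify the dynamical regime of the toy network
#'
#' Monostable-low, bistable, or monostable-high, from the number of stable
#' fixed points and their position relative to the production threshold
#' `P_star`.
#'
#' @param params A `toy_network_params` object.
#' @param ... Passed to [find_fixed_points()].
#' @return One of `"monostable_low"`, `"bistable"`, `"monostable_high"`.
#' @export
classify_regime <- function(params, ...) {
  fp <- find_fixed_points(params, ...)
  st <- fp$P[fp$stable]
  if (length(st) >= 2) return("bistable")
  if (length(st) == 0) stop("no stable fixed point located")
  if (st[1] < params$P_star) "monostable_low" else "monostable_high"
}

#' Regime diagram over a range of mRNA levels
#'
#' Sweeps the control parameter `m` and records the regime and fixed points
#' at each value; the table form of the bifurcation structure that Dve is
#' proposed to gate.
#'
#' @param m_values Numeric vector of mRNA levels to sweep.
#' @param params Base parameters (the `m` field is overridden).
#' @return A data.frame with `m`, `regime`, `n_fixed_points`, `P_low`,
#'   `P_high` (NA where a branch is absent).
#' @export
toy_regime_diagram <- function(m_values, params = toy_network_params()) {
  rows <- lapply(m_values, function(m) {
    p <- params
    p$m <- m
    fp <- find_fixed_points(p)
    st <- fp$P[fp$stable]
    data.frame(m = m, regime = classify_regime(p),
               n_fixed_points = nrow(fp),
               P_low = if (length(st)) min(st) else NA_real_,
               P_high = if (length(st)) max(st) else NA_real_)
  })
  do.call(rbind, rows)
}
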