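#' Repair rate at a given growth allocation
#'
#' Repair trades off linearly against growth: a cell growing at rate `g`
#' repairs damage at
#' `R(g) = R_max - repair_slope * (R_max - R_min) * (g / g_ref)`,
#' clamped to `[R_min, R_max]`. With `repair_slope = 1` and `g_ref = 1` this
#' is the classic two-endpoint form `R_max * (1 - g) + R_min * g`. The
#' trade-off is pinned to the physiology's reference growth range `g_ref`,
#' not to the current environment's `g_max`: after enrichment a cell growing
#' beyond `g_ref` is already allocating everything to growth, so its repair
#' stays clamped at `R_min` there.
#'
#' @param g Growth rate(s) in `[0, g_max]` (vectorised).
#' @param p A [model_params()] object.
#' @return Repair rate(s), strictly positive, in `[R_min, R_max]`.
#' @examples
#' p <- model_params()
#' repair_rate(0, p)   # R_max: all resources to repair
#' repair_rate(1, p)   # R_min: all resources to growth
#' @export
repair_rate <- function(g, p) {
  check_growth(g, p)
  r <- p$R_max - p$repair_slope * (p$R_max - p$R_min) * (g / p$g_ref)
  pmin(pmax(r, p$R_min), p$R_max)
}

#' Instantaneous rate of change of cellular damage
#'
#' Damage accrues in proportion to growth and is removed in proportion to the
#' current load: `dD/dt = g * D_max - R(g) * D`.
#'
#' @param D Current damage load(s), non-negative (vectorised with `g`).
#' @inheritParams repair_rate
#' @return `dD/dt` at the given state.
#' @examples
#' p <- model_params()
#' damage_derivative(equilibrium_damage(0.5, p), 0.5, p)  # 0 at equilibrium
#' @export
damage_derivative <- function(D, g, p) {
  check_growth(g, p)
  check_damage(D)
  g * p$D_max - repair_rate(g, p) * D
}

#' Equilibrium damage load for a cell growing at rate g
#'
#' The steady state of the damage dynamics, `D_eq(g) = D_max * g / R(g)`:
#' zero for a non-growing cell and strictly increasing in `g`.
#'
#' @inheritParams repair_rate
#' @return Equilibrium damage load(s), non-negative.
#' @examples
#' p <- model_params()
#' equilibrium_damage(1, p)  # = D_max / R_min = 100 at the defaults
#' @export
equilibrium_damage <- function(g, p) {
  check_growth(g, p)
  p$D_max * g / repair_rate(g, p)
}

#' Projected offspring damage after the relaxation time
#'
#' A daughter starts with the inherited load `D_p` and relaxes exponentially
#' toward the equilibrium set by her own growth rate over the time `delta_t`:
#' `D(delta_t) = D_eq(g) + (D_p - D_eq(g)) * exp(-R(g) * delta_t)`.
#' At `delta_t = 0` damage is entirely parental; as `delta_t` grows it is
#' entirely determined by the daughter's own growth.
#'
#' @param D_p Inherited (parental) damage load(s), non-negative.
#' @inheritParams repair_rate
#' @return Offspring damage, always between `D_p` and `D_eq(g)` inclusive.
#' @examples
#' p <- model_params(delta_t = 0.1)
#' projected_damage(2, 1, p)
#' @export
projected_damage <- function(D_p, g, p) {
  check_growth(g, p)
  check_damage(D_p, "D_p")
  deq <- equilibrium_damage(g, p)
  deq + (D_p - deq) * exp(-repair_rate(g, p) * p$delta_t)
}

#' Probability that an offspring with damage D is nonviable
#'
#' Hill-function mortality: `V(D) = D^alpha / (K^alpha + D^alpha)`, with
#' half-maximal mortality at `D = K` and steepness `alpha`. `K = Inf` gives
#' zero mortality everywhere (neutral control).
#'
#' @param D Damage load(s), non-negative.
#' @param p A [model_params()] object.
#' @return Mortality probabilities in `[0, 1)`.
#' @examples
#' p <- model_params(K = 2.5, alpha = 4)
#' mortality_probability(c(0, 2.5, 5), p)  # 0, 0.5, near 1
#' @export
mortality_probability <- function(D, p) {
  check_damage(D)
  if (!is.finite(p$K)) return(rep(0, length(D)))
  # ratio form avoids overflow of D^alpha at large alpha
  r <- (D / p$K)^p$alpha
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Expected viable-offspring production at equilibrium damage
#'
#' When damage is entirely offspring-determined (very large `delta_t`), a
#' lineage growing at `g` sits at `D_eq(g)` and produces viable offspring at
#' the effective rate `(1 - V(D_eq(g))) * g`. This deterministic curve
#' predicts the stochastic simulation's equilibrium growth rate in that limit.
#'
#' @inheritParams repair_rate
#' @return Effective growth rate(s).
#' @export
viable_equilibrium_growth <- function(g, p) {
  check_growth(g, p)
  (1 - mortality_probability(equilibrium_damage(g, p), p)) * g
}

#' Predicted equilibrium growth rate
#'
#' Maximises [viable_equilibrium_growth()] over `[0, g_max]`: the growth rate
#' a population is expected to settle at when damage is fully determined by
#' offspring growth, and the height of the reference line drawn on trajectory
#' plots. A coarse grid locates the basin; [stats::optimize()] refines it.
#'
#' @param p A [model_params()] object.
#' @param grid_n Number of coarse grid points used to bracket the optimum.
#' @return A list with elements `g_opt` (the argmax) and `value` (the
#'   effective growth there).
#' @examples
#' predicted_equilibrium_growth(model_params())
#' @export
predicted_equilibrium_growth <- function(p, grid_n = 2001L) {
  gs <- seq(0, p$g_max, length.out = grid_n)
  vals <- viable_equilibrium_growth(gs, p)
  i <- which.max(vals)
  lo <- gs[max(1L, i - 1L)]
  hi <- gs[min(grid_n, i + 1L)]
  if (lo == hi) {
    return(list(g_opt = gs[i], value = vals[i]))
  }
  opt <- stats::optimize(function(g) viable_equilibrium_growth(g, p),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  # the refined point can only improve on the grid point
  if (opt$objective >= vals[i]) {
    list(g_opt = opt$maximum, value = opt$objective)
  } else {
    list(g_opt = gs[i], value = vals[i])
  }
}

check_growth <- function(g, p) {
  if (!is.numeric(g) || anyNA(g)) {
    stop("growth rate must be numeric and non-missing", call. = FALSE)
  }
  if (any(g < 0) || any(g > p$g_max)) {
    stop(sprintf("growth rate must lie in [0, g_max = %.3g]", p$g_max),
         call. = FALSE)
  }
  invisible(g)
}

check_damage <- function(D, what = "damage") {
  if (!is.numeric(D) || anyNA(D)) {
    stop(sprintf("%s must be numeric and non-missing", what), call. = FALSE)
  }
  if (any(D < 0)) {
    stop(sprintf("%s must be non-negative", what), call. = FALSE)
  }
  invisible(D)
}
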