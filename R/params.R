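#' Model parameters for one environment
#'
#' Bundles every constant of the damage-repair life-history model for a single
#' environment: the permitted growth range, the damage and repair rates, the
#' repair-growth trade-off slope, the Hill mortality curve, the relaxation time
#' that weights parental versus offspring control of damage, and the mutation
#' kernel acting on the heritable growth rate.
#'
#' @param g_max Maximum permitted growth rate in this environment. 1.0 in the
#'   ancestral environment, 2.0 after enrichment.
#' @param D_max Maximum rate of damage production; damage accrues at
#'   `g * D_max`.
#' @param R_max Repair rate when all cellular resources are devoted to repair.
#' @param R_min Minimum repair rate (resources that cannot be diverted away
#'   from repair). Must be strictly positive so that equilibrium damage stays
#'   finite at high growth. The default 0.05 places the model's deterministic
#'   equilibrium growth near the values a stable environment supports.
#' @param repair_slope Slope of the linear repair-growth trade-off on
#'   `g / g_ref`, in (0, 1]. 1 for the reference scenario, 0.25 for cheap
#'   repair.
#' @param g_ref Reference growth range of the repair trade-off: the growth
#'   rate at which (with slope 1) repair bottoms out at `R_min`. This is a
#'   property of the cell's evolved physiology, not of the current
#'   environment: environmental enrichment raises `g_max` but leaves `g_ref`
#'   unchanged, so repair is pinned at `R_min` for `g >= g_ref`. Defaults to
#'   `g_max` (physiology adapted to the environment it lives in).
#' @param K Damage level at which offspring mortality probability is 0.5
#'   (Hill half-saturation). The reference value, anchored at the ancestral
#'   equilibrium, is `equilibrium_damage(g_ref) / 2 = 50` under the defaults.
#'   `Inf` disables mortality (useful for neutral controls).
#' @param alpha Hill steepness of the damage-mortality curve; larger values
#'   approach a step function at `K`.
#' @param delta_t Relaxation time over which a daughter's own metabolism
#'   reshapes its inherited damage. 0 means damage is fully parental; large
#'   values mean damage is fully determined by the daughter's growth rate.
#' @param mutation_scale Standard deviation of the Gaussian mutation applied
#'   to every offspring's growth rate (default kernel).
#' @param mutation_mode `"gaussian"` (every offspring perturbed by a
#'   `N(0, mutation_scale^2)` deviate, the default) or `"rare"` (each
#'   offspring mutates with probability `mutation_prob`, receiving a fixed
#'   effect of size `mutation_effect` with random sign).
#' @param mutation_prob Per-offspring mutation probability in `"rare"` mode.
#' @param mutation_effect Absolute effect size in `"rare"` mode.
#' @param inheritance Fraction of the parent's damage load present in the
#'   daughter immediately after division (1 = full transmission; 0.5 models
#'   an even split).
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()                 # ancestral defaults
#' p2 <- model_params(g_max = 2)      # enriched environment, same physiology
#' repair_rate(c(0, 0.5, 1), p)
#' @export
model_params <- function(g_max = 1.0,
                         D_max = 5,
                         R_max = 5,
                         R_min = 0.05,
                         repair_slope = 1,
                         g_ref = g_max,
                         K = D_max * g_ref / (2 * R_min),
                         alpha = 4,
                         delta_t = 0.1,
                         mutation_scale = 0.05,
                         mutation_mode = c("gaussian", "rare"),
                         mutation_prob = 0.05,
                         mutation_effect = 0.05,
                         inheritance = 1.0) {
  mutation_mode <- match.arg(mutation_mode)
  p <- structure(
    list(
      g_max = as.numeric(g_max),
      D_max = as.numeric(D_max),
      R_max = as.numeric(R_max),
      R_min = as.numeric(R_min),
      repair_slope = as.numeric(repair_slope),
      g_ref = as.numeric(g_ref),
      K = as.numeric(K),
      alpha = as.numeric(alpha),
      delta_t = as.numeric(delta_t),
      mutation_scale = as.numeric(mutation_scale),
      mutation_mode = mutation_mode,
      mutation_prob = as.numeric(mutation_prob),
      mutation_effect = as.numeric(mutation_effect),
      inheritance = as.numeric(inheritance)
    ),
    class = "model_params"
  )
  validate_model_params(p)
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in c("g_max", "D_max", "R_max", "R_min", "repair_slope", "g_ref",
              "K", "alpha", "delta_t", "mutation_scale", "mutation_prob",
              "mutation_effect", "inheritance")) {
    if (!num1(p[[f]])) {
      stop(sprintf("model_params field '%s' must be a single non-missing number", f),
           call. = FALSE)
    }
  }
  # K = Inf is the neutral (mortality-off) limit; every other field is finite
  for (f in c("g_max", "D_max", "R_max", "R_min", "repair_slope", "g_ref",
              "alpha", "delta_t", "mutation_scale", "mutation_prob",
              "mutation_effect", "inheritance")) {
    if (!is.finite(p[[f]])) {
      stop(sprintf("model_params field '%s' must be finite", f), call. = FALSE)
    }
  }
  if (p$g_max <= 0) stop("g_max must be > 0", call. = FALSE)
  if (p$D_max <= 0) stop("D_max must be > 0", call. = FALSE)
  if (p$R_max <= 0) stop("R_max must be > 0", call. = FALSE)
  if (p$R_min <= 0) stop("R_min must be > 0 (equilibrium damage diverges otherwise)",
                         call. = FALSE)
  if (p$R_min > p$R_max) stop("R_min must not exceed R_max", call. = FALSE)
  if (p$repair_slope <= 0 || p$repair_slope > 1) {
    stop("repair_slope must lie in (0, 1]", call. = FALSE)
  }
  if (p$g_ref <= 0) stop("g_ref must be > 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  if (p$alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (p$delta_t < 0) stop("delta_t must be >= 0", call. = FALSE)
  if (p$mutation_scale < 0) stop("mutation_scale must be >= 0", call. = FALSE)
  if (p$mutation_prob < 0 || p$mutation_prob > 1) {
    stop("mutation_prob must lie in [0, 1]", call. = FALSE)
  }
  if (p$mutation_effect < 0) stop("mutation_effect must be >= 0", call. = FALSE)
  if (p$inheritance < 0 || p$inheritance > 1) {
    stop("inheritance must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' Update fields of a model_params object
#'
#' @param p A [model_params()] object.
#' @param ... Named fields to replace (validated after replacement).
#' @return A new `model_params` object.
#' @examples
#' enriched <- update_params(model_params(), g_max = 2)
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "model_params"))
  upd <- list(...)
  if (length(upd) == 0L) return(p)
  if (is.null(names(upd)) || any(names(upd) == "")) {
    stop("all arguments to update_params() must be named", call. = FALSE)
  }
  unknown <- setdiff(names(upd), names(p))
  if (length(unknown)) {
    stop("unknown model_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(upd)) p[[nm]] <- upd[[nm]]
  if (is.character(p$mutation_mode)) {
    p$mutation_mode <- match.arg(p$mutation_mode, c("gaussian", "rare"))
  }
  validate_model_params(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Damage-repair model parameters\n")
  cat(sprintf("  growth:    g in [0, %.3g]\n", x$g_max))
  cat(sprintf("  damage:    D_max = %.3g\n", x$D_max))
  cat(sprintf("  repair:    R_max = %.3g, R_min = %.3g, slope = %.3g over g_ref = %.3g\n",
              x$R_max, x$R_min, x$repair_slope, x$g_ref))
  cat(sprintf("  mortality: Hill K = %.4g, alpha = %.3g\n", x$K, x$alpha))
  cat(sprintf("  damage relaxation time delta_t = %.3g\n", x$delta_t))
  if (x$mutation_mode == "gaussian") {
    cat(sprintf("  mutation:  Gaussian, sd = %.3g (every offspring)\n",
                x$mutation_scale))
  } else {
    cat(sprintf("  mutation:  rare, P = %.3g, effect = +/- %.3g\n",
                x$mutation_prob, x$mutation_effect))
  }
  if (x$inheritance != 1) {
    cat(sprintf("  damage inheritance factor = %.3g\n", x$inheritance))
  }
  invisible(x)
}
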