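#' Built-in scenario labels
#'
#' @return Character vector of the recognised scenario labels.
#' @export
scenario_labels <- function() {
  c("reference", "damage_tolerance", "cheap_repair", "damage_reduction",
    "constant_1.0", "constant_2.0")
}

#' Build a named enrichment scenario
#'
#' A scenario pairs an ancestral and an enriched parameter set. Enrichment
#' raises the maximum growth rate from 1.0 to 2.0; the escape scenarios
#' additionally alter one aspect of damage physiology in the enriched
#' environment:
#'
#' * `reference` — damage tolerance, repair and damage rates identical in
#'   both environments; only `g_max` changes.
#' * `damage_tolerance` — the Hill half-saturation rises from the ancestral
#'   `D_eq(1)/2` to `D_eq(1)/1.1`, so cells tolerate more damage before
#'   mortality bites.
#' * `cheap_repair` — the repair-growth trade-off slope drops from 1 to
#'   0.25, so fast growth diverts fewer resources from repair.
#' * `damage_reduction` — the damage rate drops from 5 to 2, so each unit of
#'   growth produces less damage.
#' * `constant_1.0`, `constant_2.0` — single stable environment throughout
#'   (no switch); controls for the equilibria each environment supports.
#'
#' `K` is anchored at the ancestral maximum growth rate: it evolves in (is
#' set by) the ancestral environment and remains fixed after the switch.
#'
#' @param label One of [scenario_labels()].
#' @param ... Named overrides applied to *both* environments' parameters
#'   (e.g. `delta_t = 0.4`, `alpha = 10`, `R_min = 1`), applied before the
#'   scenario-specific enriched-side modification. An explicit `K` override
#'   suppresses the equilibrium anchoring and fixes `K` in both environments
#'   (including for `damage_tolerance`).
#' @return An object of class `scenario`: list with `label`, `ancestral` and
#'   `enriched` [model_params()], and `constant` (logical: single
#'   environment, no switch).
#' @examples
#' sc <- build_scenario("cheap_repair", delta_t = 0.1, alpha = 4)
#' sc$enriched$repair_slope   # 0.25
#' @export
build_scenario <- function(label, ...) {
  label <- as.character(label)[1]
  if (!label %in% scenario_labels()) {
    stop("unknown scenario label '", label, "'; known labels: ",
         paste(scenario_labels(), collapse = ", "), call. = FALSE)
  }
  dots <- list(...)
  K_override <- dots$K
  base <- do.call(update_params,
                  c(list(model_params()), dots[names(dots) != "K"]))

  # K is set where the resident population equilibrates: half the equilibrium
  # damage at the maximum growth rate of the environment it is adapted to
  anc <- update_params(base, g_max = 1.0, g_ref = 1.0)
  anc <- update_params(anc, K = K_override %||% (equilibrium_damage(1.0, anc) / 2))

  if (label == "constant_1.0") {
    return(new_scenario(label, anc, anc, constant = TRUE))
  }
  if (label == "constant_2.0") {
    # a population native to the richer environment: its repair trade-off
    # spans, and its damage tolerance is anchored at, its own growth range
    env2 <- update_params(base, g_max = 2.0, g_ref = 2.0)
    env2 <- update_params(env2,
                          K = K_override %||% (equilibrium_damage(2.0, env2) / 2))
    return(new_scenario(label, env2, env2, constant = TRUE))
  }

  # enrichment raises the permitted growth range; the repair physiology
  # (g_ref) and the ancestrally evolved K carry over unchanged
  enr <- update_params(anc, g_max = 2.0)
  enr <- switch(label,
    reference = enr,
    damage_tolerance = update_params(
      enr, K = K_override %||% (equilibrium_damage(1.0, anc) / 1.1)),
    cheap_repair = update_params(enr, repair_slope = 0.25),
    damage_reduction = update_params(enr, D_max = 2)
  )
  new_scenario(label, anc, enr, constant = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_scenario <- function(label, ancestral, enriched, constant) {
  structure(list(label = label, ancestral = ancestral, enriched = enriched,
                 constant = constant),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'%s\n", x$label,
              if (x$constant) " (constant environment)" else ""))
  if (x$constant) {
    cat(sprintf("  g_max = %.3g, D_max = %.3g, K = %.4g, slope = %.3g\n",
                x$enriched$g_max, x$enriched$D_max, x$enriched$K,
                x$enriched$repair_slope))
  } else {
    cat(sprintf("  ancestral: g_max = %.3g, D_max = %.3g, K = %.4g, slope = %.3g\n",
                x$ancestral$g_max, x$ancestral$D_max, x$ancestral$K,
                x$ancestral$repair_slope))
    cat(sprintf("  enriched:  g_max = %.3g, D_max = %.3g, K = %.4g, slope = %.3g\n",
                x$enriched$g_max, x$enriched$D_max, x$enriched$K,
                x$enriched$repair_slope))
  }
  cat(sprintf("  delta_t = %.3g, alpha = %.3g\n",
              x$enriched$delta_t, x$enriched$alpha))
  invisible(x)
}

#' Run the enrichment protocol for one replicate
#'
#' For an enrichment scenario: equilibrate the population under the ancestral
#' parameters for `burn_in` generations, reset the selective-death counter,
#' switch instantaneously to the enriched parameters, and evolve for
#' `generations` further generations. Constant scenarios skip the switch and
#' simply evolve `generations` generations in their single environment from
#' the seeded state.
#'
#' @param scenario A [build_scenario()] object.
#' @param N Population size (default 1000).
#' @param generations Generations in the (post-switch) environment
#'   (default 1000).
#' @param burn_in Ancestral equilibration generations before the switch
#'   (default 1000; ignored for constant scenarios).
#' @param seed Optional integer seed set before the run; `NULL` leaves the
#'   RNG state untouched.
#' @param record If `TRUE` (default), keep the per-generation trajectory.
#' @param g0 Seeding growth rate for the initial population.
#' @return An object of class `prodigal_run`: list with the scenario, run
#'   settings, `final` summary (`mean_g`, `var_g`, `mean_D`, `var_D`,
#'   `selective_deaths`), the final `population`, and (if recorded) a
#'   `trajectory` data frame with a `phase` column (`"ancestral"` /
#'   `"enriched"` / `"constant"`). Selective deaths count post-switch events
#'   only.
#' @examples
#' run <- run_enrichment(build_scenario("reference", delta_t = 0.1),
#'                       N = 200, generations = 100, burn_in = 100, seed = 1)
#' summary(run)
#' @export
run_enrichment <- function(scenario, N = 1000L, generations = 1000L,
                           burn_in = 1000L, seed = NULL, record = TRUE,
                           g0 = 0.5) {
  stopifnot(inherits(scenario, "scenario"))
  N <- as.integer(N); generations <- as.integer(generations)
  burn_in <- as.integer(burn_in)
  if (N < 1L) stop("N must be positive", call. = FALSE)
  if (generations < 0L || burn_in < 0L) {
    stop("generations and burn_in must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  traj <- NULL
  if (scenario$constant) {
    pop <- init_population(scenario$enriched, N, g0 = g0)
    pop <- run_generations(pop, scenario$enriched, generations, record = record)
    if (record) {
      traj <- attr(pop, "trajectory")
      if (nrow(traj)) traj$phase <- "constant"
      else traj$phase <- character(0)
    }
  } else {
    pop <- init_population(scenario$ancestral, N, g0 = g0)
    if (burn_in > 0L) {
      pop <- with_run_phase(
        run_generations(pop, scenario$ancestral, burn_in, record = record),
        scenario, "ancestral")
    }
    anc_traj <- if (record) attr(pop, "trajectory") else NULL
    if (!is.null(anc_traj) && nrow(anc_traj)) anc_traj$phase <- "ancestral"
    pop$selective_deaths <- 0
    pop <- with_run_phase(
      run_generations(pop, scenario$enriched, generations, record = record),
      scenario, "enriched")
    if (record) {
      enr_traj <- attr(pop, "trajectory")
      if (nrow(enr_traj)) enr_traj$phase <- "enriched"
      else enr_traj$phase <- character(0)
      traj <- rbind(anc_traj, enr_traj)
    }
  }

  out <- structure(
    list(scenario = scenario,
         N = N, generations = generations,
         burn_in = if (scenario$constant) 0L else burn_in,
         seed = seed,
         final = list(mean_g = mean(pop$g),
                      var_g = stats::var(pop$g),
                      mean_D = mean(pop$D),
                      var_D = stats::var(pop$D),
                      selective_deaths = pop$selective_deaths),
         population = pop,
         trajectory = traj),
    class = "prodigal_run"
  )
  out
}

# re-tag extinction errors with the phase in which they occurred
with_run_phase <- function(expr, scenario, phase) {
  withCallingHandlers(
    expr,
    prodigal_extinction = function(e) {
      e$message <- sprintf("[scenario %s, %s phase] %s",
                           scenario$label, phase, e$message)
      e$phase <- phase
      stop(e)
    })
}

#' @export
print.prodigal_run <- function(x, ...) {
  cat(sprintf("Enrichment run: scenario '%s', N = %d, %d generations%s\n",
              x$scenario$label, x$N, x$generations,
              if (x$burn_in > 0) sprintf(" (+%d burn-in)", x$burn_in) else ""))
  cat(sprintf("  final mean growth %.4f (var %.3g)\n",
              x$final$mean_g, x$final$var_g))
  cat(sprintf("  final mean damage %.4f (var %.3g)\n",
              x$final$mean_D, x$final$var_D))
  cat(sprintf("  selective deaths (post-switch): %.0f\n",
              x$final$selective_deaths))
  invisible(x)
}

#' @export
summary.prodigal_run <- function(object, ...) {
  out <- data.frame(
    scenario = object$scenario$label,
    delta_t = object$scenario$enriched$delta_t,
    alpha = object$scenario$enriched$alpha,
    N = object$N,
    generations = object$generations,
    mean_g = object$final$mean_g,
    var_g = object$final$var_g,
    mean_D = object$final$mean_D,
    var_D = object$final$var_D,
    selective_deaths = object$final$selective_deaths
  )
  class(out) <- c("summary.prodigal_run", "data.frame")
  out
}

#' Plot a simulation trajectory
#'
#' Mean growth rate per generation, with a shaded band of +/- one
#' within-population standard deviation, the environment switch marked, and
#' the deterministic equilibrium prediction drawn as a horizontal reference
#' line.
#'
#' @param x A `prodigal_run` with a recorded trajectory.
#' @param what `"growth"` or `"damage"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prodigal_run <- function(x, what = c("growth", "damage"), ...) {
  what <- match.arg(what)
  tr <- x$trajectory
  if (is.null(tr) || !nrow(tr)) {
    stop("run has no recorded trajectory (record = FALSE?)", call. = FALSE)
  }
  mcol <- if (what == "growth") "mean_g" else "mean_D"
  vcol <- if (what == "growth") "var_g" else "var_D"
  gen <- seq_len(nrow(tr))
  m <- tr[[mcol]]; s <- sqrt(tr[[vcol]])
  graphics::plot(gen, m, type = "n",
                 xlab = "generation",
                 ylab = if (what == "growth") "mean growth rate" else "mean damage",
                 ylim = range(c(m - s, m + s)), ...)
  graphics::polygon(c(gen, rev(gen)), c(m - s, rev(m + s)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(gen, m, col = "navy", lwd = 1.5)
  n_anc <- sum(tr$phase == "ancestral")
  if (n_anc > 0 && n_anc < nrow(tr)) {
    graphics::abline(v = n_anc + 0.5, lty = 3)
  }
  if (what == "growth") {
    pred <- predicted_equilibrium_growth(x$scenario$enriched)
    graphics::abline(h = pred$g_opt, col = "red", lty = 2)
  }
  invisible(x)
}
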