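#' Create a population of identical cells
#'
#' Seeds `N` cells at growth rate `g0` carrying the equilibrium damage load
#' for that growth rate (unless `D0` overrides it), with the generation
#' counter and the cumulative selective-death counter at zero.
#'
#' @param p A [model_params()] object.
#' @param N Population size (held fixed across generations).
#' @param g0 Starting growth rate for every cell.
#' @param D0 Starting damage load; defaults to `equilibrium_damage(g0, p)`.
#' @return An object of class `population`: list with numeric vectors `g`
#'   and `D` of length `N`, integer `generation`, and numeric counter
#'   `selective_deaths`.
#' @examples
#' pop <- init_population(model_params(), N = 100)
#' @export
init_population <- function(p, N, g0 = 0.5, D0 = NULL) {
  stopifnot(inherits(p, "model_params"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  check_growth(g0, p)
  if (is.null(D0)) D0 <- equilibrium_damage(g0, p)
  check_damage(D0, "D0")
  structure(
    list(g = rep(as.numeric(g0), N),
         D = rep(as.numeric(D0), N),
         generation = 0L,
         selective_deaths = 0),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "Population of %d cells at generation %d\n", length(x$g), x$generation))
  cat(sprintf("  mean growth %.4f (var %.3g), mean damage %.4f (var %.3g)\n",
              mean(x$g), stats::var(x$g), mean(x$D), stats::var(x$D)))
  cat(sprintf("  cumulative selective deaths: %.0f\n", x$selective_deaths))
  invisible(x)
}

#' Sample parent indices weighted by growth rate
#'
#' Draws cell indices with replacement, each cell chosen with probability
#' proportional to its growth rate — faster dividers contribute more
#' offspring to the next generation.
#'
#' @param pop A [init_population()] object.
#' @param n Number of draws.
#' @return Integer vector of `n` cell indices.
#' @export
sample_parent <- function(pop, n = 1L) {
  stopifnot(inherits(pop, "population"))
  total <- sum(pop$g)
  if (total <= 0) {
    stop("degenerate population: all growth rates are zero, no cell can reproduce",
         call. = FALSE)
  }
  sample.int(length(pop$g), size = n, replace = TRUE, prob = pop$g)
}

#' Mutate offspring growth rates
#'
#' Applies the configured mutation kernel to parental growth rates and clamps
#' the result to the permitted range `[0, g_max]`. In `"gaussian"` mode every
#' offspring receives a `N(0, mutation_scale^2)` perturbation; in `"rare"`
#' mode each offspring mutates with probability `mutation_prob` by a fixed
#' effect `mutation_effect` of random sign.
#'
#' @param g Parental growth rate(s).
#' @param p A [model_params()] object.
#' @return Mutated growth rate(s) in `[0, g_max]`.
#' @export
mutate_growth <- function(g, p) {
  check_growth(g, p)
  n <- length(g)
  if (p$mutation_mode == "gaussian") {
    out <- g + stats::rnorm(n, 0, p$mutation_scale)
  } else {
    hit <- stats::runif(n) < p$mutation_prob
    eff <- ifelse(stats::runif(n) < 0.5, -1, 1) * p$mutation_effect
    out <- g + ifelse(hit, eff, 0)
  }
  pmin(pmax(out, 0), p$g_max)
}

#' Attempt one reproduction event per parent
#'
#' For each parent: mutate the growth rate, project the offspring damage from
#' the inherited load and the offspring's own growth over `delta_t`, then
#' kill the offspring with its Hill mortality probability. Viability is
#' evaluated on the offspring's own projected damage, which is what lets the
#' relaxation time modulate selection.
#'
#' @param parent_g,parent_D Parental growth rate(s) and damage load(s)
#'   (vectorised; recycled to common length).
#' @param p A [model_params()] object.
#' @return A data frame with columns `viable` (logical), `g` and `D`
#'   (the offspring trait values, filled also for nonviable attempts).
#' @export
attempt_reproduction <- function(parent_g, parent_D, p) {
  n <- max(length(parent_g), length(parent_D))
  parent_g <- rep_len(parent_g, n)
  parent_D <- rep_len(parent_D, n)
  check_growth(parent_g, p)
  check_damage(parent_D, "parent_D")
  g_off <- mutate_growth(parent_g, p)
  D_off <- projected_damage(p$inheritance * parent_D, g_off, p)
  dies <- stats::runif(n) < mortality_probability(D_off, p)
  data.frame(viable = !dies, g = g_off, D = D_off)
}

#' Advance a population through one or more generations
#'
#' Runs the non-overlapping-generations loop: parents are sampled with
#' replacement weighted by growth rate, each sampled parent attempts a
#' reproduction ([attempt_reproduction()] semantics), nonviable offspring
#' increment the selective-death counter, and sampling continues until all
#' `N` slots of the next generation are filled. The loop runs in compiled
#' code; trajectories are bit-reproducible given [set.seed()].
#'
#' @param pop A `population` object.
#' @param p A [model_params()] object.
#' @param n_gen Number of generations to advance.
#' @param record If `TRUE`, attach a per-generation trajectory.
#' @param max_attempts_per_gen Cap on reproduction attempts within one
#'   generation; exceeding it raises an extinction error (condition class
#'   `prodigal_extinction`). Default `1000 * N`.
#' @return The advanced `population`. If `record = TRUE` it carries a
#'   `trajectory` attribute: a data frame with columns `generation`,
#'   `mean_g`, `var_g`, `mean_D`, `var_D`, `cum_selective_deaths`,
#'   `attempts`.
#' @examples
#' set.seed(1)
#' pop <- init_population(model_params(), N = 200)
#' pop <- run_generations(pop, model_params(), n_gen = 50)
#' @export
run_generations <- function(pop, p, n_gen, record = FALSE,
                            max_attempts_per_gen = NULL) {
  stopifnot(inherits(pop, "population"), inherits(p, "model_params"))
  n_gen <- as.integer(n_gen)
  if (is.na(n_gen) || n_gen < 0L) stop("n_gen must be >= 0", call. = FALSE)
  N <- length(pop$g)
  if (is.null(max_attempts_per_gen)) max_attempts_per_gen <- 1000 * N
  if (n_gen == 0L) {
    if (record) attr(pop, "trajectory") <- empty_trajectory()
    return(pop)
  }
  res <- sim_generations_cpp(
    pop$g, pop$D, n_gen,
    p$g_max, p$D_max, p$R_max, p$R_min, p$repair_slope, p$g_ref, p$K, p$alpha,
    p$delta_t, p$mutation_scale,
    if (p$mutation_mode == "gaussian") 0L else 1L,
    p$mutation_prob, p$mutation_effect, p$inheritance,
    pop$selective_deaths, as.numeric(max_attempts_per_gen), record)

  if (res$status == 2L) {
    stop(degenerate_condition(pop$generation + res$failed_generation))
  }
  if (res$status == 1L) {
    stop(extinction_condition(pop$generation + res$failed_generation))
  }
  out <- structure(
    list(g = res$g, D = res$D,
         generation = pop$generation + res$generations_done,
         selective_deaths = res$selective_deaths),
    class = "population"
  )
  if (record) {
    tr <- as.data.frame(res$trajectory)
    names(tr) <- c("mean_g", "var_g", "mean_D", "var_D",
                   "cum_selective_deaths", "attempts")
    tr <- cbind(generation = pop$generation + seq_len(nrow(tr)), tr)
    attr(out, "trajectory") <- tr
  }
  out
}

#' @rdname run_generations
#' @export
advance_generation <- function(pop, p, max_attempts_per_gen = NULL) {
  run_generations(pop, p, n_gen = 1L, record = FALSE,
                  max_attempts_per_gen = max_attempts_per_gen)
}

#' Equilibrate a population in the ancestral environment
#'
#' Seeds `N` cells at `g0` with the matching equilibrium damage and evolves
#' them for `burn_in` generations under the ancestral parameters, so that the
#' growth-damage state reflects mutation-selection balance in that
#' environment. The selective-death counter is reset to zero afterwards, so
#' deaths reported by later phases count from the moment of release.
#'
#' @param p_ancestral Ancestral [model_params()] (typically `g_max = 1`).
#' @param N Population size.
#' @param burn_in Number of equilibration generations.
#' @param g0 Seeding growth rate.
#' @return An equilibrated `population` with `generation` and
#'   `selective_deaths` reset to zero.
#' @export
init_ancestral_population <- function(p_ancestral, N, burn_in = 1000L,
                                      g0 = 0.5) {
  pop <- init_population(p_ancestral, N, g0 = g0)
  if (burn_in > 0) pop <- run_generations(pop, p_ancestral, burn_in)
  pop$generation <- 0L
  pop$selective_deaths <- 0
  pop
}

empty_trajectory <- function() {
  data.frame(generation = integer(0), mean_g = numeric(0),
             var_g = numeric(0), mean_D = numeric(0), var_D = numeric(0),
             cum_selective_deaths = numeric(0), attempts = numeric(0))
}

extinction_condition <- function(generation) {
  structure(
    class = c("prodigal_extinction", "error", "condition"),
    list(message = sprintf(
           paste0("population extinction: reproduction attempt cap exceeded ",
                  "at generation %d (offspring mortality too high to refill ",
                  "the population)"), generation),
         call = NULL,
         generation = generation)
  )
}

degenerate_condition <- function(generation) {
  structure(
    class = c("prodigal_degenerate", "error", "condition"),
    list(message = sprintf(
           "degenerate population at generation %d: all growth rates are zero",
           generation),
         call = NULL,
         generation = generation)
  )
}
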