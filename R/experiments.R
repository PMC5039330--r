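#' Specify a parameter sweep
#'
#' A sweep crosses scenarios with the relaxation-time and Hill-steepness
#' grids and runs a fixed number of independently seeded replicates per grid
#' cell. Per-cell, per-replicate seeds are pre-derived from `master_seed` in
#' a fixed grid order, so results do not depend on execution order and rerun
#' bit-identically.
#'
#' @param scenarios Character vector of [scenario_labels()].
#' @param delta_t Grid of relaxation times (default the canonical six).
#' @param alpha Grid of Hill steepnesses (default 2, 4, 10).
#' @param replicates Independent runs per grid cell (default 100).
#' @param N Population size (default 1000).
#' @param generations Post-switch generations (default 1000).
#' @param burn_in Ancestral burn-in for enrichment scenarios (default 1000).
#' @param master_seed Integer master seed from which all replicate seeds are
#'   derived.
#' @param ... Extra [model_params()] overrides applied to every scenario
#'   (e.g. `R_min`, `mutation_mode`).
#' @return An object of class `sweep_spec`.
#' @examples
#' spec <- sweep_spec("reference", delta_t = c(0.01, 0.1), alpha = 4,
#'                    replicates = 2, N = 100, generations = 50, burn_in = 50)
#' @export
sweep_spec <- function(scenarios = "reference",
                       delta_t = c(0.01, 0.05, 0.1, 0.4, 0.8, 1.0),
                       alpha = c(2, 4, 10),
                       replicates = 100L,
                       N = 1000L,
                       generations = 1000L,
                       burn_in = 1000L,
                       master_seed = 1L,
                       ...) {
  scenarios <- as.character(scenarios)
  unknown <- setdiff(scenarios, scenario_labels())
  if (length(unknown)) {
    stop("unknown scenario label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(scenarios) || !length(delta_t) || !length(alpha)) {
    stop("scenario, delta_t and alpha grids must be non-empty", call. = FALSE)
  }
  if (any(delta_t < 0)) stop("delta_t values must be >= 0", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha values must be > 0", call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  structure(
    list(scenarios = scenarios,
         delta_t = as.numeric(delta_t),
         alpha = as.numeric(alpha),
         replicates = replicates,
         N = as.integer(N),
         generations = as.integer(generations),
         burn_in = as.integer(burn_in),
         master_seed = as.integer(master_seed),
         overrides = list(...)),
    class = "sweep_spec"
  )
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("Sweep specification\n")
  cat("  scenarios: ", paste(x$scenarios, collapse = ", "), "\n", sep = "")
  cat("  delta_t:   ", paste(x$delta_t, collapse = ", "), "\n", sep = "")
  cat("  alpha:     ", paste(x$alpha, collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d replicates x N = %d x %d generations (burn-in %d), master seed %d\n",
              x$replicates, x$N, x$generations, x$burn_in, x$master_seed))
  cat(sprintf("  total runs: %d\n",
              length(x$scenarios) * length(x$delta_t) * length(x$alpha) *
                x$replicates))
  invisible(x)
}

# fixed grid order: scenario (outer) x delta_t x alpha x replicate (inner)
sweep_grid <- function(spec) {
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      alpha = spec$alpha,
                      delta_t = spec$delta_t,
                      scenario = spec$scenarios,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("scenario", "delta_t", "alpha", "replicate")]
  rownames(grid) <- NULL
  grid
}

# one reproducible seed per run, derived from the master seed in grid order
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a parameter sweep
#'
#' Executes every (scenario, delta_t, alpha, replicate) combination of the
#' spec with its pre-derived seed and collects per-replicate final-state
#' summaries plus an aggregated per-cell table. Replicates that go extinct
#' are recorded in the `status` column (with `NA` summaries) rather than
#' aborting the sweep.
#'
#' @param spec A [sweep_spec()].
#' @param progress If `TRUE`, print one line per grid cell to standard error.
#' @return An object of class `sweep_result`: list with `spec`,
#'   `replicates` (one row per run: scenario, delta_t, alpha, replicate,
#'   seed, status, mean_g, var_g, mean_D, var_D, selective_deaths) and
#'   `summary` (per grid cell: across-replicate means and variances of the
#'   final population means, mean within-population variances, mean and
#'   total selective deaths, replicate counts).
#' @examples
#' res <- run_sweep(sweep_spec("constant_1.0", delta_t = 0.1, alpha = 4,
#'                             replicates = 2, N = 100, generations = 50))
#' res$summary
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- sweep_grid(spec)
  seeds <- derive_seeds(spec$master_seed, nrow(grid))
  scen_cache <- list()

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    key <- sprintf("%s|%g|%g", gr$scenario, gr$delta_t, gr$alpha)
    sc <- scen_cache[[key]]
    if (is.null(sc)) {
      sc <- do.call(build_scenario,
                    c(list(label = gr$scenario, delta_t = gr$delta_t,
                           alpha = gr$alpha),
                      spec$overrides))
      scen_cache[[key]] <- sc
    }
    if (progress && gr$replicate == 1L) {
      message(sprintf("sweep: %s delta_t=%g alpha=%g", gr$scenario,
                      gr$delta_t, gr$alpha))
    }
    run <- tryCatch(
      run_enrichment(sc, N = spec$N, generations = spec$generations,
                     burn_in = spec$burn_in, seed = seeds[i], record = FALSE),
      prodigal_extinction = function(e) e,
      prodigal_degenerate = function(e) e
    )
    if (inherits(run, "condition")) {
      rows[[i]] <- data.frame(
        gr, seed = seeds[i],
        status = if (inherits(run, "prodigal_extinction")) "extinct"
                 else "degenerate",
        mean_g = NA_real_, var_g = NA_real_,
        mean_D = NA_real_, var_D = NA_real_,
        selective_deaths = NA_real_)
    } else {
      rows[[i]] <- data.frame(
        gr, seed = seeds[i], status = "ok",
        mean_g = run$final$mean_g, var_g = run$final$var_g,
        mean_D = run$final$mean_D, var_D = run$final$var_D,
        selective_deaths = run$final$selective_deaths)
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  structure(list(spec = spec,
                 replicates = reps,
                 summary = aggregate_sweep(reps)),
            class = "sweep_result")
}

# across-replicate aggregation; reproducible from the per-replicate table
aggregate_sweep <- function(reps) {
  ok <- reps[reps$status == "ok", , drop = FALSE]
  cells <- unique(reps[, c("scenario", "delta_t", "alpha")])
  rownames(cells) <- NULL
  agg_one <- function(cell) {
    sel <- ok$scenario == cell$scenario & ok$delta_t == cell$delta_t &
      ok$alpha == cell$alpha
    d <- ok[sel, , drop = FALSE]
    n <- nrow(d)
    v <- function(x) if (n > 1L) stats::var(x) else NA_real_
    data.frame(
      cell,
      n_ok = n,
      n_extinct = sum(reps$scenario == cell$scenario &
                        reps$delta_t == cell$delta_t &
                        reps$alpha == cell$alpha &
                        reps$status != "ok"),
      mean_g = if (n) mean(d$mean_g) else NA_real_,
      var_mean_g = if (n) v(d$mean_g) else NA_real_,
      mean_within_var_g = if (n) mean(d$var_g) else NA_real_,
      mean_D = if (n) mean(d$mean_D) else NA_real_,
      var_mean_D = if (n) v(d$mean_D) else NA_real_,
      mean_within_var_D = if (n) mean(d$var_D) else NA_real_,
      mean_selective_deaths = if (n) mean(d$selective_deaths) else NA_real_,
      total_selective_deaths = if (n) sum(d$selective_deaths) else NA_real_)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)),
                               function(i) agg_one(cells[i, ])))
  rownames(out) <- NULL
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep result: %d runs over %d grid cells\n",
              nrow(x$replicates), nrow(x$summary)))
  n_bad <- sum(x$replicates$status != "ok")
  if (n_bad) cat(sprintf("  %d replicate(s) extinct/degenerate\n", n_bad))
  print(utils::head(x$summary, 12))
  if (nrow(x$summary) > 12) cat("  ...\n")
  invisible(x)
}

#' Summarise constant-environment sweeps
#'
#' Per-cell and pooled statistics for the stable-environment controls: the
#' across-replicate mean and variance of final mean growth for each
#' (environment, delta_t, alpha) cell, and the grand mean/variance pooled
#' over the whole grid of each environment — the quantity reported as the
#' equilibrium growth rate a stable environment supports.
#'
#' @param result A [run_sweep()] result covering `constant_1.0` and/or
#'   `constant_2.0`.
#' @return A list with `cells` (per-cell table) and `pooled` (one row per
#'   constant environment: pooled mean and variance of the replicate-final
#'   mean growth over all delta_t, alpha and replicates).
#' @export
summarize_constant_environments <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  reps <- result$replicates
  labs <- intersect(unique(reps$scenario), c("constant_1.0", "constant_2.0"))
  if (!length(labs)) {
    stop("sweep result contains no constant-environment scenario", call. = FALSE)
  }
  cells <- result$summary[result$summary$scenario %in% labs, , drop = FALSE]
  rownames(cells) <- NULL
  pooled <- do.call(rbind, lapply(labs, function(lab) {
    d <- reps[reps$scenario == lab & reps$status == "ok", , drop = FALSE]
    if (!nrow(d)) stop("no surviving replicates for ", lab, call. = FALSE)
    data.frame(scenario = lab,
               n = nrow(d),
               pooled_mean_g = mean(d$mean_g),
               pooled_var_g = if (nrow(d) > 1L) stats::var(d$mean_g) else NA_real_,
               pooled_mean_D = mean(d$mean_D),
               pooled_var_D = if (nrow(d) > 1L) stats::var(d$mean_D) else NA_real_)
  }))
  rownames(pooled) <- NULL
  list(cells = cells, pooled = pooled)
}

#' Summarise enrichment sweeps
#'
#' Per (scenario, delta_t, alpha): mean final growth, mean final damage and
#' the mean selective-death count — the three quantities the enrichment
#' figures display (growth panels, damage panels, and the point-size channel
#' inversely proportional to offspring mortality events).
#'
#' @param result A [run_sweep()] result covering at least one enrichment
#'   scenario.
#' @return A list with data frames `growth`, `damage` and `deaths`, each one
#'   row per grid cell.
#' @export
summarize_enrichment <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  labs <- intersect(unique(result$replicates$scenario),
                    c("reference", "damage_tolerance", "cheap_repair",
                      "damage_reduction"))
  if (!length(labs)) {
    stop("sweep result contains no enrichment scenario", call. = FALSE)
  }
  s <- result$summary[result$summary$scenario %in% labs, , drop = FALSE]
  rownames(s) <- NULL
  keys <- c("scenario", "delta_t", "alpha", "n_ok", "n_extinct")
  list(
    growth = s[, c(keys, "mean_g", "var_mean_g", "mean_within_var_g")],
    damage = s[, c(keys, "mean_D", "var_mean_D", "mean_within_var_D")],
    deaths = s[, c(keys, "mean_selective_deaths", "total_selective_deaths")]
  )
}

#' Plot a sweep result
#'
#' Mean final growth (or damage) against the relaxation time, one line per
#' Hill steepness, one panel per scenario, echoing the canonical figure
#' layout.
#'
#' @param x A `sweep_result`.
#' @param what `"growth"` or `"damage"`.
#' @param ... Unused.
#' @export
plot.sweep_result <- function(x, what = c("growth", "damage"), ...) {
  what <- match.arg(what)
  s <- x$summary
  ycol <- if (what == "growth") "mean_g" else "mean_D"
  scens <- unique(s$scenario)
  alphas <- sort(unique(s$alpha))
  cols <- grDevices::hcl.colors(max(3L, length(alphas)), "Dark 3")
  old <- graphics::par(mfrow = c(1, length(scens)))
  on.exit(graphics::par(old))
  for (sc in scens) {
    d <- s[s$scenario == sc, ]
    graphics::plot(range(d$delta_t), range(d[[ycol]], na.rm = TRUE),
                   type = "n", log = "x", xlab = expression(Delta * t),
                   ylab = paste("final mean", what), main = sc)
    for (j in seq_along(alphas)) {
      dj <- d[d$alpha == alphas[j], ]
      dj <- dj[order(dj$delta_t), ]
      graphics::lines(dj$delta_t, dj[[ycol]], col = cols[j], type = "b",
                      pch = 19)
    }
    graphics::legend("topright", legend = paste("alpha =", alphas),
                     col = cols[seq_along(alphas)], lty = 1, pch = 19,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
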