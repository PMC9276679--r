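#' Build a simulation state
#'
#' Bundles a tile grid with the per-agent property matrices so it can be
#' advanced step by step or simulated for a full time course.
#'
#' @param tile a tile (see [extract_tiles()]), or a bare integer grid matrix
#'   with codes 0 = empty, 1 = tumour, 2 = immune.
#' @param props property matrices from [assign_properties()]; if `NULL` they
#'   are drawn now.
#' @param seed RNG seed used when `props` must be drawn.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(tile, props = NULL, seed = NULL) {
  if (is.matrix(tile)) {
    tile <- new_tile(tile, interior = matrix(TRUE, nrow(tile), ncol(tile)),
                     ki67 = matrix(FALSE, nrow(tile), ncol(tile)),
                     origin = c(1L, 1L), tissue_fraction = 1)
  }
  stopifnot(inherits(tile, "sam_tile"))
  if (is.null(props)) props <- assign_properties(tile, seed = seed)
  structure(list(grid = tile$grid, props = props, t = 0L), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  n <- cell_counts(x)
  cat(sprintf("sim_state at t = %d steps: %d CD8, %d tumour on %dx%d\n",
              x$t, n[["n_cd8"]], n[["n_tumour"]], nrow(x$grid), ncol(x$grid)))
  invisible(x)
}

#' Advance the simulation by discrete steps
#'
#' Runs `n_steps` update passes. Each pass iterates over a freshly shuffled
#' list of the agents alive at its start; per agent the actions are evaluated
#' in the order death, proliferation, (killing for immune cells), migration.
#' Tumour cells die spontaneously (TUpdeath), divide into a free Moore
#' neighbour (TUpprol; division decrements the proliferation capacity unless
#' the cell is a stem cell, and a non-stem cell attempting division at
#' exhausted capacity dies), and migrate (TUpmig). Immune cells die
#' (IMpdeath), divide (IMpprol, same capacity semantics), attack an adjacent
#' tumour cell (IMpkill; the tumour cell's engagement capacity and the immune
#' cell's killing capacity are decremented, and the tumour cell dies when its
#' engagement capacity reaches 0 - several attacks are needed), and perform
#' IMpmig biased-random-walk moves (each random with probability IMrwalk,
#' otherwise toward the nearest tumour cell by Chebyshev distance). At the
#' end of each pass an influx event occurs with probability IMinfluxProb,
#' placing `round(IMinflRate)` fresh immune cells on free sites. All
#' neighbourhoods wrap periodically.
#'
#' @param state a [sim_state()].
#' @param params a [model_params()] object.
#' @param n_steps number of update passes.
#' @param seed RNG seed (`NULL`: continue the current stream).
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, params = model_params(), n_steps = 1L, seed = NULL) {
  stopifnot(inherits(state, "sim_state"))
  res <- with_seed(seed, abm_run_cpp(
    state$grid, state$props$prolif, state$props$stem, state$props$engcap,
    state$props$killcap, as_param_vector(params), as.integer(n_steps),
    n_steps + 1L, FALSE, FALSE))
  if (res$influx_skipped > 0)
    warning(sprintf("influx skipped %d time(s): grid full",
                    res$influx_skipped))
  structure(list(grid = res$grid,
                 props = list(prolif = res$prolif, stem = res$stem,
                              engcap = res$engcap, killcap = res$killcap),
                 t = state$t + as.integer(n_steps)),
            class = "sim_state")
}

#' Simulate a tile forward and record a daily trajectory
#'
#' Runs `steps_per_day * end_day` update steps and snapshots the lattice
#' every simulated day (matching a 24 h sampling cadence). If the tumour is
#' eradicated the run ends early and the last snapshot is retained, flagged
#' with `terminated_early`, so downstream scoring can use the last simulated
#' time point.
#'
#' @param tile a tile, or a bare class-grid matrix.
#' @param props property matrices ([assign_properties()]); drawn if `NULL`.
#' @param params a [model_params()].
#' @param end_day simulation horizon in days (>= 1).
#' @param record_grids keep the per-day class grids (set `FALSE` to save
#'   memory in large scans; the final grid is always kept).
#' @param seed RNG seed (default: `params$seed`).
#' @return An object of class `sam_trajectory` with elements `day`, `n_cd8`,
#'   `n_tumour`, `grids`, `final` (grid + property matrices),
#'   `terminated_early`.
#' @examples
#' g <- matrix(0L, 20, 20); g[sample(400, 60)] <- 1L; g[sample(400, 10)] <- 2L
#' tr <- simulate_tile(g, params = model_params(seed = 1), end_day = 2)
#' tr$n_cd8
#' @export
simulate_tile <- function(tile, props = NULL, params = model_params(),
                          end_day = params$end_day, record_grids = TRUE,
                          seed = params$seed) {
  if (end_day < 1) stop("'end_day' must be >= 1")
  st <- if (inherits(tile, "sim_state")) tile else sim_state(tile, props, seed)
  res <- with_seed(seed, abm_run_cpp(
    st$grid, st$props$prolif, st$props$stem, st$props$engcap,
    st$props$killcap, as_param_vector(params),
    as.integer(end_day) * params$steps_per_day, params$steps_per_day,
    record_grids, TRUE))
  if (res$influx_skipped > 0)
    warning(sprintf("influx skipped %d time(s): grid full",
                    res$influx_skipped))
  structure(list(day = res$day, n_cd8 = res$n_cd8, n_tumour = res$n_tumour,
                 grids = res$grids,
                 final = list(grid = res$grid,
                              props = list(prolif = res$prolif,
                                           stem = res$stem,
                                           engcap = res$engcap,
                                           killcap = res$killcap)),
                 terminated_early = res$terminated_early),
            class = "sam_trajectory")
}

#' @export
print.sam_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d daily snapshot(s)%s\n", length(x$day),
              if (x$terminated_early) " (terminated early)" else ""))
  print(data.frame(day = x$day, n_cd8 = x$n_cd8, n_tumour = x$n_tumour))
  invisible(x)
}

#' Count cells by class
#'
#' @param state a `sim_state`, `sam_trajectory` (final state), tile, or bare
#'   class-grid matrix.
#' @return Named integer vector `c(n_cd8 = ..., n_tumour = ...)`.
#' @export
cell_counts <- function(state) {
  g <- if (is.matrix(state)) state
  else if (inherits(state, "sam_trajectory")) state$final$grid
  else state$grid
  c(n_cd8 = sum(g == 2L), n_tumour = sum(g == 1L))
}
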