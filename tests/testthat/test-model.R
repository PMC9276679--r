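test_that("all-zero action probabilities freeze the state", {
  g <- make_grid(20, 60, 15, seed = 1)
  st <- sim_state(g, seed = 2)
  out <- sim_step(st, frozen_params(), n_steps = 25, seed = 3)
  expect_identical(out$grid, st$grid)
  expect_identical(out$props, st$props)
})

test_that("certain immune death empties the immune compartment in one step", {
  g <- make_grid(20, 0, 40, seed = 4)
  st <- sim_state(g, seed = 5)
  out <- sim_step(st, frozen_params(IMpdeath = 1), n_steps = 1, seed = 6)
  expect_equal(cell_counts(out)[["n_cd8"]], 0L)
})

test_that("a tumour cell with engagement capacity 2 dies after two attacks", {
  g <- matrix(0L, 9, 9)
  g[5, 5] <- 1L
  g[5, 6] <- 2L
  props <- list(prolif = matrix(5L, 9, 9), stem = matrix(FALSE, 9, 9),
                engcap = matrix(0L, 9, 9), killcap = matrix(0L, 9, 9))
  props$engcap[5, 5] <- 2L
  props$killcap[5, 6] <- 100L
  st <- sim_state(biopsam:::new_tile(g, matrix(TRUE, 9, 9),
                                     matrix(FALSE, 9, 9), c(1, 1), 1),
                  props = props)
  pars <- frozen_params(IMpkill = 1)
  s1 <- sim_step(st, pars, seed = 7)
  expect_equal(cell_counts(s1)[["n_tumour"]], 1L)
  expect_equal(s1$props$engcap[5, 5], 1L)
  expect_equal(s1$props$killcap[5, 6], 99L)
  s2 <- sim_step(s1, pars, seed = 8)
  expect_equal(cell_counts(s2)[["n_tumour"]], 0L)
})

test_that("simulation is reproducible under a fixed seed and snapshots daily", {
  fx <- make_ready_tile(L = 20, n_cd8 = 15, seed = 10)
  p <- model_params(seed = 123)
  tr1 <- simulate_tile(fx$tile, fx$props, p, end_day = 20,
                       record_grids = TRUE)
  tr2 <- simulate_tile(fx$tile, fx$props, p, end_day = 20,
                       record_grids = TRUE)
  expect_identical(tr1$n_cd8, tr2$n_cd8)
  expect_identical(tr1$final$grid, tr2$final$grid)
  if (!tr1$terminated_early) {
    expect_equal(tr1$day, 1:20)
    expect_length(tr1$grids, 20L)
  }
  expect_true(all(diff(tr1$day) > 0))
})

test_that("a tumour-free tile terminates at day one", {
  g <- make_grid(20, 0, 15, seed = 11)
  tr <- simulate_tile(g, params = frozen_params(seed = 12), end_day = 10)
  expect_true(tr$terminated_early)
  expect_equal(tr$day, 1L)
})

test_that("occupancy and class codes stay valid over many agent-steps", {
  # ~250 agents x 400 steps > 1e5 agent-updates, stepping through R each time
  fx <- make_ready_tile(L = 20, n_cd8 = 20, seed = 13)
  st <- sim_state(fx$tile, fx$props)
  pars <- model_params(TUpdeath = 0.05, IMinfluxProb = 0.5, IMinflRate = 3)
  set.seed(14)
  for (i in 1:40) {
    st <- suppressWarnings(sim_step(st, pars, n_steps = 10))
    expect_true(all(st$grid %in% c(0L, 1L, 2L)))
    expect_lte(sum(st$grid != 0L), 400L)
    # properties only where agents sit
    expect_true(all(st$props$killcap[st$grid == 0L] == 0L))
  }
})

test_that("count trajectories agree with an independent re-implementation", {
  fx <- make_ready_tile(L = 16, n_cd8 = 12, seed = 20, fill = 0.5)
  pars <- model_params()
  n_rep <- 24
  days <- 5
  set.seed(21)
  cpp <- t(vapply(seq_len(n_rep), function(i) {
    tr <- suppressWarnings(simulate_tile(fx$tile, fx$props, pars,
                                         end_day = days,
                                         record_grids = FALSE, seed = NULL))
    k <- length(tr$day)
    c(tr$n_cd8[k], tr$n_tumour[k])
  }, numeric(2)))
  ref <- t(vapply(seq_len(n_rep), function(i) {
    g <- ref_simulate(fx$tile$grid, fx$props, pars, days)
    c(sum(g == 2L), sum(g == 1L))
  }, numeric(2)))
  for (j in 1:2) {
    p <- t.test(cpp[, j], ref[, j])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("mean day-20 CD8 responds monotonically to immune rates", {
  fx <- make_ready_tile(L = 20, n_cd8 = 18, seed = 30)
  day20 <- function(pars, n_rep = 30, seed) {
    set.seed(seed)
    mean(vapply(seq_len(n_rep), function(i) {
      tr <- suppressWarnings(simulate_tile(fx$tile, fx$props, pars,
                                           end_day = 20,
                                           record_grids = FALSE,
                                           seed = NULL))
      tr$n_cd8[length(tr$day)]
    }, numeric(1)))
  }
  prol_vals <- c(0.01, 0.049, 0.15)
  m_prol <- vapply(seq_along(prol_vals), function(i)
    day20(model_params(IMpprol = prol_vals[i]), seed = 100 + i), numeric(1))
  expect_gt(cor(prol_vals, m_prol, method = "spearman"), 0)

  death_vals <- c(0.001, 0.0147, 0.076)
  m_death <- vapply(seq_along(death_vals), function(i)
    day20(model_params(IMpdeath = death_vals[i]), seed = 200 + i),
    numeric(1))
  expect_lt(cor(death_vals, m_death, method = "spearman"), 0)
})

test_that("dynamics are translation-invariant on the periodic lattice", {
  fx <- make_ready_tile(L = 20, n_cd8 = 15, seed = 40)
  shift <- function(m, dr, dc) {
    idx <- ((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1
    jdx <- ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1
    m[idx, jdx]
  }
  tile2 <- fx$tile
  tile2$grid <- shift(fx$tile$grid, 5, 7)
  props2 <- lapply(fx$props, shift, dr = 5, dc = 7)
  pars <- model_params()
  counts <- function(tile, props, seed0) {
    set.seed(seed0)
    vapply(1:40, function(i) {
      tr <- suppressWarnings(simulate_tile(tile, props, pars, end_day = 10,
                                           record_grids = FALSE,
                                           seed = NULL))
      tr$n_cd8[length(tr$day)]
    }, numeric(1))
  }
  a <- counts(fx$tile, fx$props, 41)
  b <- counts(tile2, props2, 42)
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("without killing, all tumour deaths are natural", {
  # immune cells move, proliferate and receive influx, but with IMpkill = 0
  # and tumour death/turnover off the tumour count never changes
  fx <- make_ready_tile(L = 20, n_cd8 = 20, seed = 50, fill = 0.5)
  inert <- frozen_params(IMpkill = 0, IMpdeath = 0.0147, IMpprol = 0.049,
                         IMpmig = 2, IMrwalk = 0.8, IMinfluxProb = 0.2,
                         IMinflRate = 1)
  n0 <- cell_counts(fx$tile)[["n_tumour"]]
  st <- sim_state(fx$tile, fx$props)
  set.seed(51)
  for (i in 1:10) {
    st <- suppressWarnings(sim_step(st, inert, n_steps = 2))
    expect_equal(cell_counts(st)[["n_tumour"]], n0)
  }

  # distributional control at low occupancy: a handful of non-killing
  # immune cells does not shift the early tumour growth curve
  g_t <- make_grid(24, 80, 0, seed = 52)
  g_ti <- g_t
  free <- which(g_ti == 0L)
  set.seed(53)
  g_ti[sample(free, 6)] <- 2L
  nokill <- model_params(IMpkill = 0, IMinfluxProb = 0)
  tum_day3 <- function(g, seed0) {
    set.seed(seed0)
    vapply(1:40, function(i) {
      tr <- suppressWarnings(simulate_tile(g, params = nokill, end_day = 3,
                                           record_grids = FALSE,
                                           seed = NULL))
      tr$n_tumour[length(tr$day)]
    }, numeric(1))
  }
  p <- suppressWarnings(ks.test(tum_day3(g_t, 54), tum_day3(g_ti, 55)))$p.value
  expect_gt(p, 0.01)
})

test_that("cell_counts reads any state shape", {
  expect_equal(cell_counts(matrix(0L, 5, 5)),
               c(n_cd8 = 0L, n_tumour = 0L))
  g <- matrix(0L, 10, 10)
  g[1:70] <- 1L
  g[71:75] <- 2L
  expect_equal(cell_counts(g), c(n_cd8 = 5L, n_tumour = 70L))
})
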