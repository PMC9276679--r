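test_that("sensitivity index reproduces the normalised-ratio formula", {
  expect_equal(sensitivity_index(200, 100, 100, 0.15, 0.01, 0.08),
               1 / 1.75, tolerance = 1e-12)
  expect_equal(sensitivity_index(120, 120, 60, 0.5, 0.1, 0.3), 0)
  # randomised inputs against an independently written expression
  set.seed(1)
  for (i in 1:50) {
    cmax <- runif(1, 50, 500); cmin <- runif(1, 10, 50)
    cb <- runif(1, 5, 200)
    pmin <- runif(1, 0.01, 0.2); pmax <- pmin + runif(1, 0.05, 1)
    pm <- (pmin + pmax) / 2
    direct <- ((cmax - cmin) / cb) * pm / (pmax - pmin)
    expect_equal(sensitivity_index(cmax, cmin, cb, pmax, pmin, pm), direct,
                 tolerance = 1e-12)
  }
  expect_error(sensitivity_index(1, 0, 0, 1, 0, 0.5), "baseline")
  expect_error(sensitivity_index(1, 0, 1, 1, 0, 0), "par_mid")
  expect_error(sensitivity_index(1, 0, 1, 0, 1, 0.5), "par_max")
})

test_that("one-at-a-time scan flags degenerate cases and finds real effects", {
  # zero-width range errors
  bad <- data.frame(name = "IMpprol", min = 0.1, max = 0.1, scale = "log",
                    integer = FALSE)
  fx <- make_ready_tile(L = 20, n_cd8 = 15, seed = 2)
  expect_error(run_sensitivity(list(fx$tile), list(fx$props), specs = bad,
                               repeats = 1, readout_day = 2),
               "zero-width")

  # no immune cells, frozen dynamics, scanned TUpmig: CD8 sensitivity is 0
  g <- make_grid(20, 80, 0, seed = 3)
  tile <- biopsam:::new_tile(g, matrix(TRUE, 20, 20),
                             matrix(FALSE, 20, 20), c(1, 1), 1)
  pr <- assign_properties(tile, seed = 4)
  spec_mig <- data.frame(name = "TUpmig", min = 0, max = 0.35,
                         scale = "linear", integer = FALSE)
  sens <- run_sensitivity(list(tile), list(pr), specs = spec_mig,
                          base = frozen_params(), repeats = 2,
                          readout_day = 3, seed = 5)
  expect_equal(sens$cd8_sensitivity, 0)

  # immune proliferation has a positive CD8 effect on a live tile
  spec_prol <- param_specs("sensitivity")
  spec_prol <- spec_prol[spec_prol$name == "IMpprol", ]
  sens2 <- run_sensitivity(list(fx$tile), list(fx$props), specs = spec_prol,
                           repeats = 20, readout_day = 20, seed = 6)
  expect_gt(sens2$cd8_sensitivity, 0)
})

test_that("parameter sampling respects ranges, scales and fixed defaults", {
  sets <- sample_parameter_sets(1, seed = 7)
  base <- model_params()
  for (nm in c("TUpprol", "TUpmig", "TUpdeath", "TUpmax", "TUintmax",
               "IMpmax", "IMpmig", "IMinfluxProb", "IMinflRate"))
    expect_identical(sets[[1]][[nm]], base[[nm]])
  sp <- param_specs("optimisation")
  sets2 <- sample_parameter_sets(500, seed = 8)
  vals <- attr(sets2, "values")
  for (i in seq_len(nrow(sp))) {
    v <- vals[, sp$name[i]]
    expect_true(all(v >= sp$min[i] & v <= sp$max[i]))
  }
  # log-scaled marginals uniform in log space
  big <- attr(sample_parameter_sets(20000, seed = 9), "values")
  lg <- log(big[, "IMpprol"])
  ks <- suppressWarnings(ks.test(lg, "punif", log(0.01), log(0.4)))
  expect_gt(ks$p.value, 0.01)
  # linear parameter uniform on its range
  ks2 <- suppressWarnings(ks.test(big[, "IMrwalk"], "punif", 0.7, 1))
  expect_gt(ks2$p.value, 0.01)
})

test_that("vote-based selection accepts and rejects correctly", {
  sets <- sample_parameter_sets(3, seed = 10)
  results <- data.frame(
    set = rep(1:3, each = 4), patient = rep(1:4, 3),
    sam = c(rep(0.9, 4),            # set 1: all pass
            rep(0.1, 4),            # set 2: zero votes
            c(0.9, 0.9, 0.9, NA)),  # set 3: 3/3 evaluable pass, 1 excluded
    varsam = 0.8,
    fallback_used = FALSE,
    accepted = c(rep(TRUE, 4), rep(FALSE, 4), c(TRUE, TRUE, TRUE, NA)),
    excluded = c(rep(FALSE, 8), c(FALSE, FALSE, FALSE, TRUE)))
  sel <- select_parameters(results, sets)
  expect_equal(sel$summary$votes, c(4, 0, 3))
  expect_equal(sel$summary$evaluable, c(4, 4, 3))
  expect_equal(sel$summary$accepted, c(TRUE, FALSE, TRUE))
  expect_length(sel$accepted_sets, 2L)
  # vote rule is strict: 2 of 4 votes is below the 22/37 fraction
  results$accepted[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  sel2 <- select_parameters(results, sets)
  expect_false(sel2$summary$accepted[1])
})

test_that("scoring a parameter set is deterministic and exercises the fallback", {
  co <- make_cohort(n_patients = 2, tiles = 4, end_days = 6, seed = 11)
  theta <- co$theta_star
  r1 <- evaluate_parameter_set(theta, co, repeats = 2, seed = 12)
  r2 <- evaluate_parameter_set(theta, co, repeats = 2, seed = 12)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2L)
  expect_false(any(r1$excluded))

  # near-certain immune death starves the simulated tiles of CD8:
  # the count comparison replaces the SAM
  harsh <- model_params(IMpdeath = 0.95, IMinfluxProb = 0, IMpprol = 0)
  r3 <- evaluate_parameter_set(harsh, co, repeats = 2, seed = 13)
  expect_true(all(r3$fallback_used))
  expect_false(any(r3$accepted))
})

test_that("LOCF accepts identical pairs and rejects constructed disagreement", {
  set.seed(14)
  tiles <- replicate(4, make_grid(100, 0, 300), simplify = FALSE)
  same <- list(list(baseline = tiles, on_treatment = tiles))
  expect_equal(locf_benchmark(same)$fraction, 1)

  # clustered baseline vs CSR on-treatment at matched density
  clustered <- replicate(4, {
    cm <- generate_cellmap("clustered", n_cd8 = 300, L = 100,
                           tumour_prolif_frac = 0)
    extract_tiles(cm)[[1]]$grid
  }, simplify = FALSE)
  csr <- replicate(4, make_grid(100, 0, 300), simplify = FALSE)
  diff_pair <- list(list(baseline = clustered, on_treatment = csr))
  expect_equal(locf_benchmark(diff_pair)$fraction, 0)

  # aggregation identity over a mixed set of pairs
  both <- c(same, diff_pair)
  lb <- locf_benchmark(both)
  expect_equal(lb$fraction, mean(lb$per_pair$accepted))
})

test_that("validation requires accepted sets and a holdout cohort", {
  co <- make_cohort(n_patients = 1, tiles = 4, end_days = 4, seed = 15)
  expect_error(validate(list(), co), "non-empty")
  expect_error(validate(list(model_params()), list()), "empty holdout")
})

test_that("a reduced optimisation recovers the generating parameter set", {
  co <- make_cohort(n_patients = 4, tiles = 4, end_days = 15, seed = 16)
  theta <- co$theta_star
  sets <- c(list(theta), sample_parameter_sets(15, seed = 17))
  res <- calibrate(sets, co, repeats = 2, seed = 18)
  sel <- select_parameters(res, sets)
  expect_true(sel$summary$accepted[1]) # theta* (set 1) is accepted
})
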