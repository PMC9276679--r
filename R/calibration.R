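#' One-at-a-time sensitivity index
#'
#' Normalised change in cell count per normalised change in a parameter:
#' the count range across the scanned parameter range, divided by the
#' baseline count, over the parameter range divided by its midpoint:
#' `((cd8_max - cd8_min) / cd8_baseline) / ((par_max - par_min) / par_mid)`.
#' The analogous call with tumour counts gives the tumour sensitivity.
#'
#' @param cd8_max,cd8_min cell counts at the upper/lower end of the scanned
#'   parameter range (readout day).
#' @param cd8_baseline cell count at baseline (normaliser; must be > 0).
#' @param par_max,par_min scanned parameter range ends (`par_max > par_min`).
#' @param par_mid midpoint of the scanned range (must be nonzero).
#' @return The sensitivity index (real; sign tracks the direction of the
#'   response).
#' @examples
#' sensitivity_index(200, 100, 100, 0.15, 0.01, 0.08)  # ~0.5714
#' @export
sensitivity_index <- function(cd8_max, cd8_min, cd8_baseline,
                              par_max, par_min, par_mid) {
  if (cd8_baseline <= 0) stop("'cd8_baseline' must be > 0")
  if (par_mid == 0) stop("'par_mid' must be nonzero")
  if (par_max <= par_min) stop("'par_max' must exceed 'par_min'")
  ((cd8_max - cd8_min) / cd8_baseline) / ((par_max - par_min) / par_mid)
}

scan_values <- function(spec_row, n_values) {
  if (spec_row$max <= spec_row$min) stop("zero-width scan range")
  v <- if (spec_row$scale == "log")
    exp(seq(log(spec_row$min), log(spec_row$max), length.out = n_values))
  else seq(spec_row$min, spec_row$max, length.out = n_values)
  if (isTRUE(spec_row$integer)) v <- pmax(1, round(v))
  v
}

#' One-at-a-time sensitivity analysis
#'
#' Scans each parameter independently over its stated range (the others held
#' at their defaults), simulating every tile `repeats` times per scanned
#' value and reading CD8 and tumour counts out at `readout_day`. The
#' sensitivity per parameter is [sensitivity_index()] evaluated at the range
#' endpoints, with counts averaged over tiles and repeats and baselines taken
#' from the initial tiles.
#'
#' @param tiles list of populated tiles.
#' @param props list of property sets matching `tiles` (drawn if `NULL`).
#' @param specs scan specification, see [param_specs()].
#' @param base [model_params()] holding the non-scanned values.
#' @param n_values scanned values per parameter (endpoints always included).
#' @param repeats stochastic repeats per (tile, value).
#' @param readout_day day at which counts are read out.
#' @param seed RNG seed.
#' @return data.frame with one row per parameter: range ends, CD8 and tumour
#'   sensitivities; the full scan (counts per parameter value) is attached as
#'   attribute `"scan"`.
#' @export
run_sensitivity <- function(tiles, props = NULL,
                            specs = param_specs("sensitivity"),
                            base = model_params(), n_values = 2L,
                            repeats = 5L, readout_day = 20L, seed = NULL) {
  stopifnot(length(tiles) >= 1L)
  with_seed(seed, {
    if (is.null(props)) props <- lapply(tiles, assign_properties)
    base_counts <- vapply(tiles, function(t) cell_counts(t), integer(2))
    cd8_base <- mean(base_counts["n_cd8", ])
    tum_base <- mean(base_counts["n_tumour", ])
    scan <- list()
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      sp <- specs[i, ]
      vals <- scan_values(sp, n_values)
      means <- vapply(vals, function(v) {
        pars <- base
        pars[[sp$name]] <- v
        validate_params(pars)
        cnt <- vapply(seq_along(tiles), function(ti) {
          reps <- vapply(seq_len(repeats), function(r) {
            tr <- suppressWarnings(simulate_tile(
              tiles[[ti]], props[[ti]], pars, end_day = readout_day,
              record_grids = FALSE, seed = NULL))
            k <- length(tr$day)
            c(tr$n_cd8[k], tr$n_tumour[k])
          }, numeric(2))
          rowMeans(reps)
        }, numeric(2))
        rowMeans(cnt)
      }, numeric(2))
      scan[[sp$name]] <<- data.frame(parameter = sp$name, value = vals,
                                     cd8 = means[1, ], tumour = means[2, ])
      lo <- which.min(vals); hi <- which.max(vals)
      mid <- (sp$min + sp$max) / 2
      # a compartment empty at baseline and unresponsive has zero sensitivity
      safe_index <- function(cmax, cmin, cbase) {
        if (cbase <= 0) {
          if (cmax == cmin) return(0)
          return(NA_real_)
        }
        sensitivity_index(cmax, cmin, cbase, sp$max, sp$min, mid)
      }
      data.frame(
        parameter = sp$name, par_min = sp$min, par_max = sp$max,
        cd8_sensitivity = safe_index(means[1, hi], means[1, lo], cd8_base),
        tumour_sensitivity = safe_index(means[2, hi], means[2, lo],
                                        tum_base),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "scan") <- do.call(rbind, scan)
    out
  })
}

#' Sample candidate parameter sets for the rejection calibration
#'
#' Draws `n` parameter sets with the free immune parameters (IMpprol,
#' IMpkill, IMpdeath, IMrwalk) sampled uniformly on their linear or log
#' scales within physiological ranges; all other parameters stay at the
#' defaults of `base`.
#'
#' @param n number of sets.
#' @param specs sampling specification ([param_specs()]).
#' @param base defaults for the non-free parameters.
#' @param seed RNG seed.
#' @return List of [model_params()]; the sampled values are attached as a
#'   numeric matrix in attribute `"values"`.
#' @export
sample_parameter_sets <- function(n = 1000L,
                                  specs = param_specs("optimisation"),
                                  base = model_params(), seed = NULL) {
  with_seed(seed, {
    vals <- vapply(seq_len(nrow(specs)), function(i) {
      sp <- specs[i, ]
      v <- if (sp$scale == "log")
        exp(runif(n, log(sp$min), log(sp$max)))
      else runif(n, sp$min, sp$max)
      if (isTRUE(sp$integer)) v <- pmax(1, round(v))
      v
    }, numeric(n))
    vals <- matrix(vals, nrow = n,
                   dimnames = list(NULL, specs$name))
    sets <- lapply(seq_len(n), function(i) {
      p <- base
      for (nm in specs$name) p[[nm]] <- vals[i, nm]
      validate_params(p)
      p
    })
    attr(sets, "values") <- vals
    sets
  })
}

#' Score one parameter set against a patient cohort
#'
#' For each patient, every baseline tile is simulated `repeats` times to the
#' patient's on-treatment day, the simulated RDFs are pooled into `Rs`, and
#' SAM/VarSAM are computed against the observed on-treatment RDFs `Ro`. The
#' three exception rules apply: early-terminated runs contribute their last
#' snapshot; a patient whose observed tiles mostly have fewer than
#' `min_cells` CD8 is excluded from SAM scoring; when the simulated tiles
#' mostly fall under `min_cells`, the per-tile CD8 counts are compared with
#' the two-sample t-test fallback instead.
#'
#' @param params a [model_params()] candidate.
#' @param patients list of patients, each a list with `baseline` (tiles),
#'   `props` (optional property sets), `observed` (tiles or grids) and
#'   `end_day` — the shape produced by [generate_paired_cohort()].
#' @param repeats stochastic repeats per baseline tile.
#' @param threshSAM,sam_thresh,varsam_thresh,widen,alpha scoring settings,
#'   see [sam_score()].
#' @param min_cells minimum CD8 per tile for a meaningful RDF.
#' @param seed RNG seed; equal seeds give identical scores.
#' @return data.frame with one row per patient: `patient`, `sam`, `varsam`,
#'   `fallback_used`, `accepted`, `excluded`.
#' @export
evaluate_parameter_set <- function(params, patients, repeats = 5L,
                                   threshSAM = 0.5, sam_thresh = 0.7,
                                   varsam_thresh = 0.3, min_cells = 10L,
                                   widen = 0.2, alpha = 0.05, seed = NULL) {
  if (inherits(patients, "sam_cohort")) patients <- patients$patients
  with_seed(seed, {
    rows <- lapply(seq_along(patients), function(pi) {
      pt <- patients[[pi]]
      if (!length(pt$baseline) || !length(pt$observed))
        return(data.frame(patient = pi, sam = NA_real_, varsam = NA_real_,
                          fallback_used = FALSE, accepted = NA,
                          excluded = TRUE))
      Ro <- rdf_matrix(pt$observed, min_cells = min_cells)
      sim_grids <- list()
      for (ti in seq_along(pt$baseline)) {
        pr <- if (!is.null(pt$props)) pt$props[[ti]]
        for (r in seq_len(repeats)) {
          tr <- suppressWarnings(simulate_tile(
            pt$baseline[[ti]], pr, params, end_day = pt$end_day,
            record_grids = FALSE, seed = NULL))
          sim_grids[[length(sim_grids) + 1L]] <- tr$final$grid
        }
      }
      Rs <- rdf_matrix(sim_grids, min_cells = min_cells)
      sc <- sam_score(Ro, Rs, threshSAM = threshSAM,
                      sam_thresh = sam_thresh,
                      varsam_thresh = varsam_thresh, widen = widen,
                      alpha = alpha)
      data.frame(patient = pi, sam = sc$sam, varsam = sc$varsam,
                 fallback_used = sc$fallback_used, accepted = sc$accepted,
                 excluded = sc$excluded)
    })
    do.call(rbind, rows)
  })
}

#' Score many parameter sets against a cohort
#'
#' Convenience loop over [evaluate_parameter_set()], seeding each set
#' reproducibly from `seed`.
#'
#' @param sets list of [model_params()] (e.g. [sample_parameter_sets()]).
#' @param patients cohort, as for [evaluate_parameter_set()].
#' @param ... passed to [evaluate_parameter_set()].
#' @param seed base RNG seed; set `i` is scored with `seed + i`.
#' @return data.frame with one row per (set, patient); column `set` indexes
#'   into `sets`.
#' @export
calibrate <- function(sets, patients, ..., seed = NULL) {
  res <- lapply(seq_along(sets), function(i) {
    r <- evaluate_parameter_set(sets[[i]], patients, ...,
                                seed = if (is.null(seed)) NULL else seed + i)
    r$set <- i
    r
  })
  out <- do.call(rbind, res)
  out[, c("set", setdiff(names(out), "set"))]
}

#' Select accepted parameter sets by per-patient voting
#'
#' A parameter set receives one vote per evaluable patient for which both
#' SAM and VarSAM cleared their thresholds (or the count fallback accepted).
#' Sets are accepted when their votes exceed `min_vote_fraction` of the
#' evaluable patients — the fraction generalises the 22-of-37-patients rule
#' to cohorts of any size. Patients excluded for too few observed CD8 cells
#' do not enter the vote denominator. The mean SAM per set is reported
#' alongside.
#'
#' @param results data.frame from [calibrate()].
#' @param sets the scored parameter sets (same order).
#' @param min_vote_fraction vote threshold as a fraction of evaluable
#'   patients (strict inequality).
#' @return List with `summary` (per-set votes, evaluable count, mean SAM,
#'   accepted flag) and `accepted_sets`.
#' @export
select_parameters <- function(results, sets, min_vote_fraction = 22 / 37) {
  stopifnot(all(c("set", "accepted", "excluded", "sam") %in% names(results)))
  summ <- do.call(rbind, lapply(split(results, results$set), function(d) {
    ev <- !d$excluded
    data.frame(set = d$set[1], votes = sum(d$accepted[ev] %in% TRUE),
               evaluable = sum(ev),
               mean_sam = if (any(ev & !is.na(d$sam)))
                 mean(d$sam[ev], na.rm = TRUE) else NA_real_)
  }))
  summ <- summ[order(summ$set), ]
  summ$accepted <- summ$evaluable > 0 &
    summ$votes > min_vote_fraction * summ$evaluable
  rownames(summ) <- NULL
  list(summary = summ, accepted_sets = sets[summ$set[summ$accepted]])
}

#' Last-observation-carried-forward benchmark
#'
#' Null predictor: the baseline sample itself is used as the prediction of
#' the on-treatment sample. Per pair, baseline RDFs play the role of the
#' simulated matrix and on-treatment RDFs the observed one; the accepted
#' fraction under the usual SAM/VarSAM thresholds is the reference value a
#' mechanistic model must beat.
#'
#' @param pairs list of pairs `list(baseline = , on_treatment = )` of tile
#'   collections (see [as_locf_pairs()]), or a `sam_cohort`.
#' @inheritParams evaluate_parameter_set
#' @return List with `fraction` (accepted share of evaluable pairs) and
#'   `per_pair` (data.frame of scores).
#' @export
locf_benchmark <- function(pairs, threshSAM = 0.5, sam_thresh = 0.7,
                           varsam_thresh = 0.3, min_cells = 10L,
                           widen = 0.2, alpha = 0.05) {
  if (inherits(pairs, "sam_cohort")) pairs <- as_locf_pairs(pairs)
  stopifnot(length(pairs) >= 1L)
  per <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    Ro <- rdf_matrix(pairs[[i]]$on_treatment, min_cells = min_cells)
    Rs <- rdf_matrix(pairs[[i]]$baseline, min_cells = min_cells)
    sc <- sam_score(Ro, Rs, threshSAM = threshSAM, sam_thresh = sam_thresh,
                    varsam_thresh = varsam_thresh, widen = widen,
                    alpha = alpha)
    data.frame(pair = i, sam = sc$sam, varsam = sc$varsam,
               fallback_used = sc$fallback_used, accepted = sc$accepted,
               excluded = sc$excluded)
  }))
  ev <- !per$excluded
  list(fraction = if (any(ev)) mean(per$accepted[ev] %in% TRUE) else NA_real_,
       per_pair = per)
}

#' Holdout validation of the accepted parameter sets
#'
#' Scores every accepted set against unseen patients; the model accuracy is
#' the fraction of accepted (set, patient) evaluations. As a control, the
#' exercise is repeated `n_control_draws` times with `control_size` parameter
#' sets drawn at random from the calibration sampling ranges; each replicate
#' redraws its own control sets.
#'
#' @param accepted list of accepted [model_params()] (non-empty).
#' @param holdout holdout cohort (as for [evaluate_parameter_set()]).
#' @param specs sampling specification for the control draws.
#' @param base defaults for non-free control parameters.
#' @param repeats stochastic repeats per tile.
#' @param n_control_draws control replicates.
#' @param control_size parameter sets per control replicate.
#' @param seed RNG seed.
#' @param ... further scoring settings for [evaluate_parameter_set()].
#' @return List with `accuracy`, `control_accuracy` (mean over replicates),
#'   `control_accuracies`, the per-(set, patient) `results` and
#'   `unevaluable_patients` (all-excluded holdout patients).
#' @export
validate <- function(accepted, holdout, specs = param_specs("optimisation"),
                     base = model_params(), repeats = 5L,
                     n_control_draws = 5L, control_size = 12L, seed = NULL,
                     ...) {
  if (!length(accepted)) stop("'accepted' must be a non-empty list of sets")
  if (inherits(holdout, "sam_cohort")) holdout <- holdout$patients
  if (!length(holdout)) stop("empty holdout cohort")
  with_seed(seed, {
    res <- calibrate(accepted, holdout, repeats = repeats, ..., seed = NULL)
    ev <- !res$excluded
    acc <- if (any(ev)) mean(res$accepted[ev] %in% TRUE) else NA_real_
    excl_by_pat <- tapply(res$excluded, res$patient, all)
    ctrl_acc <- vapply(seq_len(n_control_draws), function(d) {
      ctrl <- sample_parameter_sets(control_size, specs, base, seed = NULL)
      r <- calibrate(ctrl, holdout, repeats = repeats, ..., seed = NULL)
      e <- !r$excluded
      if (any(e)) mean(r$accepted[e] %in% TRUE) else NA_real_
    }, numeric(1))
    list(accuracy = acc, control_accuracy = mean(ctrl_acc, na.rm = TRUE),
         control_accuracies = ctrl_acc, results = res,
         unevaluable_patients = as.integer(names(excl_by_pat))[excl_by_pat])
  })
}
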