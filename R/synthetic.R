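#' Generate a synthetic cell map
#'
#' Emulates the per-cell coordinate tables derived from digitised biopsies so
#' the whole pipeline can be exercised with known ground truth. Three CD8
#' arrangements are supported, matching the qualitative regimes seen in real
#' tiles: `"csr"` (complete spatial randomness), `"clustered"`
#' (parent/offspring placement around random cluster centres) and
#' `"excluded"` (an immune-cold core: CD8 only outside a central disc).
#' Detected proliferating tumour cells are scattered uniformly over the
#' annotation; a configurable fraction of CD8 cells is Ki67+.
#'
#' @param pattern CD8 arrangement: `"csr"`, `"clustered"` or `"excluded"`.
#' @param n_cd8 number of CD8 cells.
#' @param L lattice side length of the annotated region.
#' @param cell_width physical size of one lattice unit (micrometres).
#' @param ki67_frac fraction of CD8 cells that are Ki67+ (proliferating).
#' @param tumour_prolif_frac fraction of annotated sites holding a detected
#'   proliferating tumour cell.
#' @param cluster_count number of CD8 cluster centres (clustered pattern);
#'   default about one per 25 cells.
#' @param cluster_radius cluster half-width in lattice units (Chebyshev).
#' @param exclusion_radius radius of the immune-cold core (excluded
#'   pattern), default `L / 3`.
#' @param annotation binary annotation mask; default: fully annotated `L x L`.
#' @param seed RNG seed.
#' @return A [cellmap()].
#' @examples
#' cm <- generate_cellmap("clustered", n_cd8 = 150, L = 100, seed = 1)
#' table(cm$cells$class)
#' @export
generate_cellmap <- function(pattern = c("csr", "clustered", "excluded"),
                             n_cd8 = 100L, L = 100L, cell_width = 5,
                             ki67_frac = 0.2, tumour_prolif_frac = 0.05,
                             cluster_count = NULL, cluster_radius = 4L,
                             exclusion_radius = NULL, annotation = NULL,
                             seed = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(annotation)) annotation <- matrix(1L, L, L)
  L <- nrow(annotation)
  ann_sites <- which(annotation == 1L)
  n_tum <- round(tumour_prolif_frac * length(ann_sites))
  if (n_cd8 + n_tum > length(ann_sites))
    stop("infeasible density: more cells than annotated sites")

  with_seed(seed, {
    cd8_sites <- switch(pattern,
      csr = sample(ann_sites, n_cd8),
      clustered = place_clustered(ann_sites, n_cd8, L,
                                  cluster_count %||% max(1L, round(n_cd8 / 25)),
                                  cluster_radius),
      excluded = {
        ctr <- (L + 1) / 2
        rr <- (ann_sites - 1L) %% L + 1L
        cc <- (ann_sites - 1L) %/% L + 1L
        rad <- exclusion_radius %||% (L / 3)
        hot <- ann_sites[sqrt((rr - ctr)^2 + (cc - ctr)^2) > rad]
        if (length(hot) < n_cd8)
          stop("infeasible density outside the excluded core")
        sample(hot, n_cd8)
      })
    tum_pool <- setdiff(ann_sites, cd8_sites)
    tum_sites <- if (n_tum > 0) sample(tum_pool, n_tum) else integer(0)

    to_xy <- function(sites) {
      r <- (sites - 1L) %% L + 1L
      c <- (sites - 1L) %/% L + 1L
      data.frame(x = (c - 1) * cell_width + cell_width / 2,
                 y = (r - 1) * cell_width + cell_width / 2)
    }
    cd8 <- to_xy(cd8_sites)
    cd8$class <- ifelse(runif(n_cd8) < ki67_frac, "cd8_prolif", "cd8")
    tum <- to_xy(tum_sites)
    if (nrow(tum)) tum$class <- "tumour_prolif"
    cells <- rbind(cd8, tum)
    cellmap(cells, annotation, cell_width)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Matern-style parent/offspring placement on the lattice: each cell picks a
# random parent centre and a uniform offset within a square of half-width
# `radius`; duplicate or off-annotation draws are retried, with a uniform
# top-up if the clusters saturate.
place_clustered <- function(ann_sites, n, L, cluster_count, radius) {
  ann <- logical(L * L); ann[ann_sites] <- TRUE
  centres <- sample(ann_sites, cluster_count, replace = cluster_count >
                      length(ann_sites))
  cr <- (centres - 1L) %% L + 1L
  cc <- (centres - 1L) %/% L + 1L
  chosen <- integer(0)
  for (iter in 1:50) {
    need <- n - length(chosen)
    if (need <= 0) break
    k <- sample.int(cluster_count, 2L * need, replace = TRUE)
    r <- cr[k] + sample(-radius:radius, 2L * need, replace = TRUE)
    c <- cc[k] + sample(-radius:radius, 2L * need, replace = TRUE)
    ok <- r >= 1L & r <= L & c >= 1L & c <= L
    s <- (c[ok] - 1L) * L + r[ok]
    s <- s[ann[s]]
    chosen <- unique(c(chosen, s))
  }
  if (length(chosen) < n)
    chosen <- c(chosen, sample(setdiff(ann_sites, chosen),
                               n - length(chosen)))
  chosen[seq_len(n)]
}

#' Generate a paired baseline/on-treatment cohort with known ground truth
#'
#' Baseline cell maps are drawn from [generate_cellmap()], turned into
#' populated tiles, and the on-treatment counterparts are produced by
#' forward-simulating every baseline tile with a known parameter set
#' `theta_star` to the patient's biopsy day. The generating parameters are
#' recorded, so calibration routines can be tested for parameter recovery.
#'
#' @param n_patients number of synthetic patients.
#' @param tiles_per_patient tiles per sample; patients below 4 tiles are
#'   flagged (`below_tile_rule`) mirroring the sample inclusion rule.
#' @param theta_star generating [model_params()].
#' @param end_days per-patient on-treatment biopsy day; default drawn from
#'   15..113, the span observed across real sampling schedules.
#' @param L tile side length.
#' @param n_cd8_range per-tile baseline CD8 count range (uniform draw).
#' @param patterns CD8 patterns cycled over tiles.
#' @param fill_density tumour back-fill target density.
#' @param ki67_frac fraction of Ki67+ CD8 at baseline.
#' @param cell_width lattice unit in micrometres.
#' @param seed RNG seed.
#' @return Object of class `sam_cohort`: list with `patients` (each holding
#'   `baseline` tiles, `props`, `observed` final grids, `end_day`,
#'   `below_tile_rule`) and `theta_star`.
#' @examples
#' co <- generate_paired_cohort(n_patients = 2, tiles_per_patient = 4,
#'                              theta_star = model_params(), end_days = c(2, 3),
#'                              L = 20, n_cd8_range = c(12, 25), seed = 1)
#' length(co$patients)
#' @export
generate_paired_cohort <- function(n_patients = 5L, tiles_per_patient = 6L,
                                   theta_star = model_params(),
                                   end_days = NULL, L = 100L,
                                   n_cd8_range = c(20L, 150L),
                                   patterns = c("csr", "clustered"),
                                   fill_density = 0.7, ki67_frac = 0.2,
                                   cell_width = 5, seed = NULL) {
  with_seed(seed, {
    if (is.null(end_days))
      end_days <- sample(15:113, n_patients, replace = TRUE)
    if (length(end_days) == 1L) end_days <- rep(end_days, n_patients)
    stopifnot(length(end_days) == n_patients)
    patients <- lapply(seq_len(n_patients), function(p) {
      baseline <- vector("list", tiles_per_patient)
      props <- vector("list", tiles_per_patient)
      observed <- vector("list", tiles_per_patient)
      for (t in seq_len(tiles_per_patient)) {
        pat <- patterns[(t - 1L) %% length(patterns) + 1L]
        n_cd8 <- sample(n_cd8_range[1]:n_cd8_range[2], 1L)
        cm <- generate_cellmap(pat, n_cd8 = n_cd8, L = L,
                               cell_width = cell_width,
                               ki67_frac = ki67_frac,
                               cluster_radius = max(2L, round(L / 25)))
        tile <- extract_tiles(cm, tile_size = L)[[1L]]
        tile <- populate_tumour(tile, target_density = fill_density)
        baseline[[t]] <- tile
        props[[t]] <- assign_properties(tile)
        tr <- suppressWarnings(simulate_tile(
          tile, props[[t]], theta_star, end_day = end_days[p],
          record_grids = FALSE, seed = NULL))
        observed[[t]] <- tr$final$grid
      }
      list(baseline = baseline, props = props, observed = observed,
           end_day = end_days[p],
           below_tile_rule = tiles_per_patient < 4L)
    })
    structure(list(patients = patients, theta_star = theta_star),
              class = "sam_cohort")
  })
}

#' @export
print.sam_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d tile(s) each\n",
              length(x$patients), length(x$patients[[1]]$baseline)))
  invisible(x)
}

#' Baseline/on-treatment pairs for the LOCF benchmark
#'
#' @param cohort a `sam_cohort`.
#' @return List of pairs usable by [locf_benchmark()].
#' @export
as_locf_pairs <- function(cohort) {
  lapply(cohort$patients, function(p)
    list(baseline = p$baseline, on_treatment = p$observed))
}
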