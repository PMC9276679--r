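#' Lattice radial distribution function of CD8 cells
#'
#' Summarises the CD8 spatial pattern on a tile as a normalised pair density
#' per inter-cell Chebyshev distance. For each CD8 cell the number of other
#' CD8 cells at Chebyshev distance `j` (a square ring) is counted, divided by
#' the number of lattice sites of that ring that actually fall inside the
#' tile (edge truncation, since observed biopsy tiles have real edges), and
#' the per-cell average is normalised by the mean CD8 density on the whole
#' tile. A value of 1 at all distances corresponds to complete spatial
#' randomness; short-range elevation indicates clustering.
#'
#' Tiles with fewer than `min_cells` CD8 cells are flagged `too_few` (their
#' RDF is dominated by noise) and carry an all-`NA` curve.
#'
#' @param x a tile, class-grid matrix (code 2 = immune), trajectory (final
#'   grid), or a 2-column matrix/data.frame of 1-based (row, col) CD8
#'   positions (then `L` is required).
#' @param M number of distance units; defaults to half the domain length.
#' @param min_cells minimum CD8 count for a meaningful RDF.
#' @param L domain side length, required when `x` is a bare position matrix.
#' @return Object of class `rdf` with fields `g` (length `M`), `n_cells`,
#'   `too_few`, `M`, `L`.
#' @examples
#' g <- matrix(0L, 100, 100); g[sample(1e4, 300)] <- 2L
#' r <- compute_rdf(g)
#' mean(r$g)
#' @export
compute_rdf <- function(x, M = NULL, min_cells = 10L, L = NULL) {
  if (inherits(x, "sam_trajectory")) x <- x$final$grid
  if (inherits(x, "sam_tile") || inherits(x, "sim_state")) x <- x$grid
  if (is.null(L)) { # class grid
    x <- as.matrix(x)
    L <- nrow(x)
    if (ncol(x) != L) stop("class grid must be square")
    pos <- which(x == 2L, arr.ind = TRUE)
  } else {          # bare (row, col) positions
    pos <- as.matrix(x)
  }
  if (is.null(M)) M <- L %/% 2L
  n <- nrow(pos)
  if (n < min_cells) {
    return(structure(list(g = rep(NA_real_, M), n_cells = n, too_few = TRUE,
                          M = M, L = L), class = "rdf"))
  }
  counts <- chebyshev_pair_counts_cpp(as.integer(pos[, 1]),
                                      as.integer(pos[, 2]), as.integer(M))
  rings <- ring_sizes(pos, M, L)
  dens <- n / L^2
  g <- colMeans(counts / rings) / dens
  structure(list(g = g, n_cells = n, too_few = FALSE, M = M, L = L),
            class = "rdf")
}

# per-cell truncated square-ring site counts: rings[i, j] = number of tile
# sites at Chebyshev distance exactly j from cell i
ring_sizes <- function(pos, M, L) {
  r <- pos[, 1]; c <- pos[, 2]
  leq <- function(d) {
    (pmin(r + d, L) - pmax(r - d, 1) + 1) * (pmin(c + d, L) - pmax(c - d, 1) + 1)
  }
  prev <- leq(0)
  out <- matrix(0, nrow(pos), M)
  for (d in seq_len(M)) {
    cur <- leq(d)
    out[, d] <- cur - prev
    prev <- cur
  }
  out
}

#' @export
print.rdf <- function(x, ...) {
  if (x$too_few)
    cat(sprintf("rdf: too few CD8 cells (%d)\n", x$n_cells))
  else
    cat(sprintf("rdf: %d CD8 cells, M = %d, g[1..5] = %s\n", x$n_cells, x$M,
                paste(signif(x$g[1:min(5, x$M)], 3), collapse = ", ")))
  invisible(x)
}

#' Stack RDFs of a tile collection into a matrix
#'
#' Rows are per-tile (or per stochastic repeat) normalised RDFs. A collection
#' is flagged unusable when the majority of its rows are `too_few`; the SAM
#' then falls back to comparing CD8 counts per tile.
#'
#' @param tiles list of tiles / grids / trajectories (or a list of `rdf`s).
#' @inheritParams compute_rdf
#' @return Object of class `rdf_matrix` with fields `mat` (rows may contain
#'   `NA` for flagged tiles), `too_few` (per row), `flagged` (majority rule),
#'   `n_cells` (per row).
#' @export
rdf_matrix <- function(tiles, M = NULL, min_cells = 10L, L = NULL) {
  rdfs <- lapply(tiles, function(t)
    if (inherits(t, "rdf")) t else compute_rdf(t, M = M, min_cells = min_cells,
                                               L = L))
  mat <- do.call(rbind, lapply(rdfs, `[[`, "g"))
  too_few <- vapply(rdfs, `[[`, logical(1), "too_few")
  structure(list(mat = mat, too_few = too_few,
                 flagged = mean(too_few) > 0.5,
                 n_cells = vapply(rdfs, `[[`, integer(1), "n_cells")),
            class = "rdf_matrix")
}

as_rdf_rows <- function(x) {
  if (inherits(x, "rdf_matrix")) {
    if (x$flagged)
      stop("RDF matrix flagged 'too few CD8 cells'; use the count fallback")
    x$mat[!x$too_few, , drop = FALSE]
  } else as.matrix(x)
}

#' Envelope bounds for RDF acceptance
#'
#' From the observed RDF matrix, the per-distance envelope is the observed
#' min-max range widened by `widen` times the range on each side, with the
#' lower bound clamped at zero:
#' `u_j = max_i Ro_ij + widen * range_i Ro_ij`,
#' `l_j = max(min_i Ro_ij - widen * range_i Ro_ij, 0)`.
#'
#' @param Ro observed RDF matrix (rows = tiles) or `rdf_matrix`.
#' @param widen widening factor (0.2 = plus/minus 20% of the range).
#' @return List with vectors `u` and `l`.
#' @examples
#' acceptance_bounds(rbind(c(1, 1), c(3, 3)))  # u = 3.4, l = 0.6
#' @export
acceptance_bounds <- function(Ro, widen = 0.2) {
  Ro <- as_rdf_rows(Ro)
  if (nrow(Ro) == 0L) stop("empty observed RDF matrix")
  hi <- apply(Ro, 2, max)
  lo <- apply(Ro, 2, min)
  rg <- hi - lo
  list(u = hi + widen * rg, l = pmax(lo - widen * rg, 0))
}

#' Spatial agreement measure between two RDF collections
#'
#' For each distance `j`, the proportion `A_j` of simulated RDF rows that lie
#' strictly inside the observed envelope (see [acceptance_bounds()]) is
#' computed; the SAM is the fraction of distances at which `A_j` reaches
#' `threshSAM`:
#' `A_j = #(l_j < Rs_kj < u_j) / N`, `SAM = #(A_j >= threshSAM) / M`.
#'
#' @param Ro observed RDF matrix (rows = on-treatment tiles).
#' @param Rs simulated RDF matrix (rows = baseline tiles x repeats).
#' @param threshSAM per-distance acceptance proportion threshold.
#' @param widen envelope widening factor.
#' @return SAM in `[0, 1]`.
#' @export
compute_sam <- function(Ro, Rs, threshSAM = 0.5, widen = 0.2) {
  Ro <- as_rdf_rows(Ro); Rs <- as_rdf_rows(Rs)
  if (ncol(Ro) != ncol(Rs)) stop("Ro and Rs must share the RDF length M")
  b <- acceptance_bounds(Ro, widen)
  inside <- sweep(Rs, 2, b$l, ">") & sweep(Rs, 2, b$u, "<")
  A <- colMeans(inside)
  mean(A >= threshSAM)
}

#' Variability agreement (VarSAM) between two RDF collections
#'
#' Ratio of the pooled RDF value ranges over the first `window` distance
#' units, taken in the direction that penalises disagreement:
#' `min(range(Rs) / range(Ro), range(Ro) / range(Rs))`. It guards against
#' artificially high SAM values produced by simulated RDFs with an
#' unrealistically narrow spread. A zero range on either side gives 0
#' (maximal disagreement).
#'
#' @inheritParams compute_sam
#' @param window number of leading distance units pooled (capped at M).
#' @return VarSAM in `[0, 1]`.
#' @export
compute_varsam <- function(Ro, Rs, window = 15L) {
  Ro <- as_rdf_rows(Ro); Rs <- as_rdf_rows(Rs)
  w <- min(window, ncol(Ro), ncol(Rs))
  ro <- Ro[, seq_len(w), drop = FALSE]
  rs <- Rs[, seq_len(w), drop = FALSE]
  rro <- diff(range(ro)); rrs <- diff(range(rs))
  if (rro == 0 || rrs == 0) return(0)
  min(rrs / rro, rro / rrs)
}

#' Count-based fallback comparison
#'
#' When the majority of simulated tiles carry too few CD8 cells for a
#' meaningful RDF, the per-tile CD8 counts are compared instead with a
#' two-sample pooled-variance t-test; the parameter set is accepted when the
#' test fails to reject that the counts share a distribution.
#'
#' @param observed_counts,simulated_counts integer vectors (length >= 2) of
#'   CD8 cells per tile.
#' @param alpha significance level.
#' @return `TRUE` (accept: not distinguishable) or `FALSE`.
#' @export
count_fallback <- function(observed_counts, simulated_counts, alpha = 0.05) {
  if (length(observed_counts) < 2L || length(simulated_counts) < 2L)
    stop("count fallback needs at least two tiles per side")
  if (stats::sd(observed_counts) == 0 && stats::sd(simulated_counts) == 0)
    return(observed_counts[1] == simulated_counts[1])
  p <- stats::t.test(observed_counts, simulated_counts,
                     var.equal = TRUE)$p.value
  p >= alpha
}

#' Score one simulated-vs-observed comparison
#'
#' Bundles SAM, VarSAM and the acceptance decision, using the count fallback
#' when the simulated RDF collection is flagged. A flagged observed
#' collection yields an excluded (NA) score: the sample cannot be evaluated
#' by the SAM.
#'
#' @param Ro,Rs `rdf_matrix` objects (observed, simulated).
#' @param observed_counts,simulated_counts per-tile CD8 counts, used for the
#'   fallback.
#' @param threshSAM per-distance proportion threshold for the SAM.
#' @param sam_thresh,varsam_thresh acceptance thresholds.
#' @param widen envelope widening factor.
#' @param alpha fallback t-test significance level.
#' @return Object of class `sam_score`: list with `sam`, `varsam`,
#'   `fallback_used`, `accepted`, `excluded`.
#' @export
sam_score <- function(Ro, Rs, observed_counts = Ro$n_cells,
                      simulated_counts = Rs$n_cells, threshSAM = 0.5,
                      sam_thresh = 0.7, varsam_thresh = 0.3, widen = 0.2,
                      alpha = 0.05) {
  stopifnot(inherits(Ro, "rdf_matrix"), inherits(Rs, "rdf_matrix"))
  if (Ro$flagged) {
    return(structure(list(sam = NA_real_, varsam = NA_real_,
                          fallback_used = FALSE, accepted = NA,
                          excluded = TRUE), class = "sam_score"))
  }
  if (Rs$flagged) {
    acc <- count_fallback(observed_counts, simulated_counts, alpha)
    return(structure(list(sam = NA_real_, varsam = NA_real_,
                          fallback_used = TRUE, accepted = acc,
                          excluded = FALSE), class = "sam_score"))
  }
  sam <- compute_sam(Ro, Rs, threshSAM, widen)
  varsam <- compute_varsam(Ro, Rs)
  structure(list(sam = sam, varsam = varsam, fallback_used = FALSE,
                 accepted = sam > sam_thresh && varsam > varsam_thresh,
                 excluded = FALSE), class = "sam_score")
}

#' @export
print.sam_score <- function(x, ...) {
  if (x$excluded) cat("sam_score: excluded (too few CD8 in observed tiles)\n")
  else if (x$fallback_used)
    cat(sprintf("sam_score: count fallback, accepted = %s\n", x$accepted))
  else cat(sprintf("sam_score: SAM %.3f, VarSAM %.3f, accepted = %s\n",
                   x$sam, x$varsam, x$accepted))
  invisible(x)
}
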