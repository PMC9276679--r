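#' Construct a cell map
#'
#' A cell map bundles the per-cell coordinates and classes detected on one
#' biopsy sample with the hand-drawn tumour annotation, rasterised onto the
#' simulation lattice. Physical coordinates are mapped to lattice sites by
#' `floor(coord / cell_width)`; one lattice unit is one cell width
#' (about 5 micrometres).
#'
#' @param cells data.frame with columns `x`, `y` (physical coordinates) and
#'   `class`, one of `"cd8"`, `"cd8_prolif"` (Ki67+ CD8) or
#'   `"tumour_prolif"` (detected proliferating tumour cell).
#' @param annotation binary matrix over the slide lattice; rows index the y
#'   axis, columns the x axis; 1 = inside the tumour annotation.
#' @param cell_width physical size of one lattice unit, in micrometres.
#' @return An object of class `cellmap`.
#' @examples
#' cm <- cellmap(data.frame(x = c(2, 12), y = c(2, 7),
#'                          class = c("cd8", "tumour_prolif")),
#'               annotation = matrix(1L, 20, 20), cell_width = 5)
#' @export
cellmap <- function(cells, annotation, cell_width = 5) {
  stopifnot(is.data.frame(cells), all(c("x", "y", "class") %in% names(cells)))
  if (nrow(cells) && !all(is.finite(cells$x) & is.finite(cells$y)))
    stop("all cell coordinates must be finite")
  bad <- setdiff(unique(cells$class), c("cd8", "cd8_prolif", "tumour_prolif"))
  if (length(bad))
    stop("unknown cell class(es): ", paste(bad, collapse = ", "))
  annotation <- matrix(as.integer(annotation != 0), nrow(annotation))
  if (cell_width <= 0) stop("'cell_width' must be positive")
  structure(list(cells = cells, annotation = annotation,
                 cell_width = cell_width),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cat(sprintf("cellmap: %d cells on a %d x %d lattice (cell width %g um)\n",
              nrow(x$cells), nrow(x$annotation), ncol(x$annotation),
              x$cell_width))
  print(table(x$cells$class))
  invisible(x)
}

new_tile <- function(grid, interior, ki67, origin, tissue_fraction) {
  structure(list(grid = grid, interior = interior, ki67 = ki67,
                 origin = origin, tissue_fraction = tissue_fraction,
                 L = nrow(grid)),
            class = "sam_tile")
}

#' @export
print.sam_tile <- function(x, ...) {
  cat(sprintf(
    "tile %dx%d at (%d, %d): %d tumour, %d immune, tissue fraction %.3f\n",
    x$L, x$L, x$origin[1], x$origin[2], sum(x$grid == 1L),
    sum(x$grid == 2L), x$tissue_fraction))
  invisible(x)
}

#' Extract model-ready tiles from a cell map
#'
#' Selects square fields of view from the annotated slide, keeping only tiles
#' with at least `min_tissue` of their area inside the tumour annotation and
#' with pairwise tile overlap of at most `max_overlap`. Candidate origins are
#' visited in raster order on a stride of
#' `ceiling(tile_size * (1 - max_overlap))` (plus the far edge, so fields of
#' view reach the annotation boundary) and accepted greedily, which makes the
#' tiling deterministic.
#'
#' Detected cells falling onto the same lattice site after discretisation are
#' resolved by keeping the first and dropping the rest (counted in the
#' `dropped` attribute of each tile).
#'
#' @param map a [cellmap()].
#' @param tile_size side length of a tile in lattice units.
#' @param min_tissue minimum fraction of tile sites inside the annotation.
#' @param max_overlap maximum pairwise overlap (shared sites / tile area).
#' @return A list of tiles (possibly empty if no placement satisfies the
#'   constraints; callers apply the >= 4 tiles per sample inclusion rule).
#' @examples
#' cm <- cellmap(data.frame(x = 10, y = 10, class = "cd8"),
#'               annotation = matrix(1L, 100, 100), cell_width = 1)
#' length(extract_tiles(cm))
#' @export
extract_tiles <- function(map, tile_size = 100L, min_tissue = 0.9,
                          max_overlap = 0.1) {
  stopifnot(inherits(map, "cellmap"))
  if (tile_size < 2) stop("'tile_size' must be >= 2")
  ann <- map$annotation
  if (sum(ann) == 0L) stop("no tissue: annotation mask is empty")
  nr <- nrow(ann); nc <- ncol(ann)
  if (nr < tile_size || nc < tile_size) return(list())

  # discretise detected cells onto the lattice (1-based)
  cr <- floor(map$cells$y / map$cell_width) + 1L
  cc <- floor(map$cells$x / map$cell_width) + 1L
  keep <- cr >= 1L & cr <= nr & cc >= 1L & cc <= nc
  cr <- cr[keep]; cc <- cc[keep]; cls <- map$cells$class[keep]

  stride <- as.integer(ceiling(tile_size * (1 - max_overlap)))
  cand <- function(n) {
    s <- seq.int(1L, n - tile_size + 1L, by = stride)
    if (s[length(s)] != n - tile_size + 1L) s <- c(s, n - tile_size + 1L)
    s
  }
  # 2-D cumulative annotation sums for O(1) tissue fractions
  C <- apply(ann, 2, cumsum)
  if (nr == 1L) C <- matrix(C, nrow = 1L)
  C <- t(apply(C, 1, cumsum))
  if (nc == 1L) C <- matrix(C, ncol = 1L)
  cs <- cbind(0, rbind(0, C))
  # annotated sites inside the tile with 1-based origin (r0, c0)
  block_sum <- function(r0, c0) {
    r1 <- r0 + tile_size; c1 <- c0 + tile_size
    cs[r1, c1] - cs[r0, c1] - cs[r1, c0] + cs[r0, c0]
  }

  accepted <- list()
  origins <- matrix(numeric(0), ncol = 2)
  area <- tile_size^2
  for (r0 in cand(nr)) for (c0 in cand(nc)) {
    tf <- block_sum(r0, c0) / area
    if (tf < min_tissue) next
    if (nrow(origins)) {
      ov <- pmax(0, tile_size - abs(origins[, 1] - r0)) *
        pmax(0, tile_size - abs(origins[, 2] - c0)) / area
      if (any(ov > max_overlap + 1e-12)) next
    }
    origins <- rbind(origins, c(r0, c0))
    accepted[[length(accepted) + 1L]] <- c(r0, c0)
  }

  lapply(accepted, function(o) {
    r0 <- o[1]; c0 <- o[2]
    grid <- matrix(0L, tile_size, tile_size)
    ki67 <- matrix(FALSE, tile_size, tile_size)
    interior <- map$annotation[r0:(r0 + tile_size - 1L),
                               c0:(c0 + tile_size - 1L)] == 1L
    inb <- cr >= r0 & cr < r0 + tile_size & cc >= c0 & cc < c0 + tile_size
    tr <- cr[inb] - r0 + 1L; tc <- cc[inb] - c0 + 1L; tcl <- cls[inb]
    dup <- duplicated(cbind(tr, tc))
    tr <- tr[!dup]; tc <- tc[!dup]; tcl <- tcl[!dup]
    idx <- cbind(tr, tc)
    grid[idx] <- ifelse(tcl == "tumour_prolif", 1L, 2L)
    ki67[idx] <- tcl %in% c("tumour_prolif", "cd8_prolif")
    t <- new_tile(grid, interior, ki67, origin = c(r0, c0),
                  tissue_fraction = block_sum(r0, c0) / area)
    attr(t, "dropped") <- sum(dup)
    t
  })
}

#' Back-fill tumour cells inside the annotation
#'
#' Cell detection only finds tumour cells in a specific cell-cycle stage
#' (Ki67+), so tiles are completed by filling empty annotation-interior sites
#' with tumour cells until the occupied fraction of interior sites reaches
#' `target_density` (70% of maximum packing by default). Detected cells are
#' never displaced.
#'
#' @param tile a tile from [extract_tiles()].
#' @param target_density target occupied fraction of annotation-interior
#'   sites, in `[0, 1]`.
#' @param seed RNG seed for reproducible placement (`NULL`: current stream).
#' @return The tile with back-filled tumour cells.
#' @examples
#' cm <- cellmap(data.frame(x = numeric(), y = numeric(),
#'                          class = character()),
#'               annotation = matrix(1L, 100, 100), cell_width = 1)
#' t <- populate_tumour(extract_tiles(cm)[[1]], seed = 1)
#' sum(t$grid == 1L)  # 7000
#' @export
populate_tumour <- function(tile, target_density = 0.7, seed = NULL) {
  stopifnot(inherits(tile, "sam_tile"))
  if (!is.numeric(target_density) || target_density < 0 || target_density > 1)
    stop("'target_density' must be in [0, 1]")
  interior <- tile$interior
  n_int <- sum(interior)
  if (n_int == 0L) return(tile)
  occ_int <- sum(tile$grid != 0L & interior)
  n_add <- max(0L, round(target_density * n_int) - occ_int)
  free <- which(interior & tile$grid == 0L)
  n_add <- min(n_add, length(free))
  if (n_add > 0L) {
    pick <- with_seed(seed, sample(free, n_add))
    tile$grid[pick] <- 1L
  }
  tile
}

#' Assign per-agent physiological properties
#'
#' Properties cannot be read off the images, so they are drawn from realistic
#' baseline distributions: tumour proliferation capacity is discrete-uniform
#' on 0..10 (detected proliferating tumour cells get 9), 20% of tumour cells
#' are stem cells, engagement capacity is discrete-uniform on {1, 2}; immune
#' proliferation capacity is discrete-uniform on 0..8 (Ki67+ CD8 get 7) and
#' killing capacity is 100, effectively unlimited. All engagement statuses
#' start at 0.
#'
#' @param tile a (typically back-filled) tile.
#' @param seed RNG seed (`NULL`: current stream).
#' @return A list of matrices aligned with the tile grid: `prolif`, `stem`,
#'   `engcap`, `killcap`.
#' @export
assign_properties <- function(tile, seed = NULL) {
  stopifnot(inherits(tile, "sam_tile"))
  L <- tile$L
  g <- tile$grid
  if (!all(g %in% c(0L, 1L, 2L))) stop("unknown cell class code in tile grid")
  prolif <- matrix(0L, L, L)
  stem <- matrix(FALSE, L, L)
  engcap <- matrix(0L, L, L)
  killcap <- matrix(0L, L, L)
  with_seed(seed, {
    tum <- which(g == 1L)
    imm <- which(g == 2L)
    prolif[tum] <- sample(0:10, length(tum), replace = TRUE)
    prolif[tum[tile$ki67[tum]]] <- 9L
    stem[tum] <- runif(length(tum)) < 0.2
    engcap[tum] <- sample(1:2, length(tum), replace = TRUE)
    prolif[imm] <- sample(0:8, length(imm), replace = TRUE)
    prolif[imm[tile$ki67[imm]]] <- 7L
    killcap[imm] <- 100L
  })
  list(prolif = prolif, stem = stem, engcap = engcap, killcap = killcap)
}
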