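#' Read a cell map from disk
#'
#' The on-disk form mirrors how cell detections are exported: a CSV/TSV of
#' per-cell physical coordinates and classes plus an annotation mask. Masks
#' can be 8-bit PNG (nonzero = annotated) or plain text with one row of
#' 0/1 digits per lattice row.
#'
#' @param cells_path CSV or TSV with columns `x`, `y`, `class`.
#' @param mask_path PNG or text mask.
#' @param cell_width lattice unit in micrometres.
#' @return A [cellmap()].
#' @export
read_cellmap <- function(cells_path, mask_path, cell_width = 5) {
  sep <- if (grepl("\\.tsv$", cells_path, ignore.case = TRUE)) "\t" else ","
  cells <- read.csv(cells_path, sep = sep, stringsAsFactors = FALSE)
  cellmap(cells, read_mask(mask_path), cell_width)
}

#' @rdname read_cellmap
#' @param map a [cellmap()].
#' @param dir output directory (created if missing); writes `cells.csv`,
#'   `mask.txt` and `meta.yaml` (cell width), round-trippable with
#'   [read_cellmap()].
#' @export
write_cellmap <- function(map, dir) {
  stopifnot(inherits(map, "cellmap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(map$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write_mask(map$annotation, file.path(dir, "mask.txt"))
  yaml::write_yaml(list(cell_width = map$cell_width),
                   file.path(dir, "meta.yaml"))
  invisible(file.path(dir))
}

read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(matrix(as.integer(img > 0.5), nrow(img)))
  }
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l)
    as.integer(strsplit(l, "")[[1]])))
}

write_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  } else {
    writeLines(apply(mask, 1, paste, collapse = ""), path)
  }
  invisible(path)
}

#' Read/write a gridstack container
#'
#' A gridstack bundles the tile class grids and per-agent property arrays of
#' one sample into a single named-array container on disk, the package's
#' interchange format between preprocessing and simulation runs.
#'
#' @param tiles list of tiles.
#' @param props optional list of property sets aligned with `tiles`.
#' @param path file path (`.rds`).
#' @param meta optional named list stored alongside (e.g. run config).
#' @return `read_gridstack`: list with `tiles`, `props`, `meta`.
#' @export
write_gridstack <- function(tiles, path, props = NULL, meta = list()) {
  saveRDS(list(tiles = tiles, props = props, meta = meta), path)
  invisible(path)
}

#' @rdname write_gridstack
#' @export
read_gridstack <- function(path) readRDS(path)

#' Write a trajectory's count time course as CSV
#'
#' @param traj a `sam_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(data.frame(day = traj$day, n_cd8 = traj$n_cd8,
                       n_tumour = traj$n_tumour),
            path, row.names = FALSE)
  invisible(path)
}

#' Render a tile as a PNG image
#'
#' Red = tumour cells, blue = immune (CD8) cells, black = non-tumour tissue,
#' matching the usual simulated-biopsy rendering.
#'
#' @param x tile, grid matrix, or trajectory (final grid).
#' @param path output PNG path.
#' @param scale integer pixel magnification per lattice site.
#' @export
render_tile <- function(x, path, scale = 3L) {
  g <- if (is.matrix(x)) x
  else if (inherits(x, "sam_trajectory")) x$final$grid
  else x$grid
  L <- nrow(g)
  img <- array(0, dim = c(L, ncol(g), 3))
  img[, , 1][g == 1L] <- 1 # tumour: red
  img[, , 3][g == 2L] <- 1 # immune: blue
  if (scale > 1L) {
    idx <- rep(seq_len(L), each = scale)
    jdx <- rep(seq_len(ncol(g)), each = scale)
    img <- img[idx, jdx, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write RDF curves and envelopes as tidy CSV
#'
#' @param R an `rdf_matrix`.
#' @param path output CSV path.
#' @param widen envelope widening for the bounds columns.
#' @export
write_rdf_csv <- function(R, path, widen = 0.2) {
  stopifnot(inherits(R, "rdf_matrix"))
  M <- ncol(R$mat)
  long <- do.call(rbind, lapply(seq_len(nrow(R$mat)), function(i)
    data.frame(tile = i, distance = seq_len(M), g = R$mat[i, ],
               too_few = R$too_few[i])))
  if (!R$flagged) {
    b <- acceptance_bounds(R, widen)
    long <- merge(long, data.frame(distance = seq_len(M), upper = b$u,
                                   lower = b$l), by = "distance")
  }
  write.csv(long[order(long$tile, long$distance), ], path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (preferred) or JSON configuration holding parameter overrides,
#' thresholds, repeats and seeds. A short content hash of the parsed config
#' is attached so outputs can record exactly which configuration produced
#' them.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list with attribute `"hash"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

# 32-bit polynomial rolling hash over the deparsed configuration
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
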