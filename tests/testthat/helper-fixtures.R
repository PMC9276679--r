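# shared fixture builders (all generated in code; nothing stored on disk)

# random class grid with given counts; codes 0 empty / 1 tumour / 2 immune
make_grid <- function(L, n_tumour, n_immune, seed = NULL) {
  build <- function() {
    g <- matrix(0L, L, L)
    s <- sample(L * L, n_tumour + n_immune)
    g[s[seq_len(n_tumour)]] <- 1L
    if (n_immune > 0) g[s[n_tumour + seq_len(n_immune)]] <- 2L
    g
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# fully annotated populated tile with properties, ready to simulate
make_ready_tile <- function(L = 20, n_cd8 = 20, seed = 1,
                            pattern = "csr", fill = 0.7) {
  cm <- generate_cellmap(pattern, n_cd8 = n_cd8, L = L, seed = seed)
  tile <- populate_tumour(extract_tiles(cm, tile_size = L)[[1]],
                          target_density = fill, seed = seed + 1)
  list(tile = tile, props = assign_properties(tile, seed = seed + 2))
}

# parameters with every stochastic action switched off (overridable)
frozen_params <- function(...) {
  zeros <- list(IMpprol = 0, IMpkill = 0, IMpdeath = 0, IMrwalk = 0,
                TUpprol = 0, TUpmig = 0, TUpdeath = 0, IMpmig = 0,
                IMinfluxProb = 0, IMinflRate = 0)
  do.call(model_params, utils::modifyList(zeros, list(...)))
}

# small synthetic cohort for calibration tests (20x20 tiles)
make_cohort <- function(n_patients = 3, tiles = 4, end_days = 10, L = 20,
                        theta = model_params(), seed = 1,
                        n_cd8_range = c(12, 30)) {
  generate_paired_cohort(n_patients = n_patients, tiles_per_patient = tiles,
                         theta_star = theta, end_days = end_days, L = L,
                         n_cd8_range = n_cd8_range, seed = seed)
}
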