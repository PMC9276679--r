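# Straightforward pure-R re-implementation of the lattice update rules, kept
# independent of the package's compiled stepper so the two can be compared
# distributionally. Slow by design; only used on small grids.

ref_simulate <- function(grid, props, params, n_steps) {
  L <- nrow(grid)
  pos <- which(grid != 0L)
  A <- data.frame(pos = pos, cls = grid[pos], prolif = props$prolif[pos],
                  stem = props$stem[pos], engcap = props$engcap[pos],
                  killcap = props$killcap[pos], engstat = 0L, alive = TRUE)
  occ <- rep(NA_integer_, L * L)
  occ[A$pos] <- seq_len(nrow(A))

  moore <- function(p) {
    r <- (p - 1L) %% L + 1L; c <- (p - 1L) %/% L + 1L
    rr <- (r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L) - 1L) %% L + 1L
    cc <- (c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L) - 1L) %% L + 1L
    (cc - 1L) * L + rr
  }
  pdist <- function(p, q) { # periodic Chebyshev
    r1 <- (p - 1L) %% L + 1L; c1 <- (p - 1L) %/% L + 1L
    r2 <- (q - 1L) %% L + 1L; c2 <- (q - 1L) %/% L + 1L
    dr <- abs(r1 - r2); dr <- pmin(dr, L - dr)
    dc <- abs(c1 - c2); dc <- pmin(dc, L - dc)
    pmax(dr, dc)
  }
  pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  kill_agent <- function(ai) {
    A$alive[ai] <<- FALSE
    occ[A$pos[ai]] <<- NA_integer_
  }
  spawn <- function(p, cls, prolif, stem, engcap, killcap) {
    A <<- rbind(A, data.frame(pos = p, cls = cls, prolif = prolif,
                              stem = stem, engcap = engcap,
                              killcap = killcap, engstat = 0L,
                              alive = TRUE))
    occ[p] <<- nrow(A)
  }

  for (s in seq_len(n_steps)) {
    alive_now <- which(A$alive)
    ord <- if (length(alive_now) > 1L) sample(alive_now) else alive_now
    for (ai in ord) {
      if (!A$alive[ai]) next
      if (A$cls[ai] == 1L) {            # ---- tumour
        if (runif(1) < params$TUpdeath) { kill_agent(ai); next }
        if (runif(1) < params$TUpprol) {
          if (A$prolif[ai] <= 0L && !A$stem[ai]) { kill_agent(ai); next }
          fr <- moore(A$pos[ai]); fr <- fr[is.na(occ[fr])]
          if (length(fr)) {
            if (A$stem[ai]) {
              dstem <- runif(1) < 0.2
              dprol <- as.integer(params$TUpmax)
            } else {
              A$prolif[ai] <- A$prolif[ai] - 1L
              dstem <- FALSE
              dprol <- A$prolif[ai]
            }
            spawn(pick1(fr), 1L, dprol, dstem,
                  sample(seq_len(max(1L, round(params$TUintmax))), 1L), 0L)
          }
        }
        if (A$engstat[ai] == 0L && runif(1) < params$TUpmig) {
          fr <- moore(A$pos[ai]); fr <- fr[is.na(occ[fr])]
          if (length(fr)) {
            np <- pick1(fr)
            occ[A$pos[ai]] <- NA_integer_; A$pos[ai] <- np; occ[np] <- ai
          }
        }
      } else {                          # ---- immune
        if (runif(1) < params$IMpdeath) { kill_agent(ai); next }
        if (runif(1) < params$IMpprol) {
          if (A$prolif[ai] <= 0L) { kill_agent(ai); next }
          fr <- moore(A$pos[ai]); fr <- fr[is.na(occ[fr])]
          if (length(fr)) {
            A$prolif[ai] <- A$prolif[ai] - 1L
            spawn(pick1(fr), 2L, A$prolif[ai], FALSE, 0L, 100L)
          }
        }
        if (runif(1) < params$IMpkill && A$killcap[ai] > 0L) {
          nb <- moore(A$pos[ai])
          tum <- nb[!is.na(occ[nb])]
          tum <- tum[A$cls[occ[tum]] == 1L]
          if (length(tum)) {
            vi <- occ[pick1(tum)]
            A$engcap[vi] <- A$engcap[vi] - 1L
            A$killcap[ai] <- A$killcap[ai] - 1L
            A$engstat[ai] <- 1L
            if (A$engcap[vi] <= 0L) kill_agent(vi) else A$engstat[vi] <- 1L
          }
        }
        if (A$engstat[ai] == 0L) {
          nmov <- floor(params$IMpmig) +
            (runif(1) < params$IMpmig - floor(params$IMpmig))
          for (m in seq_len(nmov)) {
            fr <- moore(A$pos[ai]); fr <- fr[is.na(occ[fr])]
            if (!length(fr)) next
            if (runif(1) < params$IMrwalk) {
              np <- pick1(fr)
            } else {
              tums <- which(A$alive & A$cls == 1L)
              if (!length(tums)) {
                np <- pick1(fr)
              } else {
                dd <- pdist(A$pos[ai], A$pos[tums])
                tgt <- A$pos[pick1(tums[dd == min(dd)])]
                dn <- pdist(fr, tgt)
                np <- pick1(fr[dn == min(dn)])
              }
            }
            occ[A$pos[ai]] <- NA_integer_; A$pos[ai] <- np; occ[np] <- ai
          }
        }
      }
    }
    if (runif(1) < params$IMinfluxProb) {
      for (k in seq_len(round(params$IMinflRate))) {
        free <- which(is.na(occ))
        if (!length(free)) break
        spawn(pick1(free), 2L, as.integer(params$IMpmax), FALSE, 0L, 100L)
      }
    }
    A$engstat <- 0L
  }
  g <- matrix(0L, L, L)
  g[A$pos[A$alive]] <- A$cls[A$alive]
  g
}
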