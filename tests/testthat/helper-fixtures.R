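# Shared fixtures and independent oracles. Fixtures are built in code; no
# files ship with the tests except what the tests themselves write to
# tempdirs.

# a tiny all-sea stack with hand-set layer values (one categorical layer)
tiny_stack <- function(temp, bathy = NULL, landscape = NULL,
                       origin = c(0, 0), cell_size = 0.1) {
  temp <- as.matrix(temp)
  if (is.null(bathy)) bathy <- matrix(-80, nrow(temp), ncol(temp))
  if (is.null(landscape)) landscape <- matrix(0L, nrow(temp), ncol(temp))
  mk <- function(nm, v) grid_layer(nm, v, origin[1], origin[2], cell_size)
  layer_stack(list(
    temperature = mk("temperature", temp),
    bathymetry = mk("bathymetry", bathy),
    landscape = categorical_grid_layer("landscape", landscape,
                                       origin[1], origin[2], cell_size)))
}

# the default synthetic world used by the deeper tests (cached per session)
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 1)
      tr <- truth_spec()
      st <- generate_environment(cfg, tr)
      occ <- filter_to_coverage(generate_occurrences(st, tr, cfg), st)
      cache <<- list(cfg = cfg, tr = tr, st = st, occ = occ)
    }
    cache
  }
})

# --- independent oracles ----------------------------------------------------

# single-linkage components by explicit union-find over all pairs
oracle_single_linkage <- function(lon, lat, linkage_km) {
  n <- length(lon)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && haversine_km(lon[i], lat[i], lon[j], lat[j]) <= linkage_km)
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# AUC by explicit all-pairs counting, ties worth one half
oracle_auc <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

# Horn slope by per-cell loops (same kernel, independent code path)
oracle_slope <- function(bathy) {
  z <- bathy$values
  nr <- nrow(z); nc <- ncol(z)
  K <- 2 * pi * 6371 / 360
  lats <- bathy$origin_lat + (nr - seq_len(nr) + 0.5) * bathy$cell_size
  out <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    dx <- bathy$cell_size * K * cos(lats[i] * pi / 180) * 1000
    dy <- bathy$cell_size * K * 1000
    gx <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
             (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * dx)
    gy <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
             (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * dy)
    out[i, j] <- 100 * sqrt(gx^2 + gy^2)
  }
  out
}

# maxent objective for the oracle searches (unpenalized, beta optional)
oracle_objective <- function(lambda, Fp, Fb, beta_j = 0) {
  sb <- Fb %*% lambda
  mean(Fp %*% lambda) - log(mean(exp(sb))) - sum(beta_j * abs(lambda))
}

# exhaustive grid search over weights, refined over successive rounds;
# independent of the gradient-based fitting path
oracle_grid_fit <- function(Fp, Fb, lo = -10, hi = 10, rounds = 6,
                            pts = 41) {
  m <- ncol(Fp)
  centre <- rep(0, m); half <- (hi - lo) / 2
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(m), function(j)
      seq(centre[j] - half, centre[j] + half, length.out = pts))
    best <- -Inf; best_l <- centre
    combos <- as.matrix(expand.grid(grids))
    for (k in seq_len(nrow(combos))) {
      v <- oracle_objective(combos[k, ], Fp, Fb)
      if (v > best) { best <- v; best_l <- combos[k, ] }
    }
    centre <- best_l
    half <- half * 2.2 / (pts - 1)   # shrink around the winner
  }
  centre
}
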