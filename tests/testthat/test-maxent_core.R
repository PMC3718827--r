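# Maximum-entropy model: background sampling, fitting (closed form, oracle
# equivalence, KKT), raw/logistic prediction, projection clamping, jackknife.

# small helper: data.frames carrying a single already-scaled feature; using
# a degenerate 0/1-range "temperature" makes featurize the identity on the
# linear feature
one_feature_df <- function(x) data.frame(temperature = x)

fit1 <- function(pres_x, bg_x, beta = 0) {
  maxent_fit(one_feature_df(pres_x), one_feature_df(bg_x), beta = beta,
             categorical = character(0), classes = "linear")
}

test_that("background sampling is deterministic, eligible and unbiased", {
  w <- default_world()
  b1 <- sample_background(w$st, w$occ, n = 500, mode = "global", seed = 3)
  b2 <- sample_background(w$st, w$occ, n = 500, mode = "global", seed = 3)
  expect_identical(b1, b2)
  ok <- reefsuit:::valid_mask(w$st)
  idx <- cell_index(w$st$layers$temperature, b1$lon, b1$lat)
  expect_true(all(ok[cbind(idx$row, idx$col)]))
  # bias mode: every point within 20 km of some occurrence
  bb <- sample_background(w$st, w$occ, n = 300, mode = "bias",
                          buffer_km = 20, seed = 3)
  dmin <- vapply(seq_len(nrow(bb)), function(i)
    min(haversine_km(bb$lon[i], bb$lat[i], w$occ$lon, w$occ$lat)), 0)
  expect_lte(max(dmin), 20 + 0.5)   # half a cell of rasterisation slack
  # two-cell sea: empirical frequencies within 3 binomial sd of 1/2
  temp <- matrix(NA_real_, 3, 3); temp[2, 2] <- 10; temp[2, 3] <- 11
  st2 <- tiny_stack(temp)
  s <- sample_background(st2, n = 10000, mode = "global", seed = 7)
  frac <- mean(s$lon > 0.2)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(sample_background(tiny_stack(matrix(NA_real_, 3, 3))),
               "eligible")
})

test_that("single binary feature fit matches the closed form log 4", {
  pres <- c(rep(1, 8), rep(0, 2))    # presence mean 0.8
  bg <- rep(c(0, 1), 50)             # background mean 0.5
  m <- fit1(pres, bg, beta = 0)
  expect_equal(unname(m$weights), log(4), tolerance = 1e-4)
  # full shrinkage: a huge beta zeroes the weights -> uniform raw
  m0 <- fit1(pres, bg, beta = 1e6)
  expect_equal(unname(m0$weights), 0)
  expect_equal(m0$entropy, log(100), tolerance = 1e-8)
})

test_that("small-world fits match the exhaustive grid-search oracle", {
  # 3-cell toy world, one linear feature, beta = 0 (background spans [0,1]
  # so the feature scaling is the identity)
  Fp <- matrix(c(0.9, 0.8, 0.9), ncol = 1)
  Fb <- matrix(c(0, 0.5, 1), ncol = 1)
  m <- fit1(as.vector(Fp), as.vector(Fb), beta = 0)
  lam_star <- oracle_grid_fit(Fp, Fb)
  expect_equal(unname(m$weights), unname(lam_star), tolerance = 1e-4)
  # <= 10 cells, 2 features: weights to 1e-4, raw probabilities to 1e-6
  set.seed(33)
  Fb2 <- cbind(runif(10), runif(10))
  Fp2 <- cbind(runif(6, 0.4, 1), runif(6, 0, 0.6))
  pres <- data.frame(temperature = Fp2[, 1], bathymetry = Fp2[, 2])
  bg <- data.frame(temperature = Fb2[, 1], bathymetry = Fb2[, 2])
  m2 <- maxent_fit(pres, bg, beta = 0, categorical = character(0),
                   classes = "linear")
  # undo the background min/max feature scaling for the oracle comparison
  sc <- vapply(m2$features$ranges, function(r) r[2] - r[1], 0)
  off <- vapply(m2$features$ranges, function(r) r[1], 0)
  Fb2s <- sweep(sweep(Fb2, 2, off), 2, sc, "/")
  Fp2s <- sweep(sweep(pmin(pmax(Fp2, rep(off, each = 6)),
                           rep(off + sc, each = 6)), 2, off), 2, sc, "/")
  lam2 <- oracle_grid_fit(Fp2s, Fb2s, rounds = 8)
  expect_equal(unname(m2$weights), unname(lam2), tolerance = 1e-4)
  raw_ours <- exp(Fb2s %*% m2$weights)
  raw_ours <- raw_ours / sum(raw_ours)
  raw_oracle <- exp(Fb2s %*% lam2); raw_oracle <- raw_oracle / sum(raw_oracle)
  expect_equal(as.vector(raw_ours), as.vector(raw_oracle),
               tolerance = 1e-6)
})

test_that("fitting improves the objective and satisfies the KKT box", {
  w <- default_world()
  bg <- sample_background(w$st, w$occ, n = 1500, mode = "global", seed = 5)
  pres_v <- extract_values(w$st, w$occ)
  bg_v <- extract_values(w$st, bg)
  m <- maxent_fit(pres_v, bg_v, beta = 1.0)
  expect_gt(m$gain, 0)   # better than the uniform model it starts from
  fs <- m$features
  Fp <- featurize(fs, pres_v); Fb <- featurize(fs, bg_v)
  expect_true(all(Fp >= 0 & Fp <= 1) && all(Fb >= 0 & Fb <= 1))
  sb <- as.vector(Fb %*% m$weights)
  wgt <- exp(sb - max(sb)); wgt <- wgt / sum(wgt)
  model_mean <- as.vector(t(Fb) %*% wgt)
  gap <- abs(colMeans(Fp) - model_mean)
  expect_true(all(gap <= m$beta_j + 1e-6))
  # raw probabilities over the training background sum to 1, entropy >= 0
  raw <- exp(sb - m$log_z)
  expect_equal(sum(raw), 1, tolerance = 1e-12)
  expect_gte(m$entropy, 0)
  # hinge/product features are named but rejected
  expect_error(maxent_fit(pres_v, bg_v, classes = c("linear", "hinge")),
               "hinge")
})

test_that("raw prediction normalises, is monotone, and clamps", {
  w <- default_world()
  bg <- sample_background(w$st, w$occ, n = 1000, mode = "global", seed = 6)
  m <- maxent_fit(extract_values(w$st, w$occ), extract_values(w$st, bg))
  raw <- predict_raw(m, w$st)
  expect_equal(sum(raw$values, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(is.na(raw$values[w$st$land_mask])))
  # all-zero weights -> uniform raw over valid cells
  m0 <- m; m0$weights[] <- 0
  raw0 <- predict_raw(m0, w$st)
  vals <- raw0$values[!raw0$nodata_mask]
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-15)
  # warming past the training range clamps every temperature feature
  hot <- apply_scenario(w$st, 50)
  s_hot <- reefsuit:::stack_scores(m, hot)
  f_hot <- featurize(m$features,
                     data.frame(temperature =
                                  hot$layers$temperature$values[s_hot$idx]))
  expect_true(all(f_hot[, "temperature:lin"] == 1))
})

test_that("logistic output is the entropy-calibrated transform", {
  # featureless model: raw uniform over N background cells -> logistic 0.5
  w <- default_world()
  bg <- sample_background(w$st, w$occ, n = 800, mode = "global", seed = 8)
  m <- maxent_fit(extract_values(w$st, w$occ), extract_values(w$st, bg),
                  beta = 1e9)   # full shrinkage
  expect_true(all(m$weights == 0))
  p <- predict_logistic(m, w$st)
  vals <- p$values[!p$nodata_mask]
  expect_equal(range(vals), c(0.5, 0.5), tolerance = 1e-12)
  # logistic is strictly increasing in the raw score and bounded in (0,1)
  m2 <- maxent_fit(extract_values(w$st, w$occ), extract_values(w$st, bg))
  lp <- predict_logistic(m2, w$st)
  rp <- predict_raw(m2, w$st)
  ok <- !lp$nodata_mask
  ord <- order(rp$values[ok])
  expect_true(all(diff(lp$values[ok][ord]) >= 0))
  expect_true(all(lp$values[ok] > 0 & lp$values[ok] < 1))
  # identity projection: scenario = baseline -> identical map
  expect_equal(maxent_project(m2, w$st)$values, lp$values)
})

test_that("jackknife ranks the signal-bearing variable first", {
  # construct: temperature carries all the signal, 'noise' carries none
  set.seed(44)
  n <- 400
  bg <- data.frame(temperature = runif(n), noise = runif(n))
  pres <- data.frame(temperature = rbeta(120, 8, 2), noise = runif(120))
  jk <- maxent_jackknife(pres, bg, beta = 0.5, categorical = character(0))
  expect_setequal(jk$variable, c("temperature", "noise"))
  gains <- setNames(jk$gain_with_only, jk$variable)
  expect_gt(gains["temperature"], gains["noise"])
  expect_lt(gains["noise"], 0.05)
  # nested models: full gain >= every without-v gain at beta = 0
  jk0 <- maxent_jackknife(pres, bg, beta = 0, categorical = character(0))
  expect_true(all(attr(jk0, "full_gain") >= jk0$gain_without - 1e-6))
  expect_true(all(jk0$auc_without >= 0 & jk0$auc_without <= 1))
})

test_that("model JSON serialisation round-trips predictions", {
  w <- default_world()
  bg <- sample_background(w$st, w$occ, n = 600, mode = "global", seed = 9)
  m <- maxent_fit(extract_values(w$st, w$occ), extract_values(w$st, bg))
  p <- tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  expect_equal(m2$weights, m$weights)
  expect_equal(predict_points(m2, extract_values(w$st, w$occ)),
               predict_points(m, extract_values(w$st, w$occ)))
})
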