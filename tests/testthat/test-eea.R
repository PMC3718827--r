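# Environmental envelope analysis: grouping, buffering, preferred ranges,
# landscape preference, envelope mask.

test_that("population grouping follows the linkage rule", {
  # two points ~5 km apart -> one population (1 deg lat = 111.19 km)
  o2 <- occurrence_set(c(0, 0), c(54, 54.045))
  expect_equal(length(group_populations(o2, 10)$populations), 1)
  # ~15 km apart -> two populations
  o15 <- occurrence_set(c(0, 0), c(54, 54.135))
  expect_equal(length(group_populations(o15, 10)$populations), 2)
  # chain A-B 8 km, B-C 8 km (A-C 16 km) -> one population via the chain
  oc <- occurrence_set(c(0, 0, 0), c(54, 54.072, 54.144))
  d <- haversine_matrix(oc$lon, oc$lat)
  expect_lt(d[1, 2], 10); expect_lt(d[2, 3], 10); expect_gt(d[1, 3], 10)
  expect_equal(length(group_populations(oc, 10)$populations), 1)
  # population ids ordered by southernmost member
  omix <- occurrence_set(c(0, 0, 0.5), c(54.5, 54.51, 54.0),
                         c("n1", "n2", "s"))
  g <- group_populations(omix, 10)
  expect_equal(g$populations[[1]]$member_ids, "s")
})

test_that("grouping equals the brute-force union-find oracle", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(5:50, 1)
    lon <- runif(n, -6, -5); lat <- runif(n, 54, 54.6)
    g <- group_populations(occurrence_set(lon, lat), 10)
    ours <- g$occ$population
    oracle <- oracle_single_linkage(lon, lat, 10)
    # identical partitions once labels are canonicalised by first appearance
    canon <- function(x) match(x, unique(x))
    expect_equal(canon(ours), canon(oracle))
  }
})

test_that("buffered footprints approximate disks and clip to sea", {
  # fine local grid so the 1 km disk is well resolved
  nr <- 120
  temp <- matrix(10, nr, nr)
  st <- tiny_stack(temp, origin = c(-0.03, 53.97), cell_size = 0.0005)
  occ <- occurrence_set(0, 54)
  pops <- buffer_population(group_populations(occ, 10), st, radius_km = 1)
  fp <- pops$populations[[1]]$footprint
  area <- sum(cell_area_km2(st$layers$temperature)$values[fp])
  expect_equal(area, pi, tolerance = 0.01)
  # two coincident points: footprint unchanged (idempotent union)
  occ2 <- occurrence_set(c(0, 0), c(54, 54), c("a", "b"))
  pops2 <- buffer_population(group_populations(occ2, 10), st, radius_km = 1)
  expect_identical(pops2$populations[[1]]$footprint, fp)
  # fully land-masked footprint -> empty with a warning
  stl <- st; stl$land_mask[] <- TRUE
  expect_warning(pl <- buffer_population(group_populations(occ, 10), stl, 1),
                 "land")
  expect_false(any(pl$populations[[1]]$footprint))
})

test_that("preferred_range is the type-7 interquartile interval", {
  expect_equal(preferred_range(c(0, 1, 2, 3, 4)), c(1, 3))
  expect_equal(preferred_range(1:8), c(2.75, 6.25))
  expect_equal(preferred_range(c(5, 5, 5)), c(5, 5))
  expect_equal(preferred_range(7), c(7, 7))
  expect_error(preferred_range(numeric(0)), "finite")
})

test_that("landscape preference implements the median-of-fractions rule", {
  # vertical strips: cols 1-30 code 0, 31-32 a narrow code-1 band, 33-60
  # code 2; population buffers straddle the band boundaries
  ls <- matrix(rep(c(0L, 1L, 2L), c(30, 2, 28)), 30, 60, byrow = TRUE)
  st <- tiny_stack(matrix(10, 30, 60), landscape = ls,
                   origin = c(0, 54), cell_size = 0.01)
  # P1 inside code 0; P2 straddles 0|1; P3 straddles 1|2
  # -> fractions 0: 2/3, 1: 2/3, 2: 1/3; median 2/3 -> prefer {0, 1}
  occ <- occurrence_set(c(0.15, 0.295, 0.325), c(54.05, 54.15, 54.25),
                        paste0("o", 1:3))
  pops <- group_populations(occ, linkage_km = 8)
  expect_equal(length(pops$populations), 3)
  pops <- buffer_population(pops, st, radius_km = 1)
  pref <- landscape_preference(pops, st$layers$landscape)
  f <- attr(pref, "fractions")
  expect_equal(unname(f[c("0", "1", "2")]), c(2, 2, 1) / 3)
  expect_equal(sort(as.integer(pref)), c(0L, 1L))
  expect_equal(attr(pref, "max"), 2 / 3)
  # a single population prefers every overlapped code
  p1 <- buffer_population(group_populations(occurrence_set(0.05, 54.05), 8),
                          st, 1)
  expect_equal(as.integer(landscape_preference(p1, st$layers$landscape)), 0L)
})

test_that("envelope recovery on synthetic truth", {
  w <- default_world()
  env <- build_envelope(w$st, w$occ)
  expect_length(env$continuous_ranges, 5)
  for (nm in names(env$continuous_ranges)) {
    r <- env$continuous_ranges[[nm]]
    iv <- w$tr$intervals[[nm]]
    expect_gte(r[1], iv[1]); expect_lte(r[2], iv[2])
  }
  # envelope cells satisfy the continuous truth everywhere; any cell outside
  # the truth region fails only the landscape constraint (1 km buffers can
  # admit classes adjacent to the population patches)
  em <- envelope_mask(w$st, env)
  tm <- reefsuit:::truth_mask(w$st, w$tr)
  cells <- which(em$values > 0)
  cont_ok <- rep(TRUE, length(cells))
  for (nm in names(w$tr$intervals)) {
    v <- w$st$layers[[nm]]$values[cells]
    iv <- w$tr$intervals[[nm]]
    cont_ok <- cont_ok & v >= iv[1] & v <= iv[2]
  }
  expect_true(all(cont_ok))
  outside <- cells[!tm[cells]]
  expect_true(all(!w$st$layers$landscape$values[outside] %in%
                    w$tr$preferred_landscape))
})

test_that("envelope mask is antitone in its constraints", {
  w <- default_world()
  env <- build_envelope(w$st, w$occ)
  em <- envelope_mask(w$st, env)
  base_cells <- which(em$values > 0)
  # tightening one interval never adds cells
  tighter <- env
  r <- tighter$continuous_ranges$temperature
  tighter$continuous_ranges$temperature <- c(r[1] + 0.2 * diff(r), r[2])
  cells_t <- which(envelope_mask(w$st, tighter)$values > 0)
  expect_true(all(cells_t %in% base_cells))
  # dropping the landscape constraint never shrinks the mask
  nolc <- env; nolc$preferred_landscape <- integer(0)
  cells_n <- which(envelope_mask(w$st, nolc)$values > 0)
  expect_true(all(base_cells %in% cells_n))
  expect_gte(length(cells_n), length(base_cells))
  # vacuous constraints give all valid sea; impossible interval gives none
  allc <- env
  for (nm in names(allc$continuous_ranges))
    allc$continuous_ranges[[nm]] <- c(-Inf, Inf)
  allc$preferred_landscape <-
    sort(unique(as.integer(w$st$layers$landscape$values[
      !w$st$layers$landscape$nodata_mask])))
  expect_equal(sum(envelope_mask(w$st, allc)$values > 0, na.rm = TRUE),
               sum(reefsuit:::valid_mask(w$st)))
  none <- env; none$continuous_ranges$salinity <- c(9e5, 9e5 + 1)
  em0 <- envelope_mask(w$st, none)
  expect_equal(attr(em0, "area_km2"), 0)
  # missing variable errors by name
  st2 <- w$st; st2$layers$salinity <- NULL
  expect_error(envelope_mask(st2, env), "salinity")
})

test_that("envelope area is non-increasing under warming once the warm
           edge is the only temperature limit", {
  w <- default_world()
  env <- build_envelope(w$st, w$occ)
  lo <- env$continuous_ranges$temperature[1]
  sea_min_t <- min(w$st$layers$temperature$values[
    reefsuit:::valid_mask(w$st)])
  # smallest increment at which no sea cell is below the cold edge: from
  # here on, warming can only remove cells from the envelope
  dT0 <- max(0, lo - sea_min_t)
  dts <- dT0 + c(0, 0.4, 0.8, 1.2, 1.6)
  areas <- vapply(dts, function(dt)
    attr(envelope_mask(apply_scenario(w$st, dt), env), "area_km2"), 0)
  expect_true(all(diff(areas) <= 1e-9))
})
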