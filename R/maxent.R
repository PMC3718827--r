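# Maximum-entropy presence-background suitability model, from scratch.
#
# The model is a Gibbs distribution over background locations,
# raw(x) = exp(lambda . f(x)) / Z, whose feature expectations match the
# presence sample up to an L1 budget. Fitting maximises the penalized
# log-likelihood
#     l(lambda) = mean_pres lambda.f  -  log mean_bg exp(lambda.f)
#                 - sum_j beta_j |lambda_j|
# by splitting lambda into non-negative positive/negative parts and running
# box-constrained L-BFGS-B, which is smooth, deterministic, and satisfies
# the KKT box condition |presence mean - model mean| <= beta_j at optimum.
#
# Features: per continuous variable a linear and a quadratic term scaled to
# [0,1] over the training background; per categorical class an indicator.
# Projection clamps features to the training [0,1] range. The logistic
# output uses the training-background normaliser and the entropy H of the
# fitted raw distribution: logistic = e^H raw / (1 + e^H raw), the standard
# transform with tau = 0.5 (so a featureless model scores 0.5 everywhere).

#' Sample background (pseudo-absence) points
#'
#' Uniform over eligible cell centres, with replacement. Eligible cells are
#' valid sea cells; in `"bias"` mode they are additionally within
#' `buffer_km` of at least one occurrence.
#'
#' @param stack a `LayerStack`.
#' @param occ an `OccurrenceSet` (required for `"bias"` mode).
#' @param n number of points (field default 10000).
#' @param mode `"global"` or `"bias"`.
#' @param buffer_km bias-mode buffer radius (default 20 km).
#' @param seed integer seed; sampling is deterministic given it.
#' @return object of class `BackgroundSample`: data.frame of `lon`, `lat`
#'   with attributes `mode`, `buffer_km`, `seed`.
#' @export
sample_background <- function(stack, occ = NULL, n = 10000,
                              mode = c("global", "bias"), buffer_km = 20,
                              seed = 1) {
  mode <- match.arg(mode)
  ref <- first_layer(stack)
  ok <- valid_mask(stack)
  if (mode == "bias") {
    if (is.null(occ) || nrow(occ) == 0)
      stop("bias mode requires occurrences")
    ok <- ok & within_buffer(ref, occ, buffer_km)
    if (!any(ok)) stop("no sea cells within ", buffer_km,
                       " km of any occurrence")
  }
  if (!any(ok)) stop("no eligible background cells")
  cells <- which(ok, arr.ind = TRUE)
  lats <- cell_centre_lats(ref); lons <- cell_centre_lons(ref)
  with_seed(seed, {
    k <- sample.int(nrow(cells), n, replace = TRUE)
    structure(data.frame(lon = lons[cells[k, 2]], lat = lats[cells[k, 1]]),
              mode = mode, buffer_km = buffer_km, seed = seed, n = n,
              class = c("BackgroundSample", "data.frame"))
  })
}

# logical grid: cell centre within buffer_km of >= 1 occurrence
within_buffer <- function(ref, occ, buffer_km) {
  lats <- cell_centre_lats(ref); lons <- cell_centre_lons(ref)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  hit <- matrix(FALSE, nr, nc)
  dlat <- buffer_km / KM_PER_DEGREE
  for (k in seq_len(nrow(occ))) {
    dlon <- buffer_km / (KM_PER_DEGREE * cos(occ$lat[k] * pi / 180))
    rows <- which(lats >= occ$lat[k] - dlat & lats <= occ$lat[k] + dlat)
    cols <- which(lons >= occ$lon[k] - dlon & lons <= occ$lon[k] + dlon)
    if (!length(rows) || !length(cols)) next
    dd <- outer(lats[rows], lons[cols], function(la, lo)
      haversine_km(occ$lon[k], occ$lat[k], lo, la))
    hit[rows, cols] <- hit[rows, cols] | (dd <= buffer_km)
  }
  hit
}

#' Define the feature expansion from training background values
#'
#' Linear and quadratic features per continuous variable, scaled to [0,1]
#' by the background min/max; an indicator feature per categorical class
#' observed in the background. Hinge and product feature classes are
#' deliberately not implemented and are rejected with a message.
#'
#' @param bg_values data.frame of background environmental values (from
#'   [extract_values()]).
#' @param categorical character vector naming the categorical columns.
#' @param classes feature classes to enable; subset of
#'   `c("linear", "quadratic", "categorical")`.
#' @return object of class `FeatureSet`.
#' @export
feature_set <- function(bg_values, categorical = "landscape",
                        classes = c("linear", "quadratic", "categorical")) {
  rejected <- intersect(classes, c("hinge", "product", "threshold"))
  if (length(rejected))
    stop("feature class(es) not supported in this implementation: ",
         paste(rejected, collapse = ", "))
  classes <- match.arg(classes, several.ok = TRUE)
  vars <- setdiff(names(bg_values), c("id", categorical))
  cont <- vars[vapply(bg_values[vars], is.numeric, TRUE)]
  rng <- lapply(cont, function(nm) {
    r <- range(bg_values[[nm]], na.rm = TRUE)
    if (r[1] == r[2]) r[2] <- r[1] + 1   # constant layer: degenerate scale
    r
  })
  names(rng) <- cont
  cat_classes <- list()
  for (nm in intersect(categorical, names(bg_values)))
    cat_classes[[nm]] <- sort(unique(bg_values[[nm]]))
  structure(list(continuous = cont, ranges = rng,
                 categorical = cat_classes, classes = classes),
            class = "FeatureSet")
}

#' Compute the feature matrix for a set of environmental values
#'
#' Values are clamped to the training range before scaling, so every feature
#' lies in [0,1] even on projection data.
#'
#' @param fs a `FeatureSet`.
#' @param values data.frame of environmental values.
#' @return numeric matrix, one column per feature.
#' @export
featurize <- function(fs, values) {
  cols <- list()
  for (nm in fs$continuous) {
    r <- fs$ranges[[nm]]
    x <- pmin(pmax(values[[nm]], r[1]), r[2])
    z <- (x - r[1]) / (r[2] - r[1])
    if ("linear" %in% fs$classes) cols[[paste0(nm, ":lin")]] <- z
    if ("quadratic" %in% fs$classes) cols[[paste0(nm, ":sq")]] <- z^2
  }
  if ("categorical" %in% fs$classes) {
    for (nm in names(fs$categorical)) {
      for (cl in fs$categorical[[nm]]) {
        cols[[paste0(nm, ":", cl)]] <-
          as.numeric(!is.na(values[[nm]]) & values[[nm]] == cl)
      }
    }
  }
  do.call(cbind, cols)
}

# penalized objective and gradient on split weights theta = c(l_plus, l_minus)
maxent_objective <- function(theta, Fp, Fb, beta_j) {
  m <- ncol(Fp)
  lambda <- theta[1:m] - theta[(m + 1):(2 * m)]
  sp <- Fp %*% lambda
  sb <- Fb %*% lambda
  mx <- max(sb)
  lse <- mx + log(mean(exp(sb - mx)))
  ll <- mean(sp) - lse - sum(beta_j * (theta[1:m] + theta[(m + 1):(2 * m)]))
  -ll
}

maxent_gradient <- function(theta, Fp, Fb, beta_j) {
  m <- ncol(Fp)
  lambda <- theta[1:m] - theta[(m + 1):(2 * m)]
  sb <- as.vector(Fb %*% lambda)
  w <- exp(sb - max(sb)); w <- w / sum(w)
  g <- colMeans(Fp) - as.vector(t(Fb) %*% w)    # d ll / d lambda
  -c(g - beta_j, -g - beta_j)
}

#' Fit the maximum-entropy model
#'
#' @param presence data.frame of environmental values at presence points
#'   (>= 2 rows).
#' @param background data.frame of values at background points (>= 2 rows).
#' @param beta global regularization multiplier; per-feature
#'   `beta_j = beta * sd_j(presence features) / sqrt(n_presence)` (a floor
#'   of `beta / n_presence` keeps constant features penalized).
#' @param categorical names of categorical columns.
#' @param classes enabled feature classes.
#' @param maxit optimizer iteration cap.
#' @return object of class `MaxentModel` with weights, regularization,
#'   feature scalings, training log-normalizer `log_z` (over the background
#'   sample), entropy `h` of the fitted raw distribution, and metadata.
#' @export
maxent_fit <- function(presence, background, beta = 1.0,
                       categorical = "landscape",
                       classes = c("linear", "quadratic", "categorical"),
                       maxit = 1000) {
  if (nrow(presence) < 2 || nrow(background) < 2)
    stop("need at least 2 presence and 2 background rows")
  fs <- feature_set(background, categorical, classes)
  Fp <- featurize(fs, presence)
  Fb <- featurize(fs, background)
  if (!all(is.finite(Fp)) || !all(is.finite(Fb)))
    stop("non-finite feature values")
  m <- ncol(Fp)
  sdp <- apply(Fp, 2, stats::sd)
  beta_j <- pmax(beta * sdp / sqrt(nrow(Fp)), beta / nrow(Fp))
  fit <- stats::optim(rep(0, 2 * m), maxent_objective, maxent_gradient,
                      Fp = Fp, Fb = Fb, beta_j = beta_j,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, factr = 1e4))
  if (!is.finite(fit$value)) stop("non-finite objective during fit")
  if (fit$convergence != 0 && fit$convergence != 52) {
    g <- maxent_gradient(fit$par, Fp, Fb, beta_j)
    stop("optimizer did not converge (code ", fit$convergence,
         "); last gradient norm ", format(sqrt(sum(g^2))))
  }
  lambda <- fit$par[1:m] - fit$par[(m + 1):(2 * m)]
  names(lambda) <- colnames(Fp)
  sb <- as.vector(Fb %*% lambda)
  log_z <- max(sb) + log(sum(exp(sb - max(sb))))
  raw_bg <- exp(sb - log_z)
  h <- -sum(raw_bg * log(pmax(raw_bg, 1e-300)))
  gain <- mean(Fp %*% lambda) - (log_z - log(nrow(Fb)))
  structure(list(weights = lambda, beta = beta, beta_j = beta_j,
                 features = fs, log_z = log_z, n_background = nrow(Fb),
                 entropy = h, gain = gain,
                 metadata = list(n_presence = nrow(Fp),
                                 classes = classes)),
            class = "MaxentModel")
}

#' @export
print.MaxentModel <- function(x, ...) {
  cat(sprintf(
    "<MaxentModel> %d features, %d presences vs %d background\n",
    length(x$weights), x$metadata$n_presence, x$n_background))
  cat(sprintf("  gain %.4f, entropy %.4f, %d non-zero weights\n",
              x$gain, x$entropy, sum(x$weights != 0)))
  invisible(x)
}

# linear predictor lambda.f(x) per valid cell of a stack
stack_scores <- function(model, stack) {
  need <- c(model$features$continuous, names(model$features$categorical))
  missing <- setdiff(need, names(stack$layers))
  if (length(missing))
    stop("stack is missing model variable(s): ",
         paste(missing, collapse = ", "))
  ok <- valid_mask(stack)
  idx <- which(ok)
  vals <- data.frame(row.names = seq_along(idx))
  for (nm in need) vals[[nm]] <- stack$layers[[nm]]$values[idx]
  Fm <- featurize(model$features, vals)
  list(scores = as.vector(Fm %*% model$weights), ok = ok, idx = idx)
}

#' Raw (Gibbs) prediction over a stack
#'
#' exp(lambda . f(x)) normalised to sum to one over the valid evaluation
#' cells; features are clamped to the training range.
#'
#' @param model a `MaxentModel`.
#' @param stack a `LayerStack` with all model variables.
#' @return `GridLayer` `"raw"`; values sum to 1 over valid cells.
#' @export
predict_raw <- function(model, stack) {
  s <- stack_scores(model, stack)
  e <- exp(s$scores - max(s$scores))
  raw <- e / sum(e)
  ref <- first_layer(stack)
  vals <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  vals[s$idx] <- raw
  grid_layer("raw", vals, ref$origin_lon, ref$origin_lat, ref$cell_size,
             nodata_mask = !s$ok, units = "probability")
}

#' Logistic suitability prediction over a stack
#'
#' Uses the training-background normaliser: with q(x) = exp(lambda.f(x))/Z
#' (Z from the fitted background) and H the training entropy, the output is
#' e^H q / (1 + e^H q). A featureless (all-zero-weight) model therefore
#' scores exactly 0.5 everywhere, and the output does not depend on the
#' evaluation extent.
#'
#' @inheritParams predict_raw
#' @return `GridLayer` `"suitability"` with values in (0, 1) (a
#'   `SuitabilityMap`).
#' @export
predict_logistic <- function(model, stack) {
  s <- stack_scores(model, stack)
  lq <- s$scores - model$log_z + model$entropy
  p <- 1 / (1 + exp(-lq))
  ref <- first_layer(stack)
  vals <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  vals[s$idx] <- p
  grid_layer("suitability", vals, ref$origin_lon, ref$origin_lat,
             ref$cell_size, nodata_mask = !s$ok, units = "probability")
}

#' Project the fitted model onto a scenario stack
#'
#' Same weights, scalings and entropy as training; features outside the
#' training range are clamped, not extrapolated.
#'
#' @param model a `MaxentModel`.
#' @param scenario_stack a `LayerStack` with matching geometry.
#' @return `SuitabilityMap` (`GridLayer` of logistic probabilities).
#' @export
maxent_project <- function(model, scenario_stack) {
  predict_logistic(model, scenario_stack)
}

#' Score arbitrary points under the fitted model
#' @param model a `MaxentModel`.
#' @param values data.frame of environmental values.
#' @return logistic scores in (0, 1).
#' @export
predict_points <- function(model, values) {
  Fm <- featurize(model$features, values)
  lq <- as.vector(Fm %*% model$weights) - model$log_z + model$entropy
  1 / (1 + exp(-lq))
}

#' Jackknife variable contributions
#'
#' Refits the model with each variable alone and with each variable left
#' out, reporting training gain (penalty-free log-likelihood improvement
#' over the uniform background distribution) and the training AUC without
#' each variable.
#'
#' @param presence,background environmental value data.frames.
#' @param variables variables to assess (default: all shared columns except
#'   `id`).
#' @param beta regularization multiplier passed to [maxent_fit()].
#' @param categorical categorical column names.
#' @return data.frame with one row per variable: `gain_with_only`,
#'   `gain_without`, `auc_without`; attribute `full_gain`.
#' @export
maxent_jackknife <- function(presence, background, variables = NULL,
                             beta = 1.0, categorical = "landscape") {
  all_vars <- setdiff(intersect(names(presence), names(background)), "id")
  if (is.null(variables)) variables <- all_vars
  if (length(variables) < 2) stop("jackknife needs at least 2 variables")
  fit_on <- function(vars) {
    maxent_fit(presence[vars], background[vars], beta = beta,
               categorical = intersect(categorical, vars))
  }
  full <- fit_on(all_vars)
  rows <- lapply(variables, function(v) {
    with_only <- fit_on(v)
    rest <- setdiff(all_vars, v)
    without <- fit_on(rest)
    data.frame(variable = v,
               gain_with_only = with_only$gain,
               gain_without = without$gain,
               auc_without = auc(predict_points(without, presence[rest]),
                                 predict_points(without, background[rest])))
  })
  out <- do.call(rbind, rows)
  attr(out, "full_gain") <- full$gain
  out
}

#' Serialize a fitted model to JSON
#' @param model a `MaxentModel`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model$weights), beta = model$beta,
         beta_j = model$beta_j,
         features = list(continuous = model$features$continuous,
                         ranges = model$features$ranges,
                         categorical = model$features$categorical,
                         classes = model$features$classes),
         log_z = model$log_z, n_background = model$n_background,
         entropy = model$entropy, gain = model$gain,
         metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model
#' @param path JSON path written by [write_model()].
#' @return a `MaxentModel`.
#' @export
read_model <- function(path) {
  j <- jsonlite::fromJSON(path)
  fs <- structure(list(continuous = j$features$continuous,
                       ranges = j$features$ranges,
                       categorical = j$features$categorical,
                       classes = j$features$classes),
                  class = "FeatureSet")
  structure(list(weights = unlist(j$weights), beta = j$beta,
                 beta_j = j$beta_j, features = fs, log_z = j$log_z,
                 n_background = j$n_background, entropy = j$entropy,
                 gain = j$gain, metadata = j$metadata),
            class = "MaxentModel")
}
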