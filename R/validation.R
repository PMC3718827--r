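# Model validation: repeated random hold-out splits, rank-based AUC against
# background points, and the conventional AUC rating scale.

#' Split occurrences into training and test sets
#'
#' Disjoint random partition with `|train| = round(fraction * n)`,
#' deterministic under `seed`.
#'
#' @param occ an `OccurrenceSet` (>= 4 records).
#' @param fraction training fraction in (0, 1); 0.75 and 0.90 are the
#'   conventional choices.
#' @param seed integer seed.
#' @return list with `train` and `test` `OccurrenceSet`s.
#' @export
split_occurrences <- function(occ, fraction = 0.75, seed = 1) {
  n <- nrow(occ)
  if (n < 4) stop("need at least 4 records to split")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("fraction ", fraction, " produces an empty train or test side")
  with_seed(seed, {
    ix <- sample.int(n, n_train)
    list(train = occurrence_set(occ$lon[ix], occ$lat[ix], occ$id[ix]),
         test = occurrence_set(occ$lon[-ix], occ$lat[-ix], occ$id[-ix]))
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based probability that a random presence outscores a random
#' background point, ties counted one half.
#'
#' @param presence_scores,background_scores non-empty numeric score
#'   vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("both score lists must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Rate an AUC value on the conventional scale
#'
#' Above 0.9 excellent; 0.7 to 0.9 (inclusive at both ends) good; 0.5 to
#' below 0.7 poor; below 0.5 no better than random.
#'
#' @param auc_value AUC in [0, 1].
#' @return one of `"excellent"`, `"good"`, `"poor"`, `"random"`.
#' @export
rate_auc <- function(auc_value) {
  if (!is.finite(auc_value) || auc_value < 0 || auc_value > 1)
    stop("AUC must lie in [0, 1]")
  if (auc_value > 0.9) "excellent"
  else if (auc_value >= 0.7) "good"
  else if (auc_value >= 0.5) "poor"
  else "random"
}

#' Replicate hold-out cross-validation of the suitability model
#'
#' For each replicate and each background mode (`"global"`, `"bias"`): fit
#' on the training presences against that mode's background sample, then
#' score training and held-out test presences against the same background.
#' Test AUC reuses the training background of its mode.
#'
#' @param occ filtered `OccurrenceSet`.
#' @param stack a `LayerStack`.
#' @param fraction training fraction (default 0.75).
#' @param replicates number of random splits (default 10).
#' @param seed integer seed; replicate seeds are derived from it.
#' @param modes background sampling modes to evaluate.
#' @param n_background background points per mode.
#' @param buffer_km bias-mode buffer (default 20 km).
#' @param beta regularization multiplier.
#' @return object of class `ValidationReport`: `replicates` data.frame
#'   (mode, replicate, train_auc, test_auc) and `summary` (mean, sd,
#'   rating per mode).
#' @export
cross_validate <- function(occ, stack, fraction = 0.75, replicates = 10,
                           seed = 1, modes = c("global", "bias"),
                           n_background = 10000, buffer_km = 20,
                           beta = 1.0) {
  rows <- list()
  for (mode in modes) {
    bg <- sample_background(stack, occ, n = n_background, mode = mode,
                            buffer_km = buffer_km,
                            seed = derive_seed(seed, paste0("bg_", mode)))
    bg_vals <- extract_values(stack, bg)
    for (r in seq_len(replicates)) {
      sp <- split_occurrences(occ, fraction,
                              seed = derive_seed(seed, paste0("split", r)))
      model <- maxent_fit(extract_values(stack, sp$train), bg_vals,
                          beta = beta)
      bg_scores <- predict_points(model, bg_vals)
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode, replicate = r,
        train_auc = auc(predict_points(model,
                                       extract_values(stack, sp$train)),
                        bg_scores),
        test_auc = auc(predict_points(model,
                                      extract_values(stack, sp$test)),
                       bg_scores))
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$mode), function(d) {
    data.frame(mode = d$mode[1],
               mean_train_auc = mean(d$train_auc),
               sd_train_auc = stats::sd(d$train_auc),
               mean_test_auc = mean(d$test_auc),
               sd_test_auc = stats::sd(d$test_auc),
               rating = rate_auc(mean(d$test_auc)))
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Cross-validation report (", max(x$replicates$replicate),
      " replicates)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
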