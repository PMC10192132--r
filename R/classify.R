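# Expert/novice classification on HFD features.
#
# Samples are subject-presentation pairs; features are per-channel HFD
# values (times windows, in windowed mode). Three split schemes:
#   subject_presentation  - rows shuffled and partitioned ignoring subject
#                           identity (samples of one subject may sit on
#                           both sides of a fold);
#   subject_specific      - subjects partitioned, all of a subject's rows
#                           follow the subject (no identity leakage);
#   presentation_specific - one presentation's rows only, split at the
#                           subject level.
# Hyperparameters are tuned by cross-validated accuracy under the first
# scheme and then frozen for the other two.

#' Assemble the classification sample table
#'
#' One row per (subject, presentation) task pair; feature columns are the
#' retained channels (times windows when `windowed`). `channel_set =
#' "standard32"` retains only the montage's 10/20 subset.
#'
#' @param features an `hfd_table` (task rows are used).
#' @param montage the `montage_spec`; required for `"standard32"`.
#' @param channel_set `"full"` (default) or `"standard32"`.
#' @param presentations optional subset of presentation ids.
#' @param windowed use windowed features (requires a windowed
#'   `hfd_table`); every in-scope presentation must yield the same number
#'   of windows, otherwise an error names the offender. Whole-signal
#'   tables (window 0) use `windowed = FALSE`.
#' @return Data frame of class `sample_table`: `subject_id`,
#'   `presentation_id`, `label`, then one numeric column per feature
#'   (`<channel>` or `<channel>.w<i>`).
#' @export
assemble_samples <- function(features, montage = NULL,
                             channel_set = c("full", "standard32"),
                             presentations = NULL, windowed = FALSE) {
  channel_set <- match.arg(channel_set)
  f <- features[features$condition == "task", , drop = FALSE]
  if (!is.null(presentations))
    f <- f[f$presentation_id %in% presentations, , drop = FALSE]
  if (!nrow(f)) stop_hfd("no task feature rows to assemble")
  if (windowed) {
    if (all(f$window == 0))
      stop_hfd("windowed = TRUE but the feature table is whole-signal")
  } else if (any(f$window != 0)) {
    stop_hfd("feature table is windowed; set windowed = TRUE")
  }
  if (channel_set == "standard32") {
    if (is.null(montage)) stop_hfd("montage required for channel_set = 'standard32'")
    if (!length(montage$standard32_names))
      stop_hfd("configuration error: montage has no standard32 subset")
    f <- f[f$channel %in% montage$standard32_names, , drop = FALSE]
  }
  chans <- unique(f$channel)
  key <- paste(f$subject_id, f$presentation_id, sep = "\r")
  ukey <- unique(key)
  # consistent window counts per sample
  wtab <- tapply(f$window, key, function(w) length(unique(w)))
  if (length(unique(wtab)) > 1) {
    bad <- names(wtab)[wtab != max(wtab)][1]
    stop_hfd("inconsistent window counts across samples; offending ",
             "presentation: ", sub(".*\r", "", bad))
  }
  feat_name <- if (windowed) paste0(f$channel, ".w", f$window) else f$channel
  cols <- unique(feat_name)
  X <- matrix(NA_real_, length(ukey), length(cols),
              dimnames = list(ukey, cols))
  X[cbind(match(key, ukey), match(feat_name, cols))] <- f$hfd
  if (anyNA(X)) stop_hfd("incomplete feature table: some sample/feature ",
                         "cells are missing")
  first <- !duplicated(key)
  out <- data.frame(subject_id = f$subject_id[first],
                    presentation_id = f$presentation_id[first],
                    label = f$group[first], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X[match(paste(out$subject_id,
                                                out$presentation_id,
                                                sep = "\r"), ukey), ,
                                    drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("sample_table", "data.frame")
  out
}

feature_matrix <- function(samples) {
  as.matrix(samples[, setdiff(colnames(samples),
                              c("subject_id", "presentation_id", "label")),
                    drop = FALSE])
}

partition_folds <- function(units, n_folds, seed) {
  if (n_folds > length(units))
    stop_hfd("n_folds = ", n_folds, " exceeds the ", length(units),
             " available units")
  set.seed(as.integer(seed))
  shuffled <- sample(units)
  split(shuffled, rep(seq_len(n_folds), length.out = length(shuffled)))
}

#' Build a cross-validation split plan
#'
#' @param samples a `sample_table`.
#' @param scheme `"subject_presentation"`, `"subject_specific"` or
#'   `"presentation_specific"`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @param presentation_id required for (and only for)
#'   `"presentation_specific"`: the single presentation analysed.
#' @return Object of class `split_plan`: `scheme`, `seed`,
#'   `presentation_id`, and `folds`, a list of `(train, validation)` row
#'   index vectors into `samples`. Folds partition the in-scope rows;
#'   under the subject-level schemes no subject appears on both sides of
#'   any fold.
#' @export
make_split <- function(samples,
                       scheme = c("subject_presentation", "subject_specific",
                                  "presentation_specific"),
                       n_folds = 10, seed = 0, presentation_id = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "presentation_specific" && is.null(presentation_id))
    stop_hfd("presentation_id is required for the presentation_specific scheme")
  if (scheme != "presentation_specific" && !is.null(presentation_id))
    stop_hfd("presentation_id is only meaningful for presentation_specific")
  rows <- seq_len(nrow(samples))
  if (scheme == "presentation_specific") {
    rows <- which(samples$presentation_id == presentation_id)
    if (!length(rows)) stop_hfd("no samples for presentation ", presentation_id)
  }
  folds <- if (scheme == "subject_presentation") {
    lapply(partition_folds(rows, n_folds, seed),
           function(v) list(train = setdiff(rows, v), validation = sort(v)))
  } else {
    subjects <- unique(samples$subject_id[rows])
    lapply(partition_folds(subjects, n_folds, seed), function(sv) {
      val <- rows[samples$subject_id[rows] %in% sv]
      list(train = setdiff(rows, val), validation = sort(val))
    })
  }
  structure(list(scheme = scheme, seed = as.integer(seed),
                 presentation_id = presentation_id,
                 folds = unname(folds)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s%s, %d folds (validation sizes: %s), seed %d\n",
              x$scheme,
              if (is.null(x$presentation_id)) ""
              else paste0("[", x$presentation_id, "]"),
              length(x$folds),
              paste(vapply(x$folds, function(f) length(f$validation),
                           integer(1)), collapse = ","), x$seed))
  invisible(x)
}

#' Default classifier grid
#'
#' The fixed algorithm/hyperparameter grid: k-nearest neighbours
#' (neighbours 3, 5, 7, 9, 11), linear-kernel SVM (C 0.025, 0.5, 0.75),
#' decision tree (maximum depth 3, 5, 7) and AdaBoost over depth-1 stumps
#' (25, 50, 100 estimators).
#'
#' @return Named list: per algorithm, the vector of candidate values of
#'   its tuned hyperparameter.
#' @export
default_grid <- function() {
  list(nearest_neighbors = list(param = "n_neighbors",
                                values = c(3, 5, 7, 9, 11)),
       linear_svm = list(param = "cost", values = c(0.025, 0.5, 0.75)),
       decision_tree = list(param = "max_depth", values = c(3, 5, 7)),
       adaboost = list(param = "n_estimators", values = c(25, 50, 100)))
}

# Discrete (two-class SAMME) AdaBoost over rpart stumps. No boosting
# package ships with the environment, so the classic reweighting loop is
# implemented directly: at each round a depth-1 tree is fitted under the
# current weights, its weighted error e gives the vote
# alpha = log((1-e)/e), and misclassified samples are up-weighted.
ada_fit <- function(x, y, n_estimators) {
  df <- as.data.frame(x); df$.y <- y
  w <- rep(1 / nrow(df), nrow(df))
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       cp = -1, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break                      # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break                    # perfect stump: done
  }
  if (!length(stumps)) {                       # fall back to the majority
    maj <- names(which.max(table(y)))
    return(structure(list(majority = maj, levels = levels(y)),
                     class = "ada_model"))
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "ada_model")
}

#' @export
predict.ada_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  if (!is.null(object$majority))
    return(factor(rep(object$majority, nrow(nd)), levels = object$levels))
  score <- rep(0, nrow(nd))
  for (t in seq_along(object$stumps)) {
    p <- predict(object$stumps[[t]], nd, type = "class")
    score <- score + object$alphas[t] * ifelse(p == object$levels[1], 1, -1)
  }
  factor(ifelse(score >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

# Train one classifier and predict validation labels.
fit_predict <- function(algorithm, value, x_train, y_train, x_val) {
  switch(algorithm,
    nearest_neighbors = {
      k <- min(value, nrow(x_train))
      class::knn(x_train, x_val, y_train, k = k)
    },
    linear_svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = value,
                        scale = FALSE)
      predict(fit, x_val)
    },
    decision_tree = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = value, minsplit = 2, minbucket = 1,
                            cp = 0, xval = 0))
      predict(fit, as.data.frame(x_val), type = "class")
    },
    adaboost = {
      fit <- ada_fit(x_train, y_train, value)
      predict(fit, x_val)
    },
    stop_hfd("unknown algorithm: ", algorithm))
}

# Mean validation accuracy of one (algorithm, value) over a plan's folds.
# Features are standardized with training-fold statistics only.
evaluate_plan <- function(samples, plan, algorithm, value,
                          standardize = TRUE) {
  X <- feature_matrix(samples)
  y <- factor(samples$label)
  accs <- numeric(0)
  for (fold in plan$folds) {
    ytr <- y[fold$train]
    if (length(unique(ytr)) < 2) {
      warning("skipping single-class training fold", call. = FALSE)
      next
    }
    xtr <- X[fold$train, , drop = FALSE]
    xva <- X[fold$validation, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, sd); sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xva <- sweep(sweep(xva, 2, mu), 2, sdv, "/")
    }
    pred <- fit_predict(algorithm, value, xtr, ytr, xva)
    accs <- c(accs, mean(pred == y[fold$validation]))
  }
  if (!length(accs)) stop_hfd("all folds degenerate; cannot evaluate")
  mean(accs)
}

#' Tune hyperparameters under the subject-presentation scheme
#'
#' For every algorithm of the grid, every candidate hyperparameter value
#' is scored by mean 10-fold validation accuracy under the
#' subject-presentation split, averaged over `seeds`; the best value per
#' algorithm is retained (ties break toward the first grid entry).
#'
#' @param samples a `sample_table`.
#' @param grid a [default_grid()]-shaped list.
#' @param seeds CV shuffle seeds (default 0, 1, 2).
#' @param n_folds folds (default 10).
#' @param standardize standardize features with train-fold statistics.
#' @return List with `best` (named list algorithm -> value) and `table`
#'   (the full tuning accuracy table).
#' @export
tune_case1 <- function(samples, grid = default_grid(), seeds = c(0, 1, 2),
                       n_folds = 10, standardize = TRUE) {
  plans <- lapply(seeds, function(s)
    make_split(samples, "subject_presentation", n_folds, s))
  rows <- list()
  best <- list()
  for (alg in names(grid)) {
    acc <- vapply(grid[[alg]]$values, function(v)
      mean(vapply(plans, function(p)
        evaluate_plan(samples, p, alg, v, standardize), numeric(1))),
      numeric(1))
    rows[[alg]] <- data.frame(algorithm = alg, value = grid[[alg]]$values,
                              accuracy = acc, stringsAsFactors = FALSE)
    best[[alg]] <- grid[[alg]]$values[which.max(acc)]
  }
  list(best = best, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Run the classification protocol over split schemes
#'
#' Hyperparameters are tuned once under the subject-presentation scheme
#' (unless `tuned` is supplied) and then frozen; each requested scheme is
#' evaluated per algorithm and per CV seed. For the
#' presentation-specific scheme every presentation in `presentations`
#' (default: all) is a separate task.
#'
#' @param samples a `sample_table`.
#' @param schemes character vector of schemes to evaluate.
#' @param grid a [default_grid()]-shaped list.
#' @param seeds CV shuffle seeds (default 0, 1, 2); reported accuracies
#'   are retained per seed.
#' @param n_folds folds (default 10).
#' @param presentations presentations for the presentation-specific
#'   scheme (default all in `samples`).
#' @param standardize standardize features with train-fold statistics.
#' @param tuned optional pre-tuned named list algorithm -> value.
#' @return Data frame of class `accuracy_report`: `scheme`, `algorithm`,
#'   `presentation` (`NA` except case 3), `seed`, `accuracy`; tuned
#'   values attached as attribute `tuned`.
#' @export
run_grid <- function(samples,
                     schemes = c("subject_presentation", "subject_specific"),
                     grid = default_grid(), seeds = c(0, 1, 2),
                     n_folds = 10, presentations = NULL,
                     standardize = TRUE, tuned = NULL) {
  schemes <- match.arg(schemes, c("subject_presentation", "subject_specific",
                                  "presentation_specific"),
                       several.ok = TRUE)
  if (is.null(tuned))
    tuned <- tune_case1(samples, grid, seeds, n_folds, standardize)$best
  out <- list()
  for (scheme in schemes) {
    pres_set <- if (scheme == "presentation_specific") {
      presentations %||% unique(samples$presentation_id)
    } else NA_character_
    for (pres in pres_set) {
      for (alg in names(tuned)) {
        for (s in seeds) {
          plan <- make_split(samples, scheme, n_folds, s,
                             presentation_id = if (is.na(pres)) NULL else pres)
          acc <- evaluate_plan(samples, plan, alg, tuned[[alg]], standardize)
          out[[length(out) + 1]] <- data.frame(
            scheme = scheme, algorithm = alg, presentation = pres,
            seed = s, accuracy = acc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rep <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(rep, "tuned") <- tuned
  class(rep) <- c("accuracy_report", "data.frame")
  rep
}

#' Compare the full montage against the standard 10/20 subset
#'
#' Runs the identical tuning + evaluation pipeline on the full channel
#' set and on the 32-channel standard subset.
#'
#' @param features an `hfd_table`.
#' @param montage the `montage_spec`.
#' @inheritParams run_grid
#' @return An `accuracy_report` with an extra `channel_set` column
#'   (`"full"` / `"standard32"`).
#' @export
compare_channel_sets <- function(features, montage,
                                 schemes = "subject_presentation",
                                 grid = default_grid(), seeds = c(0, 1, 2),
                                 n_folds = 10, standardize = TRUE) {
  reports <- lapply(c("full", "standard32"), function(cs) {
    s <- assemble_samples(features, montage, channel_set = cs)
    r <- run_grid(s, schemes, grid, seeds, n_folds,
                  standardize = standardize)
    r$channel_set <- cs
    r
  })
  rep <- do.call(rbind, reports)
  class(rep) <- c("accuracy_report", "data.frame")
  rep
}

#' Best algorithm per scheme (and presentation)
#'
#' Averages accuracy over seeds per (scheme, presentation, algorithm) and
#' keeps the maximum per (scheme, presentation); ties are all reported.
#'
#' @param report an `accuracy_report`.
#' @return Data frame `scheme`, `presentation`, `algorithm`,
#'   `mean_accuracy` of the best algorithm(s).
#' @export
best_per_scheme <- function(report) {
  if (!nrow(report)) stop_hfd("empty report")
  agg <- aggregate(accuracy ~ scheme + presentation + algorithm,
                   data = transform(report,
                                    presentation = ifelse(
                                      is.na(presentation), "",
                                      presentation)),
                   FUN = mean, na.action = NULL)
  keys <- interaction(agg$scheme, agg$presentation, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(agg)), keys), function(idx) {
    idx[agg$accuracy[idx] >= max(agg$accuracy[idx]) - 1e-12]
  }))
  out <- agg[sort(keep), c("scheme", "presentation", "algorithm", "accuracy")]
  names(out)[4] <- "mean_accuracy"
  out$presentation[out$presentation == ""] <- NA_character_
  rownames(out) <- NULL
  out
}
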