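check_feature_table <- function(features) {
  stopifnot(is.data.frame(features))
  needed <- c("group", feature_names())
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("Feature table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(features[feature_names()])) {
    stop("Feature table contains missing values.", call. = FALSE)
  }
  features$group <- droplevels(as.factor(features$group))
  features
}

#' Fit the random-forest diagnostic model
#'
#' An ensemble of classification trees, each grown on a bootstrap resample
#' of the training subjects with `mtry` randomly selected features per
#' split (default 5 of the 18). The model's score for a subject is the
#' fraction of trees voting for the case class.
#'
#' @param train Feature tibble with `group` plus the 18 columns of
#'   [feature_names()].
#' @param mtry Features tried at each split (<= 18). `mtry = 18`
#'   degenerates to bagged trees.
#' @param n_trees Number of trees.
#' @param seed Integer seed making the ensemble reproducible.
#' @return Object of class `eeg_forest` wrapping the fitted ensemble.
#' @export
fit_forest <- function(train, mtry = 5, n_trees = 500, seed = 1L) {
  train <- check_feature_table(train)
  if (nlevels(train$group) < 2L) {
    stop("Training data must contain both classes.", call. = FALSE)
  }
  if (mtry > length(feature_names())) {
    stop("`mtry` cannot exceed the number of features (18).", call. = FALSE)
  }
  x <- as.data.frame(train[feature_names()])
  y <- train$group
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, mtry = mtry,
                                   ntree = n_trees)
  structure(
    list(rf = rf, mtry = mtry, n_trees = n_trees, seed = seed,
         positive = if ("case" %in% levels(y)) "case" else levels(y)[2]),
    class = "eeg_forest"
  )
}

#' @export
print.eeg_forest <- function(x, ...) {
  cat(sprintf(
    "<eeg_forest> %d trees, mtry = %d, positive class '%s'\n",
    x$n_trees, x$mtry, x$positive
  ))
  invisible(x)
}

#' Case probabilities from a fitted forest
#'
#' @param object An `eeg_forest`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @return Numeric vector of case-vote fractions in `[0, 1]`.
#' @export
predict.eeg_forest <- function(object, newdata, ...) {
  x <- as.data.frame(newdata[feature_names()])
  probs <- stats::predict(object$rf, newdata = x, type = "prob")
  as.numeric(probs[, object$positive])
}
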