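.feature_names <- c("mean", "sd", "min", "max", "slope", "dmav")

#' Train a per-sensor Load/Rest classifier
#'
#' Ridge-penalized logistic regression on the window features: a desk-scale,
#' fully deterministic stand-in for the deep sequence models used on the real
#' data, honouring the same probabilistic contract (a calibrated
#' `P(Load), P(Rest)` pair per window).
#'
#' @param x feature matrix or window-feature data frame (uses the six
#'   standard feature columns).
#' @param y labels in `{Rest, Load}`; taken from `x$label` when omitted.
#' @param sensor sensor name stored with the model (e.g. `"RR"`).
#' @param lambda ridge penalty (fixed, not tuned).
#' @return A `sensor_model`: intercept and named coefficients of the logistic
#'   score for Load.
#' @export
train_sensor_classifier <- function(x, y = NULL, sensor = "", lambda = 0.01) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$label
    x <- as.matrix(x[, intersect(.feature_names, names(x)), drop = FALSE])
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("labels required", call. = FALSE)
  y <- factor(as.character(y), levels = c("Rest", "Load"))
  if (any(is.na(y))) stop("labels must be 'Rest' or 'Load'", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class; need both Rest and Load",
         call. = FALSE)
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  cf <- as.matrix(stats::coef(fit))[, 1]
  structure(list(sensor = sensor, intercept = unname(cf[1]),
                 coefficients = cf[-1], lambda = lambda,
                 feature_names = colnames(x)),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("sensor_model (%s): ridge logistic, lambda = %g\n",
              if (nzchar(x$sensor)) x$sensor else "unnamed", x$lambda))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Predict Load/Rest probabilities for feature windows
#'
#' `P(Load) = plogis(intercept + features %*% coefficients)`;
#' `P(Rest) = 1 - P(Load)`.
#'
#' @param model a [train_sensor_classifier()] result.
#' @param features numeric vector (one window) or matrix/data frame (one row
#'   per window) with the model's feature columns.
#' @return A `sensor_prediction` data frame: `sensor, p_load, p_rest`, one
#'   row per window.
#' @export
predict_sensor <- function(model, features) {
  stopifnot(inherits(model, "sensor_model"))
  if (is.data.frame(features)) {
    features <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$coefficients)) {
    stop("feature dimensionality mismatch: model expects ",
         length(model$coefficients), " features", call. = FALSE)
  }
  eta <- model$intercept + as.numeric(features %*% model$coefficients)
  p <- stats::plogis(eta)
  structure(data.frame(sensor = model$sensor, p_load = p, p_rest = 1 - p,
                       stringsAsFactors = FALSE),
            class = c("sensor_prediction", "data.frame"))
}

#' @export
predict.sensor_model <- function(object, newdata, ...) {
  predict_sensor(object, newdata)
}

#' Fuse per-sensor predictions by unweighted averaging
#'
#' The fused Load probability is the arithmetic mean of the contributing
#' sensors' Load probabilities (single-sensor fusion is the identity);
#' `p_rest = 1 - p_load`.
#'
#' @param predictions a `sensor_prediction` data frame (one row per sensor),
#'   a list of them, or a plain numeric vector of Load probabilities.
#' @return A `fused_prediction`: `p_load`, `p_rest`, `sensors`.
#' @examples
#' fuse_average(c(0.8607, 0.1393, 0.5, 0.4))
#' @export
fuse_average <- function(predictions) {
  if (is.list(predictions) && !is.data.frame(predictions)) {
    predictions <- do.call(rbind, predictions)
  }
  if (is.data.frame(predictions)) {
    sensors <- as.character(predictions$sensor)
    p <- predictions$p_load
  } else {
    p <- as.numeric(predictions)
    sensors <- names(predictions) %||% rep("", length(p))
  }
  if (!length(p)) stop("no predictions to fuse", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("Load probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p_load = mean(p), p_rest = 1 - mean(p), sensors = sensors),
            class = "fused_prediction")
}

#' @export
print.fused_prediction <- function(x, ...) {
  cat(sprintf("fused prediction: P(Load) = %.4f, P(Rest) = %.4f (%d sensors)\n",
              x$p_load, x$p_rest, length(x$sensors)))
  invisible(x)
}

#' Serialize sensor models to and from JSON
#'
#' @param model a `sensor_model`.
#' @param path file path.
#' @return `read_sensor_model()` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_sensor_model <- function(model, path) {
  stopifnot(inherits(model, "sensor_model"))
  jsonlite::write_json(list(sensor = model$sensor, intercept = model$intercept,
                            coefficients = as.list(model$coefficients),
                            lambda = model$lambda,
                            feature_names = model$feature_names),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_model
#' @export
read_sensor_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sensor = j$sensor, intercept = j$intercept,
                 coefficients = unlist(j$coefficients), lambda = j$lambda,
                 feature_names = j$feature_names),
            class = "sensor_model")
}
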