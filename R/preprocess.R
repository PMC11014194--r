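#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#'
#' @param x non-constant numeric vector.
#' @return numeric vector spanning `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  r <- range(x)
  if (!is.finite(r[1]) || !is.finite(r[2])) stop("non-finite values", call. = FALSE)
  if (r[1] == r[2]) stop("constant series cannot be min-max normalized", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Standardize to mean 0, sd 1
#'
#' Sample standard deviation with divisor `n - 1`.
#'
#' @param x numeric vector with positive sample sd.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least two values to standardize", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance series cannot be standardized", call. = FALSE)
  (x - mean(x)) / s
}

#' Leakage-free channel scaler
#'
#' Fits the min-max range and the post-normalization mean/sd on a training
#' segment only; [apply_scaler()] then transforms any later data with the
#' stored parameters (values outside the training range map outside
#' `[0, 1]`, by design). This realises the normalize-then-standardize
#' pipeline order.
#'
#' @param train numeric training segment (non-constant).
#' @return A `channel_scaler`.
#' @export
channel_scaler <- function(train) {
  y <- minmax_normalize(train)
  structure(list(min = min(train), max = max(train),
                 center = mean(y), scale = stats::sd(y)),
            class = "channel_scaler")
}

#' @rdname channel_scaler
#' @param scaler a fitted `channel_scaler`.
#' @param x new data.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "channel_scaler"))
  y <- (x - scaler$min) / (scaler$max - scaler$min)
  (y - scaler$center) / scaler$scale
}

# short channel aliases accepted by make_windows()
.channel_map <- c(gsr = "gsr_uS", hr = "hr_bpm", rr = "rr_ms", temp = "temp_C",
                  gsr_uS = "gsr_uS", hr_bpm = "hr_bpm", rr_ms = "rr_ms",
                  temp_C = "temp_C")

#' Slide fixed-length windows over one channel of a recording
#'
#' Window count is `floor((T - length) / stride) + 1`. Each window's label is
#' the majority of its per-second labels; exact ties go to `Rest` (the
#' conservative choice, avoiding spurious Load alarms).
#'
#' @param recording recording data frame as from [simulate_recording()] (or
#'   any frame with the channel column and a `label` column).
#' @param channel channel name (`"gsr"`, `"hr"`, `"rr"`, `"temp"` or the full
#'   column name).
#' @param length window length in seconds (>= 1).
#' @param stride hop between window starts in seconds (>= 1).
#' @param values optional numeric vector to window instead of a recording
#'   column (e.g. scaled values); must align with `recording`'s labels.
#' @return A `window_set`: list with `windows` (matrix, one row per window),
#'   `label`, `start_s`, `subject_id`, `channel`.
#' @export
make_windows <- function(recording, channel, length = 30, stride = 15,
                         values = NULL) {
  length <- as.integer(length); stride <- as.integer(stride)
  if (is.na(length) || length < 1 || is.na(stride) || stride < 1) {
    stop("length and stride must be >= 1 second", call. = FALSE)
  }
  col <- .channel_map[[channel]]
  if (is.null(col)) stop("unknown channel: ", channel, call. = FALSE)
  x <- if (is.null(values)) recording[[col]] else values
  labels <- recording$label
  T_total <- base::length(x)
  if (base::length(labels) != T_total) stop("values and labels misaligned", call. = FALSE)
  if (T_total < length) stop("recording shorter than one window", call. = FALSE)
  starts <- seq(1L, T_total - length + 1L, by = stride)
  win <- t(vapply(starts, function(s) x[s:(s + length - 1L)], numeric(length)))
  lab <- vapply(starts, function(s) {
    frac_load <- mean(labels[s:(s + length - 1L)] == "Load")
    if (frac_load > 0.5) "Load" else "Rest"
  }, character(1))
  structure(list(windows = win, label = lab, start_s = starts - 1L,
                 subject_id = recording$subject_id[1] %||% NA_character_,
                 channel = col),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d s, channel %s (%s)\n",
              nrow(x$windows), ncol(x$windows), x$channel,
              paste(names(table(x$label)), table(x$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Summary features of one window
#'
#' Fixed six-feature vector: mean, sample sd, min, max, least-squares slope
#' per sample, and mean absolute first difference.
#'
#' @param window non-empty numeric vector.
#' @return named numeric vector of length 6.
#' @export
extract_features <- function(window) {
  n <- length(window)
  if (!n) stop("empty window", call. = FALSE)
  slope <- if (n < 2) 0 else {
    t0 <- seq_len(n) - 1
    sum((t0 - mean(t0)) * (window - mean(window))) / sum((t0 - mean(t0))^2)
  }
  c(mean = mean(window),
    sd = if (n < 2) 0 else stats::sd(window),
    min = min(window),
    max = max(window),
    slope = slope,
    dmav = if (n < 2) 0 else mean(abs(diff(window))))
}

#' Feature matrix for a window set
#'
#' @param ws a [make_windows()] result.
#' @return data frame: six feature columns plus `label`, `start_s`,
#'   `subject_id`, `channel`.
#' @export
window_features <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  feats <- t(apply(ws$windows, 1, extract_features))
  out <- as.data.frame(feats)
  out$label <- ws$label
  out$start_s <- ws$start_s
  out$subject_id <- ws$subject_id
  out$channel <- ws$channel
  out
}

#' @rdname window_features
#' @param x window-feature data frame.
#' @param path file path.
#' @export
write_windows <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
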