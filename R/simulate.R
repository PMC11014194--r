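#' Default exogenous-variable distributions
#'
#' Exogenous variables of a [path_spec()] not listed here are drawn as
#' standard normal scores. Age is uniform over whole years 20-59; sex is
#' Bernoulli(0.5) encoded 0 = female, 1 = male. Both enter the structural
#' equations on the standardized scale (z-scores under the stated population
#' distribution), so path coefficients stay in standardized units.
#'
#' @param age_min,age_max inclusive age range in whole years.
#' @param p_male probability of the male code (1).
#' @return Named list of distribution configurations.
#' @export
default_exogenous <- function(age_min = 20, age_max = 59, p_male = 0.5) {
  list(
    age = list(dist = "uniform_int", min = age_min, max = age_max),
    sex = list(dist = "bernoulli", p = p_male)
  )
}

# z-score parameters for the supported exogenous distributions
exo_moments <- function(cfg) {
  switch(cfg$dist,
    uniform_int = {
      k <- cfg$max - cfg$min + 1
      list(mean = (cfg$min + cfg$max) / 2, sd = sqrt((k^2 - 1) / 12))
    },
    bernoulli = list(mean = cfg$p, sd = sqrt(cfg$p * (1 - cfg$p))),
    normal = list(mean = cfg$mean %||% 0, sd = cfg$sd %||% 1),
    stop("unknown exogenous distribution: ", cfg$dist, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a subject cohort from a path specification
#'
#' Draws exogenous variables from their configured distributions and then
#' each endogenous variable, in topological order, as the linear combination
#' of its parents' standardized scores plus a Gaussian disturbance with the
#' spec's standard deviation. Deterministic given `seed`.
#'
#' The returned table stores `age` in raw years and `sex` as its 0/1 code;
#' all other scores (HEXACO domains, `psych_trait`, `demog`, `cw`) are on the
#' standardized scale. Higher `psych_trait` means a more Stressed disposition.
#'
#' @param spec a [path_spec()].
#' @param n number of subjects (>= 0).
#' @param seed integer seed.
#' @param exo exogenous distribution config, see [default_exogenous()].
#' @return data frame with one row per subject; first column `subject_id`.
#' @examples
#' subjects <- simulate_subjects(default_path_spec(), n = 10, seed = 1)
#' head(subjects)
#' @export
simulate_subjects <- function(spec, n, seed, exo = default_exogenous()) {
  stopifnot(inherits(spec, "path_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("n must be a non-negative integer", call. = FALSE)
  ord <- topo_sort_arcs(spec$arcs)
  endo <- unique(spec$arcs$to)
  set.seed(as.integer(seed))
  z <- list()   # standardized scores driving the equations
  raw <- list() # values as stored in the table
  for (v in ord) {
    if (v %in% endo) {
      par_rows <- spec$arcs[spec$arcs$to == v, , drop = FALSE]
      mu <- rep(0, n)
      for (i in seq_len(nrow(par_rows))) {
        mu <- mu + par_rows$coef[i] * z[[par_rows$from[i]]]
      }
      sdv <- spec$disturbance_sd[[v]]
      z[[v]] <- mu + if (sdv > 0) stats::rnorm(n, 0, sdv) else rep(0, n)
      raw[[v]] <- z[[v]]
    } else {
      cfg <- exo[[v]] %||% list(dist = "normal", mean = 0, sd = 1)
      m <- exo_moments(cfg)
      x <- switch(cfg$dist,
        uniform_int = sample(seq(cfg$min, cfg$max), n, replace = TRUE),
        bernoulli = stats::rbinom(n, 1, cfg$p),
        normal = stats::rnorm(n, m$mean, m$sd)
      )
      raw[[v]] <- x
      z[[v]] <- if (m$sd > 0) (x - m$mean) / m$sd else x - m$mean
    }
  }
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in ord) out[[v]] <- raw[[v]]
  out
}

#' Rest/Load measurement protocol
#'
#' @param conditions character vector of block conditions, each `"Rest"` or
#'   `"Load"`.
#' @param durations block durations in seconds (positive integers).
#' @return A `cw_protocol` data frame (`condition`, `duration`); sampling is
#'   fixed at 1 Hz.
#' @examples
#' protocol(c("Rest", "Load"), c(60, 60))
#' @export
protocol <- function(conditions, durations) {
  conditions <- as.character(conditions)
  if (!length(conditions) || length(conditions) != length(durations)) {
    stop("conditions and durations must be non-empty and equal length", call. = FALSE)
  }
  if (!all(conditions %in% c("Rest", "Load"))) {
    stop("conditions must be 'Rest' or 'Load'", call. = FALSE)
  }
  durations <- as.integer(durations)
  if (any(is.na(durations)) || any(durations <= 0)) {
    stop("durations must be positive integers (seconds)", call. = FALSE)
  }
  structure(data.frame(condition = conditions, duration = durations,
                       stringsAsFactors = FALSE),
            class = c("cw_protocol", "data.frame"))
}

#' @rdname protocol
#' @details `default_protocol()` alternates four 300 s blocks
#'   (Rest, Load, Rest, Load), giving both conditions for training.
#' @export
default_protocol <- function() {
  protocol(c("Rest", "Load", "Rest", "Load"), rep(300L, 4))
}

#' Load effect on the physiological channels
#'
#' Mean shifts (in units of each channel's baseline standard deviation)
#' applied during Load blocks, with an optional Load-block variance
#' multiplier and an optional linear gain by the subject's `psych_trait`
#' score (off by default). Default directions follow physiological
#' convention under cognitive load: skin conductance and heart rate rise,
#' RR intervals and skin temperature fall.
#'
#' @param gsr,hr,rr,temp per-channel Load mean shift, baseline-sd units.
#' @param sd_multiplier multiplier on the channel sd during Load blocks.
#' @param trait_gain linear modulation: effective shift is
#'   `shift * (1 + trait_gain * psych_trait)`.
#' @return A `load_effect` list.
#' @export
load_effect <- function(gsr = 1, hr = 1, rr = -1, temp = -0.5,
                        sd_multiplier = 1, trait_gain = 0) {
  stopifnot(sd_multiplier > 0)
  structure(list(shift = c(gsr_uS = gsr, hr_bpm = hr, rr_ms = rr, temp_C = temp),
                 sd_multiplier = sd_multiplier, trait_gain = trait_gain),
            class = "load_effect")
}

#' Baseline channel distributions and plausible physical ranges
#'
#' Resting means/sds typical of wrist-worn measurement: GSR ~2 uS, HR ~70
#' bpm, RR ~850 ms, skin temperature ~33 C. Simulated values are clamped to
#' the physical range.
#'
#' @return data frame with columns `channel`, `mean`, `sd`, `lo`, `hi`.
#' @export
channel_baselines <- function() {
  data.frame(
    channel = c("gsr_uS", "hr_bpm", "rr_ms", "temp_C"),
    mean = c(2, 70, 850, 33),
    sd = c(0.4, 5, 50, 0.3),
    lo = c(0.01, 30, 300, 25),
    hi = c(20, 220, 2000, 42),
    stringsAsFactors = FALSE
  )
}

#' Simulate a labelled 1 Hz physiological recording
#'
#' Generates one second-by-second four-channel recording (GSR, HR, RR, skin
#' temperature) following a Rest/Load protocol. Channel values are Gaussian
#' around the configured baselines; during Load blocks the [load_effect()]
#' mean shifts (scaled by the channel sd, and optionally by the subject's
#' trait score) are applied. Deterministic given `seed`.
#'
#' @param subject one-row subject data frame (needs `subject_id`; uses
#'   `psych_trait` when the effect's `trait_gain` is non-zero).
#' @param protocol a [protocol()].
#' @param effect a [load_effect()].
#' @param seed integer seed.
#' @param baselines see [channel_baselines()].
#' @return data frame with columns `subject_id, t_s, gsr_uS, hr_bpm, rr_ms,
#'   temp_C, label` (label in `{Rest, Load}`), one row per second.
#' @examples
#' s <- simulate_subjects(default_path_spec(), 1, seed = 1)
#' rec <- simulate_recording(s[1, ], protocol("Rest", 60), seed = 2)
#' nrow(rec) # 60
#' @export
simulate_recording <- function(subject, protocol, effect = load_effect(),
                               seed, baselines = channel_baselines()) {
  if (!inherits(protocol, "cw_protocol")) {
    stop("protocol must be built with protocol()", call. = FALSE)
  }
  if (!nrow(protocol)) stop("empty protocol", call. = FALSE)
  labels <- rep(protocol$condition, protocol$duration)
  T_total <- length(labels)
  load_on <- labels == "Load"
  gain <- 1
  if (!is.null(effect$trait_gain) && effect$trait_gain != 0) {
    gain <- max(0, 1 + effect$trait_gain * subject$psych_trait[1])
  }
  set.seed(as.integer(seed))
  out <- data.frame(subject_id = rep(subject$subject_id[1], T_total),
                    t_s = seq_len(T_total) - 1L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(baselines))) {
    ch <- baselines$channel[i]
    mu <- rep(baselines$mean[i], T_total)
    sd <- rep(baselines$sd[i], T_total)
    mu[load_on] <- mu[load_on] + effect$shift[[ch]] * gain * baselines$sd[i]
    sd[load_on] <- sd[load_on] * effect$sd_multiplier
    x <- stats::rnorm(T_total, mu, sd)
    out[[ch]] <- pmin(pmax(x, baselines$lo[i]), baselines$hi[i])
  }
  out$label <- labels
  out
}

#' Simulate a full cohort: subjects plus recordings
#'
#' Per-subject recording seeds are split from the top-level seed as
#' `(seed + 1000003 * i) mod (2^31 - 1)`, so one seed reproduces the whole
#' cohort.
#'
#' @inheritParams simulate_subjects
#' @inheritParams simulate_recording
#' @return list with `subjects` and `recordings` (row-bound recording table).
#' @export
simulate_cohort <- function(spec, n, protocol, effect = load_effect(), seed,
                            exo = default_exogenous()) {
  subjects <- simulate_subjects(spec, n, seed, exo)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    recs[[i]] <- simulate_recording(subjects[i, ], protocol, effect,
                                    seed = split_seed(seed, i))
  }
  list(subjects = subjects,
       recordings = if (n > 0) do.call(rbind, recs) else NULL)
}

# Deterministic child-seed derivation from a top-level seed; stays < 2^31.
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

#' Read and write the cohort CSV interfaces
#'
#' Subjects: `subject_id, age, sex, hh, em, ex, ag, co, op, psych_trait`
#' (plus any further model columns such as `demog`, `cw`). Recordings:
#' `subject_id, t_s, gsr_uS, hr_bpm, rr_ms, temp_C, label`.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_*` return data frames; `write_*` return `path` invisibly.
#' @export
write_subjects <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_subjects
#' @export
write_recording <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_recording <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
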