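#' End-to-end workload assessment pipeline on a synthetic cohort
#'
#' Runs the full chain: simulate a cohort (subjects + labelled recordings),
#' preprocess each channel (leakage-free min-max + standardization fitted on
#' the training half of each recording), window and featurize, train one
#' Load/Rest classifier per sensor on the training subjects, fit the
#' structural path model, build the causal network from the fit, run
#' composite reasoning for a held-out subject (hard demographics, soft trait
#' evidence from the discretized trait score, soft sensor evidence from the
#' per-sensor mean predictions), and fold the subject's fused prediction
#' stream through the workload monitor.
#'
#' @param n_subjects cohort size (>= 3; the last ~30% are held out).
#' @param seed top-level seed; all randomness derives from it.
#' @param spec generator truth, default [default_path_spec()].
#' @param protocol_def recording protocol, default [default_protocol()].
#' @param effect Load effect on the channels, default [load_effect()].
#' @param config network calibration, default [network_config()].
#' @param window,stride windowing parameters in seconds.
#' @param risk_threshold threshold for [decide()].
#' @return list with `subjects`, `fit`, `network`, `models` (per sensor),
#'   `sensor_accuracy` (held-out), `composite` reasoning, `decision`,
#'   `monitor` (final state), `reports`, and `fused_stream`.
#' @export
cw_pipeline <- function(n_subjects = 20, seed = 1,
                        spec = default_path_spec(),
                        protocol_def = default_protocol(),
                        effect = load_effect(),
                        config = network_config(),
                        window = 30, stride = 15,
                        risk_threshold = 0.8) {
  stopifnot(n_subjects >= 3)
  cohort <- simulate_cohort(spec, n_subjects, protocol_def, effect, seed)
  subjects <- cohort$subjects
  n_train <- ceiling(0.7 * n_subjects)
  train_ids <- subjects$subject_id[seq_len(n_train)]
  test_ids <- setdiff(subjects$subject_id, train_ids)
  sensors <- c(GSR = "gsr_uS", HR = "hr_bpm", RR = "rr_ms", Temp = "temp_C")

  featurize <- function(ids) {
    out <- list()
    for (id in ids) {
      rec <- cohort$recordings[cohort$recordings$subject_id == id, ]
      half <- seq_len(floor(nrow(rec) / 2))
      for (s in names(sensors)) {
        sc <- channel_scaler(rec[[sensors[s]]][half])
        ws <- make_windows(rec, sensors[s], window, stride,
                           values = apply_scaler(sc, rec[[sensors[s]]]))
        wf <- window_features(ws)
        wf$sensor <- s
        out[[paste(id, s)]] <- wf
      }
    }
    do.call(rbind, out)
  }

  train_feats <- featurize(train_ids)
  test_feats <- featurize(test_ids)

  models <- lapply(stats::setNames(names(sensors), names(sensors)), function(s) {
    train_sensor_classifier(train_feats[train_feats$sensor == s, ], sensor = s)
  })
  sensor_accuracy <- vapply(names(sensors), function(s) {
    tf <- test_feats[test_feats$sensor == s, ]
    pred <- predict_sensor(models[[s]], tf)
    mean(ifelse(pred$p_load > 0.5, "Load", "Rest") == tf$label)
  }, numeric(1))

  fit <- fit_path_model(subjects, spec)
  network <- build_network(fit, config)

  # held-out subject scenario
  subj <- subjects[subjects$subject_id == test_ids[1], ]
  subj_feats <- test_feats[test_feats$subject_id == subj$subject_id, ]
  per_sensor <- lapply(stats::setNames(names(sensors), names(sensors)),
                       function(s) {
    predict_sensor(models[[s]], subj_feats[subj_feats$sensor == s, ])
  })
  # current status: soft evidence from the latest window of each sensor
  last_p <- vapply(per_sensor, function(p) p$p_load[nrow(p)], numeric(1))
  soft_sensors <- lapply(last_p, function(p) c(Rest = 1 - p, Load = p))
  names(soft_sensors) <- paste0(names(last_p), "_marker")

  trait_state <- discretize_trait(subj$psych_trait, config$trait_thresholds)
  ev <- evidence(
    hard = list(Age = bin_age(subj$age, config$age_breaks), Sex = c("Female", "Male")[subj$sex + 1]),
    soft = c(list(Personality_trait = trait_likelihood(trait_state)),
             soft_sensors)
  )
  composite <- reasoning(network, "composite", ev)
  decision <- decide(composite$posterior, threshold = risk_threshold,
                     modes = c("I", "II", "III"))

  # interval stream for the monitor: fused prediction per window position
  n_win <- sum(subj_feats$sensor == names(sensors)[1])
  fused_stream <- vapply(seq_len(n_win), function(i) {
    fuse_average(vapply(names(sensors), function(s) per_sensor[[s]]$p_load[i],
                        numeric(1)))$p_load
  }, numeric(1))
  mon <- monitor_stream(fused_stream, cw_monitor(interval = stride))

  list(subjects = subjects, fit = fit, network = network, models = models,
       sensor_accuracy = sensor_accuracy, composite = composite,
       decision = decision, monitor = mon$state, reports = mon$reports,
       fused_stream = fused_stream)
}
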