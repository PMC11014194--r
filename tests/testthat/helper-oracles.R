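# Independent oracles used across the suite. These deliberately avoid the
# package's factor/elimination code paths.

# Posterior by brute-force enumeration of the full joint table.
joint_posterior <- function(net, ev, query) {
  states <- net$variables
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in names(states)) {
    pa <- net$parents[[v]]
    m <- as.matrix(cbind(grid[v], grid[pa]))
    p <- p * net$cpts[[v]][m]
  }
  for (v in names(ev$hard)) p[grid[[v]] != ev$hard[[v]]] <- 0
  for (v in names(ev$soft)) {
    lik <- ev$soft[[v]]
    if (is.null(names(lik))) names(lik) <- states[[v]]
    p <- p * as.numeric(lik[grid[[v]]])
  }
  marg <- tapply(p, factor(grid[[query]], levels = states[[query]]), sum)
  as.numeric(marg) / sum(p)
}

# Random DAG network with 2-3 states per node and random CPTs.
random_network <- function(n_nodes, seed) {
  set.seed(seed)
  vars <- paste0("V", seq_len(n_nodes))
  states <- lapply(vars, function(v) paste0(v, "_", letters[seq_len(sample(2:3, 1))]))
  names(states) <- vars
  parents <- stats::setNames(vector("list", n_nodes), vars)
  cpts <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    prev <- vars[seq_len(i - 1)]
    k <- if (length(prev)) sample(0:min(2, length(prev)), 1) else 0L
    pa <- if (k > 0) sample(prev, k) else character(0)
    parents[[v]] <- pa
    nc <- length(states[[v]])
    npar <- prod(vapply(pa, function(p) length(states[[p]]), numeric(1)), 1)
    vals <- vapply(seq_len(npar), function(j) {
      w <- stats::runif(nc, 0.05, 1)
      w / sum(w)
    }, numeric(nc))
    dn <- c(stats::setNames(list(states[[v]]), v),
            stats::setNames(lapply(pa, function(p) states[[p]]), pa))
    cpts[[v]] <- array(as.numeric(vals),
                       dim = unname(c(nc, vapply(pa, function(p) length(states[[p]]), integer(1)))),
                       dimnames = dn)
  }
  cw_network(states, parents, cpts)
}

# Random evidence bundle on a random network: one hard and one soft variable
# (distinct), sometimes none.
random_evidence <- function(net, seed) {
  set.seed(seed)
  vars <- names(net$variables)
  pick <- sample(vars, min(2, length(vars)))
  hard <- list(); soft <- list()
  if (stats::runif(1) < 0.8) {
    hard[[pick[1]]] <- sample(net$variables[[pick[1]]], 1)
  }
  if (length(pick) > 1 && stats::runif(1) < 0.8) {
    soft[[pick[2]]] <- stats::runif(length(net$variables[[pick[2]]]), 0.05, 1)
  }
  evidence(hard = hard, soft = soft)
}

# Feature sets for the sensor-model tests: simulate a small cohort at a given
# Load shift level and return pooled train/test window features per sensor.
cohort_features <- function(shift, seed, n_subjects = 10, n_train = 6) {
  effect <- load_effect(gsr = shift, hr = shift, rr = -shift,
                        temp = -0.5 * shift)
  cohort <- simulate_cohort(default_path_spec(), n_subjects,
                            default_protocol(), effect, seed)
  sensors <- c(GSR = "gsr_uS", HR = "hr_bpm", RR = "rr_ms", Temp = "temp_C")
  ids <- cohort$subjects$subject_id
  featurize <- function(id_set) {
    do.call(rbind, lapply(id_set, function(id) {
      rec <- cohort$recordings[cohort$recordings$subject_id == id, ]
      do.call(rbind, lapply(names(sensors), function(s) {
        sc <- channel_scaler(rec[[sensors[s]]][seq_len(nrow(rec) %/% 2)])
        ws <- make_windows(rec, sensors[s],
                           values = apply_scaler(sc, rec[[sensors[s]]]))
        wf <- window_features(ws)
        wf$sensor <- s
        wf
      }))
    }))
  }
  list(train = featurize(ids[seq_len(n_train)]),
       test = featurize(ids[(n_train + 1):n_subjects]))
}
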