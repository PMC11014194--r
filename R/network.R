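#' Discrete Bayesian causal network
#'
#' A directed acyclic graph over discrete variables with one conditional
#' probability table (CPT) per variable. CPTs are arrays whose first
#' dimension runs over the child's states and whose remaining dimensions run
#' over the parents' states in the declared parent order; every column (child
#' distribution for a fixed parent configuration) sums to 1.
#'
#' @param variables named list: each element is the ordered character vector
#'   of a variable's states (at least 2). State order matters: argmax
#'   tie-breaks resolve to the earliest state, so states are listed from the
#'   least to the most alarming (e.g. `Restful, Neutral, Stressed`;
#'   `Rest, Load`).
#' @param parents named list mapping each variable to its (possibly empty)
#'   character vector of parents.
#' @param cpts named list of CPT arrays, `dimnames` naming the child then the
#'   parents.
#' @return An object of class `cw_network`.
#' @export
cw_network <- function(variables, parents, cpts) {
  vars <- names(variables)
  stopifnot(length(vars) > 0, !is.null(names(parents)), !is.null(names(cpts)))
  for (v in vars) {
    st <- variables[[v]]
    if (length(st) < 2 || anyDuplicated(st)) {
      stop("variable '", v, "' needs >= 2 distinct states", call. = FALSE)
    }
    pa <- parents[[v]] %||% character(0)
    if (!all(pa %in% vars)) stop("unknown parent of '", v, "'", call. = FALSE)
    cpt <- cpts[[v]]
    if (is.null(cpt)) stop("missing CPT for '", v, "'", call. = FALSE)
    want_dim <- c(length(st), vapply(pa, function(p) length(variables[[p]]), integer(1)))
    if (!identical(as.integer(dim(cpt) %||% length(cpt)), as.integer(want_dim))) {
      stop("CPT dimensions for '", v, "' do not match states/parents", call. = FALSE)
    }
    if (any(cpt < -1e-12) || any(cpt > 1 + 1e-12)) {
      stop("CPT entries for '", v, "' outside [0, 1]", call. = FALSE)
    }
    sums <- if (length(pa) == 0) sum(cpt) else
      apply(array(cpt, dim = want_dim), seq_along(want_dim)[-1], sum)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("CPT columns for '", v, "' must each sum to 1", call. = FALSE)
    }
  }
  arcs <- do.call(rbind, lapply(vars, function(v) {
    pa <- parents[[v]] %||% character(0)
    if (length(pa)) data.frame(from = pa, to = v, stringsAsFactors = FALSE)
  }))
  if (!is.null(arcs)) topo_sort_arcs(arcs) # DAG check
  structure(list(variables = variables,
                 parents = lapply(stats::setNames(vars, vars),
                                  function(v) parents[[v]] %||% character(0)),
                 cpts = cpts[vars]),
            class = "cw_network")
}

#' @export
print.cw_network <- function(x, ...) {
  cat("Discrete Bayesian causal network\n")
  for (v in names(x$variables)) {
    pa <- x$parents[[v]]
    cat(sprintf("  %-18s {%s}%s\n", v,
                paste(x$variables[[v]], collapse = ", "),
                if (length(pa)) paste0("  <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

# build a CPT array with proper dimnames
make_cpt <- function(child, child_states, parent_states = list(), values) {
  dims <- unname(c(length(child_states),
                   vapply(parent_states, length, integer(1))))
  dn <- c(stats::setNames(list(child_states), child),
          parent_states)
  array(values, dim = dims, dimnames = dn)
}

#' Discretize a psychological-trait score
#'
#' Maps a standardized trait score to `Restful` (score <= low threshold),
#' `Neutral` (strictly between), or `Stressed` (score >= high threshold).
#' Boundary values at the low threshold are Restful and at the high threshold
#' Stressed. Default thresholds at +/- 1 sd put roughly 16/68/16 percent of a
#' standard-normal cohort in the three states.
#'
#' @param score numeric score(s), standardized scale.
#' @param thresholds strictly increasing pair `c(low, high)`.
#' @return character vector of states.
#' @export
discretize_trait <- function(score, thresholds = c(-1, 1)) {
  if (length(thresholds) != 2 || !(thresholds[1] < thresholds[2])) {
    stop("thresholds must be an increasing pair (low < high)", call. = FALSE)
  }
  ifelse(score <= thresholds[1], "Restful",
         ifelse(score >= thresholds[2], "Stressed", "Neutral"))
}

#' Calibration configuration for the causal network
#'
#' Everything the published analysis leaves unstated: age bin edges, the
#' trait discretization thresholds and logistic scale, the Workload CPT given
#' the trait state, and per-sensor marker reliabilities (probability that the
#' marker agrees with the true Workload state; RR is given the highest
#' reliability, matching its reported standing as the strongest predictor).
#'
#' @param age_breaks increasing integer bin edges (left-closed decades).
#' @param trait_thresholds ordered-logistic thresholds on the latent trait.
#' @param trait_scale logistic scale of the latent trait link.
#' @param workload_given_trait named `P(Workload = Load | trait)` for
#'   `Stressed`, `Neutral`, `Restful`.
#' @param marker_reliability named per-sensor agreement probabilities.
#' @return list of calibration settings.
#' @export
network_config <- function(age_breaks = c(20, 30, 40, 50, 60),
                           trait_thresholds = c(-1, 1),
                           trait_scale = 1,
                           workload_given_trait = c(Stressed = 0.85,
                                                    Neutral = 0.50,
                                                    Restful = 0.15),
                           marker_reliability = c(GSR = 0.80, HR = 0.80,
                                                  RR = 0.86, Temp = 0.75)) {
  stopifnot(all(diff(age_breaks) > 0), trait_thresholds[1] < trait_thresholds[2],
            trait_scale > 0,
            all(workload_given_trait >= 0 & workload_given_trait <= 1),
            all(marker_reliability > 0 & marker_reliability < 1))
  list(age_breaks = age_breaks, trait_thresholds = trait_thresholds,
       trait_scale = trait_scale, workload_given_trait = workload_given_trait,
       marker_reliability = marker_reliability)
}

age_bin_labels <- function(breaks) {
  paste0(utils::head(breaks, -1), "-", utils::tail(breaks, -1) - 1)
}

#' Bin an age in years into the network's Age states
#'
#' @param age age(s) in years.
#' @param age_breaks bin edges, see [network_config()].
#' @return character state label(s), e.g. `"30-39"`.
#' @export
bin_age <- function(age, age_breaks = network_config()$age_breaks) {
  labs <- age_bin_labels(age_breaks)
  as.character(cut(age, breaks = age_breaks, labels = labs, right = FALSE,
                   include.lowest = TRUE))
}

# ordered-logistic state distribution of the trait given latent mean mu
trait_distribution <- function(mu, thresholds, scale) {
  pR <- stats::plogis((thresholds[1] - mu) / scale)
  pS <- 1 - stats::plogis((thresholds[2] - mu) / scale)
  c(Restful = pR, Neutral = 1 - pR - pS, Stressed = pS)
}

#' Build the causal network from a fitted path model
#'
#' Nodes: `Age` (binned decades, uniform prior), `Sex` (`Female`/`Male`,
#' uniform prior), `Personality_trait` (`Restful`/`Neutral`/`Stressed`) with
#' parents Age and Sex, `Workload` (`Rest`/`Load`) with parent
#' `Personality_trait`, and one marker node per sensor (`GSR_marker`, ...)
#' with parent Workload. The Personality_trait CPT is derived from the fitted
#' age and sex path coefficients through an ordered-logistic link on the
#' model-implied latent mean of each parent configuration (bin midpoints are
#' standardized with the scaling stored in the fit); the Workload and marker
#' CPTs come from the calibration config.
#'
#' @param fit a [fit_path_model()] result containing `age -> psych_trait`
#'   and `sex -> psych_trait` arcs.
#' @param config a [network_config()].
#' @return A [cw_network()].
#' @export
build_network <- function(fit, config = network_config()) {
  beta_age <- get_coefficient(fit, "age", "psych_trait")
  beta_sex <- get_coefficient(fit, "sex", "psych_trait")
  age_states <- age_bin_labels(config$age_breaks)
  mids <- (utils::head(config$age_breaks, -1) +
             utils::tail(config$age_breaks, -1) - 1) / 2
  z_age <- (mids - fit$scale$center[["age"]]) / fit$scale$scale[["age"]]
  z_sex <- (c(0, 1) - fit$scale$center[["sex"]]) / fit$scale$scale[["sex"]]
  sex_states <- c("Female", "Male")
  trait_states <- c("Restful", "Neutral", "Stressed")

  pt <- array(0, dim = c(3, length(age_states), 2))
  for (a in seq_along(age_states)) {
    for (s in 1:2) {
      mu <- beta_age * z_age[a] + beta_sex * z_sex[s]
      pt[, a, s] <- trait_distribution(mu, config$trait_thresholds,
                                       config$trait_scale)
    }
  }
  variables <- list(Age = age_states, Sex = sex_states,
                    Personality_trait = trait_states,
                    Workload = c("Rest", "Load"))
  parents <- list(Age = character(0), Sex = character(0),
                  Personality_trait = c("Age", "Sex"),
                  Workload = "Personality_trait")
  wl <- config$workload_given_trait[c("Restful", "Neutral", "Stressed")]
  cpts <- list(
    Age = make_cpt("Age", age_states,
                   values = rep(1 / length(age_states), length(age_states))),
    Sex = make_cpt("Sex", sex_states, values = c(0.5, 0.5)),
    Personality_trait = make_cpt("Personality_trait", trait_states,
                                 list(Age = age_states, Sex = sex_states),
                                 values = pt),
    Workload = make_cpt("Workload", c("Rest", "Load"),
                        list(Personality_trait = trait_states),
                        values = rbind(1 - wl, wl))
  )
  for (sens in names(config$marker_reliability)) {
    node <- paste0(sens, "_marker")
    r <- config$marker_reliability[[sens]]
    variables[[node]] <- c("Rest", "Load")
    parents[[node]] <- "Workload"
    cpts[[node]] <- make_cpt(node, c("Rest", "Load"),
                             list(Workload = c("Rest", "Load")),
                             values = c(r, 1 - r, 1 - r, r))
  }
  cw_network(variables, parents, cpts)
}

#' Synthetic scenario network calibrated to the published prediction table
#'
#' A fixture network (not derivable from data: the underlying CPTs of the
#' published analysis are unpublished) whose `Personality_trait` row for a
#' 30-39-year-old man is set to the published posterior (0 Restful,
#' 0.82 Neutral, 0.18 Stressed); all other rows use the ordered-logistic
#' link with the published age and sex coefficients (-0.011, -0.145).
#' With [trait_likelihood()]'s default Stressed odds of 41/18, soft Stressed
#' evidence moves that posterior to exactly (0, 2/3, 1/3).
#'
#' @param config a [network_config()].
#' @return A [cw_network()].
#' @export
example_network <- function(config = network_config()) {
  age_states <- age_bin_labels(config$age_breaks)
  mids <- (utils::head(config$age_breaks, -1) +
             utils::tail(config$age_breaks, -1) - 1) / 2
  # population standardization of the default generator (age 20-59 uniform)
  exo <- default_exogenous()
  am <- exo_moments(exo$age); sm <- exo_moments(exo$sex)
  z_age <- (mids - am$mean) / am$sd
  z_sex <- (c(0, 1) - sm$mean) / sm$sd
  trait_states <- c("Restful", "Neutral", "Stressed")
  pt <- array(0, dim = c(3, length(age_states), 2))
  for (a in seq_along(age_states)) {
    for (s in 1:2) {
      mu <- -0.011 * z_age[a] - 0.145 * z_sex[s]
      pt[, a, s] <- trait_distribution(mu, config$trait_thresholds,
                                       config$trait_scale)
    }
  }
  pt[, match("30-39", age_states), 2] <- c(0, 0.82, 0.18)
  variables <- list(Age = age_states, Sex = c("Female", "Male"),
                    Personality_trait = trait_states,
                    Workload = c("Rest", "Load"))
  parents <- list(Age = character(0), Sex = character(0),
                  Personality_trait = c("Age", "Sex"),
                  Workload = "Personality_trait")
  wl <- config$workload_given_trait[c("Restful", "Neutral", "Stressed")]
  cpts <- list(
    Age = make_cpt("Age", age_states,
                   values = rep(1 / length(age_states), length(age_states))),
    Sex = make_cpt("Sex", c("Female", "Male"), values = c(0.5, 0.5)),
    Personality_trait = make_cpt("Personality_trait", trait_states,
                                 list(Age = age_states,
                                      Sex = c("Female", "Male")),
                                 values = pt),
    Workload = make_cpt("Workload", c("Rest", "Load"),
                        list(Personality_trait = trait_states),
                        values = rbind(1 - wl, wl))
  )
  for (sens in names(config$marker_reliability)) {
    node <- paste0(sens, "_marker")
    r <- config$marker_reliability[[sens]]
    variables[[node]] <- c("Rest", "Load")
    parents[[node]] <- "Workload"
    cpts[[node]] <- make_cpt(node, c("Rest", "Load"),
                             list(Workload = c("Rest", "Load")),
                             values = c(r, 1 - r, 1 - r, r))
  }
  cw_network(variables, parents, cpts)
}

#' Evidence bundle for network inference
#'
#' Hard evidence fixes a variable to one observed state. Soft (virtual)
#' evidence supplies a non-negative likelihood vector over a variable's
#' states — the mechanism by which classifier probability pairs enter the
#' network without being rounded to hard states. A variable may not carry
#' both kinds at once.
#'
#' @param hard named list/character vector: variable -> observed state.
#' @param soft named list: variable -> named (or state-ordered) non-negative
#'   likelihood vector, not all zero.
#' @return An object of class `cw_evidence`.
#' @export
evidence <- function(hard = list(), soft = list()) {
  hard <- as.list(hard); soft <- as.list(soft)
  both <- intersect(names(hard), names(soft))
  if (length(both)) {
    stop("variables with both hard and soft evidence: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  for (v in names(soft)) {
    l <- as.numeric(soft[[v]])
    if (any(!is.finite(l)) || any(l < 0) || all(l == 0)) {
      stop("soft evidence for '", v,
           "' must be non-negative and not all zero", call. = FALSE)
    }
  }
  structure(list(hard = hard, soft = soft), class = "cw_evidence")
}

#' Soft-evidence likelihood favouring one trait state
#'
#' Returns a likelihood vector over `(Restful, Neutral, Stressed)` with the
#' given odds on the favoured state and 1 elsewhere. The default Stressed
#' odds (41/18) are the fixture calibration that turns the published
#' demographics-only posterior (0, 0.82, 0.18) into the published
#' what-if posterior (0, 2/3, 1/3).
#'
#' @param state favoured state.
#' @param odds likelihood ratio of the favoured state versus the others.
#' @return named numeric length-3 likelihood vector.
#' @export
trait_likelihood <- function(state = "Stressed", odds = 41 / 18) {
  states <- c("Restful", "Neutral", "Stressed")
  stopifnot(state %in% states, odds > 0)
  l <- stats::setNames(rep(1, 3), states)
  l[state] <- odds
  l
}

#' Serialize a network (and evidence) to and from JSON
#'
#' CPTs are written row-major over the parent-state product in the declared
#' parent order, together with explicit state lists, so files round-trip
#' exactly.
#'
#' @param network a [cw_network()].
#' @param path file path.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "cw_network"))
  j <- list(variables = network$variables, parents = network$parents,
            cpts = lapply(network$cpts, as.numeric))
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  variables <- lapply(j$variables, as.character)
  parents <- lapply(j$parents, function(p) as.character(unlist(p)))
  cpts <- list()
  for (v in names(variables)) {
    pa <- parents[[v]]
    cpts[[v]] <- make_cpt(v, variables[[v]],
                          stats::setNames(lapply(pa, function(p) variables[[p]]), pa),
                          values = as.numeric(j$cpts[[v]]))
  }
  cw_network(variables, parents, cpts)
}

#' @rdname write_network
#' @param ev a [evidence()] bundle.
#' @export
write_evidence <- function(ev, path) {
  stopifnot(inherits(ev, "cw_evidence"))
  jsonlite::write_json(list(hard = ev$hard,
                            soft = lapply(ev$soft, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_evidence <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  evidence(hard = lapply(j$hard, function(s) as.character(s)),
           soft = lapply(j$soft, function(l) unlist(l)))
}
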