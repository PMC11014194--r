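# Factor algebra for exact inference. A factor is an array whose dimnames
# are named by variables; 1-D factors keep dim/dimnames so matrix-subscript
# indexing works uniformly.

factor_states <- function(f) dimnames(f)

# Pointwise product of two factors over the union of their variables.
# Dense expand.grid evaluation: the networks here are small (tens of nodes
# at most, eliminated one variable at a time), so clarity wins.
factor_product <- function(f, g) {
  if (is.null(f)) return(g)
  sf <- factor_states(f); sg <- factor_states(g)
  all_states <- c(sf, sg[setdiff(names(sg), names(sf))])
  grid <- as.matrix(expand.grid(all_states, KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
  vals <- f[grid[, names(sf), drop = FALSE]] * g[grid[, names(sg), drop = FALSE]]
  array(vals, dim = lengths(all_states), dimnames = all_states)
}

# Sum a variable out of a factor.
factor_marginalize <- function(f, v) {
  st <- factor_states(f)
  keep <- setdiff(names(st), v)
  if (!length(keep)) return(sum(f))
  out <- apply(f, keep, sum)
  array(out, dim = lengths(st[keep]), dimnames = st[keep])
}

# likelihood factor for evidence on one variable
likelihood_factor <- function(network, v, lik) {
  st <- network$variables[[v]]
  l <- as.numeric(lik)
  if (!is.null(names(lik))) {
    if (!setequal(names(lik), st)) {
      stop("soft evidence states for '", v, "' do not match the variable",
           call. = FALSE)
    }
    l <- as.numeric(lik[st])
  } else if (length(l) != length(st)) {
    stop("soft evidence for '", v, "' has wrong length", call. = FALSE)
  }
  array(l, dim = length(st), dimnames = stats::setNames(list(st), v))
}

#' Exact posterior inference by variable elimination
#'
#' Computes `P(query | evidence)` exactly. Hard evidence enters as a one-hot
#' likelihood factor; soft (virtual) evidence as its likelihood vector. All
#' non-query variables are summed out one at a time (greedy smallest-product
#' ordering); the surviving factor is normalized.
#'
#' @param network a [cw_network()].
#' @param ev an [evidence()] bundle (default: none).
#' @param query variable to query.
#' @return A `cw_posterior`: `variable`, named `probabilities` summing to 1,
#'   and the evidence used.
#' @examples
#' net <- example_network()
#' infer(net, evidence(hard = list(Age = "30-39", Sex = "Male")),
#'       query = "Personality_trait")
#' @export
infer <- function(network, ev = evidence(), query) {
  stopifnot(inherits(network, "cw_network"))
  if (!inherits(ev, "cw_evidence")) stop("ev must be built with evidence()", call. = FALSE)
  vars <- names(network$variables)
  if (!query %in% vars) stop("unknown query variable: ", query, call. = FALSE)
  for (v in names(ev$hard)) {
    if (!v %in% vars) stop("unknown evidence variable: ", v, call. = FALSE)
    if (!ev$hard[[v]] %in% network$variables[[v]]) {
      stop("invalid state '", ev$hard[[v]], "' for variable '", v, "'",
           call. = FALSE)
    }
  }
  for (v in names(ev$soft)) {
    if (!v %in% vars) stop("unknown evidence variable: ", v, call. = FALSE)
  }
  factors <- unname(lapply(vars, function(v) network$cpts[[v]]))
  for (v in names(ev$hard)) {
    onehot <- as.numeric(network$variables[[v]] == ev$hard[[v]])
    names(onehot) <- network$variables[[v]]
    factors <- c(factors, list(likelihood_factor(network, v, onehot)))
  }
  for (v in names(ev$soft)) {
    factors <- c(factors, list(likelihood_factor(network, v, ev$soft[[v]])))
  }
  hidden <- setdiff(vars, query)
  while (length(hidden)) {
    # greedy: eliminate the variable whose product factor is smallest
    cost <- vapply(hidden, function(v) {
      involved <- factors[vapply(factors, function(f) v %in% names(factor_states(f)), logical(1))]
      st <- unique(unlist(lapply(involved, function(f) names(factor_states(f)))))
      prod(vapply(st, function(s) length(network$variables[[s]]), numeric(1)))
    }, numeric(1))
    v <- hidden[which.min(cost)]
    hidden <- setdiff(hidden, v)
    has_v <- vapply(factors, function(f) v %in% names(factor_states(f)), logical(1))
    if (!any(has_v)) next
    prod_f <- Reduce(factor_product, factors[has_v])
    new_f <- factor_marginalize(prod_f, v)
    factors <- factors[!has_v]
    # scalar results are normalization constants; they cancel below
    if (is.array(new_f)) factors <- c(factors, list(new_f))
  }
  res <- Reduce(factor_product, factors)
  probs <- as.numeric(res)[match(network$variables[[query]],
                                 factor_states(res)[[query]])]
  z <- sum(probs)
  if (!is.finite(z) || z <= 0) {
    stop("inconsistent evidence: zero-probability configuration", call. = FALSE)
  }
  structure(list(variable = query,
                 probabilities = stats::setNames(probs / z,
                                                 network$variables[[query]]),
                 evidence = ev),
            class = "cw_posterior")
}

#' @export
print.cw_posterior <- function(x, ...) {
  cat(sprintf("Posterior P(%s | evidence):\n", x$variable))
  for (s in names(x$probabilities)) {
    cat(sprintf("  %-10s %.4f\n", s, x$probabilities[[s]]))
  }
  invisible(x)
}

#' Mode-specific machine reasoning over the workload network
#'
#' The four reasoning modes of the ensemble scheme:
#' * `"I"` — demographics only (hard `Age`, `Sex`), querying
#'   `Personality_trait`;
#' * `"II"` — demographics plus soft trait evidence on `Personality_trait`
#'   (the what-if scenario), querying `Personality_trait`;
#' * `"III"` — soft sensor evidence on marker nodes only, querying
#'   `Workload`;
#' * `"composite"` — all three evidence streams aggregated, querying
#'   `Workload`.
#'
#' The decision label is the argmax state; ties resolve to the earliest
#' (least alarming) state in the variable's state order.
#'
#' @param network a [cw_network()].
#' @param mode `"I"`, `"II"`, `"III"` or `"composite"`.
#' @param ev an [evidence()] bundle supplying what the mode needs.
#' @return A `cw_reasoning`: `mode`, `posterior`, `decision`.
#' @export
reasoning <- function(network, mode = c("I", "II", "III", "composite"), ev) {
  mode <- match.arg(mode)
  marker_nodes <- grep("_marker$", names(network$variables), value = TRUE)
  has_demo <- all(c("Age", "Sex") %in% names(ev$hard))
  has_trait <- "Personality_trait" %in% names(ev$soft) ||
    "Personality_trait" %in% names(ev$hard)
  has_sensor <- any(marker_nodes %in% c(names(ev$soft), names(ev$hard)))
  sub_ev <- function(hard_keep, soft_keep) {
    evidence(hard = ev$hard[intersect(names(ev$hard), hard_keep)],
             soft = ev$soft[intersect(names(ev$soft), soft_keep)])
  }
  if (mode == "I") {
    if (!has_demo) stop("mode I needs hard Age and Sex evidence", call. = FALSE)
    post <- infer(network, sub_ev(c("Age", "Sex"), character(0)),
                  query = "Personality_trait")
  } else if (mode == "II") {
    if (!has_demo || !has_trait) {
      stop("mode II needs demographic and trait evidence", call. = FALSE)
    }
    post <- infer(network,
                  sub_ev(c("Age", "Sex", "Personality_trait"),
                         "Personality_trait"),
                  query = "Personality_trait")
  } else if (mode == "III") {
    if (!has_sensor) stop("mode III needs sensor marker evidence", call. = FALSE)
    post <- infer(network, sub_ev(marker_nodes, marker_nodes),
                  query = "Workload")
  } else {
    if (!has_demo || !has_trait || !has_sensor) {
      stop("composite mode needs demographic, trait and sensor evidence",
           call. = FALSE)
    }
    post <- infer(network, ev, query = "Workload")
  }
  probs <- post$probabilities
  structure(list(mode = mode, posterior = post,
                 decision = names(probs)[which.max(probs)]),
            class = "cw_reasoning")
}

#' @export
print.cw_reasoning <- function(x, ...) {
  cat(sprintf("Reasoning-%s -> decision: %s\n", x$mode, x$decision))
  print(x$posterior)
  invisible(x)
}

#' Risk decision from a Workload posterior
#'
#' Flags "High CW Risk" when the posterior Load probability reaches the
#' threshold (default 0.8).
#'
#' @param posterior a `cw_posterior` over `Workload` (states Rest/Load).
#' @param threshold risk threshold on `P(Load)`, in `[0, 1]`.
#' @param modes reasoning modes that contributed (metadata for the report).
#' @return A `cw_decision`: `p_load`, `threshold`, `high_risk`, `label`,
#'   `modes`.
#' @export
decide <- function(posterior, threshold = 0.8, modes = character(0)) {
  stopifnot(inherits(posterior, "cw_posterior"))
  st <- names(posterior$probabilities)
  if (!setequal(st, c("Rest", "Load"))) {
    stop("decision requires a posterior over Workload (Rest/Load)", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  p_load <- unname(posterior$probabilities[["Load"]])
  high <- p_load >= threshold
  structure(list(p_load = p_load, threshold = threshold, high_risk = high,
                 label = if (high) "High CW Risk" else "Nominal",
                 modes = modes),
            class = "cw_decision")
}

#' @export
print.cw_decision <- function(x, ...) {
  cat(sprintf("P(Load) = %.3f (threshold %.2f): %s\n",
              x$p_load, x$threshold, x$label))
  invisible(x)
}
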