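#' Structural path-model specification
#'
#' A `path_spec` describes a recursive linear path model on the standardized
#' scale: a set of directed arcs with real coefficients plus a Gaussian
#' disturbance standard deviation for every endogenous variable. It is both
#' the ground truth used by [simulate_subjects()] and the structure handed to
#' [fit_path_model()].
#'
#' @param arcs data frame with columns `from`, `to` (character) and `coef`
#'   (finite numeric): one row per directed arc, in standardized units.
#' @param disturbance_sd named numeric vector: one non-negative entry per
#'   endogenous variable (every variable that appears in `arcs$to`).
#' @return An object of class `path_spec` with elements `arcs` and
#'   `disturbance_sd`.
#' @seealso [default_path_spec()], [simulate_subjects()], [fit_path_model()]
#' @examples
#' spec <- path_spec(
#'   data.frame(from = "x", to = "y", coef = 0.5),
#'   disturbance_sd = c(y = sqrt(0.75))
#' )
#' print(spec)
#' @export
path_spec <- function(arcs, disturbance_sd) {
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "coef") %in% names(arcs))) {
    stop("`arcs` needs columns from, to, coef", call. = FALSE)
  }
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  arcs$coef <- as.numeric(arcs$coef)
  if (any(!is.finite(arcs$coef))) stop("arc coefficients must be finite", call. = FALSE)
  if (anyDuplicated(paste(arcs$from, arcs$to))) {
    stop("duplicate arcs in path specification", call. = FALSE)
  }
  endo <- unique(arcs$to)
  sd <- disturbance_sd
  if (is.null(names(sd)) && length(sd) == length(endo)) names(sd) <- endo
  missing_sd <- setdiff(endo, names(sd))
  if (length(missing_sd)) {
    stop("missing disturbance_sd for: ", paste(missing_sd, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    stop("disturbance sds must be finite and non-negative", call. = FALSE)
  }
  topo_sort_arcs(arcs) # errors on cycles
  structure(list(arcs = arcs, disturbance_sd = sd[endo]), class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat("Structural path specification\n")
  cat(sprintf("  %d arcs over %d variables (%d endogenous)\n",
              nrow(x$arcs),
              length(path_spec_variables(x)),
              length(x$disturbance_sd)))
  tab <- x$arcs
  tab$arc <- paste(tab$from, "->", tab$to)
  print(data.frame(arc = tab$arc, coef = tab$coef), row.names = FALSE)
  cat("disturbance sd:\n")
  print(round(x$disturbance_sd, 4))
  invisible(x)
}

# All variable names mentioned by the spec.
path_spec_variables <- function(spec) {
  unique(c(spec$arcs$from, spec$arcs$to))
}

# Kahn topological sort; alphabetical tie-break so the simulation draw order
# is reproducible regardless of arc row order. Errors on a cyclic graph.
topo_sort_arcs <- function(arcs) {
  nodes <- sort(unique(c(arcs$from, arcs$to)))
  order_out <- character(0)
  indeg <- vapply(nodes, function(v) sum(arcs$to == v), integer(1))
  ready <- nodes[indeg == 0]
  remaining <- arcs
  while (length(ready)) {
    v <- sort(ready)[1]
    ready <- setdiff(ready, v)
    order_out <- c(order_out, v)
    children <- remaining$to[remaining$from == v]
    remaining <- remaining[remaining$from != v, , drop = FALSE]
    for (ch in unique(children)) {
      if (!any(remaining$to == ch) && !(ch %in% order_out)) {
        ready <- union(ready, ch)
      }
    }
  }
  if (length(order_out) < length(nodes)) {
    stop("path specification contains a cycle", call. = FALSE)
  }
  order_out
}

#' Default path specification with the published coefficients
#'
#' Ground-truth structure used throughout the package: the six HEXACO domain
#' scores (honesty-humility `hh`, emotionality/dependence `em`, extraversion
#' `ex`, agreeableness `ag`, conscientiousness `co`, openness `op`) together
#' with standardized age and sex load directly on the composite psychological
#' trait `psych_trait` (higher = more Stressed), and a composite demographic
#' score `demog` (equal-weight blend of age and sex) carries the single
#' demographics arc into the cognitive-workload response `cw`.
#'
#' Arc coefficients are the reported standardized estimates:
#' `em` 0.310, `ex` 0.156, `ag` -0.250, `op` -0.025, `co` -0.298,
#' `hh` -0.263, `age` -0.011, `sex` -0.145 (all into `psych_trait`) and
#' `demog -> cw` -0.938. Default disturbance standard deviations are chosen
#' so that every endogenous variable has unit population variance
#' (`sqrt(1 - sum of squared parent coefficients)`; parents are independent
#' by construction), which makes the printed coefficients exact standardized
#' population truths for the generator.
#'
#' @return A [path_spec()].
#' @examples
#' spec <- default_path_spec()
#' subset(spec$arcs, from == "em")$coef # 0.310
#' @export
default_path_spec <- function() {
  arcs <- data.frame(
    from = c("em", "ex", "ag", "op", "co", "hh", "age", "sex",
             "age", "sex", "demog"),
    to = c(rep("psych_trait", 8), "demog", "demog", "cw"),
    coef = c(0.310, 0.156, -0.250, -0.025, -0.298, -0.263, -0.011, -0.145,
             0.5, 0.5, -0.938),
    stringsAsFactors = FALSE
  )
  path_spec(arcs, disturbance_sd = unit_variance_sds(arcs))
}

# Disturbance sds giving unit variance to each endogenous variable when all
# parents are independent with unit variance.
unit_variance_sds <- function(arcs) {
  endo <- unique(arcs$to)
  vapply(endo, function(v) {
    ss <- sum(arcs$coef[arcs$to == v]^2)
    if (ss > 1) stop("parent coefficients of '", v,
                     "' imply variance > 1; supply disturbance_sd explicitly",
                     call. = FALSE)
    sqrt(1 - ss)
  }, numeric(1))
}
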