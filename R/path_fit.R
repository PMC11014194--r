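#' Fit a recursive structural path model
#'
#' Equation-wise least-squares path analysis: every endogenous variable is
#' regressed on its parents. For a recursive model with observed variables
#' this yields the same coefficients as full structural-equation estimation,
#' without an iterative optimizer. With `standardize = TRUE` (default) every
#' variable is sample z-scored first, so estimates are standardized path
#' coefficients directly comparable to the generating [path_spec()].
#'
#' A chi-square fit statistic is computed from the maximum-likelihood
#' discrepancy between the sample covariance matrix `S` and the model-implied
#' covariance `Sigma = (I - B)^-1 Psi (I - B)^-T` (coefficient matrix `B`,
#' diagonal `Psi` of exogenous variances and disturbance variances):
#' `T = (n - 1) * (log det Sigma - log det S + tr(S Sigma^-1) - p)`, with
#' `p(p+1)/2 - (arcs + p)` degrees of freedom. The constrained-to-zero
#' covariances among exogenous variables are what this statistic tests.
#'
#' @param subjects data frame containing every variable named in the
#'   structure (e.g. from [simulate_subjects()]).
#' @param structure a [path_spec()] or a data frame of `from`/`to` arcs.
#' @param standardize z-score all variables before fitting (standardized
#'   coefficients). With `FALSE` the columns are used as-is.
#' @return An object of class `path_fit` with components `coefficients`
#'   (data frame `from, to, estimate, se, p_value`), `fit_stats`
#'   (`chisq, df, p_value`), `n`, `equations` (per-equation `lm` fits),
#'   `scale` (centering/scaling used), and the arc structure.
#' @seealso [get_coefficient()], [reasoning_I_summary()], [build_network()]
#' @examples
#' subjects <- simulate_subjects(default_path_spec(), 500, seed = 7)
#' fit <- fit_path_model(subjects, default_path_spec())
#' coef(fit)["em->psych_trait"]
#' @export
fit_path_model <- function(subjects, structure, standardize = TRUE) {
  arcs <- if (inherits(structure, "path_spec")) structure$arcs else
    as.data.frame(structure, stringsAsFactors = FALSE)
  vars <- unique(c(arcs$from, arcs$to))
  missing_vars <- setdiff(vars, names(subjects))
  if (length(missing_vars)) {
    stop("subject table is missing variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(lapply(subjects[vars], as.numeric))
  n <- nrow(X)
  # estimation is equation-wise, so the binding requirement is per equation:
  # more observations than regressors (+ intercept) in the largest equation
  max_eq <- max(table(arcs$to)) + 1L
  if (n <= max_eq) {
    stop("need more subjects (", n, ") than parameters in the largest ",
         "equation (", max_eq, ")", call. = FALSE)
  }
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, stats::sd, numeric(1))
  if (standardize) {
    if (any(scl == 0)) {
      stop("constant variable(s): ",
           paste(vars[scl == 0], collapse = ", "), call. = FALSE)
    }
    X <- as.data.frame(scale(X))
  } else {
    ctr[] <- 0; scl[] <- 1
  }
  endo <- unique(arcs$to)
  equations <- list()
  coefs <- NULL
  for (v in endo) {
    parents <- arcs$from[arcs$to == v]
    mm <- as.matrix(X[parents])
    if (length(parents) > 1 && kappa(stats::cor(mm)) > 1e8) {
      warning("near-collinear parents in equation for '", v, "'", call. = FALSE)
    }
    fm <- stats::lm(stats::reformulate(parents, response = v), data = X)
    sm <- summary(fm)$coefficients
    equations[[v]] <- fm
    # aliased (perfectly collinear) parents get NA estimates and no summary
    # row; keep the arc with NA inference rather than failing
    idx <- match(parents, rownames(sm))
    coefs <- rbind(coefs, data.frame(
      from = parents, to = v,
      estimate = unname(stats::coef(fm)[parents]),
      se = ifelse(is.na(idx), NA_real_, sm[idx, "Std. Error"]),
      p_value = ifelse(is.na(idx), NA_real_, sm[idx, "Pr(>|t|)"]),
      stringsAsFactors = FALSE))
  }
  fit <- structure(list(coefficients = coefs, n = n, equations = equations,
                        arcs = arcs[c("from", "to")], variables = vars,
                        endogenous = endo, standardized = standardize,
                        scale = list(center = ctr, scale = scl),
                        data = X),
                   class = "path_fit")
  fit$fit_stats <- path_chisq(fit, X)
  fit
}

# ML discrepancy chi-square for the recursive path model.
path_chisq <- function(fit, X) {
  vars <- fit$variables
  p <- length(vars)
  S <- stats::cov(X)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(nrow(fit$coefficients))) {
    B[fit$coefficients$to[i], fit$coefficients$from[i]] <-
      fit$coefficients$estimate[i]
  }
  psi <- numeric(p); names(psi) <- vars
  for (v in vars) {
    psi[v] <- if (v %in% fit$endogenous) {
      r <- stats::residuals(fit$equations[[v]])
      sum(r^2) / (length(r) - 1)
    } else stats::var(X[[v]])
  }
  A <- solve(diag(p) - B)
  Sigma <- A %*% diag(psi, p) %*% t(A)
  df <- p * (p + 1) / 2 - (nrow(fit$coefficients) + p)
  if (df <= 0 || any(psi <= 0) || fit$n <= p + 1 ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
    return(list(chisq = NA_real_, df = df, p_value = NA_real_))
  }
  Fml <- determinant(Sigma)$modulus - determinant(S)$modulus +
    sum(diag(S %*% solve(Sigma))) - p
  chisq <- max(0, (fit$n - 1) * as.numeric(Fml))
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Path model fit (%s), n = %d\n",
              if (x$standardized) "standardized" else "raw scale", x$n))
  tab <- x$coefficients
  cat(sprintf("  %-22s %9s %8s %10s\n", "arc", "estimate", "se", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-22s %9.4f %8.4f %10.3g\n",
                paste0(tab$from[i], " -> ", tab$to[i]),
                tab$estimate[i], tab$se[i], tab$p_value[i]))
  }
  if (!is.na(x$fit_stats$chisq)) {
    cat(sprintf("chi-square %.2f on %d df, p = %.3g\n",
                x$fit_stats$chisq, x$fit_stats$df, x$fit_stats$p_value))
  }
  invisible(x)
}

#' @export
summary.path_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.path_fit")
}

#' @export
print.summary.path_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-equation R-squared:\n")
  for (v in x$fit$endogenous) {
    cat(sprintf("  %-12s %.4f\n", v, summary(x$fit$equations[[v]])$r.squared))
  }
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  paste0(object$coefficients$from, "->", object$coefficients$to))
}

#' Extract one path coefficient
#'
#' Positive coefficients into `psych_trait` mean a more Stressed disposition
#' per unit of the source variable (standardized scale).
#'
#' @param fit a [fit_path_model()] result.
#' @param from,to arc endpoints.
#' @return the point estimate (length-1 numeric).
#' @export
get_coefficient <- function(fit, from, to) {
  stopifnot(inherits(fit, "path_fit"))
  i <- which(fit$coefficients$from == from & fit$coefficients$to == to)
  if (!length(i)) {
    stop("no arc '", from, " -> ", to, "' in the fitted structure", call. = FALSE)
  }
  fit$coefficients$estimate[i]
}

#' Demographic-effect summary (Reasoning-I)
#'
#' Reports the fitted demographic arcs: the age and sex effects on the
#' composite psychological trait and the combined demographics effect on the
#' cognitive-workload response. This is the summary handed to the causal
#' network builder.
#'
#' @param fit a [fit_path_model()] result.
#' @param trait_node,cw_node,demog_node variable names in the structure.
#' @return list with elements `age`, `sex`, `demographics_cw`.
#' @export
reasoning_I_summary <- function(fit, trait_node = "psych_trait",
                                cw_node = "cw", demog_node = "demog") {
  out <- list(age = get_coefficient(fit, "age", trait_node),
              sex = get_coefficient(fit, "sex", trait_node),
              demographics_cw = get_coefficient(fit, demog_node, cw_node))
  class(out) <- "reasoning_summary"
  out
}

#' @export
print.reasoning_summary <- function(x, ...) {
  cat("Demographic effects (standardized):\n")
  cat(sprintf("  age  -> trait : %8.4f\n", x$age))
  cat(sprintf("  sex  -> trait : %8.4f\n", x$sex))
  cat(sprintf("  demographics -> CW : %8.4f\n", x$demographics_cw))
  invisible(x)
}

#' @export
predict.path_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data else {
    nd <- as.data.frame(lapply(newdata[object$variables], as.numeric))
    as.data.frame(mapply(function(col, c0, s0) (col - c0) / s0,
                         nd, object$scale$center[object$variables],
                         if (object$standardized)
                           object$scale$scale[object$variables]
                         else rep(1, length(object$variables)),
                         SIMPLIFY = FALSE))
  }
  vapply(object$endogenous,
         function(v) stats::predict(object$equations[[v]], newdata = X),
         numeric(nrow(X)))
}

#' @export
residuals.path_fit <- function(object, ...) {
  vapply(object$endogenous,
         function(v) stats::residuals(object$equations[[v]]),
         numeric(object$n))
}

#' Turn a fitted path model back into a generator specification
#'
#' Estimated coefficients become arc coefficients; disturbance sds are the
#' per-equation residual standard deviations. Useful for parametric-bootstrap
#' style simulation from a fit.
#'
#' @param fit a [fit_path_model()] result.
#' @return A [path_spec()].
#' @export
as_path_spec <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  arcs <- fit$coefficients[c("from", "to")]
  arcs$coef <- fit$coefficients$estimate
  sds <- vapply(fit$endogenous, function(v) {
    r <- stats::residuals(fit$equations[[v]])
    sqrt(sum(r^2) / (length(r) - 1))
  }, numeric(1))
  path_spec(arcs, disturbance_sd = sds)
}

#' @export
simulate.path_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  simulate_subjects(as_path_spec(object), n = nsim, seed = seed)
}

#' Write the coefficient table and fit report
#'
#' Coefficients go to CSV (`source, target, estimate, se, p_value`); the fit
#' report (chi-square statistic, df, p, n) to JSON.
#'
#' @param fit a [fit_path_model()] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the fit.
#' @export
write_path_fit <- function(fit, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "path_fit"))
  if (!is.null(csv_path)) {
    tab <- fit$coefficients
    names(tab)[1:2] <- c("source", "target")
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(fit_stats = fit$fit_stats, n = fit$n),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
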