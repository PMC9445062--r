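#' Control parameters for the Cox Newton-Raphson optimizer
#'
#' @param eps_score convergence when the maximum absolute score component
#'   falls below this value.
#' @param eps_loglik alternative convergence on relative log-likelihood
#'   change between iterations.
#' @param max_iter maximum Newton iterations.
#' @param max_halving maximum step-halvings per iteration.
#' @export
cox_control <- function(eps_score = 1e-9, eps_loglik = 1e-10,
                        max_iter = 50L, max_halving = 20L) {
  list(eps_score = eps_score, eps_loglik = eps_loglik,
       max_iter = as.integer(max_iter), max_halving = as.integer(max_halving))
}

# Newton-Raphson with step-halving on a prepared (start, stop] design.
# ids groups rows for the sandwich variance. ridge adds lambda*diag to the
# information matrix (stabilisation for nearly collinear slab fits).
cox_newton <- function(start, stop, status, X, ids = seq_along(stop),
                       ties = c("breslow", "efron"), ridge = 0,
                       control = cox_control()) {
  ties <- match.arg(ties)
  tie_code <- if (ties == "breslow") 0L else 1L
  n <- length(stop)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(start) == n, length(status) == n)
  if (sum(status) < 1) stop("no events in the data")

  beta <- rep(0, p)
  ev <- .cox_eval_cpp(start, stop, as.integer(status), X, beta, tie_code, FALSE)
  loglik0 <- ev$loglik
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    info <- ev$info
    if (ridge > 0) info <- info + diag(ridge, p)
    step <- tryCatch(solve(info, ev$score), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular information matrix"
      break
    }
    h <- 1
    halvings <- 0L
    repeat {
      cand <- beta + h * step
      ev_new <- .cox_eval_cpp(start, stop, as.integer(status), X, cand,
                              tie_code, FALSE)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
      h <- h / 2
      halvings <- halvings + 1L
      if (halvings > control$max_halving) break
    }
    if (halvings > control$max_halving) {
      # the likelihood cannot be increased further from here; if the score
      # is essentially flat this is a plateau (typically a monotone
      # likelihood in a rare indicator), which is convergence for every
      # practical purpose even though some coefficient estimates are at
      # the boundary
      if (max(abs(ev$score)) < 1e-4) {
        converged <- TRUE
        diagnostic <- paste0("log-likelihood plateau; monotone likelihood ",
                             "suspected for some coefficient(s)")
      } else {
        diagnostic <- "step-halving failed to increase the log-likelihood"
      }
      break
    }
    rel_change <- abs(ev_new$loglik - ev$loglik) /
      (abs(ev$loglik) + .Machine$double.eps)
    beta <- cand
    ev <- ev_new
    if (max(abs(ev$score)) < control$eps_score ||
        rel_change < control$eps_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) {
      diagnostic <- "maximum iterations reached"
      break
    }
    if (max(abs(beta)) > 50) {
      diagnostic <- paste0("coefficient diverging (|beta| > 50); ",
                           "likely monotone likelihood / separation")
      break
    }
  }

  ev <- .cox_eval_cpp(start, stop, as.integer(status), X, beta, tie_code, TRUE)
  info <- ev$info
  if (ridge > 0) info <- info + diag(ridge, p)
  naive_cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  U <- rowsum(ev$score_resid, group = ids, reorder = FALSE)
  meat <- crossprod(U)
  robust_cov <- if (all(is.finite(naive_cov)))
    naive_cov %*% meat %*% naive_cov else naive_cov
  list(beta = beta, naive_cov = naive_cov, robust_cov = robust_cov,
       loglik = ev$loglik, loglik_null = loglik0,
       n = n, n_events = sum(status), iterations = iter,
       converged = converged, diagnostic = diagnostic,
       info = info, score = ev$score,
       schoenfeld = ev$schoenfeld, schoenfeld_time = ev$schoenfeld_time)
}

# Build the (start, stop] representation for a risk-set rule.
# Prentice: analysis rows are subcohort members plus cases; a case outside
# the subcohort enters one representable unit below its own event time, so
# it contributes to no risk set but its own.
prepare_risk_rows <- function(data, risk_rule) {
  if (!all(c("time", "event") %in% names(data)))
    stop("data must contain 'time' and 'event' columns")
  if (any(data$time <= 0)) stop("all follow-up times must be positive")
  entry <- if ("entry" %in% names(data)) data$entry else rep(0, nrow(data))
  if (risk_rule == "full_cohort") {
    keep <- rep(TRUE, nrow(data))
    start <- entry
  } else {
    if (!"in_subcohort" %in% names(data))
      stop("Prentice fitting requires an 'in_subcohort' column")
    is_case <- if ("is_case" %in% names(data)) data$is_case else
      as.logical(data$event)
    keep <- data$in_subcohort | is_case
    start <- entry
    outside <- keep & is_case & !data$in_subcohort
    # one-ulp entry just before the case's own event time
    start[outside] <- pmax(entry[outside],
                           data$time[outside] * (1 - .Machine$double.eps))
  }
  list(keep = keep, start = start)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood (full-cohort rule) or the Prentice
#' pseudo-partial likelihood (case-cohort rule) by Newton-Raphson with
#' step-halving, starting from zero. Under the Prentice rule the risk set at
#' a case's event time consists of the subcohort members still at risk plus
#' the case itself; cases outside the subcohort contribute to no other risk
#' set. Both the inverse-information ("naive") covariance and a grouped
#' sandwich ("robust") covariance from per-participant score residuals are
#' returned; reported z statistics use the robust standard errors.
#'
#' @param data data.frame with columns `time` (>0), `event` (0/1), and for
#'   the Prentice rule `in_subcohort` (and optionally `is_case`, defaulting
#'   to `event`); an optional `entry` column gives delayed-entry times and
#'   an optional `id` column groups rows for the sandwich variance.
#' @param terms character vector of covariate column names; factors are
#'   expanded to treatment-contrast indicators.
#' @param risk_rule `"prentice"` (default) or `"full_cohort"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param ridge non-negative ridge added to the information matrix
#'   (stabilisation only; default 0).
#' @param control see [cox_control()].
#' @return object of class `cox_fit`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(0, 1, 0))
#' fit <- fit_cox(d, "x", risk_rule = "full_cohort")
#' coef(fit)  # log(2)/2
#' @export
fit_cox <- function(data, terms, risk_rule = c("prentice", "full_cohort"),
                    ties = c("breslow", "efron"), ridge = 0,
                    control = cox_control()) {
  risk_rule <- match.arg(risk_rule)
  ties <- match.arg(ties)
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms))
    stop("term(s) not found in data: ", paste(missing_terms, collapse = ", "))

  rr <- prepare_risk_rows(data, risk_rule)
  d <- data[rr$keep, , drop = FALSE]
  start <- rr$start[rr$keep]

  cc <- stats::complete.cases(d[, terms, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  start <- start[cc]

  d <- droplevels(d)
  xlev <- lapply(Filter(is.factor, d[, terms, drop = FALSE]), levels)
  fml <- stats::reformulate(terms)
  X <- stats::model.matrix(fml, d)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]

  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const))
    stop("constant covariate(s) among analysis rows: ",
         paste(colnames(X)[const], collapse = ", "))

  ids <- if ("id" %in% names(d)) d$id else seq_len(nrow(d))
  res <- cox_newton(start, d$time, as.integer(d$event), X, ids = ids,
                    ties = ties, ridge = ridge, control = control)

  se_naive <- sqrt(pmax(diag(res$naive_cov), 0))
  se_robust <- sqrt(pmax(diag(res$robust_cov), 0))
  beta <- stats::setNames(res$beta, colnames(X))
  structure(list(
    term_names = colnames(X),
    terms = terms,
    formula = fml,
    xlev = xlev,
    beta = beta,
    naive_cov = res$naive_cov,
    robust_cov = res$robust_cov,
    se_naive = stats::setNames(se_naive, colnames(X)),
    se_robust = stats::setNames(se_robust, colnames(X)),
    z = stats::setNames(res$beta / se_robust, colnames(X)),
    loglik = res$loglik,
    loglik_null = res$loglik_null,
    n = res$n,
    n_events = res$n_events,
    n_dropped_incomplete = n_dropped,
    iterations = res$iterations,
    converged = res$converged,
    diagnostic = res$diagnostic,
    risk_rule = risk_rule,
    ties = ties,
    ridge = ridge,
    info = res$info,
    schoenfeld = res$schoenfeld,
    schoenfeld_time = res$schoenfeld_time
  ), class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$beta

#' @export
vcov.cox_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$robust_cov else object$naive_cov
}

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox fit (%s risk sets, %s ties): %d rows, %d events, %s\n",
              x$risk_rule, x$ties, x$n, x$n_events,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else paste0("NOT converged (", x$diagnostic, ")")))
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta),
                    `robust se` = x$se_robust, z = x$z,
                    p = 2 * stats::pnorm(-abs(x$z)), check.names = FALSE)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, conf_level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = object$term_names,
             beta = unname(object$beta),
             hr = unname(exp(object$beta)),
             lcl = unname(exp(object$beta - zq * object$se_robust)),
             ucl = unname(exp(object$beta + zq * object$se_robust)),
             se_robust = unname(object$se_robust),
             se_naive = unname(object$se_naive),
             z = unname(object$z),
             p = unname(2 * stats::pnorm(-abs(object$z))),
             stringsAsFactors = FALSE)
}

#' Per-participant linear predictor
#'
#' Returns `x' beta` for each row of `newdata` using the fitted
#' coefficients. The predictor is defined only up to an additive constant
#' (adding a constant to any covariate shifts all scores equally), which is
#' immaterial for ranking and concordance.
#'
#' @param fit a `cox_fit`.
#' @param newdata data.frame containing the fit's terms.
#' @return numeric vector of scores.
#' @export
linear_predictor <- function(fit, newdata) {
  missing_terms <- setdiff(fit$terms, names(newdata))
  if (length(missing_terms))
    stop("newdata lacks term column(s): ",
         paste(missing_terms, collapse = ", "))
  X <- stats::model.matrix(fit$formula, newdata, xlev = fit$xlev)
  X <- X[, fit$term_names, drop = FALSE]
  as.numeric(X %*% fit$beta)
}

#' Proportional-hazards test from scaled Schoenfeld residuals
#'
#' Score-type test regressing the Schoenfeld residuals on a transform of
#' event time: with residuals `r_k` at event times `t_k` and transform
#' `g`, the statistic for all terms jointly is
#' `T = d / sum((g-gbar)^2) * u' I^{-1} u` with `u = sum (g_k - gbar) r_k`,
#' referred to a chi-square with p degrees of freedom; per-term statistics
#' use the corresponding diagonal of the information matrix (1 df). For a
#' single-term model the global and per-term tests coincide.
#'
#' @param fit a converged `cox_fit`.
#' @param transform `"rank"` (default), `"identity"`, or a function of time.
#' @return data.frame with one row per term plus a `GLOBAL` row:
#'   `chisq`, `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = c("rank", "identity")) {
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  if (!fit$converged) stop("proportional-hazards test requires a converged fit")
  r <- fit$schoenfeld
  tt <- fit$schoenfeld_time
  d <- nrow(r)
  if (d < 2) stop("at least 2 events are required")
  g <- if (is.function(transform)) transform(tt)
  else switch(match.arg(transform),
              rank = rank(tt, ties.method = "average"),
              identity = tt)
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  if (ssg <= 0) stop("degenerate time transform (no variation)")
  u <- colSums(gc * r)
  p <- length(u)
  Iinv <- solve(fit$info)
  global <- as.numeric(d / ssg * (t(u) %*% Iinv %*% u))
  per_term <- d * u^2 / (ssg * diag(fit$info))
  out <- data.frame(
    term = c(fit$term_names, "GLOBAL"),
    chisq = c(per_term, global),
    df = c(rep(1, p), p),
    p = c(stats::pchisq(per_term, 1, lower.tail = FALSE),
          stats::pchisq(global, p, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize a Cox fit to JSON
#'
#' Writes term names, coefficients, both covariance matrices and the
#' convergence record.
#' @param fit a `cox_fit`.
#' @param path output file path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    term_names = fit$term_names,
    beta = unname(fit$beta),
    se_naive = unname(fit$se_naive),
    se_robust = unname(fit$se_robust),
    naive_cov = unname(fit$naive_cov),
    robust_cov = unname(fit$robust_cov),
    loglik = fit$loglik,
    n = fit$n, n_events = fit$n_events,
    iterations = fit$iterations, converged = fit$converged,
    risk_rule = fit$risk_rule, ties = fit$ties)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
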