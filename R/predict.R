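#' Covariates of the established risk-prediction model
#'
#' The conventional T2D risk model used as the comparison baseline: age,
#' sex, study area, fasting time, BMI, family history of diabetes,
#' education, systolic blood pressure, resting heart rate, plasma glucose,
#' triglycerides and statin use.
#' @return character vector of covariate names.
#' @export
base_risk_covariates <- function() {
  c("age", "sex", "area", "fasting_time", "bmi", "family_history",
    "education", "sbp", "heart_rate", "glucose", "triglycerides",
    "statin_use")
}

#' Fit a risk-prediction model on a case-cohort dataset
#'
#' Fits the covariates (plus optional selected biomarkers) under the
#' Prentice pseudo-partial likelihood and tags the model for later
#' comparison.
#'
#' @param dataset case-cohort dataset.
#' @param covariates covariate names (default [base_risk_covariates()]).
#' @param biomarkers optional character vector of biomarker columns to add
#'   (the enhanced model).
#' @param tag `"base"` or `"enhanced"` (defaults to `"enhanced"` when
#'   biomarkers are supplied).
#' @param ties tie handling.
#' @return object of class `risk_model`.
#' @export
fit_risk_model <- function(dataset, covariates = base_risk_covariates(),
                           biomarkers = NULL, tag = NULL,
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.null(tag)) tag <- if (length(biomarkers)) "enhanced" else "base"
  # covariates without variation among the analysis rows (e.g. a rare
  # exposure absent from a small case-cohort sample) cannot be estimated;
  # drop them up front rather than abort the whole model
  keep_rows <- prepare_risk_rows(dataset, "prentice")$keep
  d0 <- dataset[keep_rows, , drop = FALSE]
  constant <- vapply(covariates, function(cv) {
    v <- d0[[cv]]
    length(unique(v[!is.na(v)])) < 2
  }, TRUE)
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  terms <- c(covariates, biomarkers)
  fit <- fit_cox(dataset, terms, risk_rule = "prentice", ties = ties)
  structure(list(fit = fit, covariates = covariates,
                 biomarkers = biomarkers %||% character(0), tag = tag,
                 data_signature = c(n = nrow(dataset),
                                    events = sum(dataset$event))),
            class = "risk_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk model [%s]: %d covariates + %d biomarkers, %s\n",
              x$tag, length(x$covariates), length(x$biomarkers),
              if (x$fit$converged) "converged" else "NOT converged"))
  invisible(x)
}

risk_scores <- function(object, dataset) {
  if (inherits(object, "risk_model")) linear_predictor(object$fit, dataset)
  else if (inherits(object, "cox_fit")) linear_predictor(object, dataset)
  else as.numeric(object)
}

case_weight_vectors <- function(dataset, fraction) {
  is_case <- if ("is_case" %in% names(dataset)) dataset$is_case
  else as.logical(dataset$event)
  in_sub <- if ("in_subcohort" %in% names(dataset)) dataset$in_subcohort
  else rep(TRUE, nrow(dataset))
  w <- ifelse(is_case, 1, 1 / fraction)
  list(w = w, is_case = is_case, in_subcohort = in_sub)
}

#' Case-cohort-weighted concordance index
#'
#' Harrell-type concordance over comparable pairs (i with an event at
#' `t_i`, j still at risk beyond `t_i`), each pair weighted `w_i * w_j`
#' with weight 1 for cases and `1/f` for non-case subcohort members, where
#' `f` is the subcohort sampling fraction. Predictor ties count 1/2.
#' With `f = 1` (all weights 1) this reduces exactly to unweighted
#' Harrell's C. The confidence interval is a percentile bootstrap
#' resampling cases and non-case subcohort members as separate strata.
#'
#' @param object a `risk_model`, `cox_fit`, or numeric vector of risk
#'   scores (higher = higher predicted risk).
#' @param dataset case-cohort dataset.
#' @param fraction subcohort sampling fraction; defaults to the dataset's
#'   `sampling_fraction` attribute (error when absent).
#' @param B bootstrap replicates (default 200; 0 skips the CI).
#' @param seed bootstrap seed.
#' @param conf_level CI level.
#' @return object of class `cindex_result`: `c`, `ci_low`, `ci_high`,
#'   `weighted_pairs`, `method`, `B`, `seed`.
#' @export
weighted_cindex <- function(object, dataset, fraction = NULL, B = 200L,
                            seed = 1L, conf_level = 0.95) {
  f <- fraction %||% attr(dataset, "sampling_fraction")
  if (is.null(f)) stop("subcohort sampling fraction is required ",
                       "(attribute missing and 'fraction' not given)")
  s <- risk_scores(object, dataset)
  cw <- case_weight_vectors(dataset, f)
  res <- .wconcord_cpp(dataset$time, as.integer(dataset$event), s, cw$w)
  if (!is.finite(res$concordance))
    stop("fewer than 2 comparable pairs")
  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (B > 0) {
    set.seed(seed)
    idx_case <- which(cw$is_case)
    idx_ctrl <- which(!cw$is_case & cw$in_subcohort)
    boot <- vapply(seq_len(B), function(b) {
      idx <- c(sample(idx_case, replace = TRUE),
               sample(idx_ctrl, replace = TRUE))
      .wconcord_cpp(dataset$time[idx], as.integer(dataset$event[idx]),
                    s[idx], cw$w[idx])$concordance
    }, 1.0)
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(c = res$concordance, ci_low = ci[1], ci_high = ci[2],
                 weighted_pairs = res$weighted_pairs,
                 method = "ipw_harrell", B = B, seed = seed,
                 boot = boot),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, digits = 3, ...) {
  cat(sprintf("weighted C-index: %.*f", digits, x$c))
  if (is.finite(x$ci_low))
    cat(sprintf(" (%.*f-%.*f)", digits, x$ci_low, digits, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Compare the discrimination of two risk models
#'
#' Computes the weighted C-index of the base and enhanced models, their
#' difference, a paired stratified bootstrap CI (identical resamples
#' applied to both models), a two-sided p-value from the bootstrap normal
#' approximation of the difference, and per-subgroup C-indices (adiposity,
#' sex and age strata) for both models.
#'
#' @param base,enhanced `risk_model` objects fitted on `dataset`.
#' @param dataset case-cohort dataset.
#' @param fraction subcohort sampling fraction (defaults to the dataset
#'   attribute).
#' @param B paired bootstrap replicates.
#' @param seed bootstrap seed.
#' @param subgroups logical; include per-subgroup rows (default TRUE).
#' @param conf_level CI level.
#' @return object of class `model_comparison` with elements `table`
#'   (per-population C-indices with CIs), `delta_c`, `delta_ci`, `p`.
#' @export
compare_models <- function(base, enhanced, dataset, fraction = NULL,
                           B = 200L, seed = 1L, subgroups = TRUE,
                           conf_level = 0.95) {
  stopifnot(inherits(base, "risk_model"), inherits(enhanced, "risk_model"))
  if (!identical(base$data_signature, enhanced$data_signature))
    stop("base and enhanced models were fitted on differing datasets")
  if (base$data_signature[["n"]] != nrow(dataset))
    stop("models were not fitted on this dataset")
  f <- fraction %||% attr(dataset, "sampling_fraction")
  if (is.null(f)) stop("subcohort sampling fraction is required")

  s_base <- risk_scores(base, dataset)
  s_enh <- risk_scores(enhanced, dataset)
  cw <- case_weight_vectors(dataset, f)
  tvec <- dataset$time
  evec <- as.integer(dataset$event)

  cidx <- function(idx, s) {
    .wconcord_cpp(tvec[idx], evec[idx], s[idx], cw$w[idx])$concordance
  }
  all_idx <- seq_len(nrow(dataset))
  strata <- list(total = all_idx)
  if (subgroups) {
    for (st in c("bmi25", "wc_central", "sex", "age55")) {
      grp <- stratifier_groups(dataset, st)
      for (lev in levels(grp))
        strata[[paste(st, lev, sep = ":")]] <- which(grp == lev)
    }
  }

  c_base <- vapply(strata, cidx, 1.0, s = s_base)
  c_enh <- vapply(strata, cidx, 1.0, s = s_enh)
  delta <- c_enh["total"] - c_base["total"]

  set.seed(seed)
  idx_case <- which(cw$is_case)
  idx_ctrl <- which(!cw$is_case & cw$in_subcohort)
  nb <- length(strata)
  boot_base <- matrix(NA_real_, B, nb, dimnames = list(NULL, names(strata)))
  boot_enh <- boot_base
  for (b in seq_len(B)) {
    idx <- c(sample(idx_case, replace = TRUE),
             sample(idx_ctrl, replace = TRUE))
    for (g in names(strata)) {
      sub_idx <- idx[idx %in% strata[[g]]]
      if (length(sub_idx) < 2) next
      cb <- tryCatch(cidx(sub_idx, s_base), error = function(e) NA_real_)
      ce <- tryCatch(cidx(sub_idx, s_enh), error = function(e) NA_real_)
      boot_base[b, g] <- cb
      boot_enh[b, g] <- ce
    }
  }
  a <- (1 - conf_level) / 2
  qs <- function(x) unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE))
  tab <- data.frame(
    population = names(strata),
    n = vapply(strata, length, 1L),
    c_base = unname(c_base),
    c_base_low = apply(boot_base, 2, function(x) qs(x)[1]),
    c_base_high = apply(boot_base, 2, function(x) qs(x)[2]),
    c_enhanced = unname(c_enh),
    c_enhanced_low = apply(boot_enh, 2, function(x) qs(x)[1]),
    c_enhanced_high = apply(boot_enh, 2, function(x) qs(x)[2]),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  d_draws <- boot_enh[, "total"] - boot_base[, "total"]
  sd_d <- stats::sd(d_draws, na.rm = TRUE)
  p <- if (!is.finite(sd_d) || sd_d == 0) {
    if (abs(delta) < .Machine$double.eps) 1 else 0
  } else 2 * stats::pnorm(-abs(delta) / sd_d)
  structure(list(table = tab, delta_c = unname(delta),
                 delta_ci = qs(d_draws), p = unname(p),
                 B = B, seed = seed,
                 boot_delta = d_draws),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("delta C (enhanced - base): %.*f (%.*f to %.*f), p = %.3g\n",
              digits, x$delta_c, digits, x$delta_ci[1], digits,
              x$delta_ci[2], x$p))
  print(within(x$table, {
    c_base <- round(c_base, digits); c_enhanced <- round(c_enhanced, digits)
    c_base_low <- round(c_base_low, digits)
    c_base_high <- round(c_base_high, digits)
    c_enhanced_low <- round(c_enhanced_low, digits)
    c_enhanced_high <- round(c_enhanced_high, digits)
  }))
  invisible(x)
}

#' Write a model-comparison report
#'
#' TSV mirroring the per-population C-index table, plus an optional JSON
#' audit with the bootstrap draws.
#' @param comparison a `model_comparison`.
#' @param tsv_path TSV output path.
#' @param json_path optional JSON audit path.
#' @export
write_comparison <- function(comparison, tsv_path, json_path = NULL) {
  utils::write.table(comparison$table, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(delta_c = comparison$delta_c, delta_ci = comparison$delta_ci,
           p = comparison$p, B = comparison$B, seed = comparison$seed,
           boot_delta = comparison$boot_delta),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
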