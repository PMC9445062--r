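#' Covariate adjustment tiers for the association scan
#'
#' Three nested tiers plus the adiposity-comparison set:
#' * `basic`: age, sex, study area, education, fasting time.
#' * `full`: basic plus smoking, alcohol, physical activity, four dietary
#'   regular-consumption flags, family history of diabetes, BMI and waist
#'   circumference.
#' * `full_plus_glucose`: full plus random plasma glucose.
#' * `fig2`: full without the adiposity terms (BMI, WC) — the adjustment
#'   used when biomarker associations are compared against biomarker
#'   regressions on adiposity.
#' @return named list of covariate-name vectors.
#' @export
adjustment_tiers <- function() {
  basic <- c("age", "sex", "area", "education", "fasting_time")
  lifestyle <- c("smoking", "alcohol", "physical_activity",
                 "diet_fruit", "diet_meat", "diet_fish", "diet_dairy",
                 "family_history")
  list(basic = basic,
       full = c(basic, lifestyle, "bmi", "wc"),
       full_plus_glucose = c(basic, lifestyle, "bmi", "wc", "glucose"),
       fig2 = c(basic, lifestyle))
}

#' Standardize biomarker columns to unit subcohort SD
#'
#' Divides each biomarker column by its standard deviation computed among
#' subcohort members only (the representative population sample), with
#' optional mean-centering (default on). Scaling factors are recorded in
#' the attribute `biomarker_scaling` so that the transform can be inverted.
#'
#' @param dataset data.frame; if an `in_subcohort` column is present the
#'   SDs are computed on subcohort rows, otherwise on all rows.
#' @param panel a `biomarker_panel` (or character vector of marker names).
#' @param center logical; subtract the subcohort mean (default TRUE).
#' @return dataset with standardized biomarker columns.
#' @export
standardize_biomarkers <- function(dataset, panel, center = TRUE) {
  markers <- if (inherits(panel, "biomarker_panel")) panel_markers(panel)
  else as.character(panel)
  markers <- intersect(markers, names(dataset))
  if (!length(markers)) stop("no panel markers found in dataset")
  ref <- if ("in_subcohort" %in% names(dataset))
    dataset[dataset$in_subcohort, , drop = FALSE] else dataset
  ctr <- numeric(length(markers))
  scl <- numeric(length(markers))
  for (i in seq_along(markers)) {
    v <- ref[[markers[i]]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero or undefined subcohort SD for marker: ", markers[i])
    mu <- if (center) mean(v, na.rm = TRUE) else 0
    dataset[[markers[i]]] <- (dataset[[markers[i]]] - mu) / s
    ctr[i] <- mu; scl[i] <- s
  }
  attr(dataset, "biomarker_scaling") <-
    data.frame(marker = markers, center = ctr, scale = scl,
               stringsAsFactors = FALSE)
  dataset
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure: in sorted order `q(i) = min_{j >= i} m * p(j) / j`,
#' capped at 1; hypotheses with `q <= alpha` are rejected. Ties are broken
#' stably by input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha rejection level (default 0.05).
#' @return list with `q` (q-values in input order) and `reject` (logical).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= alpha)
}

# Build the Prentice / full-cohort design pieces shared by every marker fit
# of a scan: analysis rows, start times, covariate design matrix, ids.
scan_design <- function(dataset, covariates, risk_rule) {
  rr <- prepare_risk_rows(dataset, risk_rule)
  d <- dataset[rr$keep, , drop = FALSE]
  start <- rr$start[rr$keep]
  d <- droplevels(d)
  if (length(covariates)) {
    Xcov <- stats::model.matrix(stats::reformulate(covariates), d)
    Xcov <- Xcov[, setdiff(colnames(Xcov), "(Intercept)"), drop = FALSE]
  } else {
    Xcov <- matrix(numeric(0), nrow(d), 0)
  }
  ids <- if ("id" %in% names(d)) d$id else seq_len(nrow(d))
  list(data = d, start = start, Xcov = Xcov, ids = ids)
}

# One marker fit on a prepared scan design; returns the marker's row.
scan_fit_one <- function(des, marker_values, marker_name, ties, control,
                         conf_level = 0.95) {
  ok <- !is.na(marker_values)
  X <- cbind(marker = marker_values, des$Xcov)
  res <- tryCatch(
    cox_newton(des$start[ok], des$data$time[ok],
               as.integer(des$data$event[ok]), X[ok, , drop = FALSE],
               ids = des$ids[ok], ties = ties, control = control),
    error = function(e) NULL)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (is.null(res) || !res$converged) {
    return(data.frame(biomarker = marker_name, beta = NA_real_,
                      se = NA_real_, z = NA_real_,
                      hr = NA_real_, lcl = NA_real_, ucl = NA_real_,
                      p = NA_real_, n_events = NA_integer_,
                      converged = FALSE,
                      diagnostic = if (is.null(res)) "fit error"
                      else res$diagnostic,
                      stringsAsFactors = FALSE))
  }
  b <- res$beta[1]
  se <- sqrt(max(res$robust_cov[1, 1], 0))
  z <- b / se
  data.frame(biomarker = marker_name, beta = b, se = se, z = z,
             hr = exp(b), lcl = exp(b - zq * se), ucl = exp(b + zq * se),
             p = 2 * stats::pnorm(-abs(z)), n_events = res$n_events,
             converged = TRUE, diagnostic = NA_character_,
             stringsAsFactors = FALSE)
}

#' Per-biomarker association scan
#'
#' Fits one Prentice pseudo-partial-likelihood Cox model per
#' (biomarker, adjustment tier): the standardized biomarker as a single
#' continuous term plus the tier's covariates. Wald p-values use robust
#' standard errors; Benjamini-Hochberg q-values are computed across the
#' panel (per tier by default). Non-converging markers are recorded with a
#' diagnostic and the scan continues.
#'
#' @param dataset standardized case-cohort dataset
#'   (see [standardize_biomarkers()]).
#' @param panel a `biomarker_panel` or character vector of marker columns.
#' @param tiers character vector of tier names from [adjustment_tiers()],
#'   or a named list of covariate-name vectors.
#' @param fdr_alpha FDR level for the `significant` flag.
#' @param fdr_scope `"per_tier"` (default) or `"pooled"` across tiers.
#' @param risk_rule passed to the Cox fits (default `"prentice"`).
#' @param ties tie handling (default `"breslow"`).
#' @return data.frame (association table): one row per (biomarker, tier)
#'   with `hr`, `lcl`, `ucl`, `p`, `q`, `significant`, `n_events`.
#' @export
run_scan <- function(dataset, panel, tiers = c("basic", "full",
                                               "full_plus_glucose"),
                     fdr_alpha = 0.05,
                     fdr_scope = c("per_tier", "pooled"),
                     risk_rule = c("prentice", "full_cohort"),
                     ties = c("breslow", "efron")) {
  fdr_scope <- match.arg(fdr_scope)
  risk_rule <- match.arg(risk_rule)
  ties <- match.arg(ties)
  markers <- if (inherits(panel, "biomarker_panel")) panel_markers(panel)
  else as.character(panel)
  markers <- intersect(markers, names(dataset))
  if (!length(markers)) stop("no panel markers found in dataset")
  tier_list <- if (is.list(tiers)) tiers else adjustment_tiers()[tiers]
  if (any(vapply(tier_list, is.null, TRUE))) stop("unknown tier name")
  control <- cox_control()

  out <- list()
  for (tname in names(tier_list)) {
    covs <- tier_list[[tname]]
    des <- scan_design(dataset, covs, risk_rule)
    rows <- lapply(markers, function(mk) {
      r <- scan_fit_one(des, des$data[[mk]], mk, ties, control)
      r
    })
    tab <- do.call(rbind, rows)
    tab$tier <- tname
    tab$stratum <- "all"
    out[[tname]] <- tab
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL

  tab$q <- NA_real_
  tab$significant <- NA
  apply_fdr <- function(idx) {
    ok <- idx[!is.na(tab$p[idx])]
    if (length(ok)) {
      f <- bh_fdr(tab$p[ok], fdr_alpha)
      tab$q[ok] <<- f$q
      tab$significant[ok] <<- f$reject
    }
  }
  if (fdr_scope == "per_tier") {
    for (tname in unique(tab$tier)) apply_fdr(which(tab$tier == tname))
  } else apply_fdr(seq_len(nrow(tab)))

  tab[, c("biomarker", "tier", "stratum", "beta", "se", "z", "hr", "lcl",
          "ucl", "p", "q", "significant", "n_events", "converged",
          "diagnostic")]
}

#' Quartile-shape analysis for one biomarker
#'
#' Cuts the biomarker at subcohort quartiles and fits Q2-Q4 indicator terms
#' (Q1 reference) plus the tier covariates under the Prentice likelihood.
#'
#' @param dataset case-cohort dataset.
#' @param marker biomarker column name.
#' @param tier tier name or covariate vector (default `"full"`).
#' @param risk_rule,ties as in [run_scan()].
#' @return data.frame with rows Q2..Q4: `hr`, `lcl`, `ucl`, `p`, and the
#'   cut points as attribute `cut_points`.
#' @export
quartile_scan <- function(dataset, marker, tier = "full",
                          risk_rule = c("prentice", "full_cohort"),
                          ties = c("breslow", "efron")) {
  risk_rule <- match.arg(risk_rule)
  ties <- match.arg(ties)
  v <- dataset[[marker]]
  if (is.null(v)) stop("marker column not found: ", marker)
  if (length(unique(stats::na.omit(v))) < 8)
    stop("need at least 8 distinct values to form quartiles")
  ref <- if ("in_subcohort" %in% names(dataset))
    v[dataset$in_subcohort] else v
  cuts <- stats::quantile(ref, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
  grp <- cut(v, c(-Inf, cuts, Inf), labels = paste0("Q", 1:4))
  if (any(table(grp) == 0)) stop("empty quartile after cutting")
  d <- dataset
  d$.quartile <- grp
  covs <- if (is.character(tier) && length(tier) == 1)
    adjustment_tiers()[[tier]] else tier
  covs <- setdiff(covs, marker)
  fit <- fit_cox(d, c(".quartile", covs), risk_rule = risk_rule, ties = ties)
  s <- summary(fit)
  s <- s[startsWith(s$term, ".quartile"), , drop = FALSE]
  s$quartile <- sub("^\\.quartile", "", s$term)
  out <- s[, c("quartile", "beta", "hr", "lcl", "ucl", "p")]
  rownames(out) <- NULL
  attr(out, "cut_points") <- cuts
  out
}

#' Cochran Q heterogeneity test
#'
#' Fixed-effect heterogeneity across stratum estimates:
#' `Q = sum w_i (beta_i - beta_bar)^2` with `w_i = 1 / se_i^2` and
#' `beta_bar` the inverse-variance-weighted mean; p from a chi-square with
#' `k - 1` degrees of freedom.
#' @param beta numeric vector of stratum log hazard ratios.
#' @param se their standard errors.
#' @return list with `Q`, `df`, `p`, `beta_bar`.
#' @export
cochran_q <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  bbar <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bbar)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df,
       p = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
       beta_bar = bbar)
}

# stratum assignment for the supported population subgroupings
stratifier_groups <- function(dataset, stratifier) {
  switch(stratifier,
    age55 = factor(ifelse(dataset$age < 55, "30-54", "55-79"),
                   levels = c("30-54", "55-79")),
    sex = factor(dataset$sex),
    region = factor(dataset$region),
    bmi25 = factor(ifelse(dataset$bmi < 25, "bmi<25", "bmi>=25"),
                   levels = c("bmi<25", "bmi>=25")),
    wc_central = {
      central <- (dataset$sex == "male" & dataset$wc >= 90) |
        (dataset$sex == "female" & dataset$wc >= 80)
      factor(ifelse(central, "central", "not_central"),
             levels = c("not_central", "central"))
    },
    stop("unknown stratifier: ", stratifier))
}

#' Subgroup associations with heterogeneity test
#'
#' Fits independent Prentice Cox models for one biomarker within population
#' subgroups and tests heterogeneity of the log hazard ratios with
#' Cochran's Q. Covariates constant within a stratum (e.g. sex when
#' stratifying by sex) are dropped automatically. Strata with fewer than
#' `min_events` events are skipped with a warning and excluded from the
#' heterogeneity test.
#'
#' @param dataset standardized case-cohort dataset.
#' @param marker biomarker column name.
#' @param stratifier one of `"age55"`, `"sex"`, `"region"`, `"bmi25"`,
#'   `"wc_central"`.
#' @param tier tier name or covariate vector (default `"full"`).
#' @param min_events per-stratum event floor (default 10).
#' @param risk_rule,ties as in [run_scan()].
#' @return list with `table` (per-stratum HR rows) and `heterogeneity`
#'   (`Q`, `df`, `p`).
#' @export
subgroup_scan <- function(dataset, marker, stratifier, tier = "full",
                          min_events = 10L,
                          risk_rule = c("prentice", "full_cohort"),
                          ties = c("breslow", "efron")) {
  risk_rule <- match.arg(risk_rule)
  ties <- match.arg(ties)
  covs <- if (is.character(tier) && length(tier) == 1)
    adjustment_tiers()[[tier]] else tier
  grp <- stratifier_groups(dataset, stratifier)
  rows <- list()
  for (lev in levels(grp)) {
    d <- droplevels(dataset[!is.na(grp) & grp == lev, , drop = FALSE])
    if (sum(d$event) < min_events) {
      warning("stratum ", lev, " has fewer than ", min_events,
              " events; skipped")
      next
    }
    keep_covs <- covs[vapply(covs, function(cv) {
      v <- d[[cv]]
      length(unique(v[!is.na(v)])) > 1
    }, TRUE)]
    r <- tryCatch(
      fit_cox(d, c(marker, keep_covs), risk_rule = risk_rule, ties = ties),
      error = function(e) NULL)
    if (is.null(r) || !r$converged) {
      warning("stratum ", lev, " fit did not converge; skipped")
      next
    }
    s <- summary(r)[1, ]
    rows[[lev]] <- data.frame(stratum = lev, beta = s$beta, se = s$se_robust,
                              hr = s$hr, lcl = s$lcl, ucl = s$ucl, p = s$p,
                              n_events = r$n_events,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2)
    stop("fewer than 2 usable strata; heterogeneity not defined")
  rownames(tab) <- NULL
  het <- cochran_q(tab$beta, tab$se)
  list(table = tab, heterogeneity = het)
}

#' Exclude early follow-up (reverse-causality sensitivity analysis)
#'
#' Removes participants whose follow-up ended (event or censoring) within
#' the first `years` years and shifts the remaining participants' entry to
#' `years`, so that analysis time at risk starts there.
#'
#' @param dataset case-cohort dataset.
#' @param years exclusion window (default 2).
#' @return filtered dataset with an `entry` column.
#' @export
sensitivity_exclude_early <- function(dataset, years = 2) {
  if (years >= max(dataset$time)) stop("years must be below max follow-up")
  keep <- dataset$time > years
  out <- dataset[keep, , drop = FALSE]
  if (sum(out$event) == 0) stop("no events remain after exclusion")
  entry <- if ("entry" %in% names(out)) out$entry else rep(0, nrow(out))
  out$entry <- pmax(entry, years)
  rownames(out) <- NULL
  for (a in c("sampling_fraction", "subcohort_size", "config",
              "biomarker_scaling"))
    attr(out, a) <- attr(dataset, a)
  out
}

#' Pearson partial correlations between biomarkers
#'
#' Correlations of the residuals of each biomarker after linear regression
#' on the adjusters (default age, sex, study area), computed among
#' subcohort members.
#'
#' @param dataset data.frame (subcohort rows used when flagged).
#' @param panel `biomarker_panel` or character vector of marker columns.
#' @param adjusters covariate names (default `c("age", "sex", "area")`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
partial_correlations <- function(dataset, panel,
                                 adjusters = c("age", "sex", "area")) {
  markers <- if (inherits(panel, "biomarker_panel")) panel_markers(panel)
  else as.character(panel)
  markers <- intersect(markers, names(dataset))
  d <- if ("in_subcohort" %in% names(dataset))
    dataset[dataset$in_subcohort, , drop = FALSE] else dataset
  d <- droplevels(d)
  Z <- stats::model.matrix(stats::reformulate(adjusters), d)
  if (qr(Z)$rank < ncol(Z))
    stop("adjuster design matrix is rank deficient")
  M <- as.matrix(d[, markers, drop = FALSE])
  H <- solve(crossprod(Z))
  if (!anyNA(M)) {
    R <- M - Z %*% (H %*% crossprod(Z, M))
  } else {
    R <- M
    for (j in seq_len(ncol(M))) {
      ok <- !is.na(M[, j])
      Zj <- Z[ok, , drop = FALSE]
      cf <- solve(crossprod(Zj), crossprod(Zj, M[ok, j]))
      R[ok, j] <- M[ok, j] - Zj %*% cf
    }
  }
  out <- stats::cor(R, use = "pairwise.complete.obs")
  dimnames(out) <- list(markers, markers)
  out
}

#' PCA screen for extreme multivariate observations
#'
#' Computes the first `k` principal components of the standardized
#' biomarker matrix and flags participants with any |standardized score|
#' beyond `threshold` SD. Report-only: no rows are removed or modified.
#'
#' @param dataset data.frame or matrix of biomarker values.
#' @param panel `biomarker_panel` or marker names (ignored when `dataset`
#'   is already a plain matrix).
#' @param k number of components (default 5).
#' @param threshold flagging threshold in SD units (default 6).
#' @return list with `scores` (n x k, unit-SD columns), `flagged` (row
#'   indices), `k`, `threshold`.
#' @export
pca_screen <- function(dataset, panel = NULL, k = 5L, threshold = 6) {
  M <- if (is.matrix(dataset)) dataset else {
    markers <- if (inherits(panel, "biomarker_panel")) panel_markers(panel)
    else as.character(panel)
    as.matrix(dataset[, intersect(markers, names(dataset)), drop = FALSE])
  }
  ok <- stats::complete.cases(M)
  pc <- stats::prcomp(M[ok, , drop = FALSE], center = TRUE, scale. = TRUE)
  rank_ <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (k > rank_) stop("k = ", k, " exceeds the rank (", rank_, ") of the matrix")
  sc <- sweep(pc$x[, seq_len(k), drop = FALSE], 2,
              pc$sdev[seq_len(k)], `/`)
  scores <- matrix(NA_real_, nrow(M), k,
                   dimnames = list(NULL, colnames(sc)))
  scores[ok, ] <- sc
  flagged <- which(apply(abs(scores) > threshold, 1, any))
  list(scores = scores, flagged = flagged, k = k, threshold = threshold)
}

#' Biomarker-adiposity gradients paired with scan log hazard ratios
#'
#' For each biomarker, pairs the coefficient of a linear regression of the
#' (standardized) biomarker on standardized BMI or WC — adjusted for the
#' non-adiposity covariate set and fitted in the subcohort — with the
#' biomarker's Cox log hazard ratio from a matching scan, yielding a
#' plot-ready table of (x = adiposity gradient, y = log HR).
#'
#' @param dataset standardized case-cohort dataset.
#' @param panel `biomarker_panel` or marker names.
#' @param scan association table from [run_scan()] containing tier
#'   `"fig2"` (or the tier named in `tier`).
#' @param adiposity `"bmi"` or `"wc"`.
#' @param stratifier optional stratifier name (see [subgroup_scan()]); when
#'   given the table contains one block per stratum with stratum-specific
#'   regressions and scan rows are matched on the `stratum` column when
#'   present.
#' @param tier scan tier to take log HRs from (default `"fig2"`).
#' @return data.frame: `biomarker`, `class`, `x_slope`, `y_loghr`,
#'   `stratum`.
#' @export
adiposity_gradient <- function(dataset, panel, scan,
                               adiposity = c("bmi", "wc"),
                               stratifier = NULL, tier = "fig2") {
  adiposity <- match.arg(adiposity)
  if (is.null(scan) || !any(scan$tier == tier))
    stop("scan results for tier '", tier, "' are required")
  markers <- if (inherits(panel, "biomarker_panel")) panel_markers(panel)
  else as.character(panel)
  markers <- intersect(markers, names(dataset))
  cls <- if (inherits(panel, "biomarker_panel"))
    stats::setNames(panel$class, panel$name)[markers]
  else stats::setNames(rep(NA_character_, length(markers)), markers)
  covs <- setdiff(adjustment_tiers()$fig2, adiposity)
  scan_t <- scan[scan$tier == tier, , drop = FALSE]
  y <- stats::setNames(scan_t$beta, scan_t$biomarker)

  one_block <- function(d, label) {
    d <- droplevels(d)
    keep_covs <- covs[vapply(covs, function(cv)
      length(unique(d[[cv]])) > 1, TRUE)]
    Z <- stats::model.matrix(stats::reformulate(keep_covs), d)
    av <- scale(d[[adiposity]])[, 1]
    X <- cbind(adip = av, Z)
    slopes <- vapply(markers, function(mk) {
      v <- d[[mk]]
      ok <- !is.na(v)
      cf <- tryCatch(solve(crossprod(X[ok, , drop = FALSE]),
                           crossprod(X[ok, , drop = FALSE], v[ok])),
                     error = function(e) rep(NA_real_, ncol(X)))
      cf[1]
    }, 1)
    data.frame(biomarker = markers, class = unname(cls),
               x_slope = unname(slopes),
               y_loghr = unname(y[markers]),
               stratum = label, stringsAsFactors = FALSE)
  }

  sub <- if ("in_subcohort" %in% names(dataset))
    dataset[dataset$in_subcohort, , drop = FALSE] else dataset
  if (is.null(stratifier)) return(one_block(sub, "all"))
  grp <- stratifier_groups(sub, stratifier)
  out <- lapply(levels(grp), function(lev)
    one_block(sub[!is.na(grp) & grp == lev, , drop = FALSE], lev))
  do.call(rbind, out)
}

#' Write an association table as forest-plot-ready TSV
#' @param scan association table from [run_scan()].
#' @param path file path.
#' @param extra named character vector of header comment fields.
#' @export
write_association_tsv <- function(scan, path, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(extra))
    writeLines(paste0("# ", k, ": ", extra[[k]]), con)
  utils::write.table(scan, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
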