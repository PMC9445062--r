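#' Configuration for the synthetic cohort generator
#'
#' Defines the full data-generating process for a synthetic prospective
#' cohort: covariate distributions (calibrated to a middle-aged Chinese
#' population-cohort profile), a block-correlated biomarker model with
#' adiposity dependence, and Weibull proportional-hazards event times with
#' administrative censoring.
#'
#' Biomarker concentrations are linear in a latent standard-normal score
#' (`conc = biomarker_mean + biomarker_sd * z`), where `z` carries the
#' configured loadings on BMI and waist circumference plus a block
#' compound-symmetry residual. Hazard effects in `log_hr` are per 1 SD of
#' the latent score for measured markers, per 1 SD for continuous
#' covariates, and per unit for binary indicators.
#'
#' @param n_cohort cohort size.
#' @param follow_up_years administrative censoring time (years).
#' @param seed integer seed; mandatory for simulation.
#' @param age_mean,age_sd,age_range age distribution (normal, truncated).
#' @param female_fraction proportion of women.
#' @param n_areas number of study areas (first half urban).
#' @param education_probs probabilities of the 6 education categories.
#' @param fasting_mean,fasting_sd gamma-distributed hours since last meal.
#' @param smoking_prob,alcohol_prob ever-regular smoking/drinking.
#' @param activity_mean,activity_sd gamma-distributed MET-h/day.
#' @param diet_probs named probabilities of regular (4+ days/week)
#'   consumption of fruit, meat, fish, dairy.
#' @param family_history_prob first-degree family history of diabetes.
#' @param bmi_mean,bmi_sd,wc_mean,wc_sd,bmi_wc_cor adiposity model.
#' @param sbp_mean,sbp_sd,sbp_bmi_loading systolic blood pressure.
#' @param heart_rate_mean,heart_rate_sd resting heart rate.
#' @param statin_prob baseline statin use.
#' @param glucose_mean,glucose_sd,glucose_bmi_loading,glucose_wc_loading
#'   random plasma glucose model (latent score loads on adiposity).
#' @param glucose_marker_loadings optional named vector of loadings of the
#'   latent glucose score on measured-marker latent scores; creates
#'   marker -> glucose -> disease mediation when glucose carries a hazard
#'   effect (unlisted markers load 0).
#' @param tg_bmi_loading plasma triglyceride dependence on BMI.
#' @param panel `biomarker_panel` to emit (ratios derived automatically).
#' @param n_blocks,within_block_cor,between_block_cor block
#'   compound-symmetry correlation of measured-marker residuals
#'   (contiguous blocks in panel order); override with `biomarker_corr`.
#' @param biomarker_corr optional full PSD correlation matrix for measured
#'   markers.
#' @param bmi_loadings,wc_loadings per-measured-marker loadings of the
#'   latent biomarker score on standardized BMI / WC (scalar recycled, or
#'   named vector; unnamed markers get the scalar default).
#' @param biomarker_mean,biomarker_sd emitted concentration scale
#'   (arbitrary units; mean/sd chosen so concentrations stay positive).
#' @param weibull_shape baseline Weibull shape (1 = exponential).
#' @param target_incidence cumulative incidence by `follow_up_years` to
#'   which the baseline scale is calibrated (used when
#'   `baseline_scale = NULL`).
#' @param baseline_scale optional explicit Weibull scale parameter.
#' @param log_hr named vector of log hazard ratios (see Details).
#' @param dropout_rate exponential loss-to-follow-up rate per year
#'   (default 0: administrative censoring only).
#' @param screen_exclusion_fraction fraction of highest-glucose rows
#'   dropped at baseline (emulates exclusion of prevalent/screen-detected
#'   disease; default 0).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_cohort = 10000L,
    follow_up_years = 8,
    seed = NULL,
    age_mean = 52, age_sd = 10.5, age_range = c(30, 79),
    female_fraction = 0.62,
    n_areas = 10L,
    education_probs = c(0.12, 0.18, 0.15, 0.25, 0.20, 0.10),
    fasting_mean = 5.2, fasting_sd = 5.1,
    smoking_prob = 0.29, alcohol_prob = 0.16,
    activity_mean = 23, activity_sd = 15,
    diet_probs = c(fruit = 0.31, meat = 0.49, fish = 0.10, dairy = 0.13),
    family_history_prob = 0.08,
    bmi_mean = 23.9, bmi_sd = 3.6,
    wc_mean = 80, wc_sd = 10, bmi_wc_cor = 0.8,
    sbp_mean = 131, sbp_sd = 22, sbp_bmi_loading = 0.25,
    heart_rate_mean = 79, heart_rate_sd = 11,
    statin_prob = 0.003,
    glucose_mean = 5.9, glucose_sd = 1.2,
    glucose_bmi_loading = 0.25, glucose_wc_loading = 0.10,
    glucose_marker_loadings = NULL,
    tg_bmi_loading = 0.35,
    panel = default_panel(),
    n_blocks = 14L, within_block_cor = 0.5, between_block_cor = 0.1,
    biomarker_corr = NULL,
    bmi_loadings = 0.2, wc_loadings = 0.1,
    biomarker_mean = 5, biomarker_sd = 1,
    weibull_shape = 1,
    target_incidence = 0.10,
    baseline_scale = NULL,
    log_hr = c(age = 0.40, sex_female = -0.10, family_history = 0.35,
               bmi = 0.35, glucose = 0.70),
    dropout_rate = 0,
    screen_exclusion_fraction = 0) {
  cfg <- as.list(environment())
  stopifnot(n_cohort >= 2, follow_up_years > 0,
            female_fraction >= 0, female_fraction <= 1,
            abs(sum(education_probs) - 1) < 1e-8,
            within_block_cor >= between_block_cor,
            between_block_cor >= 0, within_block_cor < 1,
            target_incidence > 0, target_incidence < 1,
            weibull_shape > 0,
            all(is.finite(log_hr)))
  class(cfg) <- "cohort_config"
  cfg
}

# correlation matrix of measured-marker residuals: contiguous
# compound-symmetry blocks in panel order
biomarker_block_corr <- function(m, n_blocks, within, between) {
  block <- ceiling(seq_len(m) / ceiling(m / n_blocks))
  S <- matrix(between, m, m)
  for (b in unique(block)) {
    idx <- which(block == b)
    S[idx, idx] <- within
  }
  diag(S) <- 1
  S
}

resolve_loadings <- function(spec, markers, default_scalar) {
  m <- length(markers)
  if (is.null(names(spec))) {
    if (length(spec) == 1) spec <- rep(spec, m)
    if (length(spec) != m)
      stop("unnamed loading vector must have length 1 or ", m)
    return(stats::setNames(spec, markers))
  }
  out <- stats::setNames(rep(default_scalar, m), markers)
  unknown <- setdiff(names(spec), markers)
  if (length(unknown))
    stop("loading refers to unknown measured marker(s): ",
         paste(unknown, collapse = ", "))
  out[names(spec)] <- spec
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws covariates, block-correlated biomarkers with adiposity dependence,
#' and event times from a Weibull proportional-hazards model with linear
#' predictor `sum(log_hr * standardized value)`; applies administrative
#' censoring at `follow_up_years`. Reproducible: identical config (including
#' seed) yields identical output.
#'
#' @param config a [cohort_config()]; `config$seed` must be set.
#' @return data.frame with one row per participant: `id`, `time`, `event`,
#'   covariates, and one column per panel marker (measured concentrations
#'   plus derived ratios). The config is attached as attribute `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$seed))
    stop("config$seed must be set for simulation")
  cfg <- config
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_cohort)

  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
                   cfg$age_range[1]), cfg$age_range[2])
  sex <- factor(ifelse(stats::runif(n) < cfg$female_fraction,
                       "female", "male"), levels = c("male", "female"))
  area <- factor(sprintf("area%02d", sample.int(cfg$n_areas, n, replace = TRUE)),
                 levels = sprintf("area%02d", seq_len(cfg$n_areas)))
  region <- factor(ifelse(as.integer(area) <= cfg$n_areas / 2,
                          "urban", "rural"), levels = c("urban", "rural"))
  education <- factor(sprintf("edu%d",
                              sample.int(6L, n, replace = TRUE,
                                         prob = cfg$education_probs)),
                      levels = sprintf("edu%d", 1:6))
  g_shape <- (cfg$fasting_mean / cfg$fasting_sd)^2
  fasting_time <- stats::rgamma(n, shape = g_shape,
                                scale = cfg$fasting_sd^2 / cfg$fasting_mean)
  smoking <- as.integer(stats::runif(n) < cfg$smoking_prob)
  alcohol <- as.integer(stats::runif(n) < cfg$alcohol_prob)
  a_shape <- (cfg$activity_mean / cfg$activity_sd)^2
  physical_activity <- stats::rgamma(n, shape = a_shape,
                                     scale = cfg$activity_sd^2 / cfg$activity_mean)
  diet <- sapply(cfg$diet_probs, function(p) as.integer(stats::runif(n) < p))
  colnames(diet) <- paste0("diet_", names(cfg$diet_probs))
  family_history <- as.integer(stats::runif(n) < cfg$family_history_prob)

  rho <- cfg$bmi_wc_cor
  z_bmi <- stats::rnorm(n)
  z_wc <- rho * z_bmi + sqrt(1 - rho^2) * stats::rnorm(n)
  bmi <- cfg$bmi_mean + cfg$bmi_sd * z_bmi
  wc <- cfg$wc_mean + cfg$wc_sd * z_wc

  sl <- cfg$sbp_bmi_loading
  z_sbp <- sl * z_bmi + sqrt(1 - sl^2) * stats::rnorm(n)
  sbp <- cfg$sbp_mean + cfg$sbp_sd * z_sbp
  z_hr <- stats::rnorm(n)
  heart_rate <- cfg$heart_rate_mean + cfg$heart_rate_sd * z_hr
  statin_use <- as.integer(stats::runif(n) < cfg$statin_prob)

  tb <- cfg$tg_bmi_loading
  z_tg <- tb * z_bmi + sqrt(1 - tb^2) * stats::rnorm(n)
  triglycerides <- exp(0.26 + 0.45 * z_tg)

  # measured biomarkers
  meas <- measured_markers(cfg$panel)
  m <- length(meas)
  S <- if (is.null(cfg$biomarker_corr))
    biomarker_block_corr(m, cfg$n_blocks, cfg$within_block_cor,
                         cfg$between_block_cor)
  else as.matrix(cfg$biomarker_corr)
  if (nrow(S) != m || ncol(S) != m)
    stop("biomarker correlation matrix must be ", m, " x ", m)
  L <- tryCatch(chol(S), error = function(e)
    stop("biomarker correlation matrix is not positive definite"))
  resid <- matrix(stats::rnorm(n * m), n, m) %*% L
  b1 <- resolve_loadings(cfg$bmi_loadings, meas, 0.2)
  b2 <- resolve_loadings(cfg$wc_loadings, meas, 0.1)
  load_var <- b1^2 + b2^2 + 2 * b1 * b2 * rho
  if (any(load_var >= 1))
    stop("adiposity loadings imply biomarker variance >= 1 for: ",
         paste(meas[load_var >= 1], collapse = ", "))
  zmat <- outer(z_bmi, b1) + outer(z_wc, b2) +
    sweep(resid, 2, sqrt(1 - load_var), `*`)
  colnames(zmat) <- meas
  conc <- cfg$biomarker_mean + cfg$biomarker_sd * zmat

  # glucose: loads on adiposity and (optionally) on marker latent scores;
  # drawn after the biomarkers so that mediation paths are well defined
  gb <- cfg$glucose_bmi_loading; gw <- cfg$glucose_wc_loading
  gvar <- gb^2 + gw^2 + 2 * gb * gw * rho
  if (gvar >= 1) stop("glucose adiposity loadings imply variance >= 1")
  z_glu_sys <- gb * z_bmi + gw * z_wc
  if (!is.null(cfg$glucose_marker_loadings)) {
    g <- cfg$glucose_marker_loadings
    unknown <- setdiff(names(g), meas)
    if (is.null(names(g)) || length(unknown))
      stop("glucose_marker_loadings must be named after measured markers",
           if (length(unknown)) paste0("; unknown: ",
                                       paste(unknown, collapse = ", ")))
    idx <- match(names(g), meas)
    # exact variance of the systematic part from the latent covariances:
    # cov(z_j, z_bmi) = b1_j + rho b2_j; cov(z_j, z_wc) = rho b1_j + b2_j;
    # cov(z_j, z_k) = b1_j b1_k + b2_j b2_k + rho (b1_j b2_k + b2_j b1_k)
    #                 + sqrt((1-lv_j)(1-lv_k)) S[j, k]  (j != k), 1 on diag
    b1g <- b1[idx]; b2g <- b2[idx]
    Czz <- outer(b1g, b1g) + outer(b2g, b2g) +
      rho * (outer(b1g, b2g) + outer(b2g, b1g)) +
      outer(sqrt(1 - load_var[idx]), sqrt(1 - load_var[idx])) *
      S[idx, idx, drop = FALSE]
    diag(Czz) <- 1
    gvar <- gvar + drop(t(g) %*% Czz %*% g) +
      2 * sum(g * (gb * (b1g + rho * b2g) + gw * (rho * b1g + b2g)))
    if (gvar >= 1)
      stop("glucose loadings imply variance >= 1; reduce the loadings")
    z_glu_sys <- z_glu_sys + drop(zmat[, idx, drop = FALSE] %*% g)
  }
  z_glu <- z_glu_sys + sqrt(1 - gvar) * stats::rnorm(n)
  glucose <- cfg$glucose_mean + cfg$glucose_sd * z_glu

  # hazard linear predictor
  hz <- list(
    age = (age - cfg$age_mean) / cfg$age_sd,
    sex_female = as.numeric(sex == "female"),
    fasting_time = (fasting_time - cfg$fasting_mean) / cfg$fasting_sd,
    smoking = smoking, alcohol = alcohol,
    physical_activity = (physical_activity - cfg$activity_mean) /
      cfg$activity_sd,
    family_history = family_history,
    bmi = z_bmi, wc = z_wc, sbp = z_sbp, heart_rate = z_hr,
    glucose = z_glu, triglycerides = z_tg, statin_use = statin_use)
  eta <- rep(0, n)
  for (nmv in names(cfg$log_hr)) {
    v <- if (nmv %in% names(hz)) hz[[nmv]]
    else if (nmv %in% meas) zmat[, nmv]
    else stop("log_hr names unknown covariate or measured marker: ", nmv)
    eta <- eta + cfg$log_hr[[nmv]] * v
  }

  k <- cfg$weibull_shape
  C <- cfg$follow_up_years
  lambda <- cfg$baseline_scale
  if (is.null(lambda)) {
    f <- function(loglam)
      mean(1 - exp(-exp(loglam) * C^k * exp(eta))) - cfg$target_incidence
    lambda <- exp(stats::uniroot(f, c(-30, 10), tol = 1e-12)$root)
  }
  u <- stats::runif(n)
  t_event <- (-log(u) / (lambda * exp(eta)))^(1 / k)
  cens <- rep(C, n)
  if (cfg$dropout_rate > 0)
    cens <- pmin(cens, stats::rexp(n, cfg$dropout_rate))
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  time <- pmax(time, .Machine$double.eps)

  out <- data.frame(
    id = seq_len(n), time = time, event = event,
    age = age, sex = sex, area = area, region = region,
    education = education, fasting_time = fasting_time,
    smoking = smoking, alcohol = alcohol,
    physical_activity = physical_activity,
    family_history = family_history,
    bmi = bmi, wc = wc, sbp = sbp, heart_rate = heart_rate,
    glucose = glucose, triglycerides = triglycerides,
    statin_use = statin_use,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(diet))
  full <- compute_ratios(conc, cfg$panel)
  out <- cbind(out, as.data.frame(full))

  if (cfg$screen_exclusion_fraction > 0) {
    n_drop <- floor(cfg$screen_exclusion_fraction * n)
    if (n_drop > 0) {
      drop_idx <- order(out$glucose, decreasing = TRUE)[seq_len(n_drop)]
      out <- out[-drop_idx, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "config") <- cfg
  attr(out, "baseline_scale") <- lambda
  out
}

#' Case-cohort sampling of a full cohort
#'
#' Returns the analysis dataset of a case-cohort design: all incident cases
#' plus a simple random subcohort, with overlap permitted and flagged. When
#' `n_cases` is given, cases are a simple random sample of that size from
#' the cohort's events (any subcohort event is always retained as a case);
#' unsampled events are excluded from the dataset entirely.
#'
#' @param cohort output of [simulate_cohort()] (or any data.frame with
#'   `time` and `event`).
#' @param fraction subcohort sampling fraction (alternative to
#'   `subcohort_size`).
#' @param subcohort_size absolute subcohort size.
#' @param n_cases optional number of cases to sample from the events.
#' @param seed integer seed for the sampling.
#' @return data.frame of analysis rows with added logical columns
#'   `in_subcohort` and `is_case`, and attributes `sampling_fraction`,
#'   `subcohort_size` and `sampling_seed`.
#' @export
sample_case_cohort <- function(cohort, fraction = NULL, subcohort_size = NULL,
                               n_cases = NULL, seed = 1L) {
  n <- nrow(cohort)
  if (is.null(subcohort_size)) {
    if (is.null(fraction)) stop("give either fraction or subcohort_size")
    stopifnot(fraction > 0, fraction <= 1)
    subcohort_size <- if (fraction == 1) n else round(fraction * n)
  }
  if (subcohort_size > n) stop("subcohort_size exceeds cohort size")
  if (sum(cohort$event) == 0) stop("cohort contains no events; nothing to analyze")

  set.seed(seed)
  sub_idx <- if (subcohort_size == n) seq_len(n)
  else sort(sample.int(n, subcohort_size))
  in_subcohort <- logical(n)
  in_subcohort[sub_idx] <- TRUE

  is_case <- cohort$event == 1
  if (!is.null(n_cases)) {
    ev_idx <- which(cohort$event == 1)
    if (n_cases > length(ev_idx))
      stop("n_cases exceeds the number of events (", length(ev_idx), ")")
    forced <- ev_idx[in_subcohort[ev_idx]]
    if (length(forced) > n_cases)
      stop("subcohort already contains more events than n_cases")
    extra <- sample(setdiff(ev_idx, forced), n_cases - length(forced))
    is_case <- logical(n)
    is_case[c(forced, extra)] <- TRUE
  }

  keep <- in_subcohort | is_case
  out <- cohort[keep, , drop = FALSE]
  out$in_subcohort <- in_subcohort[keep]
  out$is_case <- is_case[keep]
  rownames(out) <- NULL
  attr(out, "config") <- attr(cohort, "config")
  attr(out, "sampling_fraction") <- subcohort_size / n
  attr(out, "subcohort_size") <- subcohort_size
  attr(out, "sampling_seed") <- seed
  out
}

#' Sampling fraction of a case-cohort dataset
#'
#' @param dataset a dataset produced by [sample_case_cohort()], or any
#'   data.frame carrying a `sampling_fraction` attribute.
#' @export
sampling_fraction <- function(dataset) {
  f <- attr(dataset, "sampling_fraction")
  if (is.null(f)) stop("dataset carries no sampling_fraction attribute")
  f
}

#' Default hazard effects for demonstration cohorts
#'
#' A plausible pattern of true effects on the default panel: strong positive
#' branched-chain amino acid, triglyceride-in-HDL and VLDL-size effects,
#' inverse HDL-size / large-HDL-cholesterol / docosahexaenoic-acid effects,
#' plus conventional risk-factor effects including plasma glucose.
#' @return named numeric vector of log hazard ratios per SD.
#' @export
default_marker_effects <- function() {
  c(age = 0.40, sex_female = -0.10, family_history = 0.35,
    bmi = 0.30, glucose = 0.70,
    Ile = 0.45, Leu = 0.45, Val = 0.50,
    ApoB = 0.35, ApoA1 = -0.25,
    HDL_size = -0.50, VLDL_size = 0.45,
    XL_HDL_C = -0.35, S_HDL_TG = 0.45, M_HDL_TG = 0.40,
    DHA = -0.35, LA = 0.30, TotFA = 0.25,
    Lactate = 0.30, bOHbutyrate = 0.15, GlycA = 0.10)
}

#' Preset generator configurations
#'
#' `demo_preset()` is a small cohort (3,000 participants) for fast
#' end-to-end runs; `paper_mimic_preset()` emulates the motivating study's
#' case-cohort dimensions (882 sampled cases, subcohort of 789). Both carry
#' planted marker effects from [default_marker_effects()].
#'
#' @param seed integer seed.
#' @return list with elements `config` (a [cohort_config()]) and the
#'   sampling spec (`subcohort_size` / `fraction`, `n_cases`).
#' @export
demo_preset <- function(seed = 1L) {
  list(config = cohort_config(n_cohort = 3000L, seed = seed,
                              target_incidence = 0.10,
                              log_hr = default_marker_effects()),
       fraction = 0.1, n_cases = NULL)
}

#' @rdname demo_preset
#' @export
paper_mimic_preset <- function(seed = 1L) {
  list(config = cohort_config(n_cohort = 12000L, seed = seed,
                              target_incidence = 0.09,
                              log_hr = default_marker_effects()),
       subcohort_size = 789L, n_cases = 882L)
}

#' Write / read a dataset as TSV with a seed-recording header
#'
#' Tab-delimited UTF-8 with header row; comment lines `# key: value` record
#' the seed, sampling fraction and (optionally) a config hash.
#' @param dataset data.frame to write.
#' @param path file path.
#' @param extra named character vector of additional header fields.
#' @export
write_dataset_tsv <- function(dataset, path, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  cfg <- attr(dataset, "config")
  if (!is.null(cfg) && !is.null(cfg$seed))
    writeLines(paste0("# seed: ", cfg$seed), con)
  f <- attr(dataset, "sampling_fraction")
  if (!is.null(f))
    writeLines(paste0("# sampling_fraction: ", format(f, digits = 17)), con)
  for (k in names(extra))
    writeLines(paste0("# ", k, ": ", extra[[k]]), con)
  utils::write.table(dataset, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  hdr <- list()
  lines <- readLines(path, n = 50L)
  for (l in lines[startsWith(lines, "# ")]) {
    kv <- sub("^# ", "", l)
    pos <- regexpr(": ", kv, fixed = TRUE)
    if (pos > 0)
      hdr[[substr(kv, 1, pos - 1)]] <- substr(kv, pos + 2, nchar(kv))
  }
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  for (cn in c("sex", "area", "region", "education"))
    if (cn %in% names(out)) out[[cn]] <- factor(out[[cn]])
  if (!is.null(hdr$sampling_fraction))
    attr(out, "sampling_fraction") <- as.numeric(hdr$sampling_fraction)
  attr(out, "tsv_header") <- hdr
  out
}
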