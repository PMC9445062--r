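#' Configuration for cuboid-traversal biomarker selection
#'
#' @param dims cuboid dimensions (default `c(5, 5, 9)`, holding 225
#'   markers in 19 slabs).
#' @param z_threshold absolute robust z statistic a marker must exceed in a
#'   slab regression to score a hit (default 2).
#' @param hits_required hits (out of the marker's 3 slab memberships)
#'   required for selection (default 3, i.e. all occasions).
#' @param correlation_threshold pairs of selected markers with absolute
#'   correlation above this are pruned to their first member (default 0.95).
#' @param correlation `"partial"` (age/sex/area-adjusted, subcohort;
#'   default) or `"marginal"`.
#' @param base_covariates covariates of the established risk model included
#'   in every slab regression (default [base_risk_covariates()]).
#' @param ridge ridge added to the information matrix when a slab fit fails
#'   to converge unstabilized (default 1e-6).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(dims = c(5L, 5L, 9L), z_threshold = 2,
                             hits_required = 3L,
                             correlation_threshold = 0.95,
                             correlation = c("partial", "marginal"),
                             base_covariates = base_risk_covariates(),
                             ridge = 1e-6) {
  correlation <- match.arg(correlation)
  stopifnot(z_threshold > 0, hits_required >= 1, hits_required <= 3,
            correlation_threshold > 0, correlation_threshold <= 1)
  structure(list(dims = as.integer(dims), z_threshold = z_threshold,
                 hits_required = as.integer(hits_required),
                 correlation_threshold = correlation_threshold,
                 correlation = correlation,
                 base_covariates = base_covariates, ridge = ridge),
            class = "selection_config")
}

#' Cuboid-traversal biomarker selection
#'
#' Lays the panel on an `a x b x c` cuboid and fits, for each of the
#' `a + b + c` slabs, one multivariable Prentice Cox regression containing
#' all slab markers simultaneously plus the base risk-model covariates. A
#' marker scores a hit in a slab when its absolute robust z statistic
#' exceeds the threshold; markers hitting in all `hits_required` of their
#' slab memberships enter the pre-prune set. Pruning then walks marker
#' pairs in panel order and drops the later member of each pair whose
#' absolute (partial) correlation exceeds the correlation threshold.
#'
#' A slab fit that fails to converge is retried with a small ridge on the
#' information matrix; if it still fails the slab is marked failed, its
#' markers cannot accrue that hit, and a warning is raised.
#'
#' @param dataset standardized case-cohort dataset.
#' @param panel a `biomarker_panel`.
#' @param cuboid optional `cuboid_index`; defaults to
#'   `assign_cuboid(panel, config$dims)`.
#' @param config a [selection_config()].
#' @param risk_rule,ties Cox fitting options.
#' @return object of class `selection_result`: per-slab z values, hit
#'   counts, pre-prune set, pruned pairs and the final selected set.
#' @export
cuboid_select <- function(dataset, panel, cuboid = NULL,
                          config = selection_config(),
                          risk_rule = c("prentice", "full_cohort"),
                          ties = c("breslow", "efron")) {
  risk_rule <- match.arg(risk_rule)
  ties <- match.arg(ties)
  if (is.null(cuboid)) cuboid <- assign_cuboid(panel, config$dims)
  markers <- cuboid$cells$marker
  missing <- setdiff(markers, names(dataset))
  if (length(missing))
    stop("dataset lacks marker column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  control <- cox_control()
  des <- scan_design(dataset, config$base_covariates, risk_rule)

  slab_z <- list()
  failed_slabs <- character(0)
  hit <- stats::setNames(integer(length(markers)), markers)
  tested <- stats::setNames(integer(length(markers)), markers)
  for (sl in names(cuboid$slabs)) {
    mk <- cuboid$slabs[[sl]]
    Mm <- as.matrix(des$data[, mk, drop = FALSE])
    ok <- stats::complete.cases(Mm)
    X <- cbind(Mm, des$Xcov)[ok, , drop = FALSE]
    fit1 <- tryCatch(
      cox_newton(des$start[ok], des$data$time[ok],
                 as.integer(des$data$event[ok]), X, ids = des$ids[ok],
                 ties = ties, control = control),
      error = function(e) NULL)
    if (is.null(fit1) || !fit1$converged) {
      fit1 <- tryCatch(
        cox_newton(des$start[ok], des$data$time[ok],
                   as.integer(des$data$event[ok]), X, ids = des$ids[ok],
                   ties = ties, ridge = config$ridge, control = control),
        error = function(e) NULL)
    }
    if (is.null(fit1) || !fit1$converged) {
      warning("slab ", sl, " did not converge even with ridge ",
              config$ridge, "; its markers cannot score this hit")
      failed_slabs <- c(failed_slabs, sl)
      slab_z[[sl]] <- stats::setNames(rep(NA_real_, length(mk)), mk)
      next
    }
    idx <- seq_along(mk)
    se <- sqrt(pmax(diag(fit1$robust_cov)[idx], 0))
    z <- fit1$beta[idx] / se
    names(z) <- mk
    slab_z[[sl]] <- z
    tested[mk] <- tested[mk] + 1L
    hit[mk] <- hit[mk] + as.integer(abs(z) > config$z_threshold)
  }

  pre_prune <- names(hit)[hit >= config$hits_required]
  # prune in panel declaration order
  pre_prune <- pre_prune[order(match(pre_prune, markers))]
  pruned_pairs <- data.frame(retained = character(0), dropped = character(0),
                             correlation = numeric(0),
                             stringsAsFactors = FALSE)
  selected <- pre_prune
  if (length(pre_prune) > 1) {
    R <- if (config$correlation == "partial")
      partial_correlations(dataset, pre_prune)
    else {
      sub <- if ("in_subcohort" %in% names(dataset))
        dataset[dataset$in_subcohort, , drop = FALSE] else dataset
      stats::cor(as.matrix(sub[, pre_prune, drop = FALSE]),
                 use = "pairwise.complete.obs")
    }
    keep <- stats::setNames(rep(TRUE, length(pre_prune)), pre_prune)
    for (i in seq_along(pre_prune)) {
      if (!keep[i]) next
      for (j in seq_along(pre_prune)) {
        if (j <= i || !keep[j]) next
        r <- R[pre_prune[i], pre_prune[j]]
        if (!is.na(r) && abs(r) > config$correlation_threshold) {
          keep[j] <- FALSE
          pruned_pairs <- rbind(pruned_pairs, data.frame(
            retained = pre_prune[i], dropped = pre_prune[j],
            correlation = r, stringsAsFactors = FALSE))
        }
      }
    }
    selected <- pre_prune[keep]
  }

  structure(list(slab_z = slab_z, hit_counts = hit, tested_counts = tested,
                 pre_prune = pre_prune, pruned_pairs = pruned_pairs,
                 selected = selected, failed_slabs = failed_slabs,
                 config = config, dims = cuboid$dims),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("cuboid selection (%d x %d x %d): %d slab fits, ",
                     "%d pre-prune, %d pruned, %d selected\n"),
              x$dims[1], x$dims[2], x$dims[3], length(x$slab_z),
              length(x$pre_prune), nrow(x$pruned_pairs),
              length(x$selected)))
  if (length(x$selected))
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result
#'
#' `write_selection_json()` writes the full audit trail (per-slab z values,
#' hit counts, pruned pairs, final set); `write_selection_tsv()` writes the
#' final selected set only.
#' @param result a `selection_result`.
#' @param path file path.
#' @export
write_selection_json <- function(result, path) {
  payload <- list(
    dims = result$dims,
    slab_z = lapply(result$slab_z, as.list),
    hit_counts = as.list(result$hit_counts),
    pre_prune = result$pre_prune,
    pruned_pairs = result$pruned_pairs,
    selected = result$selected,
    failed_slabs = result$failed_slabs,
    config = unclass(result$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
write_selection_tsv <- function(result, path) {
  utils::write.table(
    data.frame(marker = result$selected,
               hits = result$hit_counts[result$selected]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
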