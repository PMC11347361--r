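# Summarise a list of per-quantile rema fits into a data frame shaped like a
# pooled-results table.
meta_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(q) {
    f <- fits[[q]]
    data.frame(quantile = q, k = f$k, rr = f$rr,
               ci_lower = f$ci_lower, ci_upper = f$ci_upper,
               tau2 = f$tau2, q_stat = f$q_stat, i2 = f$i2)
  }))
}

evalue_block <- function(fit) {
  list(rr = fit$rr, ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
       e_point = evalue_point(fit$rr),
       e_ci = evalue_ci(fit$rr, fit$ci_lower, fit$ci_upper))
}

#' Run the full confounding-sensitivity analysis
#'
#' Orchestrates the pipeline: read and validate the study and scenario
#' tables, pool the studies per exposure quantile with [rema()], compute
#' E-values for the focus quantile (by default the one with the largest
#' pooled association), run every confounder scenario through
#' [analyse_scenario()], and optionally repeat the pooling and E-values on a
#' tagged subset of studies. The run is fully deterministic: identical inputs
#' and configuration give identical reports.
#'
#' @param study_csv Path to a study-estimate CSV (see [read_study_table()]).
#' @param scenario_csv Path to a confounder-scenario CSV (see
#'   [read_scenario_table()]), or `NULL` for no scenarios.
#' @param reference Reference quantile label, default `"Q1"`.
#' @param focus Focus quantile for the E-value analysis; default is the
#'   non-reference quantile with the largest pooled point estimate.
#' @param level Confidence level, default 0.95.
#' @param subset_tag If the study table has a `tag` column, repeat the
#'   analysis on the studies whose tag equals this value.
#' @param rounding Display decimals used by [emit_report()]'s rendered
#'   tables (full precision is always kept in the report itself). Default 2.
#' @param seed Optional integer recorded in the report for any downstream
#'   simulation; the pipeline itself is deterministic.
#' @return An object of class `confounding_report`.
#' @export
run_full_analysis <- function(study_csv, scenario_csv = NULL,
                              reference = "Q1", focus = NULL, level = 0.95,
                              subset_tag = NULL, rounding = 2, seed = NULL) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  studies <- read_study_table(study_csv)
  scenarios <- if (is.null(scenario_csv)) list() else
    read_scenario_table(scenario_csv)

  fits <- pool_by_quantile(studies, reference = reference, level = level)
  if (length(fits) == 0) {
    stop("no non-reference quantile could be pooled", call. = FALSE)
  }
  if (is.null(focus)) {
    focus <- names(fits)[which.max(vapply(fits, function(f) f$rr,
                                          numeric(1)))]
  }
  if (identical(focus, reference)) {
    stop("focus quantile must differ from the reference", call. = FALSE)
  }
  if (!focus %in% names(fits)) {
    stop("focus quantile '", focus, "' has no pooled estimate", call. = FALSE)
  }
  focus_fit <- fits[[focus]]

  bounding <- lapply(scenarios, analyse_scenario, observed = focus_fit)

  subset_block <- NULL
  if (!is.null(subset_tag)) {
    if (!"tag" %in% names(studies)) {
      stop("`subset_tag` given but the study table has no `tag` column",
           call. = FALSE)
    }
    sub <- studies[!is.na(studies$tag) & studies$tag == subset_tag, ,
                   drop = FALSE]
    if (nrow(sub) == 0) {
      stop("no studies carry tag '", subset_tag, "'", call. = FALSE)
    }
    sub_fits <- pool_by_quantile(sub, reference = reference, level = level)
    sub_focus <- if (focus %in% names(sub_fits)) focus else
      names(sub_fits)[which.max(vapply(sub_fits, function(f) f$rr,
                                       numeric(1)))]
    subset_block <- list(tag = subset_tag,
                         n_studies = length(unique(sub$study_id)),
                         meta = sub_fits, focus = sub_focus,
                         evalues = evalue_block(sub_fits[[sub_focus]]))
  }

  config <- list(reference = reference, focus = focus, level = level,
                 subset_tag = subset_tag, rounding = rounding, seed = seed)
  provenance <- list(
    study_csv = unname(tools::md5sum(study_csv)),
    scenario_csv = if (is.null(scenario_csv)) NULL else
      unname(tools::md5sum(scenario_csv)),
    package_version = as.character(utils::packageVersion("biasbound")))

  structure(
    list(meta = fits, focus = focus, evalues = evalue_block(focus_fit),
         scenarios = bounding, subset = subset_block,
         config = config, provenance = provenance),
    class = "confounding_report"
  )
}

#' @export
print.confounding_report <- function(x, ...) {
  cat("Confounding-sensitivity report\n")
  cat("==============================\n")
  tab <- meta_table(x$meta)
  cat(sprintf("Pooled risk ratios (reference %s):\n", x$config$reference))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: RR %.2f (%.2f, %.2f), k = %d, tau2 = %.4f\n",
                tab$quantile[i], tab$rr[i], tab$ci_lower[i],
                tab$ci_upper[i], tab$k[i], tab$tau2[i]))
  }
  ev <- x$evalues
  cat(sprintf("Focus quantile %s: E-value %.2f (CI limit: %.2f)\n",
              x$focus, round(ev$e_point, 2), round(ev$e_ci, 2)))
  if (length(x$scenarios)) {
    cat("Confounder scenarios:\n")
    for (s in x$scenarios) print(s)
  }
  if (!is.null(x$subset)) {
    cat(sprintf("Subset '%s' (%d studies): focus %s, E-value %.2f (CI limit %.2f)\n",
                x$subset$tag, x$subset$n_studies, x$subset$focus,
                round(x$subset$evalues$e_point, 2),
                round(x$subset$evalues$e_ci, 2)))
  }
  invisible(x)
}

rema_as_list <- function(f) {
  list(k = f$k, pooled_log_rr = f$theta, se_pooled = f$se, rr = f$rr,
       ci_lower = f$ci_lower, ci_upper = f$ci_upper, tau2 = f$tau2,
       q_stat = f$q_stat, i2 = f$i2)
}

report_as_list <- function(report) {
  list(
    config = report$config,
    provenance = report$provenance,
    meta = lapply(report$meta, rema_as_list),
    focus = report$focus,
    evalues = report$evalues,
    scenarios = lapply(report$scenarios, function(s) unclass(s)),
    subset = if (is.null(report$subset)) NULL else {
      s <- report$subset
      list(tag = s$tag, n_studies = s$n_studies,
           meta = lapply(s$meta, rema_as_list), focus = s$focus,
           evalues = s$evalues)
    })
}

#' Write a confounding-sensitivity report to disk
#'
#' Writes `report.json` (full precision), `meta.csv` and `scenarios.csv`
#' (rendered with the configured display rounding), one total-confounding
#' contour CSV per scenario (`curve_<name>.csv`, target bound = the focus
#' quantile's pooled risk ratio, with the target recorded in a `#` header
#' line), and `run.log` recording configuration, input hashes and headline
#' outputs. The output directory is checked for writability before anything
#' is written, so a failure never leaves a partial `report.json` behind.
#'
#' @param report A `confounding_report` from [run_full_analysis()].
#' @param output_dir Directory to write into (created if needed).
#' @param curve_points Points per contour CSV, default 200.
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(report, output_dir, curve_points = 200) {
  if (!inherits(report, "confounding_report")) {
    stop("`report` must be a confounding_report", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  r <- report$config$rounding
  paths <- character(0)

  json_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  paths <- c(paths, json_path)

  tab <- meta_table(report$meta)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "k"
  tab[num] <- lapply(tab[num], round, digits = max(r, 4))
  meta_path <- file.path(output_dir, "meta.csv")
  utils::write.csv(tab, meta_path, row.names = FALSE)
  paths <- c(paths, meta_path)

  if (length(report$scenarios)) {
    sc <- do.call(rbind, lapply(report$scenarios, function(s) {
      data.frame(name = s$name, rr_eu = round(s$rr_eu, r),
                 rr_ud = round(s$rr_ud, r), b = round(s$b, r),
                 proportion_explained_point =
                   round(s$proportion_explained_point),
                 proportion_explained_lower_ci =
                   round(s$proportion_explained_lower_ci),
                 fully_explains_point = s$fully_explains_point,
                 fully_explains_lower_ci = s$fully_explains_lower_ci,
                 required_rr_eu = if (is.na(s$required_rr_eu))
                   "unattainable" else
                     format(round(s$required_rr_eu, r)))
    }))
  } else {
    sc <- data.frame(name = character(0))
  }
  sc_path <- file.path(output_dir, "scenarios.csv")
  utils::write.csv(sc, sc_path, row.names = FALSE)
  paths <- c(paths, sc_path)

  target <- report$evalues$rr
  if (target > 1) {
    for (s in report$scenarios) {
      safe <- gsub("[^A-Za-z0-9_-]", "_", s$name)
      crv <- bounding_curve(target, n_points = curve_points)
      curve_path <- file.path(output_dir, sprintf("curve_%s.csv", safe))
      con <- file(curve_path, "w")
      writeLines(sprintf("# target_b: %.15g", target), con)
      utils::write.csv(crv, con, row.names = FALSE)
      close(con)
      paths <- c(paths, curve_path)
    }
  } else if (length(report$scenarios)) {
    warning("pooled focus RR <= 1: no total-confounding contour to emit",
            call. = FALSE)
  }

  log_path <- file.path(output_dir, "run.log")
  lines <- c(
    sprintf("INFO config reference=%s focus=%s level=%g subset_tag=%s",
            report$config$reference, report$focus, report$config$level,
            if (is.null(report$config$subset_tag)) "-" else
              report$config$subset_tag),
    sprintf("INFO input study_csv md5=%s", report$provenance$study_csv),
    if (!is.null(report$provenance$scenario_csv))
      sprintf("INFO input scenario_csv md5=%s",
              report$provenance$scenario_csv),
    sprintf("INFO meta quantile=%s rr=%.6f ci=[%.6f,%.6f] tau2=%.8f",
            names(report$meta),
            vapply(report$meta, function(f) f$rr, numeric(1)),
            vapply(report$meta, function(f) f$ci_lower, numeric(1)),
            vapply(report$meta, function(f) f$ci_upper, numeric(1)),
            vapply(report$meta, function(f) f$tau2, numeric(1))),
    sprintf("INFO evalue focus=%s e_point=%.6f e_ci=%.6f", report$focus,
            report$evalues$e_point, report$evalues$e_ci),
    vapply(report$scenarios, function(s)
      sprintf("INFO scenario name=%s b=%.6f explained_point=%.2f explained_ci=%.2f",
              s$name, s$b, s$proportion_explained_point,
              s$proportion_explained_lower_ci), character(1)))
  writeLines(lines, log_path)
  paths <- c(paths, log_path)

  invisible(paths)
}
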