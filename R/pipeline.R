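# File-based pipeline: simulate -> analyze -> report, with seed provenance.

#' Simulate a trial and write it to disk
#'
#' Runs [simulate_trial()] and writes the dataset CSV plus a JSON sidecar
#' holding the full generator configuration and seed. Logs the seed, arm
#' counts and completer count.
#'
#' @param config a [sim_config()] object.
#' @param output_dir directory for outputs (created if missing).
#' @param basename file stem (default `"trial"`).
#' @param quiet suppress log messages.
#' @return Invisibly, a list with the `trial` object and the `csv` path.
#' @export
run_simulate <- function(config, output_dir, basename = "trial",
                         quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  trial <- simulate_trial(config)
  path <- file.path(output_dir, paste0(basename, ".csv"))
  write_trial(trial, path)
  compl <- tapply(trial$responses$completed, trial$responses$participant_id,
                  all)
  if (!quiet) {
    message(sprintf("simulate: seed %d, %d participants (%s), %d completers -> %s",
                    config$seed, nrow(trial$participants),
                    paste(sprintf("%s %d", names(table(trial$participants$arm)),
                                  table(trial$participants$arm)),
                          collapse = ", "),
                    sum(compl), path))
  }
  invisible(list(trial = trial, csv = path))
}

lmm_fit_json <- function(fit) {
  list(model = "random_intercept_linear",
       formula = deparse(fit$formula),
       method = fit$method,
       coefficients = fit$coef_table,
       sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
       loglik = fit$loglik, converged = fit$converged,
       boundary = fit$boundary,
       n_obs = fit$n_obs, n_groups = fit$n_groups)
}

clmm_fit_json <- function(fit) {
  list(model = "multilevel_proportional_odds",
       formula = deparse(fit$formula),
       thresholds = fit$zeta,
       coefficients = data.frame(term = names(fit$beta), estimate = fit$beta,
                                 se = fit$se, row.names = NULL),
       sigma_u2 = fit$sigma_u2, loglik = fit$loglik,
       quadrature_nodes = fit$nodes, converged = fit$converged,
       n_obs = fit$n_obs, n_groups = fit$n_groups)
}

#' Analyse a trial dataset: WOA, summaries and multilevel fits
#'
#' Computes per-record weight-of-advice with the chosen truncation policy,
#' applies the per-protocol filter, and writes: the WOA records CSV, an
#' estimates/WOA summary (overall and by arm), moderator-by-arm summaries,
#' and JSON files for the primary random-intercept fit, the four moderator
#' interaction models (one moderator at a time), and the ordinal sensitivity
#' fit.
#'
#' @param dataset a `"woa_trial"` object or path to a dataset CSV written by
#'   [run_simulate()].
#' @param output_dir directory for result files.
#' @param policy negative-WOA policy, see [truncate_woa()].
#' @param ordinal also fit the multilevel proportional-odds sensitivity model
#'   (default TRUE; it is the slowest step).
#' @param quiet suppress log messages.
#' @return Invisibly, a list with `records`, `summaries`, `fits` and output
#'   paths.
#' @export
run_analyze <- function(dataset, output_dir,
                        policy = c("clamp", "keep", "drop"),
                        ordinal = TRUE, quiet = FALSE) {
  policy <- match.arg(policy)
  trial <- if (inherits(dataset, "woa_trial")) dataset else read_trial(dataset)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  rec <- per_protocol_filter(woa_records(trial, policy = policy))
  rec_path <- file.path(output_dir, "woa_records.csv")
  utils::write.csv(rec, rec_path, row.names = FALSE, quote = FALSE)

  estimates <- do.call(rbind, lapply(c("initial", "final", "woa"), function(v) {
    ov <- summarize_woa(rec, "overall", value = v)
    byarm <- summarize_woa(rec, "arm", value = v)
    ov$arm <- "overall"; ov$group <- NULL
    cbind(measure = v, rbind(ov[, c("arm", "n", "mean", "sd", "ci_lo", "ci_hi")],
                             byarm[, c("arm", "n", "mean", "sd", "ci_lo", "ci_hi")]))
  }))
  est_path <- file.path(output_dir, "summary_estimates.csv")
  utils::write.csv(estimates, est_path, row.names = FALSE, quote = FALSE)

  moderators <- c("profession", "total_experience", "palliative_experience",
                  "strength")
  mod_tab <- do.call(rbind, lapply(moderators, function(m) {
    s <- summarize_woa(rec, m)
    names(s)[1] <- "level"
    cbind(moderator = m, s)
  }))
  mod_path <- file.path(output_dir, "summary_moderators.csv")
  utils::write.csv(mod_tab, mod_path, row.names = FALSE, quote = FALSE)

  d <- rec[!rec$excluded & !is.na(rec$woa), , drop = FALSE]
  primary <- arm_difference(rec)
  fits <- list(primary = lmm_fit_json(primary$fit))
  fits$primary$arm_difference <- list(estimate = primary$estimate,
                                      ci95 = primary$ci95, p = primary$p)
  for (m in moderators) {
    fml <- stats::as.formula(paste("woa ~ arm *", m))
    fit_m <- fit_random_intercept(d, fml)
    wt <- wald_test(fit_m, paste0("arm:", m))
    j <- lmm_fit_json(fit_m)
    j$interaction_wald <- wt
    fits[[paste0("moderator_", m)]] <- j
  }
  if (ordinal) {
    ofit <- fit_multilevel_ordinal(d, bin ~ arm)
    fits$ordinal_sensitivity <- clmm_fit_json(ofit)
  }
  fits_path <- file.path(output_dir, "fits.json")
  jsonlite::write_json(fits, fits_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")

  all_conv <- all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (!quiet) {
    message(sprintf(paste0("analyze: %d records (%d excluded: %d tie, %d ",
                           "incomplete), arm difference %.3f [%.3f, %.3f]%s"),
                    nrow(rec), sum(rec$excluded),
                    sum(rec$reason == "tie", na.rm = TRUE),
                    sum(rec$reason == "incomplete", na.rm = TRUE),
                    primary$estimate, primary$ci95[1], primary$ci95[2],
                    if (all_conv) "" else " [NON-CONVERGENCE]"))
  }
  invisible(list(records = rec,
                 summaries = list(estimates = estimates, moderators = mod_tab),
                 fits = fits, converged = all_conv,
                 paths = c(records = rec_path, estimates = est_path,
                           moderators = mod_path, fits = fits_path)))
}

#' Render a markdown report from analysis results
#'
#' Reads the summary CSVs and fit JSON written by [run_analyze()] and renders
#' a deterministic (byte-identical across runs) markdown report: the primary
#' arm difference, moderator tables with interaction tests, and whether the
#' ordinal sensitivity model agrees in sign with the primary analysis.
#' Non-convergent fits are flagged prominently.
#'
#' @param results_dir directory produced by [run_analyze()].
#' @param file output path (default `report.md` inside `results_dir`).
#' @return The report path, invisibly; the report text as a character vector
#'   in attribute `"lines"`.
#' @export
run_report <- function(results_dir, file = file.path(results_dir, "report.md")) {
  need <- file.path(results_dir,
                    c("summary_estimates.csv", "summary_moderators.csv",
                      "fits.json"))
  absent <- need[!file.exists(need)]
  if (length(absent)) {
    stop("missing result file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  est <- utils::read.csv(need[1])
  mod <- utils::read.csv(need[2])
  fits <- jsonlite::read_json(need[3], simplifyVector = TRUE)

  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  ad <- fits$primary$arm_difference
  lines <- c(
    "# Weight-of-advice analysis report", "",
    "## Primary analysis: arm difference",
    sprintf(paste0("Clinician-arm minus algorithm-arm difference in mean WOA: ",
                   "%s [95%% CI %s, %s], p %s (random-intercept linear ",
                   "model, %s)."),
            fmt(ad$estimate), fmt(ad$ci95[1]), fmt(ad$ci95[2]),
            ifelse(ad$p < 0.001, "< 0.001", paste0("= ", fmt(ad$p))),
            fits$primary$method), "")
  woa_rows <- est[est$measure == "woa", ]
  lines <- c(lines, "Mean WOA by arm:",
             sprintf("- %s: %s (SD %s, n = %d)", woa_rows$arm,
                     fmt(woa_rows$mean), fmt(woa_rows$sd), woa_rows$n), "")

  lines <- c(lines, "## Moderator analyses (one moderator at a time)", "")
  for (m in unique(mod$moderator)) {
    key <- paste0("moderator_", m)
    wt <- fits[[key]]$interaction_wald
    lines <- c(lines, sprintf("### %s", m),
               sprintf("Arm-by-%s interaction: Wald chi-square = %s, df = %d, p %s",
                       m, fmt(wt$statistic, 2), wt$df,
                       ifelse(wt$p < 0.001, "< 0.001", paste0("= ", fmt(wt$p)))))
    sm <- mod[mod$moderator == m, ]
    lines <- c(lines, sprintf("- %s / %s: mean WOA %s [%s, %s] (n = %d)",
                              sm$level, sm$arm, fmt(sm$mean), fmt(sm$ci_lo),
                              fmt(sm$ci_hi), sm$n), "")
  }

  if (!is.null(fits$ordinal_sensitivity)) {
    os <- fits$ordinal_sensitivity
    b <- os$coefficients$estimate[os$coefficients$term == "armclinician"]
    concord <- sign(b) == sign(ad$estimate)
    lines <- c(lines, "## Ordinal sensitivity analysis",
               sprintf(paste0("Multilevel proportional-odds arm coefficient: ",
                              "%s (sigma_u^2 = %s); %s the primary analysis ",
                              "in direction."),
                       fmt(b), fmt(os$sigma_u2),
                       if (concord) "confirms" else "CONTRADICTS"), "")
  }

  bad <- names(fits)[!vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(bad)) {
    lines <- c(lines, "## WARNINGS",
               sprintf("- fit `%s` did NOT converge", bad), "")
  }
  writeLines(lines, file)
  invisible(structure(file, lines = lines))
}
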