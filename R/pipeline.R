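# End-to-end orchestration: simulate -> elicit -> fit -> audit ->
# group stats -> VLSM -> report.

#' Run configuration for a full simulated experiment
#'
#' @param cohort A \code{\link{cohort_config}}.
#' @param design A \code{\link{session_design}}.
#' @param vlsm A \code{\link{vlsm_config}}.
#' @param output_dir Directory for CSV/JSON outputs; \code{NULL} keeps the
#'   bundle in memory only.
#' @param seed Master seed. It deterministically spawns per-subject seeds,
#'   so a fixed seed makes the whole run reproducible.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(), design = session_design(),
                       vlsm = vlsm_config(), output_dir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(design, "session_design"),
            inherits(vlsm, "vlsm_config"))
  check_scalar(seed, "seed")
  structure(list(cohort = cohort, design = design, vlsm = vlsm,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

fit_row <- function(subject_id, condition, curve) {
  hyp <- fit_discount_model(curve, "hyperbolic")
  exo <- fit_discount_model(curve, "exponential")
  auc <- compute_auc(curve)$auc
  data.frame(
    subject_id = subject_id, condition = condition,
    model = c("hyperbolic", "exponential"),
    k = c(hyp$k, exo$k), log10_k = c(hyp$log10_k, exo$log10_k),
    r_squared = c(hyp$r_squared, exo$r_squared),
    converged = c(hyp$converged, exo$converged),
    auc = auc,
    half_value_days = c(half_value_delay(hyp$k, "hyperbolic"),
                        half_value_delay(exo$k, "exponential")),
    stringsAsFactors = FALSE)
}

#' Run the full simulated experiment
#'
#' Samples a cohort, runs every subject through the staircase session,
#' fits hyperbolic and exponential discount functions and computes AUC per
#' condition, audits choice consistency, runs the group-level ANOVAs
#' (log10 k, AUC, and the hyperbolic-vs-exponential R-squared model
#' comparison) with Fisher LSD post hocs and KS normality screens, and
#' maps lesion-behavior associations with four VLSM analyses (log10 k and
#' AUC, Now and Not-now) over the patients that carry lesion masks.
#'
#' When \code{output_dir} is set, stage outputs are written as
#' self-describing CSV/JSON files (cohort manifest, trials, curves, fits,
#' consistency report, group-stats JSON, per-analysis cluster tables,
#' per-subject mask coordinate files, and a group x condition summary of
#' geometric-mean k and mean AUC).
#'
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{td_experiment}: list with
#'   \code{cohort}, \code{sessions}, \code{curves_df}, \code{fits},
#'   \code{consistency}, \code{group_stats}, \code{vlsm} (list of four
#'   \code{\link{vlsm_result}}s, or NULL without patients), and
#'   \code{summary} (group x condition table).
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  n_groups_total <- sum(config$cohort$groups$n)
  seeds <- spawn_seeds(config$seed, n_groups_total + 1L)
  cohort <- sample_cohort(config$cohort, seed = seeds[1L])
  n <- nrow(cohort$subjects)
  subj_seeds <- seeds[-1L]

  sessions <- vector("list", n)
  fit_rows <- vector("list", n)
  cons_rows <- vector("list", n)
  curve_rows <- vector("list", n)
  trial_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subj_seeds[i])
    ses <- run_session(cohort$agents[[i]], config$design)
    sessions[[i]] <- ses
    sid <- cohort$subjects$subject_id[i]
    fit_rows[[i]] <- rbind(fit_row(sid, "now", ses$curves$now),
                           fit_row(sid, "notnow", ses$curves$notnow))
    cons_rows[[i]] <- do.call(rbind, lapply(c("now", "notnow"), function(cn) {
      cv <- ses$curves[[cn]]
      data.frame(subject_id = sid, condition = cn,
                 n_lenient = count_inconsistencies(cv, "lenient"),
                 n_strict = count_inconsistencies(cv, "strict"),
                 heuristic = detect_heuristic(ses$trials),
                 control_pass_immediate = unname(ses$control_pass["immediate"]),
                 control_pass_delayed = unname(ses$control_pass["delayed"]),
                 stringsAsFactors = FALSE)
    }))
    curve_rows[[i]] <- do.call(rbind, lapply(c("now", "notnow"),
                                             function(cn) {
      cv <- ses$curves[[cn]]
      data.frame(subject_id = sid, condition = cn,
                 delay_gap = cv$delay_gap, sv_estimate = cv$sv,
                 stringsAsFactors = FALSE)
    }))
    tr <- ses$trials
    tr$subject_id <- sid
    trial_rows[[i]] <- tr[, c("subject_id", setdiff(names(tr),
                                                    "subject_id"))]
  }
  fits <- do.call(rbind, fit_rows)
  consistency <- do.call(rbind, cons_rows)
  curves_df <- do.call(rbind, curve_rows)
  trials_df <- do.call(rbind, trial_rows)

  # --- group statistics on the hyperbolic fits and AUC ---
  hyp <- fits[fits$model == "hyperbolic", ]
  wide <- function(col) {
    now <- hyp[hyp$condition == "now", c("subject_id", col)]
    nn <- hyp[hyp$condition == "notnow", c("subject_id", col)]
    m <- merge(now, nn, by = "subject_id", suffixes = c("_now", "_notnow"))
    m <- m[match(cohort$subjects$subject_id, m$subject_id), ]
    out <- as.matrix(m[, -1L])
    colnames(out) <- c("now", "notnow")
    out
  }
  group <- cohort$subjects$group
  logk_tab <- wide("log10_k")
  auc_tab <- wide("auc")
  anova_logk <- mixed_anova(logk_tab, group)
  anova_auc <- mixed_anova(auc_tab, group)
  # model comparison: R2 averaged over conditions, hyperbolic vs exponential
  r2_by <- function(mod) {
    sub <- fits[fits$model == mod, ]
    tapply(sub$r_squared, sub$subject_id, mean)[
      cohort$subjects$subject_id]
  }
  r2_tab <- cbind(hyperbolic = r2_by("hyperbolic"),
                  exponential = r2_by("exponential"))
  anova_r2 <- mixed_anova(r2_tab, group)
  glabels <- unique(group)
  pairs <- utils::combn(glabels, 2L, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    a <- fisher_lsd(anova_logk, pr, "group")
    b <- fisher_lsd(anova_auc, pr, "group")
    data.frame(pair = paste(pr, collapse = " vs "),
               diff_log10_k = a$estimate, p_log10_k = a$p,
               diff_auc = b$estimate, p_auc = b$p,
               stringsAsFactors = FALSE)
  }))
  ks <- do.call(rbind, lapply(glabels, function(gl) {
    do.call(rbind, lapply(c("now", "notnow"), function(cn) {
      v <- hyp$log10_k[hyp$condition == cn &
                         group[match(hyp$subject_id,
                                     cohort$subjects$subject_id)] == gl]
      res <- if (length(v) >= 5L && stats::sd(v) > 0) ks_normality(v)
      else list(d = NA_real_, p = NA_real_)
      data.frame(group = gl, condition = cn, d = res$d, p = res$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  group_stats <- list(anova_log10_k = anova_logk, anova_auc = anova_auc,
                      anova_r_squared = anova_r2, posthoc = posthoc,
                      ks_log10_k = ks)

  # --- VLSM over the lesioned patients, four separate analyses ---
  has_mask <- !vapply(cohort$masks, is.null, TRUE)
  vlsm <- NULL
  if (sum(has_mask) >= 4L) {
    masks <- cohort$masks[has_mask]
    score_of <- function(tab, cn) tab[has_mask, cn]
    vlsm <- list(
      log10_k_now = run_vlsm(masks, score_of(logk_tab, "now"),
                             config$vlsm),
      log10_k_notnow = run_vlsm(masks, score_of(logk_tab, "notnow"),
                                config$vlsm),
      auc_now = run_vlsm(masks, score_of(auc_tab, "now"), config$vlsm),
      auc_notnow = run_vlsm(masks, score_of(auc_tab, "notnow"),
                            config$vlsm))
  }

  # --- summary table: the group x condition figure analogue ---
  summary_tab <- do.call(rbind, lapply(glabels, function(gl) {
    do.call(rbind, lapply(c("now", "notnow"), function(cn) {
      sel <- hyp$condition == cn &
        group[match(hyp$subject_id, cohort$subjects$subject_id)] == gl
      data.frame(group = gl, condition = cn,
                 geometric_mean_k = summarize_k(hyp$k[sel])$geometric_mean,
                 mean_log10_k = mean(hyp$log10_k[sel]),
                 mean_auc = mean(hyp$auc[sel]),
                 mean_half_value_days = mean(hyp$half_value_days[sel]),
                 stringsAsFactors = FALSE)
    }))
  }))

  bundle <- structure(
    list(cohort = cohort, sessions = sessions, trials = trials_df,
         curves_df = curves_df, fits = fits, consistency = consistency,
         group_stats = group_stats, vlsm = vlsm, summary = summary_tab,
         config = config),
    class = "td_experiment")
  if (!is.null(config$output_dir)) write_experiment(bundle)
  bundle
}

#' @export
print.td_experiment <- function(x, ...) {
  cat(sprintf("<td_experiment> %d subjects, seed %d\n",
              nrow(x$cohort$subjects), x$config$seed))
  cat("\nGroup x condition summary (hyperbolic fits):\n")
  s <- x$summary
  s$geometric_mean_k <- signif(s$geometric_mean_k, 3)
  s$mean_log10_k <- round(s$mean_log10_k, 2)
  s$mean_auc <- round(s$mean_auc, 3)
  s$mean_half_value_days <- round(s$mean_half_value_days, 1)
  print(s, row.names = FALSE)
  cat("\nANOVA on log10 k:\n")
  print(x$group_stats$anova_log10_k)
  invisible(x)
}

effects_list <- function(an) {
  list(effects = an$effects, cell_means = as.data.frame(an$cell_means),
       mse_between = an$mse_between, mse_within = an$mse_within,
       ss_type = an$ss_type)
}

#' Write a run's outputs to its configured directory
#'
#' @param bundle A \code{td_experiment}.
#' @param dir Output directory (defaults to the one in the run config).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(bundle, dir = bundle$config$output_dir) {
  stopifnot(inherits(bundle, "td_experiment"), !is.null(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  manifest <- bundle$cohort$subjects
  has_mask <- !vapply(bundle$cohort$masks, is.null, TRUE)
  manifest$mask_path <- ifelse(
    has_mask, file.path("masks", paste0(manifest$subject_id, ".csv")), "")
  wcsv(manifest, "manifest.csv")
  if (any(has_mask)) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (i in which(has_mask))
      write_mask_csv(bundle$cohort$masks[[i]],
                     file.path(dir, "masks",
                               paste0(manifest$subject_id[i], ".csv")))
  }
  wcsv(bundle$trials, "trials.csv")
  wcsv(bundle$curves_df, "curves.csv")
  wcsv(bundle$fits, "fits.csv")
  wcsv(bundle$consistency, "consistency.csv")
  wcsv(bundle$summary, "summary.csv")
  gs <- bundle$group_stats
  jsonlite::write_json(
    list(anova_log10_k = effects_list(gs$anova_log10_k),
         anova_auc = effects_list(gs$anova_auc),
         anova_r_squared = effects_list(gs$anova_r_squared),
         posthoc = gs$posthoc, ks_log10_k = gs$ks_log10_k),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  if (!is.null(bundle$vlsm)) {
    for (nm in names(bundle$vlsm)) {
      res <- bundle$vlsm[[nm]]
      wcsv(res$clusters, sprintf("clusters_%s.csv", nm))
    }
  }
  invisible(dir)
}
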