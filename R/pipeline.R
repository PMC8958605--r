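pkg_version <- function() {
  as.character(utils::packageVersion("iodoscreen"))
}

# md5 of a file, NA when absent
file_digest <- function(path) {
  if (is.character(path) && length(path) == 1 && file.exists(path)) {
    unname(tools::md5sum(path))
  } else {
    NA_character_
  }
}

#' Run the primary-screen stage end to end
#'
#' Validates the plate layout, scores the screen (normalization chain,
#' DeltaYFP, per-plate Z-prime), calls hits, and assembles a reproducibility
#' manifest (config snapshot, input digest, seed, per-stage counts,
#' timestamps).
#'
#' @param screen path to a screen CSV or an in-memory kinetic well data
#'   frame.
#' @param config a [screen_config].
#' @param qc_required if TRUE, fail (error) when any plate's Z-prime is at
#'   or below `config$zprime_floor`.
#' @param quiet suppress INFO logging.
#' @return list of class `screen_run`: `scores` ([score_screen] output),
#'   `hits` (ranked drug table), `layout_findings`, `manifest`.
#' @export
run_primary_screen <- function(screen, config = screen_config(),
                               qc_required = FALSE, quiet = FALSE) {
  t0 <- Sys.time()
  input_digest <- file_digest(screen)
  wells <- if (is.character(screen)) read_screen(screen, quiet = quiet) else screen
  if (!"analyzable" %in% names(wells)) {
    wells <- as_kinetic_wells(wells, quiet = TRUE)
  }

  findings <- validate_layout(wells)
  fatal <- grepl("uncomputable|undefined", findings$finding)
  if (any(fatal)) {
    stop("run_primary_screen: screen fails validation: ",
         paste(findings$finding[fatal], collapse = "; "))
  }

  scores <- score_screen(wells, config, quiet = quiet)
  hits <- call_hits(scores)

  if (qc_required) {
    bad <- scores$qc$plate_id[!is.na(scores$qc$z_factor) &
                                scores$qc$z_factor <= config$zprime_floor]
    undef <- scores$qc$plate_id[is.na(scores$qc$z_factor)]
    if (length(bad) || length(undef)) {
      stop("run_primary_screen: QC failure, plate(s) with Z-prime <= ",
           config$zprime_floor, ": ",
           paste(c(bad, undef), collapse = ", "))
    }
  }

  manifest <- list(
    tool_version = pkg_version(),
    config = unclass(config),
    input = if (is.character(screen)) screen else "<memory>",
    input_md5 = input_digest,
    seed = config$rng_seed,
    counts = list(wells_in = nrow(wells),
                  wells_analyzable = sum(wells$analyzable),
                  wells_excluded = nrow(attr(wells, "exclusions")),
                  drug_wells = sum(wells$role == "DRUG"),
                  dmso_wells = scores$stats$n_dmso,
                  hits = sum(hits$hit)),
    layout_findings = nrow(findings),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(scores = scores, hits = hits,
                 layout_findings = findings, manifest = manifest),
            class = "screen_run")
}

#' Write a run manifest as JSON
#' @param manifest the `manifest` element of a pipeline run.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Full synthetic study: screen, dose-response, uptake, risk model
#'
#' Generates a complete synthetic study from one root seed and runs every
#' analysis stage: primary-screen scoring and hit calling, secondary
#' dose-response with delta-AUC against a symporter-free reporter line and
#' 4PL EC50, radioiodide uptake fold change with perchlorate specificity,
#' and the multi-gene Cox recurrence risk score with Kaplan-Meier
#' stratification and covariate-adjusted multivariate fit.
#'
#' @param seed root RNG seed; every stage's seed derives from it.
#' @param screen_spec,cohort_spec optional overrides of the generator
#'   specifications (their `seed` fields are replaced by derivations of
#'   `seed`).
#' @param quiet suppress per-stage logging.
#' @return list of class `e2e_report` with per-stage results and a
#'   combined manifest; `print` gives the human-readable summary.
#' @export
run_end_to_end_demo <- function(seed = 1L,
                                screen_spec = NULL,
                                cohort_spec = NULL,
                                quiet = TRUE) {
  seed <- as.integer(seed)
  t0 <- Sys.time()

  # --- primary screen ---
  if (is.null(screen_spec)) screen_spec <- screen_sim_spec(seed = seed)
  screen_spec$seed <- seed
  sim <- simulate_screen(screen_spec)
  config <- screen_config(rng_seed = seed)
  run <- run_primary_screen(sim$wells, config, quiet = quiet)
  hits <- run$hits

  # --- secondary dose-response for the top hits ---
  top <- utils::head(hits$drug_id[hits$hit], 3)
  truth4pl <- four_pl_params(bottom = 0, top = 3, ec50 = 1.8, hill = 1.2)
  dr <- lapply(seq_along(top), function(i) {
    nis <- simulate_dose_response(truth4pl, noise_cv = 0.05,
                                  seed = seed + 100 + i)
    ctl <- simulate_dose_response(truth4pl, noise_cv = 0.05,
                                  seed = seed + 200 + i, control = TRUE)
    nis_curve <- dose_response_curve(top[i], "NIS_YFP",
                                     nis$dose_uM, nis$response)
    ctl_curve <- dose_response_curve(top[i], "YFP_ONLY",
                                     ctl$dose_uM, ctl$response)
    fit <- fit_ec50(nis$dose_uM, nis$response)
    data.frame(drug_id = top[i], auc_nis = nis_curve$auc,
               auc_control = ctl_curve$auc,
               delta_auc = delta_auc(nis_curve, ctl_curve),
               ec50 = fit$ec50, fit_ok = fit$fit_ok,
               stringsAsFactors = FALSE)
  })
  dr <- do.call(rbind, dr)

  # --- radioiodide uptake for the lead drug ---
  upt <- simulate_uptake(n_replicates = 6, true_fold = 4.3,
                         vehicle_pmol = 1.2, seed = seed + 300)
  fold <- fold_uptake(upt[upt$condition == "treated", ],
                      upt[upt$condition == "vehicle", ])
  spec_check <- nis_specificity_check(
    upt[upt$condition == "treated_perchlorate", ],
    upt[upt$condition == "treated", ])

  # --- recurrence risk model on a synthetic cohort ---
  if (is.null(cohort_spec)) {
    cohort_spec <- cohort_sim_spec(n_patients = 600, seed = seed + 400)
  }
  cohort_spec$seed <- seed + 400
  cs <- simulate_cohort(cohort_spec)
  model <- build_risk_model(cs$cohort, cohort_spec$genes)
  strat <- stratify_by_risk(model, cs$cohort)
  adj <- multivariate_adjusted(
    risk_group = risk_score(model, cs$cohort) > model$group_cutoff,
    covariates = cs$cohort[c("age", "gender", "disease_stage",
                             "tumor_stage", "node_status")],
    time = cs$cohort$time, event = cs$cohort$event)

  manifest <- list(tool_version = pkg_version(), seed = seed,
                   screen = run$manifest$counts,
                   cohort = list(n_patients = cohort_spec$n_patients,
                                 n_genes = cohort_spec$n_genes,
                                 n_events = sum(cs$cohort$event)),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(screen = run, hits = hits, truth = sim$truth,
                 dose_response = dr, uptake_fold = fold,
                 uptake_specificity = spec_check,
                 risk_model = model, stratification = strat,
                 adjusted_fit = adj, manifest = manifest),
            class = "e2e_report")
}

#' @export
print.e2e_report <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic YFP-iodide screen study (seed ", m$seed, ")\n", sep = "")
  cat(sprintf("  Primary screen : %d wells, %d drug wells, %d hits\n",
              m$screen$wells_in, m$screen$drug_wells, m$screen$hits))
  qc <- x$screen$scores$qc
  cat(sprintf("  QC             : median plate Z' = %.3f (floor 0.5)\n",
              stats::median(qc$z_factor, na.rm = TRUE)))
  cat("  Top hits:\n")
  top <- utils::head(x$hits[x$hits$hit, c("drug_id", "delta_yfp",
                                          "viability")], 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-10s DeltaYFP %6.2f  viability %.2f\n",
                top$drug_id[i], top$delta_yfp[i], top$viability[i]))
  }
  if (nrow(x$dose_response)) {
    cat("  Dose-response (secondary screen):\n")
    for (i in seq_len(nrow(x$dose_response))) {
      d <- x$dose_response[i, ]
      cat(sprintf("    %-10s deltaAUC %5.2f  EC50 %s uM\n", d$drug_id,
                  d$delta_auc,
                  if (d$fit_ok) sprintf("%.2f", d$ec50) else "n/a"))
    }
  }
  cat(sprintf("  Radioiodide    : fold uptake %.2f +/- %.2f (%s)\n",
              x$uptake_fold$fold, x$uptake_fold$sem,
              if (x$uptake_specificity$nis_specific) {
                "NIS-specific"
              } else {
                "not NIS-specific"
              }))
  cat(sprintf("  Risk model     : %d genes, score AUC %.3f\n",
              length(x$risk_model$genes), x$risk_model$auc))
  hr <- x$stratification$hr_fit
  cat(sprintf("  Stratification : high vs low HR %.2f (95%% CI %.2f-%.2f), log-rank p %.3g\n",
              hr$hr[1], hr$ci_low[1], hr$ci_high[1],
              x$stratification$logrank_p))
  invisible(x)
}
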