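#' Specification of a synthetic primary screen
#'
#' Defines the study conditions emulated by [simulate_screen]: a
#' ~1200-compound single-dose screen on 96-well plates (80 drug wells per
#' plate, columns 2-11), NaI-positive and PBS-negative controls in column
#' 1, DMSO vehicle controls in column 12 (120 DMSO wells screen-wide by
#' default). Fluorescence carries multiplicative log-normal plate and
#' well-position effects plus multiplicative read noise — exactly the
#' artefact structure the ratio normalizations of the scoring chain are
#' designed to remove. Every cell well that receives the 4 mM NaI
#' injection quenches at a baseline level through basal symporter
#' activity; active drugs add extra quench on top, PBS-negative wells
#' (no iodide) do not quench at all.
#'
#' @param n_plates number of 96-well plates (15 plates x 80 drugs = 1200
#'   compounds).
#' @param wells_per_plate fixed at 96.
#' @param n_dmso_total total DMSO vehicle wells across the screen; must
#'   divide evenly over plates with at most 8 per plate (column 12).
#' @param baseline_fluor mean pre-injection fluorescence (a.u.).
#' @param baseline_quench fractional quench of DMSO/null wells from the
#'   4 mM NaI injection via basal symporter activity.
#' @param plate_effect_sd,wellpos_effect_sd SDs (log scale) of the
#'   multiplicative log-normal plate and well-position effects.
#' @param noise_cv coefficient of variation of multiplicative read noise,
#'   independent per reading.
#' @param active_fraction fraction of drugs that truly increase iodide
#'   influx.
#' @param active_quench_range range of *extra* fractional quench (above
#'   baseline) for true actives, drawn uniformly.
#' @param control_quench fractional quench of the 34 mM NaI positive wells.
#' @param toxic_fraction fraction of drugs that are cytotoxic.
#' @param toxic_viability_range viability range for toxic drugs.
#' @param viability_cv replicate noise on non-toxic viability around 1.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (spec, seed).
#' @return list of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_plates = 15,
                            wells_per_plate = 96,
                            n_dmso_total = 120,
                            baseline_fluor = 50000,
                            baseline_quench = 0.30,
                            plate_effect_sd = 0.15,
                            wellpos_effect_sd = 0.08,
                            noise_cv = 0.05,
                            active_fraction = 0.08,
                            active_quench_range = c(0.30, 0.55),
                            control_quench = 0.85,
                            toxic_fraction = 0.08,
                            toxic_viability_range = c(0.10, 0.50),
                            viability_cv = 0.05,
                            seed = 1L) {
  stopifnot(wells_per_plate == 96,
            n_plates >= 1,
            active_fraction >= 0, active_fraction <= 1,
            toxic_fraction >= 0, toxic_fraction <= 1,
            baseline_quench >= 0, baseline_quench <= 1,
            control_quench >= 0, control_quench <= 1,
            all(active_quench_range >= 0), all(active_quench_range <= 1),
            noise_cv >= 0)
  if (n_dmso_total %% n_plates != 0 || n_dmso_total / n_plates > 8) {
    stop("screen_sim_spec: n_dmso_total must divide evenly over plates ",
         "with at most 8 DMSO wells per plate (column 12)")
  }
  structure(as.list(environment()), class = "screen_sim_spec")
}

#' Simulate a primary YFP-iodide screen with known ground truth
#'
#' @param spec a [screen_sim_spec].
#' @return list of class `simulated_screen`: `wells` (kinetic well data
#'   frame, directly scoreable and writable via [write_screen]) and
#'   `truth` (per drug: extra quench, activity and toxicity flags, true
#'   viability).
#' @export
simulate_screen <- function(spec = screen_sim_spec()) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  set.seed(spec$seed)

  dmso_per_plate <- spec$n_dmso_total / spec$n_plates
  n_drugs <- spec$n_plates * 80
  drug_ids <- sprintf("DRUG%04d", seq_len(n_drugs))

  is_active <- stats::runif(n_drugs) < spec$active_fraction
  q_extra <- ifelse(is_active,
                    stats::runif(n_drugs, spec$active_quench_range[1],
                                 spec$active_quench_range[2]),
                    0)
  is_toxic <- stats::runif(n_drugs) < spec$toxic_fraction
  viab <- ifelse(is_toxic,
                 stats::runif(n_drugs, spec$toxic_viability_range[1],
                              spec$toxic_viability_range[2]),
                 pmax(0, 1 + stats::rnorm(n_drugs, 0, spec$viability_cv)))

  truth <- data.frame(drug_id = drug_ids, quench_extra = q_extra,
                      is_active = is_active, is_toxic = is_toxic,
                      viability_true = viab, stringsAsFactors = FALSE)

  plate_ids <- sprintf("P%02d", seq_len(spec$n_plates))
  plate_eff <- stats::setNames(
    exp(stats::rnorm(spec$n_plates, 0, spec$plate_effect_sd)), plate_ids)
  positions <- as.vector(outer(PLATE_ROWS, PLATE_COLS, format_well))
  pos_eff <- stats::setNames(
    exp(stats::rnorm(length(positions), 0, spec$wellpos_effect_sd)),
    positions)

  rows_list <- vector("list", spec$n_plates)
  drug_i <- 0L
  for (pi in seq_len(spec$n_plates)) {
    # layout: col 1 = controls (A-D NaI, E-H PBS); col 12 = DMSO; 2-11 drugs
    well <- character(96); role <- character(96)
    drug <- rep(NA_character_, 96); dose <- rep(NA_real_, 96)
    q <- numeric(96); v <- rep(NA_real_, 96)
    k <- 0L
    for (col in PLATE_COLS) {
      for (rw in PLATE_ROWS) {
        k <- k + 1L
        well[k] <- format_well(rw, col)
        if (col == 1) {
          if (rw %in% c("A", "B", "C", "D")) {
            role[k] <- "NAI_POSITIVE"; q[k] <- spec$control_quench
          } else {
            role[k] <- "PBS_NEGATIVE"; q[k] <- 0
          }
          v[k] <- 1
        } else if (col == 12) {
          if (match(rw, PLATE_ROWS) <= dmso_per_plate) {
            role[k] <- "DMSO_CONTROL"; q[k] <- spec$baseline_quench
            v[k] <- 1
          } else {
            role[k] <- "PBS_NEGATIVE"; q[k] <- 0; v[k] <- 1
          }
        } else {
          drug_i <- drug_i + 1L
          role[k] <- "DRUG"; drug[k] <- drug_ids[drug_i]
          dose[k] <- 10
          q[k] <- min(spec$baseline_quench + q_extra[drug_i], 0.98)
          v[k] <- viab[drug_i]
        }
      }
    }
    pe <- plate_eff[pi]
    we <- pos_eff[well]
    yfp0 <- spec$baseline_fluor * pe * we *
      (1 + stats::rnorm(96, 0, spec$noise_cv))
    cyc <- sapply(1:4, function(cycle) {
      yfp0 * (1 - q * cycle / 4) * (1 + stats::rnorm(96, 0, spec$noise_cv))
    })
    rows_list[[pi]] <- data.frame(
      plate_id = plate_ids[pi], well = well, role = role, drug_id = drug,
      dose_uM = dose, yfp0 = yfp0, yfp_c1 = cyc[, 1], yfp_c2 = cyc[, 2],
      yfp_c3 = cyc[, 3], yfp_c4 = cyc[, 4], viability = v,
      stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, rows_list)
  rownames(wells) <- NULL
  wells <- as_kinetic_wells(wells, source = "<simulated>", quiet = TRUE)
  structure(list(wells = wells, truth = truth, spec = spec),
            class = "simulated_screen")
}

#' Four-parameter logistic curve parameters
#'
#' @param bottom,top asymptotic responses (top >= bottom not enforced so
#'   descending curves can be represented with hill of either sign).
#' @param ec50 half-maximal concentration (same units as dose, > 0).
#' @param hill slope factor.
#' @return list of class `four_pl_params`.
#' @export
four_pl_params <- function(bottom, top, ec50, hill) {
  stopifnot(is.finite(ec50), ec50 > 0)
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill),
            class = "four_pl_params")
}

#' Evaluate a four-parameter logistic at given doses
#' @param dose dose vector (> 0).
#' @param params a [four_pl_params].
#' @return `bottom + (top - bottom) / (1 + (ec50 / dose)^hill)`.
#' @export
four_pl <- function(dose, params) {
  with(params, bottom + (top - bottom) / (1 + (ec50 / dose)^hill))
}

#' Simulate a dose-response series from a 4PL ground truth
#'
#' Multiplicative Gaussian noise on the 4PL response. With
#' `control = TRUE` a paired flat series (top = bottom) is generated, the
#' shape expected in a reporter line without the symporter.
#'
#' @param params true [four_pl_params].
#' @param doses dose vector, all > 0 (default the secondary screen's 10
#'   doses spanning 0.1-50 uM).
#' @param noise_cv multiplicative noise CV.
#' @param seed RNG seed.
#' @param control if TRUE, responses are flat at `bottom`.
#' @return data frame: `dose_uM`, `response`.
#' @export
simulate_dose_response <- function(params,
                                   doses = c(0.1, 0.25, 0.5, 1, 2.5, 5,
                                             10, 20, 35, 50),
                                   noise_cv = 0.05, seed = 1L,
                                   control = FALSE) {
  stopifnot(inherits(params, "four_pl_params"), all(doses > 0))
  set.seed(seed)
  mu <- if (control) rep(params$bottom, length(doses)) else four_pl(doses, params)
  data.frame(dose_uM = doses,
             response = mu * (1 + stats::rnorm(length(doses), 0, noise_cv)))
}

#' Simulate a radioiodide uptake experiment
#'
#' Generates gamma-counter rows (counts per minute + total protein) whose
#' picomoles-per-microgram values center on `vehicle_pmol` for vehicle
#' wells and `vehicle_pmol * true_fold` for treated wells, with
#' multiplicative replicate noise. Perchlorate-pretreated replicates are
#' generated at a background fraction of vehicle, emulating competitive
#' symporter blockade.
#'
#' @param n_replicates replicates per arm.
#' @param true_fold true fold increase of treated over vehicle (> 0).
#' @param vehicle_pmol vehicle-arm picomoles 125-I per microgram protein.
#' @param protein_range total protein (ug) drawn uniformly per replicate.
#' @param noise_cv replicate CV.
#' @param background_frac perchlorate-arm level as a fraction of vehicle.
#' @param seed RNG seed.
#' @return data frame: sample_id, condition (vehicle / treated /
#'   treated_perchlorate), counts, total_protein, picomoles_per_ug,
#'   perchlorate_treated.
#' @export
simulate_uptake <- function(n_replicates = 3, true_fold = 1,
                            vehicle_pmol = 1,
                            protein_range = c(50, 200),
                            noise_cv = 0.05, background_frac = 0.05,
                            seed = 1L) {
  stopifnot(true_fold > 0, n_replicates >= 1)
  set.seed(seed)
  arm <- function(condition, level, perchlorate) {
    protein <- stats::runif(n_replicates, protein_range[1], protein_range[2])
    pmol <- level * (1 + stats::rnorm(n_replicates, 0, noise_cv))
    pmol <- pmax(pmol, 0)
    counts <- pmol * protein * 12000 / 5000
    data.frame(sample_id = paste0(condition, "_", seq_len(n_replicates)),
               condition = condition, counts = counts,
               total_protein = protein,
               picomoles_per_ug = picomoles_per_ug(counts, protein),
               perchlorate_treated = perchlorate,
               stringsAsFactors = FALSE)
  }
  rbind(arm("vehicle", vehicle_pmol, FALSE),
        arm("treated", vehicle_pmol * true_fold, FALSE),
        arm("treated_perchlorate", vehicle_pmol * background_frac, TRUE))
}

#' Specification of a synthetic survival cohort
#'
#' Emulates the structure of an expression + recurrence cohort: log-normal
#' FPKM expression for a gene panel, exponential event times whose hazard
#' is log-linear in the log2(FPKM + 1) expression of a known causal subset,
#' independent exponential censoring tuned to an approximate censoring
#' rate, and the usual clinical covariates.
#'
#' @param n_patients cohort size.
#' @param n_genes panel size (genes named GENE01, GENE02, ...).
#' @param causal_beta named numeric vector of true log-hazard coefficients
#'   per unit log2(FPKM + 1); names must be members of the panel.
#' @param baseline_hazard events per time unit at zero linear predictor.
#' @param censoring_rate approximate fraction censored, in [0, 1).
#' @param age_effect,stage_effect optional log-hazard effects of age
#'   (per year, centered) and of advanced disease stage.
#' @param expr_meanlog,expr_sdlog log-normal FPKM parameters.
#' @param seed RNG seed.
#' @return list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 1500,
                            n_genes = 13,
                            causal_beta = c(GENE01 = 0.60, GENE02 = 0.45,
                                            GENE03 = -0.50),
                            baseline_hazard = 0.02,
                            censoring_rate = 0.30,
                            age_effect = 0,
                            stage_effect = 0,
                            expr_meanlog = 2,
                            expr_sdlog = 0.8,
                            seed = 1L) {
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  stopifnot(all(names(causal_beta) %in% genes),
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0)
  structure(c(as.list(environment()), list(genes = genes)),
            class = "cohort_sim_spec")
}

#' Simulate an expression + recurrence cohort with known effects
#'
#' @param spec a [cohort_sim_spec].
#' @param max_retries degenerate (all-censored or all-event) draws are
#'   regenerated with a warning, at most this many times.
#' @return list of class `simulated_cohort`: `cohort` (patient_id, raw
#'   FPKM gene columns, time, event, age, gender, disease_stage,
#'   tumor_stage, node_status, rai_treated, braf_like) and `truth` (the
#'   full beta vector over the panel).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec(), max_retries = 5) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  beta <- stats::setNames(numeric(length(spec$genes)), spec$genes)
  beta[names(spec$causal_beta)] <- spec$causal_beta

  for (attempt in 0:max_retries) {
    set.seed(spec$seed + attempt)
    n <- spec$n_patients
    fpkm <- matrix(stats::rlnorm(n * length(spec$genes),
                                 spec$expr_meanlog, spec$expr_sdlog),
                   nrow = n, dimnames = list(NULL, spec$genes))
    x <- log2(fpkm + 1)

    age <- round(stats::rnorm(n, 48, 12))
    gender <- sample(c("female", "male"), n, replace = TRUE,
                     prob = c(0.73, 0.27))
    disease_stage <- sample(paste0("Stage", c("I", "II", "III", "IV")), n,
                            replace = TRUE, prob = c(0.55, 0.1, 0.2, 0.15))
    tumor_stage <- sample(paste0("T", 1:4), n, replace = TRUE,
                          prob = c(0.3, 0.35, 0.25, 0.1))
    node_status <- sample(c("N0", "N1"), n, replace = TRUE,
                          prob = c(0.55, 0.45))
    advanced <- disease_stage %in% c("StageIII", "StageIV")

    lp <- drop(x %*% beta) +
      spec$age_effect * (age - mean(age)) +
      spec$stage_effect * advanced
    lp <- lp - mean(lp)              # baseline_hazard is the typical hazard
    hazard <- spec$baseline_hazard * exp(lp)
    event_time <- stats::rexp(n, rate = hazard)

    if (spec$censoring_rate > 0) {
      cens_rate <- mean(hazard) *
        spec$censoring_rate / (1 - spec$censoring_rate)
      cens_time <- stats::rexp(n, rate = cens_rate)
    } else {
      cens_time <- rep(Inf, n)
    }
    event <- event_time <= cens_time
    time <- pmin(event_time, cens_time)

    if (any(event) && !all(event)) break
    if (attempt == max_retries) {
      stop("simulate_cohort: degenerate cohort after ", max_retries,
           " retries")
    }
    warning("simulate_cohort: degenerate draw (all censored or all events), retrying")
  }

  cohort <- data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
                       fpkm, time = time, event = event, age = age,
                       gender = gender, disease_stage = disease_stage,
                       tumor_stage = tumor_stage, node_status = node_status,
                       rai_treated = TRUE, braf_like = TRUE,
                       stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = beta, spec = spec),
            class = "simulated_cohort")
}
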