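#' Construct a dose-response curve
#'
#' @param drug_id drug label.
#' @param cell_line one of "NIS_YFP", "YFP_ONLY", "OTHER".
#' @param doses strictly increasing positive doses (uM), length >= 2.
#' @param responses response per dose (DeltaYFP or fold uptake).
#' @return list of class `dose_response_curve` with the AUC of the
#'   positive part on the log10-dose axis precomputed.
#' @export
dose_response_curve <- function(drug_id, cell_line = c("NIS_YFP",
                                                       "YFP_ONLY", "OTHER"),
                                doses, responses) {
  cell_line <- match.arg(cell_line)
  stopifnot(length(doses) == length(responses), length(doses) >= 2,
            all(doses > 0), all(diff(doses) > 0))
  structure(list(drug_id = drug_id, cell_line = cell_line,
                 doses = doses, responses = responses,
                 auc = auc_positive_log_dose(doses, responses)),
            class = "dose_response_curve")
}

#' Area under the positive part of a dose-response curve on log10 dose
#'
#' Linearly interpolates the response against log10(dose), clips the curve
#' at zero from below ("positive peaks only") and integrates exactly,
#' splitting segments at their zero crossings. A curve that never rises
#' above zero has area 0.
#'
#' @param doses strictly increasing positive doses.
#' @param responses responses at those doses.
#' @param largest_peak_only if TRUE, integrate only the largest contiguous
#'   positive excursion instead of all positive area (off by default).
#' @return nonnegative area (response units x log10-dose units).
#' @export
auc_positive_log_dose <- function(doses, responses,
                                  largest_peak_only = FALSE) {
  if (length(doses) < 2) stop("auc_positive_log_dose: need >= 2 doses")
  stopifnot(length(doses) == length(responses), all(doses > 0),
            all(diff(doses) > 0), all(is.finite(responses)))
  x <- log10(doses)
  y <- responses
  seg_area <- numeric(length(x) - 1)
  for (i in seq_len(length(x) - 1)) {
    x0 <- x[i]; x1 <- x[i + 1]; y0 <- y[i]; y1 <- y[i + 1]
    if (y0 <= 0 && y1 <= 0) {
      a <- 0
    } else if (y0 >= 0 && y1 >= 0) {
      a <- (y0 + y1) / 2 * (x1 - x0)
    } else {
      xc <- x0 + (x1 - x0) * (0 - y0) / (y1 - y0)   # zero crossing
      a <- if (y0 > 0) y0 / 2 * (xc - x0) else y1 / 2 * (x1 - xc)
    }
    seg_area[i] <- a
  }
  if (!largest_peak_only) return(sum(seg_area))
  # group contiguous positive segments into excursions, return the largest
  pos <- seg_area > 0
  if (!any(pos)) return(0)
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  max(vapply(which(runs$values), function(r) {
    sum(seg_area[starts[r]:ends[r]])
  }, numeric(1)))
}

#' Difference in positive-peak AUC between symporter and control lines
#'
#' Isolates the symporter-specific component of a drug's quench response:
#' area in the NIS-expressing reporter line minus area in the NIS-free
#' line. Negative values indicate a non-specific fluorescence effect.
#'
#' @param nis_curve [dose_response_curve] for the NIS_YFP line.
#' @param control_curve [dose_response_curve] for the YFP_ONLY line, same
#'   drug.
#' @return AUC(NIS_YFP) - AUC(YFP_ONLY).
#' @export
delta_auc <- function(nis_curve, control_curve) {
  stopifnot(inherits(nis_curve, "dose_response_curve"),
            inherits(control_curve, "dose_response_curve"))
  if (!identical(nis_curve$drug_id, control_curve$drug_id)) {
    stop("delta_auc: curves are for different drugs (",
         nis_curve$drug_id, " vs ", control_curve$drug_id, ")")
  }
  nis_curve$auc - control_curve$auc
}

#' Fit a four-parameter logistic and report EC50
#'
#' Least-squares 4PL fit on log10 dose via Levenberg-Marquardt. The EC50 is
#' reported only when the fit converges with an EC50 inside
#' `[min(dose)/10, max(dose)*10]`; otherwise `fit_ok` is FALSE and no
#' exception is raised (an unidentifiable or flat curve is an expected
#' outcome, not an error).
#'
#' @param doses positive doses (>= 4 points).
#' @param responses responses at those doses.
#' @param model "4PL" (default) or "3PL" (bottom fixed at 0).
#' @return list: `params` ([four_pl_params] or NULL), `ec50`, `fit_ok`,
#'   `rss`.
#' @export
fit_ec50 <- function(doses, responses, model = c("4PL", "3PL")) {
  model <- match.arg(model)
  if (any(doses <= 0)) stop("fit_ec50: doses must be positive")
  if (length(doses) < 4) stop("fit_ec50: need >= 4 dose points")
  stopifnot(length(doses) == length(responses))
  failed <- list(params = NULL, ec50 = NA_real_, fit_ok = FALSE,
                 rss = NA_real_)
  if (stats::sd(responses) == 0) return(failed)

  lx <- log10(doses)
  df <- data.frame(lx = lx, y = responses)
  rng <- range(responses)
  # try ascending and descending slopes, keep the best converged fit
  fits <- list()
  for (h0 in c(1, -1)) {
    start <- if (model == "4PL") {
      list(bottom = rng[1], top = rng[2], lec50 = stats::median(lx),
           hill = h0)
    } else {
      list(top = rng[2], lec50 = stats::median(lx), hill = h0)
    }
    form <- if (model == "4PL") {
      y ~ bottom + (top - bottom) / (1 + 10^((lec50 - lx) * hill))
    } else {
      y ~ top / (1 + 10^((lec50 - lx) * hill))
    }
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) return(failed)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  ec50 <- 10^cf[["lec50"]]
  if (!is.finite(ec50) ||
      ec50 < min(doses) / 10 || ec50 > max(doses) * 10) {
    return(failed)
  }
  bottom <- if (model == "4PL") cf[["bottom"]] else 0
  top <- cf[["top"]]
  hill <- cf[["hill"]]
  # the 4PL is invariant under (bottom, top, hill) -> (top, bottom, -hill);
  # report the canonical orientation with top >= bottom
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  list(params = four_pl_params(bottom = bottom, top = top,
                               ec50 = ec50, hill = hill),
       ec50 = ec50, fit_ok = TRUE, rss = min(rss))
}

#' Picomoles of 125-I per microgram protein from gamma counts
#'
#' `5000 * (counts / total_protein) / 12000` — linear in counts per minute,
#' inverse-linear in total protein.
#'
#' @param counts gamma counts per minute (>= 0).
#' @param total_protein total protein (ug, > 0).
#' @return picomoles 125-I per ug protein, vectorized.
#' @export
picomoles_per_ug <- function(counts, total_protein) {
  if (any(!is.finite(total_protein) | total_protein <= 0)) {
    stop("picomoles_per_ug: total_protein must be > 0")
  }
  if (any(counts < 0)) stop("picomoles_per_ug: counts must be >= 0")
  5000 * (counts / total_protein) / 12000
}

#' Fold increase in radioiodide uptake over vehicle
#'
#' Mean treated picomoles/ug divided by mean vehicle picomoles/ug, with the
#' standard error propagated from the two arms' replicate SEMs by the
#' first-order (delta-method) ratio formula.
#'
#' @param treated,vehicle numeric vectors of picomoles-per-ug replicates,
#'   or data frames with a `picomoles_per_ug` column (as from
#'   [simulate_uptake]).
#' @return list: `fold`, `sem`, `n_treated`, `n_vehicle`.
#' @export
fold_uptake <- function(treated, vehicle) {
  as_pmol <- function(x) {
    if (is.data.frame(x)) x$picomoles_per_ug else as.numeric(x)
  }
  t_ <- as_pmol(treated); v_ <- as_pmol(vehicle)
  if (length(t_) < 1 || length(v_) < 1) {
    stop("fold_uptake: need >= 1 replicate per arm")
  }
  mv <- mean(v_)
  if (mv <= 0) stop("fold_uptake: vehicle mean must be > 0")
  mt <- mean(t_)
  fold <- mt / mv
  sem_arm <- function(x) {
    if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  }
  rel <- sqrt((sem_arm(t_) / mt)^2 + (sem_arm(v_) / mv)^2)
  list(fold = fold, sem = abs(fold) * rel,
       n_treated = length(t_), n_vehicle = length(v_))
}

#' Perchlorate specificity check for radioiodide uptake
#'
#' Perchlorate competitively blocks the symporter; uptake that collapses
#' under perchlorate pretreatment is NIS-mediated.
#'
#' @param plus_perchlorate,minus_perchlorate picomoles-per-ug replicate
#'   vectors (or data frames with a `picomoles_per_ug` column).
#' @param cutoff ratio below which uptake is flagged NIS-specific.
#' @return list: `ratio` (mean plus / mean minus), `nis_specific`.
#' @export
nis_specificity_check <- function(plus_perchlorate, minus_perchlorate,
                                  cutoff = 0.2) {
  as_pmol <- function(x) {
    if (is.data.frame(x)) x$picomoles_per_ug else as.numeric(x)
  }
  p <- as_pmol(plus_perchlorate); m <- as_pmol(minus_perchlorate)
  if (!length(p) || !length(m)) stop("nis_specificity_check: both arms required")
  if (mean(m) <= 0) stop("nis_specificity_check: minus-perchlorate mean must be > 0")
  ratio <- mean(p) / mean(m)
  list(ratio = ratio, nis_specific = ratio < cutoff)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   quantification-cycle values; all must be finite.
#' @return `2^-[(ct_target_treated - ct_ref_treated) -
#'   (ct_target_control - ct_ref_control)]`.
#' @export
ddct_expression <- function(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop("ddct_expression: all Ct must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
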