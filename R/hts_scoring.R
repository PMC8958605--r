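#' Percentage quench of YFP fluorescence after iodide injection
#'
#' The assay's raw per-well statistic: fractional loss of fluorescence
#' between the pre-injection reading and a chosen post-injection cycle,
#' expressed in percent. Positive values mean the fluorophore was quenched,
#' i.e. iodide entered the cell.
#'
#' @param yfp0 pre-injection fluorescence (a.u.), must be > 0.
#' @param yfp4 post-injection fluorescence (a.u.) at the scoring cycle.
#' @return `100 * (yfp0 - yfp4) / yfp0`, vectorized.
#' @export
percent_yfp <- function(yfp0, yfp4) {
  if (any(!is.finite(yfp0) | yfp0 <= 0)) {
    stop("percent_yfp: yfp0 must be finite and > 0")
  }
  (yfp0 - yfp4) / yfp0 * 100
}

#' Interquartile (trimmed) mean, spreadsheet TRIMMEAN semantics
#'
#' Sorts the values, excludes `floor(n * trim_proportion / 2)` points from
#' each tail (so the total excluded count is rounded down to an even
#' number, split symmetrically) and returns the mean of the rest. With the
#' default `trim_proportion = 0.5` this is the mean of the central half —
#' the interquartile mean used for plate and well-position normalization.
#'
#' @param values numeric vector; non-finite entries are dropped first.
#' @param trim_proportion total proportion to exclude, in (0, 1).
#' @return the trimmed mean (scalar).
#' @export
interquartile_mean <- function(values, trim_proportion = 0.5) {
  stopifnot(trim_proportion > 0, trim_proportion < 1)
  x <- values[is.finite(values)]
  n <- length(x)
  if (n == 0) stop("interquartile_mean: no finite values")
  k <- floor(n * trim_proportion / 2)
  x <- sort(x)
  mean(x[(k + 1):(n - k)])
}

#' Per-plate interquartile-mean normalization
#'
#' Divides each well's %YFP by the interquartile mean of all analyzable
#' wells on its plate, removing multiplicative plate effects.
#'
#' @param pct_yfp numeric vector of %YFP values.
#' @param plate_id plate label per well.
#' @param trim_proportion passed to [interquartile_mean].
#' @return list with `s_iqm` (per well, NA for wells on flagged plates),
#'   `mu_iq_per_plate` (named vector) and `flagged_plates` (plates whose
#'   interquartile mean was zero, excluded with a warning).
#' @export
normalize_per_plate <- function(pct_yfp, plate_id, trim_proportion = 0.5) {
  plate_id <- as.character(plate_id)
  counts <- table(plate_id[is.finite(pct_yfp)])
  small <- names(counts)[counts < 4]
  if (length(small)) {
    stop("normalize_per_plate: plate(s) with fewer than 4 analyzable wells: ",
         paste(small, collapse = ", "))
  }
  mu <- tapply(pct_yfp, plate_id, interquartile_mean,
               trim_proportion = trim_proportion)
  flagged <- names(mu)[mu == 0]
  if (length(flagged)) {
    warning("normalize_per_plate: zero interquartile mean, plate(s) excluded: ",
            paste(flagged, collapse = ", "))
    mu[mu == 0] <- NA_real_
  }
  list(s_iqm = as.numeric(pct_yfp / mu[plate_id]),
       mu_iq_per_plate = mu,
       flagged_plates = flagged)
}

#' Per-well-position interquartile-mean normalization
#'
#' Divides each well's plate-normalized value by the interquartile mean of
#' that well position's values across every plate of the screen, removing
#' systematic positional (edge, dispenser) effects.
#'
#' @param s_iqm per-well plate-normalized values.
#' @param position well position label (e.g. "B02") per well.
#' @param trim_proportion passed to [interquartile_mean].
#' @return list with `s_iqmw`, `mu_iqw_per_position` (named vector) and
#'   `flagged_positions`.
#' @export
normalize_per_wellposition <- function(s_iqm, position,
                                       trim_proportion = 0.5) {
  position <- as.character(position)
  mu <- tapply(s_iqm, position, interquartile_mean,
               trim_proportion = trim_proportion)
  flagged <- names(mu)[mu == 0]
  if (length(flagged)) {
    warning("normalize_per_wellposition: zero interquartile mean, position(s) excluded: ",
            paste(flagged, collapse = ", "))
    mu[mu == 0] <- NA_real_
  }
  list(s_iqmw = as.numeric(s_iqm / mu[position]),
       mu_iqw_per_position = mu,
       flagged_positions = flagged)
}

#' DeltaYFP: fold change over plate-matched DMSO in DMSO-SD units
#'
#' The screen's hit statistic. A drug well's doubly normalized value minus
#' the mean over its plate's DMSO wells, divided by the standard deviation
#' of the doubly normalized values of all DMSO wells across the screen.
#' Positive DeltaYFP denotes increased intracellular iodide.
#'
#' @param drug_s_iqmw doubly normalized value(s) of the drug well(s).
#' @param plate_matched_dmso_s_iqmw mean S_IQMW over that plate's DMSO wells.
#' @param dmso_sd_screenwide SD of S_IQMW over all DMSO wells of the screen.
#' @return DeltaYFP, vectorized over the first two arguments.
#' @export
delta_yfp <- function(drug_s_iqmw, plate_matched_dmso_s_iqmw,
                      dmso_sd_screenwide) {
  if (!is.finite(dmso_sd_screenwide) || dmso_sd_screenwide <= 0) {
    stop("delta_yfp: screen-wide DMSO SD must be > 0; ",
         "check that the screen has >= 2 analyzable DMSO control wells")
  }
  (drug_s_iqmw - plate_matched_dmso_s_iqmw) / dmso_sd_screenwide
}

#' Z-prime assay quality factor
#'
#' `z = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values above
#' 0.5 indicate a separation window suitable for full-scale high-throughput
#' screening.
#'
#' @param pos_values,neg_values numeric vectors of the positive- and
#'   negative-control signal (>= 2 values each).
#' @return list of class `assay_quality`: `mean_pos`, `sd_pos`, `mean_neg`,
#'   `sd_neg`, `z_factor`, `suitable`.
#' @export
z_factor <- function(pos_values, neg_values) {
  pos_values <- pos_values[is.finite(pos_values)]
  neg_values <- neg_values[is.finite(neg_values)]
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    stop("z_factor: need >= 2 finite values per control arm")
  }
  z_factor_from_stats(mean(pos_values), stats::sd(pos_values),
                      mean(neg_values), stats::sd(neg_values))
}

#' @rdname z_factor
#' @param mean_pos,sd_pos,mean_neg,sd_neg summary statistics of the two
#'   control arms.
#' @export
z_factor_from_stats <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (mean_pos == mean_neg) {
    stop("z_factor: undefined when positive and negative control means are equal")
  }
  z <- 1 - 3 * (sd_pos + sd_neg) / abs(mean_pos - mean_neg)
  structure(list(mean_pos = mean_pos, sd_pos = sd_pos,
                 mean_neg = mean_neg, sd_neg = sd_neg,
                 z_factor = z, suitable = z > 0.5),
            class = "assay_quality")
}

#' Score a primary screen: the full normalization chain
#'
#' Runs the per-plate and per-well-position interquartile-mean
#' normalizations on the percent quench of every analyzable well, derives
#' DeltaYFP against plate-matched DMSO controls in screen-wide DMSO-SD
#' units, calls hits with the viability gate, and computes per-plate
#' Z-prime from the NaI-positive vs PBS-negative control wells.
#'
#' @param wells kinetic well data frame ([read_screen] /
#'   [simulate_screen]).
#' @param config a [screen_config].
#' @param quiet suppress INFO logging.
#' @return list of class `screen_scores`: `wells` (input plus `pct_yfp`,
#'   `s_iqm`, `s_iqmw`, `delta_yfp`, `hit`), `stats` (mu_iq per plate,
#'   mu_iqw per position, screen-wide DMSO SD, n_dmso), `qc` (per-plate
#'   Z-prime table), `exclusions`, and the `config` used.
#' @export
score_screen <- function(wells, config = screen_config(), quiet = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  # always re-validate: catches duplicates/addresses in hand-built tables too
  wells <- as_kinetic_wells(wells, quiet = TRUE)
  yfp_after <- wells[[paste0("yfp_c", config$cycles_used)]]
  ok <- wells$analyzable & is.finite(yfp_after)

  wells$pct_yfp <- NA_real_
  wells$pct_yfp[ok] <- percent_yfp(wells$yfp0[ok], yfp_after[ok])

  pp <- normalize_per_plate(wells$pct_yfp[ok], wells$plate_id[ok],
                            config$trim_proportion)
  wells$s_iqm <- NA_real_
  wells$s_iqm[ok] <- pp$s_iqm

  wp <- normalize_per_wellposition(wells$s_iqm[ok], wells$well[ok],
                                   config$trim_proportion)
  wells$s_iqmw <- NA_real_
  wells$s_iqmw[ok] <- wp$s_iqmw

  dmso <- ok & wells$role == "DMSO_CONTROL" & is.finite(wells$s_iqmw)
  n_dmso <- sum(dmso)
  if (n_dmso < 2) {
    stop("score_screen: need >= 2 analyzable DMSO_CONTROL wells for the ",
         "screen-wide DMSO SD (found ", n_dmso, "); check plate layout")
  }
  dmso_sd <- stats::sd(wells$s_iqmw[dmso])
  plate_dmso_mean <- tapply(wells$s_iqmw[dmso], wells$plate_id[dmso], mean)
  no_dmso <- setdiff(unique(wells$plate_id), names(plate_dmso_mean))
  if (length(no_dmso)) {
    stop("score_screen: plate(s) without DMSO control wells: ",
         paste(no_dmso, collapse = ", "),
         "; DeltaYFP needs a plate-matched DMSO term")
  }

  wells$delta_yfp <- NA_real_
  wells$delta_yfp[ok] <- delta_yfp(
    wells$s_iqmw[ok],
    as.numeric(plate_dmso_mean[as.character(wells$plate_id[ok])]),
    dmso_sd)

  above <- if (config$strict_hit_inequality) {
    wells$delta_yfp > config$hit_threshold
  } else {
    wells$delta_yfp >= config$hit_threshold
  }
  wells$hit <- wells$role == "DRUG" & !is.na(wells$delta_yfp) & above &
    !is.na(wells$viability) & wells$viability >= config$viability_floor

  qc <- plate_zprime(wells, ok)

  if (!quiet) {
    message(sprintf(
      "score_screen: %d wells (%d analyzable), %d DMSO wells (SD %.4f), %d hits",
      nrow(wells), sum(ok), n_dmso, dmso_sd, sum(wells$hit)))
  }

  structure(list(
    wells = wells,
    stats = list(mu_iq_per_plate = pp$mu_iq_per_plate,
                 mu_iqw_per_position = wp$mu_iqw_per_position,
                 plate_dmso_mean = plate_dmso_mean,
                 dmso_sd = dmso_sd,
                 n_dmso = n_dmso),
    qc = qc,
    exclusions = attr(wells, "exclusions"),
    config = config), class = "screen_scores")
}

# Per-plate Z-prime from %YFP of NaI-positive vs PBS-negative wells.
plate_zprime <- function(wells, ok) {
  plates <- unique(wells$plate_id)
  out <- data.frame(plate_id = plates, mean_pos = NA_real_,
                    sd_pos = NA_real_, mean_neg = NA_real_,
                    sd_neg = NA_real_, z_factor = NA_real_,
                    suitable = NA, stringsAsFactors = FALSE)
  for (i in seq_along(plates)) {
    sel <- ok & wells$plate_id == plates[i]
    pos <- wells$pct_yfp[sel & wells$role == "NAI_POSITIVE"]
    neg <- wells$pct_yfp[sel & wells$role == "PBS_NEGATIVE"]
    if (sum(is.finite(pos)) >= 2 && sum(is.finite(neg)) >= 2) {
      aq <- tryCatch(z_factor(pos, neg), error = function(e) NULL)
      if (!is.null(aq)) {
        out[i, 2:6] <- unlist(aq[1:5])
        out$suitable[i] <- aq$suitable
      }
    }
  }
  out
}

#' Rank hits from a scored screen
#'
#' A drug well is a hit when DeltaYFP exceeds the threshold *and* its
#' viability is at or above the viability floor (cytotoxic quenchers are
#' not counted). Output is sorted by DeltaYFP descending, ties broken by
#' drug id.
#'
#' @param scores a `screen_scores` object from [score_screen].
#' @param config optional [screen_config] to re-call hits at different
#'   thresholds; defaults to the one used at scoring time.
#' @return data frame of drug wells: plate, well, drug_id, dose_uM,
#'   delta_yfp, viability, hit.
#' @export
call_hits <- function(scores, config = NULL) {
  stopifnot(inherits(scores, "screen_scores"))
  w <- scores$wells
  if (is.null(config)) {
    config <- scores$config
  } else {
    above <- if (config$strict_hit_inequality) {
      w$delta_yfp > config$hit_threshold
    } else {
      w$delta_yfp >= config$hit_threshold
    }
    w$hit <- w$role == "DRUG" & !is.na(w$delta_yfp) & above &
      !is.na(w$viability) & w$viability >= config$viability_floor
  }
  d <- w[w$role == "DRUG", c("plate_id", "well", "drug_id", "dose_uM",
                             "pct_yfp", "s_iqmw", "delta_yfp", "viability",
                             "hit")]
  d <- d[order(-xtfrm(d$delta_yfp), d$drug_id), ]
  rownames(d) <- NULL
  d
}
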