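# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: naive loops, dense grids and exhaustive enumeration.

# Spreadsheet TRIMMEAN, written independently.
oracle_trimmean <- function(v, p = 0.5) {
  v <- sort(v[is.finite(v)])
  n <- length(v)
  k <- floor(n * p / 2)
  mean(v[(k + 1):(n - k)])
}

# Straight-line loop reimplementation of the Eq. 1-4 normalization chain.
# Returns DeltaYFP aligned to rows of `wells` (NA where not analyzable).
oracle_delta_yfp <- function(wells, trim = 0.5, cycle = 4) {
  n <- nrow(wells)
  yfp4 <- wells[[paste0("yfp_c", cycle)]]
  ok <- wells$analyzable & is.finite(yfp4)

  pct <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (ok[i]) pct[i] <- (wells$yfp0[i] - yfp4[i]) / wells$yfp0[i] * 100
  }

  s_iqm <- rep(NA_real_, n)
  for (p in unique(wells$plate_id)) {
    idx <- which(ok & wells$plate_id == p)
    mu <- oracle_trimmean(pct[idx], trim)
    for (i in idx) s_iqm[i] <- pct[i] / mu
  }

  s_iqmw <- rep(NA_real_, n)
  for (pos in unique(wells$well)) {
    idx <- which(ok & wells$well == pos)
    mu <- oracle_trimmean(s_iqm[idx], trim)
    for (i in idx) s_iqmw[i] <- s_iqm[i] / mu
  }

  dmso <- which(ok & wells$role == "DMSO_CONTROL")
  sd_dmso <- sd(s_iqmw[dmso])
  delta <- rep(NA_real_, n)
  for (p in unique(wells$plate_id)) {
    dm <- mean(s_iqmw[intersect(dmso, which(wells$plate_id == p))])
    for (i in which(ok & wells$plate_id == p)) {
      delta[i] <- (s_iqmw[i] - dm) / sd_dmso
    }
  }
  delta
}

# Dense-grid integration of max(0, piecewise-linear interpolant) on log10 dose.
oracle_auc_grid <- function(doses, responses, n_grid = 2e6) {
  x <- log10(doses)
  g <- seq(min(x), max(x), length.out = n_grid)
  y <- pmax(0, approx(x, responses, xout = g)$y)
  sum((y[-1] + y[-n_grid]) / 2 * diff(g))
}

# Two-sided Fisher exact p by full enumeration over tables with fixed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs concordance AUC with ties counted one half.
oracle_auc_pairs <- function(score, label) {
  label <- as.logical(label)
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Breslow partial log-likelihood for one covariate, maximized numerically
# (independent of survival::coxph).
oracle_cox_beta <- function(x, time, event, interval = c(-10, 10)) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(as.logical(event))) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  optimize(loglik, interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Exhaustive Youden scan over all midpoints (rule: score > t is positive).
oracle_best_j <- function(score, label) {
  label <- as.logical(label)
  u <- sort(unique(score))
  cand <- (u[-length(u)] + u[-1]) / 2
  max(vapply(cand, function(t) {
    mean(score[label] > t) + mean(score[!label] <= t) - 1
  }, numeric(1)))
}

# Small in-memory screen builder for hand-computed cases: one plate per
# element of `pct_by_plate`, wells laid out deterministically, with yfp0
# fixed at 100 so pct_yfp equals 100 - yfp_c4.
build_screen_from_pct <- function(pct_by_plate, roles_by_plate = NULL) {
  rows <- list()
  for (pi in seq_along(pct_by_plate)) {
    pct <- pct_by_plate[[pi]]
    n <- length(pct)
    wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12),
                     rep(1:12, times = 8))[seq_len(n)]
    roles <- if (is.null(roles_by_plate)) {
      rep("DRUG", n)
    } else {
      roles_by_plate[[pi]]
    }
    rows[[pi]] <- data.frame(
      plate_id = sprintf("P%02d", pi), well = wells, role = roles,
      drug_id = ifelse(roles == "DRUG", sprintf("D%02d_%02d", pi,
                                                seq_len(n)), NA),
      dose_uM = 10, yfp0 = 100, yfp_c1 = 100 - pct / 4,
      yfp_c2 = 100 - pct / 2, yfp_c3 = 100 - 3 * pct / 4,
      yfp_c4 = 100 - pct, viability = 1, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
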