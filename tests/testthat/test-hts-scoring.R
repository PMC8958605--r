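test_that("percent quench follows the fractional-loss definition", {
  expect_equal(percent_yfp(100, 80), 20)
  expect_equal(percent_yfp(50, 50), 0)
  expect_equal(percent_yfp(200, 50), 75)
  expect_equal(percent_yfp(c(100, 50), c(80, 50)), c(20, 0))
  expect_error(percent_yfp(0, 10), "yfp0")
  expect_error(percent_yfp(-5, 10), "yfp0")
})

test_that("interquartile mean matches spreadsheet TRIMMEAN semantics", {
  # n*p even: exclude 2 per tail
  expect_equal(interquartile_mean(1:8, 0.5), 4.5)
  # constant input
  expect_equal(interquartile_mean(rep(5, 4), 0.5), 5)
  # n*p = 2.5 rounds the excluded count down to 2, one per tail
  expect_equal(interquartile_mean(1:5, 0.5), 3)
  # unsorted input and NA handling
  expect_equal(interquartile_mean(c(8, NA, 3, 1, 5, 2, 7, 4, 6), 0.5),
               oracle_trimmean(1:8, 0.5))
  # random cases against the independent oracle
  set.seed(42)
  for (n in c(4, 7, 12, 96)) {
    v <- rnorm(n)
    for (p in c(0.2, 0.5, 0.8)) {
      expect_equal(interquartile_mean(v, p), oracle_trimmean(v, p))
    }
  }
  expect_error(interquartile_mean(numeric(0)), "no finite")
})

test_that("per-plate normalization divides by the plate interquartile mean", {
  # worked case: mu_IQ = mean(20, 30) = 25
  r <- normalize_per_plate(c(10, 20, 30, 40), rep("P1", 4))
  expect_equal(unname(r$mu_iq_per_plate["P1"]), 25)
  expect_equal(r$s_iqm, c(0.4, 0.8, 1.2, 1.6))

  # identical values -> all ratios 1
  r2 <- normalize_per_plate(rep(7, 6), rep("P1", 6))
  expect_equal(r2$s_iqm, rep(1, 6))

  # ratio invariance under plate-level scaling
  pct <- runif(8, 10, 60)
  expect_equal(normalize_per_plate(pct * 3, rep("P1", 8))$s_iqm,
               normalize_per_plate(pct, rep("P1", 8))$s_iqm)

  expect_error(normalize_per_plate(1:3, rep("P1", 3)), "fewer than 4")
})

test_that("per-position normalization divides by the cross-plate position mean", {
  # worked case: position B02 across 4 plates, mu_IQW = mean(1.0, 1.5)
  s <- c(0.5, 1.0, 1.5, 2.0)
  r <- normalize_per_wellposition(s, rep("B02", 4))
  expect_equal(unname(r$mu_iqw_per_position["B02"]), 1.25)
  expect_equal(r$s_iqmw, s / 1.25)

  # single-plate degenerate case: every position normalizes to 1
  r2 <- normalize_per_wellposition(c(0.7, 1.3, 0.9),
                                   c("A01", "A02", "A03"))
  expect_equal(r2$s_iqmw, rep(1, 3))

  # scaling one position across plates leaves its normalized value unchanged
  r3 <- normalize_per_wellposition(s * 10, rep("B02", 4))
  expect_equal(r3$s_iqmw, r$s_iqmw)
})

test_that("DeltaYFP is the DMSO-SD-scaled excess over plate-matched DMSO", {
  expect_equal(delta_yfp(1.10, 1.10, 0.10), 0)
  expect_equal(delta_yfp(1.25, 1.10, 0.10), 1.5)
  expect_error(delta_yfp(1, 1, 0), "SD")
})

test_that("Z-prime reproduces hand-computed values and suitability calls", {
  expect_equal(z_factor_from_stats(100, 0, 0, 0)$z_factor, 1)
  q <- z_factor_from_stats(100, 5, 0, 5)
  expect_equal(q$z_factor, 0.7)
  expect_true(q$suitable)
  q2 <- z_factor_from_stats(1, 1, 0, 1)
  expect_equal(q2$z_factor, -5)
  expect_false(q2$suitable)
  expect_error(z_factor_from_stats(1, 0.1, 1, 0.1), "undefined")

  # vector form agrees with summary-statistic form
  set.seed(1)
  pos <- rnorm(24, 60, 3); neg <- rnorm(24, 2, 3)
  expect_equal(z_factor(pos, neg)$z_factor,
               z_factor_from_stats(mean(pos), sd(pos), mean(neg),
                                   sd(neg))$z_factor)
  expect_error(z_factor(1, c(1, 2)), ">= 2")
})

test_that("hit calling applies the threshold strictly and gates on viability", {
  # 4 plates; plate 1 carries three strong actives (one cytotoxic),
  # everything else hovers around the DMSO baseline quench
  null_pct <- function(jit) c(29.8, 30.2, 29.9, 30.1, 85, 2,
                              30 + jit)
  wells <- build_screen_from_pct(list(
    c(29.8, 30.2, 29.9, 30.1, 85, 2, 36, 36, 36, 30.5, 31, 29),
    null_pct(c(0.1, -0.1, 0.05, -0.05, 0.2, -0.2)),
    null_pct(c(-0.15, 0.15, 0.1, -0.1, 0, 0.25)),
    null_pct(c(0.05, -0.2, 0.15, 0, -0.1, 0.1))))
  dmso <- rep(c(rep("DMSO_CONTROL", 4), "NAI_POSITIVE", "PBS_NEGATIVE",
                rep("DRUG", 6)), 4)
  wells$role <- dmso
  wells$drug_id[wells$role != "DRUG"] <- NA
  wells$viability[wells$plate_id == "P01" & wells$well == "A08"] <- 0.5

  scores <- score_screen(wells, screen_config(hit_threshold = 1.5),
                         quiet = TRUE)
  hits <- call_hits(scores)
  d <- scores$wells[scores$wells$role == "DRUG", ]

  strong <- d$delta_yfp > 1.5
  expect_true(any(strong))
  expect_true(all(d$hit[strong & d$viability >= 0.7]))
  expect_false(any(d$hit[d$viability < 0.7]))   # viability gate
  expect_false(any(d$hit[!strong]))

  # ranked descending, ties by drug id
  expect_false(is.unsorted(rev(hits$delta_yfp)))

  # a well exactly at the threshold is only a hit without strictness
  at <- which.max(ifelse(d$viability >= 0.7, d$delta_yfp, -Inf))
  cfg2 <- screen_config(hit_threshold = d$delta_yfp[at],
                        strict_hit_inequality = TRUE)
  rehit <- call_hits(scores, cfg2)
  expect_false(rehit$hit[rehit$drug_id == d$drug_id[at]])
  cfg3 <- screen_config(hit_threshold = d$delta_yfp[at],
                        strict_hit_inequality = FALSE)
  rehit3 <- call_hits(scores, cfg3)
  expect_true(rehit3$hit[rehit3$drug_id == d$drug_id[at]])
})

test_that("pipeline DeltaYFP matches the naive loop reimplementation", {
  for (seed in c(101, 202)) {
    sim <- simulate_screen(screen_sim_spec(n_plates = 4, n_dmso_total = 32,
                                           seed = seed))
    scores <- score_screen(sim$wells, quiet = TRUE)
    expect_equal(scores$wells$delta_yfp, oracle_delta_yfp(sim$wells),
                 tolerance = 1e-13)
  }
})

test_that("DeltaYFP is invariant to plate and well-position distortions", {
  sim <- simulate_screen(screen_sim_spec(n_plates = 4, n_dmso_total = 32,
                                         seed = 77))
  base <- score_screen(sim$wells, quiet = TRUE)$wells$delta_yfp

  for (c_ in c(0.1, 3)) {
    # raw fluorescence of one whole plate scaled
    w <- sim$wells
    sel <- w$plate_id == "P02"
    for (col in c("yfp0", paste0("yfp_c", 1:4))) {
      w[[col]][sel] <- w[[col]][sel] * c_
    }
    expect_equal(score_screen(w, quiet = TRUE)$wells$delta_yfp, base,
                 tolerance = 1e-9)

    # one well position's readings scaled on every plate
    w2 <- sim$wells
    sel2 <- w2$well == "C05"
    for (col in c("yfp0", paste0("yfp_c", 1:4))) {
      w2[[col]][sel2] <- w2[[col]][sel2] * c_
    }
    expect_equal(score_screen(w2, quiet = TRUE)$wells$delta_yfp, base,
                 tolerance = 1e-9)
  }
})

test_that("plate-matched DMSO wells have mean DeltaYFP exactly zero", {
  sim <- simulate_screen(screen_sim_spec(n_plates = 3, n_dmso_total = 24,
                                         seed = 13))
  w <- score_screen(sim$wells, quiet = TRUE)$wells
  for (p in unique(w$plate_id)) {
    dmso <- w$role == "DMSO_CONTROL" & w$plate_id == p
    expect_equal(mean(w$delta_yfp[dmso]), 0, tolerance = 1e-12)
  }
})
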