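test_that("expression transform is elementwise log2(x + 1)", {
  expect_equal(log2p1(c(0, 1, 3)), c(0, 1, 2))
  m <- matrix(c(0, 7, 15, 1), 2)
  expect_equal(log2p1(m), log2(m + 1))
  expect_error(log2p1(-0.1), "negative")
})

test_that("BH adjustment matches the step-up worked example and is order-free", {
  genes <- sprintf("G%02d", 1:4)
  set.seed(3)
  a <- matrix(rnorm(40), 10, dimnames = list(NULL, genes))
  b <- matrix(rnorm(40), 10, dimnames = list(NULL, genes))
  de <- differential_expression(a, b)
  expect_equal(de$q, p.adjust(de$p, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # permuting gene order changes no gene's q
  de2 <- differential_expression(a[, 4:1], b[, 4:1])
  expect_equal(de2$q[match(de$gene, de2$gene)], de$q)
})

test_that("differential expression finds shifted genes and zeroes self-contrasts", {
  genes <- sprintf("G%03d", 1:100)
  set.seed(11)
  base <- matrix(rnorm(50 * 100, 5), 50, dimnames = list(NULL, genes))
  de0 <- differential_expression(base, base)
  expect_equal(de0$log2fc, rep(0, 100))

  hits <- replicate(5, {
    a <- matrix(rnorm(50 * 100, 5), 50, dimnames = list(NULL, genes))
    b <- matrix(rnorm(50 * 100, 5), 50, dimnames = list(NULL, genes))
    a[, 1:10] <- a[, 1:10] + 1          # true +1 shift in 10/100 genes
    de <- differential_expression(a, b)
    c(tp = sum(de$q < 0.05 & de$gene %in% genes[1:10]),
      fp = sum(de$q < 0.05 & !de$gene %in% genes[1:10]))
  })
  expect_gte(median(hits["tp", ]), 8)
  expect_lte(median(hits["fp", ]), 2)

  # constant gene -> p = 1 by convention
  a2 <- matrix(1, 5, 2, dimnames = list(NULL, c("GA", "GB")))
  a2[, 2] <- rnorm(5)
  b2 <- a2
  b2[, 2] <- rnorm(5)
  expect_equal(differential_expression(a2, b2)$p[1], 1)
})

test_that("Fisher exact matches brute-force hypergeometric enumeration", {
  t1 <- matrix(c(5, 0, 0, 5), 2)
  r1 <- fisher_exact_2x2(t1)
  expect_equal(r1$p, 0.0079365, tolerance = 1e-4)
  expect_equal(r1$p, oracle_fisher_p(t1), tolerance = 1e-12)

  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 5), 2))$p, 1)  # zero margin

  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC equals all-pairs concordance and respects invariances", {
  # perfect separation
  expect_equal(roc_curve_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # ties counted one half
  expect_equal(roc_curve_auc(c(1, 1), c(0, 1))$auc, 0.5)

  set.seed(17)
  for (i in 1:5) {
    n <- 60
    score <- sample(round(rnorm(n), 1))   # coarse grid forces ties
    label <- runif(n) < 0.4
    if (!any(label) || all(label)) next
    expect_equal(roc_curve_auc(score, label)$auc,
                 oracle_auc_pairs(score, label))
    # invariance under strictly increasing transforms
    expect_equal(roc_curve_auc(exp(score), label)$auc,
                 roc_curve_auc(score, label)$auc)
  }

  # independent score -> AUC near 1/2
  set.seed(18)
  big <- roc_curve_auc(rnorm(4000), runif(4000) < 0.5)
  expect_lt(abs(big$auc - 0.5), 0.05)
  expect_error(roc_curve_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Youden cutpoint matches an exhaustive scan and separates cleanly", {
  # perfectly separated groups: threshold strictly between them, J = 1
  score <- c(1, 2, 3, 7, 8, 9)
  label <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cp <- optimal_cutpoint(score, label)
  expect_equal(cp$j, 1)
  expect_gt(cp$threshold, 3)
  expect_lt(cp$threshold, 7)

  set.seed(19)
  for (i in 1:5) {
    s <- rnorm(40)
    l <- runif(40) < 0.5
    if (!any(l) || all(l)) next
    expect_equal(optimal_cutpoint(s, l)$j, oracle_best_j(s, l))
  }

  # label shuffling destroys the cutpoint's value
  set.seed(20)
  j_null <- replicate(11, {
    s <- rnorm(200)
    optimal_cutpoint(s, sample(rep(c(TRUE, FALSE), 100)))$j
  })
  expect_lt(median(j_null), 0.25)
})

test_that("univariate Cox matches brute-force partial-likelihood maximization", {
  # 6-subject worked dataset with a tie
  time <- c(2, 4, 4, 6, 8, 10)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_univariate(x, time, event)
  expect_equal(fit$beta[1], oracle_cox_beta(x, time, event),
               tolerance = 1e-4)
  expect_equal(fit$hr[1], exp(fit$beta[1]))
  expect_true(fit$ci_low[1] < fit$hr[1] && fit$hr[1] < fit$ci_high[1])

  set.seed(23)
  for (i in 1:5) {
    n <- 8
    t_ <- rexp(n)
    e_ <- runif(n) < 0.8
    if (sum(e_) < 2) next
    x_ <- rbinom(n, 1, 0.5)
    if (sd(x_) == 0) next
    f <- cox_univariate(x_, t_, e_)
    if (!f$converged) next      # separation: oracle diverges too
    expect_equal(f$beta[1], oracle_cox_beta(x_, t_, e_), tolerance = 1e-4)
  }
})

test_that("Cox on identical groups gives HR 1 and flags separation", {
  t_ <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e_ <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  g <- rep(c(0, 1), each = 4)
  fit <- cox_univariate(g, t_, e_)
  expect_equal(fit$beta[1], 0, tolerance = 1e-8)
  expect_equal(fit$hr[1], 1, tolerance = 1e-8)

  # complete separation: group 1 has all the early events
  sep <- cox_univariate(c(1, 1, 1, 0, 0, 0),
                        c(1, 2, 3, 10, 11, 12),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(sep$converged)
  expect_error(cox_univariate(1:3, 1:3, c(FALSE, FALSE, FALSE)),
               "no events")
})

test_that("simulated HR = 2 arms are recovered on the log scale", {
  set.seed(29)
  n <- 1000
  g <- rep(0:1, each = n / 2)
  t_ <- rexp(n, rate = 0.05 * 2^g)
  cens <- rexp(n, rate = 0.02)
  fit <- cox_univariate(g, pmin(t_, cens), t_ <= cens)
  expect_lt(abs(fit$beta[1] - log(2)), 0.15)
})

test_that("risk model is a linear score with the fitted coefficients", {
  spec <- cohort_sim_spec(n_patients = 400, n_genes = 4,
                          causal_beta = c(GENE01 = 0.7), seed = 31)
  cs <- simulate_cohort(spec)
  m <- build_risk_model(cs$cohort, spec$genes)
  expect_true(m$converged)
  x <- log2p1(as.matrix(cs$cohort[spec$genes]))
  expect_equal(m$score, drop(x %*% m$beta))
  expect_equal(risk_score(m, cs$cohort), m$score)

  # score invariant to gene ordering
  m2 <- build_risk_model(cs$cohort, rev(spec$genes))
  expect_equal(m2$score, m$score, tolerance = 1e-8)

  # forcing a unit coefficient on one gene makes the score that gene
  m3 <- m
  m3$beta <- setNames(c(1, 0, 0, 0), spec$genes)
  expect_equal(risk_score(m3, cs$cohort), x[, "GENE01"])

  expect_error(build_risk_model(cs$cohort, c("GENE01", "NOPE")), "NOPE")
  # fewer events than genes triggers the instability warning
  tiny <- cs$cohort[c(which(!cs$cohort$event)[1:10],
                      which(cs$cohort$event)[1:3]), ]
  expect_warning(build_risk_model(tiny, spec$genes), "events")
})

test_that("risk stratification: KM anchors, log-rank symmetry, HR recovery", {
  spec <- cohort_sim_spec(n_patients = 600, n_genes = 6,
                          causal_beta = c(GENE01 = 0.9, GENE02 = 0.7),
                          baseline_hazard = 0.03, seed = 37)
  cs <- simulate_cohort(spec)
  m <- build_risk_model(cs$cohort, spec$genes)
  st <- stratify_by_risk(m, cs$cohort)

  # KM survival starts at 1 in both groups
  s0 <- summary(st$km, times = 0)
  expect_equal(s0$surv, c(1, 1))
  expect_gt(st$hr_fit$hr[1], 1)
  expect_lt(st$logrank_p, 0.01)

  # tertile mode drops the middle third
  st3 <- stratify_by_risk(m, cs$cohort, mode = "tertile")
  expect_lt(length(st3$group), nrow(cs$cohort) * 0.75)
  expect_gt(st3$hr_fit$hr[1], st$hr_fit$hr[1] * 0.8)

  # identical survival in both groups: p ~ 1, HR ~ 1
  t_ <- rep(c(1, 2, 3, 4, 5, 6, 7, 8), 2)
  e_ <- rep(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE), 2)
  d <- data.frame(time = t_, event = e_,
                  GENE01 = rep(c(1, 100), each = 8), GENE02 = 1,
                  GENE03 = 1, GENE04 = 1, GENE05 = 1, GENE06 = 1)
  m0 <- m
  m0$group_cutoff <- mean(range(risk_score(m, d)))
  st0 <- stratify_by_risk(m0, d)
  expect_equal(st0$hr_fit$hr[1], 1, tolerance = 1e-6)
  expect_gt(st0$logrank_p, 0.95)
})

test_that("covariate-adjusted fit keeps the score and drops collinear terms", {
  spec <- cohort_sim_spec(n_patients = 600, n_genes = 4,
                          causal_beta = c(GENE01 = 0.9), seed = 41)
  cs <- simulate_cohort(spec)
  m <- build_risk_model(cs$cohort, spec$genes)
  grp <- risk_score(m, cs$cohort) > m$group_cutoff
  covs <- cs$cohort[c("age", "gender", "disease_stage", "node_status")]

  fit <- multivariate_adjusted(grp, covs, cs$cohort$time, cs$cohort$event)
  i <- match("risk_group", fit$terms)
  expect_lt(fit$p[i], 0.01)
  # covariates were generated independently of hazard
  expect_gt(min(fit$p[-i]), 0.01)

  # duplicated covariate column: dropped, fit identical
  covs2 <- cbind(covs, age_copy = covs$age)
  expect_warning(
    fit2 <- multivariate_adjusted(grp, covs2, cs$cohort$time,
                                  cs$cohort$event),
    "collinear")
  expect_equal(sort(fit2$beta), sort(fit$beta), tolerance = 1e-8)

  # permuted score group: CI covers 1 in most seeds
  set.seed(43)
  cover <- replicate(10, {
    f <- multivariate_adjusted(sample(grp), covs, cs$cohort$time,
                               cs$cohort$event)
    j <- match("risk_group", f$terms)
    f$ci_low[j] <= 1 && 1 <= f$ci_high[j]
  })
  expect_gte(mean(cover), 0.9)
})
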