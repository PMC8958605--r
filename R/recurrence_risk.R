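#' log2(x + 1) expression transform
#'
#' The standard transform applied to normalized FPKM values before any
#' downstream statistics.
#'
#' @param x nonnegative numeric vector or matrix.
#' @return elementwise log2(x + 1), same shape.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log2p1: negative expression values")
  log2(x + 1)
}

#' Nonparametric differential expression with BH adjustment
#'
#' Per gene: log2 fold change as the difference of group means on the
#' transformed scale, a two-sample nonparametric p-value
#' (Kolmogorov-Smirnov by default; Wilcoxon rank-sum available), and
#' Benjamini-Hochberg q-values over the whole gene family. A gene constant
#' in both groups gets p = 1 by convention.
#'
#' @param group_a,group_b samples x genes matrices (or data frames) of
#'   log2(FPKM + 1) values with matching gene columns; >= 3 samples per
#'   group.
#' @param genes optional subset of gene columns to test.
#' @param test "ks" (default) or "wilcox".
#' @return data frame: gene, log2fc, p, q.
#' @export
differential_expression <- function(group_a, group_b, genes = NULL,
                                    test = c("ks", "wilcox")) {
  test <- match.arg(test)
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (is.null(genes)) genes <- intersect(colnames(group_a), colnames(group_b))
  if (!length(genes)) stop("differential_expression: no common genes")
  if (nrow(group_a) < 3 || nrow(group_b) < 3) {
    stop("differential_expression: need >= 3 samples per group")
  }
  res <- lapply(genes, function(g) {
    a <- group_a[, g]; b <- group_b[, g]
    p <- if (stats::sd(c(a, b)) == 0) {
      1
    } else if (test == "ks") {
      suppressWarnings(stats::ks.test(a, b)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(gene = g, log2fc = mean(a) - mean(b), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (hypergeometric) and conditional odds ratio. A
#' table with a zero margin carries no information about association and
#' returns p = 1 by convention.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list: `odds_ratio`, `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' ROC curve and AUC for a continuous score against a binary outcome
#'
#' The AUC is the Mann-Whitney concordance probability: the probability
#' that a random event subject scores higher than a random non-event
#' subject, with ties counted one half.
#'
#' @param score numeric risk score.
#' @param event_label logical (or 0/1) outcome; both classes must be
#'   present.
#' @return list: `points` (threshold, sensitivity, specificity; rule is
#'   score >= threshold predicts event) and `auc`.
#' @export
roc_curve_auc <- function(score, event_label) {
  event_label <- as.logical(event_label)
  stopifnot(length(score) == length(event_label),
            all(is.finite(score)), !any(is.na(event_label)))
  n1 <- sum(event_label); n0 <- sum(!event_label)
  if (n1 == 0 || n0 == 0) {
    stop("roc_curve_auc: both classes must be present")
  }
  r <- rank(score)
  auc <- (sum(r[event_label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(score))
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(score[event_label] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(score[!event_label] < t),
                         numeric(1)))
  list(points = pts, auc = auc)
}

#' Optimal ROC cutpoint by Youden's J
#'
#' Scans the midpoints between consecutive distinct score values and
#' returns the threshold maximizing J = sensitivity + specificity - 1
#' under the rule "score > threshold predicts event". Ties are broken
#' toward the lower threshold.
#'
#' @inheritParams roc_curve_auc
#' @return list: `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
optimal_cutpoint <- function(score, event_label) {
  event_label <- as.logical(event_label)
  n1 <- sum(event_label); n0 <- sum(!event_label)
  if (n1 == 0 || n0 == 0) {
    stop("optimal_cutpoint: both classes must be present")
  }
  u <- sort(unique(score))
  if (length(u) < 2) stop("optimal_cutpoint: score is constant")
  cand <- (u[-length(u)] + u[-1]) / 2
  j <- vapply(cand, function(t) {
    mean(score[event_label] > t) + mean(score[!event_label] <= t) - 1
  }, numeric(1))
  best <- which.max(j)            # which.max returns the first (lowest) max
  list(threshold = cand[best], j = j[best],
       sensitivity = mean(score[event_label] > cand[best]),
       specificity = mean(score[!event_label] <= cand[best]))
}

# Wrap a coxph fit into the package's flat fit summary.
cox_fit_summary <- function(fit, converged = TRUE) {
  s <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ok <- converged && all(is.finite(beta)) && all(is.finite(se)) &&
    all(abs(beta) < 15)
  structure(list(terms = names(beta),
                 beta = unname(beta),
                 se = unname(se),
                 hr = unname(exp(beta)),
                 ci_low = unname(exp(beta - 1.96 * se)),
                 ci_high = unname(exp(beta + 1.96 * se)),
                 p = unname(s$coefficients[, "Pr(>|z|)"]),
                 n = s$n, n_events = s$nevent,
                 converged = ok),
            class = "cox_fit")
}

# Fit coxph catching the separation/convergence warnings coxph emits.
fit_cox <- function(formula, data, ties = "breslow") {
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  list(fit = fit, summary = cox_fit_summary(fit, converged = !warned))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by default)
#' for a single covariate — a group indicator or a continuous expression
#' value — and reports the log hazard ratio with Wald 95% CI and p-value.
#' Monotone likelihood (complete separation) is reported via
#' `converged = FALSE` rather than an error.
#'
#' @param x covariate (numeric or 0/1 indicator).
#' @param time nonnegative follow-up times.
#' @param event logical event indicator (>= 1 event required).
#' @param ties "breslow" (default) or "efron".
#' @return a `cox_fit` list: terms, beta, se, hr, ci_low, ci_high, p,
#'   converged.
#' @export
cox_univariate <- function(x, time, event, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  stopifnot(length(x) == length(time), length(time) == length(event),
            all(time >= 0))
  if (!any(event)) stop("cox_univariate: no events")
  d <- data.frame(x = as.numeric(x), time = time, event = event)
  fit_cox(survival::Surv(time, event) ~ x, d, ties)$summary
}

#' Build a multi-gene Cox recurrence risk score
#'
#' Fits a multivariate Cox proportional-hazards model on the
#' log2(FPKM + 1) expression of the listed genes, defines each patient's
#' risk score as the linear predictor `sum(beta_g * expr_g)` on the
#' transformed scale, fixes a group cutoff on the scores, and records the
#' score's ROC AUC against the event indicator.
#'
#' @param cohort data frame with the gene columns (raw FPKM), `time` and
#'   `event`.
#' @param genes character vector of gene columns forming the signature.
#' @param cutoff_method "median" (default) or "youden" (ROC-optimal
#'   cutpoint on the score).
#' @param ties Cox tie handling.
#' @return list of class `risk_score_model`: genes, beta, fit (`cox_fit`),
#'   score (per input patient), group_cutoff, auc, converged.
#' @export
build_risk_model <- function(cohort, genes,
                             cutoff_method = c("median", "youden"),
                             ties = c("breslow", "efron")) {
  cutoff_method <- match.arg(cutoff_method)
  ties <- match.arg(ties)
  missing_genes <- setdiff(genes, names(cohort))
  if (length(missing_genes)) {
    stop("build_risk_model: gene(s) absent from cohort: ",
         paste(missing_genes, collapse = ", "))
  }
  n_events <- sum(cohort$event)
  if (n_events < length(genes)) {
    warning("build_risk_model: fewer events (", n_events,
            ") than genes (", length(genes), "); coefficients unstable")
  }
  x <- log2p1(as.matrix(cohort[genes]))
  d <- data.frame(time = cohort$time, event = as.logical(cohort$event), x)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(genes, collapse = " + ")))
  res <- fit_cox(form, d, ties)
  if (!res$summary$converged) {
    return(structure(list(genes = genes, beta = NULL, fit = res$summary,
                          score = NULL, group_cutoff = NA_real_,
                          auc = NA_real_, converged = FALSE),
                     class = "risk_score_model"))
  }
  beta <- stats::setNames(res$summary$beta, genes)
  score <- drop(x %*% beta)
  cutoff <- if (cutoff_method == "median") {
    stats::median(score)
  } else {
    optimal_cutpoint(score, d$event)$threshold
  }
  structure(list(genes = genes, beta = beta, fit = res$summary,
                 score = score, group_cutoff = cutoff,
                 auc = roc_curve_auc(score, d$event)$auc,
                 converged = TRUE),
            class = "risk_score_model")
}

#' Risk scores for (new) patients under a fitted model
#' @param model a `risk_score_model`.
#' @param cohort data frame with the model's gene columns (raw FPKM).
#' @return numeric score per row.
#' @export
risk_score <- function(model, cohort) {
  stopifnot(inherits(model, "risk_score_model"), model$converged)
  drop(log2p1(as.matrix(cohort[model$genes])) %*% model$beta)
}

#' Stratify a cohort by risk score and compare survival
#'
#' Splits patients at the model's score cutoff (or into >66th vs <33rd
#' percentile groups, dropping the middle tertile), estimates Kaplan-Meier
#' curves per group, tests the difference by the log-rank test, and
#' reports the high-vs-low hazard ratio from a univariate Cox fit on the
#' group indicator.
#'
#' @param model a converged `risk_score_model`.
#' @param cohort data frame with gene columns, `time`, `event`.
#' @param mode "cutoff" (default) or "tertile".
#' @return list: `group` (per retained patient, "high"/"low"), `keep`
#'   (row index into cohort), `km` (survfit object), `logrank_chisq`,
#'   `logrank_p`, `hr_fit` (`cox_fit` of high vs low).
#' @export
stratify_by_risk <- function(model, cohort, mode = c("cutoff", "tertile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "risk_score_model"))
  if (!model$converged) stop("stratify_by_risk: model did not converge")
  score <- risk_score(model, cohort)
  if (mode == "cutoff") {
    keep <- seq_along(score)
    group <- ifelse(score > model$group_cutoff, "high", "low")
  } else {
    qs <- stats::quantile(score, c(1 / 3, 2 / 3))
    keep <- which(score < qs[1] | score > qs[2])
    group <- ifelse(score[keep] > qs[2], "high", "low")
  }
  if (!all(c("high", "low") %in% group)) {
    stop("stratify_by_risk: a risk group is empty; adjust the cutoff")
  }
  d <- data.frame(time = cohort$time[keep],
                  event = as.logical(cohort$event[keep]),
                  group = factor(group, levels = c("low", "high")))
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  lr_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  hr_fit <- cox_univariate(as.integer(d$group == "high"), d$time, d$event)
  list(group = group, keep = keep, km = km,
       logrank_chisq = unname(lr$chisq), logrank_p = lr_p, hr_fit = hr_fit)
}

#' Multivariate Cox fit of the risk group adjusted for clinical covariates
#'
#' Joint Cox model of the high/low risk-group indicator together with
#' clinical covariates (categoricals one-hot encoded against their first
#' level); per-term HR/CI/p let the score's independence from the
#' covariates be read off. Collinear covariate columns are dropped with a
#' warning.
#'
#' @param risk_group logical or 0/1 high-risk indicator.
#' @param covariates data frame of clinical covariates (numeric or
#'   factor/character).
#' @param time,event survival outcome.
#' @param ties Cox tie handling.
#' @return a `cox_fit` list with one entry per retained term (the risk
#'   group is the term named `risk_group`).
#' @export
multivariate_adjusted <- function(risk_group, covariates, time, event,
                                  ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates),
            nrow(covariates) == length(time))
  mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  X <- cbind(risk_group = as.numeric(risk_group), mm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("multivariate_adjusted: dropping collinear term(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  d <- data.frame(time = time, event = as.logical(event), X,
                  check.names = TRUE)
  terms <- setdiff(names(d), c("time", "event"))
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(terms, collapse = " + ")))
  fit_cox(form, d, ties)$summary
}
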