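# CFU longevity curves, trapezoidal AUC comparison, acute-stress survival,
# and the hypothesis tests used throughout (t-test on AUCs, Fisher's exact
# test on counts, one-way ANOVA with post hoc t-tests).

#' Trapezoidal area under a viability curve
#'
#' The area under the curve is divided into trapezoids, one per day interval:
#' `Area = (a + b)/2 * h`, where `a` and `b` are the viability values at the
#' two ends of the interval and `h` is the interval length in days; the
#' trapezoid areas are summed. Units are viability x days.
#'
#' @param days strictly increasing nonnegative timepoints (days).
#' @param viability viability values at `days` (day-0 normalized; values above
#'   1 are allowed and not clipped).
#' @return The total area under the curve.
#' @examples
#' trapezoid_auc(c(0, 10), c(1, 0.5))  # (1 + 0.5)/2 * 10 = 7.5
#' @export
trapezoid_auc <- function(days, viability) {
  n <- length(days)
  if (n < 2L || length(viability) != n)
    stop("input error: need >= 2 (day, viability) pairs of equal length")
  if (any(diff(days) <= 0))
    stop("input error: days must be strictly increasing")
  sum((viability[-n] + viability[-1L]) / 2 * diff(days))
}

#' Per-replicate AUCs from a viability table
#'
#' @param viab data frame from [cfu_viability()] (`condition, replicate, day,
#'   viability`).
#' @return Data frame `condition, replicate, auc`.
#' @export
replicate_aucs <- function(viab) {
  key <- interaction(viab$condition, viab$replicate, drop = TRUE)
  out <- lapply(split(viab, key), function(d) {
    d <- d[order(d$day), ]
    data.frame(condition = d$condition[1L], replicate = d$replicate[1L],
               auc = trapezoid_auc(d$day, d$viability))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate), , drop = FALSE]
}

.stars <- function(p) if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"

#' Compare longevity between two conditions by AUC t-test
#'
#' Two-sided two-sample t-test on per-replicate areas under the viability
#' curves. The pooled-variance (Student's) test is the default, appropriate
#' for the usual three replicates per group; Welch's test is available by
#' flag. Significance stars follow the figure-legend convention
#' (`**` p < 0.01, `*` p < 0.05, otherwise `NS`).
#'
#' @param auc_a,auc_b numeric vectors of per-replicate AUCs (>= 2 each).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return List with `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_auc <- function(auc_a, auc_b, var_equal = TRUE) {
  if (length(auc_a) < 2L || length(auc_b) < 2L)
    stop("input error: need >= 2 replicates per group")
  if (sd(auc_a) == 0 && sd(auc_b) == 0) {
    if (mean(auc_a) == mean(auc_b)) {
      return(list(t = 0, df = length(auc_a) + length(auc_b) - 2L, p = 1,
                  stars = "NS", mean_a = mean(auc_a), mean_b = mean(auc_b)))
    }
    return(list(t = sign(mean(auc_a) - mean(auc_b)) * Inf,
                df = length(auc_a) + length(auc_b) - 2L, p = 0, stars = "**",
                mean_a = mean(auc_a), mean_b = mean(auc_b)))
  }
  tt <- t.test(auc_a, auc_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = .stars(tt$p.value),
       mean_a = mean(auc_a), mean_b = mean(auc_b))
}

#' Percent survival after an acute stress
#'
#' Percent survival is 100 times the number of CFUs on the treated (UV or
#' heat-shocked) plate divided by the number on the untreated control plate,
#' computed per replicate and averaged across replicates.
#'
#' @param assay data frame with columns `cfu_untreated`, `cfu_treated`
#'   (one row per replicate), e.g. one sample of [read_stress_csv()] output.
#' @return List with `percent_survival` (per replicate), `mean_percent`,
#'   `n_replicates`. Replicates with zero untreated CFUs are dropped with a
#'   warning; if all are dropped an error is raised.
#' @examples
#' stress_survival(data.frame(cfu_untreated = 200, cfu_treated = 50))
#' @export
stress_survival <- function(assay) {
  keep <- assay$cfu_untreated > 0
  if (any(!keep))
    warning(sum(!keep), " replicate(s) with zero untreated CFUs dropped")
  if (!any(keep)) stop("input error: no replicate with untreated CFUs > 0")
  ps <- 100 * assay$cfu_treated[keep] / assay$cfu_untreated[keep]
  list(percent_survival = ps, mean_percent = mean(ps), n_replicates = sum(keep))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (the
#' standard two-sided convention; a relative tolerance of 1e-7 guards ties
#' against floating-point noise). Other two-sided conventions can differ in
#' the third decimal.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))  # 1
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("input error: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("input error: counts must be nonnegative integers")
  if (sum(tab) == 0) stop("input error: at least one margin must be positive")
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(tab[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' One-way ANOVA with post hoc pairwise t-tests
#'
#' One-way ANOVA F and p over all groups; for each requested pair, a
#' two-sided two-sample (pooled-variance) t-test. Raw p-values are reported,
#' matching the study's convention of uncorrected post hoc comparisons; a
#' Bonferroni-adjusted column is optional.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param pairs optional list of length-2 character vectors naming the
#'   comparisons; default all pairs.
#' @param bonferroni add a Bonferroni-adjusted p column (default FALSE).
#' @return List with `F`, `df1`, `df2`, `p`, and `posthoc` (data frame
#'   `group_a, group_b, t, p, stars`, plus `p_bonferroni` if requested).
#' @export
anova_posthoc <- function(groups, pairs = NULL, bonferroni = FALSE) {
  if (length(groups) < 2L) stop("input error: need >= 2 groups")
  if (any(lengths(groups) < 2L))
    stop("input error: every group needs >= 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(values ~ g)
  an <- anova(fit)
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }  # zero residual + zero between variance
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- list()
    for (i in 1:(length(nm) - 1L)) for (j in (i + 1L):length(nm))
      pairs[[length(pairs) + 1L]] <- c(nm[i], nm[j])
  }
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    a <- groups[[pr[1L]]]; b <- groups[[pr[2L]]]
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
      tstat <- if (p == 1) 0 else sign(mean(a) - mean(b)) * Inf
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      p <- tt$p.value; tstat <- unname(tt$statistic)
    }
    data.frame(group_a = pr[1L], group_b = pr[2L], t = tstat, p = p,
               stars = .stars(p))
  }))
  if (bonferroni) ph$p_bonferroni <- stats::p.adjust(ph$p, "bonferroni")
  list(F = Fv, df1 = unname(an$Df[1L]), df2 = unname(an$Df[2L]), p = pv,
       posthoc = ph)
}

#' Exponential decay rate from CFU counts
#'
#' Fits the log-linear colony-count model `count ~ Poisson(N0 * exp(-lambda *
#' day))` per condition with a Poisson GLM (log link), pooling replicates.
#' The decay rate is the negated day coefficient; `half_life_days` is
#' `log(2) / lambda`.
#'
#' @param cfu CFU table as from [read_cfu_csv()].
#' @return Data frame `condition, lambda_per_day, half_life_days`.
#' @export
fit_decay_rate <- function(cfu) {
  out <- lapply(split(cfu, cfu$condition), function(d) {
    fit <- glm(count ~ day + offset(log(dilution)), family = poisson(), data = d)
    lam <- -unname(coef(fit)["day"])
    data.frame(condition = d$condition[1L], lambda_per_day = lam,
               half_life_days = log(2) / lam)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
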