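# The cohort statistics chain: feature-vs-grade rank tests, survival models,
# ROC cutoff selection, Kaplan-Meier curves and the stage-by-imaging
# recurrence table.

#' @importFrom survival Surv coxph survfit survdiff
NULL

#' @keywords internal
#' @noRd
checkCohort <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  invisible(cohort)
}

# rank tests -------------------------------------------------------------

#' Kruskal-Wallis test of an imaging feature across IHC grades
#'
#' Tie-corrected H with a chi-square p-value on k - 1 degrees of freedom.
#' As a rank statistic it is invariant under strictly monotone transforms of
#' the feature.
#'
#' @param cohort cohort data.frame.
#' @param featureName feature column.
#' @param marker grouping column (an IHC grade column such as `"cd163"`, or
#'   any discrete column).
#' @return list: `H`, `df`, `p`, `groups` (per-group n).
#' @examples
#' coh <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                   g = rep(0:2, each = 3))
#' kruskalWallisByGrade(coh, "x", "g")$H  # 7.2
#' @export
kruskalWallisByGrade <- function(cohort, featureName, marker) {
  checkCohort(cohort, c(featureName, marker))
  keep <- stats::complete.cases(cohort[, c(featureName, marker)])
  x <- cohort[[featureName]][keep]
  g <- factor(cohort[[marker]][keep])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty grade groups")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = nlevels(g) - 1L, p = 1,
                groups = table(g)))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, groups = table(g))
}

#' Dunn's rank-based post-hoc comparisons
#'
#' Pairwise z statistics from mean-rank differences with tie-corrected
#' variance, for groups that a significant Kruskal-Wallis test flagged.
#' Unadjusted two-sided p-values by default; Bonferroni/Holm via `adjust`.
#'
#' @param cohort,featureName,marker as in [kruskalWallisByGrade()].
#' @param pairs optional list of length-2 vectors of group labels; default all
#'   pairs.
#' @param adjust p-adjustment method (`"none"`, `"bonferroni"`, `"holm"`, or
#'   any [stats::p.adjust()] method).
#' @return data.frame: group1, group2, z, p, p_adjusted.
#' @export
dunnPosthoc <- function(cohort, featureName, marker, pairs = NULL,
                        adjust = "none") {
  checkCohort(cohort, c(featureName, marker))
  keep <- stats::complete.cases(cohort[, c(featureName, marker)])
  x <- cohort[[featureName]][keep]
  g <- droplevels(factor(cohort[[marker]][keep]))
  if (nlevels(g) < 2L) stop("need at least two groups")
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tieTerm / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- table(g)
  if (is.null(pairs)) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- as.character(pr[1]); b <- as.character(pr[2])
    if (!a %in% levels(g) || ns[[a]] == 0L || !b %in% levels(g) || ns[[b]] == 0L)
      stop("pair (", a, ", ", b, ") references an empty group")
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(sigma2 * (1 / ns[[a]] + 1 / ns[[b]]))
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  attr(out, "adjust") <- adjust
  out
}

#' Mann-Whitney U test between two groups
#'
#' U is reported for the first factor level (sum of its ranks minus
#' n1(n1+1)/2). The p-value uses exact permutation enumeration (tie-safe)
#' when both groups have at most `exactMaxN` observations, otherwise the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param cohort cohort data.frame.
#' @param featureName feature column.
#' @param groupName two-level grouping column (e.g. `"tumor_grade"`).
#' @param exactMaxN exact-enumeration threshold per group (default 8).
#' @return list: `U`, `p`, `method`, `groups`.
#' @export
mannWhitney <- function(cohort, featureName, groupName, exactMaxN = 8L) {
  checkCohort(cohort, c(featureName, groupName))
  keep <- stats::complete.cases(cohort[, c(featureName, groupName)])
  x <- cohort[[featureName]][keep]
  g <- droplevels(factor(cohort[[groupName]][keep]))
  if (nlevels(g) != 2L) stop("grouping must have exactly two non-empty levels")
  x1 <- x[g == levels(g)[1]]
  x2 <- x[g == levels(g)[2]]
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  r <- rank(c(x1, x2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exactMaxN && n2 <= exactMaxN) {
    # exact permutation distribution of U (valid with ties)
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(U = U, p = min(p, 1), method = method,
       groups = stats::setNames(c(n1, n2), levels(g)))
}

# Cox modelling ----------------------------------------------------------

#' Per-unit covariate scalings for hazard ratios
#'
#' Divisors applied before fitting so hazard ratios are per reporting unit:
#' CoV and uniformity per 0.10 increase, MTV per 10 cm^3, TLG per 10 g,
#' everything else per 1.0.
#'
#' @return named numeric of divisors.
#' @export
defaultCovariateScalings <- function() {
  c(cov_suv = 0.10, uniformity = 0.10, mtv_cm3 = 10, tlg_g = 10)
}

#' Derive model-ready covariate columns from a cohort
#'
#' Adds indicator columns: `stage_iii_iv` (TNM III-IV), `cea_ge5` (CEA
#' dichotomized at 5 ng/ml), `sex_man`, `grade_high`, `lvi_present`,
#' `adjuvant_yes`, `loc_right_colon`, `loc_rectum` (left colon reference).
#' Columns are only created when their source exists.
#'
#' @param cohort cohort data.frame.
#' @return the cohort with indicator columns appended.
#' @export
prepareCovariates <- function(cohort) {
  if ("tnm_stage" %in% names(cohort))
    cohort$stage_iii_iv <- as.integer(cohort$tnm_stage %in% c("III", "IV"))
  if ("cea_ng_ml" %in% names(cohort))
    cohort$cea_ge5 <- as.integer(cohort$cea_ng_ml >= 5)
  if ("sex" %in% names(cohort))
    cohort$sex_man <- as.integer(cohort$sex == "M")
  if ("tumor_grade" %in% names(cohort))
    cohort$grade_high <- as.integer(cohort$tumor_grade == "high")
  if ("lvi" %in% names(cohort))
    cohort$lvi_present <- as.integer(cohort$lvi == "present")
  if ("adjuvant" %in% names(cohort))
    cohort$adjuvant_yes <- as.integer(cohort$adjuvant == "yes")
  if ("tumor_location" %in% names(cohort)) {
    cohort$loc_right_colon <- as.integer(cohort$tumor_location == "right_colon")
    cohort$loc_rectum <- as.integer(cohort$tumor_location == "rectum")
  }
  cohort
}

#' Cox proportional-hazards fit with per-unit covariate scaling
#'
#' Partial-likelihood maximization (Efron tie handling) after dividing each
#' covariate by its reporting unit, so hazard ratios are per printed unit.
#' Complete-case analysis; excluded rows are counted in the result.
#'
#' @param cohort cohort data.frame (derived indicators are added via
#'   [prepareCovariates()]).
#' @param covariates character vector of covariate column names.
#' @param scalings named divisors, see [defaultCovariateScalings()].
#' @return data.frame (one row per covariate): term, unit, coef,
#'   hazard_ratio, ci_lower, ci_upper, p; attributes `loglik`, `n`, `nevent`,
#'   `excluded`.
#' @export
coxFit <- function(cohort, covariates,
                   scalings = defaultCovariateScalings()) {
  if (length(covariates) == 0L) stop("no covariates supplied")
  cohort <- prepareCovariates(cohort)
  checkCohort(cohort, c("rfs_months", "event", covariates))
  keep <- stats::complete.cases(cohort[, c("rfs_months", "event", covariates)])
  excluded <- sum(!keep)
  dat <- cohort[keep, , drop = FALSE]
  if (sum(dat$event) < 1L) stop("no events in the cohort")
  X <- as.data.frame(lapply(covariates, function(cv) {
    unit <- if (cv %in% names(scalings)) scalings[[cv]] else 1
    as.numeric(dat[[cv]]) / unit
  }), col.names = covariates, check.names = FALSE)
  qrX <- qr(as.matrix(X))
  if (qrX$rank < ncol(X)) stop("covariates are collinear")
  df <- cbind(data.frame(.time = dat$rfs_months, .event = dat$event), X)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        stop("monotone partial likelihood (perfect separation?); ",
             "consider a penalized fit: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(
    term = covariates,
    unit = vapply(covariates, function(cv)
      if (cv %in% names(scalings)) scalings[[cv]] else 1, numeric(1)),
    coef = unname(co[, "coef"]),
    hazard_ratio = unname(ci[, "exp(coef)"]),
    ci_lower = unname(ci[, "lower .95"]),
    ci_upper = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  attr(out, "loglik") <- fit$loglik[length(fit$loglik)]
  attr(out, "n") <- sm$n
  attr(out, "nevent") <- sm$nevent
  attr(out, "excluded") <- excluded
  out
}

#' Univariate screening of candidate covariates
#'
#' Fits a univariate Cox model per candidate and returns those with p below
#' `alpha`, in input order (the paper's rule for building the multivariate
#' model).
#'
#' @param cohort cohort data.frame.
#' @param candidates character vector of covariate names.
#' @param alpha significance threshold (default 0.05).
#' @param scalings per-unit divisors.
#' @return character vector of selected covariates, with attribute `table`
#'   (per-candidate coef/HR/p).
#' @export
univariateScreen <- function(cohort, candidates, alpha = 0.05,
                             scalings = defaultCovariateScalings()) {
  if (length(candidates) == 0L) stop("no candidate covariates")
  rows <- lapply(candidates, function(cv) coxFit(cohort, cv, scalings))
  tab <- do.call(rbind, rows)
  selected <- tab$term[tab$p < alpha]
  if (length(selected) == 0L)
    message("no covariate significant at alpha = ", alpha,
            "; multivariate stage should be skipped")
  structure(selected, table = tab)
}

# ROC cutoff -------------------------------------------------------------

#' Optimal dichotomization cutoff by Youden's J
#'
#' Exhaustive scan over midpoints of consecutive sorted unique feature
#' values. Both orientations (high values predict the outcome, or low values
#' do) are evaluated; the cutoff maximizing J = sensitivity + specificity - 1
#' is returned, ties broken toward the lower cutoff (and toward the
#' "high-positive" orientation).
#'
#' @param cohort cohort data.frame.
#' @param featureName feature column.
#' @param outcome binary outcome column (default `"event"`).
#' @return list: `cutoff`, `J`, `direction` (`">="` when values at or above
#'   the cutoff are called positive, otherwise `"<="`), `sensitivity`,
#'   `specificity`, `criterion = "youden"`.
#' @export
rocCutoff <- function(cohort, featureName, outcome = "event") {
  checkCohort(cohort, c(featureName, outcome))
  keep <- stats::complete.cases(cohort[, c(featureName, outcome)])
  x <- cohort[[featureName]][keep]
  y <- as.integer(cohort[[outcome]][keep])
  if (length(unique(y)) != 2L) stop("both outcome classes must be present")
  u <- sort(unique(x))
  if (length(u) < 2L) stop("feature is constant")
  cuts <- (u[-1] + u[-length(u)]) / 2
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  best <- list(J = -Inf)
  for (cc in cuts) {
    for (dir in c(">=", "<=")) {
      pred <- if (dir == ">=") x >= cc else x <= cc
      sens <- sum(pred & y == 1) / nPos
      spec <- sum(!pred & y == 0) / nNeg
      J <- sens + spec - 1
      if (J > best$J + 1e-12) {
        best <- list(cutoff = cc, J = J, direction = dir,
                     sensitivity = sens, specificity = spec)
      }
    }
  }
  c(best, list(criterion = "youden"))
}

# survival curves --------------------------------------------------------

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit estimates per group with Greenwood standard errors, the
#' survival probability at a query time (default 60 months, the 5-year mark),
#' and the log-rank chi-square/p across groups.
#'
#' @param cohort cohort data.frame.
#' @param grouping grouping column name, or a vector of group labels aligned
#'   with the cohort rows.
#' @param queryTime time (months) at which survival is reported per group.
#' @return list: `curves` (named list of data.frames time/n_risk/n_event/
#'   survival/lower/upper), `survivalAtQuery` (named, per group), `queryTime`,
#'   `chisq`, `df`, `p` (NULL when only one group).
#' @export
kmLogrank <- function(cohort, grouping, queryTime = 60) {
  checkCohort(cohort, c("rfs_months", "event"))
  g <- if (is.character(grouping) && length(grouping) == 1L &&
           grouping %in% names(cohort)) cohort[[grouping]] else grouping
  if (length(g) != nrow(cohort)) stop("grouping length mismatch")
  keep <- stats::complete.cases(data.frame(cohort$rfs_months, cohort$event, g))
  dat <- data.frame(time = cohort$rfs_months[keep],
                    event = as.integer(cohort$event[keep]),
                    group = droplevels(factor(g[keep])))
  if (nrow(dat) == 0L) stop("no usable records after removing missing values")
  if (any(table(dat$group) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat,
                           conf.type = "plain")
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(dat$group)[1], length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  curves <- lapply(split(seq_along(sm$time), strata), function(ii) {
    data.frame(time = sm$time[ii], n_risk = sm$n.risk[ii],
               n_event = sm$n.event[ii], survival = sm$surv[ii],
               lower = sm$lower[ii], upper = sm$upper[ii])
  })
  survAt <- vapply(curves, function(cv) {
    ev <- cv[cv$n_event > 0 & cv$time <= queryTime, , drop = FALSE]
    if (nrow(ev) == 0L) 1.0 else ev$survival[nrow(ev)]
  }, numeric(1))
  out <- list(curves = curves, survivalAtQuery = survAt, queryTime = queryTime,
              chisq = NULL, df = NULL, p = NULL)
  if (nlevels(dat$group) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    df <- length(sd$n) - 1L
    out$chisq <- sd$chisq
    out$df <- df
    out$p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  }
  out
}

# recurrence stratification ---------------------------------------------

#' Recurrence rates stratified by TNM stage and the CoV/SLR imaging groups
#'
#' Patients split into stage I-II vs III-IV crossed with three imaging
#' groups: both favorable (CoV > `covCutoff` and SLR < `slrCutoff`), mixed
#' (exactly one unfavorable), and both unfavorable (CoV <= `covCutoff` and
#' SLR >= `slrCutoff`). Each cell reports events / total and the rate in
#' percent (NA for an empty cell). Records missing a needed column are
#' excluded and counted.
#'
#' @param cohort cohort data.frame with `cov_suv`, `slr`, `tnm_stage`,
#'   `event`.
#' @param covCutoff CoV SUV cutoff (default 0.25).
#' @param slrCutoff SLR cutoff (default 0.83).
#' @return data.frame: stage_group, imaging_group, events, total,
#'   rate_percent; attribute `excluded`.
#' @export
recurrenceStratTable <- function(cohort, covCutoff = 0.25, slrCutoff = 0.83) {
  checkCohort(cohort, c("cov_suv", "slr", "tnm_stage", "event"))
  keep <- stats::complete.cases(cohort[, c("cov_suv", "slr", "tnm_stage", "event")])
  excluded <- sum(!keep)
  dat <- cohort[keep, , drop = FALSE]
  stage <- ifelse(dat$tnm_stage %in% c("I", "II"), "I-II", "III-IV")
  covFav <- dat$cov_suv > covCutoff
  slrFav <- dat$slr < slrCutoff
  imaging <- ifelse(covFav & slrFav, "both_favorable",
                    ifelse(!covFav & !slrFav, "both_unfavorable", "mixed"))
  cells <- expand.grid(stage_group = c("I-II", "III-IV"),
                       imaging_group = c("both_favorable", "mixed",
                                         "both_unfavorable"),
                       stringsAsFactors = FALSE)
  cells$events <- NA_integer_; cells$total <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sel <- stage == cells$stage_group[i] & imaging == cells$imaging_group[i]
    cells$total[i] <- sum(sel)
    cells$events[i] <- sum(dat$event[sel])
  }
  cells$rate_percent <- ifelse(cells$total > 0,
                               100 * cells$events / cells$total, NA_real_)
  attr(cells, "excluded") <- excluded
  attr(cells, "cutoffs") <- c(cov_suv = covCutoff, slr = slrCutoff)
  cells
}

#' Baseline description of a cohort
#'
#' Counts and percentages for the categorical covariates and IHC grades,
#' median (range) for the continuous ones.
#'
#' @param cohort cohort data.frame.
#' @return list: `n`, `categorical` (data.frame variable/level/count/percent),
#'   `continuous` (data.frame variable/median/min/max).
#' @export
cohortSummary <- function(cohort) {
  n <- nrow(cohort)
  catVars <- intersect(c("sex", "tumor_location", "tumor_grade", "lvi",
                         "tnm_stage", "adjuvant", "cd4", "cd8", "cd163",
                         "il6", "mmp11", "event"), names(cohort))
  catTab <- do.call(rbind, lapply(catVars, function(v) {
    tb <- table(cohort[[v]], useNA = "no")
    data.frame(variable = v, level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb),
               stringsAsFactors = FALSE)
  }))
  contVars <- intersect(c("age_years", "cea_ng_ml", "tumor_size_cm",
                          "rfs_months"), names(cohort))
  contTab <- do.call(rbind, lapply(contVars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    data.frame(variable = v, median = stats::median(x), min = min(x),
               max = max(x), stringsAsFactors = FALSE)
  }))
  list(n = n, categorical = catTab, continuous = contTab)
}
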