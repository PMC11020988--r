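test_that("Kruskal-Wallis matches the rank formula and is rank-invariant", {
  coh <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9), g = rep(0:2, each = 3))
  kw <- kruskalWallisByGrade(coh, "x", "g")
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$H, oracleKWNoTies(split(coh$x, coh$g)), tolerance = 1e-12)

  # identical multisets across groups -> H = 0
  cohT <- data.frame(x = rep(c(1, 2, 3), 3), g = rep(0:2, each = 3))
  expect_equal(kruskalWallisByGrade(cohT, "x", "g")$H, 0, tolerance = 1e-12)

  allTied <- data.frame(x = rep(5, 9), g = rep(0:2, each = 3))
  kwT <- kruskalWallisByGrade(allTied, "x", "g")
  expect_equal(kwT$H, 0)
  expect_equal(kwT$p, 1)

  # invariance under a strictly monotone transform
  cohM <- data.frame(x = exp(coh$x / 2), g = coh$g)
  expect_equal(kruskalWallisByGrade(cohM, "x", "g")$H, kw$H,
               tolerance = 1e-12)
  expect_error(kruskalWallisByGrade(data.frame(x = 1:5, g = rep(1, 5)),
                                    "x", "g"), "two")
})

test_that("Dunn post-hoc matches the direct formula", {
  coh <- data.frame(x = c(1:5, 6:10, 11:15), g = rep(0:2, each = 5))
  dn <- dunnPosthoc(coh, "x", "g")
  groups <- split(coh$x, coh$g)
  for (i in seq_len(nrow(dn))) {
    zi <- oracleDunnZ(groups, as.integer(dn$group1[i]) + 1L,
                      as.integer(dn$group2[i]) + 1L)
    expect_equal(dn$z[i], unname(zi), tolerance = 1e-9)
  }
  # antisymmetry
  dn21 <- dunnPosthoc(coh, "x", "g", pairs = list(c("1", "0")))
  dn12 <- dunnPosthoc(coh, "x", "g", pairs = list(c("0", "1")))
  expect_equal(dn21$z, -dn12$z, tolerance = 1e-12)

  # identical groups -> z = 0, p = 1
  cohEq <- data.frame(x = rep(c(2, 4, 6), 2), g = rep(0:1, each = 3))
  dnEq <- dunnPosthoc(cohEq, "x", "g")
  expect_equal(dnEq$z, 0, tolerance = 1e-12)
  expect_equal(dnEq$p, 1, tolerance = 1e-12)

  expect_error(dunnPosthoc(coh, "x", "g", pairs = list(c("0", "9"))), "empty")

  # Bonferroni adjustment is applied on request
  dnB <- dunnPosthoc(coh, "x", "g", adjust = "bonferroni")
  expect_equal(dnB$p_adjusted, pmin(dnB$p * 3, 1), tolerance = 1e-12)
})

test_that("Mann-Whitney U follows the documented convention", {
  coh <- data.frame(x = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  mw <- mannWhitney(coh, "x", "g")
  expect_equal(mw$U, 0)  # first level 'a' has all the small values
  expect_identical(mw$method, "exact")

  swapped <- coh; swapped$g <- rev(coh$g)
  mwS <- mannWhitney(swapped, "x", "g")
  expect_equal(mwS$U, 9 - 0)  # label swap maps U -> n1*n2 - U

  eq <- data.frame(x = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(mannWhitney(eq, "x", "g")$p, 1)

  # large groups use the tie-corrected normal approximation and match
  # wilcox.test's statistic
  set.seed(10)
  cohL <- data.frame(x = round(rnorm(60), 1), g = rep(c("a", "b"), 30))
  mwL <- mannWhitney(cohL, "x", "g")
  wt <- stats::wilcox.test(x ~ g, data = cohL, exact = FALSE, correct = FALSE)
  expect_identical(mwL$method, "normal_tie_corrected")
  expect_equal(mwL$U, unname(wt$statistic))
  expect_equal(mwL$p, wt$p.value, tolerance = 1e-9)
  expect_error(mannWhitney(data.frame(x = 1:3, g = rep("a", 3)), "x", "g"),
               "two")
})

test_that("Cox fit honours symmetry, scaling and the partial likelihood", {
  # two groups with identical event patterns -> coef 0, HR 1
  coh <- data.frame(rfs_months = rep(c(5, 10, 15, 20), 2),
                    event = rep(c(1, 0, 1, 0), 2),
                    grp = rep(0:1, each = 4))
  fit <- coxFit(coh, "grp")
  expect_equal(fit$coef, 0, tolerance = 1e-9)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-9)

  # tiny dataset, no ties: fitted coef maximizes the hand-expanded partial
  # likelihood (1-D grid search oracle)
  tiny <- data.frame(rfs_months = c(2, 4, 6, 8, 10, 12),
                     event = c(1, 1, 0, 1, 1, 0),
                     x = c(0.9, 0.2, 0.5, 0.8, 0.1, 0.4))
  fitT <- coxFit(tiny, "x")
  grid <- seq(-6, 6, by = 1e-4)
  ll <- vapply(grid, oraclePartialLogLik, numeric(1),
               time = tiny$rfs_months, event = tiny$event, x = tiny$x)
  expect_lt(abs(fitT$coef - grid[which.max(ll)]), 1e-3)
  expect_equal(oraclePartialLogLik(fitT$coef, tiny$rfs_months, tiny$event,
                                   tiny$x),
               attr(fitT, "loglik"), tolerance = 1e-6)

  # per-unit scaling: HR for cov_suv is per 0.10 increase
  set.seed(33)
  coh2 <- generateCohort(cohortSpec(nPatients = 400L, seed = 77L))
  f1 <- coxFit(coh2, "cov_suv")
  coh2$cov_scaled <- coh2$cov_suv / 0.10
  f2 <- coxFit(coh2, "cov_scaled", scalings = c(dummy = 1))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)

  noEvents <- data.frame(rfs_months = 1:5, event = rep(0, 5), x = 1:5)
  expect_error(coxFit(noEvents, "x"), "no events")
  collinear <- data.frame(rfs_months = 1:6, event = rep(1, 6),
                          a = 1:6, b = 2 * (1:6))
  expect_error(coxFit(collinear, c("a", "b")), "collinear")
  sep <- data.frame(rfs_months = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1), x = c(1, 1, 1, 0, 0, 0))
  expect_error(coxFit(sep, "x"), "penalized|separation")
})

test_that("univariate screening selects by p-value in input order", {
  coh <- generateCohort(cohortSpec(nPatients = 1000L, seed = 55L))
  coh$pure_noise <- stats::rnorm(nrow(coh))
  sel <- univariateScreen(coh, c("slr", "pure_noise"), alpha = 0.05)
  expect_true("slr" %in% sel)
  all <- univariateScreen(coh, c("slr", "pure_noise"), alpha = 1.0)
  expect_identical(as.character(all), c("slr", "pure_noise"))
  expect_message(
    univariateScreen(coh, "pure_noise", alpha = 1e-12),
    "no covariate significant")
})

test_that("strong predictors are selected and null ones rejected with power", {
  correct <- 0L
  reps <- 60
  for (k in seq_len(reps)) {
    coh <- generateCohort(cohortSpec(nPatients = 1000L, seed = 7000L + k))
    coh$pure_noise <- stats::rnorm(nrow(coh))
    sel <- suppressMessages(
      univariateScreen(coh, c("slr", "pure_noise"), alpha = 0.05))
    if ("slr" %in% sel && !"pure_noise" %in% sel) correct <- correct + 1L
  }
  expect_gte(correct / reps, 0.9)
})

test_that("ROC cutoff maximizes Youden's J and matches brute force", {
  # perfectly separating feature: lowest midpoint in the gap, J = 1
  coh <- data.frame(x = c(1, 2, 3, 7, 8, 9), event = c(0, 0, 0, 1, 1, 1))
  rc <- rocCutoff(coh, "x")
  expect_equal(rc$J, 1)
  expect_equal(rc$cutoff, 5)  # midpoint of the (3, 7) gap
  expect_identical(rc$direction, ">=")

  set.seed(21)
  for (k in 1:100) {
    n <- sample(20:60, 1)
    x <- round(stats::runif(n, 0, 10), 1)
    y <- stats::rbinom(n, 1, plogis((x - 5) / 2))
    if (length(unique(y)) < 2) next
    got <- rocCutoff(data.frame(x = x, event = y), "x")
    ref <- oracleRocCutoff(x, y)
    expect_equal(got$J, ref$J, tolerance = 1e-12)
    expect_equal(got$cutoff, ref$cutoff, tolerance = 1e-12)
  }

  # label-permuted feature: J stays small
  set.seed(99)
  high <- 0L
  for (k in 1:50) {
    x <- stats::rnorm(500)
    y <- sample(rep(0:1, each = 250))
    if (rocCutoff(data.frame(x = x, event = y), "x")$J > 0.2)
      high <- high + 1L
  }
  expect_lte(high / 50, 0.05)

  expect_error(rocCutoff(data.frame(x = 1:4, event = rep(1, 4)), "x"),
               "both outcome classes")
})

test_that("Kaplan-Meier matches the hand product-limit example", {
  coh <- data.frame(rfs_months = c(5, 10, 15, 20),
                    event = c(0, 1, 0, 1))
  km <- kmLogrank(coh, rep("all", 4), queryTime = 10)
  expect_equal(unname(km$survivalAtQuery), 2 / 3, tolerance = 1e-12)
  cv <- km$curves[[1]]
  expect_equal(cv$survival[cv$time == 20], 0)
  expect_equal(cv$survival[cv$time == 10], 2 / 3, tolerance = 1e-12)

  # no events -> survival identically 1
  noEv <- data.frame(rfs_months = c(3, 6, 9), event = c(0, 0, 0))
  kmN <- kmLogrank(noEv, rep("all", 3))
  expect_true(all(kmN$curves[[1]]$survival == 1))

  # duplicated identical groups -> log-rank chi-square 0, p = 1
  dup <- rbind(cbind(coh, g = "a"), cbind(coh, g = "b"))
  kmD <- kmLogrank(dup, "g")
  expect_equal(kmD$chisq, 0, tolerance = 1e-12)
  expect_equal(kmD$p, 1, tolerance = 1e-12)
  expect_error(kmLogrank(coh, rep(NA, 4)), "no usable records")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(8)
  t0 <- sort(stats::rexp(40, 0.1))
  coh <- data.frame(rfs_months = t0, event = rep(1, 40))
  km <- kmLogrank(coh, rep("all", 40))
  cv <- km$curves[[1]]
  emp <- vapply(cv$time, function(tt) mean(t0 > tt), numeric(1))
  expect_equal(cv$survival, emp, tolerance = 1e-12)
})

test_that("the stratified recurrence table reproduces printed-count arithmetic", {
  mk <- function(n, events, stage, covFav, slrFav) {
    data.frame(
      tnm_stage = stage,
      cov_suv = if (covFav) 0.30 else 0.20,
      slr = if (slrFav) 0.70 else 0.90,
      event = c(rep(1L, events), rep(0L, n - events))
    )
  }
  coh <- rbind(
    mk(19, 1, "I", TRUE, TRUE),    mk(15, 1, "III", TRUE, TRUE),
    mk(32, 5, "II", TRUE, FALSE),  mk(21, 6, "IV", FALSE, TRUE),
    mk(12, 4, "I", FALSE, FALSE),  mk(20, 13, "III", FALSE, FALSE)
  )
  tab <- recurrenceStratTable(coh)
  get <- function(st, im) tab$rate_percent[tab$stage_group == st &
                                           tab$imaging_group == im]
  expect_equal(get("I-II", "both_favorable"), 100 * 1 / 19, tolerance = 1e-12)
  expect_equal(get("III-IV", "both_favorable"), 100 * 1 / 15, tolerance = 1e-12)
  expect_equal(get("I-II", "mixed"), 100 * 5 / 32, tolerance = 1e-12)
  expect_equal(get("III-IV", "mixed"), 100 * 6 / 21, tolerance = 1e-12)
  expect_equal(get("I-II", "both_unfavorable"), 100 * 4 / 12, tolerance = 1e-12)
  expect_equal(get("III-IV", "both_unfavorable"), 100 * 13 / 20,
               tolerance = 1e-12)
  expect_equal(sum(tab$total), nrow(coh) - attr(tab, "excluded"))

  # empty cell reported as 0/0 with NA rate
  small <- mk(5, 2, "I", TRUE, TRUE)
  tabS <- recurrenceStratTable(small)
  expect_true(any(tabS$total == 0 & is.na(tabS$rate_percent)))

  # boundary membership: CoV exactly at the cutoff is unfavorable,
  # SLR exactly at the cutoff is unfavorable
  bnd <- data.frame(tnm_stage = "I", cov_suv = 0.25, slr = 0.83, event = 0L)
  tabB <- recurrenceStratTable(bnd)
  expect_equal(tabB$total[tabB$stage_group == "I-II" &
                          tabB$imaging_group == "both_unfavorable"], 1)

  # records with missing features are excluded and counted
  cohNA <- coh
  cohNA$cov_suv[1] <- NA
  tabNA <- recurrenceStratTable(cohNA)
  expect_equal(attr(tabNA, "excluded"), 1)
})

test_that("cohort summary reports counts, percents and medians", {
  coh <- generateCohort(cohortSpec(nPatients = 200L, seed = 14L))
  sm <- cohortSummary(coh)
  expect_equal(sm$n, 200)
  sexRow <- sm$categorical[sm$categorical$variable == "sex", ]
  expect_equal(sum(sexRow$count), 200)
  expect_equal(sum(sexRow$percent), 100, tolerance = 1e-9)
  expect_true("rfs_months" %in% sm$continuous$variable)
})

test_that("Youden cutoff agrees with pROC on a monotone-risk feature", {
  set.seed(64)
  x <- round(stats::rnorm(200, 5, 2), 2)
  y <- stats::rbinom(200, 1, stats::plogis(x - 5))
  got <- rocCutoff(data.frame(x = x, event = y), "x")
  r <- pROC::roc(y, x, direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "youden"))
  # pROC reports J + 1 as "youden"; thresholds are both inter-value midpoints
  expect_equal(got$J, unname(best$youden) - 1, tolerance = 1e-9)
  expect_equal(got$cutoff, unname(best$threshold), tolerance = 1e-9)
  expect_identical(got$direction, ">=")
})
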