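test_that("risk sets follow the relocation rule", {
  # 10 tagged at interval 0; 1 dies there, 1 censored after it
  h <- do.call(make_histories,
               as.list(c("d", "a c", rep("a a", 8))))
  rs <- build_risk_sets(h, min_n = 1L)
  expect_equal(rs$n[rs$interval == 0], 10L)
  expect_equal(rs$d[rs$interval == 0], 1L)
  expect_equal(rs$n[rs$interval == 1], 8L)
  expect_equal(rs$d[rs$interval == 1], 0L)

  # all censored before any death: zero deaths everywhere
  h2 <- rep_histories("a a c", 5)
  rs2 <- build_risk_sets(h2, min_n = 1L)
  expect_true(all(rs2$d == 0))

  # not-detected intervals are excluded from the risk set
  h3 <- make_histories("a n a", "a a a")
  rs3 <- build_risk_sets(h3, min_n = 1L)
  expect_equal(rs3$n, c(2L, 1L, 2L))

  # min_n truncation drops sparse intervals, erroring when none remain
  expect_error(build_risk_sets(h3, min_n = 3L), "min_n")
  rs4 <- build_risk_sets(h3, min_n = 2L)
  expect_equal(rs4$interval, c(0L, 2L))
})

test_that("risk sets equal the generator's own exposure tally", {
  h <- simulate_cohort_histories(60, 0.8, n_intervals = 8,
                                 detection = 0.85)
  rs <- build_risk_sets(h, min_n = 1L)
  # independent tally straight off the table
  df <- as.data.frame(h)
  for (i in seq_len(nrow(rs))) {
    sel <- df$season == rs$season[i] & df$year == rs$year[i] &
      df$state %in% c("alive-detected", "dead")
    expect_equal(rs$n[i], sum(sel))
    expect_equal(rs$d[i], sum(df$state[sel] == "dead"))
  }
})

test_that("known-fate MLE matches the binomial closed forms", {
  # one interval, n = 10, d = 1
  h <- do.call(make_histories, as.list(c("d", rep("a", 9))))
  f <- fit_known_fate(build_risk_sets(h, min_n = 1L), "constant")
  expect_equal(unname(f$estimates), 0.9, tolerance = 1e-10)
  expect_equal(unname(sqrt(diag(f$vcov))), sqrt(0.9 * 0.1 / 10),
               tolerance = 1e-8)

  # constant model pools intervals: (10,1), (8,0) -> 17/18
  h2 <- do.call(make_histories,
                as.list(c("d", "a c", rep("a a", 8))))
  f2 <- fit_known_fate(build_risk_sets(h2, min_n = 1L), "constant")
  expect_equal(unname(f2$estimates), 17 / 18, tolerance = 1e-10)

  # no deaths: boundary at 1 with zero log-likelihood
  h3 <- rep_histories("a", 10)
  f3 <- fit_known_fate(build_risk_sets(h3, min_n = 1L), "constant")
  expect_equal(unname(f3$estimates), 1)
  expect_equal(f3$logL, 0)
  expect_true(f3$boundary)

  # the time model reproduces per-interval closed forms
  f4 <- fit_known_fate(build_risk_sets(h2, min_n = 1L), "time")
  expect_equal(unname(f4$estimates), c(9 / 10, 1), tolerance = 1e-10)
  expect_equal(f4$K, 2L)
})

test_that("logit-scale optimiser agrees with closed forms on random data", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(20:80, 4)
    d <- rbinom(4, n, 0.12)
    at <- interval_at(0:3, 2000L)
    rs <- structure(data.frame(year = at$year, season = at$season,
                               interval = 0:3, n = n, d = d),
                    class = c("risk_set", "data.frame"))
    ft <- fit_known_fate(rs, "time")
    fc <- fit_known_fate(rs, "constant")
    expect_equal(unname(ft$estimates), (n - d) / n, tolerance = 1e-8)
    expect_equal(unname(fc$estimates), sum(n - d) / sum(n),
                 tolerance = 1e-8)
    # AICc definition holds on the fit
    expect_equal(fc$aicc,
                 -2 * fc$logL + 2 * fc$K +
                   2 * fc$K * (fc$K + 1) / (fc$n_eff - fc$K - 1))
  }
})

test_that("AICc ranking penalises parameters and normalises weights", {
  h <- do.call(make_histories,
               as.list(c(rep("d", 3), rep("a a a a", 40))))
  rs <- build_risk_sets(h, min_n = 1L)
  fits <- list(fit_known_fate(rs, "constant"), fit_known_fate(rs, "time"))
  tab <- rank_models(fits)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta[1], 0)
  expect_equal(tab$evidence_ratio[1], 1)

  # single model: weight 1
  tab1 <- rank_models(fits[1])
  expect_equal(tab1$weight, 1)

  # equal likelihood, K = 1 vs 2: the simpler model ranks first
  f_small <- list(model = "constant", K = 1, logL = -10, n_eff = 100,
                  aicc = -2 * -10 + 2 * 1 + 2 * 1 * 2 / 98)
  f_big <- list(model = "time", K = 2, logL = -10, n_eff = 100,
                aicc = -2 * -10 + 2 * 2 + 2 * 2 * 3 / 97)
  class(f_small) <- class(f_big) <- "known_fate_fit"
  tab2 <- rank_models(list(f_big, f_small))
  expect_equal(tab2$model[1], "constant")

  # hand-computed AICc 100, 102, 110: weights from the direct formula
  mk <- function(a) structure(list(model = "m", K = 1, logL = 0,
                                   n_eff = 50, aicc = a),
                              class = "known_fate_fit")
  tab3 <- rank_models(list(mk(100), mk(102), mk(110)))
  w <- exp(-c(0, 2, 10) / 2)
  expect_equal(tab3$weight, w / sum(w), tolerance = 1e-12)

  # mixed n_eff is an error
  f_other <- f_small; f_other$n_eff <- 99
  expect_error(rank_models(list(f_small, f_other)), "n_eff")
})

test_that("annual survival compounds seasons with delta-method variance", {
  h <- do.call(make_histories,
               as.list(c(rep("d", 5), rep("a a a a", 95))))
  f <- fit_known_fate(build_risk_sets(h, min_n = 1L), "constant")
  ann <- annual_from_seasonal(f)
  S <- unname(f$estimates)
  v <- unname(diag(f$vcov))
  expect_equal(ann$S_hat, S^4, tolerance = 1e-12)
  expect_equal(ann$SE, sqrt((4 * S^3)^2 * v), tolerance = 1e-12)
  expect_true(ann$lower <= ann$S_hat && ann$S_hat <= ann$upper)
  expect_true(ann$lower >= 0 && ann$upper <= 1)

  # time model: product of the first four seasonal estimates
  ft <- fit_known_fate(build_risk_sets(h, min_n = 1L), "time")
  annt <- annual_from_seasonal(ft)
  expect_equal(annt$S_hat, prod(ft$estimates[1:4]), tolerance = 1e-12)

  # a fit shorter than a year cannot be annualised
  h2 <- rep_histories("a a", 20)
  f2 <- fit_known_fate(build_risk_sets(h2, min_n = 1L), "time")
  expect_error(annual_from_seasonal(f2), "fewer retained")

  # power identity at 0.95
  expect_equal(0.95^4, 0.81450625)
})

test_that("without staggering or censoring the product matches Kaplan-Meier", {
  h <- simulate_cohort_histories(80, 0.8, n_intervals = 4, detection = 1)
  rs <- build_risk_sets(h, min_n = 1L)
  ft <- fit_known_fate(rs, "time")
  km <- prod((rs$n - rs$d) / rs$n)
  expect_equal(annual_from_seasonal(ft)$S_hat, km, tolerance = 1e-10)
})

test_that("censoring by cause removes those deaths and never lowers survival", {
  df <- as.data.frame(make_histories("a a d", "a d", "a a a"))
  df$cause[df$state == "dead"] <- c("Wind turbine blade-strike",
                                    "Electrocution")
  h <- capture_histories(df)

  ct <- censor_by_cause(h, turbine_causes())
  expect_equal(sum(ct$state == "dead"), 1L)
  gone <- ct[ct$individual_id == "B001", ]
  expect_equal(gone$state[3], "censored")
  expect_true(all(is.na(gone$cause)))

  # empty censor set is the identity
  expect_equal(as.data.frame(censor_by_cause(h, character())),
               as.data.frame(h))
  # undiagnosed deaths are never censored
  h2 <- make_histories("a d")
  expect_equal(sum(censor_by_cause(h2, "Undiagnosed fatality")$state ==
                     "dead"), 1L)

  # monotonicity over nested censor sets on fixed data
  fit_s <- function(hh) {
    unname(fit_known_fate(build_risk_sets(hh, min_n = 1L),
                          "constant")$estimates)
  }
  s_all <- fit_s(h)
  s_turb <- fit_s(censor_by_cause(h, turbine_causes()))
  s_hum <- fit_s(censor_by_cause(h, human_causes()))
  expect_true(s_turb >= s_all)
  expect_true(s_hum >= s_turb)
})

test_that("sex-structured models need and use sex-split risk sets", {
  df <- rbind(as.data.frame(rep_histories("a a d", 12, sex = "female")),
              as.data.frame(rep_histories("a a a", 12, sex = "male")))
  df$individual_id <- paste0(df$sex, df$individual_id)
  h <- capture_histories(df)
  rs <- build_risk_sets(h, min_n = 1L, by_sex = TRUE)
  fs <- fit_known_fate(rs, "sex")
  expect_equal(fs$K, 2L)
  expect_lt(fs$estimates[["S[female]"]], fs$estimates[["S[male]"]])
  expect_error(fit_known_fate(build_risk_sets(h, min_n = 1L), "sex"),
               "sex-split")
  ann <- annual_from_seasonal(fs)
  expect_equal(ann$sex, c("female", "male"))
})

test_that("annual estimates cover truth at close to the nominal rate", {
  set.seed(97)
  S_true <- 0.85
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    h <- simulate_cohort_histories(500, S_true, n_intervals = 12)
    f <- fit_known_fate(build_risk_sets(h, min_n = 11L), "constant")
    ann <- annual_from_seasonal(f)
    hits <- hits + (ann$lower <= S_true && S_true <= ann$upper)
  }
  expect_gte(hits / n_rep, 0.93)
})
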