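test_that("config validation catches inconsistent settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(territories = 0), "territory")
  expect_error(sim_config(nest_success = 1.2), "probabilities")
  expect_error(sim_config(brood_size_dist = c(0.5, 0.5, 0.5)),
               "summing")
  plan <- data.frame(year = 1980, fledglings = 1, juveniles_free = 0,
                     subadults = 0, floaters = 0, breeders = 0)
  expect_error(sim_config(tagging_plan = plan), "outside simulated years")
})

test_that("default study emulation tags 257 birds across the stages", {
  sim <- simulate_population(sim_config(seed = 3L))
  first <- sim$histories[!duplicated(sim$histories$individual_id), ]
  expect_equal(nrow(first), 257L)
  tab <- table(first$stage_at_entry)
  expect_equal(unname(tab[["juvenile"]]), 132L)
  expect_equal(unname(tab[["floater"]]), 21L)
  expect_equal(unname(tab[["breeder"]]), 41L)
  expect_equal(sum(tab[c("subadult1", "subadult2", "subadult3")]), 63L)
  # surveys and census cover every simulated breeding season
  expect_equal(sim$surveys$year, 1994:2000)
  expect_true(all(sim$census$breeder <= 2 * sim$config$territories))
})

test_that("fledgling sex ratio recovers the generating male proportion", {
  cfg <- sim_config(territories = 1500L, years = 1994:1996,
                    tagging_plan = data.frame(year = 1994,
                                              fledglings = 0,
                                              juveniles_free = 0,
                                              subadults = 0, floaters = 0,
                                              breeders = 0),
                    seed = 8L)
  sim <- simulate_population(cfg)
  m <- sum(sim$fledgling_sex$males)
  n <- m + sum(sim$fledgling_sex$females)
  expect_gt(n, 2000)
  se <- sqrt(0.64 * 0.36 / n)
  expect_lt(abs(m / n - 0.64), 3 * se)
})

test_that("immortal rates conserve the population exactly", {
  r1 <- vital_rates(1, 1, 1, 1, f = 0.2313)
  cfg <- sim_config(territories = 30L, years = 1994:1997, rates = r1,
                    monthly_signal_loss = 0,
                    tagging_plan = data.frame(year = 1994,
                                              fledglings = 5,
                                              juveniles_free = 0,
                                              subadults = 0, floaters = 0,
                                              breeders = 0),
                    seed = 9L)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$fatalities), 0L)
  expect_equal(sum(sim$histories$state == "dead"), 0L)
  # census grows by exactly the fledgling count each year
  tot <- rowSums(sim$census[STAGES])
  expect_equal(unname(diff(tot)), sim$surveys$fledglings[-1])
})

test_that("fixtures round-trip through the readers and are deterministic", {
  cfg <- sim_config(seed = 17L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_fixture(cfg, d1)
  p2 <- emit_fixture(cfg, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  back <- read_capture_histories(p1[["histories"]])
  expect_equal(length(unique(back$individual_id)), 257L)
  expect_s3_class(read_nest_surveys(p1[["surveys"]]), "nest_surveys")

  # zero tagging produces empty but valid files
  cfg0 <- sim_config(tagging_plan = data.frame(year = 1994,
                                               fledglings = 0,
                                               juveniles_free = 0,
                                               subadults = 0,
                                               floaters = 0,
                                               breeders = 0),
                     years = 1994:1995, seed = 2L)
  d0 <- withr::local_tempdir()
  p0 <- emit_fixture(cfg0, d0)
  empty <- utils::read.csv(p0[["histories"]])
  expect_equal(nrow(empty), 0L)
})

test_that("known-fate refits recover the generating juvenile survival", {
  set.seed(23)
  truth <- 0.842
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    sim <- simulate_population(sim_config(seed = sample.int(1e6, 1)))
    rs <- build_risk_sets(sim$histories, stage = "juvenile", min_n = 11L)
    ann <- annual_from_seasonal(fit_known_fate(rs, "constant"))
    hits <- hits + (abs(ann$S_hat - truth) <= 2 * ann$SE)
  }
  # 2 SE covers ~95% nominally; demand at least 15/20
  expect_gte(hits, 15L)
})

test_that("removing the turbine hazard raises subadult survival accordingly", {
  # with blade-strikes censored analytically, the refit should approach
  # the no-turbine generating rate
  set.seed(29)
  est <- function(h) {
    rs <- build_risk_sets(h, stage = "subadult2", min_n = 11L)
    annual_from_seasonal(fit_known_fate(rs, "constant"))
  }
  plan <- data.frame(year = 1994:1999, fledglings = 0,
                     juveniles_free = 0, subadults = 40, floaters = 0,
                     breeders = 0)
  cfg <- sim_config(territories = 120L, tagging_plan = plan, seed = 37L)
  sim <- simulate_population(cfg)
  a_all <- est(sim$histories)
  a_cens <- est(censor_by_cause(sim$histories, turbine_causes()))
  expect_gt(a_cens$S_hat, a_all$S_hat)
  # the simulated blade-strike share of subadult deaths is 28/43; the
  # censored refit should sit well above the all-deaths one
  expect_gt(a_cens$S_hat - a_all$S_hat, 0.02)
})
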