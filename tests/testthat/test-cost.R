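tc <- canonical_vital_rates("turbine_censored")

test_that("survivorship composes stage rates with fractional years", {
  expect_equal(round(survivorship(tc, 40), 3), 0.695)
  expect_equal(survivorship(tc, 0), 1)
  expect_equal(survivorship(tc, 12), tc$S_j)
  expect_equal(survivorship(tc, 48), tc$S_j * tc$S_s^3)
  expect_equal(survivorship(tc, 60), tc$S_j * tc$S_s^3 * tc$S_b)
  # non-increasing in age
  phi <- survivorship(tc, 0:80)
  expect_true(all(diff(phi) <= 1e-14))
  # multiplicative across a stage boundary: conditional survival from
  # 12 to 40 months is subadult survival over 28/12 years
  expect_equal(survivorship(tc, 40),
               survivorship(tc, 12) * tc$S_s^(28 / 12), tolerance = 1e-12)
  expect_error(survivorship(tc, -1), "non-negative")
})

test_that("pair demand follows the published worked arithmetic", {
  expect_equal(round(pairs_to_produce(1, 0.638), 3), 1.567)
  expect_equal(pairs_to_produce(1 / 0.695, 0.638), 2.256,
               tolerance = 0.001)
  expect_equal(pairs_to_produce(0, 0.638), 0)
  expect_error(pairs_to_produce(1, 0), "positive")
})

test_that("replacement chain reproduces the published series", {
  cc <- replacement_chain(tc, f2 = 0.638, fatality_age_months = 40,
                          k_rounds = 6L)
  expect_equal(cc$pairs_initial, 2.256, tolerance = 0.002)
  # recruit survivorship carries the full first adult year
  expect_equal(cc$recruit_survivorship, tc$S_j * tc$S_s^3 * tc$S_b)
  expect_equal(round(1 / cc$recruit_survivorship, 3), 1.652,
               tolerance = 0.002)
  expect_equal(cc$pairs_per_recruit, 2.590, tolerance = 0.002)
  # per-round ratio: both pair members at breeder mortality 0.080
  expect_equal(cc$replacement_ratio, 2 * 0.080 * cc$pairs_per_recruit)
  expect_equal(cc$series[2], 3.190, tolerance = 0.002)
  expect_equal(cc$series[7], 3.844, tolerance = 0.005)
  expect_true(cc$sustainable)
})

test_that("the chain is a convergent geometric series", {
  cc <- replacement_chain(tc, k_rounds = 12L)
  expect_true(all(diff(cc$series) > 0))
  expect_true(all(cc$series < cc$pairs_limit))
  P0 <- cc$pairs_initial
  r <- cc$replacement_ratio
  expect_equal(cc$pairs_limit, P0 / (1 - r), tolerance = 1e-12)
  for (k in seq_along(cc$series) - 1L)
    expect_lte(abs(cc$series[k + 1] - cc$pairs_limit),
               P0 * r^(k + 1) / (1 - r) + 1e-12)
  # an unsustainable parameterisation has no finite limit
  weak <- vital_rates(0.4, 0.4, 0.5, 0.6, 0.2313)
  cw <- replacement_chain(weak)
  expect_false(cw$sustainable)
  expect_equal(cw$pairs_limit, Inf)
})

test_that("cost decreases as survival or fecundity improve", {
  lim <- function(r, f2 = 0.638)
    replacement_chain(r, f2 = f2)$pairs_limit
  base <- lim(tc)
  for (nm in c("S_j", "S_s", "S_b")) {
    up <- unclass(tc)
    up[[nm]] <- min(up[[nm]] + 0.02, 1)
    expect_lt(lim(vital_rates(up$S_j, up$S_s, up$S_f, up$S_b, up$f)),
              base)
  }
  expect_lt(lim(tc, f2 = 0.7), base)
})

test_that("age-resolved cost is linear in the age distribution", {
  lim40 <- replacement_chain(tc, fatality_age_months = 40)$pairs_limit
  expect_equal(age_resolved_cost(tc, ages = 40, weights = 1), lim40)
  lim20 <- replacement_chain(tc, fatality_age_months = 20)$pairs_limit
  expect_equal(age_resolved_cost(tc, ages = c(20, 40),
                                 weights = c(0.5, 0.5)),
               (lim20 + lim40) / 2, tolerance = 1e-12)
  ages <- 13:48
  w <- rep(1 / length(ages), length(ages))
  brute <- mean(vapply(ages, function(a)
    replacement_chain(tc, fatality_age_months = a)$pairs_limit,
    numeric(1)))
  expect_equal(age_resolved_cost(tc, ages = ages, weights = w), brute,
               tolerance = 1e-12)
  expect_error(age_resolved_cost(tc, ages = c(20, 40),
                                 weights = c(0.7, 0.7)), "sum to 1")
})

test_that("footprints scale the reference constant to published totals", {
  fp55 <- footprint(reference_pairs_per_fatality(), 55)
  expect_equal(fp55$pairs_required, 216)
  fp65 <- footprint(reference_pairs_per_fatality(), 65)
  # 65 x 3.931 = 255.515: one pair from the printed 255 either way
  expect_equal(fp65$pairs_required_exact, 255.515, tolerance = 1e-10)
  expect_lte(abs(fp65$pairs_required - 255), 1)
  expect_equal(footprint(3.931, 0)$pairs_required, 0)
  fp_res <- footprint(reference_pairs_per_fatality(), 55,
                      resident_fraction = 0.9)
  expect_equal(fp_res$resident_pairs, 195)
  expect_error(footprint(3.9, 55, 1.2), "resident_fraction")
})

test_that("survivorship components agree with a cohort simulation oracle", {
  # simulate fledglings individual-by-individual through monthly
  # hazards and check the two survivorship quantities the chain uses
  set.seed(31)
  n <- 40000
  surv_to <- function(months) {
    alive <- rep(TRUE, n)
    for (m in seq_len(months)) {
      S <- if (m <= 12) tc$S_j else if (m <= 48) tc$S_s else tc$S_b
      alive[alive] <- runif(sum(alive)) < S^(1 / 12)
    }
    mean(alive)
  }
  phi40 <- surv_to(40)
  se40 <- sqrt(phi40 * (1 - phi40) / n)
  expect_equal(phi40, survivorship(tc, 40), tolerance = 4 * se40 / 0.695)
  phi60 <- surv_to(60)
  se60 <- sqrt(phi60 * (1 - phi60) / n)
  cc <- replacement_chain(tc)
  expect_equal(phi60, cc$recruit_survivorship,
               tolerance = 4 * se60 / 0.605)
  # balance identity: the limit satisfies L = P0 + r L
  expect_equal(cc$pairs_limit,
               cc$pairs_initial +
                 cc$replacement_ratio * cc$pairs_limit,
               tolerance = 1e-10)
})
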