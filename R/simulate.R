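#' Configuration for the individual-based population simulator
#'
#' Bundles and validates the generating parameters of the synthetic
#' territorial-raptor population: true vital rates, reproduction inputs,
#' the fledgling sex ratio, stage-specific fatality-cause probabilities,
#' the radio-tagging plan, transmitter behaviour and detection.
#' Defaults emulate the 1994--2000 field study: a saturated set of
#' breeding territories, nest success 0.44 with mean brood size 1.45
#' (0.638 fledglings of both sexes per pair), 64% male fledglings,
#' 4-year transmitter batteries, and a tagging plan totalling 257 birds
#' across the four life stages.
#'
#' @param territories Number of breeding territories.
#' @param rates True [vital_rates] generating survival and (via
#'   `nest_success` and `brood_size_dist`) reproduction.
#' @param years Calendar years simulated (first breeding pulse in June
#'   of the first year).
#' @param nest_success Annual probability that an occupied territory
#'   fledges young.
#' @param brood_size_dist Probabilities of brood sizes 1, 2, 3 among
#'   successful nests.
#' @param p_male Probability a fledgling is male.
#' @param cause_split Optional list of per-stage probability vectors
#'   over the [fatality_cause_table()] categories; the default is
#'   proportional to that table's stage columns.
#' @param tagging_plan Data frame with columns `year`, `fledglings`
#'   (tagged at the nest in June), `juveniles_free`, `subadults`,
#'   `floaters`, `breeders` (free-ranging birds tagged in January).
#' @param transmitter_life_months Battery life (censoring horizon).
#' @param monthly_detection_prob Probability a live transmittered bird
#'   is relocated in a given month of aerial survey.
#' @param monthly_signal_loss Monthly probability of premature,
#'   unexplained signal loss (censoring).
#' @param initial_floaters Adults without territories seeded at start.
#' @param seasonal_hazard_weights Optional named multipliers (one per
#'   season) on the monthly death hazard; default uniform.
#' @param seed RNG seed; all stochastic draws flow from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(territories = 60L,
                       rates = canonical_vital_rates("all_deaths"),
                       years = 1994:2000,
                       nest_success = 0.44,
                       brood_size_dist = c(0.58, 0.39, 0.03),
                       p_male = 0.64,
                       cause_split = NULL,
                       tagging_plan = NULL,
                       transmitter_life_months = 48L,
                       monthly_detection_prob = 0.9,
                       monthly_signal_loss = 0.005,
                       initial_floaters = 40L,
                       seasonal_hazard_weights = NULL,
                       seed = 1L) {
  stopifnot(inherits(rates, "vital_rates"))
  if (territories < 1L) stop("need at least one territory", call. = FALSE)
  probs <- c(nest_success, p_male, monthly_detection_prob,
             monthly_signal_loss)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  if (length(brood_size_dist) != 3L ||
      abs(sum(brood_size_dist) - 1) > 1e-8 || any(brood_size_dist < 0))
    stop("`brood_size_dist` must be 3 non-negative probabilities summing",
         " to 1", call. = FALSE)
  if (is.null(cause_split)) cause_split <- .default_cause_split()
  if (is.null(tagging_plan)) tagging_plan <- .default_tagging_plan()
  need <- c("year", "fledglings", "juveniles_free", "subadults",
            "floaters", "breeders")
  if (!all(need %in% names(tagging_plan)))
    stop("tagging plan lacks column(s): ",
         paste(setdiff(need, names(tagging_plan)), collapse = ", "),
         call. = FALSE)
  if (!all(tagging_plan$year %in% years))
    stop("tagging plan years outside simulated years", call. = FALSE)
  if (!is.null(seasonal_hazard_weights)) {
    if (!all(SEASONS %in% names(seasonal_hazard_weights)) ||
        any(seasonal_hazard_weights < 0))
      stop("`seasonal_hazard_weights` needs one non-negative weight per",
           " season", call. = FALSE)
  }
  structure(list(territories = as.integer(territories), rates = rates,
                 years = as.integer(years), nest_success = nest_success,
                 brood_size_dist = brood_size_dist, p_male = p_male,
                 cause_split = cause_split, tagging_plan = tagging_plan,
                 transmitter_life_months =
                   as.integer(transmitter_life_months),
                 monthly_detection_prob = monthly_detection_prob,
                 monthly_signal_loss = monthly_signal_loss,
                 initial_floaters = as.integer(initial_floaters),
                 seasonal_hazard_weights = seasonal_hazard_weights,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# cause probabilities per stage group, proportional to the recorded
# stage-specific fatality counts
.default_cause_split <- function() {
  tb <- fatality_cause_table()
  split <- lapply(c(juvenile = "juveniles", subadult = "subadults",
                    floater = "floaters", breeder = "breeders"),
                  function(col) {
                    n <- tb[[col]]
                    if (sum(n) == 0) n <- rowSums(tb[2:5])
                    stats::setNames(n / sum(n), tb$cause)
                  })
  split
}

# study-sized default: 257 birds tagged over 1994-1999
.default_tagging_plan <- function() {
  data.frame(year = 1994:1999,
             fledglings = c(17L, 17L, 17L, 17L, 17L, 16L),
             juveniles_free = c(5L, 5L, 5L, 6L, 5L, 5L),
             subadults = c(11L, 11L, 10L, 11L, 10L, 10L),
             floaters = c(4L, 4L, 3L, 4L, 3L, 3L),
             breeders = c(7L, 7L, 7L, 7L, 7L, 6L))
}

# stage label from age in months post-fledging
.stage_of_age <- function(age, has_territory) {
  ifelse(age < 12, "juvenile",
  ifelse(age < 24, "subadult1",
  ifelse(age < 36, "subadult2",
  ifelse(age < 48, "subadult3",
         ifelse(has_territory, "breeder", "floater")))))
}

.stage_group <- function(stage) {
  c(juvenile = "juvenile", subadult1 = "subadult", subadult2 = "subadult",
    subadult3 = "subadult", floater = "floater", breeder = "breeder")[stage]
}

#' Simulate a territorial population with radio-telemetry monitoring
#'
#' Individual-based stochastic simulation on a monthly clock.  Each
#' year's cycle: a June breeding pulse (per occupied territory, success,
#' brood size, and i.i.d. fledgling sexes), stage promotion at the June
#' boundary (all ages are months post-fledging, anchored mid-June),
#' monthly stage-specific survival (annual rates applied as monthly
#' hazards \eqn{1 - S^{1/12}} so deaths land in seasonal intervals, with
#' cause drawn from the stage's cause distribution at death), and
#' instant filling of territory vacancies by the oldest same-sex
#' floater.  New adults without a vacancy become floaters.  The tagging
#' plan and detection model turn a subset of individuals into
#' capture-history records, censored at transmitter battery death or
#' premature signal loss.
#'
#' @param config A [sim_config()].
#' @return Object of class `eagle_simulation` with elements
#'   `histories` (a [capture_histories] table for the tagged sample),
#'   `surveys` (a [nest_surveys] table of all territories),
#'   `fledgling_sex` (per-year male/female fledgling counts, the input
#'   for [g_test_parity()]), `fatalities` (observed deaths of tagged
#'   birds with cause and stage), `census` (June stage counts per
#'   year), and the `config`.
#'   Reproducible: a fixed seed gives identical output.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rates <- config$rates
  Tn <- config$territories
  y0 <- config$years[1L]
  n_years <- length(config$years)
  # months indexed 1..M, month 1 = January of the first year; run
  # through November of the last year (end of its Fall interval)
  M <- (n_years - 1L) * 12L + 11L
  cal_month <- ((seq_len(M) - 1L) %% 12L) + 1L
  cal_year <- y0 + (seq_len(M) - 1L) %/% 12L

  S_annual <- c(juvenile = rates$S_j, subadult = rates$S_s,
                floater = rates$S_f, breeder = rates$S_b)
  hw <- config$seasonal_hazard_weights
  month_death_p <- function(stage_grp, cal_m) {
    q <- 1 - S_annual[stage_grp]^(1 / 12)
    if (!is.null(hw)) {
      w <- hw[season_of(cal_m)] / mean(hw[SEASONS])
      q <- pmin(q * w, 1)
    }
    unname(q)
  }

  # individual state vectors, grown as fledglings are produced; ages at
  # month 1 (January) sit mid-stage, anchored to June fledging
  n0_juv <- round(Tn * 0.638)
  n0_s1 <- round(n0_juv * rates$S_j)
  n0_s2 <- round(n0_s1 * rates$S_s)
  n0_s3 <- round(n0_s2 * rates$S_s)
  counts <- c(2L * Tn, config$initial_floaters, n0_juv, n0_s1, n0_s2,
              n0_s3)
  ages0 <- c(rep(79L, 2L * Tn), rep(67L, config$initial_floaters),
             rep(7L, n0_juv), rep(19L, n0_s1), rep(31L, n0_s2),
             rep(43L, n0_s3))
  N <- sum(counts)
  birth_month <- 1L - ages0          # so age at month 1 equals ages0
  sex <- character(N)
  # breeders: one of each sex per territory; everything else Bernoulli
  sex[seq_len(Tn)] <- "female"
  sex[Tn + seq_len(Tn)] <- "male"
  rest <- (2L * Tn + 1L):N
  sex[rest] <- ifelse(stats::runif(length(rest)) < config$p_male,
                      "male", "female")
  alive <- rep(TRUE, N)
  territory <- rep(NA_integer_, N)
  territory[seq_len(Tn)] <- seq_len(Tn)
  territory[Tn + seq_len(Tn)] <- seq_len(Tn)
  death_month <- rep(NA_integer_, N)
  cause <- rep(NA_character_, N)
  tagged <- rep(FALSE, N)
  tag_month <- rep(NA_integer_, N)
  censor_month <- rep(NA_integer_, N)
  fledge_year <- rep(NA_integer_, N)   # June year of fledging (if simulated)
  became_breeder <- rep(NA_integer_, N) # month a territory was first held
  became_breeder[seq_len(2L * Tn)] <- 0L

  surveys <- data.frame(year = integer(), pairs_surveyed = integer(),
                        fledglings = integer(), fledged_broods = integer())
  fledgling_sex <- data.frame(year = integer(), males = integer(),
                              females = integer())
  census <- NULL
  cause_names <- names(config$cause_split[[1L]])

  grow <- function(k) {
    # append k blank individuals, return their indices
    idx <- N + seq_len(k)
    birth_month <<- c(birth_month, integer(k))
    sex <<- c(sex, character(k))
    alive <<- c(alive, rep(TRUE, k))
    territory <<- c(territory, rep(NA_integer_, k))
    death_month <<- c(death_month, rep(NA_integer_, k))
    cause <<- c(cause, rep(NA_character_, k))
    tagged <<- c(tagged, rep(FALSE, k))
    tag_month <<- c(tag_month, rep(NA_integer_, k))
    censor_month <<- c(censor_month, rep(NA_integer_, k))
    fledge_year <<- c(fledge_year, rep(NA_integer_, k))
    became_breeder <<- c(became_breeder, rep(NA_integer_, k))
    N <<- N + k
    idx
  }

  tag <- function(idx, m) {
    tagged[idx] <<- TRUE
    tag_month[idx] <<- m
    t_end <- m + config$transmitter_life_months - 1L
    loss <- if (config$monthly_signal_loss > 0)
      m + stats::rgeom(length(idx), config$monthly_signal_loss)
    else rep(.Machine$integer.max, length(idx))
    censor_month[idx] <<- pmin(t_end, loss)
  }

  fill_vacancies <- function() {
    for (sx in c("female", "male")) {
      occ <- territory[alive & sex == sx]
      vacant <- setdiff(seq_len(Tn), occ[!is.na(occ)])
      if (!length(vacant)) next
      # adults only: age >= 48 months at the current month
      pool <- which(alive & sex == sx & is.na(territory))
      pool <- pool[(m_cur - birth_month[pool]) >= 48L]
      if (!length(pool)) next
      pool <- pool[order(birth_month[pool])]   # oldest first
      take <- utils::head(pool, length(vacant))
      territory[take] <<- vacant[seq_along(take)]
      became_breeder[take] <<- m_cur
    }
  }

  for (m_cur in seq_len(M)) {
    fill_vacancies()
    is_june <- cal_month[m_cur] == 6L

    if (is_june) {
      # breeding pulse: per territory with both members present
      occ_f <- territory[alive & sex == "female"]
      occ_m <- territory[alive & sex == "male"]
      paired <- intersect(occ_f[!is.na(occ_f)], occ_m[!is.na(occ_m)])
      success <- paired[stats::runif(length(paired)) <
                          config$nest_success]
      broods <- if (length(success))
        sample(1:3, length(success), replace = TRUE,
               prob = config$brood_size_dist) else integer()
      n_new <- sum(broods)
      if (n_new > 0) {
        idx <- grow(n_new)
        birth_month[idx] <- m_cur
        sex[idx] <- ifelse(stats::runif(n_new) < config$p_male,
                           "male", "female")
        fledge_year[idx] <- cal_year[m_cur]
      }
      surveys <- rbind(surveys, data.frame(
        year = cal_year[m_cur], pairs_surveyed = length(paired),
        fledglings = n_new, fledged_broods = length(success)))
      new_sex <- if (n_new > 0) sex[(N - n_new + 1L):N] else character()
      fledgling_sex <- rbind(fledgling_sex, data.frame(
        year = cal_year[m_cur], males = sum(new_sex == "male"),
        females = sum(new_sex == "female")))
      st <- .stage_of_age(m_cur - birth_month[alive],
                          !is.na(territory[alive]))
      census <- rbind(census, data.frame(
        year = cal_year[m_cur],
        t(vapply(STAGES, function(s) sum(st == s), numeric(1)))))

      # nest tagging of this June's fledglings
      plan <- config$tagging_plan
      row <- plan[plan$year == cal_year[m_cur], , drop = FALSE]
      if (nrow(row) && row$fledglings > 0 && n_new > 0) {
        pool <- which(alive & !tagged & birth_month == m_cur)
        take <- .resample(pool, row$fledglings)
        if (length(take)) tag(take, m_cur)
      }
    }

    if (cal_month[m_cur] == 1L) {
      # winter trapping of free-ranging birds
      plan <- config$tagging_plan
      row <- plan[plan$year == cal_year[m_cur], , drop = FALSE]
      if (nrow(row)) {
        age <- m_cur - birth_month
        stg <- .stage_of_age(age, !is.na(territory))
        quota <- c(juvenile = row$juveniles_free,
                   subadult = row$subadults, floater = row$floaters,
                   breeder = row$breeders)
        for (grp in names(quota)) {
          if (quota[[grp]] <= 0) next
          pool <- which(alive & !tagged &
                          unname(.stage_group(stg)) == grp)
          take <- .resample(pool, quota[[grp]])
          if (length(take)) tag(take, m_cur)
        }
      }
    }

    # monthly survival
    live <- which(alive)
    age <- m_cur - birth_month[live]
    stg_grp <- .stage_group(.stage_of_age(age, !is.na(territory[live])))
    p_die <- month_death_p(stg_grp, cal_month[m_cur])
    dies <- live[stats::runif(length(live)) < p_die]
    if (length(dies)) {
      alive[dies] <- FALSE
      death_month[dies] <- m_cur
      for (i in dies) {
        cs <- config$cause_split[[.stage_group(
          .stage_of_age(m_cur - birth_month[i],
                        !is.na(territory[i])))]]
        cause[i] <- sample(cause_names, 1L, prob = cs)
      }
      territory[dies] <- NA_integer_
    }
  }

  hist_df <- .emit_histories(config, M, cal_month, cal_year, birth_month,
                             sex, death_month, cause, tagged, tag_month,
                             censor_month, became_breeder)
  fat <- .emit_fatalities(M, cal_month, cal_year, birth_month,
                          death_month, cause, tagged, tag_month,
                          censor_month, became_breeder)
  structure(list(histories = hist_df, surveys = nest_surveys(surveys),
                 fledgling_sex = fledgling_sex, fatalities = fat,
                 census = census, config = config),
            class = "eagle_simulation")
}

# sample up to k elements without the scalar-x pitfall of sample()
.resample <- function(pool, k) {
  k <- min(k, length(pool))
  if (k <= 0) return(integer())
  pool[sample.int(length(pool), k)]
}

# translate tagged individuals' monthly fates into seasonal
# capture-history records
.emit_histories <- function(config, M, cal_month, cal_year, birth_month,
                            sex, death_month, cause, tagged, tag_month,
                            censor_month, became_breeder) {
  ids <- which(tagged)
  if (!length(ids)) {
    empty <- data.frame(individual_id = character(), sex = character(),
                        stage_at_entry = character(),
                        entry_year = integer(),
                        entry_season = character(), year = integer(),
                        season = character(), state = character(),
                        cause = character(), stage = character(),
                        stringsAsFactors = FALSE)
    class(empty) <- c("capture_histories", "data.frame")
    return(empty)
  }
  iv_year <- season_year(cal_year, cal_month)
  iv_season <- season_of(cal_month)
  origin <- min(iv_year)
  iv_idx <- interval_index(iv_year, iv_season, origin)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    i <- ids[k]
    m0 <- tag_month[i]
    dm <- if (is.na(death_month[i])) .Machine$integer.max
    else death_month[i]
    cm <- censor_month[i]
    last_m <- min(dm, cm, M)
    span <- m0:last_m
    entry_age <- m0 - birth_month[i]
    entry_stage <- .stage_of_age(entry_age, !is.na(became_breeder[i]) &&
                                   became_breeder[i] <= m0)
    # one record per distinct interval in the monitored span
    iv <- unique(iv_idx[span])
    n_iv <- length(iv)
    state <- character(n_iv)
    for (j in seq_len(n_iv)) {
      mm <- span[iv_idx[span] == iv[j]]
      if (dm <= cm && dm %in% mm) {
        state[j] <- "dead"
      } else if (cm < dm && cm %in% mm && cm < M) {
        state[j] <- "censored"
      } else {
        det <- 1 - (1 - config$monthly_detection_prob)^length(mm)
        state[j] <- if (stats::runif(1) < det) "alive-detected"
        else "not-detected"
      }
    }
    at <- interval_at(iv, origin)
    first_mo <- vapply(iv, function(v)
      min(span[iv_idx[span] == v]), numeric(1))
    age_at_iv <- first_mo - birth_month[i]
    holds <- !is.na(became_breeder[i]) & became_breeder[i] <= first_mo
    rows[[k]] <- data.frame(
      individual_id = sprintf("GE%04d", i),
      sex = sex[i], stage_at_entry = entry_stage,
      entry_year = at$year[1L], entry_season = at$season[1L],
      year = at$year, season = at$season, state = state,
      cause = ifelse(state == "dead", cause[i], NA_character_),
      stage = .stage_of_age(age_at_iv, holds),
      stringsAsFactors = FALSE)
  }
  capture_histories(do.call(rbind, rows))
}

.emit_fatalities <- function(M, cal_month, cal_year, birth_month,
                             death_month, cause, tagged, tag_month,
                             censor_month, became_breeder) {
  obs <- which(tagged & !is.na(death_month) &
                 death_month <= pmin(censor_month, M))
  tb <- fatality_cause_table()
  age <- death_month[obs] - birth_month[obs]
  holds <- !is.na(became_breeder[obs]) &
    became_breeder[obs] <= death_month[obs]
  data.frame(
    individual_id = sprintf("GE%04d", obs),
    year = cal_year[death_month[obs]],
    season = season_of(cal_month[death_month[obs]]),
    age_months = age,
    stage = .stage_of_age(age, holds),
    cause = cause[obs],
    anthropogenic = tb$anthropogenic[match(cause[obs], tb$cause)],
    stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in the package's text formats
#'
#' Runs [simulate_population()] and writes the resulting tables as CSV:
#' `histories.csv` (wide capture-history dialect), `surveys.csv`,
#' `fatalities.csv` and `census.csv`.  The files parse cleanly through
#' [read_capture_histories()] / [read_nest_surveys()], and a fixed seed
#' yields byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly; the
#'   simulation object is attached as attribute `simulation`.
#' @export
emit_fixture <- function(config, dir) {
  sim <- simulate_population(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(histories = file.path(dir, "histories.csv"),
             surveys = file.path(dir, "surveys.csv"),
             fatalities = file.path(dir, "fatalities.csv"),
             census = file.path(dir, "census.csv"))
  if (nrow(sim$histories)) {
    write_capture_histories(sim$histories, paths[["histories"]])
  } else {
    utils::write.csv(data.frame(individual_id = character(),
                                sex = character(),
                                stage_at_entry = character(),
                                entry_year = integer(),
                                entry_season = character(),
                                cause = character()),
                     paths[["histories"]], row.names = FALSE)
  }
  utils::write.csv(sim$surveys, paths[["surveys"]], row.names = FALSE)
  utils::write.csv(sim$fatalities, paths[["fatalities"]],
                   row.names = FALSE)
  utils::write.csv(sim$census, paths[["census"]], row.names = FALSE)
  out <- invisible(paths)
  attr(out, "simulation") <- sim
  invisible(out)
}

#' Simulate a single-stage known-fate cohort
#'
#' Reduced generator used for calibration studies of the known-fate
#' estimator: `n` individuals tagged together at the start of a Winter
#' interval, subject to a constant annual survival applied as a monthly
#' hazard, monitored over `n_intervals` seasonal intervals with a given
#' per-interval relocation probability and no other censoring.
#'
#' @param n Cohort size.
#' @param annual_survival True annual survival probability.
#' @param n_intervals Seasonal intervals monitored (default 12).
#' @param detection Per-interval relocation probability (default 1).
#' @param stage Stage label recorded for the cohort.
#' @param start_year First interval's labelling year.
#' @return A [capture_histories] table.
#' @export
simulate_cohort_histories <- function(n, annual_survival,
                                      n_intervals = 12L, detection = 1,
                                      stage = "subadult1",
                                      start_year = 2000L) {
  stopifnot(n >= 1L, annual_survival >= 0, annual_survival <= 1,
            n_intervals >= 1L)
  q <- 1 - annual_survival^(1 / 12)
  # completed months before death; effectively infinite when survival
  # is certain
  death_mo <- if (q > 0) stats::rgeom(n, q) else
    rep(.Machine$integer.max %/% 4L, n)
  death_iv <- death_mo %/% 3L             # 0-based interval of death
  last <- pmin(death_iv, n_intervals - 1L)
  len <- last + 1L
  ind <- rep(seq_len(n), len)
  pos <- sequence(len) - 1L
  state <- rep("alive-detected", length(ind))
  if (detection < 1)
    state[stats::runif(length(ind)) > detection] <- "not-detected"
  dead_row <- pos == death_iv[ind]
  state[dead_row] <- "dead"
  at <- interval_at(pos, start_year)
  capture_histories(data.frame(
    individual_id = sprintf("C%05d", ind), sex = "unknown",
    stage_at_entry = stage, entry_year = start_year,
    entry_season = "Winter", year = at$year, season = at$season,
    state = state,
    cause = ifelse(state == "dead", "Undiagnosed fatality",
                   NA_character_),
    stage = stage, stringsAsFactors = FALSE))
}
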