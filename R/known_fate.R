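#' Build per-interval risk sets from capture histories
#'
#' Following the known-fate convention for radio-telemetry data, an
#' individual is included in a seasonal interval only when it was
#' relocated there: `alive-detected` intervals contribute a survivor,
#' `dead` intervals a death, and `not-detected` or `censored` intervals
#' contribute nothing.  Intervals whose sample falls below `min_n`
#' individuals are dropped (in practice this truncates the sparse tail of
#' the monitoring period).
#'
#' @param histories A [capture_histories] table.
#' @param stage Optional stage label; retains only interval records in
#'   that stage (using the per-interval `stage` column when present,
#'   otherwise `stage_at_entry`).
#' @param min_n Minimum individuals at risk for an interval to be
#'   estimable (default 11, the study's rule).
#' @param by_sex Split risk sets by sex (individuals of unknown sex are
#'   excluded).
#' @return Data frame of class `risk_set` with columns `year`, `season`,
#'   `interval` (0-based study index), `n` at risk, `d` deaths, and `sex`
#'   when `by_sex`.  Attribute `dropped` lists intervals removed by the
#'   `min_n` rule.
#' @export
build_risk_sets <- function(histories, stage = NULL, min_n = 11L,
                            by_sex = FALSE) {
  h <- capture_histories(histories)
  if (min_n < 1L) stop("`min_n` must be >= 1", call. = FALSE)
  if (!is.null(stage)) {
    if (!stage %in% STAGES) stop("unknown stage: ", stage, call. = FALSE)
    if ("stage" %in% names(h)) h <- h[!is.na(h$stage) & h$stage == stage, ]
    else h <- h[h$stage_at_entry == stage, ]
  }
  if (by_sex) h <- h[h$sex %in% c("female", "male"), ]
  h <- h[h$state %in% c("alive-detected", "dead"), , drop = FALSE]
  if (!nrow(h)) stop("no relocated intervals in the risk set", call. = FALSE)
  origin <- min(h$year)
  h$interval <- interval_index(h$year, h$season, origin)
  keys <- c("year", "season", "interval", if (by_sex) "sex")
  tallies <- data.frame(h[keys], n = 1L, d = as.integer(h$state == "dead"))
  agg <- stats::aggregate(cbind(n, d) ~ ., data = tallies, FUN = sum)
  agg <- agg[order(agg$interval), , drop = FALSE]
  # min_n applies to the total at risk in the interval (both sexes pooled)
  tot <- tapply(agg$n, agg$interval, sum)
  low <- as.integer(names(tot)[tot < min_n])
  dropped <- agg[agg$interval %in% low, , drop = FALSE]
  agg <- agg[!agg$interval %in% low, , drop = FALSE]
  if (!nrow(agg))
    stop("no interval reaches min_n = ", min_n, " individuals",
         call. = FALSE)
  rownames(agg) <- NULL
  attr(agg, "dropped") <- dropped
  attr(agg, "origin_year") <- origin
  class(agg) <- c("risk_set", "data.frame")
  agg
}

#' Analytically censor deaths of specified causes
#'
#' Re-expresses a capture-history table under a "what if" mortality
#' scenario: deaths whose cause belongs to `causes_to_censor` become
#' censorings at the death interval, so the fitted survival excludes that
#' mortality source.  Undiagnosed fatalities are never censored; they are
#' treated as natural deaths so that anthropogenic mortality is estimated
#' at its minimum.
#'
#' @param histories A [capture_histories] table.
#' @param causes_to_censor Character vector of cause categories (see
#'   [fatality_cause_table()]); e.g. [turbine_causes()] or
#'   [human_causes()].
#' @return A [capture_histories] table with matching deaths censored.
#' @export
censor_by_cause <- function(histories, causes_to_censor) {
  h <- capture_histories(histories)
  causes_to_censor <- setdiff(causes_to_censor, "Undiagnosed fatality")
  hit <- h$state == "dead" & !is.na(h$cause) &
    h$cause %in% causes_to_censor
  h$state[hit] <- "censored"
  ids <- unique(h$individual_id[hit])
  h$cause[h$individual_id %in% ids] <- NA_character_
  capture_histories(h)
}

# model structures and their parameter grouping over risk-set rows
.kf_groups <- function(rs, model) {
  switch(model,
    constant = rep("S", nrow(rs)),
    time = sprintf("S[%s %d]", rs$season, rs$year),
    sex = {
      if (is.null(rs$sex)) stop("sex model needs sex-split risk sets",
                                call. = FALSE)
      sprintf("S[%s]", rs$sex)
    },
    sex_by_time = {
      if (is.null(rs$sex)) stop("sex model needs sex-split risk sets",
                                call. = FALSE)
      sprintf("S[%s, %s %d]", rs$sex, rs$season, rs$year)
    },
    stop("unknown model structure: ", model, call. = FALSE))
}

# product-binomial log-likelihood with the 0*log(0) = 0 convention
.kf_loglik <- function(S, n, d) {
  term <- function(k, p) ifelse(k == 0, 0, k * log(p))
  sum(term(n - d, S) + term(d, 1 - S))
}

#' Fit a known-fate survival model to risk sets
#'
#' Maximises the product-binomial likelihood
#' \eqn{\prod_i S_i^{n_i-d_i}(1-S_i)^{d_i}} over one of four seasonal
#' structures: `constant` (one shared seasonal survival), `time` (one per
#' interval), `sex`, and `sex_by_time`.  The optimisation runs on the
#' logit scale with an analytic gradient, started from the closed-form
#' pooled estimates \eqn{\hat S_g = \sum(n-d)/\sum n}, which are also the
#' exact MLEs for these saturated groupings; boundary groups (all died or
#' none died) are flagged and kept at their closed-form value.
#'
#' @param risk_sets A `risk_set` from [build_risk_sets()] (sex-split for
#'   the sex models).
#' @param model One of `"constant"`, `"time"`, `"sex"`, `"sex_by_time"`.
#' @return Object of class `known_fate_fit`: seasonal `estimates`, their
#'   variance matrix `vcov` (inverse observed information), `logL`, `K`,
#'   effective sample size `n_eff` (total individual-intervals), `aicc`,
#'   a `boundary` flag, and the per-group tallies.
#' @export
fit_known_fate <- function(risk_sets,
                           model = c("constant", "time", "sex",
                                     "sex_by_time")) {
  model <- match.arg(model)
  rs <- risk_sets
  if (!nrow(rs)) stop("empty risk sets", call. = FALSE)
  grp <- .kf_groups(rs, model)
  gl <- unique(grp)
  n_g <- as.numeric(tapply(rs$n, factor(grp, levels = gl), sum))
  d_g <- as.numeric(tapply(rs$d, factor(grp, levels = gl), sum))
  if (any(d_g > n_g)) stop("more deaths than individuals at risk",
                           call. = FALSE)
  S0 <- (n_g - d_g) / n_g
  interior <- d_g > 0 & d_g < n_g
  S <- S0
  if (any(interior)) {
    # logit-scale refinement; the closed form is the exact optimum, so
    # this converges immediately and guards against future non-saturated
    # structures
    nll <- function(b) -.kf_loglik(stats::plogis(b), n_g[interior],
                                   d_g[interior])
    grad <- function(b) {
      p <- stats::plogis(b)
      -((n_g[interior] - d_g[interior]) * (1 - p) - d_g[interior] * p)
    }
    opt <- stats::optim(stats::qlogis(S0[interior]), nll, grad,
                        method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 200))
    if (opt$convergence != 0)
      stop("known-fate optimisation failed to converge (code ",
           opt$convergence, ")", call. = FALSE)
    S[interior] <- stats::plogis(opt$par)
  }
  V <- diag(x = S * (1 - S) / n_g, nrow = length(S))
  dimnames(V) <- list(gl, gl)
  names(S) <- gl
  logL <- .kf_loglik(S, n_g, d_g)
  K <- length(S)
  n_eff <- sum(rs$n)
  aicc <- if (n_eff - K - 1 > 0)
    -2 * logL + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1) else Inf
  structure(list(model = model, estimates = S, vcov = V, logL = logL,
                 K = K, n_eff = n_eff, aicc = aicc,
                 boundary = any(!interior),
                 groups = data.frame(group = gl, n = n_g, d = d_g,
                                     S = S, row.names = NULL)),
            class = "known_fate_fit")
}

#' @export
print.known_fate_fit <- function(x, ...) {
  cat("Known-fate model {S(", x$model, ")}: K = ", x$K,
      ", n_eff = ", x$n_eff, "\n", sep = "")
  cat("  logL = ", format(x$logL, digits = 6),
      ", AICc = ", format(x$aicc, digits = 6),
      if (x$boundary) "  [boundary estimate]", "\n", sep = "")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Rank a candidate set of known-fate models by AICc
#'
#' @param fits List of `known_fate_fit` objects fitted to the same data
#'   (identical effective sample size).
#' @return Data frame ordered by AICc (ties broken by smaller K) with
#'   columns `model`, `K`, `logL`, `aicc`, `delta`, `weight`,
#'   `evidence_ratio`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "known_fate_fit")) fits <- list(fits)
  n_eff <- vapply(fits, `[[`, numeric(1), "n_eff")
  if (length(unique(n_eff)) != 1L)
    stop("models were fitted to different data (n_eff differs)",
         call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    K = vapply(fits, `[[`, numeric(1), "K"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"))
  tab$delta <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab <- tab[order(tab$aicc, tab$K), , drop = FALSE]
  tab$evidence_ratio <- tab$weight[1L] / tab$weight
  rownames(tab) <- NULL
  tab
}

#' Annual survival from a seasonal known-fate fit
#'
#' Annual survival is the product of the four seasonal survivals
#' (\eqn{S^4} under the constant model).  Its variance follows by the
#' delta method from the fit's variance matrix, and the 95% confidence
#' interval is computed on the logit scale and back-transformed so the
#' bounds stay in \eqn{[0,1]}.
#'
#' @param fit A `known_fate_fit`.
#' @param seasons_per_year Seasonal intervals per year (default 4).
#' @param scenario Label carried through to the result (e.g. the
#'   censoring scenario).
#' @return Data frame of class `annual_survival` with one row per sex
#'   stratum: `S_hat`, `SE`, `lower`, `upper`, `scenario`.  For `time`
#'   structures the first `seasons_per_year` seasonal estimates (in
#'   chronological order) are multiplied.
#' @export
annual_from_seasonal <- function(fit, seasons_per_year = 4L,
                                 scenario = "all_deaths") {
  m <- seasons_per_year
  strata <- if (fit$model %in% c("sex", "sex_by_time"))
    unique(sub("^S\\[([a-z]+).*$", "\\1", names(fit$estimates)))
  else "all"
  rows <- lapply(strata, function(sx) {
    if (fit$model %in% c("constant", "sex")) {
      i <- if (sx == "all") 1L else match(sprintf("S[%s]", sx),
                                          names(fit$estimates))
      S <- fit$estimates[i]
      v <- fit$vcov[i, i]
      S_a <- S^m
      g <- m * S^(m - 1)
      var_a <- g^2 * v
    } else {
      idx <- if (sx == "all") seq_along(fit$estimates)
      else grep(sprintf("^S\\[%s,", sx), names(fit$estimates))
      if (length(idx) < m)
        stop("fewer retained seasonal estimates (", length(idx),
             ") than a year of ", m, call. = FALSE)
      idx <- idx[seq_len(m)]
      S <- fit$estimates[idx]
      S_a <- prod(S)
      g <- ifelse(S > 0, S_a / S, 0)
      var_a <- drop(t(g) %*% fit$vcov[idx, idx, drop = FALSE] %*% g)
    }
    se <- sqrt(max(var_a, 0))
    if (S_a <= 0 || S_a >= 1 || se == 0) {
      lo <- hi <- S_a
    } else {
      se_logit <- se / (S_a * (1 - S_a))
      lo <- stats::plogis(stats::qlogis(S_a) - 1.96 * se_logit)
      hi <- stats::plogis(stats::qlogis(S_a) + 1.96 * se_logit)
    }
    data.frame(sex = sx, S_hat = unname(S_a), SE = se, lower = lo,
               upper = hi, scenario = scenario, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("annual_survival", "data.frame")
  out
}
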