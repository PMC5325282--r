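#' Survivorship from fledging to a given age in months
#'
#' Composes the stage-specific annual survival rates into the
#' probability \eqn{\varphi(m)} that a fledgling survives to age `m`
#' months, with stage boundaries at 12, 24, 36 and 48 months and
#' fractional years handled as \eqn{S^{months/12}}:
#' \deqn{\varphi(m) = S_j^{\min(m,12)/12}\,
#'   S_s^{\mathrm{clamp}((m-12)/12,\,0,\,3)}\,
#'   S_b^{\max((m-48)/12,\,0)}.}
#'
#' @param rates A [vital_rates] object (a censoring scenario).
#' @param months Age in months (vectorised, non-negative).
#' @return Survival probability, non-increasing in `months`, with
#'   \eqn{\varphi(0) = 1}.
#' @examples
#' survivorship(canonical_vital_rates("turbine_censored"), 40) # 0.695
#' @export
survivorship <- function(rates, months) {
  stopifnot(inherits(rates, "vital_rates"))
  if (any(months < 0)) stop("age must be non-negative", call. = FALSE)
  rates$S_j^(pmin(months, 12) / 12) *
    rates$S_s^pmin(pmax((months - 12) / 12, 0), 3) *
    rates$S_b^pmax((months - 48) / 12, 0)
}

#' Pairs whose annual output supplies a number of fledglings
#'
#' @param fledglings_needed Expected number of fledglings required.
#' @param f2 Fledglings of both sexes per pair per year (default 0.638).
#' @return `fledglings_needed / f2` pairs.
#' @examples
#' pairs_to_produce(1, 0.638) # 1.567 pairs per recent-fledgling death
#' @export
pairs_to_produce <- function(fledglings_needed, f2 = 0.638) {
  if (f2 <= 0) stop("`f2` must be positive", call. = FALSE)
  if (any(fledglings_needed < 0)) stop("negative fledgling demand",
                                       call. = FALSE)
  fledglings_needed / f2
}

#' Published exact pairs-per-fatality count
#'
#' A previously reported closed-form value (3.931) for the asymptotic
#' number of pairs consumed per blade-strike fatality at the
#' turbine-censored rates.  It is retained as a reference constant for
#' comparison and for scaling published footprints; the iterative
#' replacement chain computed here from the same rounded inputs
#' converges to about 3.85, and the two have not been reconciled.
#'
#' @return The number 3.931.
#' @export
reference_pairs_per_fatality <- function() 3.931

#' Replacement-chain demographic cost of one fatality
#'
#' Counts the breeding pairs whose entire annual reproductive output is
#' consumed by a single fatality of a given age, including the chain of
#' pairs needed to keep those pairs themselves staffed.  The initial
#' demand is \eqn{P_0 = 1/(f_2\,\varphi(a))} pairs, whose sole surviving
#' issue is the fatality at age `a` months.  Those pairs are not
#' self-sustaining: each of their \eqn{2 P_0} members incurs annual
#' breeder mortality \eqn{1 - S_b}, and each replacement recruit is the
#' sole survivor of \eqn{1/\varphi_r} fledglings, where the recruit
#' survivorship \eqn{\varphi_r = S_j S_s^3 S_b} carries a full adult
#' year at breeder survival.  Every round therefore multiplies the
#' previous pair increment by
#' \eqn{r = 2 (1 - S_b) / (f_2 \varphi_r)}, and the cumulative count
#' after `k` rounds is \eqn{P_0 \sum_{i=0}^{k} r^i}, converging to
#' \eqn{P_0/(1-r)} when \eqn{r < 1}.
#'
#' @param rates A [vital_rates] object.
#' @param f2 Fledglings of both sexes per pair per year (default 0.638).
#' @param fatality_age_months Age at death (default 40, the estimated
#'   mean age of blade-strike death).
#' @param k_rounds Replacement rounds beyond the initial demand
#'   (default 6, i.e. seven cumulative terms).
#' @return Object of class `cost_chain`: `pairs_initial`, the cumulative
#'   `series` (terms 0..k), `pairs_limit`, `replacement_ratio`,
#'   `recruit_survivorship`, a `sustainable` flag (`FALSE` when
#'   \eqn{r \ge 1}, where no finite limit exists), and the inputs.
#' @examples
#' replacement_chain(canonical_vital_rates("turbine_censored"))
#' @export
replacement_chain <- function(rates, f2 = 0.638, fatality_age_months = 40,
                              k_rounds = 6L) {
  stopifnot(inherits(rates, "vital_rates"))
  if (k_rounds < 0) stop("`k_rounds` must be >= 0", call. = FALSE)
  phi_a <- survivorship(rates, fatality_age_months)
  P0 <- pairs_to_produce(1 / phi_a, f2)
  phi_r <- rates$S_j * rates$S_s^3 * rates$S_b
  pairs_per_recruit <- pairs_to_produce(1 / phi_r, f2)
  r <- 2 * (1 - rates$S_b) * pairs_per_recruit
  series <- P0 * cumsum(r^(0:k_rounds))
  sustainable <- r < 1
  structure(list(fatality_age_months = fatality_age_months,
                 pairs_initial = P0, series = series,
                 pairs_limit = if (sustainable) P0 / (1 - r) else Inf,
                 replacement_ratio = r,
                 recruit_survivorship = phi_r,
                 pairs_per_recruit = pairs_per_recruit,
                 sustainable = sustainable, f2 = f2,
                 scenario = rates$scenario),
            class = "cost_chain")
}

#' @export
print.cost_chain <- function(x, ...) {
  cat(sprintf("Demographic cost of one fatality at %.0f months [%s]\n",
              x$fatality_age_months, x$scenario))
  cat(sprintf("  initial pairs %.3f; per-round ratio r = %.4f\n",
              x$pairs_initial, x$replacement_ratio))
  cat("  cumulative series:",
      paste(sprintf("%.3f", x$series), collapse = ", "), "\n")
  cat(sprintf("  limit %.3f pairs per fatality%s\n", x$pairs_limit,
              if (!x$sustainable) " (UNSUSTAINABLE, r >= 1)" else ""))
  invisible(x)
}

#' Age-weighted pairs per fatality
#'
#' Averages the replacement-chain limit over a distribution of fatality
#' ages, for use when ages at death are known individually rather than
#' summarised by their mean.
#'
#' @param rates A [vital_rates] object.
#' @param f2 Fledglings of both sexes per pair per year.
#' @param ages Fatality ages in months.
#' @param weights Non-negative weights summing to 1, one per age.
#' @return Weighted mean of the per-age pairs-per-fatality limits.
#' @export
age_resolved_cost <- function(rates, f2 = 0.638, ages, weights) {
  if (length(ages) != length(weights) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be non-negative, match `ages`, and sum to 1",
         call. = FALSE)
  limits <- vapply(ages, function(a)
    replacement_chain(rates, f2, a)$pairs_limit, numeric(1))
  sum(weights * limits)
}

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Population footprint of an annual mortality toll
#'
#' Scales the per-fatality pair cost linearly by the annual death toll
#' and, optionally, by the fraction of the affected population resident
#' to the study area, yielding the number of occupied territories whose
#' entire reproductive output the toll consumes.
#'
#' @param pairs_per_fatality Pairs consumed per fatality (e.g. a
#'   [replacement_chain()] limit or [reference_pairs_per_fatality()]).
#' @param annual_deaths Fatalities per year.
#' @param resident_fraction Fraction of the toll drawn from the resident
#'   population (default 1).
#' @return Object of class `footprint_result` with `pairs_required` and
#'   `resident_pairs`, both rounded half up to whole pairs, plus the
#'   unrounded values.
#' @examples
#' footprint(reference_pairs_per_fatality(), 55) # 216 pairs
#' @export
footprint <- function(pairs_per_fatality, annual_deaths,
                      resident_fraction = 1) {
  if (pairs_per_fatality < 0 || annual_deaths < 0)
    stop("inputs must be non-negative", call. = FALSE)
  if (resident_fraction < 0 || resident_fraction > 1)
    stop("`resident_fraction` must lie in [0,1]", call. = FALSE)
  exact <- annual_deaths * pairs_per_fatality
  structure(list(annual_deaths = annual_deaths,
                 pairs_required = .round_half_up(exact),
                 resident_fraction = resident_fraction,
                 resident_pairs = .round_half_up(resident_fraction * exact),
                 pairs_required_exact = exact,
                 resident_pairs_exact = resident_fraction * exact),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf(
    "%g deaths/yr -> %.0f pairs (%.1f); resident fraction %.2f -> %.0f pairs\n",
    x$annual_deaths, x$pairs_required, x$pairs_required_exact,
    x$resident_fraction, x$resident_pairs))
  invisible(x)
}
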