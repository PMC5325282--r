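#' Summarise reproduction from nest surveys
#'
#' Per year: fledglings per surveyed pair, mean brood size among broods
#' that fledged young, and nest success (proportion of surveyed pairs
#' fledging at least one young).  Across years the mean annual
#' reproductive rate is the unweighted mean of the annual
#' fledglings-per-pair rates, with its standard error taken across years;
#' equal weighting keeps a short run of surveys from being dominated by
#' the years with the most territories visited.
#'
#' @param surveys A [nest_surveys] table.
#' @return Object of class `reproduction_summary`: `per_year` data frame
#'   (`year`, counts, `fledglings_per_pair`, `mean_brood_size`,
#'   `nest_success`), `mean_annual_rate`, and `SE`.  Years with no
#'   fledged broods get `NA` brood size.
#' @export
summarize_reproduction <- function(surveys) {
  s <- nest_surveys(surveys)
  if (!nrow(s)) stop("need at least one survey year", call. = FALSE)
  if (any(s$pairs_surveyed <= 0))
    stop("zero pairs surveyed in year ",
         s$year[s$pairs_surveyed <= 0][1L], call. = FALSE)
  per <- data.frame(
    year = s$year,
    pairs_surveyed = s$pairs_surveyed,
    fledglings = s$fledglings,
    fledged_broods = s$fledged_broods,
    fledglings_per_pair = s$fledglings / s$pairs_surveyed,
    mean_brood_size = ifelse(s$fledged_broods > 0,
                             s$fledglings / s$fledged_broods, NA_real_),
    nest_success = s$fledged_broods / s$pairs_surveyed)
  rate <- mean(per$fledglings_per_pair)
  se <- if (nrow(per) > 1)
    stats::sd(per$fledglings_per_pair) / sqrt(nrow(per)) else NA_real_
  structure(list(per_year = per, mean_annual_rate = rate, SE = se),
            class = "reproduction_summary")
}

#' @export
print.reproduction_summary <- function(x, ...) {
  print(cbind(x$per_year[1:4],
              round(x$per_year[5:7], 2)), row.names = FALSE)
  cat(sprintf("Mean annual rate: %.4f fledglings/pair (SE %.4f)\n",
              x$mean_annual_rate, x$SE))
  invisible(x)
}

#' G-test of departure from a 1:1 sex ratio
#'
#' Likelihood-ratio goodness-of-fit test
#' \eqn{G = 2\sum O \log(O/E)} with expected counts of half the total in
#' each sex and 1 degree of freedom; no continuity or Williams
#' correction is applied.  A zero cell is handled with the
#' \eqn{0\log 0 = 0} convention (with a warning).
#'
#' @param males,females Non-negative counts.
#' @return An object of class `htest` with the G statistic, df and
#'   p-value (from the chi-square distribution).
#' @examples
#' g_test_parity(68, 39) # G = 7.96, p = 0.005
#' @export
g_test_parity <- function(males, females) {
  if (males < 0 || females < 0) stop("counts must be non-negative",
                                     call. = FALSE)
  total <- males + females
  if (total < 1) stop("need at least one individual", call. = FALSE)
  if (males == 0 || females == 0)
    warning("zero cell; G computed with the 0*log(0) = 0 convention")
  E <- total / 2
  term <- function(o) if (o == 0) 0 else o * log(o / E)
  G <- 2 * (term(males) + term(females))
  structure(list(statistic = c(G = G), parameter = c(df = 1),
                 p.value = stats::pchisq(G, df = 1, lower.tail = FALSE),
                 method = "G-test of 1:1 sex-ratio parity",
                 data.name = sprintf("%d males : %d females",
                                     males, females),
                 observed = c(males = males, females = females),
                 expected = c(males = E, females = E)),
            class = "htest")
}

#' Female-fledgling reproductive rate
#'
#' The single-sex fecundity input for the matrix models: female
#' fledglings per female territory-holder per year, formed as the mean
#' annual fledgling rate times the proportion of fledglings that are
#' female.  The standard error follows by the delta method for a product
#' of independent estimates:
#' \eqn{SE^2 = p^2\,var(rate) + rate^2\,var(p)}.
#'
#' @param mean_annual_rate Fledglings (both sexes) per pair per year.
#' @param p_female Proportion of fledglings that are female (default
#'   `0.36`, one minus the observed 64% male proportion).
#' @param rate_se,p_female_se Standard errors of the two inputs
#'   (default 0).
#' @return Object of class `female_fecundity` with elements `f` and `SE`.
#' @export
female_fecundity <- function(mean_annual_rate, p_female = 0.36,
                             rate_se = 0, p_female_se = 0) {
  if (mean_annual_rate < 0 || p_female < 0 || p_female > 1)
    stop("inputs out of range", call. = FALSE)
  f <- mean_annual_rate * p_female
  se <- sqrt(p_female^2 * rate_se^2 + mean_annual_rate^2 * p_female_se^2)
  structure(list(f = f, SE = se, mean_annual_rate = mean_annual_rate,
                 p_female = p_female), class = "female_fecundity")
}

#' @export
print.female_fecundity <- function(x, ...) {
  cat(sprintf(
    "f = %.4f female fledglings per female territory-holder (SE %.4f)\n",
    x$f, x$SE))
  invisible(x)
}

#' Percentage of subadult pair members among aged breeders
#'
#' An index of recruitment stress: a rising share of subadults holding
#' territories would indicate a deficit of adult replacements.
#'
#' @param aged_birds Number of pair members whose age class was
#'   determined.
#' @param subadult_members Number of those that were subadults.
#' @return Percentage, rounded to 1 decimal place.
#' @export
subadult_pair_fraction <- function(aged_birds, subadult_members) {
  if (aged_birds <= 0) stop("no aged birds", call. = FALSE)
  if (subadult_members > aged_birds)
    stop("subadult members exceed aged birds", call. = FALSE)
  round(100 * subadult_members / aged_birds, 1)
}
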