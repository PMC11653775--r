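#' Intervention efficacy from a meta-analytic risk ratio
#'
#' Converts a protective risk ratio into a percent caries-reduction
#' efficacy: `(1 - RR) * 100`.
#'
#' @param risk_ratio Risk ratio in \[0, 1\] (protective effect).
#' @return Efficacy in percent.
#' @examples
#' efficacy_from_rr(0.9)   # 10: supervised toothbrushing
#' efficacy_from_rr(0.29)  # 71: sealant, molar teeth
#' @export
efficacy_from_rr <- function(risk_ratio) {
  if (any(!is.finite(risk_ratio)) || any(risk_ratio < 0)) {
    stop("risk_ratio must be a nonnegative number", call. = FALSE)
  }
  if (any(risk_ratio > 1)) {
    stop("risk_ratio > 1: intervention is not protective, efficacy undefined",
         call. = FALSE)
  }
  (1 - risk_ratio) * 100
}

#' All-teeth efficacy from tooth-type-specific efficacies
#'
#' Sealants act on molars only; the whole-dentition efficacy is the
#' molar efficacy weighted by the molar share of caries plus the
#' other-teeth efficacy weighted by the remainder:
#' `share * molar + (1 - share) * other`. With the national figures
#' (82% of caries on molars, 71% molar efficacy, 0% elsewhere) this gives
#' 58.22%, reported as 58%.
#'
#' @param molar_caries_share Proportion of caries occurring on molars.
#' @param molar_efficacy_pct Efficacy on molar teeth, percent.
#' @param other_teeth_efficacy_pct Efficacy on non-molar teeth, percent.
#' @return Whole-dentition efficacy in percent (unrounded).
#' @examples
#' all_teeth_efficacy(0.82, 71, 0)  # 58.22
#' @export
all_teeth_efficacy <- function(molar_caries_share, molar_efficacy_pct,
                               other_teeth_efficacy_pct) {
  if (molar_caries_share < 0 || molar_caries_share > 1) {
    stop("molar_caries_share must be a proportion in [0, 1]", call. = FALSE)
  }
  for (e in c(molar_efficacy_pct, other_teeth_efficacy_pct)) {
    if (e < 0 || e > 100) stop("efficacies must be in [0, 100] percent", call. = FALSE)
  }
  molar_caries_share * molar_efficacy_pct +
    (1 - molar_caries_share) * other_teeth_efficacy_pct
}

#' Coverage-adjusted efficacy
#'
#' The effective (population-level) efficacy of an intervention is its
#' trial efficacy scaled by the national coverage rate:
#' `base_efficacy * coverage / 100`.
#'
#' @param base_efficacy_pct Trial efficacy, percent.
#' @param coverage_pct National coverage, percent.
#' @return Adjusted efficacy in percent.
#' @examples
#' adjusted_efficacy(10, 92.5)  # 9.25: supervised toothbrushing
#' adjusted_efficacy(58, 27)    # 15.66, reported 15.7: sealant
#' @export
adjusted_efficacy <- function(base_efficacy_pct, coverage_pct) {
  for (v in c(base_efficacy_pct, coverage_pct)) {
    if (!is.finite(v) || v < 0 || v > 100) {
      stop("efficacy and coverage must be percentages in [0, 100]", call. = FALSE)
    }
  }
  base_efficacy_pct * coverage_pct / 100
}

#' Intervention scenario specification
#'
#' Bundles one scenario's efficacy arithmetic and active age window. The
#' adjusted efficacy defaults to `base_efficacy_pct * coverage_pct / 100`;
#' a pre-rounded published value may be supplied instead and is accepted if
#' within 0.05 percentage points of the product (published tables round).
#'
#' @param name Scenario label (e.g. `"base_case"`, `"stb"`, `"sealant"`,
#'   `"stb_sealant"`).
#' @param base_efficacy_pct Trial efficacy, percent.
#' @param coverage_pct Coverage, percent.
#' @param adjusted_efficacy_pct Optional published adjusted efficacy,
#'   percent; computed from the product when omitted.
#' @param start_age,end_age Ages (inclusive) during which the intervention
#'   is delivered; the efficacy multiplier applies to annual steps starting
#'   at these ages.
#' @param risk_ratio Optional meta-analytic risk ratio the efficacy derives
#'   from (recorded for provenance, not used in computation).
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, base_efficacy_pct = 0, coverage_pct = 0,
                              adjusted_efficacy_pct = NULL,
                              start_age = 6, end_age = 12,
                              risk_ratio = NULL) {
  product <- adjusted_efficacy(base_efficacy_pct, coverage_pct)
  if (is.null(adjusted_efficacy_pct)) {
    adjusted_efficacy_pct <- product
  } else if (abs(adjusted_efficacy_pct - product) > 0.05) {
    stop(sprintf(
      "adjusted_efficacy_pct (%.3f) inconsistent with base x coverage (%.3f)",
      adjusted_efficacy_pct, product), call. = FALSE)
  }
  if (adjusted_efficacy_pct > base_efficacy_pct + 1e-9) {
    stop("adjusted efficacy cannot exceed base efficacy", call. = FALSE)
  }
  if (start_age > end_age) stop("malformed intervention age window", call. = FALSE)
  structure(list(name = name,
                 risk_ratio = risk_ratio,
                 base_efficacy_pct = base_efficacy_pct,
                 coverage_pct = coverage_pct,
                 adjusted_efficacy_pct = adjusted_efficacy_pct,
                 start_age = as.integer(start_age),
                 end_age = as.integer(end_age)),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': efficacy %.4g%% x coverage %.4g%% = %.4g%% (ages %d-%d)\n",
              x$name, x$base_efficacy_pct, x$coverage_pct,
              x$adjusted_efficacy_pct, x$start_age, x$end_age))
  invisible(x)
}

#' The four national school-based prevention scenarios
#'
#' Builds the base case plus the three Ministry of Public Health
#' intervention scenarios for 6- to 12-year-olds, with their published
#' efficacy and coverage figures:
#' \itemize{
#'   \item `base_case`: no intervention (adjusted efficacy 0).
#'   \item `stb`: supervised toothbrushing — 10% efficacy (risk ratio 0.9)
#'     at 92.5% coverage, adjusted 9.25%.
#'   \item `sealant`: dental sealant — 58% all-teeth efficacy (71% on
#'     molars, 82% molar caries share) at 27% coverage, adjusted 15.66%
#'     (published as 15.7%).
#'   \item `stb_sealant`: combined — 60% efficacy (expert-determined) at
#'     33% coverage, adjusted 19.8%.
#' }
#'
#' @return Named list of four [intervention_spec()] objects.
#' @export
moph_scenarios <- function() {
  list(
    base_case = intervention_spec("base_case", 0, 0),
    stb = intervention_spec("stb",
                            base_efficacy_pct = efficacy_from_rr(0.9),
                            coverage_pct = 92.5,
                            risk_ratio = 0.9),
    sealant = intervention_spec("sealant",
                                base_efficacy_pct = 58,
                                coverage_pct = 27,
                                risk_ratio = 0.29),
    stb_sealant = intervention_spec("stb_sealant",
                                    base_efficacy_pct = 60,
                                    coverage_pct = 33))
}

#' Percent change versus the base case
#'
#' `100 * (scenario - base) / base`, the change of a scenario's endpoint
#' count relative to the no-intervention base case.
#'
#' @param scenario_value Scenario count, persons.
#' @param base_value Base-case count, persons (must be positive).
#' @return Percent change (unrounded).
#' @examples
#' percent_change(153042, 112405)  # +36.2 after rounding to 1 dp
#' @export
percent_change <- function(scenario_value, base_value) {
  if (any(base_value <= 0)) {
    stop("percent change undefined for nonpositive base value", call. = FALSE)
  }
  100 * (scenario_value - base_value) / base_value
}

#' Endpoint scenario report
#'
#' Summarizes each scenario's endpoint compartment counts at the final age
#' alongside the compartment's percentage of the cohort and its percent
#' change versus the base case, in the standard reporting layout (rows:
#' no caries, untreated caries, restoration, endodontic, missing teeth).
#' Counts are rounded to whole persons, percentages to 2 decimal places,
#' percent changes to 1.
#'
#' @param trajectories Named list of `caries_trajectory` objects sharing
#'   one configuration; must contain `base_case`.
#' @return A `scenario_report` data.frame in long format with columns
#'   `scenario`, `compartment`, `persons`, `percent`, `pct_change`.
#' @export
scenario_report <- function(trajectories) {
  if (!"base_case" %in% names(trajectories)) {
    stop("trajectories must include a 'base_case' entry", call. = FALSE)
  }
  ends <- lapply(trajectories, endpoint_counts)
  totals <- vapply(ends, sum, numeric(1))
  if (max(totals) - min(totals) > 1e-6 * max(totals)) {
    stop("trajectories do not share a common total population", call. = FALSE)
  }
  base <- ends[["base_case"]]
  out <- do.call(rbind, lapply(names(ends), function(nm) {
    counts <- ends[[nm]]
    data.frame(scenario = nm,
               compartment = compartment_names(),
               persons = round(counts),
               percent = round(100 * counts / sum(counts), 2),
               pct_change = round(percent_change(counts, base), 1),
               row.names = NULL)
  }))
  class(out) <- c("scenario_report", "data.frame")
  out
}

#' Published endpoint simulation table
#'
#' The published age-15 endpoint counts for the four scenarios (base case,
#' supervised toothbrushing, sealant, combined), used as calibration
#' targets and as worked examples for the percent-change arithmetic. Each
#' column sums to the cohort total of 678,243.
#'
#' @return Data.frame with a `compartment` column and one count column per
#'   scenario.
#' @export
published_endpoints <- function() {
  data.frame(
    compartment = compartment_names(),
    base_case   = c(112405, 280244, 119813, 12822, 152959),
    stb         = c(128655, 271467, 116808, 12574, 148739),
    sealant     = c(141097, 264507, 114601, 12390, 145648),
    stb_sealant = c(153042, 257655, 112547, 12222, 142777))
}

#' Published base-case calibration targets
#'
#' @return Named numeric vector of the five base-case endpoint counts.
#' @export
base_case_targets <- function() {
  tab <- published_endpoints()
  stats::setNames(tab$base_case, tab$compartment)
}
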