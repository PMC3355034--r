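# 100-day decision tree: expected IFI events, deaths, survivors, costs and
# acute-phase life-years per prophylaxis strategy.

#' Expected prophylaxis cost per patient
#'
#' Sum over the strategy's drug components of
#' `weight x duration_days x (drug + preparation/administration/monitoring
#' cost per day)`.  For SAT the mixture is fluconazole 81% / itraconazole
#' 19%, mirroring the trial arm; durations are trial means and accrue in
#' full on every branch.
#'
#' @param strategy One element of `config$strategies`.
#' @return Cost in EUR per patient.
#' @export
prophylaxis_cost <- function(strategy) {
  sum(vapply(strategy$components, function(k)
    k$weight * k$duration_days *
      (k$drug_cost_per_day + k$prep_admin_monitor_cost_per_day),
    numeric(1)))
}

# Vectorised tree composition shared by the scalar API and the PSA.
# By default the non-IFI death probability applies only to the no-IFI branch;
# with expose_ifi_survivors = TRUE, IFI survivors are additionally exposed.
acute_probs <- function(p_ifi, p_death_ifi, p_death_other,
                        expose_ifi_survivors = FALSE) {
  die_ifi <- p_ifi * p_death_ifi
  die_other <- if (expose_ifi_survivors)
    (1 - die_ifi) * p_death_other
  else
    (1 - p_ifi) * p_death_other
  list(die_ifi = die_ifi, die_other = die_other,
       survive = 1 - die_ifi - die_other)
}

#' Acute-phase life-years
#'
#' Within-window life-year accrual convention: 100-day survivors contribute
#' the full window (`acute_days/365.25` years), IFI-related deaths contribute
#' the arm's mean time to IFI, and other-cause deaths the window midpoint.
#' No discounting is applied (everything falls inside the first year).
#'
#' @param p_survive,p_die_ifi,p_die_other Terminal branch probabilities
#'   (must sum to 1).
#' @param mean_days_to_ifi Mean time to IFI onset, days.
#' @param acute_days Window length in days (default 100).
#' @return Expected life-years per patient accrued within the window.
#' @export
acute_life_years <- function(p_survive, p_die_ifi, p_die_other,
                             mean_days_to_ifi, acute_days = 100) {
  (p_survive * acute_days + p_die_ifi * mean_days_to_ifi +
     p_die_other * acute_days / 2) / 365.25
}

#' Run the 100-day decision tree for one strategy
#'
#' After the decision node the patient either develops a proven/probable IFI
#' (probability `p_ifi`) and then survives or dies of it (`p_death_ifi`), or
#' does not and is exposed to death from other causes (`p_death_other`).
#' Expected costs are the full prophylaxis course plus `p_ifi` times the IFI
#' episode cost.
#'
#' @param strategy One element of `config$strategies`.
#' @param shared The `shared` block of the config.
#' @return An `acute_outcome` list: `expected_ifis`, `p_die_ifi_related`,
#'   `p_die_other`, `p_survive_100d`, `cost_prophylaxis`,
#'   `cost_ifi_management`, `acute_life_years`.
#' @export
run_decision_tree <- function(strategy, shared) {
  cl <- strategy$clinical
  pr <- acute_probs(cl$p_ifi, cl$p_death_ifi, cl$p_death_other,
                    isTRUE(shared$expose_ifi_survivors))
  if (any(unlist(pr) < -1e-12) || any(unlist(pr) > 1 + 1e-12))
    stop("composed branch probabilities fall outside [0,1] for strategy '",
         strategy$name, "'")
  out <- list(
    strategy = strategy$name,
    expected_ifis = cl$p_ifi,
    p_die_ifi_related = pr$die_ifi,
    p_die_other = pr$die_other,
    p_survive_100d = pr$survive,
    cost_prophylaxis = prophylaxis_cost(strategy),
    cost_ifi_management = cl$p_ifi * shared$c_ifi,
    acute_life_years = acute_life_years(pr$survive, pr$die_ifi, pr$die_other,
                                        cl$mean_days_to_ifi,
                                        shared$acute_days))
  structure(out, class = "acute_outcome")
}

#' @export
print.acute_outcome <- function(x, ...) {
  cat(sprintf(
    "<acute_outcome> %s: E[IFI]=%.4f, P(die IFI)=%.4f, P(die other)=%.4f, P(survive)=%.4f\n",
    x$strategy, x$expected_ifis, x$p_die_ifi_related, x$p_die_other,
    x$p_survive_100d))
  cat(sprintf("  prophylaxis %.2f EUR + IFI management %.2f EUR; acute LY %.4f\n",
              x$cost_prophylaxis, x$cost_ifi_management, x$acute_life_years))
  invisible(x)
}

#' Serialise acute outcomes to a data frame
#'
#' One row per strategy, columns `strategy`, `expected_ifis`, `p_die_ifi`,
#' `p_die_other`, `p_survive`, `cost_prophylaxis`, `cost_ifi`, `acute_ly`.
#'
#' @param outcomes A list of `acute_outcome` objects.
#' @return A data frame.
#' @export
acute_outcome_table <- function(outcomes) {
  do.call(rbind, lapply(outcomes, function(x)
    data.frame(strategy = x$strategy, expected_ifis = x$expected_ifis,
               p_die_ifi = x$p_die_ifi_related, p_die_other = x$p_die_other,
               p_survive = x$p_survive_100d,
               cost_prophylaxis = x$cost_prophylaxis,
               cost_ifi = x$cost_ifi_management,
               acute_ly = x$acute_life_years,
               stringsAsFactors = FALSE)))
}
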