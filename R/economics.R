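# Incremental cost-effectiveness: per-strategy totals, dominance
# classification, ICERs and net monetary benefit.

#' Combine acute and lifetime outcomes into per-strategy totals
#'
#' Total cost is prophylaxis plus expected IFI-management cost (all costs
#' fall inside the 100-day window and are not discounted); effects are the
#' expected IFI events and total (discounted) life-years.
#'
#' @param acute An `acute_outcome` from [run_decision_tree()].
#' @param lifetime A `lifetime_outcome` from [run_markov()].
#' @return A `strategy_result` list: `strategy`, `total_cost`,
#'   `expected_ifis`, `lys`.
#' @export
strategy_result <- function(acute, lifetime) {
  structure(list(strategy = acute$strategy,
                 total_cost = acute$cost_prophylaxis + acute$cost_ifi_management,
                 expected_ifis = acute$expected_ifis,
                 lys = lifetime$lys_total),
            class = "strategy_result")
}

# Dominance classification for one effect measure (delta oriented so larger
# effect = better).  Dominance requires strictly better on effect AND cost;
# a cost difference at exactly equal effect classifies by cost sign.
classify <- function(delta_cost, delta_effect, tol = 1e-12) {
  cheaper <- delta_cost < -tol
  costlier <- delta_cost > tol
  better <- delta_effect > tol
  worse <- delta_effect < -tol
  if (!cheaper && !costlier && !better && !worse) return("equivalent")
  if (better && cheaper) return("dominant")
  if (worse && costlier) return("dominated")
  if (!better && !worse) return(if (cheaper) "dominant" else "dominated")
  "tradeoff_icer"
}

#' Compare two strategies: incremental costs, effects, ICERs, dominance
#'
#' Deltas are intervention minus comparator, with effects oriented so that
#' larger is better (IFIs avoided = comparator minus intervention).  An ICER
#' is reported only in the trade-off case; under dominance (better and
#' cheaper) or dominatedness the ICER field is `NA` and the classification
#' carries the verdict, matching the convention that the ratio is then not
#' calculated.
#'
#' @param intervention,comparator `strategy_result` objects.
#' @return A `cea_comparison` list: `delta_cost`, `delta_ifis_avoided`,
#'   `delta_lys`, `icer_per_ifi_avoided`, `icer_per_lys`,
#'   `classification_ifi`, `classification_lys`.
#' @export
compare <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  d_ifi <- comparator$expected_ifis - intervention$expected_ifis
  d_lys <- intervention$lys - comparator$lys
  cls_ifi <- classify(dc, d_ifi)
  cls_lys <- classify(dc, d_lys)
  structure(list(
    intervention = intervention$strategy, comparator = comparator$strategy,
    delta_cost = dc, delta_ifis_avoided = d_ifi, delta_lys = d_lys,
    icer_per_ifi_avoided = if (cls_ifi == "tradeoff_icer") dc / d_ifi else NA_real_,
    icer_per_lys = if (cls_lys == "tradeoff_icer") dc / d_lys else NA_real_,
    classification_ifi = cls_ifi, classification_lys = cls_lys),
    class = "cea_comparison")
}

#' Net monetary benefit of the intervention
#'
#' `threshold x delta_lys - delta_cost`; positive exactly when the
#' intervention is cost-effective at that willingness-to-pay (ICER below the
#' threshold, or dominant).
#'
#' @param comparison A `cea_comparison` from [compare()].
#' @param threshold Willingness to pay, EUR per life-year saved.
#' @return Net monetary benefit in EUR (vectorised over `threshold`).
#' @export
net_monetary_benefit <- function(comparison, threshold) {
  stopifnot(all(threshold >= 0))
  threshold * comparison$delta_lys - comparison$delta_cost
}

icer_label <- function(icer, classification) {
  switch(classification,
         dominant = "Dominant", dominated = "Dominated",
         equivalent = "Equivalent", sprintf("%.0f", icer))
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  dCost %.0f EUR, dIFI avoided %.2f, dLYS %.2f\n",
              x$delta_cost, x$delta_ifis_avoided, x$delta_lys))
  cat(sprintf("  ICER per IFI avoided: %s | ICER per LYS: %s\n",
              icer_label(x$icer_per_ifi_avoided, x$classification_ifi),
              icer_label(x$icer_per_lys, x$classification_lys)))
  invisible(x)
}

# Full pipeline for one strategy under a shared parameter set.
run_strategy <- function(strategy, shared) {
  acute <- run_decision_tree(strategy, shared)
  lifetime <- run_markov(acute$p_survive_100d, shared, acute$acute_life_years)
  list(acute = acute, lifetime = lifetime,
       result = strategy_result(acute, lifetime))
}

#' Run the base-case analysis
#'
#' Applies the effective base-case substitution (unless `effective =
#' FALSE`), runs the decision tree and the Markov projection for both
#' strategies, and compares the first strategy (intervention) against the
#' second (comparator).
#'
#' @param config An `azole_config`.
#' @param effective Substitute range-implied effective values first?
#' @return A `base_case_result` list: `config`, per-strategy `acute`,
#'   `lifetime` and `results`, the `comparison`, and a publication-shaped
#'   `table` (rows intervention / comparator / difference).
#' @export
run_base_case <- function(config, effective = TRUE) {
  if (effective && !isTRUE(config$effective))
    config <- effective_base_case(config)
  shared <- config$shared
  runs <- lapply(config$strategies, run_strategy, shared = shared)
  nm <- names(config$strategies)
  comp <- compare(runs[[nm[1]]]$result, runs[[nm[2]]]$result)
  structure(list(
    config = config,
    acute = lapply(runs, `[[`, "acute"),
    lifetime = lapply(runs, `[[`, "lifetime"),
    results = lapply(runs, `[[`, "result"),
    comparison = comp,
    table = base_case_table(runs[[nm[1]]]$result, runs[[nm[2]]]$result, comp)),
    class = "base_case_result")
}

# Publication-precision summary table: costs to whole euros, effects to two
# decimals; internal arithmetic stays full precision.
base_case_table <- function(int, comp, comparison) {
  data.frame(
    strategy = c(int$strategy, comp$strategy, "difference"),
    total_cost = round(c(int$total_cost, comp$total_cost,
                         comparison$delta_cost)),
    ifi_events = round(c(int$expected_ifis, comp$expected_ifis,
                         -comparison$delta_ifis_avoided), 2),
    lys = round(c(int$lys, comp$lys, comparison$delta_lys), 2),
    icer_per_ifi_avoided = c("", "", icer_label(
      comparison$icer_per_ifi_avoided, comparison$classification_ifi)),
    icer_per_lys = c("", "", icer_label(
      comparison$icer_per_lys, comparison$classification_lys)),
    stringsAsFactors = FALSE)
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("Base-case cost-effectiveness analysis\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
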