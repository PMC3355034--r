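# Sensitivity analyses: one-way deterministic scenarios, second-order Monte
# Carlo (PSA), cost-effectiveness acceptability curve, and the
# threshold/crossover analysis on the incremental IFI-risk reduction.

# Paths whose value changes the per-survivor Markov life expectancy.
lifetime_paths <- c("rs_aml", "rs_mds", "aml_fraction", "rs_basis_years",
                    "discount_rate", "horizon_years",
                    "background_monthly_hazard")

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full model with one parameter at a time set to each bound of
#' its scenario range (all others at the effective base case) and records
#' the incremental results and dominance classification for both effect
#' measures.
#'
#' @param config An `azole_config`; the default scenario grid is taken from
#'   `config$dsa_scenarios` (12 parameters x 2 bounds = 24 scenarios).
#' @param scenarios Optional named list `path -> c(low, high)` overriding
#'   the grid.
#' @param effective Substitute the effective base case first?
#' @return A `dsa_result` data frame, one row per (parameter, bound):
#'   `parameter`, `value`, `bound`, `delta_cost`, `delta_ifis_avoided`,
#'   `delta_lys`, `icer_per_ifi_avoided`, `icer_per_lys`,
#'   `classification_ifi`, `classification_lys`, `dominant`.
#' @export
run_dsa <- function(config, scenarios = NULL, effective = TRUE) {
  if (effective && !isTRUE(config$effective))
    config <- effective_base_case(config)
  scenarios <- scenarios %||% config$dsa_scenarios
  if (!length(scenarios)) stop("no DSA scenarios defined")
  rows <- list()
  for (path in names(scenarios)) {
    bounds <- scenarios[[path]]
    for (j in 1:2) {
      cfg <- set_param(config, path, bounds[j])
      comp <- run_base_case(cfg, effective = FALSE)$comparison
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = path, value = bounds[j],
        bound = c("low", "high")[j],
        delta_cost = comp$delta_cost,
        delta_ifis_avoided = comp$delta_ifis_avoided,
        delta_lys = comp$delta_lys,
        icer_per_ifi_avoided = icer_label(comp$icer_per_ifi_avoided,
                                          comp$classification_ifi),
        icer_per_lys = icer_label(comp$icer_per_lys, comp$classification_lys),
        classification_ifi = comp$classification_ifi,
        classification_lys = comp$classification_lys,
        dominant = comp$classification_ifi == "dominant" &&
          comp$classification_lys == "dominant",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dsa_result", "data.frame")
  out
}

# Draw one matrix of sampled parameter values per the PSA specs.
sample_psa_params <- function(config, n_draws, fix) {
  draws <- list()
  for (path in names(config$psa)) {
    spec <- config$psa[[path]]
    m <- get_param(config, path)
    sd <- spec$sd %||% ((spec$cv %||% 0) * m)
    fam <- spec$family %||% "fixed"
    if (path %in% fix || sd == 0 || fam == "fixed") next
    draws[[path]] <- switch(fam,
      beta = {
        sh <- beta_from_moments(m, sd)
        rbeta(n_draws, sh[["shape1"]], sh[["shape2"]])
      },
      gamma = {
        g <- gamma_from_moments(m, sd)
        rgamma(n_draws, shape = g$shape, scale = g$scale)
      },
      stop("unsupported PSA family '", fam, "' for ", path))
  }
  draws
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Per draw, every parameter with a non-degenerate PSA spec is sampled from
#' its moment-matched distribution (Beta for probabilities, Gamma for the
#' IFI episode cost; published SD-0 rows stay fixed), both strategies are
#' recomputed end to end, and the incremental cost, IFIs avoided and
#' life-years are recorded.  Sampling is independent across parameters.
#'
#' @param config An `azole_config`.
#' @param n_draws Number of simulations (published analysis used 1,000).
#' @param seed Optional integer seed; a fixed seed gives bit-identical runs.
#' @param fix Character vector of parameter paths to hold at the base case
#'   regardless of their spec (e.g. `"c_ifi"` for the fixed-cost analysis).
#' @param effective Substitute the effective base case first?
#' @return A `psa_result` list: `draws` (data frame with one row per
#'   simulation), `n_draws`, `seed`, `p_cost_saving`, `p_below_threshold`
#'   (at the config's willingness-to-pay), `threshold`.
#' @export
run_psa <- function(config, n_draws = 1000, seed = NULL, fix = character(),
                    effective = TRUE) {
  if (effective && !isTRUE(config$effective))
    config <- effective_base_case(config)
  stopifnot(n_draws >= 1)
  v <- validate_config(config)
  if (nrow(v))
    stop("invalid configuration for PSA:\n",
         paste0("  - ", v$path, ": ", v$rule, collapse = "\n"))
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_psa_params(config, n_draws, fix)
  shared <- config$shared
  base_val <- function(path) rep(get_param(config, path), n_draws)
  val <- function(path) draws[[path]] %||% base_val(path)

  # Per-survivor life expectancy: constant across draws unless a
  # lifetime-affecting parameter is actually sampled.
  sampled_lifetime <- intersect(names(draws), lifetime_paths)
  if (length(sampled_lifetime)) {
    le <- vapply(seq_len(n_draws), function(i) {
      sh <- shared
      for (p in sampled_lifetime) sh[[p]] <- draws[[p]][i]
      markov_life_expectancy(sh)$disc
    }, numeric(1))
  } else {
    le <- markov_life_expectancy(shared)$disc
  }

  c_ifi <- val("c_ifi")
  arm <- function(s) {
    strat <- config$strategies[[s]]
    cl <- strat$clinical
    p_ifi <- val(paste0(s, ".p_ifi"))
    p_dif <- val(paste0(s, ".p_death_ifi"))
    p_doth <- draws[[paste0(s, ".p_death_other")]] %||%
      draws[["p_death_other"]] %||% rep(cl$p_death_other, n_draws)
    proph <- Reduce(`+`, lapply(strat$components, function(k) {
      cpd <- draws[[paste0("cost_per_day.", k$name)]] %||%
        rep(k$drug_cost_per_day + k$prep_admin_monitor_cost_per_day, n_draws)
      k$weight * k$duration_days * cpd
    }))
    pr <- acute_probs(p_ifi, p_dif, p_doth, isTRUE(shared$expose_ifi_survivors))
    ly_acute <- acute_life_years(pr$survive, pr$die_ifi, pr$die_other,
                                 cl$mean_days_to_ifi, shared$acute_days)
    list(cost = proph + p_ifi * c_ifi, ifis = p_ifi,
         lys = ly_acute + pr$survive * le)
  }
  nm <- names(config$strategies)
  a <- arm(nm[1]); b <- arm(nm[2])
  df <- data.frame(draw = seq_len(n_draws),
                   cost_intervention = a$cost, cost_comparator = b$cost,
                   delta_cost = a$cost - b$cost,
                   delta_ifis_avoided = b$ifis - a$ifis,
                   delta_lys = a$lys - b$lys)
  for (p in names(draws)) df[[p]] <- draws[[p]]
  lambda <- shared$wtp_threshold
  structure(list(draws = df, n_draws = n_draws, seed = seed,
                 intervention = nm[1], comparator = nm[2],
                 threshold = lambda,
                 p_cost_saving = mean(df$delta_cost < 0),
                 p_below_threshold =
                   mean(lambda * df$delta_lys - df$delta_cost > 0)),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA draws with
#' positive net monetary benefit (`lambda * delta_lys - delta_cost > 0`).
#' At `lambda = 0` this equals the probability of being cost-saving.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param thresholds Non-decreasing non-negative grid of thresholds
#'   (EUR/LYS); default 0 to 60,000 in steps of 1,000.
#' @return Data frame with columns `threshold`, `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 60000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"), all(thresholds >= 0),
            !is.unsorted(thresholds))
  data.frame(threshold = thresholds,
             probability = vapply(thresholds, function(l)
               mean(l * psa$draws$delta_lys - psa$draws$delta_cost > 0),
               numeric(1)))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%s vs %s)%s\n", x$n_draws,
              x$intervention, x$comparator,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  cat(sprintf("  P(cost-saving) = %.3f\n", x$p_cost_saving))
  cat(sprintf("  P(ICER below %.0f EUR/LYS) = %.3f\n", x$threshold,
              x$p_below_threshold))
  invisible(x)
}

#' Crossover analysis on the incremental IFI-risk reduction
#'
#' Holding the comparator (SAT) fixed, the intervention's clinical
#' parameters are interpolated linearly towards the comparator's so that the
#' incremental IFI-risk reduction shrinks from its base-case value
#' `dp_base = p_ifi(SAT) - p_ifi(posaconazole)` to 0 (at which point the two
#' arms are clinically identical and only the prophylaxis costs differ).
#' The function locates, by root finding, the reduction `dp*` at which the
#' ICER per LYS equals the willingness-to-pay threshold, and evaluates a
#' small reference table of `dp` values.
#'
#' @param config An `azole_config`.
#' @param threshold Willingness to pay (default: config's `wtp_threshold`).
#' @param table_dp Reference reductions to tabulate (default 0, 0.02, 0.06).
#' @param effective Substitute the effective base case first?
#' @return A `crossover_result` list: `dp_base`, `dp_star` (NA if no
#'   crossing), `status` (`"crossover"` or `"dominant throughout"`),
#'   `threshold`, and `table` (columns `dp`, `delta_cost`, `delta_lys`,
#'   `icer_per_lys`, `classification`, `cost_effective`).
#' @export
crossover_benefit <- function(config, threshold = NULL,
                              table_dp = c(0, 0.02, 0.06), effective = TRUE) {
  if (effective && !isTRUE(config$effective))
    config <- effective_base_case(config)
  threshold <- threshold %||% config$shared$wtp_threshold
  stopifnot(threshold > 0)
  nm <- names(config$strategies)
  clP <- config$strategies[[nm[1]]]$clinical
  clS <- config$strategies[[nm[2]]]$clinical
  dp_base <- clS$p_ifi - clP$p_ifi
  if (dp_base <= 0)
    stop("intervention must have the lower IFI probability at base case")
  comp_at <- function(dp) {
    f <- dp / dp_base
    cfg <- config
    cfg$strategies[[nm[1]]]$clinical <-
      Map(function(s, p) s + f * (p - s), clS, clP)
    run_base_case(cfg, effective = FALSE)$comparison
  }
  nmb_at <- function(dp) net_monetary_benefit(comp_at(dp), threshold)
  eps <- dp_base * 1e-6
  lo <- nmb_at(eps); hi <- nmb_at(dp_base)
  if (lo < 0 && hi > 0) {
    dp_star <- uniroot(nmb_at, c(eps, dp_base), tol = 1e-10)$root
    status <- "crossover"
  } else {
    dp_star <- NA_real_
    status <- if (hi > 0) "dominant throughout" else "never cost-effective"
  }
  tab <- do.call(rbind, lapply(pmin(table_dp, dp_base), function(dp) {
    comp <- comp_at(dp)
    data.frame(dp = dp, delta_cost = comp$delta_cost,
               delta_lys = comp$delta_lys,
               icer_per_lys = icer_label(comp$icer_per_lys,
                                         comp$classification_lys),
               classification = comp$classification_lys,
               cost_effective = net_monetary_benefit(comp, threshold) > 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(dp_base = dp_base, dp_star = dp_star, status = status,
                 threshold = threshold, table = tab),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("<crossover_result> base IFI-risk reduction %.4f; %s\n",
              x$dp_base, x$status))
  if (!is.na(x$dp_star))
    cat(sprintf("  ICER = %.0f EUR/LYS at dp* = %.4f\n", x$threshold,
                x$dp_star))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @param thresholds Threshold grid passed to [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, thresholds = seq(0, 60000, by = 1000)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- ceac(psa, thresholds)
  ggplot2::ggplot(df, ggplot2::aes(x = threshold, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = psa$threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR per LYS)",
                  y = sprintf("P(%s cost-effective)", psa$intervention)) +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' One point per PSA draw (incremental LYS against incremental cost) with
#' the willingness-to-pay threshold line.
#'
#' @param psa A `psa_result`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(psa$draws,
                  ggplot2::aes(x = delta_lys, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_abline(slope = psa$threshold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(x = "Incremental life-years saved",
                  y = "Incremental cost (EUR)") +
    ggplot2::theme_minimal()
}
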