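# Synthetic two-arm prophylaxis trial: binomial count simulation, parameter
# estimation from counts, and parameter-recovery runs of the full pipeline.

#' Simulate two-arm prophylaxis trial counts
#'
#' Counts are generated hierarchically, matching the decision-tree topology:
#' `n_ifi ~ Binomial(n, p_ifi)`, then `n_death_ifi ~ Binomial(n_ifi,
#' p_death_ifi)` among IFI patients and `n_death_other ~ Binomial(n - n_ifi,
#' p_death_other)` among the rest.
#'
#' @param truth Named list (one element per arm) of clinical parameter lists
#'   with `p_ifi`, `p_death_ifi`, `p_death_other`.
#' @param n_per_arm Patients per arm (recycled across arms).
#' @param seed Optional integer seed.
#' @return A `trial_counts` data frame: `arm`, `n`, `n_ifi`, `n_death_ifi`,
#'   `n_death_other`.
#' @examples
#' truth <- list(
#'   posaconazole = list(p_ifi = 0.0458, p_death_ifi = 0.3571,
#'                       p_death_other = 0.158),
#'   sat = list(p_ifi = 0.11, p_death_ifi = 0.4848, p_death_other = 0.158))
#' simulate_trial(truth, n_per_arm = c(304, 298), seed = 1)
#' @export
simulate_trial <- function(truth, n_per_arm, seed = NULL) {
  stopifnot(length(truth) >= 1, all(n_per_arm > 0))
  if (!is.null(seed)) set.seed(seed)
  n_per_arm <- rep(as.integer(n_per_arm), length.out = length(truth))
  rows <- Map(function(arm, n) {
    p <- truth[[arm]]
    stopifnot(p$p_ifi >= 0, p$p_ifi <= 1, p$p_death_ifi >= 0,
              p$p_death_ifi <= 1, p$p_death_other >= 0, p$p_death_other <= 1)
    n_ifi <- rbinom(1L, n, p$p_ifi)
    data.frame(arm = arm, n = n, n_ifi = n_ifi,
               n_death_ifi = rbinom(1L, n_ifi, p$p_death_ifi),
               n_death_other = rbinom(1L, n - n_ifi, p$p_death_other),
               stringsAsFactors = FALSE)
  }, names(truth), n_per_arm)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_counts", "data.frame")
  out
}

# Proportion estimate with binomial standard error.  Zero (or full) count
# cells get a +1/2 continuity correction for the SE only, so the Beta
# moment-matching stays feasible; the point estimate remains k/n.
prop_est <- function(k, n) {
  if (n == 0) return(list(p = NA_real_, sd = NA_real_))
  p <- k / n
  p_se <- if (k == 0 || k == n) (k + 0.5) / (n + 1) else p
  list(p = p, sd = sqrt(p_se * (1 - p_se) / n))
}

#' Estimate clinical parameters from trial counts
#'
#' Point estimates are simple proportions; uncertainty is the binomial
#' standard error `sqrt(p(1-p)/n)`, emitted as a moment-matched Beta
#' distribution spec per probability (the published SD column was built the
#' same way).
#'
#' @param counts A `trial_counts` data frame from [simulate_trial()] (or
#'   observed counts in the same shape).
#' @return Named list (one element per arm), each with `clinical` (point
#'   estimates) and `specs` (per-probability list with `family`, `mean`,
#'   `sd`, and Beta `shape1`/`shape2` where feasible).
#' @examples
#' counts <- data.frame(arm = c("posaconazole", "sat"), n = c(304, 298),
#'                      n_ifi = c(14, 33), n_death_ifi = c(5, 16),
#'                      n_death_other = c(44, 51))
#' estimate_parameters(counts)$sat$clinical$p_ifi  # 33/298
#' @export
estimate_parameters <- function(counts) {
  stopifnot(all(c("arm", "n", "n_ifi", "n_death_ifi", "n_death_other")
                %in% names(counts)))
  out <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    if (row$n <= 0) stop("arm '", row$arm, "' has no patients")
    if (row$n_ifi > row$n || row$n_death_ifi > row$n_ifi ||
        row$n_death_other > row$n - row$n_ifi)
      stop("inconsistent counts for arm '", row$arm, "'")
    ests <- list(
      p_ifi = prop_est(row$n_ifi, row$n),
      p_death_ifi = prop_est(row$n_death_ifi, row$n_ifi),
      p_death_other = prop_est(row$n_death_other, row$n - row$n_ifi))
    specs <- lapply(ests, function(e) {
      spec <- list(family = "beta", mean = e$p, sd = e$sd)
      if (!is.na(e$p) && e$p > 0 && e$p < 1 && e$sd > 0 &&
          e$sd^2 < e$p * (1 - e$p)) {
        sh <- beta_from_moments(e$p, e$sd)
        spec$shape1 <- sh[["shape1"]]; spec$shape2 <- sh[["shape2"]]
      }
      spec
    })
    out[[row$arm]] <- list(clinical = lapply(ests, `[[`, "p"), specs = specs)
  }
  out
}

#' Parameter-recovery study of the full pipeline
#'
#' Per replicate: simulate trial counts at the true parameters, estimate the
#' clinical probabilities from the counts, substitute them into the cost
#' model (costs from `config`), and re-run the base-case comparison.
#' Reports per-replicate estimates and incremental cost together with the
#' truth-implied values and bias.  With `n_draws > 0` a PSA with the
#' estimated binomial uncertainties is run per replicate, giving
#' `p_cost_saving` and a 95% interval for the incremental cost (used for
#' coverage of the truth).
#'
#' @param truth Named list of per-arm clinical parameters (defaults to the
#'   effective base case of `config`); names must match the config's
#'   strategies.
#' @param n_per_arm Patients per arm.
#' @param n_replicates Number of simulated trials.
#' @param seed Optional integer seed (replicate streams derived from it).
#' @param config Cost/model configuration (default [base_case_config()]).
#' @param n_draws PSA draws per replicate (0 = skip the PSA).
#' @return A `recovery_report` list: `replicates` (data frame), `truth`
#'   (per-arm parameters and truth-implied `delta_cost`), `bias` (mean
#'   estimate minus truth per parameter and for `delta_cost`), and
#'   `coverage` (fraction of replicate PSA intervals covering the true
#'   `delta_cost`; `NA` when `n_draws = 0`).
#' @export
recover <- function(truth = NULL, n_per_arm = c(304, 298), n_replicates = 1,
                    seed = NULL, config = base_case_config(), n_draws = 0) {
  cfg0 <- if (isTRUE(config$effective)) config else effective_base_case(config)
  arms <- names(cfg0$strategies)
  if (is.null(truth))
    truth <- lapply(cfg0$strategies, function(s)
      s$clinical[c("p_ifi", "p_death_ifi", "p_death_other")])
  stopifnot(setequal(names(truth), arms))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  truth_cfg <- cfg0
  for (a in arms)
    truth_cfg$strategies[[a]]$clinical <-
      modifyList(truth_cfg$strategies[[a]]$clinical, truth[[a]])
  truth_bc <- run_base_case(truth_cfg, effective = FALSE)

  param_cols <- c("p_ifi", "p_death_ifi", "p_death_other")
  reps <- lapply(seq_len(n_replicates), function(i) {
    counts <- simulate_trial(truth, n_per_arm, seed = rep_seeds[i])
    est <- estimate_parameters(counts)
    cfg <- cfg0
    for (a in arms)
      cfg$strategies[[a]]$clinical <-
        modifyList(cfg$strategies[[a]]$clinical, est[[a]]$clinical)
    bc <- run_base_case(cfg, effective = FALSE)
    row <- data.frame(replicate = i, delta_cost = bc$comparison$delta_cost,
                      delta_ifis_avoided = bc$comparison$delta_ifis_avoided,
                      delta_lys = bc$comparison$delta_lys)
    for (a in arms) for (f in param_cols)
      row[[paste0(a, ".", f)]] <- est[[a]]$clinical[[f]]
    if (n_draws > 0) {
      for (a in arms) for (f in c("p_ifi", "p_death_ifi")) {
        path <- paste0(a, ".", f)
        if (!is.null(cfg$psa[[path]])) cfg$psa[[path]]$sd <- est[[a]]$specs[[f]]$sd
      }
      psa <- run_psa(cfg, n_draws = n_draws, fix = "p_death_other",
                     effective = FALSE)
      q <- stats::quantile(psa$draws$delta_cost, c(0.025, 0.975))
      row$p_cost_saving <- psa$p_cost_saving
      row$delta_cost_lo <- q[[1]]; row$delta_cost_hi <- q[[2]]
      row$covers_truth <- truth_bc$comparison$delta_cost >= q[[1]] &&
        truth_bc$comparison$delta_cost <= q[[2]]
    }
    row
  })
  reps <- do.call(rbind, reps)

  bias <- list(delta_cost = mean(reps$delta_cost) -
                 truth_bc$comparison$delta_cost)
  for (a in arms) for (f in param_cols)
    bias[[paste0(a, ".", f)]] <-
      mean(reps[[paste0(a, ".", f)]]) - truth[[a]][[f]]
  structure(list(
    replicates = reps,
    truth = list(params = truth,
                 delta_cost = truth_bc$comparison$delta_cost,
                 delta_ifis_avoided = truth_bc$comparison$delta_ifis_avoided),
    bias = bias,
    coverage = if (n_draws > 0) mean(reps$covers_truth) else NA_real_),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicate(s)\n", nrow(x$replicates)))
  cat(sprintf("  truth delta_cost %.2f EUR; mean estimate %.2f (bias %+.2f)\n",
              x$truth$delta_cost, x$truth$delta_cost + x$bias$delta_cost,
              x$bias$delta_cost))
  if (!is.na(x$coverage))
    cat(sprintf("  95%% interval coverage of truth: %.2f\n", x$coverage))
  invisible(x)
}
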