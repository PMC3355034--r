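# Parameter handling: effective base-case reconstruction from one-way
# sensitivity ranges, and method-of-moments fits for the PSA distributions.

#' Back-calculate an effective base-case value from a 75%/125% range
#'
#' One-way sensitivity ranges in the source tables are constructed as 75% and
#' 125% of the value actually used in the model, but the published base-case
#' column is rounded more coarsely than the range bounds.  The bounds
#' therefore pin down the underlying ("effective") value more precisely than
#' the printed base case: e.g. the posaconazole IFI probability is printed as
#' 0.05 but its range (0.0344, 0.0573) implies 0.0458.
#'
#' With `digits = NULL` the function returns the mean of `low/0.75` and
#' `high/1.25`.  With `digits` set, it additionally exploits that the printed
#' bounds are themselves rounded: it returns the shortest-decimal value `x`
#' consistent with both bounds, i.e. such that `0.75*x` and `1.25*x` round to
#' `low` and `high` at `digits` decimal places.  This recovers the value that
#' was actually entered in the original model.
#'
#' @param low,high Range bounds, `0 < low < high`.
#' @param digits Decimal places at which the bounds were printed, or `NULL`
#'   to skip the rounding-aware refinement.
#' @param label Optional parameter name used in warnings/errors.
#' @return The effective base-case value.
#' @examples
#' base_from_range(0.0825, 0.1375)              # 0.11
#' base_from_range(0.0344, 0.0573, digits = 4)  # 0.0458
#' @export
base_from_range <- function(low, high, digits = NULL, label = NULL) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low > 0 && high > low))
    stop("need 0 < low < high; got (", low, ", ", high, ")")
  a <- low / 0.75
  b <- high / 1.25
  rel <- abs(a - b) / ((a + b) / 2)
  what <- if (is.null(label)) "" else paste0(" for '", label, "'")
  if (rel > 0.10)
    stop("range (", low, ", ", high, ")", what, " is not consistent with a ",
         "75%/125% construction: back-calculations ", signif(a, 6), " and ",
         signif(b, 6), " disagree by ", round(100 * rel, 1), "%")
  if (!is.null(digits)) {
    h <- 0.5 * 10^(-digits)
    lo <- max((low - h) / 0.75, (high - h) / 1.25)
    hi <- min((low + h) / 0.75, (high + h) / 1.25)
    if (lo <= hi + 1e-12) {
      for (d in 0:digits) {
        step <- 10^(-d)
        cand <- round(ceiling((lo - 1e-12) / step) * step, d)
        if (cand <= hi + 1e-12) return(cand)
      }
    }
  }
  if (rel > 0.02)
    warning("back-calculated base values", what, " disagree by ",
            round(100 * rel, 2), "%; using their mean")
  (a + b) / 2
}

#' Substitute range-implied effective values for the printed base case
#'
#' The printed base-case probabilities are rounded to two decimals; the
#' deterministic ranges are exact 75%/125% multiples of the values actually
#' used.  Only the effective values reproduce the published cost cells
#' (0.11 x 67,984 = 7,478; 0.0458 x 67,984 = 3,114), so the model treats them
#' as the true base case.  The substitution is applied to the six acute-phase
#' clinical probabilities; costs and relative survival keep their printed
#' values (the cost ranges back-calculate to the printed values and the
#' relative-survival ranges are absolute bands, not 75/125 multiples).
#'
#' @param config An `azole_config` object.
#' @param digits Decimal precision of the printed range bounds (default 4).
#' @return The config with effective values substituted; the substitution
#'   report (columns `path`, `printed`, `effective`, `low`, `high`) is
#'   attached as attribute `"substitutions"` and via
#'   [substitution_report()].  Idempotent.
#' @export
effective_base_case <- function(config, digits = 4) {
  stopifnot(inherits(config, "azole_config"))
  prob_fields <- c("p_ifi", "p_death_ifi", "p_death_other")
  subs <- data.frame(path = character(), printed = numeric(),
                     effective = numeric(), low = numeric(), high = numeric(),
                     stringsAsFactors = FALSE)
  for (path in names(config$ranges)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (!parts[length(parts)] %in% prob_fields) next
    r <- config$ranges[[path]]
    eff <- base_from_range(r[1], r[2], digits = digits, label = path)
    printed <- get_param(config, path)
    config <- set_param(config, path, eff)
    subs <- rbind(subs, data.frame(path = path, printed = printed,
                                   effective = eff, low = r[1], high = r[2]))
  }
  attr(config, "substitutions") <- subs
  config$effective <- TRUE
  config
}

#' Report printed-versus-effective base-case substitutions
#'
#' @param config A config previously passed through [effective_base_case()].
#' @param file Optional path; if given the report is also written as CSV.
#' @return Data frame with columns `path`, `printed`, `effective`, `low`,
#'   `high` (the source range).
#' @export
substitution_report <- function(config, file = NULL) {
  subs <- attr(config, "substitutions")
  if (is.null(subs))
    stop("config has no substitution report; run effective_base_case() first")
  if (!is.null(file)) write.csv(subs, file, row.names = FALSE)
  subs
}

#' Method-of-moments Beta fit
#'
#' Returns the Beta shape parameters reproducing a requested mean and
#' standard deviation, used to turn the published (mean, SD) pairs into PSA
#' sampling distributions.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_from_moments(0.11, 0.0181)
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (!(mean > 0 && mean < 1))
    stop("Beta mean must lie in (0, 1); got ", mean)
  if (!(sd > 0))
    stop("Beta sd must be positive; got ", sd)
  if (sd^2 >= mean * (1 - mean))
    stop("sd^2 = ", signif(sd^2, 6), " >= mean*(1-mean) = ",
         signif(mean * (1 - mean), 6), ": overdispersed for a Beta")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Method-of-moments Gamma fit
#'
#' Returns shape/scale reproducing a requested mean and SD.  `sd = 0` rows
#' (as printed for the daily treatment costs and relative survival) are
#' degenerate: the fit is flagged `fixed` and sampling always returns the
#' mean.
#'
#' @param mean Mean, strictly positive.
#' @param sd Standard deviation, `>= 0`.
#' @return List with elements `fixed` (logical), `value` (the mean), and for
#'   `sd > 0` also `shape` and `scale`.
#' @examples
#' gamma_from_moments(67984, 16996)   # shape 16, scale 4249
#' gamma_from_moments(103.69, 0)      # degenerate (fixed)
#' @export
gamma_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (!(mean > 0)) stop("Gamma mean must be positive; got ", mean)
  if (sd < 0) stop("sd must be non-negative; got ", sd)
  if (sd == 0) return(list(fixed = TRUE, value = mean))
  list(fixed = FALSE, value = mean, shape = mean^2 / sd^2, scale = sd^2 / mean)
}

# One violation record; used by validate_config().
violation <- function(path, rule, observed) {
  data.frame(path = path, rule = rule, observed = as.character(observed),
             stringsAsFactors = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration -- probabilities in
#' \[0, 1\], non-negative costs, mixture weights summing to 1, exactly two
#' strategies, feasible PSA distribution moments, resolvable PSA parameter
#' paths -- and returns the violations as data rather than raising.
#'
#' @param config An `azole_config` (or a plain list with the same structure).
#' @return Data frame with columns `path`, `rule`, `observed`; zero rows if
#'   the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- violation(...)
  strat <- config$strategies
  if (length(strat) != 2L)
    add("strategies", "exactly two strategies required", length(strat))
  sh <- config$shared
  for (s in names(strat)) {
    cl <- strat[[s]]$clinical
    for (f in c("p_ifi", "p_death_ifi", "p_death_other")) {
      p <- cl[[f]]
      if (is.null(p)) { add(paste0(s, ".", f), "missing", "NULL"); next }
      if (p < 0 || p > 1) add(paste0(s, ".", f), "probability in [0,1]", p)
    }
    md <- cl$mean_days_to_ifi
    if (is.null(md) || md < 0 || md > (sh$acute_days %||% 100))
      add(paste0(s, ".mean_days_to_ifi"), "in [0, acute_days]", md %||% "NULL")
    comps <- strat[[s]]$components
    if (length(comps) < 1L) {
      add(paste0(s, ".components"), "at least one component", 0)
    } else {
      w <- vapply(comps, function(k) k$weight %||% NA_real_, numeric(1))
      if (abs(sum(w) - 1) > 1e-8)
        add(paste0(s, ".components"), "mixture weights sum to 1", sum(w))
      for (k in comps) {
        for (f in c("drug_cost_per_day", "prep_admin_monitor_cost_per_day",
                    "duration_days"))
          if ((k[[f]] %||% -1) < 0)
            add(paste0(s, ".", k$name, ".", f), "non-negative", k[[f]] %||% "NULL")
      }
    }
  }
  if ((sh$c_ifi %||% 0) <= 0) add("c_ifi", "positive", sh$c_ifi %||% "NULL")
  for (f in c("rs_aml", "rs_mds")) {
    r <- sh[[f]]
    if (is.null(r) || r <= 0 || r > 1) add(f, "in (0,1]", r %||% "NULL")
  }
  af <- sh$aml_fraction
  if (is.null(af) || af < 0 || af > 1) add("aml_fraction", "in [0,1]", af %||% "NULL")
  dr <- sh$discount_rate
  if (is.null(dr) || dr < 0 || dr >= 1) add("discount_rate", "in [0,1)", dr %||% "NULL")
  if ((sh$horizon_years %||% 0) <= 0)
    add("horizon_years", "positive", sh$horizon_years %||% "NULL")
  if ((sh$wtp_threshold %||% -1) < 0)
    add("wtp_threshold", "non-negative", sh$wtp_threshold %||% "NULL")
  # PSA specs must resolve and be moment-feasible
  for (path in names(config$psa)) {
    spec <- config$psa[[path]]
    m <- tryCatch(get_param(config, path), error = function(e) NULL)
    if (is.null(m)) { add(path, "psa path resolves to a parameter", "unresolved"); next }
    sd <- spec$sd %||% ((spec$cv %||% 0) * m)
    if (sd < 0) add(path, "psa sd non-negative", sd)
    fam <- spec$family %||% "fixed"
    if (!fam %in% c("beta", "gamma", "fixed"))
      add(path, "psa family in {beta, gamma, fixed}", fam)
    if (fam == "beta" && sd > 0) {
      if (!(m > 0 && m < 1)) add(path, "beta mean in (0,1)", m)
      else if (sd^2 >= m * (1 - m)) add(path, "beta sd^2 < mean*(1-mean)", sd)
    }
    if (fam == "gamma" && m <= 0) add(path, "gamma mean positive", m)
  }
  for (path in names(config$ranges)) {
    r <- config$ranges[[path]]
    if (length(r) != 2L || !(r[1] > 0 && r[2] > r[1]))
      add(path, "range is (low, high) with 0 < low < high", paste(r, collapse = ", "))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(path = character(), rule = character(), observed = character(),
               stringsAsFactors = FALSE)
}
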