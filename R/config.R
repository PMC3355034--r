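# Configuration loading and parameter-path resolution.
#
# A configuration is a single YAML (or JSON) file with five blocks:
# strategies, shared, ranges (the published 75%/125% one-way ranges, used to
# back-calculate the effective base case), dsa_scenarios (the one-way
# sensitivity grid) and psa (distribution specs).  The bundled
# `base_case.yaml` encodes the published tables verbatim (printed values).

known_keys <- list(
  top      = c("strategies", "shared", "ranges", "dsa_scenarios", "psa"),
  strategy = c("clinical", "components", "name"),
  clinical = c("p_ifi", "p_death_ifi", "p_death_other", "mean_days_to_ifi"),
  component = c("name", "drug_cost_per_day", "prep_admin_monitor_cost_per_day",
                "duration_days", "weight"),
  shared   = c("c_ifi", "rs_aml", "rs_mds", "aml_fraction", "rs_basis_years",
               "discount_rate", "wtp_threshold", "horizon_years", "acute_days",
               "background_monthly_hazard", "expose_ifi_survivors"),
  psa      = c("family", "sd", "cv")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration file, checks it for unknown keys,
#' fills shared-parameter defaults, and validates every structural invariant
#' (via [validate_config()]); all violations are reported at once.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return An `azole_config` object.
#' @seealso [base_case_config()] for the bundled published base case.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !length(raw))
    stop("config file is empty or not parseable: ", path)
  check_keys(raw, known_keys$top, path)
  if (is.null(raw$strategies) || is.null(raw$shared))
    stop("config must contain 'strategies' and 'shared' blocks: ", path)
  for (s in names(raw$strategies)) {
    check_keys(raw$strategies[[s]], known_keys$strategy, paste0("strategies$", s))
    check_keys(raw$strategies[[s]]$clinical, known_keys$clinical,
               paste0("strategies$", s, "$clinical"))
    for (k in seq_along(raw$strategies[[s]]$components))
      check_keys(raw$strategies[[s]]$components[[k]], known_keys$component,
                 paste0("strategies$", s, "$components[[", k, "]]"))
    raw$strategies[[s]]$name <- s
  }
  check_keys(raw$shared, known_keys$shared, "shared")
  for (p in names(raw$psa))
    check_keys(raw$psa[[p]], known_keys$psa, paste0("psa$", p))
  defaults <- list(rs_basis_years = 5, discount_rate = 0.03,
                   wtp_threshold = 30000, horizon_years = 50,
                   acute_days = 100, background_monthly_hazard = 0,
                   expose_ifi_survivors = FALSE)
  raw$shared <- modifyList(defaults, raw$shared)
  raw$ranges <- lapply(raw$ranges, as.numeric)
  raw$dsa_scenarios <- lapply(raw$dsa_scenarios, as.numeric)
  config <- structure(raw[known_keys$top[known_keys$top %in% names(raw)]],
                      class = "azole_config")
  config$effective <- FALSE
  v <- validate_config(config)
  if (nrow(v))
    stop("invalid configuration (", path, "):\n",
         paste0("  - ", v$path, ": ", v$rule, " (observed ", v$observed, ")",
                collapse = "\n"), call. = FALSE)
  config
}

#' Bundled base-case configuration
#'
#' Loads the configuration shipped with the package, which encodes the
#' published clinical probabilities, unit costs, treatment durations, SAT
#' mixture weights, one-way sensitivity ranges and PSA distribution specs
#' (EUR at November-2009 price level).
#'
#' @return An `azole_config` object (printed values; pass through
#'   [effective_base_case()] to substitute the range-implied values).
#' @export
base_case_config <- function() {
  load_config(system.file("extdata", "base_case.yaml", package = "azolecea",
                          mustWork = TRUE))
}

# Parameter paths -------------------------------------------------------
#
# "<strategy>.<clinical field>"  e.g. "posaconazole.p_ifi"
# "p_death_other"                the shared non-IFI death probability
# "cost_per_day.<component>"     total daily cost of one drug
# shared scalars by name         "c_ifi", "rs_aml", "discount_rate", ...

find_component <- function(config, comp) {
  for (s in names(config$strategies)) {
    comps <- config$strategies[[s]]$components
    for (k in seq_along(comps))
      if (comps[[k]]$name == comp) return(c(strategy = s, index = k))
  }
  NULL
}

#' Read a model parameter by path
#'
#' @param config An `azole_config`.
#' @param path Parameter path, e.g. `"posaconazole.p_ifi"`, `"c_ifi"`,
#'   `"cost_per_day.fluconazole"`, or `"p_death_other"` (shared across arms).
#' @return The parameter value.
#' @export
get_param <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (path == "p_death_other") {
    vals <- vapply(config$strategies,
                   function(s) s$clinical$p_death_other, numeric(1))
    if (diff(range(vals)) > 1e-12)
      stop("'p_death_other' differs between arms; use a per-arm path")
    return(vals[[1]])
  }
  if (parts[1] == "cost_per_day") {
    loc <- find_component(config, parts[2])
    if (is.null(loc)) stop("unknown drug component: ", parts[2])
    k <- config$strategies[[loc["strategy"]]]$components[[as.integer(loc["index"])]]
    return(k$drug_cost_per_day + k$prep_admin_monitor_cost_per_day)
  }
  if (parts[1] %in% names(config$strategies)) {
    val <- config$strategies[[parts[1]]]$clinical[[parts[2]]]
    if (is.null(val)) stop("unknown clinical field: ", path)
    return(val)
  }
  if (parts[1] %in% names(config$shared)) return(config$shared[[parts[1]]])
  stop("unknown parameter path: ", path)
}

#' Set a model parameter by path
#'
#' Setting `"cost_per_day.<drug>"` rescales the drug and
#' preparation/administration components proportionally so their sum equals
#' the new total.  Setting `"p_death_other"` updates both arms.
#'
#' @inheritParams get_param
#' @param value New value.
#' @return The modified config.
#' @export
set_param <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (path == "p_death_other") {
    for (s in names(config$strategies))
      config$strategies[[s]]$clinical$p_death_other <- value
    return(config)
  }
  if (parts[1] == "cost_per_day") {
    loc <- find_component(config, parts[2])
    if (is.null(loc)) stop("unknown drug component: ", parts[2])
    s <- loc["strategy"]; k <- as.integer(loc["index"])
    comp <- config$strategies[[s]]$components[[k]]
    tot <- comp$drug_cost_per_day + comp$prep_admin_monitor_cost_per_day
    f <- value / tot
    comp$drug_cost_per_day <- comp$drug_cost_per_day * f
    comp$prep_admin_monitor_cost_per_day <-
      comp$prep_admin_monitor_cost_per_day * f
    config$strategies[[s]]$components[[k]] <- comp
    return(config)
  }
  if (parts[1] %in% names(config$strategies)) {
    if (!parts[2] %in% known_keys$clinical)
      stop("unknown clinical field: ", path)
    config$strategies[[parts[1]]]$clinical[[parts[2]]] <- value
    return(config)
  }
  if (parts[1] %in% known_keys$shared) {
    config$shared[[parts[1]]] <- value
    return(config)
  }
  stop("unknown parameter path: ", path)
}

#' @export
print.azole_config <- function(x, ...) {
  cat("<azole_config> ", if (isTRUE(x$effective)) "(effective base case)"
      else "(printed base case)", "\n", sep = "")
  for (s in names(x$strategies)) {
    cl <- x$strategies[[s]]$clinical
    comps <- vapply(x$strategies[[s]]$components, function(k)
      sprintf("%s %.0f%% x %dd x %.2f EUR/d", k$name, 100 * k$weight,
              as.integer(k$duration_days),
              k$drug_cost_per_day + k$prep_admin_monitor_cost_per_day),
      character(1))
    cat(sprintf("  %-14s p_ifi=%.4f p_death_ifi=%.4f p_death_other=%.4f | %s\n",
                s, cl$p_ifi, cl$p_death_ifi, cl$p_death_other,
                paste(comps, collapse = " + ")))
  }
  sh <- x$shared
  cat(sprintf("  shared: c_ifi=%.0f EUR, rs_aml=%.2f, rs_mds=%.2f (basis %gy), aml_fraction=%.2f\n",
              sh$c_ifi, sh$rs_aml, sh$rs_mds, sh$rs_basis_years, sh$aml_fraction))
  cat(sprintf("  discount=%.0f%%/y after year 1, WTP=%.0f EUR/LYS, horizon=%gy\n",
              100 * sh$discount_rate, sh$wtp_threshold, sh$horizon_years))
  invisible(x)
}
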