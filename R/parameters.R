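# Parameter housing: load, validate and export the model inputs.

.param_roles <- c("probability", "cost_per_month", "cost_per_visit",
                  "cost_per_unit", "utility", "hazard_ratio",
                  "visits_per_month", "rate")
.param_families <- c("beta", "gamma", "lognormal", "fixed")

# every name the strategies and reward builders resolve; completeness is
# validated against this list
.required_params <- c(
  "p_rec_yr1", "p_rec_yr3", "p_rec_yr5",
  "p_death_gist_yr1", "p_death_gist_yr3", "p_death_gist_yr5",
  "p_death_gist_yr7", "p_death_gist_yr9",
  "hr_adjuvant_1yr", "hr_adjuvant_3yr",
  "p_prog_imatinib", "p_prog_sunitinib",
  "p_death_imatinib", "p_death_sunitinib", "p_death_bsc",
  "p_disc_1yr_m1_6", "p_disc_1yr_m7_12", "p_disc_3yr_m1_6", "p_disc_3yr_m7_36",
  "imatinib_tablet_price", "sunitinib_capsule_price",
  "cost_drug_imatinib_month", "cost_drug_sunitinib_month",
  "cost_norec_noadj", "cost_norec_adj",
  "cost_rec_imatinib", "cost_rec_sunitinib", "cost_rec_bsc",
  "cost_ae_adjuvant",
  "cost_travel_visit", "cost_food_visit", "cost_caregiver_visit",
  "visits_norec_noadj", "visits_norec_adj", "visits_rec",
  "u_norec_noadj", "u_norec_adj", "u_rec_imatinib", "u_rec_sunitinib",
  "u_rec_bsc"
)

#' Path to the shipped default parameter file
#'
#' Returns the YAML file carrying every model input (mean, SE, distribution
#' family, role, time band) together with the model scalars (discount rate,
#' start age, willingness-to-pay threshold, horizon).
#'
#' @return Path to the installed `parameters.yaml`.
#' @export
default_parameter_file <- function() {
  path <- system.file("extdata", "parameters.yaml", package = "gistcea")
  if (!nzchar(path)) stop("shipped parameters.yaml not found")
  path
}

.validate_spec_row <- function(name, mean, se, family, role) {
  errs <- character()
  bad <- function(msg) sprintf("parameter '%s': %s", name, msg)
  if (!family %in% .param_families) {
    return(bad(paste0("unknown family '", family, "'")))
  }
  if (!role %in% .param_roles) {
    return(bad(paste0("unknown role '", role, "'")))
  }
  if (!is.finite(mean) || !is.finite(se) || se < 0) {
    return(bad("mean must be finite and se finite and >= 0"))
  }
  if (role %in% c("probability", "utility") && (mean < 0 || mean > 1)) {
    errs <- c(errs, bad(sprintf("role %s requires mean in [0, 1], got %g", role, mean)))
  }
  if (grepl("^cost_", role) && mean < 0) {
    errs <- c(errs, bad(sprintf("role %s requires mean >= 0, got %g", role, mean)))
  }
  if (role == "visits_per_month" && mean < 0) {
    errs <- c(errs, bad(sprintf("visits per month must be >= 0, got %g", mean)))
  }
  if (role == "hazard_ratio" && mean <= 0) {
    errs <- c(errs, bad(sprintf("hazard ratio must be > 0, got %g", mean)))
  }
  if (family == "beta" && !role %in% c("probability", "utility")) {
    errs <- c(errs, bad(paste0("family beta only valid for probability/utility, not ", role)))
  }
  if (family == "gamma" &&
      !role %in% c("cost_per_month", "cost_per_visit", "cost_per_unit", "visits_per_month")) {
    errs <- c(errs, bad(paste0("family gamma only valid for costs/visits, not ", role)))
  }
  if (family == "lognormal" && role != "hazard_ratio") {
    errs <- c(errs, bad(paste0("family lognormal only valid for hazard ratios, not ", role)))
  }
  errs
}

#' Load and validate the model parameter set
#'
#' Reads a YAML parameter file (see [default_parameter_file()] for the
#' schema), validates every entry against its role's range and family
#' constraints, checks completeness against the names the model resolves,
#' and returns a validated parameter set. All violations are reported
#' together, each naming the offending parameter.
#'
#' @param path Parameter file; defaults to the shipped configuration.
#' @param cost_parse Which parse of the ambiguous recurrence monitoring cost
#'   cells to use: `"large"` (shipped default) or `"small"`; the candidate
#'   values are documented in the parameter file itself.
#' @return An object of class `gist_params`: list with `specs` (data frame
#'   of name/mean/se/family/role/band), `values` (named vector of point
#'   values), and `scalars` (discount rate, start age, WTP, horizon,
#'   background-mortality switch).
#' @export
load_parameters <- function(path = default_parameter_file(),
                            cost_parse = c("large", "small")) {
  cost_parse <- match.arg(cost_parse)
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) stop("parameter file has no 'parameters' block: ", path)

  if (cost_parse == "small") {
    alt <- raw$alternative_parses$small
    if (is.null(alt)) stop("parameter file has no alternative_parses$small block")
    for (nm in names(alt)) {
      raw$parameters[[nm]]$mean <- alt[[nm]]$mean
      raw$parameters[[nm]]$se <- alt[[nm]]$se
    }
  }

  specs <- do.call(rbind, lapply(names(raw$parameters), function(nm) {
    p <- raw$parameters[[nm]]
    data.frame(name = nm,
               mean = as.numeric(p$mean %||% NA_real_),
               se = as.numeric(p$se %||% NA_real_),
               family = as.character(p$family %||% NA_character_),
               role = as.character(p$role %||% NA_character_),
               band = as.character(p$band %||% NA_character_),
               stringsAsFactors = FALSE)
  }))

  errs <- character()
  missing <- setdiff(.required_params, specs$name)
  if (length(missing)) {
    errs <- c(errs, paste0("missing required parameter '", missing, "'"))
  }
  for (i in seq_len(nrow(specs))) {
    errs <- c(errs, .validate_spec_row(specs$name[i], specs$mean[i], specs$se[i],
                                       specs$family[i], specs$role[i]))
  }

  defaults <- list(annual_discount_rate = 0.03, start_age = 60,
                   cycle_length_months = 1, wtp = 160000,
                   horizon_cycles = 480, include_background_mortality = TRUE)
  scalars <- utils::modifyList(defaults, raw$scalars %||% list())
  if (scalars$annual_discount_rate < 0) errs <- c(errs, "annual_discount_rate must be >= 0")
  if (scalars$start_age < 0) errs <- c(errs, "start_age must be >= 0")
  if (scalars$horizon_cycles < 1) errs <- c(errs, "horizon_cycles must be >= 1")

  if (length(errs)) {
    stop("parameter validation failed:\n  ", paste(errs, collapse = "\n  "))
  }

  values <- stats::setNames(specs$mean, specs$name)
  structure(list(specs = specs, values = values, scalars = scalars),
            class = "gist_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gist_params <- function(x, ...) {
  cat("GIST cost-utility model parameters:", nrow(x$specs), "inputs\n")
  cat(sprintf("  discount %.1f%%/yr, start age %g y, WTP %s THB/QALY, horizon %d cycles\n",
              100 * x$scalars$annual_discount_rate, x$scalars$start_age,
              format(x$scalars$wtp, big.mark = ","), x$scalars$horizon_cycles))
  invisible(x)
}

#' Point value of a named parameter
#'
#' @param params A `gist_params` object.
#' @param name Parameter name.
#' @return The point value.
#' @export
param_value <- function(params, name) {
  if (!name %in% names(params$values)) stop("unknown parameter '", name, "'")
  unname(params$values[[name]])
}

#' Replace point values of parameters
#'
#' Returns a copy of the parameter set with the named point values replaced
#' (means in `specs` are left untouched; only the resolved values change).
#' Used by the sensitivity analyses.
#'
#' @param params A `gist_params` object.
#' @param replacements Named numeric vector or list of new point values.
#' @return Modified `gist_params`.
#' @export
set_param_values <- function(params, replacements) {
  repl <- unlist(replacements)
  unknown <- setdiff(names(repl), names(params$values))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params$values[names(repl)] <- repl
  params
}

#' Export the resolved parameter set as CSV for audit
#'
#' @param params A `gist_params` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_parameters <- function(params, path) {
  out <- params$specs
  out$value <- unname(params$values[out$name])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
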