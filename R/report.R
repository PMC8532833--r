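#' Read a study configuration file
#'
#' Reads a JSON or YAML experiment configuration of the form
#' ```
#' drugs:
#'   - {name: meropenem, cmax_mg_L: 120, half_life_h: 1.0, dosing_interval_h: 8}
#' hardware: {v_central_mL: 180, flow_mL_min: 0.7, infusion_min: 30}
#' ```
#' and returns validated target and hardware objects.  Schema violations
#' are reported with the path of the offending field.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with `targets` (list of [drug_target()]) and `hardware`
#'   (a [hardware_config()] with one line per drug).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  parse_study_config(cfg)
}

#' @rdname read_study_config
#' @param cfg A configuration list already parsed from JSON/YAML.
#' @export
parse_study_config <- function(cfg) {
  need_field <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop(sprintf("config error at %s: missing required field '%s'",
                   where, field), call. = FALSE)
    x[[field]]
  }
  if (is.null(cfg$drugs) || length(cfg$drugs) == 0L)
    stop("config error at $drugs: at least one drug is required",
         call. = FALSE)
  hw <- need_field(cfg, "hardware", "$")
  targets <- lapply(seq_along(cfg$drugs), function(i) {
    d <- cfg$drugs[[i]]
    where <- sprintf("$drugs[%d]", i)
    drug_target(
      name = as.character(need_field(d, "name", where)),
      cmax = as.numeric(need_field(d, "cmax_mg_L", where)),
      half_life = as.numeric(need_field(d, "half_life_h", where)),
      dosing_interval = as.numeric(need_field(d, "dosing_interval_h", where)),
      doses_per_24h = if (!is.null(d$doses_per_24h))
        as.integer(d$doses_per_24h) else NULL)
  })
  hardware <- hardware_config(
    v_central = as.numeric(need_field(hw, "v_central_mL", "$hardware")),
    flow_ml_min = as.numeric(need_field(hw, "flow_mL_min", "$hardware")),
    n_lines = length(targets),
    infusion_duration = as.numeric(need_field(hw, "infusion_min",
                                              "$hardware")) / 60)
  list(targets = targets, hardware = hardware)
}

#' Design sheet as a plain list (for JSON emission)
#'
#' @param design A [design_parallel()] result.
#' @return A list mirroring the printed design table: hardware, system
#'   turnover, and one record per drug with reservoir volume, doses and
#'   initial supplemental concentration.
#' @export
design_sheet <- function(design) {
  stopifnot(inherits(design, "parallel_design"))
  hw <- design$hardware
  list(
    hardware = list(v_central_mL = hw$v_central,
                    flow_mL_min = hw$flow_ml_min,
                    flow_mL_h = hw$flow_ml_h,
                    n_lines = hw$n_lines,
                    infusion_h = hw$infusion_duration),
    k_total_per_h = design$k_total,
    drugs = lapply(seq_len(nrow(design$lines)), function(i) {
      ln <- design$lines[i, ]
      list(drug = ln$drug, cmax_mg_L = ln$cmax, half_life_h = ln$half_life,
           k_per_h = ln$k, v_supp_mL = ln$v_supp,
           central_dose_ug = ln$central_dose,
           supp_dose_ug = ln$supp_dose,
           supp_conc_init_mg_L = ln$supp_conc_init,
           auc24_target_mg_h_L = ln$doses_per_24h * ln$cmax / ln$k)
    }))
}

#' Validate observed concentration data against a study design
#'
#' The full validation pipeline on observed (or synthetic) data: per-drug
#' one-compartment fits pooled across days, per-day fits for the half-life
#' confidence envelope, AUC24 by integrating each best fit, the
#' within-tolerance acceptance verdicts against the targets, and the
#' target-versus-observed quality-control regression across all records.
#'
#' @param targets List of [drug_target()]s.
#' @param hardware A [hardware_config()].
#' @param observations Observation data frame with columns `drug`,
#'   `time_h` (or `time`), `conc_mg_L` (or `conc`), `replicate`, `day`.
#' @param lloq Lower limit of quantification, mg/L (default 1).
#' @param weighting Passed to [fit_one_compartment()].
#' @param tolerance Acceptance tolerance on Cmax and half-life ratios
#'   (default 0.20).
#' @param ci_level Confidence level for the half-life envelope (default
#'   0.80).
#' @param seed Optional integer recorded in the report metadata.
#' @return An object of class `validation_report`.
#' @export
validate_study <- function(targets, hardware, observations, lloq = 1,
                           weighting = "proportional", tolerance = 0.20,
                           ci_level = 0.80, seed = NULL) {
  targets <- check_target_list(targets)
  design <- design_parallel(targets, hardware)
  schedule <- build_schedule(design, horizon = 24)
  obs <- normalise_observations(observations)
  if (is.null(obs$drug)) stop("observations must have a 'drug' column",
                              call. = FALSE)
  if (is.null(obs$day)) obs$day <- 1L
  unknown <- setdiff(unique(obs$drug), design$lines$drug)
  if (length(unknown))
    stop("observations contain drugs absent from the config: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  sample_times <- sort(unique(obs$time))
  pre_dose <- pre_dose_flags(sample_times, schedule)
  intended <- simulate_closed_form(design, schedule, times = sample_times,
                                   pre_dose = pre_dose)

  per_drug <- lapply(targets, function(tg) {
    d_obs <- obs[obs$drug == tg$name, , drop = FALSE]
    if (nrow(d_obs) == 0L)
      stop("no observations for drug ", tg$name, call. = FALSE)
    fit <- fit_one_compartment(d_obs, schedule, weighting = weighting,
                               lloq = lloq, drug = tg$name)
    day_fits <- lapply(split(d_obs, d_obs$day), function(dd)
      tryCatch(fit_one_compartment(dd, schedule, weighting = weighting,
                                   lloq = lloq, drug = tg$name),
               error = function(e) NULL))
    day_fits <- Filter(Negate(is.null), day_fits)
    ci <- tryCatch(halflife_confidence_interval(day_fits, level = ci_level),
                   error = function(e) NULL)
    verdict <- acceptance_check(fit, tg, tolerance = tolerance)
    list(target = tg, fit = fit, day_fits = day_fits, halflife_ci = ci,
         verdict = verdict)
  })
  names(per_drug) <- vapply(targets, `[[`, character(1), "name")

  truth_at <- function(drug, time) {
    p <- intended[[drug]]
    p$c_central[match(time, p$times)]
  }
  obs$target_conc <- mapply(truth_at, obs$drug, obs$time)
  qc_pairs <- obs[obs$target_conc >= lloq & obs$conc >= lloq, , drop = FALSE]
  regression <- if (nrow(qc_pairs) >= 3L)
    target_vs_observed_regression(qc_pairs$target_conc, qc_pairs$conc)
  else NULL

  structure(
    list(design = design, sheet = design_sheet(design), drugs = per_drug,
         regression = regression,
         meta = list(seed = seed, n_obs = nrow(obs), lloq = lloq,
                     weighting = weighting, tolerance = tolerance,
                     ci_level = ci_level,
                     package_version = as.character(
                       utils::packageVersion("hfimdesign")))),
    class = "validation_report")
}

# internal: flag sampling times that coincide with a dose start (troughs
# drawn just before the dose)
pre_dose_flags <- function(times, schedule) {
  starts <- unique(schedule$start[schedule$start > 0])
  vapply(times, function(t) any(abs(t - starts) < 1e-9), logical(1))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (d in x$drugs) {
    f <- d$fit
    ci_txt <- if (!is.null(d$halflife_ci))
      sprintf(", %g%% CI %.3g-%.3g h", 100 * d$halflife_ci$level,
              d$halflife_ci$lower, d$halflife_ci$upper) else ""
    cat(sprintf(
      "  %-12s t1/2 %.3g h (target %.3g)%s; Cmax %.4g mg/L (target %g); AUC24 %.5g; r2 %.3f -> %s\n",
      d$target$name, f$half_life_est, d$target$half_life, ci_txt,
      f$cmax_est, d$target$cmax, f$auc24, f$r2,
      if (d$verdict$pass) "PASS" else "FAIL"))
  }
  if (!is.null(x$regression))
    cat(sprintf(
      "  QC: observed = %.3f x target + %.3f (r2 %.3f); obs/target %0.f-%0.f%% (median %0.f%%)\n",
      x$regression$slope, x$regression$intercept, x$regression$r2,
      x$regression$ratio_pct$min, x$regression$ratio_pct$max,
      x$regression$ratio_pct$median))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' Lossless, stable serialisation of the report's numeric content (design
#' sheet, per-drug estimates, verdicts, regression, metadata).
#'
#' @param report A [validate_study()] result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  body <- list(
    design = report$sheet,
    drugs = lapply(report$drugs, function(d) {
      f <- d$fit
      list(drug = d$target$name,
           k_per_h = f$k_est, se_k = f$se_k, v_mL = f$v_est,
           half_life_h = f$half_life_est, cmax_mg_L = f$cmax_est,
           auc24_mg_h_L = f$auc24, r2 = f$r2, n_obs = f$n_obs,
           converged = f$converged,
           halflife_ci = if (!is.null(d$halflife_ci))
             list(level = d$halflife_ci$level, lower = d$halflife_ci$lower,
                  upper = d$halflife_ci$upper) else NULL,
           verdict = list(cmax_ratio = d$verdict$cmax_ratio,
                          halflife_ratio = d$verdict$halflife_ratio,
                          pass = d$verdict$pass,
                          tolerance = d$verdict$tolerance))
    }),
    regression = report$regression,
    meta = report$meta)
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Write observations or profiles in the tidy CSV dialect
#'
#' Observations: `drug, time_h, conc_mg_L, replicate, day, below_lloq`.
#' Profiles: `drug, compartment, time_h, conc_mg_L`.
#' Schedules: `drug, compartment, start_h, duration_h, amount_ug`.
#'
#' @param x An `hfim_observations`, `simulated_profiles` or
#'   `dose_schedule` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hfim_csv <- function(x, path) {
  df <- if (inherits(x, "simulated_profiles")) as.data.frame(x)
  else if (inherits(x, "dose_schedule")) {
    data.frame(drug = x$drug, compartment = x$compartment,
               start_h = x$start, duration_h = x$duration,
               amount_ug = x$amount)
  } else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read observations from the tidy CSV dialect
#'
#' @param path CSV with columns `drug`, `time_h`, `conc_mg_L` and
#'   optionally `replicate`, `day`, `below_lloq`.
#' @return A data frame of observations.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "time_h", "conc_mg_L")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("observation CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(num(df$time_h)) | !is.finite(num(df$conc_mg_L)))
  df$time_h <- num(df$time_h)
  df$conc_mg_L <- num(df$conc_mg_L)
  if (length(bad))
    stop(sprintf("observation CSV has non-numeric records (first at line %d)",
                 bad[1L] + 1L), call. = FALSE)
  df
}
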