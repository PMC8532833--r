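#' Per-drug pharmacokinetic target
#'
#' Describes the concentration-time profile one antibiotic should follow in
#' the central compartment: the unbound peak concentration, the elimination
#' half-life, and how often it is dosed.
#'
#' @param name Drug label (e.g. `"meropenem"`).
#' @param cmax Target unbound maximum concentration, mg/L. Must be positive.
#' @param half_life Target elimination half-life, h. Must be positive.
#' @param dosing_interval Dosing interval tau, h. Must be positive.
#' @param doses_per_24h Number of doses per 24 h. Defaults to
#'   `floor(24 / dosing_interval)`; stored explicitly so irregular regimens
#'   (e.g. a single dose with a nominal 8 h interval) can be expressed.
#' @param auc24_target Optional target daily exposure, mg·h/L. When `NULL`
#'   it can be computed with [target_auc24()].
#' @return An object of class `drug_target`.
#' @seealso [design_parallel()], [target_auc24()]
#' @examples
#' drug_target("meropenem", cmax = 120, half_life = 1, dosing_interval = 8)
#' @export
drug_target <- function(name, cmax, half_life, dosing_interval,
                        doses_per_24h = NULL, auc24_target = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(cmax) || length(cmax) != 1L || !is.finite(cmax) || cmax <= 0)
    stop("'cmax' must be a single positive number (mg/L)", call. = FALSE)
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("'half_life' must be a single positive number (h)", call. = FALSE)
  if (!is.numeric(dosing_interval) || length(dosing_interval) != 1L ||
      !is.finite(dosing_interval) || dosing_interval <= 0)
    stop("'dosing_interval' must be a single positive number (h)", call. = FALSE)
  if (is.null(doses_per_24h)) doses_per_24h <- max(1L, floor(24 / dosing_interval))
  doses_per_24h <- as.integer(doses_per_24h)
  if (doses_per_24h < 1L)
    stop("'doses_per_24h' must be at least 1", call. = FALSE)
  structure(
    list(name = name, cmax = cmax, half_life = half_life,
         dosing_interval = dosing_interval, doses_per_24h = doses_per_24h,
         auc24_target = auc24_target),
    class = "drug_target")
}

#' @export
print.drug_target <- function(x, ...) {
  cat(sprintf("<drug_target> %s: Cmax %g mg/L, t1/2 %g h, q%gh x %d/day\n",
              x$name, x$cmax, x$half_life, x$dosing_interval, x$doses_per_24h))
  invisible(x)
}

#' Hollow-fiber system hardware configuration
#'
#' The shared hardware of a parallel-design HFIM run: one central vessel
#' (stirred flask plus tubing and the hollow-fiber cartridge, lumped) fed by
#' `n_lines` diluent lines at a common flow rate.  The system is
#' iso-volumetric: total inflow equals outflow, so the central volume is
#' constant and drugs are washed out at the total turnover rate.
#'
#' @param v_central Central compartment volume, mL.
#' @param flow_ml_min Flow per diluent line, mL/min (as pump settings are
#'   usually quoted); converted once to mL/h internally, since half-lives
#'   and rate constants are per hour.
#' @param n_lines Number of parallel diluent lines (one per drug).
#' @param infusion_duration Duration of each drug infusion, h (0 = bolus).
#' @return An object of class `hardware_config` with the per-line flow
#'   stored in mL/h as `flow_ml_h`.
#' @examples
#' hardware_config(v_central = 180, flow_ml_min = 0.7, n_lines = 3)
#' @export
hardware_config <- function(v_central, flow_ml_min, n_lines,
                            infusion_duration = 0.5) {
  if (!is.numeric(v_central) || length(v_central) != 1L || v_central <= 0)
    stop("'v_central' must be a single positive volume (mL)", call. = FALSE)
  if (!is.numeric(flow_ml_min) || length(flow_ml_min) != 1L || flow_ml_min <= 0)
    stop("'flow_ml_min' must be a single positive flow (mL/min)", call. = FALSE)
  n_lines <- as.integer(n_lines)
  if (is.na(n_lines) || n_lines < 1L)
    stop("'n_lines' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(infusion_duration) || length(infusion_duration) != 1L ||
      infusion_duration < 0)
    stop("'infusion_duration' must be a non-negative duration (h)", call. = FALSE)
  structure(
    list(v_central = v_central, flow_ml_min = flow_ml_min,
         flow_ml_h = flow_ml_min * 60, n_lines = n_lines,
         infusion_duration = infusion_duration),
    class = "hardware_config")
}

#' @export
print.hardware_config <- function(x, ...) {
  cat(sprintf(
    "<hardware_config> Vc %g mL, %d line(s) x %g mL/min (%g mL/h), Tinf %g h\n",
    x$v_central, x$n_lines, x$flow_ml_min, x$flow_ml_h, x$infusion_duration))
  invisible(x)
}

#' First-order elimination rate constant from half-life
#'
#' @param half_life Half-life, h (positive; vectorised).
#' @return Rate constant k = ln(2) / half_life, per h.
#' @examples
#' elimination_rate(8) # ceftriaxone-like, 0.0866 /h
#' @export
elimination_rate <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) || any(half_life <= 0))
    stop("'half_life' must be positive and finite (h)", call. = FALSE)
  log(2) / half_life
}

#' Total turnover rate of the central compartment
#'
#' All diluent lines discharge into the central vessel, so every drug is
#' diluted at the same total rate regardless of which supplemental tank it
#' occupies.
#'
#' @param hardware A [hardware_config()].
#' @return k_total = n_lines x flow / v_central, per h.
#' @examples
#' system_turnover(hardware_config(180, 0.7, 3)) # 0.7 /h
#' @export
system_turnover <- function(hardware) {
  stopifnot(inherits(hardware, "hardware_config"))
  hardware$n_lines * hardware$flow_ml_h / hardware$v_central
}

# relative tolerance for k_i vs k_total feasibility comparisons; equality
# within this band is treated as exact (supplemental dose 0)
.k_tol <- 1e-9

#' Compute the parallel-design setup and dosing plan
#'
#' Each drug is assigned its own supplemental tank on its own diluent line.
#' The tank volume is chosen so the tank's washout rate equals the drug's
#' target elimination rate (`v_supp = Q / k`), and the supplemental dose
#' puts the tank concentration at exactly the level that places the
#' two-compartment state (tank, central) on the slow eigenvector of the
#' dilution system.  The central concentration of each drug then declines
#' mono-exponentially at its own target rate even though the central vessel
#' itself turns over much faster.
#'
#' Central doses follow the bolus proportionality rule Cmax = dose / volume;
#' the realised peak under a 30-min infusion is somewhat lower, which the
#' simulator quantifies.
#'
#' @param targets List of [drug_target()] objects, one per drug.
#' @param hardware A [hardware_config()]; `n_lines` must equal the number
#'   of targets.
#' @return An object of class `parallel_design`: the hardware, the system
#'   turnover rate `k_total` (per h), and a data frame `lines` with one row
#'   per drug (columns `drug`, `cmax`, `half_life`, `dosing_interval`,
#'   `doses_per_24h`, `k` per h, `v_supp` mL, `central_dose` µg,
#'   `supp_dose` µg, `supp_conc_init` mg/L).
#' @examples
#' tg <- three_drug_targets()
#' hw <- hardware_config(180, 0.7, 3)
#' design_parallel(tg, hw)
#' @export
design_parallel <- function(targets, hardware) {
  stopifnot(inherits(hardware, "hardware_config"))
  targets <- check_target_list(targets)
  if (length(targets) != hardware$n_lines)
    stop(sprintf("design requires one line per drug: %d target(s) but %d line(s)",
                 length(targets), hardware$n_lines), call. = FALSE)
  q <- hardware$flow_ml_h
  vc <- hardware$v_central
  k_total <- system_turnover(hardware)
  k <- vapply(targets, function(t) elimination_rate(t$half_life), numeric(1))
  bad <- k > k_total * (1 + .k_tol)
  if (any(bad)) {
    i <- which(bad)[1L]
    min_flow <- k[i] * vc / (hardware$n_lines * 60)
    stop(sprintf(
      paste0("infeasible design: drug '%s' needs k = %.4g /h but the system ",
             "turnover is only %.4g /h; increase per-line flow to at least ",
             "%.4g mL/min"),
      targets[[i]]$name, k[i], k_total, min_flow), call. = FALSE)
  }
  cmax <- vapply(targets, `[[`, numeric(1), "cmax")
  # mg/L x mL = µg throughout
  v_supp <- q / k
  central_dose <- cmax * vc
  supp_conc_init <- pmax(0, k_total - k) * vc * cmax / q
  supp_dose <- supp_conc_init * v_supp
  lines <- data.frame(
    drug = vapply(targets, `[[`, character(1), "name"),
    cmax = cmax,
    half_life = vapply(targets, `[[`, numeric(1), "half_life"),
    dosing_interval = vapply(targets, `[[`, numeric(1), "dosing_interval"),
    doses_per_24h = vapply(targets, `[[`, integer(1), "doses_per_24h"),
    k = k, v_supp = v_supp, central_dose = central_dose,
    supp_dose = supp_dose, supp_conc_init = supp_conc_init,
    stringsAsFactors = FALSE)
  structure(list(hardware = hardware, lines = lines, k_total = k_total,
                 targets = targets),
            class = "parallel_design")
}

#' @export
print.parallel_design <- function(x, digits = 4, ...) {
  cat(sprintf("<parallel_design> %d drug(s), k_total = %.4g /h\n",
              nrow(x$lines), x$k_total))
  df <- x$lines
  df$k <- signif(df$k, digits)
  df$v_supp <- signif(df$v_supp, digits)
  df$supp_dose <- signif(df$supp_dose, digits + 1)
  df$supp_conc_init <- signif(df$supp_conc_init, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Steady-state daily exposure implied by a drug target
#'
#' Daily exposure under the bolus dose convention: each dose contributes
#' Cmax / k to the area under the curve at steady state, so
#' AUC24 = doses_per_24h x Cmax / k.  Note this steady-state convention
#' differs from integrating a single-dose profile over 0-24 h from a cold
#' start, noticeably so for half-lives that are long relative to the
#' dosing interval (see [auc24_from_fit()]).
#'
#' @param target A [drug_target()].
#' @return AUC24 in mg·h/L.
#' @examples
#' target_auc24(drug_target("ceftriaxone", 30, 8, 24)) # 346.3
#' @export
target_auc24 <- function(target) {
  stopifnot(inherits(target, "drug_target"))
  target$doses_per_24h * target$cmax / elimination_rate(target$half_life)
}

#' Feasibility report for a set of targets on given hardware
#'
#' A drug is feasible when its required elimination rate does not exceed
#' the total system turnover (the supplemental tank can only slow a drug's
#' decline, never speed it up).  Unlike [design_parallel()], this never
#' throws: it reports per-drug rates and the minimum per-line flow that
#' would make every drug feasible.
#'
#' @param targets List of [drug_target()] objects (may be empty).
#' @param hardware A [hardware_config()].
#' @return A list with `k_total` (per h), a data frame `drugs` (columns
#'   `drug`, `k`, `feasible`), `all_feasible`, and `min_flow_ml_min`, the
#'   smallest per-line flow making all drugs feasible.
#' @examples
#' check_feasibility(three_drug_targets(), hardware_config(180, 0.7, 3))
#' @export
check_feasibility <- function(targets, hardware) {
  stopifnot(inherits(hardware, "hardware_config"))
  targets <- check_target_list(targets)
  k_total <- system_turnover(hardware)
  if (length(targets) == 0L) {
    return(list(k_total = k_total,
                drugs = data.frame(drug = character(0), k = numeric(0),
                                   feasible = logical(0)),
                all_feasible = TRUE,
                min_flow_ml_min = 0))
  }
  k <- vapply(targets, function(t) elimination_rate(t$half_life), numeric(1))
  feasible <- k <= k_total * (1 + .k_tol)
  min_flow <- max(k) * hardware$v_central / (hardware$n_lines * 60)
  list(k_total = k_total,
       drugs = data.frame(drug = vapply(targets, `[[`, character(1), "name"),
                          k = k, feasible = feasible,
                          stringsAsFactors = FALSE),
       all_feasible = all(feasible),
       min_flow_ml_min = min_flow)
}

#' Three-drug reference targets
#'
#' The meropenem / ceftazidime / ceftriaxone target set used throughout the
#' package examples: unbound Cmax 120, 120 and 30 mg/L; half-lives 1.0, 2.5
#' and 8.0 h; the first two dosed every 8 h, ceftriaxone once daily.  These
#' mimic the unbound profiles of 2 g human doses.
#'
#' @return A list of three [drug_target()] objects.
#' @export
three_drug_targets <- function() {
  list(
    drug_target("meropenem",   cmax = 120, half_life = 1.0,
                dosing_interval = 8,  doses_per_24h = 3L),
    drug_target("ceftazidime", cmax = 120, half_life = 2.5,
                dosing_interval = 8,  doses_per_24h = 3L),
    drug_target("ceftriaxone", cmax = 30,  half_life = 8.0,
                dosing_interval = 24, doses_per_24h = 1L))
}

#' Reference hardware configuration
#'
#' 180 mL central volume (flask plus tubing plus cartridge, lumped), three
#' diluent lines at 0.7 mL/min each, 30-min infusions.
#'
#' @return A [hardware_config()].
#' @export
reference_hardware <- function() {
  hardware_config(v_central = 180, flow_ml_min = 0.7, n_lines = 3L,
                  infusion_duration = 0.5)
}

# internal: accept a single drug_target or a list of them
check_target_list <- function(targets) {
  if (inherits(targets, "drug_target")) targets <- list(targets)
  if (!is.list(targets) ||
      !all(vapply(targets, inherits, logical(1), "drug_target")))
    stop("'targets' must be a list of drug_target objects", call. = FALSE)
  nm <- vapply(targets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate drug names in targets", call. = FALSE)
  targets
}
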