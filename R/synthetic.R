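#' The reference serial-sampling schedule
#'
#' Twelve sampling times over 24 h — 1, 2, 4, 6, 8, 9, 16, 17, 18, 20, 22
#' and 24 h after the first doses — with the 8 h and 16 h samples drawn
#' immediately before the scheduled doses (troughs, evaluated as the limit
#' from the left).  Samples are drawn in duplicate from the circulatory
#' loop, so the schedule implies 24 records per drug per day.
#'
#' @return Data frame with columns `time` (h) and `pre_dose` (logical).
#' @export
default_sampling_schedule <- function() {
  data.frame(time = c(1, 2, 4, 6, 8, 9, 16, 17, 18, 20, 22, 24),
             pre_dose = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                          FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Multiplicative assay-noise model
#'
#' Proportional (lognormal) assay error: an observation is
#' truth x exp(eps) with eps ~ Normal(0, sigma) and
#' sigma = sqrt(log(1 + cv^2)), so the coefficient of variation of the
#' observation equals `cv` and the back-transformed median equals the
#' truth.  The default cv of 7% matches the upper intra-day variability
#' bound of the LC-MS/MS assays these data emulate; observations below the
#' lower limit of quantification are flagged.
#'
#' @param cv Coefficient of variation (fraction, >= 0; default 0.07).
#' @param lloq Lower limit of quantification, mg/L (default 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.07, lloq = 1, seed = 1L) {
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0)
    stop("'cv' must be a single non-negative fraction", call. = FALSE)
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq < 0)
    stop("'lloq' must be a single non-negative concentration", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(cv = cv, lloq = lloq, seed = seed,
                 sigma = sqrt(log(1 + cv^2))),
            class = "noise_model")
}

# internal: 31-bit polynomial string hash, folded with the run seed, so
# every (drug, day, replicate, time) record has its own reproducible RNG
# substream independent of enumeration order
record_seed <- function(seed, drug, day, replicate, time_index) {
  key <- paste(drug, day, replicate, time_index, sep = "|")
  h <- (abs(seed) %% 2147483647) + 1
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Generate noisy assay observations from true profiles
#'
#' Applies the multiplicative lognormal noise of a [noise_model()] to the
#' true central-compartment concentrations at the requested sampling
#' times, independently per record.  The random stream is split by
#' (drug, day, replicate, time), so any subset of the design regenerates
#' identically.  A zero truth yields a zero observation flagged below the
#' limit of quantification.
#'
#' @param profiles A `simulated_profiles` object evaluated at (at least)
#'   the sampling times, e.g. from [simulate_closed_form()] with the
#'   schedule's times and pre-dose flags.
#' @param sampling Data frame with columns `time` and `pre_dose` (see
#'   [default_sampling_schedule()]); all times must be present in
#'   `profiles`.
#' @param noise A [noise_model()].
#' @param replicates Duplicate samples per time point (default 2).
#' @param days Number of experiment days (default 1); days use disjoint
#'   noise substreams but share the same truth.
#' @return Data frame of class `hfim_observations` with columns `drug`,
#'   `day`, `replicate`, `time_h`, `conc_mg_L`, `truth_mg_L`,
#'   `below_lloq`.
#' @export
generate_observations <- function(profiles, sampling, noise,
                                  replicates = 2L, days = 1L) {
  stopifnot(inherits(profiles, "simulated_profiles"),
            inherits(noise, "noise_model"))
  if (is.numeric(sampling)) sampling <- data.frame(time = sampling,
                                                   pre_dose = FALSE)
  out <- list()
  for (p in profiles) {
    idx <- match(sampling$time, p$times)
    if (anyNA(idx))
      stop(sprintf("profile for '%s' does not cover all sampling times",
                   p$drug), call. = FALSE)
    truth <- p$c_central[idx]
    for (day in seq_len(days)) for (rep in seq_len(replicates)) {
      conc <- numeric(length(truth))
      for (i in seq_along(truth)) {
        if (truth[i] <= 0) { conc[i] <- 0; next }
        if (noise$cv == 0) { conc[i] <- truth[i]; next }
        rs <- record_seed(noise$seed, p$drug, day, rep, i)
        old <- .Random.seed_save()
        set.seed(rs)
        conc[i] <- truth[i] * exp(stats::rnorm(1L, 0, noise$sigma))
        .Random.seed_restore(old)
      }
      out[[length(out) + 1L]] <- data.frame(
        drug = p$drug, day = day, replicate = rep,
        time_h = sampling$time, conc_mg_L = conc, truth_mg_L = truth,
        below_lloq = conc < noise$lloq, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hfim_observations", "data.frame")
  res
}

# save/restore the global RNG state so seeded substreams do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a complete synthetic validation study
#'
#' End-to-end fixture builder: computes the parallel design, builds the
#' dosing schedule, evaluates the exact concentration-time profiles, and
#' draws noisy duplicate observations on the reference sampling schedule
#' for the requested number of days.  With the defaults (three drugs, two
#' days, duplicate samples at twelve times) this yields 144 observations.
#'
#' @param targets List of [drug_target()]s (default [three_drug_targets()]).
#' @param hardware A [hardware_config()] (default [reference_hardware()]).
#' @param noise A [noise_model()].
#' @param days Number of experiment days (default 2).
#' @param replicates Duplicates per sampling time (default 2).
#' @param sampling Sampling schedule (default
#'   [default_sampling_schedule()]).
#' @param horizon Simulation horizon, h (default 24).
#' @return A list of class `hfim_study`: `design`, `schedule`,
#'   `truth` (profiles on a 0.1 h grid), `sample_truth` (profiles at the
#'   sampling times, pre-dose aware), `observations`, `sampling`, and a
#'   `manifest` recording seed and parameters.
#' @export
generate_study <- function(targets = three_drug_targets(),
                           hardware = reference_hardware(),
                           noise = noise_model(),
                           days = 2L, replicates = 2L,
                           sampling = default_sampling_schedule(),
                           horizon = 24) {
  design <- design_parallel(targets, hardware)
  schedule <- build_schedule(design, horizon = horizon)
  grid <- sort(unique(c(seq(0, horizon, by = 0.1), sampling$time)))
  truth <- simulate_closed_form(design, schedule, times = grid)
  sample_truth <- simulate_closed_form(design, schedule,
                                       times = sampling$time,
                                       pre_dose = sampling$pre_dose)
  observations <- generate_observations(sample_truth, sampling, noise,
                                        replicates = replicates, days = days)
  structure(
    list(design = design, schedule = schedule, truth = truth,
         sample_truth = sample_truth, observations = observations,
         sampling = sampling,
         manifest = list(seed = noise$seed, cv = noise$cv, lloq = noise$lloq,
                         days = days, replicates = replicates,
                         horizon = horizon,
                         drugs = design$lines$drug)),
    class = "hfim_study")
}

#' @export
print.hfim_study <- function(x, ...) {
  cat(sprintf(
    "<hfim_study> %d drug(s), %d day(s), %d observations (cv = %g, seed = %d)\n",
    length(x$manifest$drugs), x$manifest$days, nrow(x$observations),
    x$manifest$cv, x$manifest$seed))
  invisible(x)
}
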