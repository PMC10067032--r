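# Synthetic cohort generator: Table-1-like covariates and per-vignette
# (initial, advice, final) triples from an explicit advice-weighting model.

TOTAL_EXPERIENCE_LEVELS <- c("<=14", "15+")
PALLIATIVE_EXPERIENCE_LEVELS <- c("<=5", "6-14", "15+")
AGE_BAND_LEVELS <- c("21-30", "31-40", "41-50", "51+")
GENDER_LEVELS <- c("male", "female")
SETTING_LEVELS <- c("hospice", "hospital", "community", "other", "multiple")

default_covariate_proportions <- function() {
  list(
    profession = c(doctor = 0.49, nurse = 0.41, other = 0.10),
    total_experience = c("<=14" = 0.35, "15+" = 0.65),
    palliative_experience = c("<=5" = 0.30, "6-14" = 0.36, "15+" = 0.34),
    age_band = c("21-30" = 0.07, "31-40" = 0.24, "41-50" = 0.38, "51+" = 0.31),
    gender = c(male = 0.08, female = 0.92),
    setting = c(hospice = 0.55, hospital = 0.10, community = 0.10,
                other = 0.01, multiple = 0.24)
  )
}

#' Default generative advice weight by arm and advice strength
#'
#' Mean weight placed on advice, as a function of study arm and advice
#' strength. The default table encodes the qualitative pattern of a two-arm
#' prognostic-advice trial: weights are higher in the algorithm arm than the
#' clinician arm at every strength, and intermediate-strength (75%) advice is
#' weighted least within each arm. Averaged over the 2:2:1 strength mix the
#' arm means are 0.44 (algorithm) and 0.32 (clinician).
#'
#' @param arm `"algorithm"` or `"clinician"` (vectorised).
#' @param strength advice strength in percent: 50, 75 or 90 (vectorised).
#' @param ... further covariates, ignored by the default model.
#' @return Numeric vector of weights in \[0, 1\].
#' @seealso [constant_weights()] for an arm-only weight function.
#' @export
default_true_weight <- function(arm, strength, ...) {
  tab <- matrix(c(0.48, 0.36, 0.50,   # algorithm at 50 / 75 / 90
                  0.31, 0.27, 0.37),  # clinician at 50 / 75 / 90
                nrow = 2, byrow = TRUE,
                dimnames = list(ARM_LEVELS, c("50", "75", "90")))
  tab[cbind(as.character(arm), as.character(strength))]
}

#' Constant per-arm advice weight function
#'
#' Factory for a weight function that depends on the arm only, used in
#' identifiability and parameter-recovery experiments where the estimand must
#' equal a known constant per arm.
#'
#' @param algorithm,clinician true mean weights in \[0, 1\] for the two arms.
#' @return A function `(arm, strength, ...)` returning the arm's weight.
#' @export
#' @examples
#' w <- constant_weights(0.44, 0.31)
#' w(c("algorithm", "clinician"), c(90, 50))
constant_weights <- function(algorithm, clinician) {
  check_scalar_number(algorithm, "algorithm", 0, 1)
  check_scalar_number(clinician, "clinician", 0, 1)
  force(algorithm); force(clinician)
  function(arm, strength, ...) {
    ifelse(as.character(arm) == "algorithm", algorithm, clinician)
  }
}

#' Generator preset for identifiability and parameter-recovery experiments
#'
#' The weight-of-advice statistic divides by `|a - i|` but keeps the sign of
#' `f - i`, so when advice sits below the initial estimate, moving towards the
#' advice yields a negative raw value that the default policy clamps to 0. A
#' generative weight is therefore only the estimand of mean WOA when advice
#' exceeds the initial estimate. This preset places every vignette anchor
#' well below its advice value (advice-above-anchor design), uses constant
#' per-arm weights, and turns dropout/tie nuisances off unless requested, so
#' that computed WOA recovers the generative weight.
#'
#' @param n_participants cohort size (default 284, i.e. 142 per arm).
#' @param w_algorithm,w_clinician true mean advice weights per arm.
#' @param response_sd,weight_sd,initial_sd as in [sim_config()]; recovery
#'   defaults are noise-free.
#' @param tie_probability,dropout_probability,integer_estimates,seed as in
#'   [sim_config()]; recovery defaults are complete, tie-free, real-valued.
#' @param ... further arguments passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
#' @examples
#' cfg <- recovery_config(n_participants = 40, response_sd = 0, seed = 1)
#' rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
#' summarize_woa(rec, "arm") # arm means equal the true weights
recovery_config <- function(n_participants = 284,
                            w_algorithm = 0.44, w_clinician = 0.31,
                            response_sd = 0, weight_sd = 0, initial_sd = 0,
                            tie_probability = 0, dropout_probability = 0,
                            integer_estimates = FALSE, seed = 1L, ...) {
  sim_config(n_participants = n_participants,
             vignette_anchors = c(v1 = 55, v2 = 50, v3 = 40, v4 = 35, v5 = 20),
             initial_sd = initial_sd,
             true_weight = constant_weights(w_algorithm, w_clinician),
             weight_sd = weight_sd, response_sd = response_sd,
             tie_probability = tie_probability,
             dropout_probability = dropout_probability,
             integer_estimates = integer_estimates, seed = seed, ...)
}

#' Configuration of the synthetic trial generator
#'
#' Bundles every knob of the generative model: cohort size, covariate
#' marginals, vignette anchors, the true advice-weight function, noise levels,
#' tie and dropout rates, and the master seed. Defaults emulate the design of
#' a 323-participant two-arm vignette trial of two-week survival estimates;
#' see the package vignette for the rationale behind each default.
#'
#' @param n_participants number of enrolled participants (default 323).
#' @param covariate_proportions named list of per-covariate category
#'   probabilities; each element must sum to 1. Defaults to the trial's
#'   marginal covariate distribution.
#' @param vignette_anchors named vector, mean initial estimate (percent) per
#'   vignette. Defaults average 65 and rise with advice strength.
#' @param initial_sd SD (percent) of initial estimates around their anchor.
#' @param true_weight function `(arm, strength, profession, total_experience,
#'   palliative_experience)` returning the mean advice weight in \[0, 1\].
#' @param weight_sd SD of the participant-level random deviation added to the
#'   mean weight (participant weights are clamped to \[0, 1\]). This is the
#'   between-participant heterogeneity the random-intercept model targets.
#' @param response_sd SD of the noise on the final estimate. On
#'   `noise_scale = "gap"` the SD is `response_sd * |a - i|` percent, i.e.
#'   `response_sd` is noise on the weight-of-advice scale; on `"percent"` it
#'   is an absolute SD in percent.
#' @param noise_scale `"gap"` (default) or `"percent"`.
#' @param tie_probability probability that an initial estimate is set exactly
#'   equal to the advice, making WOA undefined for that record.
#' @param dropout_probability probability that a participant fails to complete
#'   all five vignettes (per-protocol exclusion).
#' @param integer_estimates round estimates to whole percent (default TRUE);
#'   set FALSE for exact real-valued estimates in identifiability checks.
#' @param block_sizes randomisation block sizes, default `c(4, 6, 8)`.
#' @param seed master integer seed; named substreams for allocation,
#'   covariates, schedules, responses and dropout are derived from it.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 20, seed = 1)
#' trial <- simulate_trial(cfg)
#' head(trial$responses)
sim_config <- function(n_participants = 323,
                       covariate_proportions = default_covariate_proportions(),
                       vignette_anchors = c(v1 = 75, v2 = 70, v3 = 65,
                                            v4 = 60, v5 = 55),
                       initial_sd = 19,
                       true_weight = default_true_weight,
                       weight_sd = 0.2,
                       response_sd = 0.15,
                       noise_scale = c("gap", "percent"),
                       tie_probability = 0.05,
                       dropout_probability = 0.124,
                       integer_estimates = TRUE,
                       block_sizes = c(4L, 6L, 8L),
                       seed = 1L) {
  check_scalar_number(n_participants, "n_participants", lower = 1)
  noise_scale <- match.arg(noise_scale)
  for (nm in names(covariate_proportions)) {
    p <- covariate_proportions[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("proportions for `%s` must be nonnegative and sum to 1", nm),
           call. = FALSE)
    }
  }
  missing_anchor <- setdiff(names(vignette_strengths()), names(vignette_anchors))
  if (length(missing_anchor)) {
    stop("`vignette_anchors` missing vignette(s): ",
         paste(missing_anchor, collapse = ", "), call. = FALSE)
  }
  if (any(vignette_anchors < 0 | vignette_anchors > 100)) {
    stop("`vignette_anchors` must lie in [0, 100]", call. = FALSE)
  }
  check_scalar_number(initial_sd, "initial_sd", lower = 0)
  check_scalar_number(weight_sd, "weight_sd", lower = 0)
  check_scalar_number(response_sd, "response_sd", lower = 0)
  check_scalar_number(tie_probability, "tie_probability", 0, 1)
  check_scalar_number(dropout_probability, "dropout_probability", 0, 1)
  check_flag(integer_estimates, "integer_estimates")
  stopifnot(is.function(true_weight))
  structure(
    list(n_participants = as.integer(n_participants),
         covariate_proportions = covariate_proportions,
         vignette_anchors = vignette_anchors,
         initial_sd = initial_sd,
         true_weight = true_weight,
         weight_sd = weight_sd,
         response_sd = response_sd,
         noise_scale = noise_scale,
         tie_probability = tie_probability,
         dropout_probability = dropout_probability,
         integer_estimates = integer_estimates,
         block_sizes = as.integer(block_sizes),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic trial configuration: %d participants, seed %d\n",
    "  initial ~ truncN(anchor, %.3g) on [0,100]; weight sd %.3g;",
    " response sd %.3g (%s scale)\n",
    "  tie prob %.3g; dropout prob %.3g; %s estimates\n"),
    x$n_participants, x$seed, x$initial_sd, x$weight_sd, x$response_sd,
    x$noise_scale, x$tie_probability, x$dropout_probability,
    if (x$integer_estimates) "integer" else "real"))
  invisible(x)
}

# Normal draw truncated (not clamped) to [lo, hi], via inverse CDF.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (all(sd == 0)) return(pmin(hi, pmax(lo, rep_len(mean, n))))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Sample participant covariate profiles
#'
#' Draws each covariate independently from the configured marginal
#' proportions and assigns arms from a blocked 1:1 randomisation list.
#'
#' @param config a [sim_config()] object.
#' @return Data frame with one row per participant: `participant_id`, `arm`,
#'   `profession`, `total_experience`, `palliative_experience`, `age_band`,
#'   `gender`, `setting`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  alloc <- generate_allocation(n, config$block_sizes,
                               seed = derive_seed(config$seed, "allocation"))
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  with_seed(derive_seed(config$seed, "covariates"), {
    cp <- config$covariate_proportions
    data.frame(
      participant_id = sprintf("p%04d", seq_len(n)),
      arm = alloc$arm[seq_len(n)],
      profession = draw(cp$profession),
      total_experience = draw(cp$total_experience),
      palliative_experience = draw(cp$palliative_experience),
      age_band = draw(cp$age_band),
      gender = draw(cp$gender),
      setting = draw(cp$setting),
      stringsAsFactors = FALSE)
  })
}

#' Draw initial survival estimates for vignettes
#'
#' Initial estimates follow a normal distribution centred on the vignette's
#' anchor, truncated to \[0, 100\] and (by default) rounded to whole percent.
#' With probability `tie_probability` a draw is replaced by the vignette's
#' advice value exactly, which later makes the weight of advice undefined.
#'
#' Draws come from the current RNG stream; seed the stream (or use
#' [simulate_trial()]) for reproducibility.
#'
#' @param vignette_id vector of vignette ids (`"v1"`..`"v5"`).
#' @param config a [sim_config()] object.
#' @return Numeric vector of initial estimates in \[0, 100\].
#' @export
generate_initial <- function(vignette_id, config) {
  stopifnot(inherits(config, "sim_config"))
  anchors <- config$vignette_anchors[vignette_id]
  if (anyNA(anchors)) stop("unknown vignette id", call. = FALSE)
  i <- rtruncnorm(length(anchors), as.numeric(anchors), config$initial_sd)
  if (config$integer_estimates) i <- round(i)
  if (config$tie_probability > 0) {
    tie <- stats::runif(length(i)) < config$tie_probability
    i[tie] <- vignette_strengths()[vignette_id[tie]]
  }
  i
}

#' Combine an initial estimate with advice into a final estimate
#'
#' The generative advice-combination rule is linear:
#' `f = i + w * (a - i) + noise`, truncated to \[0, 100\] and (by default)
#' rounded. With zero noise the weight of advice computed from `(i, a, f)`
#' recovers `w` exactly, which makes `w` the estimand of the downstream
#' analysis.
#'
#' @param i initial estimates (percent).
#' @param a advice values (percent).
#' @param w advice weights in \[0, 1\], recycled to the length of `i`.
#' @param config a [sim_config()] object; supplies `response_sd`,
#'   `noise_scale` and `integer_estimates`.
#' @return Numeric vector of final estimates in \[0, 100\].
#' @export
#' @examples
#' cfg <- sim_config(response_sd = 0, seed = 1)
#' generate_final(60, 90, 0.5, cfg) # 75
generate_final <- function(i, a, w, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(w < 0 | w > 1)) stop("`w` must lie in [0, 1]", call. = FALSE)
  w <- rep_len(w, length(i))
  sd_eff <- switch(config$noise_scale,
                   gap = config$response_sd * abs(a - i),
                   percent = rep_len(config$response_sd, length(i)))
  f <- i + w * (a - i) + stats::rnorm(length(i), 0, sd_eff)
  f <- pmin(100, pmax(0, f))
  if (config$integer_estimates) f <- round(f)
  f
}

#' Mark incomplete participants' records
#'
#' Each participant independently fails to complete the study with probability
#' `dropout_probability`; for such a participant a uniformly chosen nonempty
#' subset of their records is marked `completed = FALSE`, leaving between 0
#' and 4 completed vignettes.
#'
#' @param responses response data frame with `participant_id` rows.
#' @param config a [sim_config()] object.
#' @return `responses` with its `completed` column updated.
#' @export
apply_dropout <- function(responses, config) {
  stopifnot(inherits(config, "sim_config"))
  responses$completed <- TRUE
  if (config$dropout_probability == 0) return(responses)
  ids <- unique(responses$participant_id)
  drops <- ids[stats::runif(length(ids)) < config$dropout_probability]
  for (id in drops) {
    rows <- which(responses$participant_id == id)
    k <- sample(length(rows), 1L)
    responses$completed[sample(rows, k)] <- FALSE
  }
  responses
}

#' Simulate a complete two-arm advice-taking trial
#'
#' Runs the full generative pipeline: blocked allocation, covariate sampling,
#' per-participant vignette order, initial estimates, participant-level advice
#' weights, final estimates, and dropout. All randomness derives from the
#' config's master seed through named substreams, so identical configs give
#' byte-identical datasets.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"woa_trial"`: list with `participants` (one row
#'   per participant, including the perceived `advisor_label`), `responses`
#'   (one row per participant x vignette with `position`, `advice`, `initial`,
#'   `final`, `completed`, and the latent `true_weight`), and `config`.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_participants = 12, seed = 42))
#' table(trial$participants$arm)
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  participants <- sample_cohort(config)
  participants$advisor_label <- advisor_label(participants$arm,
                                              participants$profession)
  n <- nrow(participants)
  strengths <- vignette_strengths()

  order_mat <- with_seed(derive_seed(config$seed, "schedule"), {
    t(vapply(seq_len(n), function(j) sample(names(strengths)),
             character(length(strengths))))
  })

  responses <- data.frame(
    participant_id = rep(participants$participant_id, each = 5L),
    vignette_id = as.vector(t(order_mat)),
    position = rep(1:5, times = n),
    stringsAsFactors = FALSE)
  responses$advice <- as.integer(strengths[responses$vignette_id])

  idx <- match(responses$participant_id, participants$participant_id)
  mean_w <- config$true_weight(
    arm = participants$arm[idx],
    strength = responses$advice,
    profession = participants$profession[idx],
    total_experience = participants$total_experience[idx],
    palliative_experience = participants$palliative_experience[idx])

  with_seed(derive_seed(config$seed, "responses"), {
    # participant-level heterogeneity: one weight deviation per participant,
    # clamped so every realised weight stays a valid degree of adherence
    b <- stats::rnorm(n, 0, config$weight_sd)
    w <- pmin(1, pmax(0, mean_w + b[idx]))
    responses$true_weight <- w
    responses$initial <- generate_initial(responses$vignette_id, config)
    responses$final <- generate_final(responses$initial, responses$advice,
                                      w, config)
  })

  responses <- with_seed(derive_seed(config$seed, "dropout"),
                         apply_dropout(responses, config))

  structure(list(participants = participants, responses = responses,
                 config = config),
            class = "woa_trial")
}

#' @export
print.woa_trial <- function(x, ...) {
  compl <- stats::aggregate(completed ~ participant_id, x$responses, all)
  cat(sprintf(paste0(
    "Simulated advice-taking trial: %d participants (%d completers), ",
    "%d vignette responses\n"),
    nrow(x$participants), sum(compl$completed), nrow(x$responses)))
  print(table(arm = x$participants$arm))
  invisible(x)
}

#' Write / read a simulated trial as CSV with a JSON provenance sidecar
#'
#' The dataset is one flat CSV (participant covariates repeated on each
#' response row); the sidecar records the full generator configuration and
#' seed so the dataset can be regenerated.
#'
#' @param trial a `"woa_trial"` object.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path stem>_config.json`.
#' @return `write_trial()` returns the CSV path invisibly; `read_trial()`
#'   returns a `"woa_trial"` object (with `config = NULL` if no sidecar).
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "woa_trial"))
  df <- merge(trial$participants[, c("participant_id", "arm", "profession",
                                     "total_experience",
                                     "palliative_experience", "age_band",
                                     "gender", "setting")],
              trial$responses[, c("participant_id", "vignette_id", "position",
                                  "advice", "initial", "final", "completed")],
              by = "participant_id")
  df <- df[order(df$participant_id, df$position), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- trial$config
  cfg_json <- cfg[setdiff(names(cfg), "true_weight")]
  cfg_json$true_weight <- "<R function; not serialised>"
  jsonlite::write_json(cfg_json, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_config.json")
}

#' @rdname write_trial
#' @param path input CSV path.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "arm", "profession", "total_experience",
                "palliative_experience", "age_band", "gender", "setting",
                "vignette_id", "position", "advice", "initial", "final",
                "completed")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$completed <- as.logical(df$completed)
  participants <- unique(df[, c("participant_id", "arm", "profession",
                                "total_experience", "palliative_experience",
                                "age_band", "gender", "setting")])
  participants$advisor_label <- advisor_label(participants$arm,
                                              participants$profession)
  responses <- df[, c("participant_id", "vignette_id", "position", "advice",
                      "initial", "final", "completed")]
  cfg <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) cfg <- jsonlite::read_json(sp, simplifyVector = TRUE)
  structure(list(participants = participants, responses = responses,
                 config = cfg),
            class = "woa_trial")
}
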