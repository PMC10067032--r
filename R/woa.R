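# Weight-of-advice: the per-record statistic, its capping/exclusion rules,
# per-protocol filtering, ordinal binning, and descriptive summaries.

#' Weight of advice for one estimate/advice/estimate triple
#'
#' `WOA = (f - i) / |a - i|`: the fraction of the distance from the initial
#' estimate `i` towards the advice `a` covered by the final estimate `f`.
#' 0 means the advice was fully discounted, 1 fully adopted. The denominator
#' is an absolute value but the numerator is not, so moving away from the
#' advice gives a negative raw value and overshooting beyond it a value above
#' 1 (handled by [truncate_woa()]). When `a == i` no weight is defined and
#' `NA` is returned (the record is excluded as a tie).
#'
#' @param i,a,f initial estimate, advice, final estimate; percentages in
#'   \[0, 100\], vectorised.
#' @return Numeric vector of raw WOA values, `NA` where `a == i`.
#' @export
#' @examples
#' compute_woa(60, 90, 75) # 0.5
#' compute_woa(90, 90, 80) # NA: tie, no weight defined
compute_woa <- function(i, a, f) {
  for (nm in c("i", "a", "f")) {
    x <- get(nm)
    if (any(!is.finite(x) | x < 0 | x > 100)) {
      stop(sprintf("`%s` must lie in [0, 100]", nm), call. = FALSE)
    }
  }
  out <- (f - i) / abs(a - i)
  out[a == i] <- NA_real_
  out
}

#' Cap and clamp raw weight-of-advice values
#'
#' Raw values above 1 are always capped at 1. Negative raw values are handled
#' by `policy`: `"clamp"` (default) sets them to 0, consistent with the 0-1
#' range of the statistic; `"keep"` retains them; `"drop"` replaces them with
#' `NA` so they leave the analysis.
#'
#' @param raw numeric vector of raw WOA values (`NA` allowed, passed through).
#' @param policy `"clamp"`, `"keep"` or `"drop"`.
#' @return Numeric vector; under `"clamp"` all non-missing values lie in
#'   \[0, 1\].
#' @export
#' @examples
#' truncate_woa(c(1.167, 0.42, -0.5))                  # 1.00 0.42 0.00
#' truncate_woa(-0.5, policy = "keep")                 # -0.5
truncate_woa <- function(raw, policy = c("clamp", "keep", "drop")) {
  policy <- match.arg(policy)
  out <- pmin(raw, 1)
  if (policy == "clamp") out <- pmax(out, 0)
  if (policy == "drop") out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Ordinal weight-of-advice category
#'
#' Bins a WOA value in \[0, 1\] into five ordered categories with left-closed,
#' right-open boundaries — `[0, 0.2)`, `[0.2, 0.4)`, `[0.4, 0.6)`,
#' `[0.6, 0.8)` — except the last, `[0.8, 1]`, which is closed at 1.
#'
#' @param woa numeric vector in \[0, 1\]; `NA` passes through.
#' @return Integer vector of categories 1-5.
#' @export
#' @examples
#' bin_woa(c(0, 0.19, 0.2, 0.99, 1)) # 1 1 2 5 5
bin_woa <- function(woa) {
  if (any(!is.na(woa) & (woa < 0 | woa > 1))) {
    stop("`woa` must lie in [0, 1]; truncate raw values first", call. = FALSE)
  }
  out <- findInterval(woa, c(0.2, 0.4, 0.6, 0.8)) + 1L
  out[is.na(woa)] <- NA_integer_
  out
}

#' Derive per-record weight-of-advice data from a trial
#'
#' Computes raw WOA per response, applies the truncation policy and ordinal
#' binning, marks tie exclusions, and attaches the participant covariates
#' needed downstream. Run [per_protocol_filter()] on the result to add the
#' completeness exclusion.
#'
#' @param trial a `"woa_trial"` object (from [simulate_trial()] or
#'   [read_trial()]).
#' @param policy negative-raw-value policy passed to [truncate_woa()].
#' @return Data frame of class `"woa_records"`: one row per response with
#'   `participant_id`, `vignette_id`, `arm`, `strength`, covariates,
#'   `completed`, `raw_woa`, `woa`, `bin`, `excluded`, `reason`.
#' @export
woa_records <- function(trial, policy = c("clamp", "keep", "drop")) {
  stopifnot(inherits(trial, "woa_trial"))
  policy <- match.arg(policy)
  r <- trial$responses
  p <- trial$participants
  idx <- match(r$participant_id, p$participant_id)
  rec <- data.frame(
    participant_id = r$participant_id,
    vignette_id = r$vignette_id,
    arm = p$arm[idx],
    strength = r$advice,
    profession = p$profession[idx],
    total_experience = p$total_experience[idx],
    palliative_experience = p$palliative_experience[idx],
    initial = r$initial,
    final = r$final,
    completed = r$completed,
    stringsAsFactors = FALSE)
  rec$raw_woa <- compute_woa(r$initial, r$advice, r$final)
  rec$woa <- truncate_woa(rec$raw_woa, policy)
  rec$bin <- bin_woa(pmin(1, pmax(0, rec$woa)))
  rec$bin[is.na(rec$woa) | rec$woa < 0 | rec$woa > 1] <- NA_integer_
  rec$excluded <- is.na(rec$raw_woa)
  rec$reason <- ifelse(is.na(rec$raw_woa), "tie", NA_character_)
  if (policy == "drop") {
    neg <- !rec$excluded & is.na(rec$woa)
    rec$excluded[neg] <- TRUE
    rec$reason[neg] <- "negative"
  }
  class(rec) <- c("woa_records", "data.frame")
  rec
}

#' Per-protocol filter: exclude participants who did not complete the study
#'
#' Any participant with fewer than five completed vignette responses has all
#' of their records marked `excluded` with reason `"incomplete"`. The filter
#' is idempotent and never removes rows; downstream summaries and models use
#' only non-excluded records.
#'
#' @param records a `"woa_records"` data frame (must carry `completed`).
#' @return The records with exclusion flags updated.
#' @export
per_protocol_filter <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("participant_id", "completed") %in% names(records)))
  n_done <- tapply(records$completed, records$participant_id, sum)
  incomplete <- names(n_done)[n_done < 5]
  hit <- records$participant_id %in% incomplete
  records$excluded[hit] <- TRUE
  records$reason[hit] <- "incomplete"
  records
}

#' Descriptive weight-of-advice summaries
#'
#' Per-group record count, mean, SD and normal-approximation 95% confidence
#' interval of the mean, over non-excluded records. Groupings mirror the
#' standard presentation of a two-arm advice-taking trial: overall, by arm,
#' or a moderator crossed with arm.
#'
#' @param records a `"woa_records"` data frame (run [per_protocol_filter()]
#'   first for a per-protocol summary).
#' @param grouping `"overall"`, `"arm"`, or one of `"profession"`,
#'   `"total_experience"`, `"palliative_experience"`, `"strength"` (each
#'   crossed with arm).
#' @param value column to summarise (default `"woa"`).
#' @return Data frame of class `"woa_summary"` with the grouping columns and
#'   `n`, `mean`, `sd`, `ci_lo`, `ci_hi`. Empty groups keep `n = 0` with `NA`
#'   moments.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_participants = 40, seed = 3))
#' rec <- per_protocol_filter(woa_records(trial))
#' summarize_woa(rec, "arm")
summarize_woa <- function(records,
                          grouping = c("overall", "arm", "profession",
                                       "total_experience",
                                       "palliative_experience", "strength"),
                          value = "woa") {
  grouping <- match.arg(grouping)
  # tie exclusions only remove WOA-scale values; probability-estimate columns
  # remain summarisable for every per-protocol record
  drop <- if (value %in% c("woa", "raw_woa", "bin")) {
    records$excluded
  } else {
    !is.na(records$reason) & records$reason == "incomplete"
  }
  keep <- !drop & !is.na(records[[value]])
  # group levels come from the full record set, so groups emptied by
  # exclusions still appear (with n = 0 and undefined moments)
  group_cols <- switch(grouping, overall = character(0), arm = "arm",
                       c(grouping, "arm"))
  if (length(group_cols) == 0) {
    labels <- data.frame(group = "overall", stringsAsFactors = FALSE)
    key <- factor(rep("overall", sum(keep)))
  } else {
    fullkey <- interaction(lapply(group_cols, function(cl)
      factor(records[[cl]])), sep = ":", lex.order = TRUE)
    key <- fullkey[keep]
    parts <- strsplit(levels(fullkey), ":", fixed = TRUE)
    labels <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(labels) <- group_cols
  }
  agg <- function(v) {
    n <- length(v)
    m <- if (n > 0) mean(v) else NA_real_
    s <- if (n > 1) stats::sd(v) else NA_real_
    half <- if (n > 1) stats::qnorm(0.975) * s / sqrt(n) else NA_real_
    c(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  }
  stats_mat <- t(vapply(split(records[[value]][keep], key), agg, numeric(5)))
  out <- cbind(labels, as.data.frame(stats_mat))
  out$n <- as.integer(out$n)
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  attr(out, "value") <- value
  class(out) <- c("woa_summary", "data.frame")
  out
}

#' @export
print.woa_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s summary by %s (non-excluded records)\n",
              toupper(attr(x, "value") %||% "woa"),
              attr(x, "grouping") %||% "group"))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
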