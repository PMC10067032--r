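# Trial design: blocked randomisation, vignette schedules, advisor labelling,
# and the two-sample sample-size helper.

#' Advice strengths attached to the five study vignettes
#'
#' The trial uses five patient vignettes whose advised two-week survival
#' probabilities are fixed at 90, 90, 75, 75 and 50 percent; only the
#' presentation order is randomised per participant.
#'
#' @return Named integer vector mapping vignette id (`"v1"`..`"v5"`) to advice
#'   strength in percent.
#' @export
#' @examples
#' vignette_strengths()
vignette_strengths <- function() {
  c(v1 = 90L, v2 = 90L, v3 = 75L, v4 = 75L, v5 = 50L)
}

#' Generate a blocked 1:1 randomisation list
#'
#' Builds an allocation list in randomly permuted balanced blocks, the standard
#' mixed-block scheme for two-arm trials: each block's size is drawn uniformly
#' from `block_sizes`, and within a block exactly half the entries are
#' `"algorithm"` and half `"clinician"`. Whole blocks are appended until the
#' list holds at least `n` entries, so overall arm imbalance at any prefix
#' never exceeds half the largest block size.
#'
#' @param n number of participants the list must cover (positive integer).
#' @param block_sizes even positive block sizes to mix over; defaults to
#'   `c(4, 6, 8)`.
#' @param seed integer seed; identical inputs give identical lists.
#' @return An object of class `"woa_alloc"`: a list with `arm` (character
#'   vector of length >= `n`), `block` (block index per entry),
#'   `block_boundaries` (end index of each complete block), `block_sizes`,
#'   `n`, `seed`.
#' @export
#' @examples
#' al <- generate_allocation(12, block_sizes = 4, seed = 1)
#' table(al$arm)
generate_allocation <- function(n, block_sizes = c(4L, 6L, 8L), seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  if (n != round(n)) stop("`n` must be a whole number", call. = FALSE)
  if (length(block_sizes) == 0 || any(!is.finite(block_sizes)) ||
      any(block_sizes <= 0) || any(block_sizes %% 2 != 0)) {
    stop("`block_sizes` must be even positive integers (1:1 balance requires even blocks)",
         call. = FALSE)
  }
  block_sizes <- as.integer(sort(unique(block_sizes)))
  with_seed(seed, {
    arm <- character(0)
    block <- integer(0)
    boundaries <- integer(0)
    b <- 0L
    while (length(arm) < n) {
      b <- b + 1L
      size <- if (length(block_sizes) == 1L) block_sizes else
        sample(block_sizes, 1L)
      entries <- sample(rep(ARM_LEVELS, each = size / 2L))
      arm <- c(arm, entries)
      block <- c(block, rep(b, size))
      boundaries <- c(boundaries, length(arm))
    }
    structure(
      list(arm = arm, block = block, block_boundaries = boundaries,
           block_sizes = block_sizes, n = as.integer(n), seed = seed),
      class = "woa_alloc")
  })
}

#' @export
print.woa_alloc <- function(x, ...) {
  cat(sprintf("Blocked 1:1 allocation list: %d entries in %d blocks (sizes %s)\n",
              length(x$arm), length(x$block_boundaries),
              paste(x$block_sizes, collapse = "/")))
  tab <- table(factor(x$arm, ARM_LEVELS))
  cat(sprintf("  algorithm %d, clinician %d (first %d entries cover the cohort)\n",
              tab[["algorithm"]], tab[["clinician"]], x$n))
  invisible(x)
}

#' Randomise the presentation order of the five vignettes
#'
#' Draws a uniformly random permutation of the five fixed vignettes; the
#' multiset of advice strengths (90, 90, 75, 75, 50) is invariant because the
#' strengths travel with the vignette ids.
#'
#' @param seed integer seed.
#' @return A list of class `"woa_schedule"` with `order` (vignette ids in
#'   presentation order) and `strengths` (advice strength per presented
#'   vignette, same order).
#' @export
#' @examples
#' schedule_vignettes(seed = 7)
schedule_vignettes <- function(seed = NULL) {
  strengths <- vignette_strengths()
  with_seed(seed, {
    ord <- sample(names(strengths))
    structure(list(order = ord, strengths = strengths[ord]),
              class = "woa_schedule")
  })
}

#' @export
print.woa_schedule <- function(x, ...) {
  cat("Vignette presentation order:",
      paste(sprintf("%s(%d%%)", x$order, x$strengths), collapse = " "), "\n")
  invisible(x)
}

#' Perceived source of advice shown to a participant
#'
#' The advice values are identical in both arms; only the label differs. The
#' algorithm arm is told the advice comes from the PiPS-B14 prognostic tool.
#' In the clinician arm the advisor is framed as a colleague from a different
#' profession: doctors are told the advice is from a nurse, while nurses and
#' other healthcare professionals are told it is from a doctor.
#'
#' @param arm `"algorithm"` or `"clinician"` (vectorised).
#' @param profession `"doctor"`, `"nurse"` or `"other"` (vectorised).
#' @return Character vector: `"algorithm_pips_b14"`, `"nurse"` or `"doctor"`.
#' @export
#' @examples
#' advisor_label("clinician", "doctor")
#' advisor_label("algorithm", "other")
advisor_label <- function(arm, profession) {
  arm <- as.character(arm)
  profession <- as.character(profession)
  if (!all(arm %in% ARM_LEVELS)) {
    stop("`arm` must be 'algorithm' or 'clinician'", call. = FALSE)
  }
  if (!all(profession %in% PROFESSION_LEVELS)) {
    stop("`profession` must be 'doctor', 'nurse' or 'other'", call. = FALSE)
  }
  out <- rep("algorithm_pips_b14", length.out = max(length(arm), length(profession)))
  arm <- rep_len(arm, length(out))
  profession <- rep_len(profession, length(out))
  clin <- arm == "clinician"
  out[clin] <- ifelse(profession[clin] == "doctor", "nurse", "doctor")
  out
}

#' Two-sample sample size for a mean weight-of-advice difference
#'
#' Smallest total sample size (split 1:1) such that a two-sample z-test on the
#' difference in mean WOA between arms attains the requested power:
#' `n per arm = ceiling(2 * (z[1-alpha/2] + z[power])^2 * (sd / difference)^2)`.
#'
#' @param sd assumed common standard deviation of WOA (per-participant scale).
#' @param difference smallest mean WOA difference worth detecting.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return Total sample size across both arms (even integer).
#' @export
#' @examples
#' required_sample_size(sd = 0.3, difference = 0.3) # 32 in total
required_sample_size <- function(sd, difference, alpha = 0.05, power = 0.80) {
  check_scalar_number(sd, "sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(difference, "difference", lower = 0, strict_lower = TRUE)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(power, "power", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  per_arm <- ceiling(2 * z^2 * (sd / difference)^2)
  2L * as.integer(per_arm)
}
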