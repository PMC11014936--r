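#' Coefficient of variation of control scores
#'
#' Plate-uniformity statistic: `100 * sd(x) / mean(x)` with the sample
#' (n - 1) standard deviation. Computed over the negative-control (DMSO)
#' Actin scores of a plate and compared against the usual 10% validation
#' bound.
#'
#' @param scores Numeric vector of at least 2 finite control scores with
#'   non-zero mean.
#' @return CV in percent.
#' @examples
#' control_cv(c(98, 100, 102)) # 2
#' @export
control_cv <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2 || any(!is.finite(scores))) {
    abort("control_cv needs at least 2 finite scores")
  }
  m <- mean(scores)
  if (m == 0) abort("control_cv undefined: mean score is zero")
  100 * sd(scores) / m
}

#' Z'-factor assay window
#'
#' The standard high-throughput-screening quality statistic
#' `Z' = 1 - 3 (s_pos + s_neg) / |m_pos - m_neg|`, with sample standard
#' deviations of the positive- and negative-control scores. `Z'` is at
#' most 1 (exactly 1 only for two noiseless arms) and is invariant under a
#' common affine rescaling of all scores; values of 0.5 and above denote
#' an excellent separation band.
#'
#' @param neg_scores,pos_scores Numeric vectors, at least 2 values each.
#' @return The Z'-factor (dimensionless).
#' @examples
#' z_prime(c(95, 100, 105), c(17, 20, 23))
#' @export
z_prime <- function(neg_scores, pos_scores) {
  neg_scores <- as.numeric(neg_scores)
  pos_scores <- as.numeric(pos_scores)
  if (length(neg_scores) < 2 || length(pos_scores) < 2 ||
      any(!is.finite(c(neg_scores, pos_scores)))) {
    abort("z_prime needs at least 2 finite scores in each arm")
  }
  sep <- abs(mean(pos_scores) - mean(neg_scores))
  if (sep == 0) abort("z_prime undefined: no separation between control means")
  1 - 3 * (sd(pos_scores) + sd(neg_scores)) / sep
}

#' Validate a plate against the HTS criteria
#'
#' Evaluates a measured plate against the two plate-acceptance criteria of
#' the screen: negative-control CV at most `cv_max` percent and Z'-factor
#' at least `z_min`. Controls flagged `EMPTY_WELL` are excluded from the
#' statistics and counted in the report; a plate without at least two
#' usable controls per arm cannot be validated.
#'
#' @param measurements Measurement tibble ([quantify_plate()] or
#'   [simulate_control_plate()] output); may contain several plates, which
#'   are validated independently.
#' @param cv_max Maximum admissible CV, percent (default 10).
#' @param z_min Minimum admissible Z'-factor (default 0.5).
#'
#' @return A tibble of class `qc_report`, one row per plate: `plate_id`,
#'   `n_neg`, `n_pos`, `n_excluded`, `cv_percent`, `z_prime`, `pass_cv`,
#'   `pass_zprime`, `overall_pass`, `note` (boundary cases are noted since
#'   the criteria are applied as closed comparisons).
#' @export
validate_plate <- function(measurements, cv_max = 10, z_min = 0.5) {
  stopifnot(is.data.frame(measurements))
  out <- measurements %>%
    group_by(.data$plate_id) %>%
    dplyr::group_modify(~ validate_one_plate(.x, cv_max, z_min)) %>%
    ungroup()
  class(out) <- c("qc_report", class(out))
  out
}

validate_one_plate <- function(m, cv_max, z_min) {
  usable <- !has_flag(m$qc_flags, "EMPTY_WELL") & is.finite(m$actin_score)
  neg <- m$actin_score[m$kind == "negative_control" & usable]
  pos <- m$actin_score[m$kind == "positive_control" & usable]
  n_excluded <- sum(!usable & m$kind %in% c("negative_control", "positive_control"))
  if (length(neg) < 2 || length(pos) < 2) {
    abort(sprintf(
      "insufficient usable controls (%d negative, %d positive; %d excluded)",
      length(neg), length(pos), n_excluded
    ))
  }
  cv <- control_cv(neg)
  zp <- z_prime(neg, pos)
  note <- c(
    if (cv == cv_max) "CV exactly at the bound",
    if (zp == z_min) "Z' exactly at the bound"
  )
  tibble(
    n_neg = length(neg), n_pos = length(pos), n_excluded = n_excluded,
    cv_percent = cv, z_prime = zp,
    pass_cv = cv <= cv_max, pass_zprime = zp >= z_min,
    overall_pass = cv <= cv_max && zp >= z_min,
    note = paste(note, collapse = "; ")
  )
}

#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("cv_percent", "z_prime"),
                        names_to = "statistic", values_to = "value")
}

#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    n_plates = nrow(x),
    n_pass = sum(x$overall_pass),
    pass_rate = mean(x$overall_pass),
    median_cv = median(x$cv_percent),
    median_zprime = median(x$z_prime)
  )
}
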