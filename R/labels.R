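#' The four ordinal fatigue classes
#'
#' Perceived exertion on the Borg CR10 scale is banded into four fatigue
#' states used as classification targets: `Low < Moderate < High < VeryHigh`.
#'
#' @return Character vector of the four class names in ordinal order.
#' @export
fatigue_classes <- function() c("Low", "Moderate", "High", "VeryHigh")

fatigue_factor <- function(x) {
  factor(x, levels = fatigue_classes(), ordered = FALSE)
}

#' Map Borg CR10 readings to fatigue classes
#'
#' Bands the 0-10 category-ratio scale of perceived exertion into the four
#' fatigue states: 0-2 -> Low, 3-5 -> Moderate, 6-8 -> High, 9-10 -> VeryHigh.
#'
#' @param borg Integer vector of Borg CR10 values in 0..10.
#' @return Factor with levels `fatigue_classes()`.
#' @examples
#' borg_to_class(c(0, 4, 10))
#' @export
borg_to_class <- function(borg) {
  if (length(borg) == 0) stop("`borg` must be non-empty", call. = FALSE)
  if (any(!is.finite(borg)) || any(borg != round(borg)) ||
      any(borg < 0) || any(borg > 10)) {
    stop("Borg CR10 readings must be integers in 0..10", call. = FALSE)
  }
  # band boundaries follow the CR10 descriptor grouping:
  # 0-2 no exertion..easy, 3-5 moderate, 6-8 hard, 9-10 extremely hard/maximal
  cls <- cut(borg, breaks = c(-0.5, 2.5, 5.5, 8.5, 10.5),
             labels = fatigue_classes())
  factor(as.character(cls), levels = fatigue_classes())
}

#' Age-predicted maximal heart rate (Tanaka)
#'
#' `HRmax = 206.9 - 0.7 * age`, the age-predicted maximum heart rate for
#' healthy adults.
#'
#' @param age Age in years, strictly positive.
#' @return Maximal heart rate in beats per minute.
#' @examples
#' tanaka_hrmax(20) # 192.9
#' @export
tanaka_hrmax <- function(age) {
  if (length(age) == 0 || any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive and finite", call. = FALSE)
  }
  206.9 - 0.7 * age
}

#' Physiological stop rule for a walking bout
#'
#' A bout must be stopped if any heart-rate sample exceeds 90% of the
#' participant's maximal heart rate, or if a Borg CR10 value of 10 (maximum
#' exertion) is reported.
#'
#' @param hr Numeric vector of heart-rate samples (bpm); must be non-empty.
#' @param hrmax Maximal heart rate in bpm (e.g. from [tanaka_hrmax()]).
#' @param borg Single Borg CR10 reading for the bout.
#' @return A list with `stop` (logical) and `reason` (`"hr"`, `"borg"` or
#'   `NA` when no rule fires). The HR rule takes precedence when both fire.
#' @examples
#' safety_stop(hr = c(120, 150), hrmax = tanaka_hrmax(22), borg = 6)
#' @export
safety_stop <- function(hr, hrmax, borg) {
  if (length(hr) == 0) stop("heart-rate series is empty", call. = FALSE)
  if (!is.finite(hrmax) || hrmax <= 0) stop("`hrmax` must be positive", call. = FALSE)
  borg_to_class(borg) # validates the reading
  if (any(hr > 0.9 * hrmax)) {
    list(stop = TRUE, reason = "hr")
  } else if (borg == 10) {
    list(stop = TRUE, reason = "borg")
  } else {
    list(stop = FALSE, reason = NA_character_)
  }
}
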