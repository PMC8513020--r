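#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text geom_step labs scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Cumulative feature-importance curve
#'
#' @param object An [rank_features()] ranking.
#' @param ... Unused.
#' @return A ggplot: cumulative relative importance against the number of
#'   top-ranked features retained.
#' @export
autoplot.importance_ranking <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$cumulative)) +
    geom_step() +
    geom_point(size = 0.8) +
    labs(x = "features retained (by importance rank)",
         y = "cumulative relative importance",
         title = "Random-forest feature importance") +
    theme_minimal()
}

#' Confusion-matrix heatmap of a fitted classifier
#'
#' @param object A `fatigue_fit`.
#' @param ... Unused.
#' @return A ggplot tile map of the confusion counts (rows = true class).
#' @export
autoplot.fatigue_fit <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("truth", "predicted", "n")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = paste0(object$spec$algorithm, " confusion matrix"),
         x = "predicted class", y = "true class") +
    theme_minimal()
}

#' Foot angular-velocity trace with ground-truth heel strikes
#'
#' @param object A `fatigue_cohort`.
#' @param participant,bout Which recording to show (defaults: first
#'   participant, baseline bout).
#' @param seconds How many seconds of signal to draw (default 5).
#' @param ... Unused.
#' @return A ggplot of the sagittal foot gyro with heel-strike markers.
#' @export
autoplot.fatigue_cohort <- function(object, participant = 1, bout = 0,
                                    seconds = 5, ...) {
  i <- which(object$recordings$participant == participant &
               object$recordings$bout == bout)
  if (length(i) == 0) stop("no such recording", call. = FALSE)
  rec <- object$recordings$recording[[i]]
  fs <- rec$fs$imu
  n <- min(nrow(rec$foot_gyro), ceiling(seconds * fs))
  df <- tibble::tibble(time_s = (seq_len(n) - 1) / fs,
                       gyro_z = rec$foot_gyro[seq_len(n), "z"])
  hs <- object$truth$heel_strikes[[
    which(object$truth$participant == participant & object$truth$bout == bout)]]
  hs <- hs[hs <= df$time_s[n]]
  ggplot(df, aes(x = .data$time_s, y = .data$gyro_z)) +
    geom_line(linewidth = 0.3) +
    geom_point(data = tibble::tibble(time_s = hs,
                                     gyro_z = approx(df$time_s, df$gyro_z,
                                                     hs)$y),
               colour = "red", size = 1.5) +
    labs(x = "time (s)", y = "foot sagittal angular velocity (deg/s)",
         title = sprintf("Participant %d, bout %d: heel strikes", participant,
                         bout)) +
    theme_minimal()
}
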