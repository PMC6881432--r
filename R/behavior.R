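#' Attraction index
#'
#' Time spent in the arena area next to the stimulus group minus time spent
#' in the opposite area, in seconds.
#'
#' @param dur_stimulus,dur_opposite durations in seconds (>= 0), or a
#'   data.frame of behavior records with those columns as the first argument.
#' @return numeric AI.
#' @export
attraction_index <- function(dur_stimulus, dur_opposite = NULL) {
  if (is.data.frame(dur_stimulus)) {
    rec <- dur_stimulus
    dur_stimulus <- rec$dur_stimulus
    dur_opposite <- rec$dur_opposite
  }
  if (any(dur_stimulus < 0) || any(dur_opposite < 0))
    stop("durations must be non-negative")
  dur_stimulus - dur_opposite
}

#' Gregarious-behavior probability P_greg
#'
#' Logistic phase classifier of arena behavior,
#' \deqn{P_{greg} = e^\eta / (1 + e^\eta), \quad
#'   \eta = -2.11 + 0.005\,AI + 0.012\,TDM + 0.015\,TDMV,}
#' with AI the attraction index, TDM the total distance moved and TDMV the
#' total duration of movement, in the tracking system's units. The
#' coefficients are fixed constants of the published model, not refit.
#'
#' @param ai attraction index.
#' @param tdm total distance moved.
#' @param tdmv total duration of movement.
#' @return probability in (0,1); 1 = fully gregarious behavior.
#' @export
pgreg <- function(ai, tdm, tdmv) {
  if (!all(is.finite(ai)) || !all(is.finite(tdm)) || !all(is.finite(tdmv)))
    stop("P_greg inputs must be finite")
  eta <- -2.11 + 0.005 * ai + 0.012 * tdm + 0.015 * tdmv
  stats::plogis(eta)
}

#' Score behavior records with P_greg
#'
#' @param records data.frame with columns \code{dur_stimulus},
#'   \code{dur_opposite}, \code{total_distance_moved},
#'   \code{total_duration_movement}.
#' @return the records with added \code{ai} and \code{p_greg} columns.
#' @export
pgreg_records <- function(records) {
  records$ai <- attraction_index(records)
  records$p_greg <- pgreg(records$ai, records$total_distance_moved,
                          records$total_duration_movement)
  records
}

#' Compare P_greg between two groups of animals
#'
#' Medians per group and a two-sided Mann-Whitney (Wilcoxon rank-sum) test,
#' exact when sample sizes permit.
#'
#' @param records_a,records_b behavior-record data.frames (or bare numeric
#'   P_greg vectors).
#' @return list with \code{median_a}, \code{median_b}, \code{p_value},
#'   \code{n_a}, \code{n_b}.
#' @export
compare_groups <- function(records_a, records_b) {
  pa <- if (is.data.frame(records_a)) pgreg_records(records_a)$p_greg
        else records_a
  pb <- if (is.data.frame(records_b)) pgreg_records(records_b)$p_greg
        else records_b
  if (!length(pa) || !length(pb)) stop("each group needs at least 1 record")
  wt <- suppressWarnings(stats::wilcox.test(pa, pb,
                                            alternative = "two.sided"))
  list(median_a = stats::median(pa), median_b = stats::median(pb),
       p_value = wt$p.value, n_a = length(pa), n_b = length(pb))
}
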