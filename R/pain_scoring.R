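#' A single welfare observation of one mouse
#'
#' Raw material for the four-category pain rubric: physiological
#' measurements, binary sign flags, and an activity log (timestamps of
#' movement/grooming events within the observation period).
#'
#' @param body_weight Current body weight, g (> 0).
#' @param prev_body_weight Weight at the previous measurement, g, or `NA`
#'   for a first observation (the weight criterion is then skipped).
#' @param body_temp Body temperature, degrees C.
#' @param diarrhea,hunched_posture,rough_hair_coat,pinched_face,distended_abdomen,reluctance_to_move
#'   Logical sign flags.
#' @param activity_event_times Times (s) of movement/grooming events
#'   within `[0, observation_duration]`.
#' @param observation_duration Observation period, s (default 300 = 5 min).
#' @return An object of class `pain_observation`.
#' @export
pain_observation <- function(body_weight, prev_body_weight = NA_real_,
                             body_temp, diarrhea = FALSE,
                             hunched_posture = FALSE,
                             rough_hair_coat = FALSE, pinched_face = FALSE,
                             distended_abdomen = FALSE,
                             reluctance_to_move = FALSE,
                             activity_event_times = numeric(0),
                             observation_duration = 300) {
  if (body_weight <= 0 || (!is.na(prev_body_weight) && prev_body_weight <= 0))
    stop("body weights must be > 0", call. = FALSE)
  if (!is.finite(body_temp)) stop("body_temp must be finite", call. = FALSE)
  if (observation_duration <= 0)
    stop("observation_duration must be > 0", call. = FALSE)
  if (length(activity_event_times) &&
      (min(activity_event_times) < 0 ||
       max(activity_event_times) > observation_duration))
    stop("activity events must lie within [0, observation_duration]",
         call. = FALSE)
  structure(list(body_weight = body_weight,
                 prev_body_weight = prev_body_weight,
                 body_temp = body_temp, diarrhea = isTRUE(diarrhea),
                 hunched_posture = isTRUE(hunched_posture),
                 rough_hair_coat = isTRUE(rough_hair_coat),
                 pinched_face = isTRUE(pinched_face),
                 distended_abdomen = isTRUE(distended_abdomen),
                 reluctance_to_move = isTRUE(reluctance_to_move),
                 activity_event_times = sort(as.numeric(activity_event_times)),
                 observation_duration = observation_duration),
            class = "pain_observation")
}

#' Physiological-characteristics category score
#'
#' Scores 1 when body weight changed by strictly more than
#' `weight_threshold` (default 10%) in either direction since the
#' previous measurement, when body temperature falls outside the normal
#' range (35.8--37.4 C), or when diarrhea is present. The temperature
#' rule defaults to flagging deviation in *either* direction — tumor
#' burden depresses body temperature below range — with
#' `temp_rule = "above"` restricting to hyperthermia only.
#'
#' @param obs A [pain_observation()].
#' @param weight_threshold Relative weight-change threshold (fraction).
#' @param temp_range Normal temperature range, degrees C.
#' @param temp_rule `"outside"` (default) or `"above"`.
#' @return 0 or 1.
#' @export
score_physiological <- function(obs, weight_threshold = 0.10,
                                temp_range = c(35.8, 37.4),
                                temp_rule = c("outside", "above")) {
  stopifnot(inherits(obs, "pain_observation"))
  temp_rule <- match.arg(temp_rule)
  weight_flag <- !is.na(obs$prev_body_weight) &&
    abs(obs$body_weight - obs$prev_body_weight) / obs$prev_body_weight >
      weight_threshold
  temp_flag <- if (temp_rule == "above") obs$body_temp > temp_range[2L]
               else obs$body_temp < temp_range[1L] || obs$body_temp > temp_range[2L]
  as.integer(weight_flag || temp_flag || obs$diarrhea)
}

#' Posture category score
#'
#' @param obs A [pain_observation()].
#' @return 1 if hunched posture, else 0.
#' @export
score_posture <- function(obs) {
  stopifnot(inherits(obs, "pain_observation"))
  as.integer(obs$hunched_posture)
}

#' Appearance category score
#'
#' @param obs A [pain_observation()].
#' @return 1 if any of rough hair coat, pinched face, distended/swollen
#'   abdomen, or reluctance to move; else 0.
#' @export
score_appearance <- function(obs) {
  stopifnot(inherits(obs, "pain_observation"))
  as.integer(obs$rough_hair_coat || obs$pinched_face ||
               obs$distended_abdomen || obs$reluctance_to_move)
}

#' Activity category score
#'
#' Scores 1 when the animal showed no movement/grooming event for
#' strictly more than `max_gap` seconds at any point in the observation.
#' The gaps from the observation start to the first event and from the
#' last event to the end count: an animal inactive for the first 40 s
#' scores 1.
#'
#' @param obs A [pain_observation()].
#' @param max_gap Inactivity threshold, s.
#' @return 0 or 1.
#' @export
score_activity <- function(obs, max_gap = 30) {
  stopifnot(inherits(obs, "pain_observation"))
  gaps <- diff(c(0, obs$activity_event_times, obs$observation_duration))
  as.integer(any(gaps > max_gap))
}

#' Total four-category pain score
#'
#' Each category (physiological, posture, appearance, activity)
#' contributes 0 or 1; the total ranges 0 (normal) to 4 (most painful).
#'
#' @param obs A [pain_observation()].
#' @param ... Passed on to [score_physiological()] and
#'   [score_activity()] (thresholds, temperature rule).
#' @return A list of class `pain_score` with the four category scores and
#'   `total`.
#' @export
total_pain_score <- function(obs, ...) {
  stopifnot(inherits(obs, "pain_observation"))
  dots <- list(...)
  phys_args <- dots[names(dots) %in%
                      c("weight_threshold", "temp_range", "temp_rule")]
  act_args <- dots[names(dots) %in% "max_gap"]
  s <- list(physiological = do.call(score_physiological, c(list(obs), phys_args)),
            posture = score_posture(obs),
            appearance = score_appearance(obs),
            activity = do.call(score_activity, c(list(obs), act_args)))
  s$total <- s$physiological + s$posture + s$appearance + s$activity
  structure(s, class = "pain_score")
}

#' @export
print.pain_score <- function(x, ...) {
  cat(sprintf(paste0("<pain_score> total %d/4 (physiological %d, ",
                     "posture %d, appearance %d, activity %d)\n"),
              x$total, x$physiological, x$posture, x$appearance, x$activity))
  invisible(x)
}
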