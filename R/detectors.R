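#' Detector configuration
#'
#' Three detector layouts are supported. *Type1*: majority vote over `M`
#' feature classifiers of a single muscle (rest wins only with at least
#' `floor(M/2) + 1` rest votes, so ties go to movement). *Type2*: majority
#' vote over the Type1 outputs of several muscles. *Type2Info*: Type2
#' restricted to the `subset_size` most informative muscles (the subset is
#' passed explicitly via `muscles`, typically from [rank_muscles()]).
#'
#' @param type `"Type1"`, `"Type2"` or `"Type2Info"`.
#' @param muscle single muscle label (Type1).
#' @param muscles muscle labels (Type2 / Type2Info).
#' @param features voting features per muscle (default
#'   [default_feature_set()]).
#' @param subset_size P, the Type2Info subset size (default 3).
#' @param debounce consecutive movement steps required before an onset is
#'   declared (default 1).
#' @return object of class `detector_config`.
#' @export
detector_config <- function(type = c("Type1", "Type2", "Type2Info"),
                            muscle = NULL, muscles = NULL,
                            features = default_feature_set(),
                            subset_size = 3, debounce = 1) {
  type <- match.arg(type)
  if (type == "Type1") {
    if (is.null(muscle) || length(muscle) != 1)
      stop("Type1 requires exactly one muscle")
    muscles <- muscle
  } else {
    if (is.null(muscles)) muscles <- EMG_CHANNELS
    if (type == "Type2Info") {
      if (subset_size > length(muscles))
        stop("subset_size must not exceed the number of muscles")
      muscles <- muscles[seq_len(subset_size)]
    }
  }
  structure(list(type = type, muscles = muscles, features = features,
                 n_features = length(features), subset_size = subset_size,
                 debounce = debounce),
            class = "detector_config")
}

#' Majority vote with ties to movement
#'
#' The decision is rest only when at least `floor(M/2) + 1` of the `M`
#' voters say rest; otherwise movement. Applied to feature votes within a
#' muscle (Type1) and to muscle votes across Type1 sub-detectors (Type2).
#'
#' @param votes integer/logical vector (or matrix, voters in columns) of
#'   binary decisions, 0/FALSE = rest, 1/TRUE = movement.
#' @return binary decision(s): 0 = rest, 1 = movement (vector for matrix
#'   input, one per row).
#' @export
majority_vote <- function(votes) {
  if (is.matrix(votes)) {
    M <- ncol(votes)
    if (M < 1) stop("empty vote set")
    rest <- rowSums(votes == 0)
    return(as.integer(rest < floor(M / 2) + 1))
  }
  M <- length(votes)
  if (M < 1) stop("empty vote set")
  as.integer(sum(votes == 0) < floor(M / 2) + 1)
}

#' @rdname majority_vote
#' @param feature_labels binary votes of the M feature classifiers of one
#'   muscle.
#' @export
type1_vote <- function(feature_labels) majority_vote(feature_labels)

#' @rdname majority_vote
#' @param channel_labels binary votes of the K Type1 sub-detectors.
#' @export
type2_vote <- function(channel_labels) majority_vote(channel_labels)

# onset times: first step of every 0->1 transition whose movement run
# lasts at least `debounce` steps
detect_onsets <- function(labels, times, debounce = 1) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a movement run starting at step 1 is not a 0->1 transition
  keep <- r$values == 1L & r$lengths >= debounce & starts > 1L
  times[starts[keep]]
}

#' Run an onset detector over a session's feature series
#'
#' Streams every (muscle, feature) classifier with sequential threshold
#' adaptation, combines the per-step binary decisions by majority voting
#' (per muscle, then — for multi-muscle detectors — across muscles) and
#' extracts debounced movement-onset times.
#'
#' @param features named list of `feature_series` (one per muscle), from
#'   [feature_matrix()].
#' @param models nested list `models[[muscle]][[feature]]` of initial
#'   mixture parameters (from [emg_gmm()] fits on a training session).
#' @param config a [detector_config].
#' @param L adaptive memory length, steps (default 1000).
#' @param adapt `FALSE` freezes thresholds at their initial values.
#' @return object of class `detection_result`: `labels` (0/1 per step),
#'   `times` (step timestamps, s), `onsets` (detected onset times, s),
#'   `theta_traces` (per muscle.feature), `config`.
#' @export
run_detector <- function(features, models, config, L = 1000, adapt = TRUE) {
  stopifnot(inherits(config, "detector_config"))
  muscles <- config$muscles
  miss_m <- setdiff(muscles, names(features))
  if (length(miss_m))
    stop("no feature series for muscle(s): ", paste(miss_m, collapse = ", "))
  times <- features[[muscles[1]]]$times
  theta_traces <- list()
  muscle_labels <- matrix(0L, length(times), length(muscles),
                          dimnames = list(NULL, muscles))
  for (m in muscles) {
    fl <- matrix(0L, length(times), length(config$features),
                 dimnames = list(NULL, config$features))
    for (f in config$features) {
      mod <- models[[m]][[f]]
      if (is.null(mod))
        stop("missing model for (", m, ", ", f, ")")
      st <- classify_stream(features[[m]]$values[, f], mod, L = L,
                            adapt = adapt)
      fl[, f] <- st$labels
      theta_traces[[paste(m, f, sep = ".")]] <- st$theta
    }
    muscle_labels[, m] <- majority_vote(fl)
  }
  labels <- if (config$type == "Type1") muscle_labels[, 1]
    else majority_vote(muscle_labels)
  onsets <- detect_onsets(labels, times, config$debounce)
  structure(list(labels = as.integer(labels), times = times,
                 onsets = onsets, theta_traces = theta_traces,
                 config = config),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("detection_result:", x$config$type, "on",
      paste(x$config$muscles, collapse = ", "), "\n")
  cat("  ", length(x$labels), "steps,", sum(x$labels), "movement-labelled,",
      length(x$onsets), "onsets\n")
  invisible(x)
}

#' Write a detection result to disk
#'
#' CSV of per-step labels plus a JSON sidecar with onset times and
#' configuration.
#'
#' @param result a `detection_result`.
#' @param path output CSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_detection <- function(result, path) {
  data.table::fwrite(data.table::data.table(time_s = result$times,
                                            label = result$labels), path)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(onsets_s = result$onsets,
                            config = unclass(result$config)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
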