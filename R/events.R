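#' @name event-sequences
#' @title Event sequences over (marker, z-threshold) pairs
#'
#' @description The model's latent object is an ordering of all progression
#' events, one event per marker per z threshold. Events are identified by
#' integer ids laid out marker-major: with R thresholds per marker, event
#' `(i, r)` has id `(i - 1) * R + r`. A sequence is a permutation of all ids
#' that keeps each marker's thresholds in increasing order (a marker must
#' reach z = 1 before z = 2 before z = 3).
NULL

event_marker <- function(id, n_thresh) (id - 1L) %/% n_thresh + 1L
event_thresh <- function(id, n_thresh) (id - 1L) %% n_thresh + 1L

#' Validate an event sequence
#'
#' @param s integer vector of event ids.
#' @param panel a [marker_panel()].
#' @return `TRUE` if `s` is a permutation of all events with within-marker
#'   threshold order preserved, else `FALSE`.
#' @export
validate_event_sequence <- function(s, panel) {
  N <- n_events(panel)
  R <- length(panel$z_thresholds)
  if (length(s) != N || !setequal(s, seq_len(N))) return(FALSE)
  pos <- integer(N)
  pos[s] <- seq_len(N)
  for (i in seq_len(n_markers(panel))) {
    ids <- (i - 1L) * R + seq_len(R)
    if (is.unsorted(pos[ids], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Draw a random valid event sequence
#'
#' A uniform random permutation of the event set with each marker's threshold
#' events then rearranged into increasing-threshold order within their
#' positions, giving a valid sequence.
#'
#' @param panel a [marker_panel()].
#' @return integer event-id vector of length [n_events()].
#' @export
random_event_sequence <- function(panel) {
  N <- n_events(panel)
  R <- length(panel$z_thresholds)
  s <- sample.int(N)
  for (i in seq_len(n_markers(panel))) {
    ids <- (i - 1L) * R + seq_len(R)
    where <- sort(match(ids, s))
    s[where] <- ids
  }
  s
}

#' Expected z-score trajectory under a sequence
#'
#' Each marker accumulates linearly from one z threshold to the next: the
#' trajectory passes through (0, 0), then (position of event (i, r), z_r) for
#' each threshold, and reaches `z_max` at the terminal stage N. Between those
#' control points the expected z is linear in stage.
#'
#' @param sequence valid event-id vector.
#' @param panel a [marker_panel()].
#' @param marker_index marker (1-based).
#' @param stage integer stage(s) in `[0, N]`.
#' @return expected z value(s) at the requested stage(s).
#' @export
expected_trajectory <- function(sequence, panel, marker_index, stage) {
  if (any(stage < 0 | stage > n_events(panel))) stop("stage out of range")
  E <- trajectory_matrix(sequence, panel)
  E[marker_index, stage + 1L]
}

# full markers x (N+1) matrix of expected z at stages 0..N
trajectory_matrix <- function(sequence, panel) {
  N <- n_events(panel)
  R <- length(panel$z_thresholds)
  M <- n_markers(panel)
  pos <- integer(N)
  pos[sequence] <- seq_len(N)
  E <- matrix(0, M, N + 1L)
  for (i in seq_len(M)) {
    ks <- pos[(i - 1L) * R + seq_len(R)]
    # terminal anchor at z_max; ties = max lets the anchor win when the
    # marker's last event sits at the final stage
    E[i, ] <- stats::approx(x = c(0, ks, N), y = c(0, panel$z_thresholds, panel$z_max),
                            xout = 0:N, ties = max)$y
  }
  E
}
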