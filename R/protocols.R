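# Time-dependent driving-force protocols.
#
# A protocol carries a scalar main-drive amplitude a(t) >= 0, applied to every
# forward edge (toward decreasing state index), plus a list of stressor
# events whose amplitude s(t) acts on the backward edges as an opposing
# drive. Segment boundaries are left-closed, right-open.

new_driving_protocol <- function(segments, stressors = list()) {
  segments <- as.data.frame(segments)
  need <- c("t_start", "t_end", "a_start", "a_end")
  if (!all(need %in% names(segments))) stop("malformed protocol segments")
  if (nrow(segments) > 0) {
    o <- order(segments$t_start)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$t_end <= segments$t_start))
      stop("every segment needs t_end > t_start")
    if (nrow(segments) > 1 &&
        any(segments$t_start[-1] < segments$t_end[-nrow(segments)] - 1e-12))
      stop("protocol segments must not overlap")
    if (any(segments$a_start < 0 | segments$a_end < 0))
      stop("drive amplitudes must be >= 0")
  }
  structure(list(segments = segments, stressors = stressors),
            class = "driving_protocol")
}

#' Zero (undriven) protocol
#' @return a `driving_protocol` with `a(t) = 0` everywhere.
#' @export
zero_protocol <- function() {
  new_driving_protocol(data.frame(t_start = numeric(), t_end = numeric(),
                                  a_start = numeric(), a_end = numeric()))
}

#' Rectangular driving protocol
#'
#' The driving force appears suddenly at `t_on`, stays constant at
#' `amplitude`, and drops back to zero at `t_off` (left-closed, right-open:
#' `a(t_on) = amplitude`, `a(t_off) = 0`).
#'
#' @param amplitude drive energy per forward edge (>= 0).
#' @param t_on,t_off switch-on and switch-off times, `0 <= t_on < t_off`.
#' @return a `driving_protocol`.
#' @export
protocol_rectangular <- function(amplitude, t_on, t_off) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (!(t_on >= 0 && t_off > t_on)) stop("need 0 <= t_on < t_off")
  new_driving_protocol(data.frame(t_start = t_on, t_end = t_off,
                                  a_start = amplitude, a_end = amplitude))
}

#' Trapezoidal driving protocol
#'
#' The drive ramps linearly from 0 to `amplitude` over
#' `[t_rise0, t_rise1)`, holds the plateau until `t_fall0`, and ramps
#' linearly back to zero over `[t_fall0, t_fall1)`. A degenerate plateau
#' (`t_rise1 == t_fall0`) gives a triangular profile.
#'
#' @param amplitude plateau drive energy (>= 0).
#' @param t_rise0,t_rise1,t_fall0,t_fall1 breakpoints with
#'   `t_rise0 < t_rise1 <= t_fall0 < t_fall1`.
#' @return a `driving_protocol`.
#' @export
protocol_trapezoidal <- function(amplitude, t_rise0, t_rise1, t_fall0, t_fall1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (!(t_rise0 < t_rise1 && t_rise1 <= t_fall0 && t_fall0 < t_fall1))
    stop("need t_rise0 < t_rise1 <= t_fall0 < t_fall1")
  seg <- data.frame(
    t_start = c(t_rise0, t_rise1, t_fall0),
    t_end   = c(t_rise1, t_fall0, t_fall1),
    a_start = c(0, amplitude, amplitude),
    a_end   = c(amplitude, amplitude, 0)
  )
  seg <- seg[seg$t_end > seg$t_start, , drop = FALSE]  # drop empty plateau
  new_driving_protocol(seg)
}

#' Define a stressor event
#'
#' A stressor is an opposing driving force `delta_stress` acting on the
#' backward edges. A `"pulse"` is reversible (finite duration); a `"step"` is
#' irreversible (persists to the end of the run, `duration = Inf`).
#'
#' @param kind `"pulse"` or `"step"`.
#' @param amplitude opposing drive energy (>= 0).
#' @param t_on onset time.
#' @param duration pulse length; ignored (forced `Inf`) for a step.
#' @return a `stressor_event` list.
#' @export
stressor_event <- function(kind = c("pulse", "step"), amplitude, t_on,
                           duration = Inf) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("stressor amplitude must be >= 0")
  if (t_on < 0) stop("t_on must be >= 0")
  if (kind == "pulse" && !is.finite(duration))
    stop("a pulse needs a finite duration")
  if (kind == "step") duration <- Inf
  structure(list(kind = kind, amplitude = amplitude, t_on = t_on,
                 duration = duration), class = "stressor_event")
}

#' Add a stressor event to a protocol
#' @param protocol a `driving_protocol`.
#' @param event a [stressor_event()].
#' @return the protocol with the event appended.
#' @export
add_stressor <- function(protocol, event) {
  stopifnot(inherits(protocol, "driving_protocol"),
            inherits(event, "stressor_event"))
  protocol$stressors <- c(protocol$stressors, list(event))
  protocol
}

#' Main-drive amplitude a(t)
#'
#' @param protocol a `driving_protocol`.
#' @param t time (vectorized), must be >= 0.
#' @return numeric vector of drive amplitudes.
#' @export
drive_amplitude <- function(protocol, t) {
  if (any(t < 0)) stop("protocol is undefined for t < 0")
  a <- numeric(length(t))
  seg <- protocol$segments
  for (i in seq_len(nrow(seg))) {
    within <- t >= seg$t_start[i] & t < seg$t_end[i]
    if (any(within)) {
      frac <- (t[within] - seg$t_start[i]) / (seg$t_end[i] - seg$t_start[i])
      a[within] <- seg$a_start[i] + frac * (seg$a_end[i] - seg$a_start[i])
    }
  }
  a
}

#' Stressor (opposing-drive) amplitude s(t)
#'
#' Sum of the amplitudes of all active stressor events at `t`; event windows
#' are left-closed, right-open.
#'
#' @inheritParams drive_amplitude
#' @return numeric vector of opposing-drive amplitudes.
#' @export
stressor_amplitude <- function(protocol, t) {
  if (any(t < 0)) stop("protocol is undefined for t < 0")
  s <- numeric(length(t))
  for (ev in protocol$stressors) {
    within <- t >= ev$t_on & t < ev$t_on + ev$duration
    s[within] <- s[within] + ev$amplitude
  }
  s
}

#' Evaluate a protocol into a full driving-field matrix
#'
#' Places the main amplitude `a(t)` on every forward edge and the stressor
#' amplitude `s(t)` on every backward edge; zero elsewhere. Protocols are
#' pure: evaluating twice at the same `t` gives identical fields.
#'
#' @param protocol a `driving_protocol`.
#' @param t scalar time (>= 0).
#' @param n_states,topology system geometry.
#' @return a `driving_field` matrix.
#' @export
evaluate_field <- function(protocol, t, n_states,
                           topology = c("chain", "ring")) {
  topology <- match.arg(topology)
  stopifnot(length(t) == 1)
  idx <- edge_indices(n_states, topology)
  d <- matrix(0, n_states, n_states)
  d[idx$forward] <- drive_amplitude(protocol, t)
  d[idx$backward] <- stressor_amplitude(protocol, t)
  driving_field(d, topology)
}

# largest amplitudes anywhere in the protocol (for the Euler stability guard)
protocol_max_amplitudes <- function(protocol) {
  seg <- protocol$segments
  a <- if (nrow(seg)) max(seg$a_start, seg$a_end) else 0
  s <- if (length(protocol$stressors))
    max(vapply(protocol$stressors, `[[`, numeric(1), "amplitude")) else 0
  c(forward = a, backward = s)
}

#' @export
print.driving_protocol <- function(x, ...) {
  cat(sprintf("Driving protocol: %d segment(s), %d stressor(s)\n",
              nrow(x$segments), length(x$stressors)))
  if (nrow(x$segments)) print(x$segments, row.names = FALSE)
  for (ev in x$stressors)
    cat(sprintf("  stressor: %s, amplitude %g, t_on %g, duration %g\n",
                ev$kind, ev$amplitude, ev$t_on, ev$duration))
  invisible(x)
}
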