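#' Instantaneous Symmetry Index over a time window
#'
#' The ISI is the absolute area between the right and left curves, normalized
#' by the sum of the absolute areas under both curves:
#' `ISI = int |R - L| dt / (int |R| dt + int |L| dt)` over `[t1, t2]`.
#' 0 means perfect bilateral symmetry; 1 means a fully one-sided signal.
#' Integrals are trapezoidal; the window bounds snap to the nearest samples.
#'
#' @param R,L right and left signal series (here: per-wheel linear velocity).
#' @param t time series, seconds.
#' @param t1,t2 window bounds, seconds (defaults: full range).
#' @return The ISI, a unitless scalar in `[0, 1]` for nonnegative signals.
#' @export
compute_isi <- function(R, L, t, t1 = t[1], t2 = t[length(t)]) {
  n <- length(t)
  if (length(R) != n || length(L) != n) {
    stop("compute_isi: R, L and t must share length", call. = FALSE)
  }
  if (t1 < t[1] - 1e-9 || t2 > t[n] + 1e-9 || t2 <= t1) {
    stop("compute_isi: window [t1, t2] must lie within t and have t2 > t1",
         call. = FALSE)
  }
  i1 <- snap_index(t, t1)
  i2 <- snap_index(t, t2)
  if (i2 <= i1) stop("compute_isi: window shorter than one sample", call. = FALSE)
  num <- trapz_window(t, abs(R - L), i1, i2)
  den <- trapz_window(t, abs(R), i1, i2) + trapz_window(t, abs(L), i1, i2)
  if (den == 0) {
    stop("compute_isi: undefined ISI (both signals identically zero on window)",
         call. = FALSE)
  }
  num / den
}

#' ISI over the start/middle/end cycle windows of a sprint
#'
#' Computes the ISI of left/right wheel velocity at three points of the
#' sprint: the start (first three propulsion cycles), the middle (cycles
#' between start and end), the end (last five cycles), plus the whole sprint
#' window.
#'
#' @param v_left,v_right camber-corrected per-wheel linear velocity, m/s,
#'   on the full stream grid.
#' @param t full time vector, seconds.
#' @param cycles a [segment_cycles()] result.
#' @param window the matching [detect_sprint_window()].
#' @return An object of class `symmetry_result`: `isi_start`, `isi_middle`
#'   (NA when the middle window is empty), `isi_end`, `isi_overall`, and the
#'   window time `spans`.
#' @export
isi_by_window <- function(v_left, v_right, t, cycles, window) {
  spans <- cycle_spans(cycles, window, t)
  isi_of <- function(sp) {
    if (is.null(sp)) return(NA_real_)
    compute_isi(v_right, v_left, t, sp[1], sp[2])
  }
  structure(list(isi_start = isi_of(spans$start),
                 isi_middle = isi_of(spans$middle),
                 isi_end = isi_of(spans$end),
                 isi_overall = isi_of(spans$overall),
                 spans = spans[c("start", "middle", "end", "overall")]),
            class = "symmetry_result")
}
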