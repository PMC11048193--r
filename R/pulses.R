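# Pulse segmentation and conversion to calibrated Stokes-domain traces.

#' Degree of polarization
#'
#' `DOP = sqrt(q^2 + u^2 + v^2)` from the intensity-normalized Stokes
#' components; 0 is unpolarized, 1 fully polarized light. Values exceeding
#' 1 (possible under noise) are clipped to 1; the returned vector carries a
#' `clipped` attribute marking samples that exceeded `1 + tolerance`.
#'
#' @param q,u,v Normalized Stokes components (vectorized).
#' @param tolerance Clipping QC tolerance (default `1e-6`).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' compute_dop(0.6, 0, 0.8)  # fully polarized: 1
#' compute_dop(0, 0, 0)      # unpolarized: 0
#' @export
compute_dop <- function(q, u, v, tolerance = 1e-6) {
  if (!all(is.finite(q), is.finite(u), is.finite(v)))
    abort("non-finite polarization components.")
  val <- sqrt(q^2 + u^2 + v^2)
  clipped <- val > 1 + tolerance
  out <- pmin(val, 1)
  attr(out, "clipped") <- clipped
  out
}

#' Detect particle pulses in a raw stream
#'
#' Baseline and noise scale on the trigger channel are estimated robustly
#' (median and MAD over the whole record). Contiguous runs above
#' `baseline + threshold_sigma * scale` are taken as candidate pulses,
#' padded outward to the nearest samples at baseline level, merged when
#' closer than `min_gap`, and kept when at least `min_width` samples long.
#'
#' @param stream A `pfec_stream` (or data frame with columns `I1..I4`,
#'   `F`).
#' @param threshold_sigma Detection threshold in robust noise units (> 0).
#' @param min_width Minimum pulse width in samples.
#' @param min_gap Minimum below-threshold gap between distinct pulses.
#' @param trigger Channel used for detection (default `"I1"`).
#' @return A tibble with one row per pulse: `pulse_id`, `start`, `end`
#'   (0-based half-open), `n_samples` and a `samples` list-column of
#'   per-pulse channel windows. Per-channel baseline estimates are attached
#'   as the `baseline` attribute.
#' @export
detect_pulses <- function(stream, threshold_sigma = 5, min_width = 5,
                          min_gap = 3, trigger = "I1") {
  chans <- c("I1", "I2", "I3", "I4", "F")
  if (!all(chans %in% names(stream)))
    abort("stream must have columns I1, I2, I3, I4, F.")
  if (threshold_sigma <= 0) abort("`threshold_sigma` must be > 0.")
  x <- stream[[trigger]]
  if (length(x) == 0) return(empty_pulse_table())
  if (!all(vapply(stream[chans], function(v) all(is.finite(v)), TRUE)))
    abort("non-finite samples in stream.")
  base <- median(x)
  scale <- mad(x)
  thr <- base + threshold_sigma * scale
  above <- x > thr
  if (!any(above)) return(empty_pulse_table(stream, chans))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])   # 1-based inclusive

  # pad each run outward to the nearest samples back at baseline level
  pad_level <- base + scale
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]
    while (s > 1L && x[s - 1L] > pad_level) s <- s - 1L
    e <- runs[i, 2]
    while (e < length(x) && x[e + 1L] > pad_level) e <- e + 1L
    runs[i, ] <- c(s, e)
  }
  # merge overlapping / nearly touching windows
  o <- order(runs[, 1])
  runs <- runs[o, , drop = FALSE]
  merged <- list(runs[1, ])
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (runs[i, 1] - last[2] - 1L < min_gap) {
      merged[[length(merged)]] <- c(last[1], max(last[2], runs[i, 2]))
    } else merged[[length(merged) + 1L]] <- runs[i, ]
  }
  runs <- do.call(rbind, merged)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= min_width, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_pulse_table(stream, chans))

  baseline <- vapply(stream[chans], median, 0)
  samples <- lapply(seq_len(nrow(runs)), function(i) {
    as_tibble(stream[runs[i, 1]:runs[i, 2], chans])
  })
  out <- tibble(pulse_id = seq_len(nrow(runs)),
                start = runs[, 1] - 1L,          # to 0-based half-open
                end = runs[, 2],
                n_samples = runs[, 2] - runs[, 1] + 1L,
                samples = samples)
  attr(out, "baseline") <- baseline
  out
}

empty_pulse_table <- function(stream = NULL, chans = c("I1", "I2", "I3", "I4", "F")) {
  out <- tibble(pulse_id = integer(), start = integer(), end = integer(),
                n_samples = integer(), samples = list())
  attr(out, "baseline") <- if (is.null(stream)) {
    stats::setNames(rep(0, 5), chans)
  } else vapply(stream[chans], median, 0)
  out
}

#' Convert one pulse window to a calibrated Stokes-domain trace
#'
#' Per-sample baseline-subtracted components are mapped through the
#' instrument matrix; the normalized components `q = Q/I`, `u = U/I`,
#' `v = V/I` are formed sample-wise and clipped to `[-1, 1]`. Samples whose
#' recovered intensity falls below `floor_frac` of the pulse peak are
#' excluded from all four Stokes-domain traces (division by a small `I` is
#' unstable there). The per-pulse DOP uses the intensity-weighted means of
#' `q`, `u`, `v`; `F` is the mean of the fluorescence channel over the full
#' window minus its baseline.
#'
#' @param samples Data frame of one pulse window with columns `I1..I4`,
#'   `F` (e.g. a [simulate_pulse()] record or one element of the `samples`
#'   list-column of [detect_pulses()]).
#' @param A An `instrument_matrix`.
#' @param baseline Named per-channel baseline vector (`I1..I4`, `F`);
#'   defaults to the record's own `baseline` attribute or zeros.
#' @param floor_frac Low-intensity floor as a fraction of the pulse peak.
#' @return A `stokes_trace`: a list with per-sample `I_trace`, `q_trace`,
#'   `u_trace`, `v_trace` (equal length), scalars `I_mean, q_mean, u_mean,
#'   v_mean, dop, F`, `n_samples`, and QC counters.
#' @export
to_stokes_trace <- function(samples, A, baseline = NULL, floor_frac = 0.1) {
  check_invertible(A, "`A`")
  baseline <- baseline %||% attr(samples, "baseline") %||%
    c(I1 = 0, I2 = 0, I3 = 0, I4 = 0, F = 0)
  comp <- as.matrix(samples[, c("I1", "I2", "I3", "I4")])
  comp <- sweep(comp, 2, baseline[c("I1", "I2", "I3", "I4")])
  S <- comp %*% t(unclass(A))
  I <- S[, 1]
  peak <- max(I)
  keep <- I > 0 & I >= floor_frac * peak
  if (!any(keep)) abort("empty pulse: all samples below the intensity floor.")
  I_k <- I[keep]
  q <- pmin(1, pmax(-1, S[keep, 2] / I_k))
  u <- pmin(1, pmax(-1, S[keep, 3] / I_k))
  v <- pmin(1, pmax(-1, S[keep, 4] / I_k))
  n_clip <- sum(abs(S[keep, 2:4] / I_k) > 1 + 1e-9)
  w <- I_k / sum(I_k)
  dop <- compute_dop(sum(w * q), sum(w * u), sum(w * v))
  structure(
    list(I_trace = I_k, q_trace = q, u_trace = u, v_trace = v,
         I_mean = mean(I_k), q_mean = mean(q), u_mean = mean(u),
         v_mean = mean(v), dop = as.numeric(dop),
         F = mean(samples$F) - unname(baseline["F"]),
         n_samples = sum(keep),
         qc = c(n_below_floor = sum(!keep), n_clipped = n_clip,
                dop_clipped = as.integer(attr(dop, "clipped")))),
    class = "stokes_trace")
}

#' @export
print.stokes_trace <- function(x, ...) {
  cat("<stokes_trace> ", x$n_samples, " samples\n", sep = "")
  cat(sprintf("  I = %.4g  q = %.4f  u = %.4f  v = %.4f  DOP = %.4f  F = %.4g\n",
              x$I_mean, x$q_mean, x$u_mean, x$v_mean, x$dop, x$F))
  invisible(x)
}

#' Convert a table of detected pulses to Stokes-domain traces
#'
#' Applies [to_stokes_trace()] to every row of a [detect_pulses()] table;
#' pulses whose samples all fall below the intensity floor are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param pulses Tibble from [detect_pulses()] (needs the `samples`
#'   list-column), or a list of [simulate_pulse()] records.
#' @param A An `instrument_matrix`.
#' @param baseline Optional named per-channel baseline; defaults to the
#'   table's `baseline` attribute.
#' @param floor_frac Low-intensity floor (fraction of pulse peak).
#' @return Tibble with one row per retained pulse: identifiers, the
#'   summary columns `I_mean, q_mean, u_mean, v_mean, dop, F, n_samples`,
#'   QC counts, a `trace` list-column of `stokes_trace` objects, and a
#'   `label` column when input pulses carry labels.
#' @export
stokes_traces <- function(pulses, A, baseline = NULL, floor_frac = 0.1) {
  if (is.list(pulses) && !is.data.frame(pulses)) {
    labels <- vapply(pulses, function(p) attr(p, "label") %||% NA_character_, "")
    pulses <- tibble(pulse_id = seq_along(pulses),
                     start = NA_integer_, end = NA_integer_,
                     n_samples = vapply(pulses, nrow, 0L),
                     samples = lapply(pulses, as_tibble),
                     label = labels)
    attr(pulses, "baseline") <- c(I1 = 0, I2 = 0, I3 = 0, I4 = 0, F = 0)
  }
  baseline <- baseline %||% attr(pulses, "baseline") %||%
    c(I1 = 0, I2 = 0, I3 = 0, I4 = 0, F = 0)
  traces <- lapply(pulses$samples, function(s) {
    tryCatch(to_stokes_trace(s, A, baseline = baseline,
                             floor_frac = floor_frac),
             error = function(e) NULL)
  })
  ok <- !vapply(traces, is.null, TRUE)
  traces <- traces[ok]
  kept <- pulses[ok, setdiff(names(pulses), "samples")]
  out <- dplyr::bind_cols(
    kept[setdiff(names(kept), "n_samples")],
    tibble(
      I_mean = vapply(traces, `[[`, 0, "I_mean"),
      q_mean = vapply(traces, `[[`, 0, "q_mean"),
      u_mean = vapply(traces, `[[`, 0, "u_mean"),
      v_mean = vapply(traces, `[[`, 0, "v_mean"),
      dop = vapply(traces, `[[`, 0, "dop"),
      F = vapply(traces, `[[`, 0, "F"),
      n_samples = vapply(traces, `[[`, 0L, "n_samples"),
      n_below_floor = vapply(traces, function(t) unname(t$qc["n_below_floor"]), 0),
      trace = traces))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write a per-pulse summary table as CSV
#'
#' @param traces Output of [stokes_traces()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pulse_table <- function(traces, path) {
  flat <- traces[setdiff(names(traces), "trace")]
  readr::write_csv(flat, path)
  invisible(path)
}
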