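# Pulse-shape statistics and assembly of the 38-dimensional pulse-feature
# vector (or the 6-dimensional pulse-average baseline) per particle.

#' Eight pulse-shape statistics of one trace
#'
#' Computes, for a per-sample signal `X`:
#' peak-to-peak `max(X) - min(X)`; population variance and standard
#' deviation (divide by `N`, no Bessel correction); root mean square
#' `sqrt(mean(X^2))`; skewness and kurtosis as the third and fourth
#' standardized population moments; the waveform factor `rms / mean`; and
#' the clearance factor, implemented verbatim as printed in the source
#' instrument's feature table: `peak-to-peak / mean^2`. The conventional
#' clearance factor `peak-to-peak / mean(sqrt(|X|))^2` is available with
#' `clearance = "conventional"`.
#'
#' Degenerate cases return `NA` sentinels rather than `NaN`: skewness and
#' kurtosis when the standard deviation is 0; waveform and clearance
#' factors when their denominator mean is 0.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @param clearance `"verbatim"` (default) or `"conventional"`.
#' @return One-row tibble with columns `peak, var, std, rms, sk, ku, wf,
#'   cl`.
#' @examples
#' pulse_statistics(c(1, 2, 3, 2))
#' @export
pulse_statistics <- function(x, clearance = c("verbatim", "conventional")) {
  clearance <- match.arg(clearance)
  if (length(x) < 2) abort("pulse trace must have at least 2 samples.")
  if (!all(is.finite(x))) abort("non-finite samples in pulse trace.")
  n <- length(x)
  mu <- mean(x)
  peak <- max(x) - min(x)
  m2 <- sum((x - mu)^2) / n
  std <- sqrt(m2)
  rms <- sqrt(sum(x^2) / n)
  if (std > 0) {
    sk <- (sum((x - mu)^3) / n) / std^3
    ku <- (sum((x - mu)^4) / n) / std^4
  } else {
    sk <- NA_real_
    ku <- NA_real_
  }
  if (mu != 0) {
    wf <- rms / mu
    cl <- if (clearance == "verbatim") peak / mu^2
          else peak / mean(sqrt(abs(x)))^2
  } else {
    wf <- NA_real_
    cl <- NA_real_
  }
  tibble(peak = peak, var = m2, std = std, rms = rms,
         sk = sk, ku = ku, wf = wf, cl = cl)
}

stat_suffixes <- c("peak", "var", "std", "rms", "sk", "ku", "wf", "cl")

#' Canonical feature column names
#'
#' Fixed, documented ordering of the feature vector: the six pulse
#' averages (`I_mean, q_mean, u_mean, v_mean, dop, F`) followed, in
#' pulse-feature mode, by the eight statistics of each Stokes-domain trace
#' (`I`, `q`, `u`, `v`), 38 columns in total.
#'
#' @param mode `"pfec"` (38 features) or `"pac"` (6 features).
#' @return Character vector of column names.
#' @export
feature_names <- function(mode = c("pfec", "pac")) {
  mode <- match.arg(mode)
  avg <- c("I_mean", "q_mean", "u_mean", "v_mean", "dop", "F")
  if (mode == "pac") return(avg)
  c(avg, as.vector(t(outer(c("I", "q", "u", "v"), stat_suffixes, paste,
                           sep = "_"))))
}

impute_stats <- function(s) {
  # defined-limit imputation for degenerate traces; count what was imputed
  n_imp <- sum(is.na(unlist(s)))
  if (is.na(s$sk)) s$sk <- 0
  if (is.na(s$ku)) s$ku <- 3
  if (is.na(s$wf)) s$wf <- 1
  if (is.na(s$cl)) s$cl <- 0
  list(s = s, n = n_imp)
}

#' Assemble per-particle feature vectors
#'
#' `pfec_features()` builds the 38-dimensional pulse-feature vector for
#' each trace: the six averages plus the eight [pulse_statistics()] of
#' each of the four Stokes-domain traces `I`, `q`, `u`, `v`.
#' `pac_features()` keeps only the six pulse averages. Degenerate
#' statistics (constant traces) are imputed with their defined limits
#' (skewness 0, kurtosis 3, waveform factor 1, clearance factor 0) and
#' counted in the `qc_imputed` column.
#'
#' @param traces Output of [stokes_traces()] (needs the `trace`
#'   list-column), or a single `stokes_trace`.
#' @param clearance Passed to [pulse_statistics()].
#' @return A tibble with the feature columns of [feature_names()] in fixed
#'   order, a `qc_imputed` count, and a `label` column when the input has
#'   one.
#' @export
pfec_features <- function(traces, clearance = c("verbatim", "conventional")) {
  clearance <- match.arg(clearance)
  traces <- as_trace_table(traces)
  rows <- purrr::map(traces$trace, function(tr) {
    n_imp <- 0L
    blocks <- purrr::map(
      list(I = tr$I_trace, q = tr$q_trace, u = tr$u_trace, v = tr$v_trace),
      function(x) {
        imp <- impute_stats(pulse_statistics(x, clearance = clearance))
        n_imp <<- n_imp + imp$n
        imp$s
      })
    stats <- dplyr::bind_cols(purrr::imap(blocks, function(s, nm) {
      stats::setNames(s, paste(nm, stat_suffixes, sep = "_"))
    }))
    dplyr::bind_cols(
      tibble(I_mean = tr$I_mean, q_mean = tr$q_mean, u_mean = tr$u_mean,
             v_mean = tr$v_mean, dop = tr$dop, F = tr$F),
      stats, tibble(qc_imputed = n_imp))
  })
  out <- dplyr::bind_rows(rows)
  attach_label(out[c(feature_names("pfec"), "qc_imputed")], traces)
}

#' @rdname pfec_features
#' @export
pac_features <- function(traces) {
  traces <- as_trace_table(traces)
  out <- tibble(
    I_mean = vapply(traces$trace, `[[`, 0, "I_mean"),
    q_mean = vapply(traces$trace, `[[`, 0, "q_mean"),
    u_mean = vapply(traces$trace, `[[`, 0, "u_mean"),
    v_mean = vapply(traces$trace, `[[`, 0, "v_mean"),
    dop = vapply(traces$trace, `[[`, 0, "dop"),
    F = vapply(traces$trace, `[[`, 0, "F"))
  attach_label(out, traces)
}

as_trace_table <- function(traces) {
  if (inherits(traces, "stokes_trace")) {
    return(tibble(trace = list(traces)))
  }
  if (!is.data.frame(traces) || !"trace" %in% names(traces))
    abort("`traces` must be a stokes_traces() table or a single stokes_trace.")
  traces
}

attach_label <- function(out, traces) {
  if ("label" %in% names(traces)) out$label <- traces$label
  out
}

#' Write / read a feature table as CSV
#'
#' @param features Feature tibble from [pfec_features()] or
#'   [pac_features()].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
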