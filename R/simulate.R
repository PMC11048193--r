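# Synthetic signal generator: forward model of the five-channel prototype
# (four polarization channels + fluorescence) at the level of pulses and
# time series, with a known ground-truth instrument matrix.

#' Unit-peak transit envelope
#'
#' Generalized-Gaussian bell `exp(-|t/s|^flatness)` with side-dependent
#' scale (asymmetry = log-ratio of trailing to leading scale), sampled at
#' `n` equally spaced points over the support where the envelope exceeds
#' 5 % of its peak.
#'
#' @param n Number of samples (>= 3).
#' @param flatness Positive exponent; 2 is a Gaussian bell, larger values
#'   flatten the top, values below 1 sharpen it into a cusp.
#' @param asymmetry Log-ratio of trailing to leading scale; 0 is symmetric.
#' @return Numeric vector of length `n` with maximum 1.
#' @export
gg_envelope <- function(n, flatness = 2, asymmetry = 0) {
  stopifnot(n >= 3, flatness > 0, is.finite(asymmetry))
  s_lead <- exp(-asymmetry / 2)
  s_trail <- exp(asymmetry / 2)
  half_width <- log(20)^(1 / flatness)     # exp(-x^flatness) = 0.05
  t <- seq(-s_lead * half_width, s_trail * half_width, length.out = n)
  s <- ifelse(t < 0, s_lead, s_trail)
  exp(-abs(t / s)^flatness)
}

check_invertible <- function(A, what = "instrument matrix") {
  A <- unclass(A)
  if (!is.matrix(A) || any(dim(A) != 4L) || !all(is.finite(A)))
    abort(paste0(what, " must be a finite 4x4 matrix."))
  if (rcond(A) < 1e-12)
    abort(paste0(what, " is numerically singular."))
  invisible(A)
}

# one particle's noise-free channel-space pulse (internal workhorse)
synth_pulse <- function(archetype, A_inv_true) {
  shp <- archetype$shape
  n <- max(3L, as.integer(round(rnorm(1, shp$width_mean, shp$width_sd))))
  amp <- archetype$mean_stokes[1] * exp(rnorm(1, 0, archetype$stokes_dispersion[1]))
  quv <- archetype$mean_stokes[2:4] + rnorm(3, 0, archetype$stokes_dispersion[2:4])
  nrm <- sqrt(sum(quv^2))
  if (nrm > 1) quv <- quv / nrm           # clip to the physical ball
  flevel <- archetype$fluorescence_level *
    exp(rnorm(1, 0, archetype$fluorescence_dispersion))
  env <- gg_envelope(n, flatness = shp$flatness, asymmetry = shp$asymmetry)
  intensity <- amp * env
  S <- rbind(intensity, quv[1] * intensity, quv[2] * intensity,
             quv[3] * intensity)
  list(channels = A_inv_true %*% S,    # 4 x n, measured-component space
       fluor = flevel * intensity,
       n = n, quv = quv, amp = amp)
}

#' Simulate a single particle transit
#'
#' Forward model of one pulse: a bell-shaped intensity envelope with
#' per-particle Stokes components drawn around the archetype mean, mapped
#' into measured-channel space through the inverse of the true instrument
#' matrix, with multiplicative log-normal channel noise. The fluorescence
#' channel is the intensity envelope scaled by the particle's fluorescence
#' level.
#'
#' @param archetype A [species_archetype()].
#' @param A_true True instrument matrix (4x4, invertible); default the
#'   ideal analyzer of [default_instrument_matrix()].
#' @param noise_level Nonnegative relative noise scale (log-normal sigma).
#' @param seed Optional integer seed (local RNG; caller's stream untouched).
#' @return A `pfec_pulse`: a tibble with columns `I1..I4`, `F` and
#'   attributes `label`, `baseline` (0), and `truth` (the drawn amplitude,
#'   normalized Stokes components and width).
#' @examples
#' a <- species_archetype("x", c(1, 0.5, 0, 0), stokes_dispersion = rep(0, 4))
#' p <- simulate_pulse(a, noise_level = 0, seed = 1)
#' @export
simulate_pulse <- function(archetype, A_true = default_instrument_matrix(),
                           noise_level = 0.02, seed = NULL) {
  stopifnot(inherits(archetype, "species_archetype"))
  if (noise_level < 0) abort("`noise_level` must be >= 0.")
  check_invertible(A_true, "`A_true`")
  A_inv <- solve(unclass(A_true))
  with_seed_or_local(seed, {
    p <- synth_pulse(archetype, A_inv)
    ch <- p$channels * exp(matrix(rnorm(length(p$channels), 0, noise_level),
                                  nrow = 4))
    fl <- p$fluor * exp(rnorm(p$n, 0, noise_level))
    out <- tibble(I1 = ch[1, ], I2 = ch[2, ], I3 = ch[3, ], I4 = ch[4, ],
                  F = fl)
    structure(out,
              label = archetype$label,
              baseline = c(I1 = 0, I2 = 0, I3 = 0, I4 = 0, F = 0),
              truth = list(amplitude = p$amp, quv = p$quv, width = p$n),
              class = c("pfec_pulse", class(out)))
  })
}

#' Simulate a raw five-channel signal stream
#'
#' Particles arrive as a Poisson process; each particle's category is drawn
#' from `mixture`, its pulse synthesized by the forward model and placed at
#' a uniform position. A constant baseline is added to every channel and
#' multiplicative log-normal noise applied to the assembled record. The
#' ground-truth intervals and labels are returned alongside.
#'
#' @param panel Named list of [species_archetype()] objects.
#' @param mixture Probability vector over the panel (must sum to 1);
#'   default uniform.
#' @param duration Record length in samples.
#' @param arrival_rate Expected particles per sample; the expected
#'   occupancy `arrival_rate * mean width` must stay below 1
#'   (single-particle regime).
#' @param A_true,noise_level As in [simulate_pulse()].
#' @param baseline_level Additive per-channel baseline (detector units).
#' @param coincidence If `FALSE` (default) pulses are placed without
#'   overlap; `TRUE` allows coincident particles as a stress condition.
#' @param seed Optional integer seed.
#' @return A `pfec_stream`: a tibble with columns `t`, `I1..I4`, `F` and a
#'   `truth` attribute (tibble `start`, `end`, `label`; 0-based half-open
#'   sample intervals), retrievable with [stream_truth()].
#' @export
simulate_stream <- function(panel, mixture = NULL, duration = 50000,
                            arrival_rate = 0.002,
                            A_true = default_instrument_matrix(),
                            noise_level = 0.02, baseline_level = 0.05,
                            coincidence = FALSE, seed = NULL) {
  stopifnot(length(panel) >= 1)
  lapply(panel, function(a) stopifnot(inherits(a, "species_archetype")))
  if (duration <= 0) abort("`duration` must be positive.")
  if (noise_level < 0) abort("`noise_level` must be >= 0.")
  mixture <- mixture %||% rep(1 / length(panel), length(panel))
  if (length(mixture) != length(panel))
    abort("`mixture` must have one probability per archetype.")
  if (abs(sum(mixture) - 1) > 1e-6) abort("`mixture` must sum to 1.")
  mean_width <- mean(vapply(panel, function(a) a$shape$width_mean, 0))
  if (arrival_rate * mean_width >= 1)
    abort("expected occupancy >= 1; lower `arrival_rate` (single-particle regime).")
  check_invertible(A_true, "`A_true`")
  A_inv <- solve(unclass(A_true))
  duration <- as.integer(duration)

  with_seed_or_local(seed, {
    n_particles <- rpois(1, arrival_rate * duration)
    ch <- matrix(0, nrow = 5, ncol = duration)   # I1..I4, F
    occupied <- logical(duration)
    truth <- list()
    if (n_particles > 0) {
      labels <- sample(names(panel), n_particles, replace = TRUE,
                       prob = mixture)
      for (k in seq_len(n_particles)) {
        p <- synth_pulse(panel[[labels[k]]], A_inv)
        placed <- FALSE
        for (try in 1:50) {
          start <- sample.int(duration - p$n + 1L, 1L) - 1L  # 0-based
          idx <- (start + 1L):(start + p$n)
          if (coincidence || !any(occupied[idx])) { placed <- TRUE; break }
        }
        if (!placed) next                      # crowded record: drop
        occupied[idx] <- TRUE
        ch[1:4, idx] <- ch[1:4, idx] + p$channels
        ch[5, idx] <- ch[5, idx] + p$fluor
        truth[[length(truth) + 1L]] <-
          tibble(start = start, end = start + p$n, label = labels[k])
      }
    }
    ch <- ch + baseline_level
    ch <- ch * exp(matrix(rnorm(length(ch), 0, noise_level), nrow = 5))
    truth_tbl <- if (length(truth)) {
      dplyr::arrange(dplyr::bind_rows(truth), .data$start)
    } else {
      tibble(start = integer(), end = integer(), label = character())
    }
    out <- tibble(t = seq_len(duration) - 1L,
                  I1 = ch[1, ], I2 = ch[2, ], I3 = ch[3, ], I4 = ch[4, ],
                  F = ch[5, ])
    structure(out, truth = truth_tbl, sample_rate = 1,
              class = c("pfec_stream", class(out)))
  })
}

#' Ground-truth particle table of a simulated stream
#' @param stream A `pfec_stream`.
#' @return Tibble with columns `start`, `end` (0-based half-open) and
#'   `label`.
#' @export
stream_truth <- function(stream) {
  attr(stream, "truth") %||%
    tibble(start = integer(), end = integer(), label = character())
}

#' Simulate a polarimeter calibration set
#'
#' Emulates the calibration procedure: a set of reference incident Stokes
#' states (as read by a reference polarimeter) is measured through the
#' inverse of the true instrument matrix, with multiplicative Gaussian
#' channel noise. The first four canonical states span rank 4 by
#' construction; extra states beyond eight are random partially polarized
#' states.
#'
#' @param A_true True 4x4 instrument matrix.
#' @param n_states Number of calibration states (>= 4).
#' @param noise_level Relative noise standard deviation (e.g. 0.005 for
#'   0.5 % channel noise).
#' @param seed Optional integer seed.
#' @return A `pfec_calibration` tibble with one row per state and columns
#'   `S_I, S_Q, S_U, S_V` (reference Stokes) and `I1..I4` (measured
#'   components).
#' @export
simulate_calibration_set <- function(A_true = default_instrument_matrix(),
                                     n_states = 8, noise_level = 0.005,
                                     seed = NULL) {
  if (n_states < 4) abort("at least 4 calibration states are required.")
  if (noise_level < 0) abort("`noise_level` must be >= 0.")
  check_invertible(A_true, "`A_true`")
  A_inv <- solve(unclass(A_true))
  canonical <- rbind(
    c(1, 0, 0, 0),    # unpolarized
    c(1, 1, 0, 0),    # horizontal
    c(1, 0, 1, 0),    # +45 linear
    c(1, 0, 0, 1),    # right circular
    c(1, -1, 0, 0),   # vertical
    c(1, 0, -1, 0),   # -45 linear
    c(1, 0, 0, -1),   # left circular
    c(1, 0.5, 0.3, 0.2))  # partially polarized
  with_seed_or_local(seed, {
    S <- canonical[seq_len(min(n_states, 8L)), , drop = FALSE]
    while (nrow(S) < n_states) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      S <- rbind(S, c(1, runif(1, 0.2, 0.9) * dir))
    }
    M <- A_inv %*% t(S)                          # 4 x n measured components
    M <- M * (1 + matrix(rnorm(length(M), 0, noise_level), nrow = 4))
    out <- tibble(S_I = S[, 1], S_Q = S[, 2], S_U = S[, 3], S_V = S[, 4],
                  I1 = M[1, ], I2 = M[2, ], I3 = M[3, ], I4 = M[4, ])
    structure(out, class = c("pfec_calibration", class(out)))
  })
}

#' Write / read a simulated stream as CSV with a truth sidecar
#'
#' The stream is stored as plain CSV with columns `t, I1, I2, I3, I4, F`;
#' the ground-truth particle table goes to a sidecar CSV
#' (`<path>.truth.csv` by default) with columns `start, end, label`.
#'
#' @param stream A `pfec_stream`.
#' @param path Output CSV path.
#' @param truth_path Sidecar path, or `NULL` to skip the sidecar.
#' @return `write_stream_csv()` returns `path` invisibly;
#'   `read_stream_csv()` returns a `pfec_stream`.
#' @export
write_stream_csv <- function(stream, path,
                             truth_path = paste0(path, ".truth.csv")) {
  readr::write_csv(as_tibble(stream), path)
  if (!is.null(truth_path)) readr::write_csv(stream_truth(stream), truth_path)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path, truth_path = paste0(path, ".truth.csv")) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(t = "i", .default = "d"))
  need <- c("t", "I1", "I2", "I3", "I4", "F")
  if (!all(need %in% names(out)))
    abort("stream CSV must have columns t, I1, I2, I3, I4, F.")
  truth <- NULL
  if (!is.null(truth_path) && file.exists(truth_path)) {
    truth <- readr::read_csv(truth_path, show_col_types = FALSE,
                             col_types = readr::cols(start = "i", end = "i",
                                                     label = "c"))
  }
  structure(out, truth = truth, sample_rate = 1,
            class = c("pfec_stream", class(out)))
}
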