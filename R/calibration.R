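# Stokes calibration: estimate and apply the 4x4 instrument matrix A that
# maps measured polarization components [I1, I2, I3, I4] to the Stokes
# vector (I, Q, U, V).

#' Ideal instrument matrix of a division-of-amplitude analyzer
#'
#' The reference design splits the collected light so that the four
#' channels measure `(I+Q)/2`, `(I-Q)/2`, `(I+U)/2`, `(I+V)/2`; the
#' instrument matrix is the inverse of that measurement map. Useful as a
#' well-conditioned ground truth for the simulator and as a default
#' calibration-free matrix.
#'
#' @return An `instrument_matrix` (4x4).
#' @export
default_instrument_matrix <- function() {
  M <- 0.5 * rbind(c(1, 1, 0, 0),
                   c(1, -1, 0, 0),
                   c(1, 0, 1, 0),
                   c(1, 0, 0, 1))
  new_instrument_matrix(solve(M), n_states = NA_integer_)
}

#' Draw a random well-conditioned instrument matrix
#'
#' Rejection-samples a 4x4 standard-normal matrix until its condition
#' number falls below `max_condition`. Used as a ground truth in
#' calibration simulation studies.
#'
#' @param max_condition Upper bound on the 2-norm condition number.
#' @param seed Optional integer seed.
#' @return An `instrument_matrix`.
#' @export
random_instrument_matrix <- function(max_condition = 50, seed = NULL) {
  stopifnot(max_condition > 1)
  with_seed_or_local(seed, {
    repeat {
      A <- matrix(rnorm(16), 4)
      if (kappa(A, exact = TRUE) < max_condition)
        return(new_instrument_matrix(A))
    }
  })
}

new_instrument_matrix <- function(A, n_states = NA_integer_) {
  A <- unclass(A)
  dimnames(A) <- list(c("I", "Q", "U", "V"), c("I1", "I2", "I3", "I4"))
  structure(A, condition_number = kappa(A, exact = TRUE),
            n_states = n_states, class = "instrument_matrix")
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat("<instrument_matrix>  condition number ",
      signif(attr(x, "condition_number"), 4), sep = "")
  ns <- attr(x, "n_states")
  if (!is.na(ns)) cat(", estimated from ", ns, " states", sep = "")
  cat("\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Estimate the instrument matrix from a calibration set
#'
#' Solves for the matrix `A` minimizing the least-squares misfit between
#' the reference Stokes vectors and `A` applied to the measured components,
#' over all calibration states. With exactly four states this reduces to
#' the plain matrix inverse relation `A = S_ref %*% solve(M)`; with more
#' states the Moore-Penrose least-squares solution is used.
#'
#' @param cal A `pfec_calibration` tibble (columns `S_I..S_V`, `I1..I4`)
#'   as produced by [simulate_calibration_set()], or any data frame with
#'   those columns.
#' @param condition_cap Error if the estimated matrix's condition number
#'   exceeds this cap (default `1e6`).
#' @return An `instrument_matrix` with attributes `condition_number` and
#'   `n_states`.
#' @export
estimate_instrument_matrix <- function(cal, condition_cap = 1e6) {
  need <- c("S_I", "S_Q", "S_U", "S_V", "I1", "I2", "I3", "I4")
  if (!all(need %in% names(cal)))
    abort("calibration set needs columns S_I..S_V and I1..I4.")
  if (nrow(cal) < 4) abort("at least 4 calibration states are required.")
  S <- t(as.matrix(cal[, c("S_I", "S_Q", "S_U", "S_V")]))   # 4 x n
  M <- t(as.matrix(cal[, c("I1", "I2", "I3", "I4")]))       # 4 x n
  if (!all(is.finite(S)) || !all(is.finite(M)))
    abort("calibration set contains non-finite values.")
  if (qr(M)$rank < 4) abort("degenerate calibration states: rank < 4.")
  # A = S M^T (M M^T)^-1  -- normal equations of min ||S - A M||_F
  G <- M %*% t(M)
  A <- S %*% t(M) %*% solve(G)
  A <- new_instrument_matrix(A, n_states = nrow(cal))
  if (attr(A, "condition_number") > condition_cap)
    abort("estimated instrument matrix exceeds the condition-number cap.")
  A
}

#' Apply the instrument matrix to measured components
#'
#' Maps measured polarization components to Stokes vectors,
#' `S = A %*% c(I1, I2, I3, I4)`, one row per sample. Rows with
#' non-positive recovered total intensity are flagged non-physical; rows
#' whose polarized magnitude exceeds the total intensity can optionally be
#' projected back onto the physical ball `Q^2 + U^2 + V^2 <= I^2`.
#'
#' @param A An `instrument_matrix` (or plain invertible 4x4 matrix).
#' @param components Numeric length-4 vector, or a matrix / data frame
#'   with columns `I1..I4` (one row per sample).
#' @param project If `TRUE` (default), clip `(Q, U, V)` of super-physical
#'   rows to the ball of radius `I`.
#' @return A tibble with columns `I, Q, U, V`, `physical` (logical) and
#'   `clipped` (logical QC flag).
#' @export
apply_instrument_matrix <- function(A, components, project = TRUE) {
  check_invertible(A, "`A`")
  if (is.data.frame(components)) {
    components <- as.matrix(components[, c("I1", "I2", "I3", "I4")])
  } else if (is.null(dim(components))) {
    stopifnot(length(components) == 4L)
    components <- matrix(components, nrow = 1)
  }
  if (!all(is.finite(components))) abort("non-finite components.")
  S <- components %*% t(unclass(A))                   # n x 4
  I <- S[, 1]
  pol <- sqrt(S[, 2]^2 + S[, 3]^2 + S[, 4]^2)
  physical <- I > 0
  clipped <- physical & pol > I
  if (project && any(clipped)) {
    f <- I[clipped] / pol[clipped]
    S[clipped, 2:4] <- S[clipped, 2:4] * f
  }
  tibble(I = S[, 1], Q = S[, 2], U = S[, 3], V = S[, 4],
         physical = physical, clipped = clipped)
}

#' Persist an instrument matrix as JSON with metadata
#'
#' @param A An `instrument_matrix`.
#' @param path Output path.
#' @return `write_instrument_matrix()` returns `path` invisibly;
#'   `read_instrument_matrix()` returns an `instrument_matrix`.
#' @export
write_instrument_matrix <- function(A, path) {
  stopifnot(inherits(A, "instrument_matrix"))
  jsonlite::write_json(
    list(dim = dim(unclass(A)),
         A = as.vector(unclass(A)),   # column-major
         condition_number = attr(A, "condition_number"),
         n_states = attr(A, "n_states"),
         date = format(Sys.Date())),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_instrument_matrix
#' @export
read_instrument_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(as.numeric(unlist(obj$A)), nrow = 4)
  out <- new_instrument_matrix(A, n_states = obj$n_states %||% NA_integer_)
  out
}

#' @method tidy instrument_matrix
#' @export
tidy.instrument_matrix <- function(x, ...) {
  A <- unclass(x)
  tibble(stokes = rep(rownames(A), times = 4),
         channel = rep(colnames(A), each = 4),
         value = as.vector(A))
}
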