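#' Define a species archetype for the signal simulator
#'
#' An archetype is a phenomenological description of how one particle
#' category scatters polarized light: its mean Stokes response, the spread
#' of that response across individual particles, the statistics of the
#' transit-pulse envelope, and its fluorescence yield. Archetypes stand in
#' for biological variety (phyla, species, sediments, microplastics); they
#' encode no optical physics.
#'
#' @param label Category name (e.g. `"Cyanophyta"`).
#' @param mean_stokes Numeric length-4 vector `(I, q, u, v)`: `I` is the
#'   peak-amplitude scale in detector units (> 0); `q`, `u`, `v` are the
#'   mean normalized polarization components, each in `[-1, 1]` with
#'   `q^2 + u^2 + v^2 <= 1`.
#' @param stokes_dispersion Numeric length-4 nonnegative vector: particle-
#'   to-particle spread. Component 1 is the log-scale standard deviation of
#'   the peak amplitude (log-normal); components 2-4 are normal standard
#'   deviations of `q`, `u`, `v` (draws are clipped back to the physical
#'   ball).
#' @param shape List of transit-envelope parameters:
#'   \describe{
#'     \item{width_mean}{mean pulse width in samples (>= 3), measured across
#'       the support where the envelope exceeds 5 % of its peak;}
#'     \item{width_sd}{standard deviation of the width across particles;}
#'     \item{asymmetry}{log-ratio of the trailing to leading envelope scale
#'       (0 = time-symmetric bell);}
#'     \item{flatness}{exponent of the generalized-Gaussian bell
#'       `exp(-|t/s|^flatness)`: 2 is a Gaussian bell, large values give a
#'       flat-topped transit, values below 1 a cusp-like spike.}
#'   }
#' @param fluorescence_level Nonnegative mean fluorescence relative to the
#'   particle's scattered intensity (the fluorescence trace is this factor
#'   times the intensity envelope).
#' @param fluorescence_dispersion Nonnegative relative spread of the
#'   fluorescence level across particles.
#'
#' @return An object of class `species_archetype` (a validated list).
#' @examples
#' a <- species_archetype("Cyanophyta", mean_stokes = c(5, 0.35, 0.10, 0.05))
#' a
#' @export
species_archetype <- function(label,
                              mean_stokes,
                              stokes_dispersion = c(0.2, 0.03, 0.03, 0.03),
                              shape = list(width_mean = 60, width_sd = 15,
                                           asymmetry = 0, flatness = 2),
                              fluorescence_level = 0.5,
                              fluorescence_dispersion = 0.1) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  mean_stokes <- as.numeric(mean_stokes)
  stokes_dispersion <- as.numeric(stokes_dispersion)
  if (length(mean_stokes) != 4L || !all(is.finite(mean_stokes)))
    abort("`mean_stokes` must be a finite numeric 4-vector (I, q, u, v).")
  if (mean_stokes[1] <= 0)
    abort("`mean_stokes[1]` (intensity amplitude scale) must be > 0.")
  quv <- mean_stokes[2:4]
  if (any(abs(quv) > 1) || sum(quv^2) > 1 + 1e-12)
    abort("mean (q, u, v) must lie in the unit ball: q^2 + u^2 + v^2 <= 1.")
  if (length(stokes_dispersion) != 4L || any(stokes_dispersion < 0))
    abort("`stokes_dispersion` must be four nonnegative numbers.")
  shp <- utils::modifyList(
    list(width_mean = 60, width_sd = 15, asymmetry = 0, flatness = 2),
    as.list(shape))
  if (shp$width_mean < 3) abort("mean pulse width must be >= 3 samples.")
  if (shp$width_sd < 0) abort("width dispersion must be >= 0.")
  if (shp$flatness <= 0) abort("envelope flatness exponent must be > 0.")
  if (fluorescence_level < 0 || fluorescence_dispersion < 0)
    abort("fluorescence level and dispersion must be >= 0.")
  structure(
    list(label = label,
         mean_stokes = mean_stokes,
         stokes_dispersion = stokes_dispersion,
         shape = shp,
         fluorescence_level = fluorescence_level,
         fluorescence_dispersion = fluorescence_dispersion),
    class = "species_archetype")
}

#' @export
print.species_archetype <- function(x, ...) {
  cat("<species_archetype> ", x$label, "\n", sep = "")
  cat("  mean Stokes (I, q, u, v): ",
      paste(signif(x$mean_stokes, 4), collapse = ", "), "\n", sep = "")
  cat("  envelope: width ", x$shape$width_mean, " +/- ", x$shape$width_sd,
      " samples, asymmetry ", x$shape$asymmetry,
      ", flatness ", x$shape$flatness, "\n", sep = "")
  cat("  fluorescence level: ", x$fluorescence_level, "\n", sep = "")
  invisible(x)
}

#' Built-in demonstration archetype panel
#'
#' Four categories loosely emulating the monitoring setting: two
#' phytoplankton phyla with distinct polarization signatures, one
#' cyanobacteria category with high fluorescence, and a non-algal
#' suspended-particulate category with low fluorescence. Parameter values
#' are illustrative defaults for the simulator, not measured quantities.
#'
#' @return A named list of [species_archetype()] objects.
#' @export
demo_panel <- function() {
  list(
    Chlorophyta = species_archetype(
      "Chlorophyta", mean_stokes = c(6, 0.45, 0.15, 0.05),
      stokes_dispersion = c(0.25, 0.04, 0.04, 0.03),
      shape = list(width_mean = 70, width_sd = 18, asymmetry = 0.3,
                   flatness = 2),
      fluorescence_level = 0.6, fluorescence_dispersion = 0.12),
    Bacillariophyta = species_archetype(
      "Bacillariophyta", mean_stokes = c(9, 0.10, 0.40, 0.10),
      stokes_dispersion = c(0.25, 0.04, 0.04, 0.03),
      shape = list(width_mean = 90, width_sd = 22, asymmetry = 0,
                   flatness = 4),
      fluorescence_level = 0.45, fluorescence_dispersion = 0.12),
    Cyanophyta = species_archetype(
      "Cyanophyta", mean_stokes = c(4, 0.30, -0.20, 0.15),
      stokes_dispersion = c(0.25, 0.04, 0.04, 0.03),
      shape = list(width_mean = 50, width_sd = 12, asymmetry = 0.5,
                   flatness = 1.2),
      fluorescence_level = 1.0, fluorescence_dispersion = 0.15),
    other_SPM = species_archetype(
      "other_SPM", mean_stokes = c(12, 0.65, 0.05, -0.05),
      stokes_dispersion = c(0.35, 0.05, 0.05, 0.04),
      shape = list(width_mean = 40, width_sd = 15, asymmetry = 0,
                   flatness = 2.5),
      fluorescence_level = 0.05, fluorescence_dispersion = 0.3))
}

#' Archetype panel with identical average signatures but different pulse shapes
#'
#' Constructs categories whose six pulse-average quantities
#' (mean intensity, mean q/u/v, DOP, fluorescence) are matched by design,
#' while the transit-envelope shapes differ (flat-topped, Gaussian and
#' cusp-like bells). Peak amplitudes are rescaled by each envelope's form
#' factor so the mean in-pulse intensity is equal across categories. On
#' such a panel the pulse-average feature set carries no class information
#' and only the pulse-shape statistics can discriminate.
#'
#' @param flatness Numeric vector of envelope flatness exponents, one per
#'   category (default three categories: flat-top, Gaussian, spike).
#' @param mean_intensity Target mean in-pulse intensity (detector units).
#' @param quv Shared mean normalized polarization components.
#' @param floor_frac In-pulse intensity floor used when computing the form
#'   factor; keep equal to the floor used downstream (default 0.1).
#' @param fluorescence Target mean fluorescence relative to
#'   `mean_intensity` (shared across categories).
#' @return Named list of [species_archetype()] objects.
#' @export
shape_contrast_panel <- function(flatness = c(8, 2, 0.8),
                                 mean_intensity = 5,
                                 quv = c(0.3, 0.2, 0.1),
                                 floor_frac = 0.1,
                                 fluorescence = 0.5) {
  stopifnot(length(flatness) >= 2, all(flatness > 0))
  labs <- paste0("shape", seq_along(flatness))
  panel <- lapply(seq_along(flatness), function(i) {
    # form factors of the unit-peak envelope on a fine deterministic grid:
    # over the above-floor samples (the intensity average downstream) and
    # over the full window (the fluorescence average downstream)
    env <- gg_envelope(2001L, flatness = flatness[i], asymmetry = 0)
    ff_floor <- mean(env[env >= floor_frac * max(env)])
    ff_full <- mean(env)
    amp <- mean_intensity / ff_floor
    species_archetype(
      labs[i],
      mean_stokes = c(amp, quv),
      stokes_dispersion = c(0.2, 0.03, 0.03, 0.03),
      shape = list(width_mean = 60, width_sd = 12, asymmetry = 0,
                   flatness = flatness[i]),
      fluorescence_level = fluorescence * mean_intensity / (amp * ff_full),
      fluorescence_dispersion = 0.08)
  })
  stats::setNames(panel, labs)
}

#' Read or write an archetype panel as YAML
#'
#' Panels are stored as a named map of archetype definitions so that
#' simulation studies are fully described by a text config.
#'
#' @param path File path.
#' @param panel Named list of [species_archetype()] objects.
#' @return `read_archetype_panel()` returns a named list of archetypes;
#'   `write_archetype_panel()` returns `path` invisibly.
#' @export
read_archetype_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) abort("empty archetype panel.")
  out <- lapply(names(raw), function(nm) {
    a <- raw[[nm]]
    species_archetype(
      label = a$label %||% nm,
      mean_stokes = unlist(a$mean_stokes),
      stokes_dispersion = unlist(a$stokes_dispersion %||%
                                   c(0.2, 0.03, 0.03, 0.03)),
      shape = a$shape %||% list(),
      fluorescence_level = a$fluorescence_level %||% 0.5,
      fluorescence_dispersion = a$fluorescence_dispersion %||% 0.1)
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_archetype_panel
#' @export
write_archetype_panel <- function(panel, path) {
  stopifnot(length(panel) > 0)
  ser <- lapply(panel, function(a) {
    stopifnot(inherits(a, "species_archetype"))
    list(label = a$label,
         mean_stokes = as.numeric(a$mean_stokes),
         stokes_dispersion = as.numeric(a$stokes_dispersion),
         shape = a$shape,
         fluorescence_level = a$fluorescence_level,
         fluorescence_dispersion = a$fluorescence_dispersion)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
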