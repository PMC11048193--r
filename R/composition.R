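# Sample-level reporting: composition proportions, phylum renormalization,
# dominant / common species labels, and the correlation statistic.

#' Summarize per-particle predictions into sample compositions
#'
#' Counts predicted categories within each sample and converts them to
#' proportions (summing to 1 per sample), in a fixed category order.
#'
#' @param predictions Data frame of classified particles with a sample
#'   identifier column and a predicted-label column.
#' @param sample_col,label_col Column names (defaults `"sample_id"`,
#'   `"label"`).
#' @param categories Fixed category order; default the sorted labels
#'   observed.
#' @return A `pfec_composition` tibble with columns `sample_id`,
#'   `category`, `n`, `proportion` (every sample x category pair present,
#'   zeros included).
#' @export
summarize_composition <- function(predictions, sample_col = "sample_id",
                                  label_col = "label", categories = NULL) {
  if (nrow(predictions) == 0) abort("empty prediction table.")
  if (!all(c(sample_col, label_col) %in% names(predictions)))
    abort("prediction table needs sample and label columns.")
  lab <- as.character(predictions[[label_col]])
  categories <- categories %||% sort(unique(lab))
  if (!all(lab %in% categories)) abort("labels outside `categories`.")
  out <- tibble(sample_id = as.character(predictions[[sample_col]]),
                category = factor(lab, categories)) |>
    dplyr::count(.data$sample_id, .data$category, .drop = FALSE,
                 name = "n") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = as.character(.data$category))
  structure(out, class = c("pfec_composition", class(out)))
}

#' Drop categories and renormalize the remaining proportions
#'
#' Removes the given categories (typically non-algal suspended matter)
#' from a composition and rescales the retained proportions to sum to 1
#' per sample, preserving their ratios.
#'
#' @param comp A `pfec_composition` (or tibble with `sample_id`,
#'   `category`, `proportion`).
#' @param drop Character vector of categories to remove.
#' @return A `pfec_composition` over the retained categories.
#' @export
renormalize_phyla <- function(comp, drop = "other_SPM") {
  stopifnot(all(c("sample_id", "category", "proportion") %in% names(comp)))
  kept <- dplyr::filter(as_tibble(comp), !.data$category %in% drop)
  if (nrow(kept) == 0) abort("no retained categories.")
  tot <- dplyr::summarise(dplyr::group_by(kept, .data$sample_id),
                          total = sum(.data$proportion))
  if (any(tot$total <= 0))
    abort("all retained proportions are zero in at least one sample.")
  out <- kept |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$proportion / sum(.data$proportion)) |>
    dplyr::ungroup()
  structure(out, class = c("pfec_composition", class(as_tibble(out))))
}

#' Dominant / common species labels
#'
#' Applies the field thresholds over the microalgae + cyanobacteria pool:
#' a species is *dominant* when its proportion strictly exceeds 10 % of
#' the pool, *common* when it lies in the inclusive 1 %-10 % range, and
#' *neither* below 1 %. The boundaries 1 % and 10 % both map to *common*.
#'
#' @param species_proportions Named numeric vector, or a data frame with
#'   `species` and `proportion` columns; proportions are fractions of the
#'   total microalgae + cyanobacteria and must be nonnegative with sum
#'   <= 1 (+ tolerance).
#' @return Tibble with columns `species`, `proportion`, `status`
#'   (`"dominant"`, `"common"` or `"neither"`).
#' @export
label_dominance <- function(species_proportions) {
  if (is.data.frame(species_proportions)) {
    sp <- species_proportions$species
    p <- species_proportions$proportion
  } else {
    sp <- names(species_proportions)
    p <- as.numeric(species_proportions)
  }
  if (length(p) == 0)
    return(tibble(species = character(), proportion = numeric(),
                  status = character()))
  if (any(p < 0)) abort("negative proportions.")
  if (sum(p) > 1 + 1e-9) abort("proportions sum above 1.")
  status <- dplyr::case_when(p > 0.10 ~ "dominant",
                             p >= 0.01 ~ "common",
                             TRUE ~ "neither")
  tibble(species = sp, proportion = p, status = status)
}

#' Dominance grid across samples
#'
#' Formats per-sample dominance labels as the conventional grid:
#' `+++` dominant, `++` common, blank otherwise.
#'
#' @param labels Tibble with columns `sample_id`, `species`, `status`.
#' @return A wide tibble, one row per species, one column per sample.
#' @export
dominance_grid <- function(labels) {
  stopifnot(all(c("sample_id", "species", "status") %in% names(labels)))
  labels |>
    dplyr::mutate(mark = dplyr::case_when(
      .data$status == "dominant" ~ "+++",
      .data$status == "common" ~ "++",
      TRUE ~ "")) |>
    dplyr::select("species", "sample_id", "mark") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "mark",
                       values_fill = "")
}

#' Pearson correlation coefficient
#'
#' `r = Cov(x, y) / sqrt(Var(x) Var(y))` with population (1/n) moments;
#' the ratio is identical under the sample-moment convention. Values near
#' +1 indicate strong positive linear association, near -1 strong
#' negative association.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), each with positive
#'   variance.
#' @return A `pfec_correlation` list with `r`, `n`, `cov`, `var_x`,
#'   `var_y`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch.")
  if (length(x) < 3) abort("need at least 3 pairs.")
  if (!all(is.finite(x), is.finite(y))) abort("non-finite values.")
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / n
  vx <- sum((x - mean(x))^2) / n
  vy <- sum((y - mean(y))^2) / n
  if (vx == 0 || vy == 0) abort("zero variance: correlation undefined.")
  structure(list(r = cv / sqrt(vx * vy), n = n, cov = cv,
                 var_x = vx, var_y = vy),
            class = "pfec_correlation")
}

#' @export
print.pfec_correlation <- function(x, ...) {
  cat(sprintf("<pfec_correlation> r = %.4f (n = %d)\n", x$r, x$n))
  invisible(x)
}

#' @method glance pfec_correlation
#' @export
glance.pfec_correlation <- function(x, ...) {
  tibble(r = x$r, n = x$n, cov = x$cov, var_x = x$var_x, var_y = x$var_y)
}

#' Write a composition table as CSV (sites by categories)
#'
#' @param comp A `pfec_composition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(comp, path) {
  wide <- as_tibble(comp) |>
    dplyr::select("sample_id", "category", "proportion") |>
    tidyr::pivot_wider(names_from = "category", values_from = "proportion")
  readr::write_csv(wide, path)
  invisible(path)
}
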