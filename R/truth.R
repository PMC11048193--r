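# Matching detected pulses against a simulator ground-truth table.

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Match detected pulses to ground-truth particles
#'
#' Each detected pulse is assigned the label of the truth interval it
#' overlaps most (ties to the earlier interval); pulses overlapping no
#' truth interval stay unlabeled.
#'
#' @param pulses Tibble from [detect_pulses()] (columns `start`, `end`).
#' @param truth Truth tibble (`start`, `end`, `label`), e.g.
#'   [stream_truth()].
#' @return The `pulses` tibble with added `label` (NA when unmatched) and
#'   `truth_id` columns.
#' @export
match_truth <- function(pulses, truth) {
  if (nrow(pulses) == 0) {
    pulses$label <- character()
    pulses$truth_id <- integer()
    return(pulses)
  }
  lab <- rep(NA_character_, nrow(pulses))
  tid <- rep(NA_integer_, nrow(pulses))
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(pulses))) {
      ov <- interval_overlap(pulses$start[i], pulses$end[i],
                             truth$start, truth$end)
      j <- which.max(ov)
      if (ov[j] > 0) {
        lab[i] <- truth$label[j]
        tid[i] <- j
      }
    }
  }
  pulses$label <- lab
  pulses$truth_id <- tid
  pulses
}

#' Detection recall and precision against ground truth
#'
#' Recall: fraction of truth particles overlapped by at least one detected
#' pulse. Precision: fraction of detected pulses overlapping at least one
#' truth particle.
#'
#' @inheritParams match_truth
#' @return One-row tibble with `recall`, `precision`, `n_truth`,
#'   `n_detected`.
#' @export
detection_metrics <- function(pulses, truth) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(j) {
    any(interval_overlap(truth$start[j], truth$end[j],
                         pulses$start, pulses$end) > 0)
  }, TRUE)
  hit_pulse <- vapply(seq_len(nrow(pulses)), function(i) {
    any(interval_overlap(pulses$start[i], pulses$end[i],
                         truth$start, truth$end) > 0)
  }, TRUE)
  tibble(recall = if (nrow(truth)) mean(hit_truth) else NA_real_,
         precision = if (nrow(pulses)) mean(hit_pulse) else NA_real_,
         n_truth = nrow(truth), n_detected = nrow(pulses))
}
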