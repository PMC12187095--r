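# evaluation helpers for synthetic ground truth --------------------------------

#' Match detected candidates to ground-truth particles
#'
#' Greedy one-to-one matching: candidates (strongest first) claim the nearest
#' unclaimed truth particle within `max(min_dist, truth radius)` of their
#' center. Used to score detection and to label training sets.
#'
#' @param candidates Tibble from [detect_candidates()].
#' @param truth Ground-truth tibble (e.g. `sim_fov(...)$truth`) with `row`,
#'   `col`, `radius` and optionally `class`.
#' @param min_dist Minimum matching radius (px).
#' @return `candidates` with columns `truth_index` (`NA` when unmatched) and
#'   `truth_class`.
#' @export
match_candidates <- function(candidates, truth, min_dist = 2) {
  candidates <- as_tibble(candidates)
  truth <- as_tibble(truth)
  idx <- rep(NA_integer_, nrow(candidates))
  if (nrow(candidates) > 0 && nrow(truth) > 0) {
    ord <- order(-candidates$score)
    used <- rep(FALSE, nrow(truth))
    for (i in ord) {
      d <- sqrt((truth$row - candidates$row[i])^2 +
                  (truth$col - candidates$col[i])^2)
      ok <- which(!used & d <= pmax(min_dist, truth$radius))
      if (length(ok) > 0) {
        j <- ok[which.min(d[ok])]
        idx[i] <- j
        used[j] <- TRUE
      }
    }
  }
  candidates$truth_index <- idx
  candidates$truth_class <- ifelse(
    is.na(idx), NA_character_,
    if ("class" %in% names(truth)) truth$class[idx] else "lysosome"
  )
  candidates
}

#' Detection precision, recall and F1 against ground truth
#'
#' Only truth particles of `truth_class` (default lysosomes) count as
#' positives; candidates matched to other truth classes are not penalized as
#' false positives (they detected a real object).
#'
#' @inheritParams match_candidates
#' @param truth_class Truth class treated as positive.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_scores <- function(candidates, truth, truth_class = "lysosome",
                             min_dist = 2) {
  matched <- match_candidates(candidates, truth, min_dist)
  pos_truth <- if ("class" %in% names(truth)) {
    sum(truth$class == truth_class)
  } else {
    nrow(truth)
  }
  tp <- sum(matched$truth_class == truth_class, na.rm = TRUE)
  fp <- sum(is.na(matched$truth_index))
  fn <- pos_truth - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (pos_truth > 0) tp / pos_truth else NA_real_
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1)
}

#' Build a labelled training set from synthetic fields of view
#'
#' Runs detection on each field, matches candidates to the ground truth and
#' labels them: matched-to-lysosome is positive, everything else (decoys and
#' unmatched clutter) negative. The result feeds
#' [train_radius_intensity_classifier()].
#'
#' @param fovs List of `phox_fov` objects.
#' @param ... Passed to [detect_candidates()].
#' @return A tibble of annotated particles with `is_lysosome`.
#' @export
annotate_from_truth <- function(fovs, ...) {
  purrr::map(fovs, function(fov) {
    cand <- detect_candidates(fov, ...)
    cand <- match_candidates(cand, fov$truth)
    cand$is_lysosome <- !is.na(cand$truth_class) &
      cand$truth_class == "lysosome"
    cand
  }) |> dplyr::bind_rows()
}
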