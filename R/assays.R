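#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' For each sample, the Ct of every gene is referenced to the housekeeping
#' gene (`dCt = Ct_gene - Ct_housekeeping`, replicate wells averaged first),
#' then to the control condition (`ddCt = dCt_sample - dCt_control`), and
#' expressed as fold-change `2^-ddCt`. Replicate spread is propagated by the
#' range method: per-replicate ddCt values give a fold-change interval
#' `[2^-max(ddCt), 2^-min(ddCt)]`. No amplification-efficiency correction is
#' applied.
#'
#' @param ct A data frame with columns `sample`, `gene`, `ct` and optionally
#'   `replicate` (technical/biological replicate wells).
#' @param housekeeping Name of the housekeeping gene (must be measured in
#'   every sample).
#' @param control Name of the control sample/condition.
#' @param average_replicates Average replicate Cts before computing dCt
#'   (default); otherwise dCt is computed per replicate and then averaged.
#' @return A tibble: `sample`, `gene`, `dct`, `ddct`, `fold_change`,
#'   `fold_lo`, `fold_hi` (range-method spread; `NA` without replicates).
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("ctrl", "hyp"), each = 2),
#'   gene = rep(c("ACTB", "CA9"), 2),
#'   ct = c(15, 24, 15, 22)
#' )
#' ddct_fold_change(ct, housekeeping = "ACTB", control = "ctrl")
#' @export
ddct_fold_change <- function(ct, housekeeping, control,
                             average_replicates = TRUE) {
  ct <- as_tibble(ct)
  check_columns(ct, c("sample", "gene", "ct"), "ct")
  if (!"replicate" %in% names(ct)) ct$replicate <- 1L
  if (!all(is.finite(ct$ct))) abort("Ct values must be finite.")
  samples <- unique(ct$sample)
  hk <- ct[ct$gene == housekeeping, ]
  if (!all(samples %in% hk$sample)) {
    abort(sprintf("Housekeeping gene `%s` is not measured in every sample.",
                  housekeeping))
  }
  if (!control %in% samples) {
    abort(sprintf("Control condition `%s` not present.", control))
  }

  # per sample x gene x replicate dCt (replicates of the housekeeping gene
  # averaged within replicate id when present, else across the sample)
  hk_mean <- dplyr::summarise(
    dplyr::group_by(hk, .data$sample, .data$replicate),
    hk_ct = mean(.data$ct), .groups = "drop"
  )
  goi <- ct[ct$gene != housekeeping, ]
  if (average_replicates) {
    goi <- dplyr::summarise(
      dplyr::group_by(goi, .data$sample, .data$gene),
      ct = mean(.data$ct), .groups = "drop"
    )
    hk_all <- dplyr::summarise(dplyr::group_by(hk_mean, .data$sample),
                               hk_ct = mean(.data$hk_ct), .groups = "drop")
    dct <- dplyr::left_join(goi, hk_all, by = "sample")
    dct$dct <- dct$ct - dct$hk_ct
    dct_rep <- NULL
  } else {
    dct_rep <- dplyr::left_join(goi, hk_mean,
                                by = c("sample", "replicate"))
    dct_rep$dct <- dct_rep$ct - dct_rep$hk_ct
    dct <- dplyr::summarise(
      dplyr::group_by(dct_rep, .data$sample, .data$gene),
      dct = mean(.data$dct), .groups = "drop"
    )
  }
  ctrl <- dct[dct$sample == control, c("gene", "dct")]
  names(ctrl)[2] <- "dct_control"
  out <- dplyr::left_join(dct[, c("sample", "gene", "dct")], ctrl,
                          by = "gene")
  out$ddct <- out$dct - out$dct_control
  out$fold_change <- 2^(-out$ddct)

  # range-method spread from per-replicate ddCt when replicates exist
  out$fold_lo <- NA_real_
  out$fold_hi <- NA_real_
  if (!average_replicates && !is.null(dct_rep)) {
    spread <- dplyr::left_join(dct_rep, ctrl, by = "gene")
    spread$ddct <- spread$dct - spread$dct_control
    rng <- dplyr::summarise(
      dplyr::group_by(spread, .data$sample, .data$gene),
      fold_lo = 2^(-max(.data$ddct)), fold_hi = 2^(-min(.data$ddct)),
      .groups = "drop"
    )
    out <- dplyr::rows_update(out, rng, by = c("sample", "gene"))
  }
  as_tibble(out)
}

#' Proteasome activity from luminescence traces
#'
#' Peak luminescence of treated wells minus a background, normalized to cell
#' growth (an SRB absorbance measured on a parallel plate). Two background
#' modes are supported and labelled in the output: `"epoxomicin"` subtracts
#' the peak of proteasome-inhibited wells of the same condition;
#' `"cell_free"` subtracts the peak of cell-free substrate wells. Activities
#' at or below zero (background exceeding signal) are reported as-is and
#' flagged, never clipped.
#'
#' @param traces A data frame with columns `condition`, `role` (one of
#'   `treated`, `epoxomicin_background`, `cell_free`), `time_min`,
#'   `luminescence` and `growth` (per-condition SRB value, constant within a
#'   condition's treated wells).
#' @param mode Background mode, `"epoxomicin"` or `"cell_free"`.
#' @return A tibble: `condition`, `peak`, `background`, `activity`,
#'   `mode`, `flagged`.
#' @export
proteasome_activity <- function(traces, mode = c("epoxomicin", "cell_free")) {
  mode <- match.arg(mode)
  traces <- as_tibble(traces)
  check_columns(traces, c("condition", "role", "time_min", "luminescence",
                          "growth"), "traces")
  bg_role <- if (mode == "epoxomicin") "epoxomicin_background" else "cell_free"
  if (!any(traces$role == bg_role)) {
    abort(sprintf("No `%s` wells present for mode `%s`.", bg_role, mode))
  }
  cell_free_bg <- if (mode == "cell_free") {
    max(traces$luminescence[traces$role == "cell_free"])
  } else {
    NA_real_
  }
  treated <- traces[traces$role == "treated", ]
  dplyr::group_by(treated, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      peak <- max(df$luminescence)
      bg <- if (mode == "epoxomicin") {
        rows <- traces$role == bg_role & traces$condition == key$condition
        if (!any(rows)) {
          abort(sprintf("No epoxomicin background wells for condition `%s`.",
                        key$condition))
        }
        max(traces$luminescence[rows])
      } else {
        cell_free_bg
      }
      growth <- df$growth[1]
      check_number(growth, "growth", lower = 1e-12)
      activity <- (peak - bg) / growth
      tibble(peak = peak, background = bg, activity = activity,
             mode = mode, flagged = activity <= 0)
    }) |>
    dplyr::ungroup()
}
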