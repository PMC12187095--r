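#' Default effect classes for the proteomics simulator
#'
#' Five response archetypes mirror the ways proteins respond to hypoxia at
#' alkaline versus acidic extracellular pH: class A is induced by hypoxia at
#' alkaline pH but the response is strongly suppressed by acidosis (the
#' HIF-1 alpha pattern); B is induced with partial acid suppression; C is
#' induced with acid synergy; D is downregulated by hypoxia at either pH.
#' Remaining proteins are null. Fractions must sum to at most 1.
#'
#' @param frac_a,frac_b,frac_c,frac_d Fractions of proteins per class.
#' @return A tibble with columns `class`, `fraction`, `hyp_fc_alk`
#'   (hypoxia log2 fold-change at alkaline pH), `hyp_fc_acid` (at acidic pH)
#'   and `acid_main` (acidosis main effect, log2).
#' @export
default_effect_classes <- function(frac_a = 0.01, frac_b = 0.02,
                                   frac_c = 0.02, frac_d = 0.01) {
  tibble(
    class = c("A", "B", "C", "D"),
    fraction = c(frac_a, frac_b, frac_c, frac_d),
    hyp_fc_alk = c(3.0, 3.0, 2.0, -2.0),
    hyp_fc_acid = c(0.2, 1.5, 3.5, -2.0),
    acid_main = c(0, 0, 0.5, 0)
  )
}

#' Specification for a simulated factorial proteomics experiment
#'
#' Generates a proteins x samples log2 label-free-quantification matrix for a
#' crossed pH x O2 design with replicate batches, plus intensity-dependent
#' left-censored missingness. Per protein,
#' `log2 LFQ = baseline + condition effect + batch offset + residual noise`,
#' and an entry goes missing with probability that rises logistically as the
#' underlying abundance falls below a low quantile of the abundance
#' distribution (a detection-limit model; the mechanism generating
#' missingness in real data is not observed, this is the standard
#' left-censoring stand-in).
#'
#' @param n_proteins Number of proteins.
#' @param n_batches Number of replicate batches (each spans all 4 conditions;
#'   default 3 gives the standard 2 x 2 x 3 = 12-sample design).
#' @param effect_classes Tibble as returned by [default_effect_classes()].
#' @param baseline_mean,baseline_sd Mean and SD of per-protein baseline
#'   abundance (log2 units).
#' @param batch_sd SD of batch offsets (log2 units).
#' @param residual_sd Residual SD (log2 units).
#' @param censoring `list(quantile =, max_prob =)`: missingness probability
#'   is `max_prob * plogis((x0 - x) / scale)` where `x0` is the given
#'   quantile of true abundances; `NULL` disables censoring.
#' @param censor_scale Logistic scale of the censoring curve (log2 units).
#' @param reference_protein_index Row forced into class A and labelled as the
#'   HIF-1 alpha analogue, used as the reference of the correlation screen.
#' @param seed Integer seed.
#' @return A `proteomics_sim_spec` object.
#' @export
proteomics_sim_spec <- function(n_proteins = 2000, n_batches = 3,
                                effect_classes = default_effect_classes(),
                                baseline_mean = 25, baseline_sd = 2,
                                batch_sd = 0.3, residual_sd = 0.5,
                                censoring = list(quantile = 0.1,
                                                 max_prob = 0.5),
                                censor_scale = 1,
                                reference_protein_index = 1,
                                seed = 1) {
  check_number(n_proteins, "n_proteins", lower = 4)
  check_number(n_batches, "n_batches", lower = 2)
  check_columns(effect_classes,
                c("class", "fraction", "hyp_fc_alk", "hyp_fc_acid",
                  "acid_main"), "effect_classes")
  if (sum(effect_classes$fraction) > 1) {
    abort("Effect-class fractions must sum to at most 1 (remainder is null).")
  }
  check_number(batch_sd, "batch_sd", lower = 0)
  check_number(residual_sd, "residual_sd", lower = 0)
  if (!is.null(censoring)) {
    check_number(censoring$quantile, "censoring$quantile", lower = 0, upper = 1)
    check_number(censoring$max_prob, "censoring$max_prob", lower = 0, upper = 1)
  }
  check_number(reference_protein_index, "reference_protein_index",
               lower = 1, upper = n_proteins)
  check_number(seed, "seed")
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_batches = as.integer(n_batches),
         effect_classes = as_tibble(effect_classes),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         batch_sd = batch_sd, residual_sd = residual_sd,
         censoring = censoring, censor_scale = censor_scale,
         reference_protein_index = as.integer(reference_protein_index),
         seed = seed),
    class = "proteomics_sim_spec"
  )
}

#' The factorial design table for a pH x O2 x batch layout
#'
#' @param n_batches Number of replicate batches.
#' @return A tibble with columns `sample`, `ph` (`acidic`/`alkaline`),
#'   `o2` (`normoxia`/`hypoxia`), `batch`.
#' @export
factorial_design <- function(n_batches = 3) {
  d <- tidyr::expand_grid(batch = paste0("b", seq_len(n_batches)),
                          ph = c("alkaline", "acidic"),
                          o2 = c("normoxia", "hypoxia"))
  d$sample <- sprintf("%s_%s_%s", substr(d$ph, 1, 3), substr(d$o2, 1, 3),
                      d$batch)
  d[, c("sample", "ph", "o2", "batch")]
}

condition_effect <- function(ph, o2, cls_row) {
  hyp <- o2 == "hypoxia"
  acid <- ph == "acidic"
  eff <- ifelse(acid, cls_row$acid_main, 0)
  eff + ifelse(hyp, ifelse(acid, cls_row$hyp_fc_acid, cls_row$hyp_fc_alk), 0)
}

#' Simulate a factorial label-free proteomics abundance matrix
#'
#' @param spec A [proteomics_sim_spec()].
#' @return A list with `values` (numeric matrix, proteins x samples, `NA` for
#'   censored entries), `complete` (the uncensored matrix), `design` (tibble
#'   from [factorial_design()]), `truth` (tibble: `protein`, `class`,
#'   `baseline`, the class effect sizes) and `reference_protein` (its id).
#' @examples
#' sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 50, seed = 4))
#' table(sim$truth$class)
#' @export
sim_abundance_matrix <- function(spec) {
  stopifnot(inherits(spec, "proteomics_sim_spec"))
  design <- factorial_design(spec$n_batches)
  n_s <- nrow(design)
  n_p <- spec$n_proteins
  cls_tab <- spec$effect_classes
  with_seed(spec$seed, {
    n_per_class <- round(cls_tab$fraction * n_p)
    classes <- rep("null", n_p)
    idx <- setdiff(seq_len(n_p), spec$reference_protein_index)
    pos <- 1
    for (k in seq_len(nrow(cls_tab))) {
      take <- idx[seq_len(n_per_class[k]) + pos - 1]
      classes[take] <- cls_tab$class[k]
      pos <- pos + n_per_class[k]
    }
    # the reference (HIF-1 alpha analogue) follows the acid-suppressed
    # hypoxia-induced archetype: class A when present, else the first class
    ref_class <- if ("A" %in% cls_tab$class) "A" else cls_tab$class[1]
    classes[spec$reference_protein_index] <- ref_class
    proteins <- sprintf("P%04d", seq_len(n_p))
    proteins[spec$reference_protein_index] <- "HIF1A_ref"
    baseline <- rnorm(n_p, spec$baseline_mean, spec$baseline_sd)
    batch_off <- setNames(rnorm(spec$n_batches, 0, spec$batch_sd),
                          paste0("b", seq_len(spec$n_batches)))
    null_row <- tibble(acid_main = 0, hyp_fc_alk = 0, hyp_fc_acid = 0)
    eff <- matrix(0, n_p, n_s)
    for (i in seq_len(n_p)) {
      row <- if (classes[i] == "null") null_row else
        cls_tab[cls_tab$class == classes[i], ]
      eff[i, ] <- condition_effect(design$ph, design$o2, row)
    }
    complete <- baseline +
      eff +
      matrix(batch_off[design$batch], n_p, n_s, byrow = TRUE) +
      matrix(rnorm(n_p * n_s, 0, spec$residual_sd), n_p, n_s)
    dimnames(complete) <- list(proteins, design$sample)
    values <- complete
    if (!is.null(spec$censoring)) {
      x0 <- quantile(complete, spec$censoring$quantile)
      p_miss <- spec$censoring$max_prob *
        stats::plogis((x0 - complete) / spec$censor_scale)
      miss <- matrix(rbinom(n_p * n_s, 1, p_miss) == 1, n_p, n_s)
      values[miss] <- NA_real_
    }
    truth <- dplyr::left_join(
      tibble(protein = proteins, class = classes, baseline = baseline),
      cls_tab[, c("class", "hyp_fc_alk", "hyp_fc_acid", "acid_main")],
      by = "class"
    )
    truth <- tidyr::replace_na(truth, list(hyp_fc_alk = 0, hyp_fc_acid = 0,
                                           acid_main = 0))
    list(values = values, complete = complete, design = design,
         truth = truth,
         reference_protein = proteins[spec$reference_protein_index])
  })
}
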