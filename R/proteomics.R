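#' Left-censored imputation of missing abundances (minProb)
#'
#' Replaces each missing entry of a log2 abundance matrix with a draw from a
#' narrow normal distribution centered at a low quantile (`q`, default 0.01)
#' of that sample's observed values, modelling detection-limit missingness.
#' The spread is `sd_frac` times the sample's observed standard deviation.
#' Observed entries are preserved bit-exactly; the imputation mask is
#' attached as the `"imputed"` attribute.
#'
#' @param mat Numeric matrix, proteins x samples, `NA` = missing.
#' @param q Quantile of the observed per-sample distribution at which to
#'   center imputed draws.
#' @param sd_frac Spread of the imputation distribution as a fraction of the
#'   per-sample observed SD.
#' @param seed Optional integer seed for reproducible draws.
#' @return The completed matrix with attribute `"imputed"` (logical matrix).
#' @export
impute_minprob <- function(mat, q = 0.01, sd_frac = 0.01, seed = NULL) {
  stopifnot(is.matrix(mat))
  check_number(q, "q", lower = 0, upper = 1)
  check_number(sd_frac, "sd_frac", lower = 0)
  miss <- is.na(mat)
  if (!any(miss)) {
    attr(mat, "imputed") <- miss
    return(mat)
  }
  if (any(colSums(!miss) == 0)) {
    abort("At least one sample has no observed values; cannot impute.")
  }
  draw <- function() {
    out <- mat
    for (j in seq_len(ncol(mat))) {
      mj <- miss[, j]
      if (!any(mj)) next
      obs <- mat[!mj, j]
      out[mj, j] <- rnorm(sum(mj), mean = quantile(obs, q),
                          sd = sd_frac * sd(obs))
    }
    out
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  attr(out, "imputed") <- miss
  out
}

# sum-coded design matrix: batch blocks, ph and o2 as +/- 1/2 so single
# coefficients are the main effects and interaction on the log2 scale
factorial_model_matrix <- function(design) {
  check_columns(design, c("sample", "ph", "o2", "batch"), "design")
  if (dplyr::n_distinct(design$ph) < 2 || dplyr::n_distinct(design$o2) < 2 ||
      dplyr::n_distinct(design$batch) < 2) {
    abort("Design must have at least 2 levels of pH, O2 and batch.")
  }
  combos <- unique(paste(design$ph, design$o2))
  if (length(combos) < 4) {
    abort("Design must contain the full 2 x 2 pH-O2 crossing.")
  }
  acid <- ifelse(design$ph == "acidic", 0.5, -0.5)
  hyp <- ifelse(design$o2 == "hypoxia", 0.5, -0.5)
  batch <- factor(design$batch)
  contrasts(batch) <- stats::contr.sum(nlevels(batch))
  bm <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, bm, acidosis = acid, hypoxia = hyp,
             interaction = acid * hyp)
  X
}

#' Per-protein factorial ANOVA with batch correction
#'
#' Fits, for every protein, the linear model
#' `log2 abundance ~ batch + acidosis + hypoxia + acidosis:hypoxia` (batch as
#' a fixed blocking factor, pH and O2 sum-coded so each effect is a single
#' degree of freedom) and reports F and p for the acidosis main effect, the
#' hypoxia main effect and their interaction, each Benjamini-Hochberg
#' adjusted across proteins per effect. The four pairwise condition
#' contrasts (hypoxia vs normoxia within each pH, acidic vs alkaline within
#' each O2 level) are reported as log2 fold-changes with t-test p and BH q.
#'
#' `method = "moderated"` substitutes limma's empirical-Bayes moderated
#' statistics (shrinking the per-protein variances towards a common prior),
#' which is what dedicated proteomics pipelines do; the ordinary
#' least-squares F-tests are the default so results are self-contained and
#' exactly reproducible by hand.
#'
#' @param mat Complete numeric matrix (proteins x samples).
#' @param design Tibble with columns `sample`, `ph` (`acidic`/`alkaline`),
#'   `o2` (`normoxia`/`hypoxia`), `batch`; rows must match the matrix
#'   columns.
#' @param method `"ls"` (ordinary least squares) or `"moderated"` (limma
#'   empirical Bayes; requires limma).
#' @return A tibble with one row per protein: `protein`, `constant` flag,
#'   per-effect `F_*`, `p_*`, `q_*` (`acidosis`, `hypoxia`, `interaction`),
#'   and per-contrast `lfc_*`, `p_*`, `q_*` for `hyp_alk`, `hyp_acid`,
#'   `acid_nor`, `acid_hyp`.
#' @export
fit_factorial_anova <- function(mat, design, method = c("ls", "moderated")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat))
  design <- as_tibble(design)
  if (nrow(design) != ncol(mat)) {
    abort("`design` must have one row per matrix column.")
  }
  if (!is.null(colnames(mat)) &&
      !identical(colnames(mat), design$sample)) {
    design <- design[match(colnames(mat), design$sample), ]
    if (any(is.na(design$sample))) {
      abort("Matrix column names do not match design samples.")
    }
  }
  if (any(is.na(mat))) {
    abort("Matrix contains missing values; impute first (see impute_minprob()).")
  }
  X <- factorial_model_matrix(design)
  df_res <- nrow(X) - ncol(X)
  if (df_res <= 0) abort("Zero residual degrees of freedom in the design.")
  proteins <- rownames(mat) %||% sprintf("P%04d", seq_len(nrow(mat)))
  constant <- apply(mat, 1, function(x) var(x) == 0)

  eff_names <- c("acidosis", "hypoxia", "interaction")
  if (method == "ls") {
    fit <- lm.fit(X, t(mat))
    coefs <- t(fit$coefficients)           # proteins x terms
    res <- t(fit$residuals)
    rss <- rowSums(res^2)
    sigma2 <- rss / df_res
    xtxi <- chol2inv(chol(crossprod(X)))
    se_scale <- sqrt(diag(xtxi))
    names(se_scale) <- colnames(X)
    stats_eff <- purrr::map(eff_names, function(term) {
      tstat <- coefs[, term] / (sqrt(sigma2) * se_scale[term])
      Fv <- tstat^2
      p <- pf(Fv, 1, df_res, lower.tail = FALSE)
      list(F = Fv, p = p)
    })
  } else {
    if (!requireNamespace("limma", quietly = TRUE)) {
      abort("`method = \"moderated\"` requires the limma package.")
    }
    lfit <- limma::eBayes(limma::lmFit(mat, X))
    stats_eff <- purrr::map(eff_names, function(term) {
      j <- match(term, colnames(X))
      tstat <- lfit$t[, j]
      list(F = tstat^2, p = lfit$p.value[, j])
    })
    sigma2 <- lfit$s2.post
    coefs <- lfit$coefficients
    df_res <- lfit$df.residual[1] + lfit$df.prior
    if (!is.finite(df_res)) df_res <- nrow(X) - ncol(X)
  }
  names(stats_eff) <- eff_names

  out <- tibble(protein = proteins, constant = constant)
  for (term in eff_names) {
    Fv <- stats_eff[[term]]$F
    p <- stats_eff[[term]]$p
    p[constant] <- 1
    Fv[constant] <- 0
    out[[paste0("F_", term)]] <- unname(Fv)
    out[[paste0("p_", term)]] <- unname(p)
    out[[paste0("q_", term)]] <- p.adjust(p, "BH")
  }

  # pairwise condition contrasts from cell means, pooled residual variance
  cond <- paste(design$ph, design$o2, sep = ".")
  cells <- c(alk_nor = "alkaline.normoxia", alk_hyp = "alkaline.hypoxia",
             ac_nor = "acidic.normoxia", ac_hyp = "acidic.hypoxia")
  cellmeans <- vapply(cells, function(cl) {
    rowMeans(mat[, cond == cl, drop = FALSE])
  }, numeric(nrow(mat)))
  ns <- vapply(cells, function(cl) sum(cond == cl), numeric(1))
  contrasts <- list(
    hyp_alk = c("alk_hyp", "alk_nor"),
    hyp_acid = c("ac_hyp", "ac_nor"),
    acid_nor = c("ac_nor", "alk_nor"),
    acid_hyp = c("ac_hyp", "alk_hyp")
  )
  for (cn in names(contrasts)) {
    a <- contrasts[[cn]][1]; b <- contrasts[[cn]][2]
    lfc <- cellmeans[, a] - cellmeans[, b]
    se <- sqrt(sigma2 * (1 / ns[a] + 1 / ns[b]))
    p <- 2 * pt(abs(lfc / se), df_res, lower.tail = FALSE)
    p[constant] <- 1
    out[[paste0("lfc_", cn)]] <- unname(lfc)
    out[[paste0("p_", cn)]] <- unname(p)
    out[[paste0("q_", cn)]] <- p.adjust(p, "BH")
  }
  out
}

#' Correlation screen against a reference protein
#'
#' Correlates every protein's abundance profile across samples with a
#' reference row (e.g. HIF-1 alpha), reporting the correlation coefficient,
#' two-sided p-value and BH-adjusted q. The reference row is excluded from
#' its own screen; zero-variance rows are flagged and excluded from the
#' multiple-testing family.
#'
#' @param mat Complete numeric matrix (proteins x samples).
#' @param reference_protein Row name (or index) of the reference.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble: `protein`, `correlation`, `p`, `q`, `flagged`.
#' @export
correlate_with_reference <- function(mat, reference_protein,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 4) abort("Need at least 4 samples for the screen.")
  proteins <- rownames(mat) %||% sprintf("P%04d", seq_len(nrow(mat)))
  ref_i <- if (is.character(reference_protein)) {
    match(reference_protein, proteins)
  } else {
    as.integer(reference_protein)
  }
  if (is.na(ref_i) || ref_i < 1 || ref_i > nrow(mat)) {
    abort("Reference protein not found in the matrix.")
  }
  ref <- mat[ref_i, ]
  if (var(ref) == 0) abort("Reference profile has zero variance.")
  rows <- setdiff(seq_len(nrow(mat)), ref_i)
  res <- purrr::map(rows, function(i) {
    x <- mat[i, ]
    if (var(x) == 0) {
      return(tibble(protein = proteins[i], correlation = NA_real_,
                    p = NA_real_, flagged = TRUE))
    }
    ct <- suppressWarnings(cor.test(x, ref, method = method))
    tibble(protein = proteins[i], correlation = unname(ct$estimate),
           p = ct$p.value, flagged = FALSE)
  }) |> dplyr::bind_rows()
  res$q <- NA_real_
  res$q[!res$flagged] <- p.adjust(res$p[!res$flagged], "BH")
  res
}

#' Cluster hypoxia-response profiles
#'
#' Selects proteins with a significant hypoxic response (by default the
#' hypoxia-versus-normoxia contrast at alkaline pH, `q_hyp_alk <
#' q_threshold`; `mode = "interaction"` selects interaction-significant
#' proteins instead), standardizes each selected row to z-scores across
#' samples, and cuts an average-linkage hierarchical clustering of the
#' Euclidean distances into `k` groups. Groups are relabelled by their
#' response pattern: among hypoxia-upregulated clusters, letters run from
#' the most acid-suppressed (`A`) to the most acid-potentiated, and
#' downregulated clusters take the final letters (so with `k = 4`, `D` is
#' the hypoxia-downregulated group). In interaction mode the cluster whose
#' mean response is selectively positive under acidic hypoxia is labelled
#' `E`.
#'
#' @param mat Complete numeric matrix (proteins x samples).
#' @param design Factorial design tibble.
#' @param effects Result of [fit_factorial_anova()].
#' @param q_threshold Selection threshold on the BH-adjusted q.
#' @param k Number of clusters.
#' @param mode `"alkaline_hypoxia"` (default) or `"interaction"`.
#' @param linkage Agglomeration method for [stats::hclust()] (Ward by default; average linkage tends to chain adjacent response archetypes).
#' @return A list with `assignments` (tibble: `protein`, `cluster`,
#'   `lfc_hyp_alk`, `lfc_hyp_acid` -- the scatter coordinates of hypoxic
#'   response under alkalosis versus acidosis), `profiles` (standardized
#'   matrix), `summaries` (per-cluster mean responses) and `selected_label`
#'   (in interaction mode, the acidic-hypoxia-selective group).
#' @export
cluster_hypoxic_responses <- function(mat, design, effects,
                                      q_threshold = 0.05, k = 4,
                                      mode = c("alkaline_hypoxia",
                                               "interaction"),
                                      linkage = "ward.D2") {
  mode <- match.arg(mode)
  effects <- as_tibble(effects)
  sel_col <- if (mode == "alkaline_hypoxia") "q_hyp_alk" else "q_interaction"
  check_columns(effects, c("protein", sel_col, "lfc_hyp_alk", "lfc_hyp_acid"),
                "effects")
  sel <- effects[effects[[sel_col]] < q_threshold & !effects$constant, ]
  if (nrow(sel) < k) {
    abort(sprintf("Only %d protein(s) pass selection; cannot form %d clusters.",
                  nrow(sel), k))
  }
  rows <- match(sel$protein, rownames(mat))
  # cluster on batch-averaged condition profiles: averaging over the
  # replicate blocks removes batch offsets before standardization
  cond <- paste(design$ph, design$o2, sep = ".")
  prof <- vapply(unique(cond), function(cl) {
    rowMeans(mat[rows, cond == cl, drop = FALSE])
  }, numeric(length(rows)))
  rownames(prof) <- sel$protein
  prof <- t(scale(t(prof)))
  hc <- stats::hclust(stats::dist(prof), method = linkage)
  raw <- stats::cutree(hc, k = k)

  summaries <- dplyr::summarise(
    dplyr::group_by(tibble(raw = raw, alk = sel$lfc_hyp_alk,
                           acid = sel$lfc_hyp_acid), .data$raw),
    n = dplyr::n(), mean_alk = mean(.data$alk), mean_acid = mean(.data$acid)
  )
  if (mode == "alkaline_hypoxia") {
    up <- summaries[summaries$mean_alk >= 0, ]
    down <- summaries[summaries$mean_alk < 0, ]
    # upregulated groups ordered by acid response relative to alkaline
    up <- up[order(up$mean_acid - up$mean_alk), ]
    ordered <- c(up$raw, down$raw[order(down$mean_alk)])
    labels <- setNames(LETTERS[seq_len(k)], ordered)
    selected_label <- NA_character_
  } else {
    # group E: selectively increased under acidic hypoxia
    sel_score <- summaries$mean_acid - pmax(summaries$mean_alk, 0)
    ordered <- summaries$raw[order(-sel_score)]
    labels <- setNames(c("E", LETTERS[5 + seq_len(k - 1)]), ordered)
    selected_label <- "E"
  }
  cluster <- unname(labels[as.character(raw)])
  assignments <- tibble(protein = sel$protein, cluster = cluster,
                        lfc_hyp_alk = sel$lfc_hyp_alk,
                        lfc_hyp_acid = sel$lfc_hyp_acid)
  summaries$cluster <- unname(labels[as.character(summaries$raw)])
  list(assignments = assignments, profiles = prof,
       summaries = summaries[, c("cluster", "n", "mean_alk", "mean_acid")],
       selected_label = selected_label)
}

#' Fisher enrichment of a category within a selected set
#'
#' Builds the 2 x 2 table (in/out of the selected set x in/out of the
#' category) over a common identifier universe and tests enrichment with a
#' one-sided Fisher exact test (hypergeometric upper tail).
#'
#' @param universe Character vector of all identifiers under consideration.
#' @param set Identifiers in the selected set (e.g. proteins downregulated
#'   under acidotic hypoxia).
#' @param category Identifiers in the category (e.g. proteins with half-life
#'   under 8 h).
#' @return A list with `table` (2 x 2 matrix), `odds_ratio`, `p` (one-sided)
#'   and `overlap`.
#' @examples
#' fisher_enrichment(paste0("p", 1:100), paste0("p", 1:20), paste0("p", 15:40))
#' @export
fisher_enrichment <- function(universe, set, category) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty universe.")
  set <- intersect(unique(set), universe)
  category <- intersect(unique(category), universe)
  in_set <- universe %in% set
  in_cat <- universe %in% category
  tab <- matrix(c(sum(in_set & in_cat), sum(!in_set & in_cat),
                  sum(in_set & !in_cat), sum(!in_set & !in_cat)),
                nrow = 2,
                dimnames = list(set = c("in", "out"),
                                category = c("in", "out")))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       overlap = tab[1, 1])
}

#' Benjamini-Hochberg adjustment (step-up)
#'
#' Thin wrapper over [stats::p.adjust()] kept as the package's single point
#' of FDR control.
#'
#' @param p Numeric vector of p-values.
#' @return BH-adjusted q-values.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")
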