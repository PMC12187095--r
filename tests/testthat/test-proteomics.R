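test_that("minProb imputation draws near the low quantile, left of observed", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 400, seed = 3))
  mat <- sim$values

  # a complete matrix is returned unchanged
  complete <- sim$complete
  expect_identical(impute_minprob(complete),
                   structure(complete, imputed = is.na(complete)))

  out <- impute_minprob(mat, seed = 11)
  miss <- is.na(mat)
  # observed entries preserved bit-exactly
  expect_identical(out[!miss], mat[!miss])
  # reproducible under the seed
  expect_identical(out, impute_minprob(mat, seed = 11))

  for (j in which(colSums(miss) > 2)) {
    obs <- mat[!miss[, j], j]
    imp <- out[miss[, j], j]
    # centered near the 1% quantile of the observed sample ...
    expect_lt(abs(mean(imp) - quantile(obs, 0.01)), 0.5)
    # ... hence left of the observed mean in every sample
    expect_lt(mean(imp), mean(obs))
  }

  allmiss <- mat
  allmiss[, 1] <- NA
  expect_error(impute_minprob(allmiss), "no observed values")
})

test_that("factorial ANOVA matches brute-force sums of squares", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 8,
                                                  censoring = NULL, seed = 5))
  eff <- fit_factorial_anova(sim$values, sim$design)
  d <- sim$design
  for (i in seq_len(8)) {
    y <- sim$values[i, ]
    ph <- factor(d$ph); o2 <- factor(d$o2); batch <- factor(d$batch)
    contrasts(ph) <- contr.sum(2); contrasts(o2) <- contr.sum(2)
    contrasts(batch) <- contr.sum(3)
    a <- anova(lm(y ~ batch + ph * o2))
    expect_equal(eff$F_acidosis[i], a["ph", "F value"], tolerance = 1e-8)
    expect_equal(eff$F_hypoxia[i], a["o2", "F value"], tolerance = 1e-8)
    expect_equal(eff$F_interaction[i], a["ph:o2", "F value"],
                 tolerance = 1e-8)
    expect_equal(eff$p_interaction[i], a["ph:o2", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("constant protein rows are flagged, never significant", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 10,
                                                  censoring = NULL, seed = 1))
  mat <- sim$values
  mat[3, ] <- 20
  eff <- fit_factorial_anova(mat, sim$design)
  expect_true(eff$constant[3])
  expect_equal(eff$p_acidosis[3], 1)
  expect_equal(eff$p_hyp_alk[3], 1)
  expect_false(any(eff$constant[-3]))
})

test_that("global-null simulation holds the type-I error near 5%", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(
    n_proteins = 5000, effect_classes = default_effect_classes(0, 0, 0, 0),
    censoring = NULL, seed = 17))
  eff <- fit_factorial_anova(sim$values, sim$design)
  for (p in list(eff$p_acidosis, eff$p_hypoxia, eff$p_interaction)) {
    rate <- mean(p < 0.05)
    # binomial error around 0.05 at n = 5000: 3 Sds ~ 0.009
    expect_lt(abs(rate - 0.05), 0.01)
  }
  # BH discoveries are essentially absent under the global null
  expect_lte(sum(eff$q_interaction < 0.05), 2)
  expect_lte(sum(eff$q_hypoxia < 0.05), 2)
})

test_that("interaction power matches the noncentral-F oracle and is high", {
  # 10% of proteins carry a pH-dependent hypoxic response of +/-2 log2
  # units (double difference 4), residual sd 0.5, 3 batches
  classes <- tibble::tibble(class = "X", fraction = 0.1, hyp_fc_alk = -2,
                            hyp_fc_acid = 2, acid_main = 0)
  sim <- sim_abundance_matrix(proteomics_sim_spec(
    n_proteins = 1500, effect_classes = classes, censoring = NULL,
    residual_sd = 0.5, seed = 23))
  truth_idx <- sim$truth$class == "X"

  eff <- fit_factorial_anova(sim$values, sim$design)
  # Monte-Carlo power at fixed alpha vs the noncentral-F oracle:
  # lambda = delta^2 / (sigma^2 * 4/3) with delta = 4, sigma = 0.5
  alpha <- 0.01
  mc_power <- mean(eff$p_interaction[truth_idx] < alpha)
  lambda <- 16 / (0.25 * 4 / 3)
  fcrit <- qf(1 - alpha, 1, 6)
  oracle_power <- 1 - pf(fcrit, 1, 6, ncp = lambda)
  expect_lt(abs(mc_power - oracle_power), 0.1)

  # moderated statistics reach >= 90% power at q < 0.05
  effm <- fit_factorial_anova(sim$values, sim$design, method = "moderated")
  expect_gte(mean(effm$q_interaction[truth_idx] < 0.05), 0.9)
  # and stay clean on the nulls
  expect_lt(mean(effm$q_interaction[!truth_idx] < 0.05), 0.01)
})

test_that("the reference correlation screen behaves at the extremes", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 60,
                                                  censoring = NULL, seed = 2))
  mat <- sim$values
  ref <- mat["HIF1A_ref", ]
  mat[2, ] <- ref                 # identical profile
  mat[3, ] <- -ref                # sign flip
  mat[4, ] <- 21                  # zero variance
  scr <- correlate_with_reference(mat, "HIF1A_ref")
  expect_false("HIF1A_ref" %in% scr$protein)
  expect_equal(scr$correlation[scr$protein == rownames(mat)[2]], 1)
  expect_equal(scr$correlation[scr$protein == rownames(mat)[3]], -1)
  expect_true(scr$flagged[scr$protein == rownames(mat)[4]])

  # Spearman option works on the same interface
  scr_s <- correlate_with_reference(mat, "HIF1A_ref", method = "spearman")
  expect_equal(scr_s$correlation[scr_s$protein == rownames(mat)[2]], 1)
})

test_that("a null correlation screen yields (almost) no discoveries", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(
    n_proteins = 1000, effect_classes = default_effect_classes(0, 0, 0, 0),
    censoring = NULL, seed = 31))
  scr <- correlate_with_reference(sim$values, 1)
  expect_lte(sum(scr$q < 0.05, na.rm = TRUE), 2)
})

test_that("archetype clustering recovers the response groups", {
  # two well-separated archetypes -> two clusters with perfect membership
  classes <- tibble::tibble(class = c("up", "down"), fraction = c(0.1, 0.1),
                            hyp_fc_alk = c(3, -3), hyp_fc_acid = c(3, -3),
                            acid_main = 0)
  sim <- sim_abundance_matrix(proteomics_sim_spec(
    n_proteins = 300, effect_classes = classes, censoring = NULL,
    residual_sd = 0.3, seed = 8))
  eff <- fit_factorial_anova(sim$values, sim$design, method = "moderated")
  cl <- cluster_hypoxic_responses(sim$values, sim$design, eff, k = 2)
  truecl <- sim$truth$class[match(cl$assignments$protein,
                                  sim$truth$protein)]
  # a handful of nulls may pass the q-filter (that is what FDR 5% means);
  # membership of the archetype proteins themselves must be perfect
  expect_gte(mean(truecl %in% c("up", "down")), 0.9)
  arch <- truecl %in% c("up", "down")
  expect_equal(ari(cl$assignments$cluster[arch], truecl[arch]), 1)

  # the hypoxia-downregulated archetype lands in the cluster whose mean
  # hypoxic response is negative
  down_label <- unique(cl$assignments$cluster[truecl == "down"])
  expect_length(down_label, 1)
  s <- cl$summaries
  expect_lt(s$mean_alk[s$cluster == down_label], 0)

  expect_error(cluster_hypoxic_responses(sim$values, sim$design, eff,
                                         k = 200),
               "cannot form")
})

test_that("four-group clustering tracks generator labels (mean ARI >= 0.8)", {
  aris <- sapply(7:11, function(s) {
    sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 800,
                                                    censoring = NULL,
                                                    seed = s))
    eff <- fit_factorial_anova(sim$values, sim$design, method = "moderated")
    cl <- cluster_hypoxic_responses(sim$values, sim$design, eff)
    truecl <- sim$truth$class[match(cl$assignments$protein,
                                    sim$truth$protein)]
    ari(cl$assignments$cluster, truecl)
  })
  expect_gte(mean(aris), 0.8)
})

test_that("interaction mode isolates the acid-synergy group", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 800,
                                                  censoring = NULL,
                                                  seed = 12))
  eff <- fit_factorial_anova(sim$values, sim$design, method = "moderated")
  cl <- cluster_hypoxic_responses(sim$values, sim$design, eff,
                                  mode = "interaction", k = 3)
  expect_equal(cl$selected_label, "E")
  e_true <- sim$truth$class[match(
    cl$assignments$protein[cl$assignments$cluster == "E"],
    sim$truth$protein)]
  # the E group is dominated by the acid-synergy archetype
  expect_gte(mean(e_true == "C"), 0.8)
})

test_that("Fisher enrichment equals the brute-force hypergeometric tail", {
  # proportionally identical set and category: odds ratio ~ 1, p ~ 1
  uni <- paste0("p", 1:200)
  res0 <- fisher_enrichment(uni, uni[1:50], uni[seq(1, 200, by = 4)])
  expect_lt(abs(log(res0$odds_ratio)), 0.8)
  expect_gt(res0$p, 0.2)

  # toy table against exhaustive tail summation
  uni <- paste0("g", 1:1000)
  set <- uni[1:100]
  category <- c(uni[1:30], uni[500:549])       # 80 total, overlap 30
  res <- fisher_enrichment(uni, set, category)
  expect_equal(res$overlap, 30)
  brute <- sum(sapply(30:80, function(k) {
    choose(80, k) * choose(920, 100 - k) / choose(1000, 100)
  }))
  expect_equal(res$p, brute, tolerance = 1e-9)

  expect_error(fisher_enrichment(character(0), "a", "b"), "Empty")
})

test_that("BH adjustment reproduces the step-up rule and is monotone in p", {
  set.seed(13)
  p <- c(runif(400), rbeta(100, 0.2, 5))
  q <- adjust_bh(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # direct step-up implementation
  for (alpha in c(0.01, 0.05, 0.1)) {
    m <- length(p)
    ps <- sort(p)
    k <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
    rejected_direct <- if (is.finite(k)) p <= ps[k] else rep(FALSE, m)
    expect_identical(q <= alpha + 1e-12, rejected_direct)
  }
})

test_that("standardized profiles are exact z-scores", {
  sim <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 300,
                                                  censoring = NULL, seed = 9))
  eff <- fit_factorial_anova(sim$values, sim$design, method = "moderated")
  cl <- cluster_hypoxic_responses(sim$values, sim$design, eff)
  expect_equal(unname(rowMeans(cl$profiles)),
               rep(0, nrow(cl$profiles)), tolerance = 1e-9)
  expect_equal(unname(apply(cl$profiles, 1, sd)),
               rep(1, nrow(cl$profiles)), tolerance = 1e-9)
})
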