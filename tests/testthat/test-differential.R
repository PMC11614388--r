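# Fold change, enrichment calls, Wilcoxon, BH FDR, pooled summaries and
# full differential tables.

test_that("fold change and log2FC behave, including the pseudo-abundance floor", {
  expect_equal(fold_change(2.27, 1), 2.27)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0, 1, pseudo = 0.01), 0.01)
  expect_error(fold_change(0, 0), "both group means")
  expect_error(fold_change(0, 1), "pseudo")
  expect_equal(log2fc(1), 0)
  expect_error(log2fc(0), "> 0")
  # antisymmetry to machine precision
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(log2fc(fold_change(a, b)), -log2fc(fold_change(b, a)),
                 tolerance = 1e-14)
  }
})

test_that("enrichment classification applies |log2FC| > 1 and p < 0.05", {
  lab <- function(l, p) classify_enrichment(l, p, label_treated = "HFD 3d",
                                            label_control = "CT")
  expect_equal(lab(1.18, 0.01), "HFD 3d")
  expect_equal(lab(-1.14, 0.02), "CT")
  expect_equal(lab(1.83, 0.24), "Not Sig")   # large FC, weak p
  expect_equal(lab(0.68, 0.004), "Not Sig")  # strong p, sub-threshold FC
  expect_equal(lab(1.0, 0.01), "Not Sig")    # threshold is strict
})

test_that("exact Wilcoxon matches full enumeration for all n1, n2 <= 6", {
  set.seed(707)
  for (n1 in 1:6) for (n2 in 1:6) {
    a <- rnorm(n1)
    b <- rnorm(n2)
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact"),
                 enum_wilcoxon_p(a, b), tolerance = 1e-12,
                 info = paste("n1 =", n1, "n2 =", n2))
  }
  # complete separation at n = 6 per group: the smallest achievable p
  expect_equal(wilcoxon_rank_sum(1:6, 7:12), 2 / choose(12, 6),
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(1:2, 3:4), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 4, 5), c(2, 3, 6)), 1)
})

test_that("Wilcoxon modes: ties forbid exact, normal approx has corrections", {
  expect_error(wilcoxon_rank_sum(c(1, 2, 2), c(2, 3, 4), mode = "exact"),
               "ties")
  # auto falls back to the tie/continuity-corrected normal approximation
  p_auto <- wilcoxon_rank_sum(c(1, 2, 2), c(2, 3, 4))
  expect_true(p_auto > 0 && p_auto <= 1)
  p_norm <- wilcoxon_rank_sum(1:6, 7:12, mode = "normal-approx")
  expect_gt(p_norm, 2 / choose(12, 6))  # approximation is conservative here
  expect_lte(p_norm, 1)
})

test_that("BH q-values match the step-up oracle and are monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(808)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pooled two-group summary is exact", {
  s <- pooled_summary(3, 1, 5, 3, 1, 5)
  expect_equal(s$mean, 3)
  # duplicating a group changes the df ratio: sd^2 = 2(n-1)/(2n-1) * s^2,
  # exactly what summarizing the concatenated raw data gives
  a <- c(1.5, 2.5, 3, 3.5, 4.5)  # mean 3, sd(a) rescaled below
  a <- 3 + (a - 3) / sd(a)
  expect_equal(s$sd, sd(c(a, a)), tolerance = 1e-12)
  # composing group summaries equals summarizing the concatenated data
  set.seed(909)
  for (i in 1:10) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = 2, sd = runif(1, 0.5, 3))
    s <- pooled_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    expect_equal(s$mean, mean(c(a, b)), tolerance = 1e-9)
    expect_equal(s$sd, sd(c(a, b)), tolerance = 1e-9)
  }
})

test_that("differential tables assemble, sort, flag and classify", {
  fx <- bundled_fixture("csf_3dHFD", seed = 5)
  dt <- differential_table(fx$abundances, fx$groups, treated = "HFD_3d")
  expect_equal(nrow(dt), 34)
  expect_true(all(c("fc", "log2fc", "p", "minus_log10_p", "enrichment")
                  %in% names(dt)))
  # |log2FC|-descending sort by default, p-ascending behind the flag
  expect_true(all(diff(abs(dt$log2fc)) <= 1e-12))
  dtp <- differential_table(fx$abundances, fx$groups, treated = "HFD_3d",
                            test = "wilcoxon", with_fdr = TRUE, sort = "p")
  expect_true(all(diff(dtp$p) >= -1e-12))
  expect_true(all(dtp$q >= dtp$p - 1e-12))
  # a broken metabolite row is flagged, not fatal
  ab <- fx$abundances
  ab["Carnitine", ] <- 0
  dt2 <- differential_table(ab, fx$groups, treated = "HFD_3d")
  bad <- dt2[dt2$metabolite == "Carnitine", ]
  expect_false(is.na(bad$note))
  expect_equal(sum(!is.na(dt2$note)), 1)
  expect_error(differential_table(fx$abundances, rep("A", 20)), "two groups")
})

test_that("a true 2.5-fold effect at n = 10, CV 20% is reliably called", {
  des <- study_design(group_sizes = c(CT = 10L, HFD = 10L),
                      baseline = c(hit = 1e6, null1 = 2e6, null2 = 5e5),
                      effects = c(hit = 2.5), treated = "HFD")
  hits <- 0
  n_sim <- 200
  for (r in seq_len(n_sim)) {
    sim <- simulate_two_group_table(des, noise_model(cv = 0.20), seed = 9000 + r)
    dt <- differential_table(sim$abundances, sim$groups, treated = "HFD")
    if (dt$enrichment[dt$metabolite == "hit"] == "HFD") hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("permuted group labels stay at the nominal false-call level", {
  fx <- bundled_fixture("csf_3dHFD", seed = 21)
  set.seed(321)
  n_perm <- 300
  p_under_null <- matrix(NA_real_, n_perm, nrow(fx$abundances))
  for (r in seq_len(n_perm)) {
    g <- sample(fx$groups)
    dt <- differential_table(fx$abundances, g, treated = "HFD_3d", sort = "p")
    p_under_null[r, ] <- dt$p[match(rownames(fx$abundances), dt$metabolite)]
  }
  # p-values under permutation are approximately uniform per metabolite
  rate <- mean(p_under_null < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(p_under_null)) + 0.01)
})
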