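test_that("causal clusters are evenly spaced with the exact effect ratio", {
  model <- simulate_hmm_model(p = 600, K = 5, seed = 1)
  variants <- variant_table(model)
  spec <- place_causal_clusters(variants, seed = 2)
  expect_length(spec$idx, 30)                      # 6 clusters of 5
  expect_equal(as.vector(table(spec$cluster)), rep(5L, 6))
  # each cluster fits in a 0.1-Mb window
  for (ci in unique(spec$cluster)) {
    bps <- variants$bp[spec$idx[spec$cluster == ci]]
    expect_lte(max(bps) - min(bps), 1e5)
  }
  # cluster centers are evenly spaced
  centers <- vapply(unique(spec$cluster), function(ci)
    mean(range(variants$bp[spec$idx[spec$cluster == ci]])), numeric(1))
  expect_lt(sd(diff(centers)) / mean(diff(centers)), 0.25)
  # smallest over largest magnitude is exactly 1/19
  mags <- abs(spec$beta)
  expect_equal(min(mags) / max(mags), 1 / 19, tolerance = 1e-12)
  # within a cluster all magnitudes agree (per-cluster draw)
  expect_true(all(tapply(mags, spec$cluster, function(v) diff(range(v))) == 0))
  # ratio one means equal magnitudes everywhere
  spec1 <- place_causal_clusters(variants, effect_ratio = 1, seed = 3)
  expect_true(all(abs(spec1$beta) == 1))
  # per-variant draws still respect the exact ratio
  specv <- place_causal_clusters(variants, per_variant = TRUE, seed = 4)
  mv <- abs(specv$beta)
  expect_equal(min(mv) / max(mv), 1 / 19, tolerance = 1e-12)
})

test_that("a window without enough variants is skipped with a warning", {
  # variants at both ends of the span, none in the middle window
  variants <- data.frame(id = paste0("v", 1:20), chrom = "1",
                         bp = c(1:10 * 2000, 1:10 * 2000 + 180000))
  expect_warning(
    spec <- place_causal_clusters(variants, n_clusters = 3, cluster_size = 5,
                                  seed = 5),
    "skipped")
  expect_equal(max(spec$cluster), 2)
})

test_that("gaussian traits realize the requested heritability exactly", {
  study <- small_true_study(n = 5000, p = 120, K = 4, seed = 6)
  spec <- place_causal_clusters(study$variants, n_clusters = 2, seed = 7,
                                h2 = 0.5)
  y <- simulate_gaussian_trait(study$X, spec, seed = 8)
  g <- scale(study$X[, spec$idx]) %*% spec$beta
  fit <- lm(y ~ g)
  r2 <- summary(fit)$r.squared
  expect_equal(r2, 0.5, tolerance = 0.02)
  # h2 = 0: pure noise, no correlation with causal variants
  spec0 <- spec
  spec0$h2 <- 0
  y0 <- simulate_gaussian_trait(study$X, spec0, seed = 9)
  expect_lt(max(abs(cor(y0, study$X[, spec$idx]))), 0.06)
  # scale invariance: doubling beta gives the identical trait
  spec2 <- spec
  spec2$beta <- 2 * spec$beta
  expect_identical(simulate_gaussian_trait(study$X, spec, seed = 8),
                   simulate_gaussian_trait(study$X, spec2, seed = 8))
  spec_bad <- spec
  spec_bad$h2 <- 1.2
  expect_error(simulate_gaussian_trait(study$X, spec_bad), "h2")
})

test_that("probit traits threshold the latent liability", {
  study <- small_true_study(n = 2000, p = 80, K = 3, seed = 10)
  spec <- place_causal_clusters(study$variants, n_clusters = 2, seed = 11,
                                family = "probit")
  # low threshold: nearly all cases
  y <- simulate_probit_trait(study$X, spec, latent_h2 = 0.4, threshold = -2.5,
                             seed = 12)
  expect_gt(attr(y, "case_fraction"), 0.99)
  # a rare-disease threshold gives the intended imbalance
  y2 <- simulate_probit_trait(study$X, spec, latent_h2 = 0.4,
                              threshold = qnorm(0.9), seed = 13)
  expect_lt(abs(attr(y2, "case_fraction") - 0.1), 0.05)
  # degenerate draws are refused
  expect_error(simulate_probit_trait(study$X, spec, latent_h2 = 0.4,
                                     threshold = 10, seed = 14),
               "degenerate")
  # no heritability: genotypes carry no signal
  y0 <- simulate_probit_trait(study$X, spec, latent_h2 = 0, threshold = 0,
                              seed = 15)
  expect_lt(max(abs(cor(y0, study$X[, spec$idx]))), 0.07)
})

test_that("discovery scoring matches a brute-force set oracle", {
  set.seed(16)
  for (i in 1:50) {
    p <- 100
    spec <- list(idx = sort(sample(p, 8)), cluster = rep(1:2, each = 4))
    nd <- sample(0:6, 1)
    from <- sort(sample(p - 5, max(nd, 1)))[seq_len(nd)]
    d <- data.frame(from = from, to = pmin(from + sample(0:5, max(nd, 1),
                                                         replace = TRUE)[seq_len(nd)], p))
    ev <- evaluate_discoveries(d, spec)
    truth <- if (nd == 0) 0 else
      vapply(seq_len(nd), function(k)
        length(intersect(spec$idx, seq(d$from[k], d$to[k]))) > 0, logical(1))
    expect_equal(ev$n_true, as.integer(sum(truth)))
    expect_equal(ev$fdp, if (nd == 0) 0 else sum(!truth) / nd)
  }
  ev0 <- evaluate_discoveries(data.frame(), list(idx = 3, cluster = 1))
  expect_equal(ev0$fdp, 0)
  expect_equal(ev0$n_total, 0L)
})

test_that("locus detection respects the base-pair margin", {
  variants <- data.frame(id = paste0("v", 1:100), chrom = "1", bp = 1:100 * 2000)
  spec <- list(idx = 50, cluster = 1)           # causal SNP at 100 kb
  d <- data.frame(from = 20, to = 25, bp_min = 40000, bp_max = 50000)
  # discovery ends 50 kb away from the causal SNP
  expect_equal(evaluate_locus_detection(d, spec, variants,
                                        margin_bp = 1e5)$power, 1)
  expect_equal(evaluate_locus_detection(d, spec, variants,
                                        margin_bp = 1e4)$power, 0)
  # margin zero requires covering the causal SNP
  dcov <- data.frame(from = 48, to = 52, bp_min = 96000, bp_max = 104000)
  expect_equal(evaluate_locus_detection(dcov, spec, variants,
                                        margin_bp = 0)$power, 1)
  expect_equal(evaluate_locus_detection(data.frame(), spec, variants)$power, 0)
})
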