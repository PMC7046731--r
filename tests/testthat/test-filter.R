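# independent brute-force threshold: evaluate the ratio at every candidate
brute_threshold <- function(W, q, offset = 1) {
  ts <- sort(unique(abs(W[W != 0])))
  ok <- vapply(ts, function(t)
    (offset + sum(W <= -t)) / max(1, sum(W >= t)) <= q, logical(1))
  if (any(ok)) min(ts[ok]) else Inf
}

test_that("threshold worked examples select the expected groups", {
  W <- c(5, 4, 3, 2, 1, -1)
  tau <- knockoff_threshold(W, q = 0.5)
  expect_equal(tau, 1)
  part <- new_partition(seq_len(6),
                        variants = data.frame(id = letters[1:6], chrom = "1",
                                              bp = 1:6 * 100))
  sel <- knockoff_select(W, tau, part, q = 0.5)
  expect_equal(sel$group, 1:5)
  expect_equal(attr(sel, "threshold"), 1)
  # singleton-resolution selection reports single-variant ranges
  expect_true(all(sel$from == sel$to))
})

test_that("the one-over-q power floor appears at the boundary", {
  W10 <- seq(0.1, 1, by = 0.1)            # 10 strictly positive
  expect_equal(knockoff_threshold(W10, q = 0.1), 0.1)  # (1+0)/10 = 0.1
  W9 <- W10[-1]                            # only 9 positive
  expect_equal(knockoff_threshold(W9, q = 0.1), Inf)
  # all negative: nothing can be selected
  expect_equal(knockoff_threshold(-W10, q = 0.2), Inf)
  part <- new_partition(rep(1:10, each = 1),
                        variants = data.frame(id = paste0("v", 1:10),
                                              chrom = "1", bp = 1:10))
  expect_equal(nrow(knockoff_select(W9, Inf, part)), 0)
})

test_that("threshold agrees with brute force on fuzzed vectors", {
  set.seed(20)
  for (i in 1:1000) {
    L <- sample(3:60, 1)
    W <- round(rnorm(L) * sample(c(1, 10), 1), 2)
    q <- runif(1, 0.05, 0.6)
    expect_identical(knockoff_threshold(W, q), brute_threshold(W, q))
  }
  expect_error(knockoff_threshold(numeric(0), 0.1), "empty")
  expect_error(knockoff_threshold(c(1, NA), 0.1), "finite")
})

test_that("lowering q never enlarges the discovery set", {
  set.seed(21)
  for (i in 1:50) {
    W <- rnorm(80) + c(rep(2, 20), rep(0, 60))
    qs <- sort(runif(2, 0.05, 0.5))
    sel_lo <- which(W >= knockoff_threshold(W, qs[1]))
    sel_hi <- which(W >= knockoff_threshold(W, qs[2]))
    expect_true(all(sel_lo %in% sel_hi))
  }
})

test_that("offset zero warns about the lost guarantee", {
  expect_warning(knockoff_threshold(c(2, 1, -1), q = 0.3, offset = 0),
                 "guarantee")
})

test_that("local FDR is near one under the null and orders signals first", {
  # fully null: symmetric W
  set.seed(22)
  means <- vapply(1:10, function(i) {
    W <- rnorm(400)
    mean(local_fdr(W)[W > 0], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means) - 1), 0.15)
  # mixture: 10% strong signals
  set.seed(23)
  W <- c(rnorm(360), rnorm(40, mean = 5))
  lf <- local_fdr(W)
  is_sig <- c(rep(FALSE, 360), rep(TRUE, 40)) & W > 0
  expect_lt(mean(lf[is_sig], na.rm = TRUE),
            mean(lf[W > 0 & !is_sig], na.rm = TRUE))
  # huge outlier is confidently non-null
  W2 <- c(rnorm(400), 50)
  expect_lt(local_fdr(W2)[401], 0.1)
  # monotone non-increasing in w
  lfp <- lf[W > 0]
  wp <- W[W > 0]
  expect_true(all(diff(lfp[order(wp)]) <= 1e-12))
  # refuses tiny inputs
  out <- local_fdr(rnorm(50))
  expect_true(all(is.na(out)))
  expect_true(isTRUE(attr(out, "too_few")))
})

make_toy_multires <- function() {
  variants <- data.frame(id = paste0("v", 1:8), chrom = "1", bp = 1:8 * 1000)
  parts <- list(new_partition(c(1, 1, 1, 1, 2, 2, 2, 2), variants),
                new_partition(c(1, 1, 2, 2, 3, 3, 4, 4), variants),
                new_partition(1:8, variants))
  list(variants = variants, parts = parts)
}

toy_select <- function(part, groups, q = 0.1) {
  W <- rep(-1, part$L)
  W[groups] <- 2
  knockoff_select(W, 2, part, q = q)
}

test_that("simplified count keeps the most specific supported finding", {
  toy <- make_toy_multires()
  # same locus at all three resolutions: only the finest kept
  d <- list(toy_select(toy$parts[[1]], 1),
            toy_select(toy$parts[[2]], 2),
            toy_select(toy$parts[[3]], 3))
  out <- simplified_count(d, toy$parts)
  expect_equal(nrow(out$simplified), 1)
  expect_equal(out$simplified$level, 3)
  expect_equal(out$simplified$from, 3L)
  expect_false(any(unlist(out$flags)))
})

test_that("unsupported fine discoveries float and are excluded", {
  toy <- make_toy_multires()
  d <- list(toy_select(toy$parts[[1]], 1),       # coarse locus: variants 1-4
            toy_select(toy$parts[[2]], c(1, 4)), # group 4 (variants 7-8) floats
            knockoff_select(rep(-1, 8), Inf, toy$parts[[3]]))
  out <- simplified_count(d, toy$parts)
  expect_equal(out$flags[[2]], c(FALSE, TRUE))
  # kept: the supported mid-level discovery (group 1), not the floating one
  expect_equal(sort(out$simplified$level), 2)
  expect_equal(out$simplified$group[out$simplified$level == 2], 1)
})

test_that("disjoint loci at different resolutions are all kept", {
  toy <- make_toy_multires()
  d <- list(toy_select(toy$parts[[1]], 1),              # variants 1-4
            toy_select(toy$parts[[2]], c(1, 3)),        # 1-2 and 5-6
            knockoff_select(rep(-1, 8), Inf, toy$parts[[3]]))
  out <- simplified_count(d, toy$parts)
  # mid discovery in 1-2 supersedes the coarse one; 5-6 floats (no coarse
  # support at variants 5-8), so only the supported mid finding remains
  expect_equal(out$flags[[2]], c(FALSE, TRUE))
  expect_equal(out$simplified$level, 2)
  # truly disjoint: coarse locus 2 plus a supported fine finding elsewhere
  d2 <- list(toy_select(toy$parts[[1]], c(1, 2)),
             toy_select(toy$parts[[2]], 3),
             knockoff_select(rep(-1, 8), Inf, toy$parts[[3]]))
  out2 <- simplified_count(d2, toy$parts)
  expect_equal(sort(out2$simplified$level), c(1, 2))
  # the coarse group 1 (no finer finding inside) and the mid group 3 survive
  expect_equal(out2$simplified$from[out2$simplified$level == 1], 1L)
  # summary never exceeds the per-resolution total
  expect_lte(nrow(out2$simplified), sum(vapply(d2, nrow, integer(1))))
})
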