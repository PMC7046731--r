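#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact (conditional) test for a biallelic variant: the probability of each
#' possible heterozygote count given the observed allele counts is computed
#' in log space, and the p-value sums the probabilities of all outcomes no
#' more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  n_alt <- 2 * n_hom_alt + n_het
  n_rare <- min(n_alt, 2 * n - n_alt)
  # heterozygote counts sharing the allele counts have the parity of n_rare
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2          # rare homozygotes
    hc <- n - h - hr                # common homozygotes
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(hc + 1) - lgamma(h + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Quality-control filter on genotypes
#'
#' Keeps variants with minor allele frequency above `maf_min` and exact
#' Hardy-Weinberg p-value at least `hwe_p_min` (defaults mirror the common
#' GWAS choices of 0.1 percent and 1e-6). Missing genotypes are ignored in
#' both computations.
#'
#' @param X n x p genotype matrix (0/1/2, `NA` missing).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param hwe_p_min minimum HWE exact p-value (inclusive).
#' @return the filtered matrix, with attributes `kept` (column indices),
#'   `removed_maf` and `removed_hwe`.
#' @export
qc_filter <- function(X, maf_min = 0.001, hwe_p_min = 1e-6) {
  X <- as.matrix(X)
  p <- ncol(X)
  maf <- vapply(seq_len(p), function(j) {
    v <- X[, j]
    f <- mean(v, na.rm = TRUE) / 2
    min(f, 1 - f)
  }, numeric(1))
  hwe <- vapply(seq_len(p), function(j) {
    v <- X[, j]
    hwe_exact_p(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
                sum(v == 2, na.rm = TRUE))
  }, numeric(1))
  bad_maf <- maf <= maf_min | is.na(maf)
  bad_hwe <- !bad_maf & hwe < hwe_p_min
  keep <- which(!bad_maf & !bad_hwe)
  out <- X[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  attr(out, "removed_maf") <- which(bad_maf)
  attr(out, "removed_hwe") <- which(bad_hwe)
  out
}

#' Mean-impute missing genotypes
#'
#' Per-variant mean imputation, the deterministic preprocessing used before
#' HMM fitting and regression.
#'
#' @param X genotype matrix with possible `NA`s.
#' @return numeric matrix without missing values.
#' @export
mean_impute <- function(X) {
  X <- as.matrix(X)
  for (j in which(colSums(is.na(X)) > 0)) {
    v <- X[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    X[, j] <- v
  }
  X
}
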