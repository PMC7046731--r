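#' Random haplotype-cluster HMM for synthetic studies
#'
#' Generates a ground-truth model emulating local LD on a regular variant
#' grid: uniform cluster weights, cluster/site-specific allele frequencies
#' drawn from Uniform(0.05, 0.95) (keeping variants comfortably polymorphic)
#' and per-site jump probabilities from Uniform(0.02, 0.08), so LD decays
#' over a few tens of kilobases at the default 2-kb spacing.
#'
#' @param p number of variants.
#' @param K number of haplotype clusters.
#' @param seed integer seed.
#' @param spacing_bp distance between adjacent variants (default 2000, so a
#'   0.1-Mb causal window holds about 50 variants).
#' @param r_range range of the per-site jump probability.
#' @param theta_range range of the emission frequencies.
#' @param chrom chromosome label.
#' @return a [haplotype_hmm()].
#' @export
simulate_hmm_model <- function(p = 600, K = 5, seed = 1, spacing_bp = 2000,
                               r_range = c(0.02, 0.08),
                               theta_range = c(0.05, 0.95), chrom = "1") {
  set.seed(seed)
  alpha <- matrix(1 / K, p, K)
  theta <- matrix(runif(p * K, theta_range[1], theta_range[2]), p, K)
  r <- c(1, runif(p - 1, r_range[1], r_range[2]))
  haplotype_hmm(alpha, theta, r, positions = spacing_bp * seq_len(p),
                chrom = chrom)
}

#' Variant table for a model
#'
#' @param model a [haplotype_hmm()].
#' @param H optional haplotype matrix for empirical allele frequencies.
#' @return data.frame with columns `id`, `chrom`, `bp`, `a1`, `a2`, `maf`.
#' @export
variant_table <- function(model, H = NULL) {
  p <- model$p
  af <- if (!is.null(H)) colMeans(H) else rowSums(model$alpha * model$theta)
  data.frame(id = sprintf("snp%05d", seq_len(p)), chrom = model$chrom,
             bp = model$positions, a1 = "A", a2 = "B",
             maf = pmin(af, 1 - af))
}

#' Place clustered causal variants
#'
#' Causal variants sit in evenly spaced windows of fixed width (default
#' 0.1 Mb, 5 variants each). Each cluster receives one relative effect
#' magnitude, drawn uniformly and then linearly rescaled so that the ratio
#' of the smallest to the largest magnitude equals `effect_ratio` exactly;
#' signs are random per variant. Effects attach to standardized genotypes,
#' so rarer variants carry stronger per-allele effects.
#'
#' @param variants a [variant_table()]-style data.frame.
#' @param n_clusters number of causal clusters (default 6).
#' @param cluster_size causal variants per cluster (default 5).
#' @param cluster_width_bp window width in bp (default 1e5).
#' @param effect_ratio smallest/largest relative magnitude (default 1/19).
#' @param seed integer seed.
#' @param h2 target heritability stored in the spec (default 0.3).
#' @param family trait family stored in the spec.
#' @param threshold liability threshold for probit traits.
#' @param per_variant when TRUE, draw a relative magnitude per variant
#'   instead of one per cluster.
#' @return object of class `causal_spec`: list with `idx` (causal variant
#'   indices), `cluster` (cluster id per causal variant), `beta` (signed
#'   standardized effects, aligned to `idx`), `h2`, `family`, `threshold`.
#' @export
place_causal_clusters <- function(variants, n_clusters = 6, cluster_size = 5,
                                  cluster_width_bp = 1e5,
                                  effect_ratio = 1 / 19, seed = 1,
                                  h2 = 0.3, family = "gaussian",
                                  threshold = 0, per_variant = FALSE) {
  set.seed(seed)
  bp <- variants$bp
  span <- range(bp)
  centers <- span[1] + (seq_len(n_clusters) - 0.5) / n_clusters *
    (span[2] - span[1])
  idx <- integer(0)
  cluster <- integer(0)
  kept <- 0L
  for (ci in seq_len(n_clusters)) {
    inwin <- which(bp >= centers[ci] - cluster_width_bp / 2 &
                   bp <= centers[ci] + cluster_width_bp / 2)
    if (length(inwin) < cluster_size) {
      warning(sprintf("window %d has %d < %d variants: skipped",
                      ci, length(inwin), cluster_size))
      next
    }
    kept <- kept + 1L
    pick <- sort(sample(inwin, cluster_size))
    idx <- c(idx, pick)
    cluster <- c(cluster, rep(kept, cluster_size))
  }
  if (kept == 0) stop("no causal window had enough variants")
  n_unit <- if (per_variant) length(idx) else kept
  u <- runif(n_unit)
  if (n_unit == 1 || diff(range(u)) == 0 || effect_ratio == 1) {
    mag <- rep(1, n_unit)
  } else {
    mag <- effect_ratio + (1 - effect_ratio) * (u - min(u)) / (max(u) - min(u))
    mag[which.min(u)] <- effect_ratio  # endpoints exact
    mag[which.max(u)] <- 1
  }
  magv <- if (per_variant) mag else mag[cluster]
  beta <- magv * sample(c(-1, 1), length(idx), replace = TRUE)
  structure(list(idx = idx, cluster = cluster, beta = beta, h2 = h2,
                 family = family, threshold = threshold),
            class = "causal_spec")
}

# standardized genetic score with unit sample variance
genetic_score <- function(X, spec) {
  Xc <- scale(X[, spec$idx, drop = FALSE])
  if (any(!is.finite(Xc))) stop("causal variant with zero variance")
  g <- as.vector(Xc %*% spec$beta)
  g / stats::sd(g)
}

#' Gaussian trait from a causal specification
#'
#' `y = sqrt(h2) * g + sqrt(1 - h2) * e`, where `g` is the standardized
#' genetic score and `e` is Gaussian noise residualized against `g` and
#' rescaled to unit sample variance, so the realized heritability
#' `var(g-part)/var(y)` equals `h2` exactly rather than in expectation.
#'
#' @param X genotype matrix.
#' @param spec a [place_causal_clusters()] result with `family = "gaussian"`.
#' @param seed integer seed.
#' @return numeric phenotype vector of length `nrow(X)`.
#' @export
simulate_gaussian_trait <- function(X, spec, seed = 1) {
  if (spec$h2 < 0 || spec$h2 >= 1) stop("h2 must lie in [0, 1)")
  set.seed(seed)
  n <- nrow(X)
  e <- rnorm(n)
  if (spec$h2 == 0) return(e)
  g <- genetic_score(X, spec)
  e <- stats::residuals(stats::lm.fit(cbind(1, g), e))
  e <- e / stats::sd(e)
  sqrt(spec$h2) * g + sqrt(1 - spec$h2) * e
}

#' Binary trait from a liability-threshold (probit) model
#'
#' A latent Gaussian liability is built as in [simulate_gaussian_trait()]
#' with heritability `latent_h2`; the trait is the indicator that the
#' liability exceeds `threshold`. The realized case fraction is attached as
#' an attribute.
#'
#' @param X genotype matrix.
#' @param spec a [place_causal_clusters()] result.
#' @param latent_h2 heritability of the latent liability.
#' @param threshold liability threshold (on the roughly unit-variance
#'   liability scale; e.g. `qnorm(0.8)` for about 20 percent cases).
#' @param seed integer seed.
#' @return integer 0/1 vector with attribute `case_fraction`.
#' @export
simulate_probit_trait <- function(X, spec, latent_h2 = 0.5, threshold = 0,
                                  seed = 1) {
  spec$h2 <- latent_h2
  liab <- simulate_gaussian_trait(X, spec, seed = seed)
  y <- as.integer(liab > threshold)
  if (all(y == 1) || all(y == 0))
    stop("degenerate draw: all cases or all controls; adjust the threshold")
  attr(y, "case_fraction") <- mean(y)
  y
}

#' Score a discovery set against the causal truth
#'
#' A discovery is false when its reported variant range contains no causal
#' variant.
#'
#' @param discoveries a `discovery_set` (or data.frame with `from`, `to`).
#' @param spec a [place_causal_clusters()] result.
#' @return list with `fdp`, `n_true`, `n_false`, `n_total`.
#' @export
evaluate_discoveries <- function(discoveries, spec) {
  n_total <- nrow(discoveries)
  if (is.null(n_total) || n_total == 0)
    return(list(fdp = 0, n_true = 0L, n_false = 0L, n_total = 0L))
  true <- vapply(seq_len(n_total), function(i) {
    any(spec$idx >= discoveries$from[i] & spec$idx <= discoveries$to[i])
  }, logical(1))
  list(fdp = sum(!true) / max(1, n_total), n_true = sum(true),
       n_false = sum(!true), n_total = n_total)
}

#' Region-level detection power
#'
#' A causal cluster counts as detected when any discovery's base-pair range
#' comes within `margin_bp` of any of its causal variants.
#'
#' @param discoveries a `discovery_set` with `bp_min`, `bp_max` columns.
#' @param spec a [place_causal_clusters()] result.
#' @param variants the variant table (for causal base-pair positions).
#' @param margin_bp detection margin in bp (default 1e5).
#' @return list with `power`, `n_detected`, `n_regions`.
#' @export
evaluate_locus_detection <- function(discoveries, spec, variants,
                                     margin_bp = 1e5) {
  stopifnot(margin_bp >= 0)
  regions <- unique(spec$cluster)
  if (is.null(nrow(discoveries)) || nrow(discoveries) == 0)
    return(list(power = 0, n_detected = 0L, n_regions = length(regions)))
  detected <- vapply(regions, function(ci) {
    bps <- variants$bp[spec$idx[spec$cluster == ci]]
    any(vapply(bps, function(b) {
      dist <- ifelse(b >= discoveries$bp_min & b <= discoveries$bp_max, 0,
                     pmin(abs(b - discoveries$bp_min),
                          abs(b - discoveries$bp_max)))
      any(dist <= margin_bp)
    }, logical(1)))
  }, logical(1))
  list(power = mean(detected), n_detected = sum(detected),
       n_regions = length(regions))
}

#' Full synthetic study
#'
#' Draws a ground-truth HMM, phased haplotypes for `n` diploid samples,
#' the genotype matrix, a clustered causal architecture and a trait.
#'
#' @param n number of diploid samples.
#' @param p number of variants.
#' @param K number of haplotype clusters of the generating model.
#' @param h2 trait heritability (latent heritability for probit).
#' @param family `"gaussian"` or `"probit"`.
#' @param threshold liability threshold for probit traits.
#' @param n_clusters,cluster_size causal architecture (defaults 6 clusters
#'   of 5).
#' @param seed integer seed.
#' @return list with `model`, `H` (2n x p), `X` (n x p), `variants`, `spec`
#'   and `y`.
#' @export
simulate_study <- function(n = 2000, p = 600, K = 5, h2 = 0.3,
                           family = "gaussian", threshold = 0,
                           n_clusters = 6, cluster_size = 5, seed = 1) {
  model <- simulate_hmm_model(p = p, K = K, seed = seed)
  H <- sample_haplotypes(model, 2 * n, seed = seed + 1)$H
  X <- haplotypes_to_genotypes(H)
  variants <- variant_table(model, H)
  spec <- place_causal_clusters(variants, n_clusters = n_clusters,
                                cluster_size = cluster_size, seed = seed + 2,
                                h2 = h2, family = family,
                                threshold = threshold)
  y <- if (family == "gaussian") {
    simulate_gaussian_trait(X, spec, seed = seed + 3)
  } else {
    simulate_probit_trait(X, spec, latent_h2 = h2, threshold = threshold,
                          seed = seed + 3)
  }
  list(model = model, H = H, X = X, variants = variants, spec = spec, y = y)
}
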