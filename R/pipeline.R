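#' Multi-resolution knockoff analysis of phased haplotypes
#'
#' End-to-end pipeline: fit the haplotype-cluster HMM, build nested LD-based
#' partitions, generate group knockoffs at every resolution, compute
#' sparse-regression importance statistics on the augmented design and apply
#' the knockoff filter at each resolution. Partitions are built from the
#' haplotypes alone, before the phenotype is touched, and the knockoff
#' generation never sees `y`.
#'
#' @param H phased binary haplotype matrix (2 rows per sample).
#' @param y phenotype vector (numeric, or 0/1 for binary traits).
#' @param variants variant table (`id`, `chrom`, `bp` columns).
#' @param Z optional covariate matrix (unpenalized in the regression).
#' @param K number of HMM clusters.
#' @param q nominal FDR level.
#' @param family `"gaussian"` or `"binomial"`.
#' @param mean_group_sizes target mean group sizes in variants, coarse to
#'   fine (default `c(10, 3, 1)`; 1 means single-variant resolution).
#' @param seed master seed; all stages derive their seeds from it.
#' @param em_args list of arguments for [fit_hmm_em()] (`max_iter`, `tol`,
#'   `n_restarts`).
#' @param model optional pre-fitted [haplotype_hmm()]; skips the EM stage.
#' @param ld_window LD window in variants for [ld_r2()].
#' @param nfolds CV folds for the lasso.
#' @param compute_local_fdr whether to attach local-FDR estimates.
#' @return object of class `mrk_analysis`: list with `model`, `mrp`
#'   (partitions), `stats` (per resolution: T, T_tilde, W, lambda_cv),
#'   `discoveries` (list of `discovery_set`), `simplified` and `q`.
#' @export
mrk_analyze <- function(H, y, variants, Z = NULL, K = 5, q = 0.1,
                        family = "gaussian",
                        mean_group_sizes = c(10, 3, 1), seed = 1,
                        em_args = list(max_iter = 20, tol = 1e-3,
                                       n_restarts = 2),
                        model = NULL, ld_window = 1000, nfolds = 10,
                        compute_local_fdr = FALSE) {
  H <- check_haplotypes(H)
  p <- ncol(H)
  n <- nrow(H) / 2
  stopifnot(length(y) == n)
  if (is.null(model)) {
    model <- do.call(fit_hmm_em,
                     c(list(H = H, K = K, seed = seed,
                            positions = variants$bp,
                            chrom = variants$chrom[1]), em_args))
  }
  ld <- ld_r2(H, window = ld_window)
  tree <- build_dendrogram(ld)
  n_groups <- pmax(1, round(p / mean_group_sizes))
  mrp <- cut_partitions_by_groups(tree, n_groups, variants = variants)
  X <- haplotypes_to_genotypes(H)
  stats <- vector("list", length(mrp$partitions))
  discoveries <- vector("list", length(mrp$partitions))
  for (i in seq_along(mrp$partitions)) {
    part <- mrp$partitions[[i]]
    Xt <- genotype_knockoffs_from_phased(model, H, part, seed = seed + 1000 * i)
    st <- importance_stats(Z, X, Xt, y, part, family = family,
                           nfolds = nfolds, fold_seed = seed,
                           seed = seed + 1000 * i + 1)
    tau <- knockoff_threshold(st$W, q = q)
    lf <- if (compute_local_fdr) local_fdr(st$W) else NULL
    discoveries[[i]] <- knockoff_select(st$W, tau, part, q = q,
                                        local_fdr = lf)
    st$threshold <- tau
    stats[[i]] <- st
  }
  simp <- simplified_count(discoveries, mrp)
  structure(list(model = model, mrp = mrp, stats = stats,
                 discoveries = discoveries, simplified = simp$simplified,
                 floating = simp$flags, q = q),
            class = "mrk_analysis")
}

#' @exportS3Method base::print
print.mrk_analysis <- function(x, ...) {
  cat(sprintf("Multi-resolution knockoff analysis (q = %.2f)\n", x$q))
  for (i in seq_along(x$discoveries)) {
    d <- x$discoveries[[i]]
    cat(sprintf("  resolution %d (%s): %d group(s) selected of %d\n",
                i, attr(d, "label"), nrow(d), attr(d, "n_groups")))
  }
  cat(sprintf("  simplified count: %d\n",
              if (is.null(nrow(x$simplified))) 0 else nrow(x$simplified)))
  invisible(x)
}

#' One simulated replicate of the full pipeline, scored against the truth
#'
#' Generates a synthetic study, runs [mrk_analyze()] and evaluates the
#' false-discovery proportion and detection power at every resolution.
#'
#' @param seed replicate seed.
#' @param n,p,K,h2,family,threshold passed to [simulate_study()].
#' @param q nominal FDR level.
#' @param n_clusters number of causal clusters in the simulated architecture.
#' @param mean_group_sizes resolution ladder (see [mrk_analyze()]).
#' @param em_args EM settings (see [mrk_analyze()]).
#' @param nfolds CV folds.
#' @return list with `fdp` (per resolution), `power` (locus-detection power
#'   per resolution), `n_sel` (discovery counts) and the analysis object.
#' @export
mrk_replicate <- function(seed, n = 2000, p = 600, K = 5, h2 = 0.3,
                          family = "gaussian", threshold = 0, q = 0.1,
                          n_clusters = 6, mean_group_sizes = c(10, 3, 1),
                          em_args = list(max_iter = 20, tol = 1e-3,
                                         n_restarts = 2), nfolds = 10) {
  sim <- simulate_study(n = n, p = p, K = K, h2 = h2, family = family,
                        threshold = threshold, n_clusters = n_clusters,
                        seed = seed)
  fam <- if (family == "probit") "binomial" else family
  ana <- mrk_analyze(sim$H, sim$y, sim$variants, K = K, q = q, family = fam,
                     mean_group_sizes = mean_group_sizes,
                     seed = seed + 7, em_args = em_args, nfolds = nfolds)
  fdp <- vapply(ana$discoveries, function(d) evaluate_discoveries(d, sim$spec)$fdp,
                numeric(1))
  pow <- vapply(ana$discoveries, function(d)
    evaluate_locus_detection(d, sim$spec, sim$variants)$power, numeric(1))
  nsel <- vapply(ana$discoveries, nrow, integer(1))
  list(fdp = fdp, power = pow, n_sel = nsel, analysis = ana, spec = sim$spec)
}
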