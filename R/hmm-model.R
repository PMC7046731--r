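#' Haplotype-cluster hidden Markov model
#'
#' Constructs the fastPHASE-style haplotype-cluster HMM that defines the
#' genotype distribution used for knockoff construction. Latent states are
#' `K` ancestral haplotype clusters; the chain moves along the genome with
#' per-site jump probabilities `r` (a jump redraws the cluster from the
#' site's weight vector `alpha[j, ]`, modeling recombination), and alleles
#' are emitted with cluster-specific frequencies `theta`.
#'
#' @param alpha p x K matrix of per-site cluster weights; each row must sum
#'   to one. Row `j` is both the jump destination distribution at site `j`
#'   and, for `j = 1`, the initial state distribution.
#' @param theta p x K matrix of alternate-allele emission frequencies in
#'   `[0, 1]`.
#' @param r length-p vector of jump probabilities in `[0, 1]`; `r[1]` must
#'   equal 1 (the first site always draws from `alpha[1, ]`).
#' @param positions length-p vector of 1-based base-pair coordinates,
#'   strictly increasing.
#' @param chrom chromosome label.
#' @return An object of class `haplotype_hmm` with fields `K`, `p`, `alpha`,
#'   `theta`, `r`, `positions`, `chrom`.
#' @export
haplotype_hmm <- function(alpha, theta, r, positions = NULL, chrom = "1") {
  alpha <- as.matrix(alpha)
  theta <- as.matrix(theta)
  p <- nrow(alpha)
  K <- ncol(alpha)
  if (is.null(positions)) positions <- seq_len(p)
  stopifnot(nrow(theta) == p, ncol(theta) == K, length(r) == p,
            length(positions) == p)
  if (any(abs(rowSums(alpha) - 1) > 1e-8))
    stop("each row of alpha must sum to 1")
  if (any(theta < 0 | theta > 1)) stop("theta entries must lie in [0, 1]")
  if (any(r < 0 | r > 1)) stop("r entries must lie in [0, 1]")
  if (abs(r[1] - 1) > 1e-12) stop("r[1] must equal 1")
  if (p > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  structure(
    list(K = K, p = p, alpha = unname(alpha), theta = unname(theta),
         r = as.numeric(r), positions = as.numeric(positions),
         chrom = as.character(chrom)),
    class = "haplotype_hmm"
  )
}

#' @exportS3Method base::print
print.haplotype_hmm <- function(x, ...) {
  cat(sprintf("Haplotype-cluster HMM: K = %d clusters, p = %d variants, chr %s\n",
              x$K, x$p, x$chrom))
  cat(sprintf("  mean jump probability (r[2:p]): %.4f\n",
              if (x$p > 1) mean(x$r[-1]) else NA_real_))
  invisible(x)
}

check_haplotypes <- function(H, model = NULL) {
  H <- as.matrix(H)
  if (!all(H %in% c(0L, 1L))) stop("haplotype matrix must be binary {0,1}")
  storage.mode(H) <- "integer"
  if (!is.null(model) && ncol(H) != model$p)
    stop(sprintf("dimension mismatch: model has p = %d, H has %d columns",
                 model$p, ncol(H)))
  H
}

#' Per-haplotype log-likelihood under the HMM
#'
#' Forward algorithm with per-site scaling (log-space accumulation), so long
#' chromosomes do not underflow.
#'
#' @param model a [haplotype_hmm()].
#' @param H binary haplotype matrix (haplotypes in rows).
#' @return numeric vector of log-likelihoods, one per row of `H`.
#' @export
haplotype_loglik <- function(model, H) {
  H <- check_haplotypes(H, model)
  cpp_hap_loglik(H, model$alpha, model$theta, model$r)
}

#' Fit the haplotype-cluster HMM by EM
#'
#' Baum-Welch with the jump-parameterized transitions, run from several
#' random restarts; the restart with the highest final log-likelihood is
#' returned. Initialization: `theta ~ Uniform(0.1, 0.9)`, uniform `alpha`,
#' constant jump probability 0.1.
#'
#' @param H binary haplotype matrix, no missing entries.
#' @param K number of latent clusters (>= 1).
#' @param max_iter maximum EM iterations per restart.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param n_restarts number of random restarts.
#' @param seed integer seed controlling the restarts.
#' @param positions,chrom optional variant coordinates for the fitted model.
#' @return a [haplotype_hmm()] with attribute `"loglik_trace"` holding the
#'   per-iteration log-likelihood sequence of the winning restart.
#' @export
fit_hmm_em <- function(H, K, max_iter = 50, tol = 1e-4, n_restarts = 3,
                       seed = 1, positions = NULL, chrom = "1") {
  H <- check_haplotypes(H)
  n_hap <- nrow(H)
  p <- ncol(H)
  if (K < 1) stop("K must be >= 1")
  if (n_hap < 2) stop("need at least 2 haplotypes")
  if (K > n_hap) stop("degenerate model: K exceeds the number of haplotypes")
  if (K == 1) {
    # closed form: single cluster, theta = empirical allele frequencies
    freq <- colMeans(H)
    model <- haplotype_hmm(matrix(1, p, 1), cbind(freq),
                           c(1, rep(0.5, p - 1))[seq_len(p)],
                           positions = positions, chrom = chrom)
    attr(model, "loglik_trace") <- sum(haplotype_loglik(model, H))
    return(model)
  }
  best <- NULL
  best_ll <- -Inf
  set.seed(seed)
  for (s in seq_len(n_restarts)) {
    theta0 <- matrix(runif(p * K, 0.1, 0.9), p, K)
    alpha0 <- matrix(1 / K, p, K)
    r0 <- c(1, rep(0.1, p - 1))
    fit <- cpp_em_fit(H, alpha0, theta0, r0, max_iter, tol)
    ll <- tail(fit$loglik, 1)
    if (ll > best_ll) {
      best_ll <- ll
      best <- fit
    }
  }
  r <- best$r
  r[1] <- 1
  model <- haplotype_hmm(best$alpha, best$theta, r, positions = positions,
                         chrom = chrom)
  attr(model, "loglik_trace") <- best$loglik
  model
}

#' Sample haplotypes from the HMM
#'
#' @param model a [haplotype_hmm()].
#' @param n_hap number of haplotypes to draw.
#' @param seed integer seed.
#' @return list with `H` (n_hap x p binary matrix) and `Z` (the latent
#'   cluster paths actually used for emission, 1-based).
#' @export
sample_haplotypes <- function(model, n_hap, seed = NULL) {
  stopifnot(n_hap >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- model$p
  K <- model$K
  Z <- matrix(0L, n_hap, p)
  Z[, 1] <- sample_categorical(n_hap, model$alpha[1, ])
  if (p > 1) {
    for (j in 2:p) {
      jump <- runif(n_hap) < model$r[j]
      z <- Z[, j - 1]
      if (any(jump)) z[jump] <- sample_categorical(sum(jump), model$alpha[j, ])
      Z[, j] <- z
    }
  }
  pr <- matrix(model$theta[cbind(rep(seq_len(p), each = n_hap), as.vector(Z))],
               n_hap, p)
  H <- matrix(as.integer(runif(n_hap * p) < pr), n_hap, p)
  list(H = H, Z = Z)
}

# vectorized categorical sampling from one probability vector
sample_categorical <- function(n, prob) {
  findInterval(runif(n), cumsum(prob) / sum(prob)) + 1L
}

#' Sample latent paths from the posterior P(Z | H)
#'
#' Backward sampling from the scaled forward quantities; the draw is exact.
#'
#' @param model a [haplotype_hmm()].
#' @param H binary haplotype matrix (one or more rows).
#' @param seed integer seed.
#' @return integer matrix of latent paths (1-based), one row per haplotype.
#' @export
posterior_latent_sample <- function(model, H, seed = NULL) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  H <- check_haplotypes(H, model)
  if (!is.null(seed)) set.seed(seed)
  cpp_posterior_sample(H, model$alpha, model$theta, model$r)
}

#' Write / read the HMM parameter file
#'
#' Plain-text serialization: a header with `K`, `p` and the chromosome,
#' then one line per site with position, jump probability, the `K` cluster
#' weights and the `K` emission frequencies. Numbers are printed with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param model a [haplotype_hmm()].
#' @param path file path.
#' @return `write_hmm` returns `path` invisibly; `read_hmm` returns the model.
#' @export
write_hmm <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# haplotype-hmm v1",
               sprintf("K %d", model$K),
               sprintf("p %d", model$p),
               sprintf("chrom %s", model$chrom)), con)
  num <- function(x) sprintf("%.17g", x)
  for (j in seq_len(model$p)) {
    writeLines(paste(c(num(model$positions[j]), num(model$r[j]),
                       num(model$alpha[j, ]), num(model$theta[j, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# haplotype-hmm v1") stop("not an HMM parameter file")
  K <- as.integer(strsplit(lines[2], " ")[[1]][2])
  p <- as.integer(strsplit(lines[3], " ")[[1]][2])
  chrom <- strsplit(lines[4], " ")[[1]][2]
  body <- do.call(rbind, lapply(lines[4 + seq_len(p)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  haplotype_hmm(alpha = body[, 2 + seq_len(K), drop = FALSE],
                theta = body[, 2 + K + seq_len(K), drop = FALSE],
                r = body[, 2], positions = body[, 1], chrom = chrom)
}
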