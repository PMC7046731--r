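# Shared fixtures and independent brute-force oracles.

# random valid haplotype-cluster HMM
tiny_hmm <- function(p, K, seed = 1, r_range = c(0.2, 0.8)) {
  set.seed(seed)
  alpha <- matrix(runif(p * K, 0.2, 1), p, K)
  alpha <- alpha / rowSums(alpha)
  theta <- matrix(runif(p * K, 0.1, 0.9), p, K)
  r <- c(1, runif(p - 1, r_range[1], r_range[2]))
  haplotype_hmm(alpha, theta, r)
}

# all binary haplotypes of length p, one per row (site 1 varies slowest)
all_haps <- function(p) {
  as.matrix(rev(expand.grid(rev(rep(list(0:1), p))))) |> unname()
}

# brute-force P(h) by summing over every latent path (independent of the
# package's forward recursion)
brute_hap_prob <- function(model, h) {
  K <- model$K
  p <- model$p
  paths <- as.matrix(rev(expand.grid(rev(rep(list(seq_len(K)), p)))))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    z <- paths[i, ]
    pr <- model$alpha[1, z[1]] *
      (if (h[1] == 1) model$theta[1, z[1]] else 1 - model$theta[1, z[1]])
    if (p > 1) for (j in 2:p) {
      q <- (1 - model$r[j]) * (z[j] == z[j - 1]) + model$r[j] * model$alpha[j, z[j]]
      pr <- pr * q *
        (if (h[j] == 1) model$theta[j, z[j]] else 1 - model$theta[j, z[j]])
    }
    tot <- tot + pr
  }
  tot
}

# all contiguous partitions of 1..p as group-index vectors
contiguous_partitions <- function(p) {
  out <- list()
  for (mask in 0:(2^(p - 1) - 1)) {
    cuts <- as.integer(intToBits(mask))[seq_len(p - 1)]
    out[[length(out) + 1]] <- as.integer(cumsum(c(1L, cuts)))
  }
  out
}

# largest deviation of a joint (h, h-tilde) table from group-swap invariance
max_swap_deviation <- function(res, g) {
  key <- apply(res$haps, 1, paste, collapse = "")
  idx <- function(h) match(paste(h, collapse = ""), key)
  worst <- 0
  for (gg in unique(g)) {
    sites <- which(g == gg)
    for (i in seq_len(nrow(res$haps))) {
      for (j in seq_len(nrow(res$haps))) {
        h1 <- res$haps[i, ]
        h2 <- res$haps[j, ]
        s1 <- h1; s1[sites] <- h2[sites]
        s2 <- h2; s2[sites] <- h1[sites]
        worst <- max(worst, abs(res$pmf[i, j] - res$pmf[idx(s1), idx(s2)]))
      }
    }
  }
  worst
}

# small phased study drawn from a known model (no EM), for statistics tests
small_true_study <- function(n = 400, p = 60, K = 3, seed = 5) {
  model <- simulate_hmm_model(p = p, K = K, seed = seed)
  H <- sample_haplotypes(model, 2 * n, seed = seed + 1)$H
  list(model = model, H = H, X = haplotypes_to_genotypes(H),
       variants = variant_table(model, H))
}
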