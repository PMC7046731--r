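#' Dense Markov-chain view of the HMM latent process
#'
#' Expands the jump-parameterized latent chain into an initial distribution
#' and per-site dense transition matrices. Used by the reference knockoff
#' sampler and the exact enumeration oracles; the production sampler exploits
#' the jump structure directly.
#'
#' @param model a [haplotype_hmm()].
#' @return list with `K`, `p`, `q1` (initial distribution) and `Q` (list of
#'   K x K matrices; `Q[[j]]` is the transition into site `j`, `j >= 2`).
#' @export
hmm_chain <- function(model) {
  K <- model$K
  p <- model$p
  Q <- vector("list", p)
  for (j in seq_len(p)[-1]) {
    Q[[j]] <- (1 - model$r[j]) * diag(K) +
      model$r[j] * matrix(model$alpha[j, ], K, K, byrow = TRUE)
  }
  list(K = K, p = p, q1 = model$alpha[1, ], Q = Q)
}

as_group_index <- function(partition, p) {
  g <- if (inherits(partition, "variant_partition")) partition$group
       else as.integer(partition)
  if (length(g) != p) stop("partition must cover all p sites")
  if (g[1] != 1L || any(diff(g) < 0L) || any(diff(g) > 1L))
    stop("groups must be contiguous runs in genomic order")
  g
}

#' Group knockoff copy of one latent Markov path (reference implementation)
#'
#' Sequential-conditional-independent-pairs over groups: for g = 1..L the
#' knockoff segment for group g is drawn jointly from the knockoff
#' conditional given the original path and the knockoffs of earlier groups.
#' Group-internal normalizing constants are carried between groups so that
#' the joint law of (z, z-tilde) is exchangeable under swapping any group.
#' This dense implementation is quadratic in K per transition and is meant
#' for small instances and cross-checks; [hmm_group_knockoffs()] uses the
#' O(p K^2) compiled path.
#'
#' @param chain a [hmm_chain()]-style list (fields `K`, `p`, `q1`, `Q`).
#' @param z integer latent path (1-based), length p.
#' @param partition a [new_partition()] or group index vector.
#' @param seed optional integer seed.
#' @return integer knockoff path of length p.
#' @export
sample_group_knockoff_chain <- function(chain, z, partition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- chain$K
  p <- chain$p
  g <- as_group_index(partition, p)
  zt <- integer(p)
  nprev <- rep(1, K)
  for (s in unique(g)) {
    sites <- which(g == s)
    a <- sites[1]
    b <- sites[length(sites)]
    if (a == 1) {
      V <- chain$q1
    } else {
      qz <- chain$Q[[a]][z[a - 1], ]
      qt <- chain$Q[[a]][zt[a - 1], ]
      num <- qz * qt
      V <- ifelse(num > 0, num / pmax(nprev, 1e-300), 0)
    }
    if (sum(V) <= 0) stop("zero-probability path")
    phi <- matrix(0, p, K)
    phi[a, ] <- V / sum(V)
    for (j in seq_len(b - a) + a) {
      v <- as.vector(phi[j - 1, ] %*% chain$Q[[j]])
      phi[j, ] <- v / sum(v)
    }
    w <- if (b == p) phi[b, ] else phi[b, ] * chain$Q[[b + 1]][, z[b + 1]]
    zt[b] <- sample.int(K, 1, prob = w)
    for (j in rev(seq_len(b - a) + a) - 1) {
      w <- phi[j, ] * chain$Q[[j + 1]][, zt[j + 1]]
      zt[j] <- sample.int(K, 1, prob = w)
    }
    if (b < p) {
      nprev <- as.vector(phi[b, ] %*% chain$Q[[b + 1]])
      nprev <- nprev / sum(nprev)
    }
  }
  zt
}

all_paths <- function(K, p) {
  as.matrix(rev(expand.grid(rev(rep(list(seq_len(K)), p)))))
}

#' Exact law of the latent chain and its group knockoff (tiny instances)
#'
#' Enumerates the sampler's conditional probabilities over all state paths,
#' without Monte Carlo.
#'
#' @param chain a [hmm_chain()]-style list.
#' @param partition group index or `variant_partition`.
#' @return list with `paths` (K^p x p matrix, row i is path i) and `joint`
#'   (K^p x K^p matrix: `joint[i, j] = P(z = paths[i, ], ztilde = paths[j, ])`).
#' @export
scip_joint_pmf <- function(chain, partition) {
  K <- chain$K
  p <- chain$p
  g <- as_group_index(partition, p)
  paths <- all_paths(K, p)
  npath <- nrow(paths)
  pz <- apply(paths, 1, function(z) {
    pr <- chain$q1[z[1]]
    if (p > 1) for (j in 2:p) pr <- pr * chain$Q[[j]][z[j - 1], z[j]]
    pr
  })
  # path index for a state vector (site 1 slowest, matching all_paths order)
  idx_of <- function(z) sum((z - 1) * K^((p:1) - 1)) + 1
  joint <- matrix(0, npath, npath)
  gids <- unique(g)
  for (i in seq_len(npath)) {
    z <- paths[i, ]
    # recursive expansion over groups of the conditional P(ztilde | z)
    expand <- function(s_idx, zt, pr, nprev) {
      if (s_idx > length(gids)) {
        joint[i, idx_of(zt)] <<- joint[i, idx_of(zt)] + pz[i] * pr
        return(invisible(NULL))
      }
      sites <- which(g == gids[s_idx])
      a <- sites[1]
      b <- sites[length(sites)]
      if (a == 1) {
        V <- chain$q1
      } else {
        num <- chain$Q[[a]][z[a - 1], ] * chain$Q[[a]][zt[a - 1], ]
        V <- ifelse(num > 0, num / pmax(nprev, 1e-300), 0)
      }
      segs <- all_paths(K, length(sites))
      u <- apply(segs, 1, function(v) {
        w <- V[v[1]]
        if (length(sites) > 1)
          for (t in 2:length(sites)) w <- w * chain$Q[[sites[t]]][v[t - 1], v[t]]
        if (b < p) w <- w * chain$Q[[b + 1]][v[length(v)], z[b + 1]]
        w
      })
      tot <- sum(u)
      if (b < p) {
        # n_s(k): normalizer as a function of the next true state
        phi <- V
        if (length(sites) > 1)
          for (t in 2:length(sites)) phi <- as.vector(phi %*% chain$Q[[sites[t]]])
        nnew <- as.vector(phi %*% chain$Q[[b + 1]])
        nnew <- nnew / sum(nnew)
      } else nnew <- nprev
      for (vi in seq_len(nrow(segs))) {
        if (u[vi] <= 0) next
        zt2 <- zt
        zt2[sites] <- segs[vi, ]
        expand(s_idx + 1, zt2, pr * u[vi] / tot, nnew)
      }
    }
    expand(1, integer(p), 1, rep(1, K))
  }
  list(paths = paths, joint = joint)
}

#' Exact joint law of a haplotype and its knockoff (tiny instances)
#'
#' Enumerates P(h, h-tilde) over all 2^p x 2^p haplotype pairs by summing the
#' sampler's conditional probabilities over all latent path pairs, composed
#' with the emission law. The workhorse test oracle for the exchangeability
#' contract: for every group G, the table must be invariant under swapping
#' the G-coordinates of h and h-tilde.
#'
#' @param model a [haplotype_hmm()] with `p <= 4` and `K <= 3`.
#' @param partition group index or `variant_partition`.
#' @return list with `haps` (2^p x p binary matrix) and `pmf`
#'   (2^p x 2^p matrix over (h, h-tilde) pairs).
#' @export
exact_joint_pmf_small <- function(model, partition) {
  if (model$p > 4 || model$K > 3)
    stop("instance too large for exact enumeration (need p <= 4, K <= 3)")
  chain <- hmm_chain(model)
  sc <- scip_joint_pmf(chain, partition)
  haps <- all_paths(2, model$p) - 1L
  p <- model$p
  npath <- nrow(sc$paths)
  # emission matrix: E[i, hh] = P(h = haps[hh, ] | z = paths[i, ])
  E <- matrix(0, npath, nrow(haps))
  for (i in seq_len(npath)) {
    th <- model$theta[cbind(seq_len(p), sc$paths[i, ])]
    for (hh in seq_len(nrow(haps))) {
      h <- haps[hh, ]
      E[i, hh] <- prod(ifelse(h == 1, th, 1 - th))
    }
  }
  pmf <- t(E) %*% sc$joint %*% E
  list(haps = haps, pmf = pmf)
}

#' Group knockoffs of haplotypes under the HMM
#'
#' Three steps per haplotype: (1) draw a latent path from the exact
#' posterior given the haplotype, (2) draw a group knockoff copy of the path
#' under the latent Markov chain, (3) re-emit alleles at the knockoff states
#' from the emission frequencies. The output satisfies group-swap
#' exchangeability with the input for the given partition. The phenotype is
#' never an input here: knockoffs are null by construction.
#'
#' @param model a [haplotype_hmm()].
#' @param H binary haplotype matrix (haplotypes in rows).
#' @param partition a [new_partition()] or group index vector.
#' @param seed integer seed.
#' @return binary knockoff haplotype matrix, same shape as `H`.
#' @export
hmm_group_knockoffs <- function(model, H, partition, seed = NULL) {
  H <- check_haplotypes(H, model)
  g <- as_group_index(partition, model$p)
  if (!is.null(seed)) set.seed(seed)
  Z <- cpp_posterior_sample(H, model$alpha, model$theta, model$r)
  Zt <- cpp_knockoff_chain(Z, model$alpha, model$r, g)
  n_hap <- nrow(H)
  p <- model$p
  pr <- matrix(model$theta[cbind(rep(seq_len(p), each = n_hap), as.vector(Zt))],
               n_hap, p)
  Ht <- matrix(as.integer(runif(n_hap * p) < pr), n_hap, p)
  Ht
}

#' Knockoff genotypes from phased haplotypes
#'
#' Rows (2i-1, 2i) of `H` are the two phased haplotypes of individual i.
#' Each haplotype gets an independent knockoff copy given its own latent
#' posterior; knockoff genotypes are the within-individual sums, avoiding
#' any implicit re-phasing of the genotypes.
#'
#' @param model a [haplotype_hmm()].
#' @param H phased haplotype matrix with an even number of rows.
#' @param partition a [new_partition()] or group index vector.
#' @param seed integer seed.
#' @return n x p integer matrix of knockoff genotypes in {0, 1, 2}, with
#'   attributes `seed` and `provenance = "phased"`.
#' @export
genotype_knockoffs_from_phased <- function(model, H, partition, seed = NULL) {
  H <- check_haplotypes(H, model)
  if (nrow(H) %% 2 != 0)
    stop("phased haplotype matrix must have an even number of rows")
  Ht <- hmm_group_knockoffs(model, H, partition, seed = seed)
  odd <- seq(1, nrow(H), by = 2)
  Xt <- Ht[odd, , drop = FALSE] + Ht[odd + 1, , drop = FALSE]
  attr(Xt, "seed") <- seed
  attr(Xt, "provenance") <- "phased"
  Xt
}

#' Genotypes from phased haplotypes
#'
#' @param H phased haplotype matrix with an even number of rows.
#' @return n x p integer genotype matrix (within-individual haplotype sums).
#' @export
haplotypes_to_genotypes <- function(H) {
  if (nrow(H) %% 2 != 0) stop("odd number of haplotype rows")
  odd <- seq(1, nrow(H), by = 2)
  H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
}
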