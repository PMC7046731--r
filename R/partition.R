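#' Banded linkage-disequilibrium matrix (r-squared)
#'
#' Squared Pearson correlation between allele counts of variant pairs within
#' a window; pairs further apart than `window` variants are set to 0.
#' Works on either genotypes (0/1/2) or haplotypes (0/1).
#'
#' @param X numeric matrix, samples (or haplotypes) in rows, variants in
#'   columns, in genomic order.
#' @param window maximum variant-count separation for which r-squared is
#'   computed (default 1000).
#' @return p x p symmetric matrix of class `ld_matrix` with unit diagonal
#'   and a `window` attribute. Monomorphic variants get off-diagonal 0 with
#'   a warning.
#' @export
ld_r2 <- function(X, window = 1000) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to compute LD")
  p <- ncol(X)
  mono <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (any(mono))
    warning(sprintf("%d monomorphic variant(s): off-diagonal r^2 set to 0",
                    sum(mono)))
  storage.mode(X) <- "double"
  suppressWarnings(r <- if (anyNA(X)) stats::cor(X, use = "pairwise.complete.obs")
                        else stats::cor(X))
  r2 <- r * r
  r2[is.na(r2)] <- 0
  if (window < p - 1) {
    idx <- abs(outer(seq_len(p), seq_len(p), "-")) > window
    r2[idx] <- 0
  }
  diag(r2) <- 1
  structure(r2, window = window, class = c("ld_matrix", "matrix"))
}

#' Adjacency-constrained hierarchical clustering of variants
#'
#' Agglomerative clustering on the dissimilarity `1 - r^2` in which only
#' genomically adjacent clusters may merge, so every cluster is a contiguous
#' run of variants. Complete linkage is used: the dissimilarity between two
#' blocks is the largest pairwise dissimilarity across them, which bounds
#' how dissimilar two variants inside one group can be. Complete linkage is
#' reducible, so merge heights are non-decreasing. Ties are broken by the
#' leftmost pair.
#'
#' @param ld an [ld_r2()] matrix.
#' @return object of class `ld_dendrogram`: list with `boundary` (the
#'   inter-variant boundary removed by each merge, in merge order), `height`
#'   (the dissimilarity at each merge) and `p`.
#' @export
build_dendrogram <- function(ld) {
  p <- nrow(ld)
  if (is.null(p) || p == 0) stop("empty LD matrix")
  if (p == 1)
    return(structure(list(boundary = integer(0), height = numeric(0), p = 1L),
                     class = "ld_dendrogram"))
  # dense block-level dissimilarity, updated in place with the complete-
  # linkage Lance-Williams rule D(L, I+J) = max(D(L, I), D(L, J)); blocks
  # form a doubly linked list so only adjacent pairs are merge candidates
  D <- 1 - unclass(ld)
  end <- seq_len(p)
  nxt <- c(2:p, NA)
  prv <- c(NA, 1:(p - 1))
  # d[b] = linkage between block b and its right neighbor
  d <- c(D[cbind(1:(p - 1), 2:p)], Inf)
  boundary <- integer(p - 1)
  height <- numeric(p - 1)
  for (m in seq_len(p - 1)) {
    b <- which.min(d)  # which.min takes the first minimum: leftmost tie-break
    boundary[m] <- end[b]
    height[m] <- d[b]
    rb <- nxt[b]
    newrow <- pmax(D[b, ], D[rb, ])
    D[b, ] <- newrow
    D[, b] <- newrow
    end[b] <- end[rb]
    nxt[b] <- nxt[rb]
    if (!is.na(nxt[rb])) prv[nxt[rb]] <- b
    d[b] <- if (is.na(nxt[b])) Inf else D[b, nxt[b]]
    d[rb] <- Inf
    if (!is.na(prv[b])) d[prv[b]] <- D[prv[b], b]
  }
  structure(list(boundary = boundary, height = height, p = p),
            class = "ld_dendrogram")
}

#' Variant partition
#'
#' @param group integer vector: group index per variant (1..L), contiguous
#'   and non-decreasing along genomic order.
#' @param variants optional data.frame with columns `id`, `chrom`, `bp`
#'   (one row per variant) used to annotate group ranges.
#' @param label resolution label.
#' @return object of class `variant_partition`: list with `group`, `L`,
#'   `label` and `ranges` (one row per group: first/last variant index and
#'   base-pair bounds).
#' @export
new_partition <- function(group, variants = NULL, label = NULL) {
  group <- as.integer(group)
  p <- length(group)
  if (p == 0) stop("empty partition")
  if (group[1] != 1L || any(diff(group) < 0L) || any(diff(group) > 1L))
    stop("group index must be non-decreasing with unit jumps, starting at 1")
  L <- group[p]
  from <- which(!duplicated(group))
  to <- c(from[-1] - 1L, p)
  ranges <- data.frame(group = seq_len(L), from = from, to = to,
                       n_snps = to - from + 1L)
  if (!is.null(variants)) {
    ranges$chrom <- variants$chrom[from]
    ranges$bp_min <- variants$bp[from]
    ranges$bp_max <- variants$bp[to]
  }
  if (is.null(label)) {
    label <- if (all(ranges$n_snps == 1L)) "single variant"
    else if (!is.null(variants))
      sprintf("%.4g bp", mean(ranges$bp_max - ranges$bp_min + 1))
    else sprintf("%.3g snps", mean(ranges$n_snps))
  }
  structure(list(group = group, L = L, label = label, ranges = ranges),
            class = "variant_partition")
}

cut_tree_at <- function(tree, h) {
  keep <- setdiff(seq_len(tree$p - 1), tree$boundary[tree$height <= h])
  present <- logical(tree$p - 1)
  present[keep] <- TRUE
  as.integer(cumsum(c(1L, present)))
}

#' Cut the dendrogram into nested multi-resolution partitions
#'
#' Each height yields one partition (merges with height at or below the cut
#' are applied); because every cut applies a subset of the merges of any
#' higher cut, the partitions are nested by construction: every finer group
#' lies entirely within one coarser group.
#'
#' @param tree a [build_dendrogram()] result.
#' @param heights dissimilarity thresholds in `[0, 1]`, sorted descending
#'   (coarse to fine).
#' @param variants optional variant table for range annotation.
#' @return object of class `multires_partition`: list with `partitions`
#'   (coarse to fine), `heights` and `tree`.
#' @export
cut_partitions <- function(tree, heights, variants = NULL) {
  if (any(heights < 0 | heights > 1)) stop("heights must lie in [0, 1]")
  if (is.unsorted(rev(heights))) stop("heights must be sorted descending")
  parts <- lapply(heights, function(h)
    new_partition(cut_tree_at(tree, h), variants = variants))
  structure(list(partitions = parts, heights = heights, tree = tree),
            class = "multires_partition")
}

#' Cut the dendrogram targeting group counts
#'
#' Convenience used by the pipeline: picks, for each target number of
#' groups, the cut height realizing the closest achievable group count
#' (ties among equal merge heights are applied together, so the realized
#' count can be smaller than the target).
#'
#' @param tree a [build_dendrogram()] result.
#' @param n_groups target group counts, increasing (coarse to fine).
#' @param variants optional variant table.
#' @return a `multires_partition`.
#' @export
cut_partitions_by_groups <- function(tree, n_groups, variants = NULL) {
  p <- tree$p
  heights <- vapply(n_groups, function(L) {
    m <- p - L
    if (m <= 0) return(0)
    min(tree$height[m], 1)
  }, numeric(1))
  heights <- rev(cummax(rev(heights)))  # enforce descending after ties
  cut_partitions(tree, heights, variants = variants)
}

#' Check that a list of partitions is nested
#'
#' The coarser group label must be a function of the finer label for every
#' consecutive pair.
#'
#' @param mrp a `multires_partition` or list of `variant_partition`s
#'   ordered coarse to fine.
#' @return TRUE invisibly; errors if nestedness fails.
#' @export
check_nested <- function(mrp) {
  parts <- if (inherits(mrp, "multires_partition")) mrp$partitions else mrp
  if (length(parts) > 1) {
    for (i in 2:length(parts)) {
      coarse <- parts[[i - 1]]$group
      fine <- parts[[i]]$group
      tab <- tapply(coarse, fine, function(v) length(unique(v)))
      if (any(tab != 1))
        stop(sprintf("partitions %d and %d are not nested", i - 1, i))
    }
  }
  invisible(TRUE)
}
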