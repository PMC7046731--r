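#' Knockoff filter threshold
#'
#' Data-dependent threshold controlling the FDR at level `q` for statistics
#' whose null signs are symmetric:
#' `tau = min{ t in {|W_g| : W_g != 0} : (offset + #{W_g <= -t}) / max(1, #{W_g >= t}) <= q }`,
#' or `+Inf` (no discoveries) if no candidate qualifies. The default
#' `offset = 1` gives provable FDR control; `offset = 0` is the relaxed
#' variant without the guarantee (a warning is issued). A consequence of the
#' `offset = 1` numerator is a power floor: no discovery is possible unless
#' at least `1/q` findings can be made at once.
#'
#' @param W numeric vector of group statistics.
#' @param q nominal FDR level in (0, 1).
#' @param offset 1 (default, knockoffs+) or 0.
#' @return the threshold `tau` (possibly `+Inf`).
#' @export
knockoff_threshold <- function(W, q = 0.1, offset = 1) {
  if (length(W) == 0) stop("empty W")
  if (!all(is.finite(W))) stop("W must be finite")
  stopifnot(q > 0, q < 1)
  if (offset == 0)
    warning("offset = 0 relaxes the filter: the FDR guarantee is lost")
  ts <- sort(unique(abs(W[W != 0])))
  for (t in ts) {
    ratio <- (offset + sum(W <= -t)) / max(1, sum(W >= t))
    if (ratio <= q) return(t)
  }
  Inf
}

#' Select groups passing the knockoff filter
#'
#' @param W numeric vector of group statistics.
#' @param tau threshold from [knockoff_threshold()].
#' @param partition a [new_partition()] with range annotation.
#' @param q nominal level recorded in the result.
#' @param local_fdr optional per-group local-FDR estimates to attach.
#' @return object of class `discovery_set`: data.frame of selected groups
#'   (columns `group`, range columns from the partition, `W`, `local_fdr`)
#'   with attributes `q`, `threshold`, `label` and `n_groups`.
#' @export
knockoff_select <- function(W, tau, partition, q = 0.1, local_fdr = NULL) {
  sel <- which(W >= tau)
  out <- partition$ranges[sel, , drop = FALSE]
  out$W <- W[sel]
  out$local_fdr <- if (!is.null(local_fdr)) local_fdr[sel]
                   else rep(NA_real_, length(sel))
  rownames(out) <- NULL
  structure(out, q = q, threshold = tau, label = partition$label,
            n_groups = partition$L, class = c("discovery_set", "data.frame"))
}

#' Local false discovery rate from the sign-symmetry of null statistics
#'
#' Two-group estimate using the reflection of the negative statistics as a
#' sample from the positive half of the null: for w > 0,
#' `fdr(w) = (n_neg * f_neg(w)) / (n_pos * f_pos(w))`, where `f_neg` is a
#' kernel density of the reflected negatives and `f_pos` of the positives.
#' Estimates are clipped to [0, 1] and made monotone non-increasing in w by
#' isotonic adjustment. Requires a few hundred groups to be meaningful.
#'
#' @param W numeric vector of group statistics.
#' @param min_groups below this many groups the estimate is refused and a
#'   vector of `NA` is returned with attribute `too_few = TRUE`.
#' @return numeric vector aligned to `W`: estimates for strictly positive
#'   entries, `NA` elsewhere.
#' @export
local_fdr <- function(W, min_groups = 200) {
  out <- rep(NA_real_, length(W))
  if (length(W) < min_groups) {
    attr(out, "too_few") <- TRUE
    return(out)
  }
  pos <- W[W > 0]
  neg <- -W[W < 0]
  if (length(pos) == 0) return(out)
  if (length(neg) < 2) {
    out[W > 0] <- 0
    return(out)
  }
  bw <- stats::bw.nrd0(c(pos, neg))
  fpos <- function(x) kde_reflect(x, pos, bw)
  fneg <- function(x) kde_reflect(x, neg, bw)
  w <- W[W > 0]
  est <- (length(neg) * fneg(w)) / pmax(length(pos) * fpos(w), 1e-300)
  est <- pmin(pmax(est, 0), 1)
  # isotonic: non-increasing in w
  ord <- order(w)
  iso <- stats::isoreg(-est[ord])
  est[ord] <- pmin(pmax(-iso$yf, 0), 1)
  out[W > 0] <- est
  out
}

# Gaussian KDE on [0, Inf) with reflection at zero
kde_reflect <- function(x, sample, bw) {
  vapply(x, function(xi) {
    mean(stats::dnorm(xi, sample, bw) + stats::dnorm(-xi, sample, bw))
  }, numeric(1))
}

#' Simplified multi-resolution summary of discoveries
#'
#' Keeps, for each locus, only the most specific supported finding: a
#' discovery at a finer resolution is "supported" when a discovery at the
#' immediately coarser resolution contains it; unsupported fine discoveries
#' are flagged as floating and excluded from the summary, and a coarser
#' discovery is dropped when a supported finer discovery lies within it.
#'
#' @param discoveries list of `discovery_set`s ordered coarse to fine.
#' @param partitions the matching list of `variant_partition`s (or a
#'   `multires_partition`); needed to resolve containment, and checked for
#'   nestedness.
#' @return list with `simplified` (data.frame of kept discoveries with a
#'   `resolution` column) and `flags` (per-resolution logical vectors:
#'   `floating`).
#' @export
simplified_count <- function(discoveries, partitions) {
  parts <- if (inherits(partitions, "multires_partition")) partitions$partitions
           else partitions
  stopifnot(length(discoveries) == length(parts))
  check_nested(parts)
  R <- length(discoveries)
  floating <- vector("list", R)
  supported <- vector("list", R)
  for (i in seq_len(R)) {
    d <- discoveries[[i]]
    if (i == 1) {
      supported[[i]] <- rep(TRUE, nrow(d))
    } else {
      coarse_sel <- discoveries[[i - 1]]$group
      # coarser group containing each fine discovery: label of its first variant
      parent <- parts[[i - 1]]$group[parts[[i]]$ranges$from[d$group]]
      supported[[i]] <- parent %in% coarse_sel
    }
    floating[[i]] <- !supported[[i]]
  }
  kept <- vector("list", R)
  for (i in seq_len(R)) {
    d <- discoveries[[i]]
    keep <- supported[[i]]
    if (i < R) {
      # drop if a supported finer discovery lies within this group
      for (j in seq(i + 1, R)) {
        dj <- discoveries[[j]]
        if (nrow(dj) == 0) next
        fine_ok <- supported_chain(supported, j)
        anc <- parts[[i]]$group[parts[[j]]$ranges$from[dj$group]]
        covered <- unique(anc[fine_ok])
        keep <- keep & !(d$group %in% covered)
      }
    }
    if (nrow(d) > 0 && any(keep)) {
      kd <- as.data.frame(d)[keep, , drop = FALSE]
      kd$resolution <- attr(d, "label")
      kd$level <- i
      kept[[i]] <- kd
    }
  }
  simplified <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  if (is.null(simplified)) simplified <- data.frame()
  rownames(simplified) <- NULL
  list(simplified = simplified, flags = lapply(floating, as.logical))
}

# supported at level j for the purpose of replacing coarser findings:
# supported relative to its immediate coarser level
supported_chain <- function(supported, j) supported[[j]]
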