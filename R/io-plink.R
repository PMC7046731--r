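#' Read a PLINK BED/BIM/FAM triple
#'
#' Genotypes are returned as counts of allele1 (the fifth BIM column, PLINK's
#' A1): the two-bit codes 00/10/11 map to 2/1/0 copies of allele1 and 01 maps
#' to missing. Variant-major (SNP-major) layout is required.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return list with `X` (n x p integer matrix, `NA` for missing),
#'   `variants` (data.frame: `chrom`, `id`, `cm`, `bp`, `a1`, `a2`) and
#'   `samples` (data.frame: `fid`, `iid`).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  variants <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                                col.names = c("chrom", "id", "cm", "bp",
                                              "a1", "a2"))
  samples <- utils::read.table(fam, header = FALSE,
                               stringsAsFactors = FALSE)[, 1:2]
  names(samples) <- c("fid", "iid")
  n <- nrow(samples)
  p <- nrow(variants)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("BED magic bytes invalid")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major BED files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * p) stop("truncated or oversized BED payload")
  # lookup: for each byte value, the 4 allele1 counts (NA for missing)
  codes <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  byte_int <- 0:255
  lut <- cbind(codes[bitwAnd(byte_int, 3L) + 1L],
               codes[bitwAnd(bitwShiftR(byte_int, 2L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(byte_int, 4L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(byte_int, 6L), 3L) + 1L])
  vals <- as.integer(raw[-(1:3)])
  G <- matrix(t(lut[vals + 1L, , drop = FALSE]), nrow = 4 * bpv, ncol = p)
  X <- G[seq_len(n), , drop = FALSE]
  rownames(X) <- samples$iid
  colnames(X) <- variants$id
  list(X = X, variants = variants, samples = samples)
}

#' Write a PLINK BED/BIM/FAM triple
#'
#' Inverse of [read_plink()]: `X` holds allele1 counts (0/1/2, `NA` for
#' missing).
#'
#' @param X n x p genotype matrix.
#' @param variants data.frame with `chrom`, `id`, `bp`, `a1`, `a2` (and
#'   optionally `cm`).
#' @param samples optional data.frame with `fid`, `iid`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(X, variants, prefix, samples = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(nrow(variants) == p)
  if (is.null(samples))
    samples <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                          iid = sprintf("I%05d", seq_len(n)))
  cm <- if ("cm" %in% names(variants)) variants$cm else 0
  utils::write.table(data.frame(variants$chrom, variants$id, cm, variants$bp,
                                variants$a1, variants$a2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(samples$fid, samples$iid, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # two-bit codes indexed by count: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  code_of <- function(v) {
    out <- integer(length(v))
    out[is.na(v)] <- 1L
    out[!is.na(v) & v == 0] <- 3L
    out[!is.na(v) & v == 1] <- 2L
    out[!is.na(v) & v == 2] <- 0L
    out
  }
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bpv - n
  for (j in seq_len(p)) {
    cj <- c(code_of(X[, j]), rep(1L, pad))  # pad with missing code
    m <- matrix(cj, nrow = 4)
    bytes <- m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read / write the haplotype TSV dialect
#'
#' Header row of variant ids (first column `sample`); one row per
#' haplotype, sample ids carrying `_1`/`_2` suffixes for the two phased
#' haplotypes of an individual.
#'
#' @param H binary haplotype matrix.
#' @param variants variant table supplying column names.
#' @param path file path.
#' @return `read_haplotypes` returns the integer matrix with sample ids as
#'   rownames; `write_haplotypes` returns `path` invisibly.
#' @export
write_haplotypes <- function(H, variants, path) {
  ids <- paste0(rep(sprintf("I%05d", seq_len(nrow(H) / 2)), each = 2),
                c("_1", "_2"))
  df <- data.frame(sample = ids, H, check.names = FALSE)
  names(df) <- c("sample", variants$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  H <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(H) <- "integer"
  rownames(H) <- df$sample
  H
}

#' Read a phenotype/covariate table
#'
#' TSV with `FID`/`IID` keys followed by the phenotype column and optional
#' covariate columns.
#'
#' @param path file path.
#' @param phenotype name of the phenotype column (default: third column).
#' @param covariates character vector of covariate column names.
#' @return list with `y`, `Z` (matrix or NULL) and the full data.frame.
#' @export
read_phenotypes <- function(path, phenotype = NULL, covariates = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(phenotype)) phenotype <- names(df)[3]
  y <- df[[phenotype]]
  Z <- if (length(covariates) > 0) as.matrix(df[, covariates, drop = FALSE])
       else NULL
  list(y = y, Z = Z, table = df)
}
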