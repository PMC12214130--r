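#' Expression-based gene filter
#'
#' A gene is retained when, jointly, (i) at least `min_prop` of the
#' individuals of at least one sex have `TPM > tpm_threshold` and read
#' count `> count_threshold`, and (ii) at least `nonzero_prop` of all
#' individuals have a nonzero read count. Proportions are computed over
#' non-missing samples.
#'
#' @param counts,tpm Gene x sample matrices (aligned; `NA` = missing).
#' @param metadata Data frame with `individual_id` and `sex` covering every
#'   column of `counts`.
#' @param tpm_threshold,count_threshold,min_prop,nonzero_prop Filter
#'   settings (defaults 0.1, 6, 0.2, 0.05).
#' @return Character vector of retained gene ids (rownames of `counts`).
#' @export
filter_genes <- function(counts, tpm, metadata, tpm_threshold = 0.1,
                         count_threshold = 6, min_prop = 0.2,
                         nonzero_prop = 0.05) {
  stopifnot(identical(dim(counts), dim(tpm)))
  sex <- metadata$sex[match(colnames(counts), metadata$individual_id)]
  if (any(is.na(sex))) stop("sex missing for some samples in the matrix")
  expressed <- (tpm > tpm_threshold) & (counts > count_threshold)
  prop_by_sex <- function(s) {
    cols <- which(sex == s)
    if (length(cols) == 0) return(rep(0, nrow(counts)))
    rowMeans(expressed[, cols, drop = FALSE], na.rm = TRUE)
  }
  pf <- prop_by_sex("female")
  pm <- prop_by_sex("male")
  nz <- rowMeans(counts > 0, na.rm = TRUE)
  keep <- (pmax(pf, pm, na.rm = TRUE) >= min_prop) & (nz >= nonzero_prop)
  keep[is.na(keep)] <- FALSE
  rownames(counts)[keep]
}

#' Log-transform, centre and scale read counts per gene
#'
#' Per gene: `x -> log2(x + pseudocount)`, subtract the gene mean, divide
#' by the gene SD (over non-missing samples). Genes with zero variance are
#' flagged and dropped from the returned matrix.
#'
#' @param counts Gene x sample matrix of nonnegative counts.
#' @param pseudocount Added before the log (default 1).
#' @return Matrix of per-gene standardized log counts with attribute
#'   `flagged` listing zero-variance genes.
#' @export
log_center_scale <- function(counts, pseudocount = 1) {
  if (is.null(dim(counts)) || ncol(counts) < 2) {
    stop("at least two samples are required (per-gene SD undefined)")
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  lg <- log2(counts + pseudocount)
  mu <- rowMeans(lg, na.rm = TRUE)
  sdv <- apply(lg, 1, stats::sd, na.rm = TRUE)
  bad <- is.na(sdv) | sdv == 0
  z <- (lg[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  attr(z, "flagged") <- if (is.null(rownames(lg))) which(bad)
  else rownames(lg)[bad]
  z
}

#' Hidden-confounder factors by truncated SVD
#'
#' Estimates `k` latent expression factors as the top left singular
#' vectors of the sample x gene matrix of standardized log counts. Missing
#' entries are set to zero (the per-gene centre) for the decomposition.
#' Factor signs are fixed by making each factor's largest-magnitude
#' loading positive, so results are deterministic.
#'
#' @param mat Gene x sample matrix (output of [log_center_scale()]).
#' @param k Number of factors; must satisfy `0 < k < min(genes, samples)`.
#' @return Sample x k matrix of orthonormal factors.
#' @export
latent_factors <- function(mat, k) {
  if (k <= 0) stop("k must be positive")
  if (k >= min(dim(mat))) stop("k must be smaller than min(genes, samples)")
  x <- t(mat)
  x[is.na(x)] <- 0
  sv <- svd(x, nu = k, nv = 0)
  u <- sv$u
  for (j in seq_len(k)) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- colnames(mat)
  colnames(u) <- paste0("F", seq_len(k))
  u
}

#' Residualize expression on covariates while protecting sex
#'
#' Every non-sex covariate is first replaced by its residual after an
#' ordinary least-squares regression on sex, so that components of the
#' confounders aligned with sex are not removed from the expression
#' matrix. Expression is then residualized on the sex-orthogonalized
#' covariates plus an intercept. Collinear covariate columns are dropped
#' with a warning.
#'
#' @param mat Gene x sample matrix (standardized log counts).
#' @param covariates List with element `sex` (character or 0/1 vector,
#'   aligned to columns of `mat`) and any of `pcs`, `factors`, `top_eqtl`
#'   (sample x p matrices). `top_eqtl` may instead be a sample x gene
#'   matrix of per-gene dosages, applied gene-wise.
#' @return Gene x sample matrix of residuals (sex effects retained).
#' @export
residualize_protect_sex <- function(mat, covariates) {
  if (is.null(covariates$sex)) stop("covariates must include sex")
  n <- ncol(mat)
  sex <- covariates$sex
  if (!is.numeric(sex)) sex <- as.numeric(factor(sex)) - 1
  if (length(sex) != n) stop("sex not aligned with samples")
  shared <- cbind(covariates$pcs, covariates$factors)
  eqtl <- covariates$top_eqtl
  gene_wise_eqtl <- !is.null(eqtl) && !is.null(dim(eqtl)) &&
    ncol(eqtl) == nrow(mat) && !is.null(colnames(eqtl))
  if (!is.null(eqtl) && !gene_wise_eqtl) shared <- cbind(shared, eqtl)

  sex_design <- cbind(1, sex)
  adjust <- function(cmat) {
    if (is.null(cmat)) return(NULL)
    cmat <- as.matrix(cmat)
    stats::lm.fit(sex_design, cmat)$residuals
  }
  shared_adj <- adjust(shared)
  eqtl_adj <- if (gene_wise_eqtl) adjust(eqtl) else NULL

  resid_one <- function(y, extra = NULL) {
    design <- cbind(`(Intercept)` = 1, shared_adj, extra)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      warning("dropping ", ncol(design) - qrd$rank,
              " collinear covariate column(s)")
      design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    }
    ok <- !is.na(y)
    out <- rep(NA_real_, length(y))
    out[ok] <- stats::lm.fit(design[ok, , drop = FALSE], y[ok])$residuals
    out
  }
  res <- mat
  if (gene_wise_eqtl) {
    for (gi in seq_len(nrow(mat))) {
      gid <- rownames(mat)[gi]
      extra <- if (gid %in% colnames(eqtl_adj))
        eqtl_adj[, gid, drop = FALSE] else NULL
      res[gi, ] <- resid_one(mat[gi, ], extra)
    }
  } else {
    ## missingness is column-wise within a tissue, so one design serves all
    design <- cbind(`(Intercept)` = 1, shared_adj)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      warning("dropping ", ncol(design) - qrd$rank,
              " collinear covariate column(s)")
      design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    }
    ok_cols <- colSums(is.na(mat)) < nrow(mat)
    y <- t(mat[, ok_cols, drop = FALSE])
    if (anyNA(y)) {
      for (gi in seq_len(nrow(mat))) res[gi, ] <- resid_one(mat[gi, ])
    } else {
      fit <- stats::lm.fit(design[ok_cols, , drop = FALSE], y)
      res[, ok_cols] <- t(fit$residuals)
      res[, !ok_cols] <- NA_real_
    }
  }
  res
}

#' Z-score expression residuals per gene
#'
#' Standardizes each gene across the group's non-missing samples to mean 0
#' and SD 1. Zero-variance genes are flagged (attribute `flagged`) and
#' returned as `NA`. Groups of fewer than three samples are computed
#' anyway with a warning.
#'
#' @param mat Gene x sample matrix of corrected expression.
#' @return Z-score matrix with attribute `flagged`.
#' @export
zscores <- function(mat) {
  if (ncol(mat) < 3) {
    warning("group has fewer than 3 samples; Z scores are underpowered")
  }
  mu <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
  bad <- is.na(sdv) | sdv == 0
  z <- (mat - mu) / ifelse(bad, NA_real_, sdv)
  attr(z, "flagged") <- rownames(mat)[bad]
  z
}
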