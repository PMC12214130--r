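#' Per-group corrected Z-score tensor
#'
#' Runs the expression chain for one stratification group: per tissue,
#' subset to the group's samples with that tissue, filter genes (on the
#' combined group so all groups share one gene universe), log-centre-scale,
#' estimate latent factors by truncated SVD, residualize on genetic PCs
#' and factors with sex protection, and Z-score. Tissues where a gene is
#' filtered out, or samples missing a tissue, are `NA`.
#'
#' @param bundle A `cohort_bundle`.
#' @param members Individual ids of the group (default: everyone).
#' @param sex_labels Optional named sex vector overriding the metadata
#'   (used by the permutation control).
#' @param n_factors Latent factors per tissue (default 5, capped below the
#'   matrix rank).
#' @param gene_universe Optional precomputed retained gene ids.
#' @return Gene x individual x tissue Z-score array.
#' @export
ztensor_for_group <- function(bundle, members = NULL, sex_labels = NULL,
                              n_factors = 5, gene_universe = NULL) {
  md <- bundle$metadata
  members <- members %||% md$individual_id
  sex <- sex_labels %||% stats::setNames(md$sex, md$individual_id)
  tissues <- dimnames(bundle$counts)[[3]]
  genes <- gene_universe %||% pipeline_gene_universe(bundle)
  zt <- array(NA_real_,
              dim = c(length(genes), length(members), length(tissues)),
              dimnames = list(genes, members, tissues))
  for (ti in tissues) {
    cnt <- bundle$counts[genes, members, ti]
    have <- colSums(!is.na(cnt)) > 0
    if (sum(have) < 4) next
    cnt <- cnt[, have, drop = FALSE]
    lz <- log_center_scale(cnt)
    if (nrow(lz) == 0) next
    k <- min(n_factors, min(dim(lz)) - 1)
    fac <- if (k >= 1) latent_factors(lz, k) else NULL
    covs <- list(sex = unname(sex[colnames(lz)]),
                 pcs = as.matrix(md[match(colnames(lz), md$individual_id),
                                    c("PC1", "PC2", "PC3")]),
                 factors = fac)
    corrected <- residualize_protect_sex(lz, covs)
    z <- zscores(corrected)
    zt[rownames(z), colnames(z), ti] <- z
  }
  zt
}

## gene universe from the combined group's filter, per spec: filtering uses
## the combined group's sexes even when Z-scoring is per group
pipeline_gene_universe <- function(bundle) {
  tissues <- dimnames(bundle$counts)[[3]]
  keep <- character(0)
  for (ti in tissues) {
    cnt <- bundle$counts[, , ti]
    tpm <- bundle$tpm[, , ti]
    keep <- union(keep, filter_genes(cnt, tpm, bundle$metadata))
  }
  rownames(bundle$counts)[rownames(bundle$counts) %in% keep]
}

#' Median multi-tissue Z per gene and individual
#'
#' @param z_tensor Gene x individual x tissue array.
#' @return Gene x individual matrix of medians over non-missing tissues.
#' @export
median_z_matrix <- function(z_tensor) {
  apply(z_tensor, c(1, 2), stats::median, na.rm = TRUE)
}

#' Score rare variants and classify sex-biased effects
#'
#' The full scoring chain on a synthetic cohort: corrected Z scores
#' (sex-protected), median multi-tissue Z, gene-level annotation layer,
#' separate over- and under-outlier hierarchical models, signed posteriors
#' per (gene, individual) (each instance is scored by the model matching
#' the sign of its median Z), per-variant per-sex median posteriors, and
#' the sex-bias classification.
#'
#' @param bundle A `cohort_bundle`.
#' @param sex_labels Optional named sex vector overriding the metadata
#'   (permutation control).
#' @param delta Sex-bias threshold on the posterior difference
#'   (default 0.2).
#' @param l2_lambda,n_factors Model and correction settings.
#' @param g_window_bp G-layer window (default 10000).
#' @return List with `z_tensor`, `median_z`, `scores` (per instance),
#'   `sex_posteriors` (per variant-gene, with `category`), and the fitted
#'   `params_over` / `params_under`.
#' @export
score_sex_posteriors <- function(bundle, sex_labels = NULL, delta = 0.2,
                                 l2_lambda = 1, n_factors = 5,
                                 g_window_bp = 10000) {
  md <- bundle$metadata
  sex <- sex_labels %||% stats::setNames(md$sex, md$individual_id)
  zt <- ztensor_for_group(bundle, sex_labels = sex, n_factors = n_factors)
  medz <- median_z_matrix(zt)
  al <- build_annotation_layer(bundle$variants, bundle$gene_models,
                               bundle$annotations, window_bp = g_window_bp)
  scores <- NULL
  params <- list()
  for (mode in c("over", "under")) {
    inst <- tryCatch(
      prepare_instances(medz, al, mode = mode, n2_pairs = bundle$n2_pairs),
      error = function(e) NULL)
    if (is.null(inst) || length(unique(inst$e[!inst$is_n2_heldout])) < 2) next
    fit <- train_em(inst, l2_lambda = l2_lambda)
    params[[mode]] <- fit
    sc <- posterior(inst, fit)
    sc$mode <- mode
    scores <- rbind(scores, sc)
  }
  if (is.null(scores)) stop("no trainable outlier mode in this cohort")
  ## keep, per (gene, individual), the score from the model matching the
  ## sign of the median Z (over-model for positive, under for negative)
  want <- ifelse(scores$signed_score >= 0, "over", "under")
  scores <- scores[scores$mode == want, , drop = FALSE]
  scores <- scores[!duplicated(paste(scores$gene_id, scores$individual_id)), ,
                   drop = FALSE]
  md2 <- md
  md2$sex <- unname(sex[md$individual_id])
  gene_map <- variant_gene_map(bundle$variants, bundle$gene_models,
                               window_bp = g_window_bp, maf_max = 0.01)
  sp <- sex_stratified_posteriors(scores, md2, bundle$variants, gene_map)
  if (nrow(sp) > 0) {
    sp$category <- classify_sex_bias(sp$female_post, sp$male_post,
                                     delta = delta)
  } else {
    sp$category <- character(0)
  }
  list(z_tensor = zt, median_z = medz, scores = scores,
       sex_posteriors = sp, params_over = params$over,
       params_under = params$under)
}

## (variant, gene) pairs within the G-layer window, rare variants only
variant_gene_map <- function(variants, gene_models, window_bp = 10000,
                             maf_max = 0.01) {
  rare <- variants[variants$maf < maf_max, , drop = FALSE]
  trip <- collapse_pairs_all(rare, gene_models, window_bp)
  unique(trip[, c("variant_id", "gene_id")])
}
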