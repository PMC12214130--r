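#' Classify sex-biased rare variants from per-sex signed posteriors
#'
#' Sexual antagonism is checked first: both sexes' posteriors exceed
#' `delta` in magnitude with opposite signs. Otherwise a variant is
#' female-biased when `|female| - |male| > delta` (category `female_under`
#' if the female posterior is negative, `female_over` if positive), and
#' symmetrically for males; anything else is `unbiased`.
#'
#' @param female_post,male_post Signed posteriors in `[-1, 1]`.
#' @param delta Bias threshold (default 0.2).
#' @return Character vector of categories.
#' @export
classify_sex_bias <- function(female_post, male_post, delta = 0.2) {
  stopifnot(length(female_post) == length(male_post))
  if (any(abs(c(female_post, male_post)) > 1 + 1e-9, na.rm = TRUE)) {
    stop("signed posteriors must lie in [-1, 1]")
  }
  f <- female_post
  m <- male_post
  out <- rep("unbiased", length(f))
  antag <- abs(f) > delta & abs(m) > delta & sign(f) * sign(m) < 0
  fbias <- !antag & (abs(f) - abs(m) > delta)
  mbias <- !antag & (abs(m) - abs(f) > delta)
  out[antag] <- "antagonistic"
  out[fbias & f < 0] <- "female_under"
  out[fbias & f > 0] <- "female_over"
  out[mbias & m < 0] <- "male_under"
  out[mbias & m > 0] <- "male_over"
  out
}

#' Sex-label permutation control for sex-bias calls
#'
#' Reruns the whole scoring chain (`Z` computation, outlier signal,
#' posterior estimation, per-sex medians, classification) `n_perm` times
#' with sex labels randomly permuted, and counts, per variant-gene pair,
#' in how many permutations it is classified sex-biased. The default
#' retention rule keeps an observed sex-biased call only when that count
#' is zero (a conservative null control); `rule = "literal"` instead
#' keeps calls that are sex-biased in at least one permutation.
#'
#' @param bundle A `cohort_bundle`.
#' @param n_perm Number of permutations (default 5).
#' @param seed Integer seed.
#' @param rule `"conservative"` or `"literal"`.
#' @param delta Bias threshold passed to the classifier.
#' @param ... Further arguments to [score_sex_posteriors()].
#' @return The observed `sex_posteriors` table with extra columns
#'   `perm_biased_count` and `retained`.
#' @export
permutation_control <- function(bundle, n_perm = 5, seed = 1,
                                rule = c("conservative", "literal"),
                                delta = 0.2, ...) {
  rule <- match.arg(rule)
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- score_sex_posteriors(bundle, delta = delta, ...)$sex_posteriors
  key <- paste(observed$variant_id, observed$gene_id)
  perm_count <- stats::setNames(integer(length(key)), key)
  md <- bundle$metadata
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm_sex <- stats::setNames(sample(md$sex), md$individual_id)
    sp <- tryCatch(
      score_sex_posteriors(bundle, sex_labels = perm_sex, delta = delta,
                           ...)$sex_posteriors,
      error = function(e) NULL)
    if (is.null(sp) || nrow(sp) == 0) next
    biased <- sp$category != "unbiased"
    pk <- paste(sp$variant_id, sp$gene_id)[biased]
    hit <- key %in% pk
    perm_count[hit] <- perm_count[hit] + 1L
  }
  observed$perm_biased_count <- unname(perm_count)
  is_biased <- observed$category != "unbiased"
  observed$retained <- if (rule == "conservative") {
    is_biased & observed$perm_biased_count == 0
  } else {
    is_biased & observed$perm_biased_count >= 1
  }
  observed
}

#' Link sex-biased variants to gene-drug tables
#'
#' Joins sex-biased and non-biased functional variants (maximum absolute
#' signed posterior above `functional_cut`) to drugs through their genes,
#' counts unique variants, genes and drugs per class, and computes the
#' relative risk of a sex-biased functional variant being linked to the
#' drug table versus a non-biased functional variant.
#'
#' @param records Sex-posterior table with `variant_id`, `gene_id`,
#'   `female_post`, `male_post`, `category` (and optionally `retained`).
#' @param gene_drug_table Data frame `gene_id`, `drug`.
#' @param adr_table Optional data frame `drug` (e.g. drugs with known
#'   sex-differential adverse reactions); when given, a second relative
#'   risk is computed against links restricted to those drugs.
#' @param functional_cut Threshold defining functional variants
#'   (default 0.2).
#' @return List with `links` (variant-gene-drug rows), `counts`, `rr`
#'   (and `rr_adr` when `adr_table` is given).
#' @export
pharmaco_link <- function(records, gene_drug_table, adr_table = NULL,
                          functional_cut = 0.2) {
  if (is.null(gene_drug_table) || nrow(gene_drug_table) == 0) {
    stop("empty gene-drug table")
  }
  functional <- pmax(abs(records$female_post), abs(records$male_post)) >
    functional_cut
  biased <- records$category != "unbiased"
  if ("retained" %in% names(records)) biased <- biased & records$retained
  rec <- records[functional, , drop = FALSE]
  biased <- biased[functional]
  links <- merge(rec, gene_drug_table, by = "gene_id")
  links$sex_biased <- links$variant_id %in% rec$variant_id[biased]
  count_class <- function(b) {
    sub <- links[links$sex_biased == b, , drop = FALSE]
    c(variants = length(unique(sub$variant_id)),
      genes = length(unique(sub$gene_id)),
      drugs = length(unique(sub$drug)))
  }
  counts <- rbind(sex_biased = count_class(TRUE),
                  non_biased = count_class(FALSE))
  linked <- function(b) {
    v <- unique(rec$variant_id[biased == b])
    inl <- v %in% links$variant_id
    c(with = sum(inl), without = sum(!inl))
  }
  sb <- linked(TRUE)
  nb <- linked(FALSE)
  rr <- relative_risk(unname(sb["with"]), unname(sb["without"]),
                      unname(nb["with"]), unname(nb["without"]))
  out <- list(links = links, counts = counts, rr = rr)
  if (!is.null(adr_table)) {
    adr_links <- links[links$drug %in% adr_table$drug, , drop = FALSE]
    in_adr <- function(b) {
      v <- unique(rec$variant_id[biased == b])
      inl <- v %in% adr_links$variant_id
      c(with = sum(inl), without = sum(!inl))
    }
    sba <- in_adr(TRUE)
    nba <- in_adr(FALSE)
    out$rr_adr <- relative_risk(unname(sba["with"]), unname(sba["without"]),
                                unname(nba["with"]), unname(nba["without"]))
  }
  out
}

#' Sex-specific TF regulatory score
#'
#' For TF `i` and gene `j`, `r_ij = sum_v s_iv p_vj / sum_{v,i} s_iv
#' p_vj`, where `s_iv` is the predicted motif disruption of TF `i` by
#' variant `v`, `p_vj` the variant's posterior on gene `j`, and `v` runs
#' over the variants admitted by the mask (regulatory variants within the
#' gene's window). The denominator normalizes across TFs, so scores sum to
#' one per gene; genes with a (near-)zero denominator are flagged and
#' excluded from rankings.
#'
#' @param disruption TF x variant matrix of motif-disruption scores.
#' @param posteriors Data frame `variant_id`, `gene_id`, `post` (one sex's
#'   posteriors).
#' @param mask Optional data frame `variant_id`, `gene_id` restricting
#'   which pairs enter the sum (default: all rows of `posteriors`).
#' @return Data frame `tf_id`, `gene_id`, `score`, `flagged`.
#' @export
tf_regulatory_score <- function(disruption, posteriors, mask = NULL) {
  use <- posteriors
  if (!is.null(mask)) {
    mk <- paste(mask$variant_id, mask$gene_id)
    use <- use[paste(use$variant_id, use$gene_id) %in% mk, , drop = FALSE]
  }
  use <- use[use$variant_id %in% colnames(disruption), , drop = FALSE]
  if (nrow(use) == 0) {
    return(data.frame(tf_id = character(), gene_id = character(),
                      score = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (gid in unique(use$gene_id)) {
    sub <- use[use$gene_id == gid, , drop = FALSE]
    s <- disruption[, sub$variant_id, drop = FALSE]
    num <- drop(s %*% sub$post)          # per-TF sum over variants
    den <- sum(num)
    flagged <- abs(den) < 1e-12
    rows[[gid]] <- data.frame(
      tf_id = rownames(disruption), gene_id = gid,
      score = if (flagged) NA_real_ else num / den,
      flagged = flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-summarized sex difference in TF regulatory scores
#'
#' Per TF, the mean over shared (non-flagged) genes of the female minus
#' male regulatory score; positive values indicate an increased predicted
#' female binding effect. When permuted-model differences are supplied,
#' a TF is retained only if its observed absolute difference exceeds the
#' maximum absolute difference across all permuted models.
#'
#' @param scores_female,scores_male Outputs of [tf_regulatory_score()] for
#'   the two sexes.
#' @param perm_diffs Optional numeric matrix (TF x permutations) of
#'   permuted-model differences.
#' @return Data frame `tf_id`, `difference`, `n_genes`, `rank`, and
#'   `retained` when `perm_diffs` is given, ordered by difference.
#' @export
sex_tf_difference <- function(scores_female, scores_male, perm_diffs = NULL) {
  fk <- paste(scores_female$tf_id, scores_female$gene_id)
  mk <- paste(scores_male$tf_id, scores_male$gene_id)
  common <- intersect(fk[!scores_female$flagged], mk[!scores_male$flagged])
  if (length(common) == 0) stop("the two sexes share no scored genes")
  f <- scores_female[match(common, fk), , drop = FALSE]
  m <- scores_male[match(common, mk), , drop = FALSE]
  d <- stats::aggregate(list(difference = f$score - m$score),
                        by = list(tf_id = f$tf_id), FUN = mean)
  n <- stats::aggregate(list(n_genes = f$score),
                        by = list(tf_id = f$tf_id), FUN = length)
  out <- merge(d, n, by = "tf_id")
  out <- out[order(-out$difference), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(perm_diffs)) {
    mx <- apply(abs(perm_diffs), 1, max)[out$tf_id]
    out$retained <- abs(out$difference) > mx
  }
  rownames(out) <- NULL
  out
}
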