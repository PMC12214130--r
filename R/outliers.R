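#' Build the four stratification groups
#'
#' Returns the female, male, combined-all and combined-equal-size groups.
#' The combined-equal group takes, within each sex, the half of the
#' individuals with the most tissues (ties broken by a seeded shuffle), so
#' its sex counts are `ceiling(N_F/2)` and `ceiling(N_M/2)`. With
#' `equalize_sex = TRUE` the male group is subset to the female group's
#' size, again preferring individuals with the most tissues.
#'
#' @param metadata Data frame with `individual_id`, `sex` and
#'   `tissues_present` (list-column).
#' @param seed Integer seed for tie-breaking.
#' @param equalize_sex Subset the larger sex group to the smaller's size.
#' @return Named list of `strat_group` lists (`group_id`, `member_ids`).
#' @export
stratify_groups <- function(metadata, seed = 1, equalize_sex = FALSE) {
  if (!all(c("female", "male") %in% metadata$sex)) {
    stop("both sexes must be present in the metadata")
  }
  n_tis <- vapply(metadata$tissues_present, length, integer(1))
  set.seed(seed)
  tiebreak <- stats::runif(nrow(metadata))
  top_k <- function(ids, k) {
    ord <- order(-n_tis[match(ids, metadata$individual_id)],
                 tiebreak[match(ids, metadata$individual_id)])
    ids[ord][seq_len(k)]
  }
  females <- metadata$individual_id[metadata$sex == "female"]
  males <- metadata$individual_id[metadata$sex == "male"]
  male_members <- males
  if (equalize_sex && length(males) > length(females)) {
    male_members <- top_k(males, length(females))
  } else if (equalize_sex && length(females) > length(males)) {
    females <- top_k(females, length(males))
  }
  eq <- c(top_k(females, ceiling(length(females) / 2)),
          top_k(male_members, ceiling(length(male_members) / 2)))
  grp <- function(id, members) {
    structure(list(group_id = id, member_ids = sort(members)),
              class = "strat_group")
  }
  list(female = grp("female", females),
       male = grp("male", male_members),
       combined_all = grp("combined_all", c(females, male_members)),
       combined_equal = grp("combined_equal", eq))
}

#' Single-tissue outlier indicator
#'
#' `TRUE` where the absolute Z score strictly exceeds the threshold;
#' missing values are `FALSE`.
#'
#' @param z_matrix Gene x sample Z-score matrix.
#' @param threshold Outlier threshold (default 2.5).
#' @return Logical matrix of the same shape.
#' @export
single_tissue_outliers <- function(z_matrix, threshold = 2.5) {
  out <- abs(z_matrix) > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Multi-tissue outlier calls
#'
#' A (gene, individual) pair is called when it is a single-tissue outlier
#' (`|Z| > z_threshold`) in at least `min_tissues` tissues and the
#' absolute median Z across the individual's non-missing tissues exceeds
#' `z_threshold`. Individuals with fewer than `min_tissues` tissues for a
#' gene are ineligible. After calling, every call is dropped for genes
#' called in more than `max_individuals` individuals within the group.
#'
#' @param z_tensor Gene x individual x tissue array of Z scores (`NA` for
#'   missing tissues).
#' @param min_tissues Minimum outlier tissues (default 3).
#' @param z_threshold Z threshold (default 2.5).
#' @param max_individuals Maximum called individuals per gene before the
#'   gene is removed (default 2).
#' @param group_id Label attached to the calls.
#' @return Data frame with `gene_id`, `individual_id`, `group_id`,
#'   `median_z`, `n_outlier_tissues`, `direction`.
#' @export
multi_tissue_outliers <- function(z_tensor, min_tissues = 3,
                                  z_threshold = 2.5, max_individuals = 2,
                                  group_id = "combined_all") {
  stopifnot(length(dim(z_tensor)) == 3)
  n_present <- apply(!is.na(z_tensor), c(1, 2), sum)
  n_out <- apply(abs(z_tensor) > z_threshold, c(1, 2), sum, na.rm = TRUE)
  med <- apply(z_tensor, c(1, 2), stats::median, na.rm = TRUE)
  hit <- which(n_present >= min_tissues & n_out >= min_tissues &
                 abs(med) > z_threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(gene_id = character(), individual_id = character(),
                      group_id = character(), median_z = numeric(),
                      n_outlier_tissues = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  calls <- data.frame(
    gene_id = rownames(z_tensor)[hit[, 1]],
    individual_id = colnames(z_tensor)[hit[, 2]],
    group_id = group_id,
    median_z = med[hit],
    n_outlier_tissues = n_out[hit],
    direction = ifelse(med[hit] > 0, "over", "under"),
    stringsAsFactors = FALSE
  )
  per_gene <- table(calls$gene_id)
  drop_genes <- names(per_gene)[per_gene > max_individuals]
  calls <- calls[!(calls$gene_id %in% drop_genes), , drop = FALSE]
  calls <- calls[order(calls$gene_id, calls$individual_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Compare outlier status between a stratified and a combined group
#'
#' For every (gene, individual) cell present in both groups' Z tensors,
#' reports whether it is called in the stratified group only, the combined
#' group only, both, or neither, together with both groups' median Z and
#' the gene's chromosome class (X vs autosome).
#'
#' @param calls_stratified,calls_combined Call tables from
#'   [multi_tissue_outliers()].
#' @param z_stratified,z_combined The corresponding Z tensors.
#' @param gene_models Gene model table (`gene_id`, `chrom`).
#' @return List with `table` (per-pair status) and `summary` (counts per
#'   status and chromosome class).
#' @export
compare_groups <- function(calls_stratified, calls_combined,
                           z_stratified, z_combined, gene_models = NULL) {
  genes <- intersect(rownames(z_stratified), rownames(z_combined))
  inds <- intersect(colnames(z_stratified), colnames(z_combined))
  if (length(genes) == 0 || length(inds) == 0) {
    stop("the two groups share no genes or no individuals; mismatched cohorts?")
  }
  med <- function(z) apply(z, c(1, 2), stats::median, na.rm = TRUE)
  ms <- med(z_stratified[genes, inds, , drop = FALSE])
  mc <- med(z_combined[genes, inds, , drop = FALSE])
  key <- function(calls) paste(calls$gene_id, calls$individual_id)
  grid <- expand.grid(gene_id = genes, individual_id = inds,
                      stringsAsFactors = FALSE)
  gkey <- paste(grid$gene_id, grid$individual_id)
  in_s <- gkey %in% key(calls_stratified)
  in_c <- gkey %in% key(calls_combined)
  status <- ifelse(in_s & in_c, "both",
                   ifelse(in_s, "stratified_only",
                          ifelse(in_c, "combined_only", "neither")))
  tab <- data.frame(grid,
                    status = status,
                    median_z_stratified = ms[cbind(grid$gene_id, grid$individual_id)],
                    median_z_combined = mc[cbind(grid$gene_id, grid$individual_id)],
                    stringsAsFactors = FALSE)
  if (!is.null(gene_models)) {
    chrom <- gene_models$chrom[match(tab$gene_id, gene_models$gene_id)]
    tab$chrom_class <- ifelse(chrom == "chrX", "X", "autosome")
  } else {
    tab$chrom_class <- NA_character_
  }
  summary <- as.data.frame(table(status = tab$status,
                                 chrom_class = tab$chrom_class),
                           stringsAsFactors = FALSE)
  list(table = tab, summary = summary)
}
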