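#' Write a cohort bundle to plain-text fixture files
#'
#' Emits a VCF 4.2 (variants with carriers as genotypes; INFO fields MAF,
#' CADD, CATS, CAUSAL), per-tissue TSV count / TPM / latent-expression
#' matrices, a metadata TSV, BED gene models (0-based half-open), TSV
#' annotation and TF-disruption matrices, and JSON truth/config/N2 tables.
#' The file set round-trips losslessly through [read_fixture()].
#'
#' @param bundle A `cohort_bundle`.
#' @param directory Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  path <- function(...) file.path(directory, ...)
  wt <- function(x, file) {
    utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                       path(file), sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  tissues <- dimnames(bundle$counts)[[3]]
  for (ti in tissues) {
    wt(bundle$counts[, , ti], paste0("counts_", ti, ".tsv"))
    wt(bundle$tpm[, , ti], paste0("tpm_", ti, ".tsv"))
    wt(bundle$log_mu[, , ti], paste0("logmu_", ti, ".tsv"))
  }
  md <- bundle$metadata
  md_out <- data.frame(individual_id = md$individual_id, sex = md$sex,
                       PC1 = md$PC1, PC2 = md$PC2, PC3 = md$PC3,
                       tissues_present = vapply(md$tissues_present, paste,
                                                character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  utils::write.table(md_out, path("metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- bundle$gene_models
  utils::write.table(
    data.frame(gm$chrom, gm$start - 1L, gm$end, gm$gene_id),
    path("gene_models.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_vcf(bundle$variants, md$individual_id, path("variants.vcf"))
  wt(bundle$annotations, "annotations.tsv")
  wt(bundle$tf_disruption, "tf_disruption.tsv")
  jsonlite::write_json(bundle$truth, path("truth.json"), digits = NA)
  jsonlite::write_json(bundle$n2_pairs, path("n2_pairs.json"), digits = NA)
  cfg <- bundle$config
  cfg$effect_table <- lapply(cfg$effect_table, unclass)
  jsonlite::write_json(unclass(cfg), path("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

write_vcf <- function(variants, sample_ids, file) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Deleteriousness score\">",
    "##INFO=<ID=CATS,Number=1,Type=String,Description=\"Annotation categories\">",
    "##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description=\"Planted causal variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", paste(unique(variants$chrom)), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- character(nrow(variants))
  if (nrow(variants) > 0) {
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      info <- paste0("MAF=", format(v$maf, digits = 15, scientific = TRUE),
                     ";CADD=", format(v$deleteriousness, digits = 15),
                     ";CATS=", paste(v$categories[[1]], collapse = "|"),
                     if (v$causal) ";CAUSAL" else "")
      gt <- ifelse(sample_ids %in% v$carriers[[1]], "0/1", "0/0")
      body[i] <- paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".",
                         "PASS", info, "GT", gt), collapse = "\t")
    }
  }
  writeLines(c(header, body), file)
}

#' Read a cohort bundle back from fixture files
#'
#' Inverse of [write_fixture()].
#'
#' @param directory Directory written by [write_fixture()].
#' @return A `cohort_bundle`.
#' @export
read_fixture <- function(directory) {
  path <- function(...) file.path(directory, ...)
  rt <- function(file) {
    as.matrix(utils::read.table(path(file), sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
  }
  md_raw <- utils::read.table(path("metadata.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  metadata <- data.frame(individual_id = md_raw$individual_id,
                         sex = md_raw$sex, PC1 = md_raw$PC1,
                         PC2 = md_raw$PC2, PC3 = md_raw$PC3,
                         stringsAsFactors = FALSE)
  metadata$tissues_present <- strsplit(md_raw$tissues_present, ",", fixed = TRUE)
  cfg_raw <- jsonlite::read_json(path("config.json"), simplifyVector = TRUE)
  cfg_raw$maf_spectrum <- as.data.frame(cfg_raw$maf_spectrum)
  effects <- cfg_raw$effect_table
  cfg_raw$effect_table <- list()
  config <- do.call(cohort_config,
                    cfg_raw[intersect(names(cfg_raw),
                                      names(formals(cohort_config)))])
  if (length(effects) > 0 && NROW(effects) > 0) {
    ef <- as.data.frame(effects)
    config$effect_table <- lapply(seq_len(nrow(ef)), function(i) {
      planted_effect(gene_id = ef$gene_id[i], effect_size = ef$effect_size[i],
                     direction = ef$direction[i], sex_scope = ef$sex_scope[i],
                     carrier_count = ef$carrier_count[i],
                     variant_id = ef$variant_id[i])
    })
  }
  tissues <- sort(sub("^counts_(.*)\\.tsv$", "\\1",
                      list.files(directory, pattern = "^counts_.*\\.tsv$")))
  load_tensor <- function(prefix) {
    mats <- lapply(tissues, function(ti) rt(paste0(prefix, "_", ti, ".tsv")))
    arr <- array(NA_real_, dim = c(dim(mats[[1]]), length(tissues)),
                 dimnames = c(dimnames(mats[[1]]), list(tissues)))
    for (i in seq_along(tissues)) arr[, , i] <- mats[[i]]
    arr
  }
  counts <- load_tensor("counts")
  gm_raw <- utils::read.table(path("gene_models.bed"), sep = "\t",
                              header = FALSE, stringsAsFactors = FALSE)
  gene_models <- data.frame(gene_id = gm_raw$V4, chrom = gm_raw$V1,
                            start = gm_raw$V2 + 1L, end = gm_raw$V3,
                            stringsAsFactors = FALSE)
  truth <- as.data.frame(jsonlite::read_json(path("truth.json"),
                                             simplifyVector = TRUE))
  if (nrow(truth) == 0) {
    truth <- data.frame(gene_id = character(), variant_id = character(),
                        effect_size = numeric(), direction = character(),
                        sex_scope = character(), carrier_count = integer(),
                        stringsAsFactors = FALSE)
  }
  n2 <- as.data.frame(jsonlite::read_json(path("n2_pairs.json"),
                                          simplifyVector = TRUE))
  if (nrow(n2) == 0) n2 <- empty_n2_pairs()
  variants <- load_variants(path("variants.vcf"))
  ## restore original (simulation) variant order for field-by-field equality
  variants <- variants[order(variants$variant_id), , drop = FALSE]
  rownames(variants) <- NULL
  ann <- rt("annotations.tsv")
  structure(list(
    counts = counts, tpm = load_tensor("tpm"), log_mu = load_tensor("logmu"),
    metadata = metadata, gene_models = gene_models,
    variants = variants,
    annotations = ann[variants$variant_id, , drop = FALSE],
    tf_disruption = rt("tf_disruption.tsv")[, variants$variant_id,
                                            drop = FALSE],
    truth = truth, n2_pairs = n2, config = config
  ), class = "cohort_bundle")
}
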