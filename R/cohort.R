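#' Planted rare-variant effect
#'
#' Ground-truth description of one functional rare variant injected into a
#' synthetic cohort: the standardized expression shift its carriers receive
#' in the sexes covered by `sex_scope`. For `antagonistic` effects,
#' `direction` is the direction in females and males receive the opposite
#' sign.
#'
#' @param gene_id Target gene id (e.g. `"G0001"`), or `NA` to let
#'   [simulate_cohort()] assign genes round-robin.
#' @param effect_size Absolute expression shift in Z units (positive).
#' @param direction `"over"` or `"under"`.
#' @param sex_scope One of `"female_only"`, `"male_only"`, `"both"`,
#'   `"antagonistic"`.
#' @param carrier_count Number of carrier individuals.
#' @param variant_id Optional id; assigned during simulation if `NA`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(gene_id = NA, effect_size, direction = c("over", "under"),
                           sex_scope = c("both", "female_only", "male_only",
                                         "antagonistic"),
                           carrier_count = 1, variant_id = NA) {
  direction <- match.arg(direction)
  sex_scope <- match.arg(sex_scope)
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("effect_size must be a nonnegative number (direction carries the sign)")
  }
  if (carrier_count < 1) stop("carrier_count must be at least 1")
  structure(list(gene_id = gene_id, variant_id = variant_id,
                 effect_size = effect_size, direction = direction,
                 sex_scope = sex_scope, carrier_count = carrier_count),
            class = "planted_effect")
}

#' Synthetic cohort configuration
#'
#' Parameters of the generative model behind [simulate_cohort()]. Latent
#' log2 expression is gene baseline + latent-factor loadings x factors +
#' a sex main effect on a subset of genes + planted variant effects +
#' i.i.d. Gaussian noise; read counts are Poisson draws of the
#' exponentiated latent values, and TPM-like values rescale the latent
#' expression per sample.
#'
#' @param n_female,n_male Individuals per sex.
#' @param n_genes,n_tissues Genes and tissues.
#' @param tissue_missingness Probability a sample is missing a tissue.
#' @param n_latent_factors Number of hidden confounding factors.
#' @param factor_sd Factor standard deviation (strength of confounding).
#' @param noise_sd Residual log2-scale noise SD; planted Z-scale effects
#'   are converted to log2 shifts with this unit.
#' @param baseline_mean,baseline_sd Gene baseline log2-expression.
#' @param sex_effect_fraction Fraction of genes with a sex main effect.
#' @param sex_effect_sd SD of the per-gene sex main effect (log2 scale).
#' @param maf_spectrum Data frame with columns `maf` (upper bound of the
#'   frequency class; `0` denotes singletons) and `weight` (sums to 1).
#' @param window_bp Half-window around genes where variants are placed.
#' @param variants_per_gene Background variants simulated per gene.
#' @param effect_table List of [planted_effect()] objects.
#' @param n_annotations Number of genomic annotation features (default 30).
#' @param annotation_informativeness In `[0, 1]`; 0 makes causal and
#'   background annotation vectors identically distributed.
#' @param n_tf Number of transcription factors in the disruption matrix.
#' @param tf_target Optional list(tf =, boost =) planting elevated
#'   disruption of one TF's motif at female-scoped causal variants.
#' @param x_fraction Fraction of genes placed on chrX.
#' @param n2_pair_fraction Fraction of variants converted to N2 pairs.
#' @param n2_seed Optional separate seed for the N2 pair assignment
#'   (defaults to `seed + 1`).
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_female = 60, n_male = 60, n_genes = 100,
                          n_tissues = 4, tissue_missingness = 0.1,
                          n_latent_factors = 3, factor_sd = 1,
                          noise_sd = 0.5, baseline_mean = 7, baseline_sd = 1,
                          sex_effect_fraction = 0.2, sex_effect_sd = 0.5,
                          maf_spectrum = data.frame(
                            maf = c(0, 0.001, 0.01),
                            weight = c(0.7, 0.2, 0.1)),
                          window_bp = 5000, variants_per_gene = 3,
                          effect_table = list(), n_annotations = 30,
                          annotation_informativeness = 0.5,
                          n_tf = 25, tf_target = NULL,
                          x_fraction = 0.1, n2_pair_fraction = 0,
                          n2_seed = NULL, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_female", "n_male", "n_genes", "n_tissues",
              "n_latent_factors", "n_annotations", "n_tf",
              "variants_per_gene")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(f, " must be at least 1")
  }
  for (f in c("tissue_missingness", "annotation_informativeness",
              "n2_pair_fraction", "sex_effect_fraction", "x_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (factor_sd <= 0 || noise_sd <= 0) stop("factor_sd and noise_sd must be positive")
  if (abs(sum(maf_spectrum$weight) - 1) > 1e-8) {
    stop("maf_spectrum weights must sum to 1")
  }
  if (length(effect_table) > 0 &&
      !all(vapply(effect_table, inherits, logical(1), "planted_effect"))) {
    stop("effect_table must be a list of planted_effect objects")
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a multi-tissue expression + rare-variant cohort
#'
#' Generates the full synthetic study described by the configuration:
#' sample metadata (sex, 3 genetic PCs, tissue membership), gene models,
#' latent log2 expression with hidden confounders and planted effects,
#' Poisson read counts and TPM-like values, a rare-variant table with a
#' configurable site-frequency spectrum, a 30-feature annotation matrix,
#' a TF-disruption matrix, and the ground-truth effect table.
#'
#' All stochastic structure (metadata, baselines, factors, noise, variant
#' placement, carriers) is drawn before planted effects are added, so two
#' configurations differing only in `effect_size` produce latent
#' expression differing exactly by the injected shifts.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle` list with elements `counts`, `tpm`, `log_mu`
#'   (gene x sample x tissue arrays, `NA` for missing tissues),
#'   `metadata`, `gene_models`, `variants`, `annotations`,
#'   `tf_disruption`, `truth`, `n2_pairs`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_female + config$n_male
  g <- config$n_genes
  t_ <- config$n_tissues
  ids <- sprintf("IND%04d", seq_len(n))
  sex <- c(rep("female", config$n_female), rep("male", config$n_male))
  pcs <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(ids, paste0("PC", 1:3)))
  present <- matrix(stats::runif(n * t_) >= config$tissue_missingness, n, t_)
  ## every sample keeps at least one tissue
  fix <- which(rowSums(present) == 0)
  if (length(fix) > 0) {
    keep_t <- 1 + (fix %% t_)
    present[cbind(fix, keep_t)] <- TRUE
  }
  tissues <- sprintf("TIS%02d", seq_len(t_))
  metadata <- data.frame(individual_id = ids, sex = sex,
                         pcs, stringsAsFactors = FALSE)
  metadata$tissues_present <- apply(present, 1, function(r) tissues[r],
                                    simplify = FALSE)

  ## gene models: X-chromosome block first, autosomes round-robin
  gene_ids <- sprintf("G%04d", seq_len(g))
  n_x <- round(config$x_fraction * g)
  chrom <- c(rep("chrX", n_x),
             paste0("chr", 1 + (seq_len(g - n_x) - 1) %% 22))
  idx_on_chrom <- stats::ave(seq_len(g), chrom, FUN = seq_along)
  start <- 1e5 + (idx_on_chrom - 1) * 2e5
  gene_models <- data.frame(gene_id = gene_ids, chrom = chrom,
                            start = start, end = start + 2e4,
                            stringsAsFactors = FALSE)

  baseline <- stats::rnorm(g, config$baseline_mean, config$baseline_sd)
  loadings <- matrix(stats::rnorm(g * config$n_latent_factors),
                     g, config$n_latent_factors)
  factors <- matrix(stats::rnorm(n * config$n_latent_factors,
                                 sd = config$factor_sd),
                    n, config$n_latent_factors)
  n_sex_genes <- round(config$sex_effect_fraction * g)
  sex_beta <- numeric(g)
  if (n_sex_genes > 0) {
    sex_genes <- sample.int(g, n_sex_genes)
    sex_beta[sex_genes] <- stats::rnorm(n_sex_genes, sd = config$sex_effect_sd)
  }
  tissue_offset <- matrix(stats::rnorm(g * t_, sd = 0.3), g, t_)
  is_male <- as.numeric(sex == "male")

  log_mu <- array(NA_real_, dim = c(g, n, t_),
                  dimnames = list(gene_ids, ids, tissues))
  base_gs <- baseline + loadings %*% t(factors) + outer(sex_beta, is_male)
  for (ti in seq_len(t_)) {
    noise <- matrix(stats::rnorm(g * n, sd = config$noise_sd), g, n)
    log_mu[, , ti] <- base_gs + tissue_offset[, ti] + noise
  }

  ## ---- variants -------------------------------------------------------
  vres <- simulate_variants(config, gene_models, metadata)
  variants <- vres$variants
  truth <- vres$truth

  ## N2 rewiring happens before effects are injected, so planted effects
  ## always act on the carriers recorded in the variant table
  n2_pairs <- empty_n2_pairs()
  if (config$n2_pair_fraction > 0) {
    rewired <- rewire_n2_pairs(variants, gene_models, metadata,
                               config$n2_pair_fraction,
                               seed = config$n2_seed %||% (config$seed + 1L))
    variants <- rewired$variants
    n2_pairs <- rewired$n2_pairs
  }

  ## planted effects: shift carrier cells in scoped sexes, all tissues
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      vrow <- variants[variants$variant_id == truth$variant_id[i], ]
      carriers <- vrow$carriers[[1]]
      shift_z <- truth$effect_size[i] *
        ifelse(truth$direction[i] == "over", 1, -1)
      shift <- shift_z * config$noise_sd
      scope <- truth$sex_scope[i]
      for (cid in carriers) {
        cs <- metadata$sex[metadata$individual_id == cid]
        s <- switch(scope,
                    both = shift,
                    female_only = if (cs == "female") shift else 0,
                    male_only = if (cs == "male") shift else 0,
                    antagonistic = if (cs == "female") shift else -shift)
        if (s != 0) {
          gi <- match(truth$gene_id[i], gene_ids)
          log_mu[gi, cid, ] <- log_mu[gi, cid, ] + s
        }
      }
    }
  }

  ## observation layer: Poisson counts of 2^mu, TPM rescaled per sample
  counts <- array(NA_real_, dim = dim(log_mu), dimnames = dimnames(log_mu))
  tpm <- counts
  for (ti in seq_len(t_)) {
    here <- which(present[, ti])
    mu <- 2^log_mu[, here, ti, drop = FALSE]
    dim(mu) <- c(g, length(here))
    counts[, here, ti] <- stats::rpois(g * length(here), lambda = mu)
    tpm[, here, ti] <- sweep(mu, 2, colSums(mu), "/") * 1e6
  }
  ## mask latent values for absent tissues so all tensors share missingness
  for (ti in seq_len(t_)) log_mu[, !present[, ti], ti] <- NA_real_

  annotations <- simulate_annotations(variants, truth,
                                      config$annotation_informativeness,
                                      n_annotations = config$n_annotations)
  tf_disruption <- simulate_tf_disruption(config, variants, truth)

  structure(list(
    counts = counts, tpm = tpm, log_mu = log_mu, metadata = metadata,
    gene_models = gene_models, variants = variants,
    annotations = annotations, tf_disruption = tf_disruption,
    truth = truth, n2_pairs = n2_pairs, config = config
  ), class = "cohort_bundle")
}

## Background variants per gene plus one variant per planted effect.
simulate_variants <- function(config, gene_models, metadata) {
  n <- nrow(metadata)
  g <- nrow(gene_models)
  spec <- config$maf_spectrum[order(config$maf_spectrum$maf), , drop = FALSE]
  ## class with maf = 0 denotes cohort singletons (exactly one carrier);
  ## their annotated population MAF is drawn below the rarest real class
  pos_edges <- spec$maf[spec$maf > 0]
  singleton_upper <- if (length(pos_edges) > 0) min(1e-4, pos_edges[1] / 2) else 1e-4
  vocab <- c("TF_binding_site", "stop_gained", "splice", "intron",
             "intergenic", "UTR5", "UTR3", "upstream", "regulatory_region",
             "missense", "synonymous", "non_coding")
  draw_maf <- function(k) {
    cls <- sample.int(nrow(spec), k, replace = TRUE, prob = spec$weight)
    maf <- vapply(seq_len(k), function(i) {
      ci <- cls[i]
      hi <- spec$maf[ci]
      if (hi <= 0) return(stats::runif(1, singleton_upper / 10, singleton_upper))
      lo <- if (ci == 1) 0 else max(spec$maf[ci - 1], singleton_upper)
      stats::runif(1, lo, hi)
    }, numeric(1))
    list(maf = maf, singleton = spec$maf[cls] <= 0)
  }
  rows <- list()
  vcount <- 0L
  add_variant <- function(gene_row, maf, carriers, causal) {
    vcount <<- vcount + 1L
    pos <- round(stats::runif(1, gene_row$start - config$window_bp,
                              gene_row$end + config$window_bp))
    n_cat <- sample(1:3, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    data.frame(
      variant_id = sprintf("V%05d", vcount),
      chrom = gene_row$chrom, pos = pos,
      ref = ref,
      alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
      maf = maf,
      deleteriousness = stats::rgamma(1, shape = 2, scale = 5) +
        if (causal) 8 else 0,
      categories = I(list(sample(vocab, n_cat))),
      carriers = I(list(carriers)),
      causal = causal,
      stringsAsFactors = FALSE
    )
  }
  for (gi in seq_len(g)) {
    mafs <- draw_maf(config$variants_per_gene)
    for (vi in seq_len(config$variants_per_gene)) {
      k <- if (mafs$singleton[vi]) 1L else
        max(1L, stats::rbinom(1, 2 * n, mafs$maf[vi]))
      carriers <- sample(metadata$individual_id, min(k, n))
      rows[[length(rows) + 1]] <-
        add_variant(gene_models[gi, ], mafs$maf[vi], carriers, causal = FALSE)
    }
  }
  ## planted effects -> dedicated rare variants
  truth_rows <- list()
  effects <- config$effect_table
  if (length(effects) > 0) {
    females <- metadata$individual_id[metadata$sex == "female"]
    males <- metadata$individual_id[metadata$sex == "male"]
    for (ei in seq_along(effects)) {
      eff <- effects[[ei]]
      gene_id <- eff$gene_id
      if (is.na(gene_id)) {
        gene_id <- gene_models$gene_id[1 + (ei - 1) %% g]
      }
      if (!gene_id %in% gene_models$gene_id) {
        stop("planted effect ", ei, " names unknown gene ", gene_id)
      }
      k <- eff$carrier_count
      carriers <- draw_effect_carriers(eff, k, females, males, ei)
      ## single-carrier planted variants are cohort singletons with an
      ## ultra-rare population frequency, like background singletons
      maf <- if (k == 1) stats::runif(1, singleton_upper / 10, singleton_upper)
      else min(k / (2 * n), 0.009)
      row <- add_variant(gene_models[gene_models$gene_id == gene_id, ],
                         maf, carriers, causal = TRUE)
      rows[[length(rows) + 1]] <- row
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        gene_id = gene_id, variant_id = row$variant_id,
        effect_size = eff$effect_size, direction = eff$direction,
        sex_scope = eff$sex_scope, carrier_count = k,
        stringsAsFactors = FALSE
      )
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(), variant_id = character(),
               effect_size = numeric(), direction = character(),
               sex_scope = character(), carrier_count = integer(),
               stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

## Carriers for a planted effect. Sex-scoped effects still draw carriers
## from both sexes (balanced, scoped sex first) so the variant remains
## scorable per sex downstream; the expression shift itself is applied only
## in scoped cells. Errors when the scoped sex cannot supply its share.
draw_effect_carriers <- function(eff, k, females, males, idx) {
  scope <- eff$sex_scope
  n_scoped <- ceiling(k / 2)
  pick <- function(pool, m, side) {
    if (m > length(pool)) {
      stop("planted effect ", idx, " (", scope, ", carrier_count ", k,
           ") needs ", m, " ", side, " carriers but only ",
           length(pool), " exist")
    }
    sample(pool, m)
  }
  if (k == 1) {
    pool <- switch(scope, female_only = females, male_only = males,
                   c(females, males))
    return(pick(pool, 1, if (scope == "male_only") "male" else "female"))
  }
  if (scope == "female_only" || scope == "antagonistic" || scope == "both") {
    c(pick(females, n_scoped, "female"), pick(males, k - n_scoped, "male"))
  } else {
    c(pick(males, n_scoped, "male"), pick(females, k - n_scoped, "female"))
  }
}

#' Simulate the genomic-annotation feature matrix
#'
#' Draws one row of `n_annotations` standard-normal features per variant;
#' causal variants (those in the truth table) receive a mean shift of
#' `0.5 * informativeness` on every feature, so at `informativeness = 0`
#' causal and background variants are identically distributed and at 1 a
#' linear classifier separates them well.
#'
#' @param variants Variant table (`variant_id` column).
#' @param truth Truth table (`variant_id` column marks causal variants).
#' @param informativeness Real in `[0, 1]`.
#' @param n_annotations Number of features (default 30).
#' @return Numeric matrix, variants x annotations, rownames = variant ids.
#' @export
simulate_annotations <- function(variants, truth, informativeness,
                                 n_annotations = 30) {
  if (informativeness < 0 || informativeness > 1) {
    stop("informativeness must be in [0, 1]")
  }
  v <- nrow(variants)
  m <- matrix(stats::rnorm(v * n_annotations), v, n_annotations,
              dimnames = list(variants$variant_id,
                              sprintf("A%02d", seq_len(n_annotations))))
  causal <- variants$variant_id %in% truth$variant_id
  if (any(causal)) {
    m[causal, ] <- m[causal, , drop = FALSE] + 0.5 * informativeness
  }
  m
}

## TF x variant motif-disruption scores, N(0, 1); optionally one TF gets a
## boosted disruption at female-scoped causal variants (planted TF signal).
simulate_tf_disruption <- function(config, variants, truth) {
  v <- nrow(variants)
  m <- matrix(stats::rnorm(config$n_tf * v), config$n_tf, v,
              dimnames = list(sprintf("TF%02d", seq_len(config$n_tf)),
                              variants$variant_id))
  tgt <- config$tf_target
  if (!is.null(tgt)) {
    female_scoped <- truth$variant_id[truth$sex_scope %in%
                                        c("female_only", "antagonistic")]
    hit <- variants$variant_id %in% female_scoped
    if (any(hit)) m[tgt$tf, hit] <- m[tgt$tf, hit] + tgt$boost
  }
  m
}

#' Plant N2 carrier pairs into a cohort
#'
#' Rebuilds the cohort with a fraction of its (gene, variant) units
#' converted to N2 pairs: exactly two individuals share the identical
#' variant, recorded in `bundle$n2_pairs` so downstream model training can
#' hold them out. Rewiring happens before effect injection, so planted
#' effects act on the pair members. Pair members are drawn per pair, so
#' an individual may belong to several pairs (as in real cohorts).
#'
#' @param bundle A `cohort_bundle`.
#' @param fraction Fraction of variants to convert, in `[0, 1]`.
#' @param seed Integer seed for the pair assignment.
#' @return A rebuilt bundle with `n2_pairs` populated.
#' @export
make_n2_pairs <- function(bundle, fraction, seed = 1) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n_pairs <- round(fraction * nrow(bundle$variants))
  if (n_pairs > nrow(bundle$metadata)) {
    stop("fraction requests ", n_pairs, " N2 pairs but only ",
         nrow(bundle$metadata), " individuals are available")
  }
  config <- bundle$config
  config$n2_pair_fraction <- fraction
  config$n2_seed <- seed
  simulate_cohort(config)
}

## carrier rewiring for the chosen N2 units
rewire_n2_pairs <- function(variants, gene_models, metadata, fraction, seed) {
  n_pairs <- round(fraction * nrow(variants))
  ids <- metadata$individual_id
  if (n_pairs > length(ids)) {
    stop("fraction requests ", n_pairs, " N2 pairs but only ",
         length(ids), " individuals are available")
  }
  if (n_pairs == 0) {
    return(list(variants = variants, n2_pairs = empty_n2_pairs()))
  }
  set.seed(seed)
  chosen <- sample.int(nrow(variants), n_pairs)
  pair_rows <- vector("list", n_pairs)
  for (i in seq_along(chosen)) {
    pair <- sample(ids, 2)
    variants$carriers[[chosen[i]]] <- pair
    pair_rows[[i]] <- data.frame(
      variant_id = variants$variant_id[chosen[i]],
      gene_id = nearest_gene(variants[chosen[i], ], gene_models),
      individual_1 = pair[1], individual_2 = pair[2],
      stringsAsFactors = FALSE
    )
  }
  list(variants = variants, n2_pairs = do.call(rbind, pair_rows))
}

empty_n2_pairs <- function() {
  data.frame(variant_id = character(), gene_id = character(),
             individual_1 = character(), individual_2 = character(),
             stringsAsFactors = FALSE)
}

nearest_gene <- function(vrow, gene_models) {
  gm <- gene_models[gene_models$chrom == vrow$chrom, , drop = FALSE]
  d <- pmax(gm$start - vrow$pos, vrow$pos - gm$end, 0)
  gm$gene_id[which.min(d)]
}
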