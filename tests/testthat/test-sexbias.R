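# Sex-bias classification, permutation control, pharmacogenetic links and
# TF regulatory scores.

test_that("classification matches the stated rules", {
  expect_identical(classify_sex_bias(-0.5, -0.1), "female_under")
  expect_identical(classify_sex_bias(0.5, 0.1), "female_over")
  expect_identical(classify_sex_bias(-0.1, -0.5), "male_under")
  expect_identical(classify_sex_bias(0.1, 0.5), "male_over")
  expect_identical(classify_sex_bias(0.3, 0.3), "unbiased")
  expect_identical(classify_sex_bias(0.45, -0.35), "antagonistic")
  expect_identical(classify_sex_bias(-0.45, 0.35), "antagonistic")
  # antagonism takes precedence even when magnitudes also differ by > 0.2
  expect_identical(classify_sex_bias(0.9, -0.25), "antagonistic")
  # just at the threshold: not biased (strict inequality)
  expect_identical(classify_sex_bias(0.2, 0.0), "unbiased")
  expect_identical(classify_sex_bias(0.21, 0.0), "female_over")
  expect_error(classify_sex_bias(1.2, 0), "\\[-1, 1\\]")
})

test_that("classification is antisymmetric under swapping the sexes", {
  set.seed(5)
  f <- runif(300, -1, 1)
  m <- runif(300, -1, 1)
  a <- classify_sex_bias(f, m)
  b <- classify_sex_bias(m, f)
  swap <- c(female_under = "male_under", female_over = "male_over",
            male_under = "female_under", male_over = "female_over",
            antagonistic = "antagonistic", unbiased = "unbiased")
  expect_identical(unname(swap[a]), b)
})

test_that("permutation control is deterministic and mostly clears a null", {
  effs <- under_effects(3, effect_size = 6, carrier_count = 2, stride = 9,
                        direction = c("under", "over"))
  cfg <- cohort_config(n_female = 45, n_male = 45, n_genes = 100,
                       n_tissues = 4,
                       maf_spectrum = data.frame(maf = c(0, 0.001, 0.01),
                                                 weight = c(0.3, 0.3, 0.4)),
                       effect_table = effs,
                       annotation_informativeness = 0.7, seed = 61)
  b <- simulate_cohort(cfg)
  pc1 <- permutation_control(b, n_perm = 3, seed = 17)
  pc2 <- permutation_control(b, n_perm = 3, seed = 17)
  expect_identical(pc1, pc2)
  # sex-neutral cohort: under 1% of scored variants retained as biased
  # (aggregate over three seeds for a stable denominator)
  scored <- nrow(pc1); retained <- sum(pc1$retained)
  for (s in 62:63) {
    cfg$seed <- s
    pcs <- permutation_control(simulate_cohort(cfg), n_perm = 5,
                               seed = s + 100)
    scored <- scored + nrow(pcs)
    retained <- retained + sum(pcs$retained)
  }
  expect_lt(retained, max(1, 0.01 * scored) + 1e-9)
  expect_error(permutation_control(b, n_perm = 0), "at least 1")
})

test_that("the literal retention rule keeps permutation-replicated calls", {
  records <- data.frame(variant_id = "v", gene_id = "g",
                        female_post = 0.8, male_post = 0.1,
                        n_female = 1, n_male = 1)
  # exercise only the rule arithmetic via a synthetic observed table
  obs <- records
  obs$category <- classify_sex_bias(obs$female_post, obs$male_post)
  obs$perm_biased_count <- 2L
  conservative <- obs$category != "unbiased" & obs$perm_biased_count == 0
  literal <- obs$category != "unbiased" & obs$perm_biased_count >= 1
  expect_false(conservative)
  expect_true(literal)
})

test_that("pharmaco links count variants, genes and drugs per class", {
  records <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    female_post = c(0.8, -0.6, 0.5, 0.25, 0.9),
    male_post = c(0.1, -0.55, 0.45, 0.22, 0.85))
  records$category <- classify_sex_bias(records$female_post,
                                        records$male_post)
  drugs <- data.frame(gene_id = c("gA", "gA", "gB", "gE"),
                      drug = c("d1", "d2", "d3", "d4"))
  out <- pharmaco_link(records, drugs)
  # v1 (female_over, gA) links to two drugs; non-biased functional v2 (gA),
  # v3 (gB), v5 (gD, unlinked)
  expect_identical(unname(out$counts["sex_biased", "drugs"]), 2L)
  expect_identical(unname(out$counts["sex_biased", "variants"]), 1L)
  expect_identical(unname(out$counts["non_biased", "drugs"]), 3L)
  expect_true(out$rr$rr > 0)
  # a variant near two genes counts once per gene-drug pair
  rec2 <- rbind(records,
                data.frame(variant_id = "v1", gene_id = "gB",
                           female_post = 0.8, male_post = 0.1,
                           category = "female_over"))
  out2 <- pharmaco_link(rec2, drugs)
  expect_identical(unname(out2$counts["sex_biased", "drugs"]), 3L)
  expect_identical(unname(out2$counts["sex_biased", "variants"]), 1L)
  # ADR subset restricts the second relative risk
  adr <- data.frame(drug = "d3")
  out3 <- pharmaco_link(records, drugs, adr_table = adr)
  expect_true(out3$rr_adr$corrected)  # no sex-biased variant linked to d3
  expect_error(pharmaco_link(records, drugs[0, ]), "empty")

  # with no sex-biased genes in the table, RR uses continuity correction
  drugs_miss <- data.frame(gene_id = "gZ", drug = "d9")
  out4 <- pharmaco_link(records, drugs_miss)
  expect_true(out4$rr$corrected)
})

test_that("synthetic 2x enrichment of sex-biased genes yields RR above 1", {
  set.seed(6)
  n <- 400
  biased <- rep(c(TRUE, FALSE), each = n / 2)
  in_db <- ifelse(biased, runif(n) < 0.5, runif(n) < 0.25)
  records <- data.frame(
    variant_id = sprintf("v%03d", 1:n),
    gene_id = sprintf("g%03d", 1:n),
    female_post = ifelse(biased, 0.8, 0.5),
    male_post = ifelse(biased, 0.1, 0.45))
  records$category <- classify_sex_bias(records$female_post,
                                        records$male_post)
  drugs <- data.frame(gene_id = records$gene_id[in_db], drug = "dX")
  out <- pharmaco_link(records, drugs)
  expect_gt(out$rr$rr, 1)
  expect_gt(out$rr$ci_low, 1)
})

test_that("TF regulatory scores are normalized across TFs per gene", {
  disruption <- matrix(c(2, 1), 2, 1,
                       dimnames = list(c("TFa", "TFb"), "v1"))
  post <- data.frame(variant_id = "v1", gene_id = "gA", post = 0.5)
  sc <- tf_regulatory_score(disruption, post)
  expect_equal(sc$score, c(2 / 3, 1 / 3))
  # a single TF and variant normalizes to exactly one
  sc1 <- tf_regulatory_score(disruption["TFa", , drop = FALSE], post)
  expect_equal(sc1$score, 1)
  # random instances: per-gene scores sum to 1, matching a brute-force loop
  set.seed(7)
  d2 <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(sprintf("TF%d", 1:5), sprintf("v%d", 1:8)))
  p2 <- data.frame(variant_id = rep(sprintf("v%d", 1:8), 2),
                   gene_id = rep(c("gA", "gB"), each = 8),
                   post = runif(16, -1, 1))
  sc2 <- tf_regulatory_score(d2, p2)
  for (g in c("gA", "gB")) {
    sub <- sc2[sc2$gene_id == g, ]
    expect_equal(sum(sub$score), 1, tolerance = 1e-12)
    pv <- p2[p2$gene_id == g, ]
    brute <- sapply(rownames(d2), function(tf) {
      sum(sapply(seq_len(nrow(pv)), function(i) {
        d2[tf, pv$variant_id[i]] * pv$post[i]
      }))
    })
    expect_equal(sub$score, unname(brute / sum(brute)), tolerance = 1e-12)
  }
  # zero denominator is flagged
  d0 <- matrix(0, 1, 1, dimnames = list("TFa", "v1"))
  sc0 <- tf_regulatory_score(d0, post)
  expect_true(sc0$flagged)
  expect_true(is.na(sc0$score))
})

test_that("sex differences in TF scores rank a planted TF first", {
  # identical posteriors in both sexes: all differences zero
  set.seed(8)
  d <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(sprintf("TF%d", 1:4), sprintf("v%d", 1:6)))
  p <- data.frame(variant_id = sprintf("v%d", 1:6),
                  gene_id = rep(c("gA", "gB"), 3), post = runif(6))
  sf <- tf_regulatory_score(d, p)
  diff0 <- sex_tf_difference(sf, sf)
  expect_true(all(abs(diff0$difference) < 1e-12))

  # planted female-specific elevation: each gene carries one variant whose
  # female posterior is high and which disrupts TF03's motif strongly,
  # plus background variants with sex-shared posteriors; the normalized
  # score then tilts toward TF03 in females only
  set.seed(9)
  n_tf <- 10; n_gene <- 8; v_per_gene <- 3
  vids <- sprintf("v%02d", seq_len(n_gene * v_per_gene))
  gids <- rep(sprintf("g%02d", seq_len(n_gene)), each = v_per_gene)
  causal <- rep(c(TRUE, FALSE, FALSE), n_gene)
  disr <- matrix(rnorm(n_tf * length(vids)), n_tf, length(vids),
                 dimnames = list(sprintf("TF%02d", seq_len(n_tf)), vids))
  disr["TF03", causal] <- disr["TF03", causal] + 4
  pf <- data.frame(variant_id = vids, gene_id = gids,
                   post = ifelse(causal, 0.9, 0.1))
  pm <- data.frame(variant_id = vids, gene_id = gids, post = 0.1)
  sf2 <- tf_regulatory_score(disr, pf)
  sm2 <- tf_regulatory_score(disr, pm)
  dd <- sex_tf_difference(sf2, sm2)
  expect_identical(dd$tf_id[which.max(abs(dd$difference))], "TF03")
  expect_gt(dd$difference[dd$tf_id == "TF03"], 0)

  # permuted-difference retention keeps only dominant observed signals
  perm <- matrix(rnorm(nrow(dd) * 4, sd = 1e-3), nrow(dd), 4,
                 dimnames = list(dd$tf_id, NULL))
  dd2 <- sex_tf_difference(sf2, sm2, perm_diffs = perm)
  expect_true(dd2$retained[dd2$tf_id == "TF03"])
  expect_error(sex_tf_difference(sf2, sm2[0, ]), "share no")
})
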