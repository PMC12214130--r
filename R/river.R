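#' Build model instances from outlier signal and annotations
#'
#' One instance per (gene, individual) pair with a qualifying rare variant
#' nearby: the G layer is the gene-level annotation vector, the E layer is
#' the median Z across the individual's tissues binarized at the two-sided
#' normal `p_threshold` (`|Z| > 1.96` at 0.05), restricted by mode to one
#' direction (`over`: `Z > q`, `under`: `Z < -q`). Genes without any
#' individual at `|median Z| > z_filter` are removed. Instances belonging
#' to N2 pairs are flagged `is_n2_heldout` for exclusion from training.
#'
#' @param median_z Gene x individual matrix of median Z scores.
#' @param annotation_layer Output of [build_annotation_layer()].
#' @param mode `"over"` or `"under"`.
#' @param p_threshold Two-sided normal p value for E binarization.
#' @param z_filter Gene filter: keep genes with at least one
#'   `|median Z| > z_filter` individual (default 2).
#' @param n2_pairs Optional N2 pair table (`gene_id`, `individual_1`,
#'   `individual_2`).
#' @return List with `g` (matrix), `e` (0/1), `median_z`, `gene_id`,
#'   `individual_id`, `is_n2_heldout`, `mode`.
#' @export
prepare_instances <- function(median_z, annotation_layer,
                              mode = c("over", "under"),
                              p_threshold = 0.05, z_filter = 2,
                              n2_pairs = NULL) {
  mode <- match.arg(mode)
  keep_genes <- rownames(median_z)[
    apply(abs(median_z) > z_filter, 1, any, na.rm = TRUE)]
  if (length(keep_genes) == 0) {
    stop("all genes filtered out: none has an individual with |median Z| > ",
         z_filter)
  }
  al <- annotation_layer[annotation_layer$gene_id %in% keep_genes, ,
                         drop = FALSE]
  mz <- median_z[cbind(al$gene_id, al$individual_id)]
  ok <- !is.na(mz)
  al <- al[ok, , drop = FALSE]
  mz <- mz[ok]
  zcut <- stats::qnorm(1 - p_threshold / 2)
  e <- if (mode == "over") as.integer(mz > zcut) else as.integer(mz < -zcut)
  g <- as.matrix(al[, setdiff(colnames(al), c("gene_id", "individual_id")),
                    drop = FALSE])
  held <- rep(FALSE, nrow(al))
  if (!is.null(n2_pairs) && nrow(n2_pairs) > 0) {
    hk <- c(paste(n2_pairs$gene_id, n2_pairs$individual_1),
            paste(n2_pairs$gene_id, n2_pairs$individual_2))
    held <- paste(al$gene_id, al$individual_id) %in% hk
  }
  list(g = g, e = e, median_z = mz, gene_id = al$gene_id,
       individual_id = al$individual_id, is_n2_heldout = held, mode = mode)
}

## L2-penalized logistic regression by Newton-Raphson with fractional
## responses w in [0,1]; the intercept is unpenalized.
penalized_logistic <- function(x, w, lambda, beta0 = NULL,
                               tol = 1e-9, max_iter = 50) {
  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- beta0 %||% numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(xd, w - mu)) - pen %*% beta
    wt <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(xd * wt, xd) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit the hierarchical annotation-outlier model by EM
#'
#' The model posits a latent functional status `Z` per (gene, individual)
#' instance with prior `P(Z = 1 | G) = logistic(beta . G)` and emission
#' `P(E | Z) = theta`, a 2x2 row-stochastic table. The E-step computes
#' `P(Z | G, E)`; the M-step refits an L2-penalized weighted logistic
#' regression for `beta` and re-estimates `theta` from expected counts
#' (with a 0.5 pseudocount). Iteration stops when the penalized
#' log-likelihood gain falls below `tol`.
#'
#' `beta` is initialized from a plain penalized logistic fit of E on G;
#' `theta` starts at the informative table `rbind(c(0.99, 0.01),
#' c(0.7, 0.3))` (rows: Z = 0, 1; columns: E = 0, 1).
#'
#' @param instances Output of [prepare_instances()] (held-out N2 instances
#'   are excluded automatically).
#' @param l2_lambda L2 penalty on the annotation weights (default 1,
#'   selected by held-out likelihood on synthetic instance sets).
#' @param tol Convergence tolerance on the penalized log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param theta_init 2x2 starting emission table.
#' @param theta_fixed Keep `theta` at its initial value (useful for
#'   degenerate-case checks).
#' @return A `river_params` list: `beta` (with intercept), `theta`,
#'   `l2_lambda`, `converged`, `loglik_trace`.
#' @export
train_em <- function(instances, l2_lambda = 1, tol = 1e-6,
                     max_iter = 100,
                     theta_init = rbind(c(0.99, 0.01), c(0.7, 0.3)),
                     theta_fixed = FALSE) {
  use <- !instances$is_n2_heldout
  g <- instances$g[use, , drop = FALSE]
  e <- instances$e[use]
  if (length(unique(e)) < 2) {
    stop("both outlier classes must be present in the E layer")
  }
  theta <- theta_init
  if (any(abs(rowSums(theta) - 1) > 1e-8)) stop("theta rows must sum to 1")
  beta <- penalized_logistic(g, e, l2_lambda)
  xd <- cbind(1, g)
  loglik <- function(beta, theta) {
    prior <- stats::plogis(drop(xd %*% beta))
    lik <- prior * theta[2, e + 1] + (1 - prior) * theta[1, e + 1]
    sum(log(pmax(lik, 1e-300))) - l2_lambda / 2 * sum(beta[-1]^2)
  }
  trace <- loglik(beta, theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## E-step
    prior <- stats::plogis(drop(xd %*% beta))
    num <- prior * theta[2, e + 1]
    den <- num + (1 - prior) * theta[1, e + 1]
    r <- num / pmax(den, 1e-300)
    ## M-step
    beta <- penalized_logistic(g, r, l2_lambda, beta0 = beta)
    if (!theta_fixed) {
      c11 <- sum(r * e) + 0.5
      c10 <- sum(r * (1 - e)) + 0.5
      c01 <- sum((1 - r) * e) + 0.5
      c00 <- sum((1 - r) * (1 - e)) + 0.5
      theta <- rbind(c(c00, c01) / (c00 + c01),
                     c(c10, c11) / (c10 + c11))
    }
    ll <- loglik(beta, theta)
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1] < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  structure(list(beta = beta, theta = theta, l2_lambda = l2_lambda,
                 converged = converged, loglik_trace = trace),
            class = "river_params")
}

#' Posterior probability of functional status
#'
#' `P(Z = 1 | G, E)` by Bayes' rule from the fitted prior and emission
#' table; the signed score multiplies the posterior by the sign of the
#' instance's median Z.
#'
#' @param instances Output of [prepare_instances()].
#' @param params A `river_params` fit.
#' @param e_override Optional 0/1 vector replacing the instances' own E
#'   (used for N2-pair prediction).
#' @return Data frame `gene_id`, `individual_id`, `prior`, `posterior`,
#'   `signed_score`.
#' @export
posterior <- function(instances, params, e_override = NULL) {
  xd <- cbind(1, instances$g)
  prior <- stats::plogis(drop(xd %*% params$beta))
  e <- e_override %||% instances$e
  num <- prior * params$theta[2, e + 1]
  den <- num + (1 - prior) * params$theta[1, e + 1]
  post <- num / pmax(den, 1e-300)
  data.frame(gene_id = instances$gene_id,
             individual_id = instances$individual_id,
             prior = prior, posterior = post,
             signed_score = post * sign(instances$median_z),
             stringsAsFactors = FALSE)
}

#' Evaluate the model on held-out N2 pairs
#'
#' For each held-out pair, the second member's binary outlier status is
#' predicted from the full posterior computed with the first member's E
#' (both orderings are used), and from the annotation-only prior. Both are
#' summarized as the area under the precision-recall curve.
#'
#' @param params A `river_params` fit.
#' @param instances Output of [prepare_instances()].
#' @param n2_pairs N2 pair table.
#' @return List with `auprc_full`, `auprc_g_only`, `n_pairs`,
#'   `prevalence`.
#' @export
evaluate_n2 <- function(params, instances, n2_pairs) {
  key <- paste(instances$gene_id, instances$individual_id)
  i1 <- match(paste(n2_pairs$gene_id, n2_pairs$individual_1), key)
  i2 <- match(paste(n2_pairs$gene_id, n2_pairs$individual_2), key)
  ok <- !is.na(i1) & !is.na(i2)
  i1 <- i1[ok]; i2 <- i2[ok]
  pred_idx <- c(i2, i1)    # member predicted
  obs_idx <- c(i1, i2)     # member providing E
  labels <- instances$e[pred_idx]
  if (sum(labels) == 0) stop("no positive labels among held-out N2 pairs")
  sub <- list(g = instances$g[pred_idx, , drop = FALSE],
              e = instances$e[pred_idx],
              median_z = instances$median_z[pred_idx],
              gene_id = instances$gene_id[pred_idx],
              individual_id = instances$individual_id[pred_idx])
  full <- posterior(sub, params, e_override = instances$e[obs_idx])
  list(auprc_full = auprc(full$posterior, labels),
       auprc_g_only = auprc(full$prior, labels),
       n_pairs = length(i1),
       prevalence = mean(labels))
}

#' Area under the precision-recall curve
#'
#' Trapezoidal interpolation over the precision-recall points obtained by
#' sweeping the score threshold (ties handled as a block).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  ## collapse tied scores to one operating point
  last <- !duplicated(sc, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels)
  prec <- c(prec[1], prec)
  rec <- c(0, rec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Per-variant, per-sex median signed posteriors
#'
#' For each variant carried by at least one female and one male with a
#' scored instance on the same gene, the median signed score within each
#' sex's carriers.
#'
#' @param scores Data frame from [posterior()] with `signed_score`.
#' @param metadata Sample metadata (`individual_id`, `sex`).
#' @param variants Variant table (`variant_id`, `carriers` list-column).
#' @param gene_map Data frame `variant_id`, `gene_id` linking variants to
#'   the genes they are scored against (e.g. window membership).
#' @return Data frame `variant_id`, `gene_id`, `female_post`, `male_post`,
#'   `n_female`, `n_male`.
#' @export
sex_stratified_posteriors <- function(scores, metadata, variants, gene_map) {
  sex_of <- stats::setNames(metadata$sex, metadata$individual_id)
  skey <- paste(scores$gene_id, scores$individual_id)
  rows <- list()
  for (i in seq_len(nrow(gene_map))) {
    vid <- gene_map$variant_id[i]
    gid <- gene_map$gene_id[i]
    carriers <- variants$carriers[[match(vid, variants$variant_id)]]
    idx <- match(paste(gid, carriers), skey)
    hit <- !is.na(idx)
    if (!any(hit)) next
    cs <- sex_of[carriers[hit]]
    sc <- scores$signed_score[idx[hit]]
    nf <- sum(cs == "female"); nm <- sum(cs == "male")
    if (nf == 0 || nm == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = vid, gene_id = gid,
      female_post = stats::median(sc[cs == "female"]),
      male_post = stats::median(sc[cs == "male"]),
      n_female = nf, n_male = nm, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(variant_id = character(), gene_id = character(),
                      female_post = numeric(), male_post = numeric(),
                      n_female = integer(), n_male = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
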