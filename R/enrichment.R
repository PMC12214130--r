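#' Relative risk of carrying a qualifying variant, outliers vs non-outliers
#'
#' Computes the ratio of proportions
#' `rr = (a / (a + b)) / (c / (c + d))` for a 2x2 table with `a` outliers
#' carrying a qualifying variant, `b` outliers without one, and `c`/`d` the
#' same split among non-outliers. The 95% confidence interval is Wald on
#' the log relative risk with `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`;
#' the p value is a two-sided Fisher exact test on the raw counts. When a
#' numerator cell (`a` or `c`) is zero, a 0.5 continuity correction is
#' applied to all four cells for the point estimate and CI (the Fisher p
#' still uses raw counts) and the result is flagged `corrected = TRUE`.
#'
#' @param a,b,c,d Nonnegative integer counts: outliers with / without a
#'   variant, non-outliers with / without.
#' @return A one-row `data.frame` with columns `rr`, `ci_low`, `ci_high`,
#'   `p`, `corrected`, and the four counts.
#' @export
relative_risk <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (a + b == 0 || c + d == 0) {
    stop("both the outlier and non-outlier margins must be nonzero")
  }
  corrected <- (a == 0 || c == 0)
  cc <- if (corrected) 0.5 else 0
  a2 <- a + cc; b2 <- b + cc; c2 <- c + cc; d2 <- d + cc
  rr <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  ci_low <- exp(log(rr) - stats::qnorm(0.975) * se)
  ci_high <- exp(log(rr) + stats::qnorm(0.975) * se)
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  data.frame(rr = rr, ci_low = ci_low, ci_high = ci_high, p = p,
             corrected = corrected, a = a, b = b, c = c, d = d)
}

#' Rare-variant enrichment of outliers across MAF bins
#'
#' For each stratification group, MAF bin and outlier direction, builds the
#' 2x2 table of outlier status against presence of a qualifying nearby
#' variant over the tested gene-by-individual universe, and computes the
#' relative risk, Wald CI and Fisher p. Non-outliers are all tested pairs
#' in the group that were not called. Benjamini-Hochberg adjustment is
#' applied across bins within each (group, direction) stratum.
#'
#' @param calls Outlier calls as returned by [multi_tissue_outliers()]
#'   (columns `gene_id`, `individual_id`, `group_id`, `direction`).
#' @param pairs Gene-individual variant pairs from [collapse_to_gene()]
#'   (columns `gene_id`, `individual_id`, `maf`).
#' @param universe Data frame of all tested pairs (columns `gene_id`,
#'   `individual_id`); outliers must be a subset of it.
#' @param bin_edges Upper edges of the cumulative MAF bins.
#' @param group_id Label attached to the results.
#' @param directions Outlier direction strata to evaluate.
#' @return A `data.frame` with one row per (direction, bin).
#' @export
outlier_variant_enrichment <- function(calls, pairs, universe,
                                       bin_edges = c(1e-4, 1e-3, 0.01, 0.05, 0.1),
                                       group_id = "combined_all",
                                       directions = c("all", "over", "under")) {
  if (nrow(universe) == 0) stop("empty gene-individual universe")
  ukey <- paste(universe$gene_id, universe$individual_id)
  pkey <- paste(pairs$gene_id, pairs$individual_id)
  res <- list()
  for (dir in directions) {
    use <- if (dir == "all") calls else calls[calls$direction == dir, , drop = FALSE]
    okey <- paste(use$gene_id, use$individual_id)
    is_out <- ukey %in% okey
    for (edge in sort(bin_edges)) {
      in_bin <- pkey[pairs$maf <= edge]
      has_var <- ukey %in% in_bin
      a <- sum(is_out & has_var)
      b <- sum(is_out & !has_var)
      c_ <- sum(!is_out & has_var)
      d_ <- sum(!is_out & !has_var)
      if (a + b == 0) next  # no outliers in this direction
      row <- relative_risk(a, b, c_, d_)
      row$maf_bin <- paste0("0-", format(edge, scientific = FALSE))
      row$direction <- dir
      row$group_id <- group_id
      res[[length(res) + 1]] <- row
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable strata (no outlier calls)")
  out$p_adj <- NA_real_
  for (dir in unique(out$direction)) {
    idx <- out$direction == dir
    out$p_adj[idx] <- bh_adjust(out$p[idx])
  }
  rownames(out) <- NULL
  out
}

#' Per-category Fisher enrichment between two variant sets
#'
#' For each annotation category, tabulates how many variants in each of two
#' disjoint sets carry the category and tests the 2x2 with Fisher's exact
#' test; a variant carrying several categories contributes once to each.
#' Categories absent from both sets are skipped (with a message).
#'
#' @param set_a,set_b Data frames with columns `variant_id` and
#'   `categories` (list-column of character vectors, or comma-separated
#'   strings).
#' @param categories Optional character vector restricting which categories
#'   are tested (default: all observed).
#' @return Data frame with `category`, counts, `odds_ratio`, `p`, `p_adj`.
#' @export
annotation_enrichment <- function(set_a, set_b, categories = NULL) {
  cats_of <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else strsplit(as.character(x), ",", fixed = TRUE)
  }
  ca <- cats_of(set_a$categories)
  cb <- cats_of(set_b$categories)
  if (length(intersect(set_a$variant_id, set_b$variant_id)) > 0) {
    stop("variant sets must be disjoint")
  }
  all_cats <- categories %||% sort(unique(c(unlist(ca), unlist(cb))))
  res <- list()
  for (cat in all_cats) {
    a_with <- sum(vapply(ca, function(v) cat %in% v, logical(1)))
    b_with <- sum(vapply(cb, function(v) cat %in% v, logical(1)))
    if (a_with + b_with == 0) {
      message("category absent from both sets, skipped: ", cat)
      next
    }
    tab <- matrix(c(a_with, length(ca) - a_with,
                    b_with, length(cb) - b_with), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    res[[length(res) + 1]] <- data.frame(
      category = cat, a_with = a_with, a_without = length(ca) - a_with,
      b_with = b_with, b_without = length(cb) - b_with,
      odds_ratio = unname(ft$estimate), p = ft$p.value
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no categories to test")
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing `|A intersect B|` or more elements of `A` when
#' sampling `|B|` elements from the universe without replacement.
#'
#' @param set_a,set_b Character vectors of element ids.
#' @param universe Character vector containing both sets.
#' @return The upper-tail p value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment; `NaN`/`NA` inputs are propagated and excluded
#' from the ranking.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
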