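#' Load variants from a VCF, removing blacklisted regions
#'
#' Reads a VCF 4.2 file (INFO fields `MAF`, `CADD`, `CATS`; carriers taken
#' from genotype columns with any non-reference allele) and removes
#' variants falling in intervals of a BED blacklist. Intervals are
#' half-open: a variant at position `p` is removed when
#' `start <= p < end`.
#'
#' @param vcf_path Path to the VCF file.
#' @param blacklist_bed Optional path to a BED file of excluded intervals.
#' @return Variant table (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `deleteriousness`, `categories`, `carriers` list-columns).
#' @export
load_variants <- function(vcf_path, blacklist_bed = NULL) {
  validate_vcf_lines(vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      maf = numeric(), deleteriousness = numeric(),
                      categories = I(list()), carriers = I(list()),
                      causal = logical(), stringsAsFactors = FALSE))
  }
  info_field <- function(field) {
    unname(vcfR::extract.info(vcf, element = field))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  carriers <- lapply(seq_len(nrow(fix)), function(i) {
    g <- gt[i, ]
    names(g)[!is.na(g) & grepl("[1-9]", g)]
  })
  out <- data.frame(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    maf = as.numeric(info_field("MAF")),
    deleteriousness = as.numeric(info_field("CADD")),
    categories = I(strsplit(info_field("CATS"), "|", fixed = TRUE)),
    carriers = I(carriers),
    causal = grepl("(^|;)CAUSAL($|;)", fix$INFO),
    stringsAsFactors = FALSE
  )
  if (!is.null(blacklist_bed)) {
    bl <- read_bed(blacklist_bed)
    if (nrow(bl) > 0) {
      vr <- GenomicRanges::GRanges(out$chrom,
                                   IRanges::IRanges(out$pos, out$pos))
      br <- GenomicRanges::GRanges(bl$chrom,
                                   IRanges::IRanges(bl$start, bl$end - 1))
      hit <- GenomicRanges::countOverlaps(vr, br) > 0
      out <- out[!hit, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

## Light structural validation so malformed lines are reported by number.
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      stop("malformed VCF line ", i, ": expected at least 8 fields, found ", nf)
    }
  }
  invisible(TRUE)
}

## BED reader (0-based half-open); columns chrom, start, end[, name]
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name")[1:4],
                           fill = TRUE)
  bed[, 1:min(4, ncol(bed)), drop = FALSE]
}

#' Collapse variants to the rarest qualifier per gene and individual
#'
#' For each gene and carrier individual, keeps the minimum-MAF variant
#' among the individual's carried variants that lie within
#' `[start - window_bp, end + window_bp]` (closed, 1-based) of the gene on
#' the same chromosome and have deleteriousness at or above
#' `cadd_threshold`. MAF ties are broken by smaller distance to the gene
#' body, then by smaller position.
#'
#' @param variants Variant table (see [load_variants()]).
#' @param gene_models Data frame `gene_id`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @param window_bp Window around the gene body (default 5000).
#' @param cadd_threshold Minimum deleteriousness (default 0).
#' @param maf_max Optional MAF cap (e.g. 0.01 to restrict to rare
#'   variants); `NULL` for no cap.
#' @return Data frame `gene_id`, `individual_id`, `variant_id`, `maf`,
#'   `deleteriousness`, `distance`.
#' @export
collapse_to_gene <- function(variants, gene_models, window_bp = 5000,
                             cadd_threshold = 0, maf_max = NULL) {
  v <- variants[variants$deleteriousness >= cadd_threshold, , drop = FALSE]
  if (!is.null(maf_max)) v <- v[v$maf <= maf_max, , drop = FALSE]
  if (nrow(v) == 0 || nrow(gene_models) == 0) {
    return(data.frame(gene_id = character(), individual_id = character(),
                      variant_id = character(), maf = numeric(),
                      deleteriousness = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  vr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start - window_bp,
                     gene_models$end + window_bp))
  ov <- GenomicRanges::findOverlaps(vr, gr)
  if (length(ov) == 0) {
    return(data.frame(gene_id = character(), individual_id = character(),
                      variant_id = character(), maf = numeric(),
                      deleteriousness = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  vi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  dist <- pmax(gene_models$start[gi] - v$pos[vi],
               v$pos[vi] - gene_models$end[gi], 0)
  expanded <- data.table::data.table(
    gene_id = gene_models$gene_id[gi],
    variant_id = v$variant_id[vi],
    maf = v$maf[vi],
    deleteriousness = v$deleteriousness[vi],
    pos = v$pos[vi],
    distance = dist,
    carriers = v$carriers[vi]
  )
  expanded <- expanded[, list(individual_id = unlist(carriers)),
                       by = c("gene_id", "variant_id", "maf",
                              "deleteriousness", "pos", "distance")]
  data.table::setorder(expanded, gene_id, individual_id, maf, distance, pos)
  best <- expanded[, utils::head(.SD, 1), by = c("gene_id", "individual_id")]
  out <- as.data.frame(best[, c("gene_id", "individual_id", "variant_id",
                                "maf", "deleteriousness", "distance")])
  out[order(out$gene_id, out$individual_id), , drop = FALSE]
}

#' Assign MAF bins
#'
#' Returns, for each MAF, the cumulative bins (`(0, edge]`, right-closed)
#' containing it and its disjoint interval bin (`(prev_edge, edge]`). A
#' value belongs to every cumulative bin whose edge is at or above it.
#'
#' @param maf Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param bin_edges Sorted upper bin edges (defaults to the conventional
#'   0.0001 / 0.001 / 0.01 / 0.05 / 0.1 grid).
#' @return List with `cumulative` (list of character vectors) and
#'   `interval` (character vector; `NA` when above the last edge).
#' @export
maf_bin <- function(maf, bin_edges = c(1e-4, 1e-3, 0.01, 0.05, 0.1)) {
  if (any(maf < 0 | maf > 0.5)) stop("MAF outside [0, 0.5]")
  edges <- sort(bin_edges)
  fmt <- function(x) {
    vapply(x, function(e) format(e, scientific = FALSE, trim = TRUE,
                                 drop0trailing = TRUE), character(1))
  }
  cum_labels <- paste0("0-", fmt(edges))
  int_labels <- paste0(fmt(c(0, edges[-length(edges)])), "-", fmt(edges))
  cumulative <- lapply(maf, function(m) cum_labels[m <= edges])
  interval <- vapply(maf, function(m) {
    i <- which(m <= edges)[1]
    if (is.na(i)) NA_character_ else int_labels[i]
  }, character(1))
  list(cumulative = cumulative, interval = interval)
}

#' Gene-level genomic annotation layer
#'
#' Summarizes the per-variant annotation vectors over all rare variants
#' (MAF below `maf_max`) carried by an individual within `window_bp` of a
#' gene, by element-wise maximum (default), sum or mean. Pairs with no
#' qualifying variant are omitted (their feature vector is the zero
#' vector).
#'
#' @param variants Variant table with `carriers` list-column.
#' @param gene_models Gene model table.
#' @param annotations Variant x feature matrix (rownames = variant ids).
#' @param window_bp Window around the gene body (default 10000).
#' @param maf_max Rare-variant MAF cutoff (default 0.01).
#' @param agg Aggregator: `"max"`, `"sum"` or `"mean"`.
#' @return Data frame with `gene_id`, `individual_id` and one column per
#'   annotation feature.
#' @export
build_annotation_layer <- function(variants, gene_models, annotations,
                                   window_bp = 10000, maf_max = 0.01,
                                   agg = c("max", "sum", "mean")) {
  agg <- match.arg(agg)
  rare <- variants[variants$maf < maf_max, , drop = FALSE]
  pairs <- collapse_pairs_all(rare, gene_models, window_bp)
  if (nrow(pairs) == 0) {
    out <- data.frame(gene_id = character(), individual_id = character())
    for (cn in colnames(annotations)) out[[cn]] <- numeric()
    return(out)
  }
  aggfun <- switch(agg, max = function(m) apply(m, 2, max),
                   sum = colSums, mean = colMeans)
  dt <- data.table::as.data.table(pairs)
  res <- dt[, {
    m <- annotations[variant_id, , drop = FALSE]
    as.list(aggfun(m))
  }, by = c("gene_id", "individual_id")]
  out <- as.data.frame(res)
  out[order(out$gene_id, out$individual_id), , drop = FALSE]
}

## all (gene, individual, variant) triples within the window (no collapse)
collapse_pairs_all <- function(variants, gene_models, window_bp) {
  if (nrow(variants) == 0) {
    return(data.frame(gene_id = character(), individual_id = character(),
                      variant_id = character(), stringsAsFactors = FALSE))
  }
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start - window_bp,
                     gene_models$end + window_bp))
  ov <- GenomicRanges::findOverlaps(vr, gr)
  vi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  if (length(vi) == 0) {
    return(data.frame(gene_id = character(), individual_id = character(),
                      variant_id = character(), stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(gene_id = gene_models$gene_id[gi],
                               variant_id = variants$variant_id[vi],
                               carriers = variants$carriers[vi])
  as.data.frame(dt[, list(individual_id = unlist(carriers)),
                   by = c("gene_id", "variant_id")])
}
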