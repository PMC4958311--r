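# Gene-level amplification/deletion calls from human segmented copy number
# and basal-like enrichment testing across species.

#' Call per-gene copy-number states from segmentation
#'
#' For each gene and each sample, the segment with maximal overlap of the
#' gene's span defines the gene's log2 value (ties broken toward the
#' lower-coordinate segment); the value is thresholded at `tau` (default
#' 0.3): strictly greater than `tau` is `amplified`, strictly less than
#' `-tau` is `deleted`, otherwise `neutral`.  Gene-sample cells covered by no
#' segment are `neutral` and counted in the `n_uncovered` attribute.
#'
#' @param seg Segment table ([read_seg()]).
#' @param gene_models Human gene models (gene, chrom, start, end).
#' @param samples Optional sample set (default: samples present in `seg`).
#' @param tau Log2 threshold (default 0.3, strict on both sides).
#' @return Character gene x sample matrix with values amplified / neutral /
#'   deleted.
#' @export
call_gene_states <- function(seg, gene_models, samples = NULL, tau = 0.3) {
  if (is.null(samples)) samples <- sort(unique(seg$sample))
  genes_gr <- as_granges0(gene_models$chrom, gene_models$start,
                          gene_models$end)
  states <- matrix("neutral", nrow(gene_models), length(samples),
                   dimnames = list(gene_models$gene, samples))
  uncovered <- 0L
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    seg_gr <- as_granges0(ss$chrom, ss$start, ss$end)
    hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(genes_gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(seg_gr)[S4Vectors::subjectHits(hits)]))
    best <- tapply(seq_along(ov), S4Vectors::queryHits(hits), function(k) {
      k[order(-ov[k], S4Vectors::subjectHits(hits)[k])][1]
    })
    gi <- as.integer(names(best))
    val <- ss$seg_mean[S4Vectors::subjectHits(hits)[unlist(best)]]
    uncovered <- uncovered + nrow(gene_models) - length(gi)
    states[gi, s] <- ifelse(val > tau, "amplified",
                            ifelse(val < -tau, "deleted", "neutral"))
  }
  if (uncovered > 0) {
    message("call_gene_states: ", uncovered,
            " gene-sample cell(s) covered by no segment; set neutral")
  }
  attr(states, "n_uncovered") <- uncovered
  states
}

#' Basal-like enrichment of copy-number events
#'
#' For each gene, tests whether the event of the stated direction
#' (`amplified` for murine gains, `deleted` for murine losses) is enriched in
#' human basal-like versus non-basal samples with a two-sided Fisher's exact
#' test.  A gene is flagged conserved when p < `alpha` and the basal-like
#' affected rate exceeds the non-basal rate.
#'
#' @param states Gene x sample state matrix ([call_gene_states()]).
#' @param labels Human labels: values `basal-like` vs anything else
#'   (non-basal).
#' @param direction Per-gene direction: named character vector or a single
#'   value recycled over rows (`"amplified"` or `"deleted"`).
#' @param alpha Significance cut (default 0.05).
#' @param basal_class Label value identifying basal-like samples.
#' @return data.frame with gene, direction, pct_basal, pct_nonbasal, p,
#'   conserved.
#' @export
basal_enrichment <- function(states, labels, direction,
                             alpha = 0.05, basal_class = "basal-like") {
  lab <- align_labels(labels, colnames(states))
  basal <- lab == basal_class
  if (!any(basal) || all(basal)) stop("need both basal-like and non-basal samples")
  genes <- rownames(states)
  dir <- if (length(direction) == 1) {
    stats::setNames(rep(direction, length(genes)), genes)
  } else direction
  stopifnot(all(genes %in% names(dir)))
  affected <- states == matrix(dir[genes], nrow(states), ncol(states))
  a <- rowSums(affected[, basal, drop = FALSE])
  b <- rowSums(affected[, !basal, drop = FALSE])
  out <- data.frame(gene = genes, direction = unname(dir[genes]),
                    pct_basal = 100 * a / sum(basal),
                    pct_nonbasal = 100 * b / sum(!basal),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p <- if (nrow(out) > 0) {
    fisher_p2(a, b, sum(basal) - a, sum(!basal) - b)
  } else numeric(0)
  out$conserved <- out$p < alpha & out$pct_basal > out$pct_nonbasal
  out
}

#' Map murine candidate genes to human gene ids
#'
#' Every murine gene maps to zero or more human genes through the homolog
#' map (many-to-many pairs all emitted); murine genes with no mapping are
#' reported in the `unmapped` attribute.
#'
#' @param genes Character vector of murine gene ids.
#' @param homolog_map data.frame (mouse_gene, human_gene).
#' @return data.frame (mouse_gene, human_gene) with attribute `unmapped`.
#' @export
map_murine_candidates <- function(genes, homolog_map) {
  hit <- homolog_map[homolog_map$mouse_gene %in% genes, , drop = FALSE]
  rownames(hit) <- NULL
  attr(hit, "unmapped") <- setdiff(genes, hit$mouse_gene)
  hit
}
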