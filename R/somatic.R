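# Gene-level collapsing of somatic SNVs and structural variants, and
# per-gene subtype enrichment via Fisher's exact test.

#' Collapse somatic mutations to a gene x sample binary matrix
#'
#' An entry is TRUE iff the sample carries at least one non-silent mutation
#' in the gene; all non-silent mutations affecting the same gene are treated
#' equally regardless of the actual change, and silent classes
#' (`SILENT_CLASSES`) are excluded.
#'
#' @param catalog Mutation catalog (see [read_mutations()]).
#' @param samples Character vector fixing the column set (cohort samples);
#'   defaults to the samples present in the catalog.
#' @param gene_models Optional gene models; genes in the catalog but absent
#'   from the models trigger a warning and are retained by symbol.
#' @return Logical gene x sample matrix.
#' @export
collapse_mutations <- function(catalog, samples = NULL, gene_models = NULL) {
  ns <- catalog[catalog$classification %in% NONSILENT_CLASSES, , drop = FALSE]
  collapse_hits(ns$gene, ns$sample, samples, gene_models)
}

collapse_hits <- function(genes, hit_samples, samples, gene_models) {
  if (is.null(samples)) samples <- sort(unique(hit_samples))
  ug <- sort(unique(genes))
  if (!is.null(gene_models)) {
    unknown <- setdiff(ug, gene_models$gene)
    if (length(unknown) > 0) {
      warning("gene(s) absent from gene models, retained by symbol: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  m <- matrix(FALSE, length(ug), length(samples),
              dimnames = list(ug, samples))
  keep <- hit_samples %in% samples
  m[cbind(match(genes[keep], ug), match(hit_samples[keep], samples))] <- TRUE
  m
}

#' Collapse structural variants to a gene x sample binary matrix
#'
#' A gene is marked for a sample iff either SV endpoint falls inside the
#' gene's span `[start, end)` (0-based half-open: an endpoint exactly at
#' `start` is inside, one exactly at `end` is outside).
#'
#' @param catalog SV catalog (see [read_svs()]).
#' @param gene_models Gene models data.frame (gene, chrom, start, end).
#' @param samples Optional character vector fixing the column set.
#' @return Logical gene x sample matrix (rows = genes hit at least once).
#' @export
collapse_svs <- function(catalog, gene_models, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(catalog$sample))
  if (nrow(catalog) == 0) {
    return(matrix(FALSE, 0, length(samples),
                  dimnames = list(character(0), samples)))
  }
  ends <- data.frame(
    sample = rep(catalog$sample, 2),
    chrom = c(catalog$chromA, catalog$chromB),
    pos = c(catalog$posA, catalog$posB),
    stringsAsFactors = FALSE
  )
  genes_gr <- as_granges0(gene_models$chrom, gene_models$start,
                          gene_models$end, names = gene_models$gene)
  pts <- as_granges0(ends$chrom, ends$pos, ends$pos + 1L)
  hits <- GenomicRanges::findOverlaps(pts, genes_gr)
  g <- gene_models$gene[S4Vectors::subjectHits(hits)]
  s <- ends$sample[S4Vectors::queryHits(hits)]
  collapse_hits(g, s, samples, gene_models = NULL)
}

#' Per-gene class enrichment (Fisher's exact test)
#'
#' For each gene, builds the 2x2 table (affected vs not) x (class_x vs all
#' others) and computes a two-sided Fisher's exact p (hypergeometric
#' enumeration of tables with probability at or below the observed one).  No
#' multiple-testing correction is applied; the number of tests performed is
#' recorded in the `n_tests` attribute.
#'
#' @param binary Logical gene x sample matrix ([collapse_mutations()] /
#'   [collapse_svs()]).
#' @param labels Class labels.
#' @param class_x Class of interest.
#' @param alpha Significance cut for the `significant` flag (default 0.05).
#' @return data.frame with gene, affected_in, affected_out, unaffected_in,
#'   unaffected_out, p, significant.
#' @export
class_enrichment <- function(binary, labels, class_x, alpha = 0.05) {
  lab <- align_labels(labels, colnames(binary))
  if (!class_x %in% lab) stop("class ", class_x, " absent from labels")
  in_class <- lab == class_x
  n_in <- sum(in_class)
  n_out <- sum(!in_class)
  a <- rowSums(binary[, in_class, drop = FALSE])
  b <- rowSums(binary[, !in_class, drop = FALSE])
  out <- data.frame(gene = rownames(binary),
                    class_x = class_x,
                    affected_in = a, affected_out = b,
                    unaffected_in = n_in - a, unaffected_out = n_out - b,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p <- if (nrow(out) > 0) {
    fisher_p2(out$affected_in, out$affected_out,
              out$unaffected_in, out$unaffected_out)
  } else numeric(0)
  out$significant <- out$p < alpha
  attr(out, "n_tests") <- nrow(out)
  out[order(out$p), , drop = FALSE]
}

#' Class enrichment restricted to whole-genome profiled samples
#'
#' Repeats [class_enrichment()] on the subset of samples whose assay flag is
#' `"wgs"`, to rule out enrichments that are artifacts of mixed
#' whole-genome/exome profiling; intended to be reported alongside the
#' full-cohort test.
#'
#' @inheritParams class_enrichment
#' @param labels Labels data.frame with an `assay` column (values `wgs` /
#'   `exome`).
#' @return As [class_enrichment()], restricted to wgs samples.
#' @export
wgs_only_enrichment <- function(binary, labels, class_x, alpha = 0.05) {
  assay <- align_assay(labels, colnames(binary))
  keep <- assay == "wgs"
  sub <- binary[, keep, drop = FALSE]
  lab <- align_labels(labels, colnames(binary))[keep]
  if (!class_x %in% lab) {
    stop("class ", class_x, " absent after restriction to wgs samples")
  }
  class_enrichment(sub, stats::setNames(lab, colnames(sub)), class_x, alpha)
}
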