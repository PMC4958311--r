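# Subtype expression signatures, cross-species signature scoring and tumor
# differentiation scores (D-Scores).

#' Build a subtype expression signature
#'
#' Runs a two-class (class x versus all others) SAM analysis at the given
#' target FDR (default 0) and defines the signature as all genes highly
#' expressed in the class of interest, i.e. the `called_up` set.
#'
#' @inheritParams sam_analysis
#' @param ... Passed to [sam_analysis()] (target_fdr, n_permutations, seed,
#'   s0).
#' @return A `gene_signature`: list with `class_x`, `genes`, `sam`
#'   (provenance [sam_analysis()] result).
#' @export
build_signature <- function(matrix, labels, class_x, ...) {
  res <- sam_analysis(matrix, labels, class_x, ...)
  structure(list(class_x = class_x, genes = res$called_up, direction = "up",
                 sam = res),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature:", x$class_x, "-", length(x$genes), "up genes at FDR",
      x$sam$target_fdr, "\n")
  invisible(x)
}

#' Score a signature across a target cohort
#'
#' Each target gene row is standardized (z-score across samples); the score
#' of a sample is the mean of the standardized values of the signature genes
#' mapped into the target matrix.  A homolog map allows a murine signature to
#' be scored in a human cohort: each signature gene's mapped target rows are
#' averaged first (many-to-many resolved by averaging), then the mean over
#' signature genes is taken.  Unmapped genes and zero-variance target rows
#' are dropped with a message/warning.
#'
#' @param signature A `gene_signature` or a plain character vector of gene
#'   ids.
#' @param target_matrix Numeric gene x sample matrix (log2 scale).
#' @param homolog_map Optional data.frame (mouse_gene, human_gene); `NULL`
#'   means the signature ids are in the target namespace already.
#' @return Named numeric vector of per-sample scores.
#' @export
score_signature <- function(signature, target_matrix, homolog_map = NULL) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  sig_name <- if (inherits(signature, "gene_signature")) signature$class_x
              else "signature"
  if (length(genes) == 0) stop("empty signature: ", sig_name)
  sds <- apply(target_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance target row(s) dropped")
    target_matrix <- target_matrix[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (target_matrix - rowMeans(target_matrix)) / sds
  if (is.null(homolog_map)) {
    mapped <- intersect(genes, rownames(z))
    per_gene <- z[mapped, , drop = FALSE]
    n_unmapped <- length(genes) - length(mapped)
  } else {
    hm <- homolog_map[homolog_map$mouse_gene %in% genes &
                        homolog_map$human_gene %in% rownames(z), , drop = FALSE]
    per_gene <- do.call(rbind, lapply(split(hm$human_gene, hm$mouse_gene),
      function(h) colMeans(z[h, , drop = FALSE])))
    n_unmapped <- length(genes) - length(unique(hm$mouse_gene))
  }
  if (is.null(per_gene) || nrow(per_gene) == 0) {
    stop("no gene of signature '", sig_name, "' maps into the target matrix")
  }
  if (n_unmapped > 0) {
    message(n_unmapped, " signature gene(s) not mapped into target; dropped")
  }
  colMeans(per_gene)
}

#' Tumor differentiation scores (D-Scores)
#'
#' Places each tumor on a stem-cell to mature-luminal axis using three
#' centroid expression patterns: adult mammary stem cell (aMaSC), luminal
#' progenitor (LumProg) and mature luminal (MatureLum).  Each sample's
#' Spearman correlation to each centroid is computed over the shared genes,
#' and D-Score = cor(MatureLum) - cor(aMaSC): low = stem-like, high =
#' mature-luminal-like, with luminal progenitors intermediate by
#' construction.  This centroid-correlation difference is a transparent
#' surrogate for the published differentiation-score construction, with the
#' same ordinal semantics.
#'
#' @param matrix Numeric gene x sample matrix.
#' @param centroids Named list with numeric gene-named vectors `aMaSC`,
#'   `LumProg`, `MatureLum`.
#' @return A `dscore_result`: data.frame with sample, cor_amasc, cor_lumprog,
#'   cor_maturelum, d_score.
#' @export
differentiation_score <- function(matrix, centroids) {
  stopifnot(all(c("aMaSC", "LumProg", "MatureLum") %in% names(centroids)))
  cors <- lapply(centroids[c("aMaSC", "LumProg", "MatureLum")], function(cen) {
    shared <- intersect(names(cen), rownames(matrix))
    if (length(shared) < 5) {
      stop("centroid overlaps matrix in only ", length(shared),
           " genes (< 5)")
    }
    apply(matrix[shared, , drop = FALSE], 2, stats::cor, y = cen[shared],
          method = "spearman")
  })
  out <- data.frame(sample = colnames(matrix),
                    cor_amasc = cors$aMaSC,
                    cor_lumprog = cors$LumProg,
                    cor_maturelum = cors$MatureLum,
                    d_score = cors$MatureLum - cors$aMaSC,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dscore_result", "data.frame")
  out
}

#' Pairwise class comparison of D-Scores
#'
#' Two-sided pooled-variance (Student's) two-sample t-test for every pair of
#' classes; p-values are reported unadjusted.  A degenerate pair with zero
#' pooled variance yields t = 0, p = 1 with a warning.
#'
#' @param dscores A `dscore_result` (or data.frame with sample, d_score).
#' @param labels Class labels (named vector or labels data.frame).
#' @return data.frame with class_a, class_b, mean_a, mean_b, t, df, p.
#' @export
compare_dscores <- function(dscores, labels) {
  lab <- align_labels(labels, dscores$sample)
  classes <- sort(unique(lab))
  pairs <- utils::combn(classes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- dscores$d_score[lab == pairs[1, k]]
    b <- dscores$d_score[lab == pairs[2, k]]
    if (length(a) < 2 || length(b) < 2) {
      stop("class pair ", pairs[1, k], "/", pairs[2, k],
           " needs >= 2 samples per class")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      warning("zero pooled variance for ", pairs[1, k], " vs ", pairs[2, k])
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(class_a = pairs[1, k], class_b = pairs[2, k],
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
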