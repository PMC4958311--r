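# Murine aCGH copy-number pipeline: probe filtering, genomic-order ten-probe
# averaging, SAM region calling, median class profiles, gene-level copy
# number and the DNA-RNA cis-correlation filter.

#' Filter aCGH probes on control intensity and presence
#'
#' A probe-sample value is kept only when the spot is present and its
#' control-channel intensity is strictly greater than `min_ctrl` (default
#' 10); a probe is kept only when surviving values cover strictly more than
#' `min_presence` (default 70%) of the samples.  Remaining missing values of
#' surviving probes are imputed with the probe's sample-wise median so that
#' window arithmetic stays defined; imputations are logged.
#'
#' @param pt A `probe_table` (see [read_probes()]).
#' @param min_ctrl Control-channel intensity cut (strict >).
#' @param min_presence Required fraction of samples with data (strict >).
#' @return A `probe_table` with surviving probes and complete ratio values;
#'   the `ctrl`/`present` matrices reflect the surviving values.
#' @export
filter_probes <- function(pt, min_ctrl = 10, min_presence = 0.7) {
  ok <- pt$present & (pt$ctrl > min_ctrl)
  ratio <- pt$ratio
  ratio[!ok] <- NA_real_
  frac <- rowMeans(ok)
  keep <- frac > min_presence
  if (!any(keep)) stop("all probes removed by the control/presence filters")
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("filter_probes: dropped ", n_drop, " probe(s) at <= ",
            round(100 * min_presence), "% presence")
  }
  ratio <- ratio[keep, , drop = FALSE]
  n_imp <- sum(is.na(ratio))
  if (n_imp > 0) {
    med <- apply(ratio, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(ratio), arr.ind = TRUE)
    ratio[idx] <- med[idx[, 1]]
    message("filter_probes: imputed ", n_imp,
            " missing value(s) with probe medians")
  }
  probe_table(info = pt$info[keep, , drop = FALSE], ratio = ratio,
              ctrl = pt$ctrl[keep, , drop = FALSE],
              present = ok[keep, , drop = FALSE])
}

#' Ten-probe windowed average of aCGH ratios
#'
#' Probes are taken in genomic order and grouped into consecutive,
#' non-overlapping windows of exactly `width` probes per chromosome (default
#' 10); each window's ratios are averaged per sample to form one feature.
#' The trailing remainder of fewer than `width` probes on each chromosome is
#' dropped and logged; a chromosome with fewer than `width` probes yields no
#' features (warning).
#'
#' @param pt A filtered `probe_table`.
#' @param width Probes per window (default 10).
#' @return A `feature_matrix`: list with `info` (feature, chrom, start, end,
#'   n_probes; 0-based half-open span of the member probes) and `values`
#'   (feature x sample matrix).
#' @export
ten_probe_average <- function(pt, width = 10L) {
  chroms <- unique(pt$info$chrom)
  info_rows <- list()
  val_rows <- list()
  dropped <- 0L
  for (ch in chroms) {
    ix <- which(pt$info$chrom == ch)
    ix <- ix[order(pt$info$pos[ix])]
    n_win <- length(ix) %/% width
    dropped <- dropped + length(ix) %% width
    if (n_win == 0) {
      warning("chromosome ", ch, " has < ", width, " probes; no features")
      next
    }
    for (w in seq_len(n_win)) {
      rows <- ix[((w - 1L) * width + 1L):(w * width)]
      info_rows[[length(info_rows) + 1L]] <- data.frame(
        feature = paste0(ch, ":w", w), chrom = ch,
        start = min(pt$info$pos[rows]),
        end = max(pt$info$pos[rows]) + 1L,
        n_probes = width, stringsAsFactors = FALSE)
      val_rows[[length(val_rows) + 1L]] <-
        colMeans(pt$ratio[rows, , drop = FALSE])
    }
  }
  if (dropped > 0) {
    message("ten_probe_average: dropped ", dropped,
            " trailing probe(s) in incomplete windows")
  }
  if (length(info_rows) == 0) stop("no chromosome produced any feature")
  info <- do.call(rbind, info_rows)
  values <- do.call(rbind, val_rows)
  dimnames(values) <- list(info$feature, colnames(pt$ratio))
  structure(list(info = info, values = values), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$info), "windowed features x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' Call class-enriched copy-number regions
#'
#' Runs a two-class SAM analysis (class x versus all others) on the windowed
#' features at the given target FDR (default 0); features called up are
#' gains, features called down are losses, and strictly adjacent called
#' features of the same direction on the same chromosome are merged into
#' regions.
#'
#' @param fm A `feature_matrix`.
#' @param labels Class labels.
#' @param class_x Class of interest.
#' @param ... Passed to [sam_analysis()].
#' @return data.frame of regions (class, chrom, start, end, direction,
#'   n_features, features as comma-joined ids) with the `sam_result` attached
#'   as attribute `sam`.
#' @export
call_regions <- function(fm, labels, class_x, ...) {
  res <- sam_analysis(fm$values, labels, class_x, ...)
  regions <- rbind(merge_called(fm, res$called_up, "gain", class_x),
                   merge_called(fm, res$called_down, "loss", class_x))
  attr(regions, "sam") <- res
  regions
}

merge_called <- function(fm, called, direction, class_x) {
  empty <- data.frame(class = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), n_features = integer(0),
                      features = character(0), stringsAsFactors = FALSE)
  if (length(called) == 0) return(empty)
  ix <- sort(match(called, fm$info$feature))
  runs <- split(ix, cumsum(c(1, diff(ix) != 1 |
                               fm$info$chrom[ix][-1] !=
                                 fm$info$chrom[ix][-length(ix)])))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(class = class_x, chrom = fm$info$chrom[r[1]],
               start = min(fm$info$start[r]), end = max(fm$info$end[r]),
               direction = direction, n_features = length(r),
               features = paste(fm$info$feature[r], collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Median class copy-number profile
#'
#' Per-feature median of the windowed log2 ratios within each class, in
#' genomic order (the display behind per-class copy-number landscape plots).
#'
#' @param fm A `feature_matrix`.
#' @param labels Class labels.
#' @return Matrix feature x class of medians, rows in genomic order.
#' @export
median_class_profile <- function(fm, labels) {
  lab <- align_labels(labels, colnames(fm$values))
  classes <- sort(unique(lab))
  out <- vapply(classes, function(cl) {
    apply(fm$values[, lab == cl, drop = FALSE], 1, stats::median)
  }, numeric(nrow(fm$values)))
  dimnames(out) <- list(fm$info$feature, classes)
  out
}

#' Gene-level copy number from windowed features
#'
#' Each gene is assigned the windowed feature with maximal overlap of its
#' span (ties broken toward the lower-coordinate feature); genes overlapping
#' no feature are dropped with a log message.
#'
#' @param fm A `feature_matrix`.
#' @param gene_models Gene models data.frame (gene, chrom, start, end).
#' @return Numeric gene x sample matrix with attribute `feature_of` (named
#'   character: assigned feature per gene).
#' @export
gene_level_cn <- function(fm, gene_models) {
  genes_gr <- as_granges0(gene_models$chrom, gene_models$start,
                          gene_models$end)
  feat_gr <- as_granges0(fm$info$chrom, fm$info$start, fm$info$end)
  hits <- GenomicRanges::findOverlaps(genes_gr, feat_gr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(genes_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(feat_gr)[S4Vectors::subjectHits(hits)]))
  best <- tapply(seq_along(ov), S4Vectors::queryHits(hits), function(k) {
    k[order(-ov[k], S4Vectors::subjectHits(hits)[k])][1]
  })
  gi <- as.integer(names(best))
  fi <- S4Vectors::subjectHits(hits)[unlist(best)]
  n_drop <- nrow(gene_models) - length(gi)
  if (n_drop > 0) {
    message("gene_level_cn: ", n_drop, " gene(s) overlap no feature; dropped")
  }
  m <- fm$values[fi, , drop = FALSE]
  rownames(m) <- gene_models$gene[gi]
  attr(m, "feature_of") <- stats::setNames(fm$info$feature[fi],
                                           gene_models$gene[gi])
  m
}

#' DNA-RNA cis-correlation filter
#'
#' For every gene inside the called regions, computes the Pearson
#' correlation between its gene-level DNA copy number and its expression
#' across the shared samples; genes are retained when the signed correlation
#' is at least `cutoff` (default 0.5), for gain and loss regions alike.
#' Zero-variance genes have undefined r and are excluded with a warning.
#'
#' @param gene_cn Gene x sample copy-number matrix ([gene_level_cn()]).
#' @param expression Gene x sample expression matrix.
#' @param regions Region table from [call_regions()].
#' @param gene_models Gene models (to locate genes inside regions).
#' @param cutoff Signed Pearson cutoff (default 0.5).
#' @return data.frame with gene, class, direction, chrom, r, pass; contains
#'   every in-region gene with a defined r (filtered set = `pass`).
#' @export
dna_rna_correlation <- function(gene_cn, expression, regions, gene_models,
                                cutoff = 0.5) {
  shared <- intersect(colnames(gene_cn), colnames(expression))
  if (length(shared) < 3) stop("need >= 3 shared samples, got ", length(shared))
  empty <- data.frame(gene = character(0), class = character(0),
                      direction = character(0), chrom = character(0),
                      r = numeric(0), pass = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0) return(empty)
  genes_gr <- as_granges0(gene_models$chrom, gene_models$start,
                          gene_models$end)
  reg_gr <- as_granges0(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(genes_gr, reg_gr)
  if (length(hits) == 0) return(empty)
  out <- data.frame(gene = gene_models$gene[S4Vectors::queryHits(hits)],
                    class = regions$class[S4Vectors::subjectHits(hits)],
                    direction = regions$direction[S4Vectors::subjectHits(hits)],
                    chrom = regions$chrom[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- out[out$gene %in% rownames(gene_cn) &
               out$gene %in% rownames(expression), , drop = FALSE]
  cn <- gene_cn[out$gene, shared, drop = FALSE]
  ex <- expression[out$gene, shared, drop = FALSE]
  sd0 <- apply(cn, 1, stats::sd) == 0 | apply(ex, 1, stats::sd) == 0
  if (any(sd0)) {
    warning(sum(sd0), " zero-variance gene(s) excluded from correlation")
    out <- out[!sd0, , drop = FALSE]
    cn <- cn[!sd0, , drop = FALSE]
    ex <- ex[!sd0, , drop = FALSE]
  }
  out$r <- if (nrow(out) > 0) {
    vapply(seq_len(nrow(out)),
           function(i) stats::cor(cn[i, ], ex[i, ]), numeric(1))
  } else numeric(0)
  out$pass <- out$r >= cutoff
  rownames(out) <- NULL
  out
}
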