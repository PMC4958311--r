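# Rank-based GARP-style essentiality scoring of pooled shRNA dropout
# screens, with a permutation null and the >= 5%-of-lines essentiality
# filter.
#
# The score is a deliberately simple surrogate for the published GARP
# pipeline: the mean of a gene's two most-depleted shRNA dropout scores in a
# cell line, compared against random shRNA tuples from the same line.  Only
# the thresholded p < 0.05 essentiality calls feed the driver funnel.

#' GARP-style essentiality score
#'
#' Mean of the two most-depleted (lowest) shRNA dropout scores for the gene
#' in the cell line; a single-shRNA gene scores its one value.  More negative
#' = more essential.
#'
#' @param screen Screen table ([read_screen()]).
#' @param gene Gene id.
#' @param cell_line Cell-line id.
#' @return Scalar score.
#' @export
garp_score <- function(screen, gene, cell_line) {
  x <- screen$dropout_score[screen$gene_id == gene &
                              screen$cell_line == cell_line]
  if (length(x) == 0) {
    stop("gene ", gene, " absent from cell line ", cell_line)
  }
  mean(sort(x)[seq_len(min(2L, length(x)))])
}

#' Permutation p-value for a GARP score
#'
#' The null distribution is the GARP score of random shRNA k-tuples (k = the
#' gene's shRNA count in the line, capped at 2) drawn without replacement
#' within each tuple from the line's full shRNA pool.  The sampled estimator
#' uses a pseudocount, p = (1 + #null <= observed) / (1 + n_draws); with
#' `exact = TRUE` all distinct tuples are enumerated and p is the exact
#' proportion.
#'
#' @inheritParams garp_score
#' @param n_draws Number of null draws (ignored when `exact = TRUE`).
#' @param seed Integer seed.
#' @param exact Enumerate all tuples instead of sampling.
#' @return Scalar p-value in (0, 1].
#' @export
garp_pvalue <- function(screen, cell_line, gene, n_draws = 1000, seed = 1,
                        exact = FALSE) {
  line <- screen[screen$cell_line == cell_line, , drop = FALSE]
  pool <- line$dropout_score
  if (length(pool) < 2) stop("cell line ", cell_line, " has < 2 shRNAs")
  x <- line$dropout_score[line$gene_id == gene]
  if (length(x) == 0) stop("gene ", gene, " absent from cell line ", cell_line)
  k <- min(2L, length(x))
  obs <- mean(sort(x)[seq_len(k)])
  if (exact) {
    null <- if (k == 1) pool else {
      idx <- utils::combn(length(pool), 2)
      (pool[idx[1, ]] + pool[idx[2, ]]) / 2
    }
    return(sum(null <= obs) / length(null))
  }
  null <- with_seed(seed, {
    if (k == 1) {
      pool[sample.int(length(pool), n_draws, replace = TRUE)]
    } else {
      i1 <- sample.int(length(pool), n_draws, replace = TRUE)
      i2 <- sample.int(length(pool) - 1L, n_draws, replace = TRUE)
      i2 <- i2 + (i2 >= i1)
      (pool[i1] + pool[i2]) / 2
    }
  })
  (1 + sum(null <= obs)) / (1 + n_draws)
}

#' Gene essentiality across a screen
#'
#' Computes the GARP-style score and permutation p for each requested gene in
#' every cell line; a gene is essential in a line when p < `alpha`, and the
#' per-gene essential-line fraction is reported.
#'
#' @param screen Screen table.
#' @param genes Genes to evaluate (default: all genes in the screen).
#' @param n_draws Null draws per gene-line.
#' @param seed Integer seed.
#' @param alpha Per-line significance cut (default 0.05).
#' @return An `essentiality_table`: list with `scores` and `p` (gene x line
#'   matrices) and `summary` (data.frame gene, n_essential_lines, n_lines,
#'   fraction).
#' @export
essentiality_table <- function(screen, genes = NULL, n_draws = 1000,
                               seed = 1, alpha = 0.05) {
  if (is.null(genes)) genes <- sort(unique(screen$gene_id))
  lines <- sort(unique(screen$cell_line))
  scores <- p <- matrix(NA_real_, length(genes), length(lines),
                        dimnames = list(genes, lines))
  for (li in seq_along(lines)) {
    line <- screen[screen$cell_line == lines[li], , drop = FALSE]
    pool <- line$dropout_score
    # one shared null per (line, k) keeps per-gene cost flat
    nulls <- with_seed(seed + li, list(
      k1 = pool[sample.int(length(pool), n_draws, replace = TRUE)],
      k2 = {
        i1 <- sample.int(length(pool), n_draws, replace = TRUE)
        i2 <- sample.int(length(pool) - 1L, n_draws, replace = TRUE)
        i2 <- i2 + (i2 >= i1)
        (pool[i1] + pool[i2]) / 2
      }))
    for (gi in seq_along(genes)) {
      x <- line$dropout_score[line$gene_id == genes[gi]]
      if (length(x) == 0) next
      k <- min(2L, length(x))
      obs <- mean(sort(x)[seq_len(k)])
      null <- if (k == 1) nulls$k1 else nulls$k2
      scores[gi, li] <- obs
      p[gi, li] <- (1 + sum(null <= obs)) / (1 + n_draws)
    }
  }
  n_ess <- rowSums(p < alpha, na.rm = TRUE)
  summary <- data.frame(gene = genes, n_essential_lines = n_ess,
                        n_lines = length(lines),
                        fraction = n_ess / length(lines),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = scores, p = p, summary = summary, alpha = alpha),
            class = "essentiality_table")
}

#' @export
print.essentiality_table <- function(x, ...) {
  cat("essentiality_table:", nrow(x$scores), "gene(s) x", ncol(x$scores),
      "cell line(s), alpha =", x$alpha, "\n")
  invisible(x)
}

#' Essentiality filter (at least 5% of cell lines)
#'
#' A gene passes when it is essential (per-line p < alpha, as recorded in the
#' table) in at least `min_fraction` of the cell lines; with the default 29
#' lines and 5% this means at least 2 lines.
#'
#' @param tab An `essentiality_table`.
#' @param min_fraction Required essential-line fraction (default 0.05).
#' @return Character vector of passing genes.
#' @export
essential_filter <- function(tab, min_fraction = 0.05) {
  tab$summary$gene[tab$summary$fraction >= min_fraction]
}
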