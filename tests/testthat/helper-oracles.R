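# Independent oracles used to validate the package's implementations.
# These deliberately use different algorithms (direct enumeration, naive
# double loops) from the code paths they check.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables with the observed margins; tables whose probability is at or below
# the observed one (1 + 1e-7 relative tie tolerance) are summed.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c          # margin: affected
  n <- b + d          # margin: unaffected
  k <- a + b          # margin: in-class
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# One-pass SAM d-statistic oracle using running-moment formulas (distinct
# from the package's centered-sum implementation).
sam_d_oracle <- function(matrix, in_class, s0) {
  n1 <- sum(in_class)
  n2 <- sum(!in_class)
  apply(matrix, 1, function(x) {
    xi <- x[in_class]
    xo <- x[!in_class]
    num <- mean(xi) - mean(xo)
    pooled <- ((n1 - 1) * stats::var(xi) + (n2 - 1) * stats::var(xo)) /
      (n1 + n2 - 2)
    s <- sqrt((1 / n1 + 1 / n2) * pooled)
    num / (s + s0)
  })
}

# Naive windowed-average oracle: explicit double loop over chromosomes and
# windows.
ten_probe_oracle <- function(info, ratio, width = 10) {
  out <- list()
  for (ch in unique(info$chrom)) {
    ix <- which(info$chrom == ch)
    ix <- ix[order(info$pos[ix])]
    n_win <- length(ix) %/% width
    if (n_win == 0) next
    for (w in seq_len(n_win)) {
      rows <- ix[((w - 1) * width + 1):(w * width)]
      vals <- numeric(ncol(ratio))
      for (j in seq_len(ncol(ratio))) vals[j] <- mean(ratio[rows, j])
      out[[paste0(ch, ":w", w)]] <- vals
    }
  }
  out
}

# Naive maximal-overlap assignment of genes to intervals (0-based half-open).
max_overlap_oracle <- function(genes, intervals) {
  vapply(seq_len(nrow(genes)), function(i) {
    ov <- pmin(genes$end[i], intervals$end) - pmax(genes$start[i], intervals$start)
    ov[intervals$chrom != genes$chrom[i]] <- 0L
    if (all(ov <= 0)) return(NA_integer_)
    which.max(ov)    # first maximum = lower-coordinate tie-break
  }, integer(1))
}

# Naive SV endpoint-in-gene scan.
sv_collapse_oracle <- function(catalog, gene_models, samples) {
  genes <- gene_models$gene
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (r in seq_len(nrow(catalog))) {
    for (side in list(c("chromA", "posA"), c("chromB", "posB"))) {
      ch <- catalog[[side[1]]][r]
      p <- catalog[[side[2]]][r]
      hit <- gene_models$chrom == ch & gene_models$start <= p &
        p < gene_models$end
      if (any(hit)) m[which(hit), catalog$sample[r]] <- TRUE
    }
  }
  m
}
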