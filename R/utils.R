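# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps generator and permutation seeds
# from leaking into user code.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Normalize a class-label argument to a character vector aligned with
# `samples`.  Accepts a named vector, an unnamed vector of matching length,
# or a data.frame with columns sample/class.
align_labels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample", "class") %in% names(labels)))
    vec <- stats::setNames(as.character(labels$class), labels$sample)
  } else {
    vec <- labels
  }
  if (!is.null(names(vec))) {
    missing <- setdiff(samples, names(vec))
    if (length(missing) > 0) {
      stop("no class label for sample(s): ", paste(missing, collapse = ", "))
    }
    vec <- vec[samples]
  } else if (length(vec) != length(samples)) {
    stop("labels length ", length(vec), " does not match ", length(samples),
         " samples")
  }
  as.character(vec)
}

# Assay flags (e.g. wgs/exome) aligned with samples; same conventions.
align_assay <- function(labels, samples) {
  if (is.data.frame(labels) && "assay" %in% names(labels)) {
    vec <- stats::setNames(as.character(labels$assay), labels$sample)
    return(vec[samples])
  }
  stop("assay flags required: supply a labels data.frame with an 'assay' column")
}

stop_if_dup <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    stop("duplicate ", what, ": ", paste(utils::head(d, 5), collapse = ", "))
  }
  invisible(x)
}

# Two-sided Fisher's exact test p for a 2x2 table given as four counts
# (affected-in, affected-out, unaffected-in, unaffected-out).  Vectorized and
# memoized over repeated tables; delegates to stats::fisher.test.
fisher_p2 <- function(a, b, c, d) {
  key <- paste(a, b, c, d)
  uk <- unique(key)
  pu <- vapply(uk, function(k) {
    v <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
    stats::fisher.test(matrix(v, nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  unname(pu[match(key, uk)])
}

# 1-based closed GRanges from internal 0-based half-open coordinates.
as_granges0 <- function(chrom, start, end, names = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(names)) names(gr) <- names
  gr
}
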