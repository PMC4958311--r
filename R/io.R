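# Readers and writers for every external format the pipeline touches.
#
# TSV dialect: tab-separated, UTF-8, '#' comment lines ignored.  All genomic
# coordinates are held internally as 0-based half-open intervals; formats with
# a different native convention (SEG: 1-based inclusive) are converted at the
# boundary and restored on write.

#' Mutation classification vocabulary
#'
#' Classifications counted as non-silent when collapsing somatic mutations to
#' gene level, and those treated as silent.  Any other value is rejected at
#' ingestion.
#'
#' @format Character vectors.
#' @export
NONSILENT_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site",
                       "inframe_indel", "nonstop")

#' @rdname NONSILENT_CLASSES
#' @export
SILENT_CLASSES <- c("silent", "synonymous", "intron", "utr")

read_tsv_raw <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      stop("file ", path, " lacks required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  df
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a gene-by-sample expression matrix
#'
#' The on-disk format is a TSV whose first column (`gene`) holds gene
#' identifiers and whose remaining columns are samples; values are on the
#' log2 scale.  Genes with any missing value are dropped with a message:
#' downstream statistics require complete rows (presence-based filtering is a
#' probe-level concern, handled in [filter_probes()]).
#'
#' @param path File path.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  stop_if_dup(genes, "gene id")
  stop_if_dup(names(df)[-1], "sample id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-numeric expression value at gene ", genes[bad[1, 1]],
           ", sample ", colnames(m)[bad[1, 2]])
    }
    m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
  }
  rownames(m) <- genes
  incomplete <- rowSums(is.na(m)) > 0
  if (any(incomplete)) {
    message("dropping ", sum(incomplete), " gene(s) with missing values")
    m <- m[!incomplete, , drop = FALSE]
  }
  m
}

#' @rdname read_expression
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
}

#' Read and write sample class labels
#'
#' TSV with columns `sample`, `class` and optionally `assay` (e.g. `wgs` /
#' `exome`).
#'
#' @param path File path.
#' @return data.frame with one row per sample.
#' @export
read_labels <- function(path) {
  df <- read_tsv_raw(path, required = c("sample", "class"))
  stop_if_dup(df$sample, "sample id")
  df$sample <- as.character(df$sample)
  df$class <- as.character(df$class)
  df
}

#' @rdname read_labels
#' @param labels data.frame with columns sample, class and optionally assay.
#' @export
write_labels <- function(labels, path) write_tsv_raw(labels, path)

#' Read and write SEG-format segmented copy number
#'
#' Standard SEG columns (`ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`), 1-based inclusive on disk.  Internally coordinates are
#' normalized to 0-based half-open; [write_seg()] restores the file
#' convention, so write-then-read is an identity.
#'
#' @param path File path.
#' @return data.frame with columns sample, chrom, start, end, n_markers,
#'   seg_mean (0-based half-open coordinates).
#' @export
read_seg <- function(path) {
  df <- read_tsv_raw(path, required = c("ID", "chrom", "loc.start", "loc.end",
                                        "num.mark", "seg.mean"))
  seg <- data.frame(sample = as.character(df$ID),
                    chrom = as.character(df$chrom),
                    start = as.integer(df$loc.start) - 1L,
                    end = as.integer(df$loc.end),
                    n_markers = as.integer(df$num.mark),
                    seg_mean = as.numeric(df$seg.mean),
                    stringsAsFactors = FALSE)
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  check_seg_overlaps(seg)
  seg
}

check_seg_overlaps <- function(seg) {
  for (key in split(seq_len(nrow(seg)), paste(seg$sample, seg$chrom))) {
    if (length(key) < 2) next
    s <- seg[key, ]
    o <- order(s$start)
    s <- s[o, ]
    bad <- which(s$start[-1] < s$end[-nrow(s)])
    if (length(bad) > 0) {
      stop("overlapping segments for sample ", s$sample[1], " on ",
           s$chrom[1], ": [", s$start[bad[1]], ",", s$end[bad[1]], ") and [",
           s$start[bad[1] + 1], ",", s$end[bad[1] + 1], ")")
    }
  }
  invisible(seg)
}

#' @rdname read_seg
#' @param seg Segment table as returned by [read_seg()].
#' @export
write_seg <- function(seg, path) {
  df <- data.frame(ID = seg$sample, chrom = seg$chrom,
                   loc.start = seg$start + 1L, loc.end = seg$end,
                   num.mark = seg$n_markers, seg.mean = seg$seg_mean,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
}

#' Read and write gene models in BED format
#'
#' BED3+name(+score+strand); BED is natively 0-based half-open, matching the
#' internal convention.  Rows with `start >= end` are rejected.
#'
#' @param path File path.
#' @return data.frame with columns gene, chrom, start, end, strand, sorted by
#'   (chrom, start).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED gene models need >= 4 columns (chrom,start,end,name)")
  gm <- data.frame(gene = as.character(df[[4]]),
                   chrom = as.character(df[[1]]),
                   start = as.integer(df[[2]]),
                   end = as.integer(df[[3]]),
                   strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
                   stringsAsFactors = FALSE)
  if (any(gm$start >= gm$end)) {
    i <- which(gm$start >= gm$end)[1]
    stop("BED row with start >= end: ", gm$gene[i])
  }
  stop_if_dup(gm$gene, "gene id")
  gm[order(gm$chrom, gm$start), , drop = FALSE]
}

#' @rdname read_bed
#' @param gene_models data.frame as returned by [read_bed()].
#' @export
write_bed <- function(gene_models, path) {
  df <- data.frame(gene_models$chrom, gene_models$start, gene_models$end,
                   gene_models$gene, 0L, gene_models$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a MAF-lite somatic mutation catalog
#'
#' Columns: `sample`, `gene`, `chrom`, `pos`, `classification`.  The
#' classification must come from the fixed vocabulary
#' (`NONSILENT_CLASSES` or `SILENT_CLASSES`).  An empty (header-only) file
#' yields an empty catalog.
#'
#' @param path File path.
#' @return data.frame mutation catalog.
#' @export
read_mutations <- function(path) {
  df <- read_tsv_raw(path, required = c("sample", "gene", "chrom", "pos",
                                        "classification"))
  vocab <- c(NONSILENT_CLASSES, SILENT_CLASSES)
  bad <- setdiff(unique(df$classification), vocab)
  if (length(bad) > 0) {
    stop("unknown mutation classification(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(vocab, collapse = ", "))
  }
  df$sample <- as.character(df$sample)
  df$gene <- as.character(df$gene)
  df
}

#' @rdname read_mutations
#' @param catalog Mutation catalog data.frame.
#' @export
write_mutations <- function(catalog, path) write_tsv_raw(catalog, path)

#' Read and write a structural-variant catalog
#'
#' BEDPE-like columns: `sample`, `chromA`, `posA`, `chromB`, `posB`,
#' `sv_type`.  Endpoint order is kept exactly as given.
#'
#' @param path File path.
#' @return data.frame SV catalog.
#' @export
read_svs <- function(path) {
  df <- read_tsv_raw(path, required = c("sample", "chromA", "posA", "chromB",
                                        "posB", "sv_type"))
  df$sample <- as.character(df$sample)
  df
}

#' @rdname read_svs
#' @param catalog SV catalog data.frame.
#' @export
write_svs <- function(catalog, path) write_tsv_raw(catalog, path)

#' Read and write a probe-level aCGH table
#'
#' Wide TSV with columns `probe`, `chrom`, `pos`, then one column triplet per
#' sample: `ratio.<sample>` (log2 test/reference ratio), `ctrl.<sample>`
#' (control-channel intensity) and `present.<sample>` (0/1 spot presence).
#' Probes are sorted by (chrom, pos) at ingestion.
#'
#' @param path File path.
#' @return A `probe_table`: list with `info` (probe, chrom, pos), and probe x
#'   sample matrices `ratio`, `ctrl`, `present`.
#' @export
read_probes <- function(path) {
  df <- read_tsv_raw(path, required = c("probe", "chrom", "pos"))
  rcols <- grep("^ratio\\.", names(df), value = TRUE)
  samples <- sub("^ratio\\.", "", rcols)
  if (length(samples) == 0) stop("probe table has no ratio.<sample> columns")
  need <- c(paste0("ctrl.", samples), paste0("present.", samples))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("probe table lacks column(s): ", paste(miss, collapse = ", "))
  }
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  stop_if_dup(df$probe, "probe id")
  grab <- function(prefix) {
    m <- as.matrix(df[, paste0(prefix, ".", samples), drop = FALSE])
    dimnames(m) <- list(df$probe, samples)
    m
  }
  probe_table(info = data.frame(probe = as.character(df$probe),
                                chrom = as.character(df$chrom),
                                pos = as.integer(df$pos),
                                stringsAsFactors = FALSE),
              ratio = grab("ratio"), ctrl = grab("ctrl"),
              present = grab("present") != 0)
}

#' @rdname read_probes
#' @param pt A `probe_table`.
#' @export
write_probes <- function(pt, path) {
  samples <- colnames(pt$ratio)
  df <- pt$info
  for (s in samples) df[[paste0("ratio.", s)]] <- pt$ratio[, s]
  for (s in samples) df[[paste0("ctrl.", s)]] <- pt$ctrl[, s]
  for (s in samples) df[[paste0("present.", s)]] <- as.integer(pt$present[, s])
  write_tsv_raw(df, path)
}

#' Construct a probe_table
#'
#' @param info data.frame with columns probe, chrom, pos.
#' @param ratio,ctrl Numeric probe x sample matrices.
#' @param present Logical probe x sample matrix.
#' @return A `probe_table` object.
#' @export
probe_table <- function(info, ratio, ctrl, present) {
  stopifnot(nrow(info) == nrow(ratio), all(dim(ratio) == dim(ctrl)),
            all(dim(ratio) == dim(present)))
  structure(list(info = info, ratio = ratio, ctrl = ctrl, present = present),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat("probe_table:", nrow(x$info), "probes x", ncol(x$ratio), "samples on",
      length(unique(x$info$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read and write a mouse-to-human homolog map
#'
#' Two-column TSV (`mouse_gene`, `human_gene`).  Many-to-many pairs are
#' permitted; exact duplicate pairs are rejected.
#'
#' @param path File path.
#' @return data.frame with columns mouse_gene, human_gene.
#' @export
read_homologs <- function(path) {
  df <- read_tsv_raw(path, required = c("mouse_gene", "human_gene"))
  stop_if_dup(paste(df$mouse_gene, df$human_gene), "homolog pair")
  df$mouse_gene <- as.character(df$mouse_gene)
  df$human_gene <- as.character(df$human_gene)
  df
}

#' @rdname read_homologs
#' @param map Homolog map data.frame.
#' @export
write_homologs <- function(map, path) write_tsv_raw(map, path)

#' Read and write an shRNA dropout screen
#'
#' TSV with columns `cell_line`, `shrna_id`, `gene_id`, `dropout_score`
#' (more negative = more depleted).
#'
#' @param path File path.
#' @return data.frame screen table.
#' @export
read_screen <- function(path) {
  df <- read_tsv_raw(path, required = c("cell_line", "shrna_id", "gene_id",
                                        "dropout_score"))
  df$cell_line <- as.character(df$cell_line)
  df$gene_id <- as.character(df$gene_id)
  df$dropout_score <- as.numeric(df$dropout_score)
  df
}

#' @rdname read_screen
#' @param screen Screen data.frame.
#' @export
write_screen <- function(screen, path) write_tsv_raw(screen, path)
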