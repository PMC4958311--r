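# Synthetic multi-omic cohort generator with planted structure.
#
# Emulates a three-subtype murine mammary tumor cohort (expression, aCGH
# probes, somatic mutations, SVs), a human basal/non-basal segmentation
# cohort, a mouse-human homolog map and a pooled shRNA dropout screen, with
# a TruthRecord listing every planted element so each pipeline stage can be
# validated against known ground truth.

MURINE_CLASSES <- c("BasalEx", "ClaudinLowEx", "LuminalEx")

#' Configuration for the synthetic cohort
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 3 classes x 8 tumors, 2000 genes on 5 chromosomes (400 probes
#' each, one probe per gene), a gain amplicon of 8 genes (2 cis-driven
#' drivers + 6 passengers) in BasalEx and in LuminalEx, an 8-gene deletion
#' in BasalEx, a copy-number-neutral ClaudinLowEx carrying one
#' class-enriched mutated gene, 20 basal-like / 20 non-basal human samples
#' and a 29-line shRNA screen in which every planted driver is depleted in 3
#' lines.
#'
#' @param seed Integer RNG seed; the same seed gives byte-identical cohorts.
#' @param n_tumors_per_class Named integer vector over the three murine
#'   classes.
#' @param n_genes Total genes (must divide evenly over chromosomes).
#' @param n_chromosomes Number of chromosomes.
#' @param probes_per_chromosome aCGH probes per chromosome.
#' @param planted_amplicons List of plants: each
#'   `list(class, chrom, start_gene, end_gene, drivers, log2_gain)` with
#'   1-based within-chromosome gene indices and `drivers` inside
#'   `[start_gene, end_gene]`.
#' @param planted_deletions Same shape with negative `log2_loss`.
#' @param planted_mutated_gene `list(class, chrom, gene, carrier_fraction)`
#'   or NULL.
#' @param planted_sv_gene Same shape or NULL.
#' @param signature_effect Log2 shift of each class's signature genes.
#' @param n_signature_genes Signature genes planted per class.
#' @param cis_slope Expression change per unit log2 copy number for drivers.
#' @param cis_noise_sd,trans_noise_sd Expression noise sd for cis-driven and
#'   other genes.
#' @param probe_noise_sd aCGH probe measurement noise sd.
#' @param human_n_basal,human_n_nonbasal Human cohort sizes.
#' @param human_conserved_fraction Probability that a basal-like sample
#'   carries the ortholog amplification/deletion of a planted driver.
#' @param human_background_rate Same probability for non-basal samples.
#' @param screen_n_lines Cell lines in the shRNA screen (default 29).
#' @param screen_shrnas_per_gene shRNAs per gene (default 4).
#' @param screen_essential_lines Lines in which each planted driver is
#'   depleted (default 3 of 29, i.e. >5%).
#' @param background_mutations,background_silent,background_svs Mean counts
#'   per sample (Poisson) of random non-silent mutations, silent mutations
#'   and SVs.
#' @param homolog_dropout Fraction of non-planted genes missing from the
#'   homolog map.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(
    seed = 1,
    n_tumors_per_class = c(BasalEx = 8, ClaudinLowEx = 8, LuminalEx = 8),
    n_genes = 2000,
    n_chromosomes = 5,
    probes_per_chromosome = 400,
    planted_amplicons = list(
      list(class = "BasalEx", chrom = "chr2", start_gene = 102,
           end_gene = 109, drivers = c(103, 107), log2_gain = 1.0),
      list(class = "LuminalEx", chrom = "chr4", start_gene = 202,
           end_gene = 209, drivers = c(203, 207), log2_gain = 1.0)
    ),
    planted_deletions = list(
      list(class = "BasalEx", chrom = "chr3", start_gene = 52,
           end_gene = 59, drivers = 53, log2_loss = -1.0)
    ),
    planted_mutated_gene = list(class = "ClaudinLowEx", chrom = "chr1",
                                gene = 301, carrier_fraction = 0.75),
    planted_sv_gene = list(class = "BasalEx", chrom = "chr5", gene = 151,
                           carrier_fraction = 0.75),
    signature_effect = 2.0,
    n_signature_genes = 30,
    cis_slope = 1.0,
    cis_noise_sd = 0.3,
    trans_noise_sd = 0.5,
    probe_noise_sd = 0.15,
    human_n_basal = 20,
    human_n_nonbasal = 20,
    human_conserved_fraction = 0.7,
    human_background_rate = 0.02,
    screen_n_lines = 29,
    screen_shrnas_per_gene = 4,
    screen_essential_lines = 3,
    background_mutations = 5,
    background_silent = 3,
    background_svs = 2,
    homolog_dropout = 0.02) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  counts <- c(unlist(cfg$n_tumors_per_class), cfg$n_genes, cfg$n_chromosomes,
              cfg$probes_per_chromosome, cfg$screen_n_lines,
              cfg$screen_shrnas_per_gene)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (!setequal(names(cfg$n_tumors_per_class), MURINE_CLASSES)) {
    stop("n_tumors_per_class must name exactly: ",
         paste(MURINE_CLASSES, collapse = ", "))
  }
  if (cfg$n_genes %% cfg$n_chromosomes != 0) {
    stop("n_genes must be divisible by n_chromosomes")
  }
  gpc <- cfg$n_genes / cfg$n_chromosomes
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  for (pl in c(cfg$planted_amplicons, cfg$planted_deletions)) {
    if (!pl$class %in% MURINE_CLASSES) stop("unknown class in plant: ", pl$class)
    if (!pl$chrom %in% chroms) stop("plant on unknown chromosome ", pl$chrom)
    if (pl$start_gene < 1 || pl$end_gene > gpc || pl$start_gene > pl$end_gene) {
      stop("planted region [", pl$start_gene, ",", pl$end_gene,
           "] outside chromosome bounds (1..", gpc, ")")
    }
    if (any(pl$drivers < pl$start_gene | pl$drivers > pl$end_gene)) {
      stop("driver gene indices must lie inside their planted region")
    }
  }
  for (pl in list(cfg$planted_mutated_gene, cfg$planted_sv_gene)) {
    if (is.null(pl)) next
    if (pl$carrier_fraction <= 0 || pl$carrier_fraction > 1) {
      stop("carrier_fraction must lie in (0, 1]")
    }
    if (pl$gene < 1 || pl$gene > gpc) stop("planted gene outside chromosome")
  }
  invisible(cfg)
}

#' A configuration with no planted structure (null cohort)
#'
#' All plants removed and signature effect zero: downstream enrichment
#' stages should return (almost always) empty candidate lists.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, planted_amplicons = list(),
                planted_deletions = list(), planted_mutated_gene = NULL,
                planted_sv_gene = NULL, signature_effect = 0, ...)
}

# Gene layout: genes_per_chrom slots of 50 kb, gene occupies the first 20 kb
# of its slot; one probe sits 10 kb into each slot when probe and gene
# counts coincide, otherwise probes are spread evenly.
gene_layout <- function(cfg, prefix) {
  gpc <- cfg$n_genes / cfg$n_chromosomes
  chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), each = gpc)
  idx <- rep(seq_len(gpc), cfg$n_chromosomes)
  start <- (idx - 1L) * 50000L
  data.frame(gene = sprintf("%sG%02d.%04d", prefix,
                            rep(seq_len(cfg$n_chromosomes), each = gpc), idx),
             chrom = chrom, start = start, end = start + 20000L,
             strand = "+", idx = idx, stringsAsFactors = FALSE)
}

probe_layout <- function(cfg) {
  gpc <- cfg$n_genes / cfg$n_chromosomes
  chrom_len <- gpc * 50000
  ppc <- cfg$probes_per_chromosome
  pos <- if (ppc == gpc) (seq_len(ppc) - 1L) * 50000L + 10000L
         else as.integer(round((seq_len(ppc) - 0.5) * chrom_len / ppc))
  data.frame(probe = sprintf("P%02d.%04d",
                             rep(seq_len(cfg$n_chromosomes), each = ppc),
                             rep(seq_len(ppc), cfg$n_chromosomes)),
             chrom = rep(paste0("chr", seq_len(cfg$n_chromosomes)), each = ppc),
             pos = rep(pos, cfg$n_chromosomes), stringsAsFactors = FALSE)
}

plant_span <- function(pl) {
  c(start = (pl$start_gene - 1L) * 50000L,
    end = (pl$end_gene - 1L) * 50000L + 20000L)
}

#' Generate a synthetic multi-omic cohort
#'
#' Deterministic given `config$seed`.  Planted drivers are cis-driven (their
#' expression follows their per-tumor copy number, so the DNA-RNA Pearson
#' correlation is high by construction); passengers in the same amplicon get
#' copy number but expression independent of it.  Basal-like human samples
#' carry the ortholog event of each planted driver with probability
#' `human_conserved_fraction`; planted drivers are depleted in
#' `screen_essential_lines` screen lines.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with expression, probes
#'   (`probe_table`), labels, mutations, svs, human_seg, human_labels,
#'   genes_mouse, genes_human, homologs, screen, truth.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    gm <- gene_layout(cfg, "m")
    gh <- gene_layout(cfg, "h")
    samples <- unlist(lapply(MURINE_CLASSES, function(cl) {
      sprintf("%s_%02d", cl, seq_len(cfg$n_tumors_per_class[[cl]]))
    }))
    lab <- rep(MURINE_CLASSES, unlist(cfg$n_tumors_per_class[MURINE_CLASSES]))
    assay <- ifelse(lab == "ClaudinLowEx", "wgs", "exome")
    for (cl in c("BasalEx", "LuminalEx")) {
      assay[which(lab == cl)[1:min(2, sum(lab == cl))]] <- "wgs"
    }
    labels <- data.frame(sample = samples, class = lab, assay = assay,
                         stringsAsFactors = FALSE)
    n <- length(samples)

    # --- true gene-level copy number (log2), per tumor dosage U(0.7,1.3) ---
    cn_true <- matrix(0, nrow(gm), n, dimnames = list(gm$gene, samples))
    plants <- c(lapply(cfg$planted_amplicons, function(p) {
                  p$effect <- p$log2_gain; p$direction <- "gain"; p
                }),
                lapply(cfg$planted_deletions, function(p) {
                  p$effect <- p$log2_loss; p$direction <- "loss"; p
                }))
    for (pl in plants) {
      rows <- which(gm$chrom == pl$chrom & gm$idx >= pl$start_gene &
                      gm$idx <= pl$end_gene)
      carriers <- which(lab == pl$class)
      dosage <- pl$effect * stats::runif(length(carriers), 0.7, 1.3)
      cn_true[rows, carriers] <- rep(dosage, each = length(rows))
    }

    # --- signature genes: drawn from genes untouched by any plant ---
    planted_rows <- which(rowSums(cn_true != 0) > 0)
    free <- setdiff(seq_len(nrow(gm)), planted_rows)
    sig_genes <- list()
    for (cl in MURINE_CLASSES) {
      pick <- sample(free, cfg$n_signature_genes)
      free <- setdiff(free, pick)
      sig_genes[[cl]] <- gm$gene[sort(pick)]
    }

    # --- expression ---
    baseline <- stats::rnorm(nrow(gm), 8, 1)
    expr <- baseline +
      matrix(stats::rnorm(nrow(gm) * n, 0, cfg$trans_noise_sd), nrow(gm), n)
    dimnames(expr) <- list(gm$gene, samples)
    for (cl in MURINE_CLASSES) {
      expr[sig_genes[[cl]], lab == cl] <-
        expr[sig_genes[[cl]], lab == cl] + cfg$signature_effect
    }
    driver_genes <- unlist(lapply(plants, function(pl) {
      gm$gene[gm$chrom == pl$chrom & gm$idx %in% pl$drivers]
    }))
    if (length(driver_genes) > 0) {
      expr[driver_genes, ] <- baseline[match(driver_genes, gm$gene)] +
        cfg$cis_slope * cn_true[driver_genes, , drop = FALSE] +
        matrix(stats::rnorm(length(driver_genes) * n, 0, cfg$cis_noise_sd),
               length(driver_genes), n)
    }

    # --- aCGH probes ---
    pinfo <- probe_layout(cfg)
    probe_cn <- matrix(0, nrow(pinfo), n)
    for (pl in plants) {
      span <- plant_span(pl)
      rows <- which(pinfo$chrom == pl$chrom & pinfo$pos >= span["start"] &
                      pinfo$pos < span["end"])
      if (length(rows) == 0) next
      carriers <- which(lab == pl$class)
      # same per-tumor dosage as the gene-level truth
      g <- gm$gene[gm$chrom == pl$chrom & gm$idx == pl$drivers[1]]
      probe_cn[rows, carriers] <- rep(cn_true[g, carriers],
                                      each = length(rows))
    }
    ratio <- probe_cn + matrix(stats::rnorm(length(probe_cn), 0,
                                            cfg$probe_noise_sd),
                               nrow(pinfo), n)
    ctrl <- matrix(stats::rlnorm(length(probe_cn), log(50), 1), nrow(pinfo), n)
    # ~2% random spot dropouts; together with the ~5% control-channel
    # failures this yields value-level filtering (imputed downstream) while
    # whole-probe drops stay rare, keeping window boundaries stable
    present <- matrix(stats::runif(length(probe_cn)) > 0.02, nrow(pinfo), n)
    dimnames(ratio) <- dimnames(ctrl) <- dimnames(present) <-
      list(pinfo$probe, samples)
    probes <- probe_table(info = pinfo, ratio = ratio, ctrl = ctrl,
                          present = present)

    # --- somatic mutations ---
    mut <- random_mutations(cfg, gm, samples)
    if (!is.null(cfg$planted_mutated_gene)) {
      pm <- cfg$planted_mutated_gene
      g <- gm[gm$chrom == pm$chrom & gm$idx == pm$gene, ]
      carriers <- samples[lab == pm$class][
        stats::runif(sum(lab == pm$class)) < pm$carrier_fraction]
      if (length(carriers) > 0) {
        mut <- rbind(mut, data.frame(
          sample = carriers, gene = g$gene, chrom = g$chrom,
          pos = g$start + sample.int(20000L, length(carriers), replace = TRUE),
          classification = "missense", stringsAsFactors = FALSE))
      }
    }

    # --- structural variants ---
    svs <- random_svs(cfg, gm, samples)
    if (!is.null(cfg$planted_sv_gene)) {
      ps <- cfg$planted_sv_gene
      g <- gm[gm$chrom == ps$chrom & gm$idx == ps$gene, ]
      carriers <- samples[lab == ps$class][
        stats::runif(sum(lab == ps$class)) < ps$carrier_fraction]
      if (length(carriers) > 0) {
        svs <- rbind(svs, data.frame(
          sample = carriers, chromA = g$chrom,
          posA = g$start + sample.int(20000L, length(carriers),
                                      replace = TRUE) - 1L,
          chromB = "chr1",
          posB = sample.int(1000000L, length(carriers), replace = TRUE),
          sv_type = "translocation", stringsAsFactors = FALSE))
      }
    }

    # --- homolog map (1:1 minus a random dropout of non-planted genes) ---
    protected <- unique(c(driver_genes,
                          unlist(lapply(plants, function(pl) {
                            gm$gene[gm$chrom == pl$chrom &
                                      gm$idx >= pl$start_gene &
                                      gm$idx <= pl$end_gene]
                          })),
                          unlist(sig_genes)))
    droppable <- setdiff(gm$gene, protected)
    dropped <- sample(droppable,
                      round(cfg$homolog_dropout * length(droppable)))
    keep <- !(gm$gene %in% dropped)
    homologs <- data.frame(mouse_gene = gm$gene[keep],
                           human_gene = gh$gene[keep],
                           stringsAsFactors = FALSE)

    # --- human segmented cohort ---
    driver_tab <- do.call(rbind, lapply(plants, function(pl) {
      data.frame(gene = gm$gene[gm$chrom == pl$chrom & gm$idx %in% pl$drivers],
                 class = pl$class, chrom = pl$chrom,
                 idx = pl$drivers, direction = pl$direction,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(driver_tab)) {
      driver_tab$human_gene <- gh$gene[match(driver_tab$gene, gm$gene)]
    }
    human <- human_cohort(cfg, gh, driver_tab)

    # --- shRNA screen ---
    screen <- shrna_screen(cfg, gh, driver_tab)

    # --- truth record ---
    passenger_tab <- do.call(rbind, lapply(plants, function(pl) {
      idx <- setdiff(seq(pl$start_gene, pl$end_gene), pl$drivers)
      if (length(idx) == 0) return(NULL)
      data.frame(gene = gm$gene[gm$chrom == pl$chrom & gm$idx %in% idx],
                 class = pl$class, direction = pl$direction,
                 designed_fail_stage = "cis_correlation",
                 stringsAsFactors = FALSE)
    }))
    expected <- if (is.null(driver_tab)) {
      stats::setNames(rep(list(character(0)), 3), MURINE_CLASSES)
    } else {
      lapply(stats::setNames(MURINE_CLASSES, MURINE_CLASSES), function(cl) {
        sort(driver_tab$gene[driver_tab$class == cl &
                               driver_tab$direction == "gain"])
      })
    }
    truth <- list(
      seed = cfg$seed,
      classes = MURINE_CLASSES,
      signature_genes = sig_genes,
      drivers = driver_tab,
      passengers = passenger_tab,
      amplicons = cfg$planted_amplicons,
      deletions = cfg$planted_deletions,
      mutated_gene = if (is.null(cfg$planted_mutated_gene)) NULL else {
        pm <- cfg$planted_mutated_gene
        list(gene = gm$gene[gm$chrom == pm$chrom & gm$idx == pm$gene],
             class = pm$class)
      },
      sv_gene = if (is.null(cfg$planted_sv_gene)) NULL else {
        ps <- cfg$planted_sv_gene
        list(gene = gm$gene[gm$chrom == ps$chrom & gm$idx == ps$gene],
             class = ps$class)
      },
      expected_candidates = expected,
      essential_lines = attr(screen, "essential_lines")
    )

    structure(list(expression = expr, probes = probes, labels = labels,
                   mutations = mut, svs = svs, human_seg = human$seg,
                   human_labels = human$labels,
                   genes_mouse = gm[, c("gene", "chrom", "start", "end",
                                        "strand")],
                   genes_human = gh[, c("gene", "chrom", "start", "end",
                                        "strand")],
                   homologs = homologs, screen = screen, truth = truth,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

random_mutations <- function(cfg, gm, samples) {
  rows <- list()
  for (s in samples) {
    n_ns <- stats::rpois(1, cfg$background_mutations)
    n_si <- stats::rpois(1, cfg$background_silent)
    if (n_ns + n_si == 0) next
    gi <- sample.int(nrow(gm), n_ns + n_si, replace = TRUE)
    rows[[s]] <- data.frame(
      sample = s, gene = gm$gene[gi], chrom = gm$chrom[gi],
      pos = gm$start[gi] + sample.int(20000L, n_ns + n_si, replace = TRUE),
      classification = c(
        sample(NONSILENT_CLASSES, n_ns, replace = TRUE),
        sample(SILENT_CLASSES, n_si, replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(sample = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      classification = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_svs <- function(cfg, gm, samples) {
  chroms <- unique(gm$chrom)
  chrom_len <- max(gm$end[gm$chrom == chroms[1]]) + 30000L
  rows <- list()
  for (s in samples) {
    k <- stats::rpois(1, cfg$background_svs)
    if (k == 0) next
    rows[[s]] <- data.frame(
      sample = s,
      chromA = sample(chroms, k, replace = TRUE),
      posA = sample.int(chrom_len, k, replace = TRUE) - 1L,
      chromB = sample(chroms, k, replace = TRUE),
      posB = sample.int(chrom_len, k, replace = TRUE) - 1L,
      sv_type = sample(c("deletion", "inversion", "translocation"), k,
                       replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(sample = character(0), chromA = character(0),
                      posA = integer(0), chromB = character(0),
                      posB = integer(0), sv_type = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Human cohort: per-sample SEG records on the human gene layout.  Baseline
# segments are near-neutral N(0, 0.05); each planted driver's ortholog gene
# span is amplified (seg mean ~ +0.7) or deleted (~ -0.7) with probability
# human_conserved_fraction in basal-like samples, human_background_rate in
# non-basal samples.
human_cohort <- function(cfg, gh, driver_tab) {
  samples <- c(sprintf("HB_%02d", seq_len(cfg$human_n_basal)),
               sprintf("HN_%02d", seq_len(cfg$human_n_nonbasal)))
  basal <- c(rep(TRUE, cfg$human_n_basal), rep(FALSE, cfg$human_n_nonbasal))
  labels <- data.frame(sample = samples,
                       class = ifelse(basal, "basal-like", "non-basal"),
                       stringsAsFactors = FALSE)
  chroms <- unique(gh$chrom)
  chrom_len <- max(gh$end) + 30000L
  rows <- list()
  for (si in seq_along(samples)) {
    p_event <- if (basal[si]) cfg$human_conserved_fraction
               else cfg$human_background_rate
    for (ch in chroms) {
      dt <- if (is.null(driver_tab)) NULL
            else driver_tab[driver_tab$chrom == ch, , drop = FALSE]
      bp <- unique(sort(c(0L, as.integer(round(chrom_len * (1:3) / 4)),
                          chrom_len,
                          if (!is.null(dt) && nrow(dt) > 0) {
                            c((dt$idx - 1L) * 50000L,
                              (dt$idx - 1L) * 50000L + 20000L)
                          })))
      seg_start <- bp[-length(bp)]
      seg_end <- bp[-1]
      mean_val <- stats::rnorm(length(seg_start), 0, 0.05)
      if (!is.null(dt) && nrow(dt) > 0) {
        for (di in seq_len(nrow(dt))) {
          span <- c((dt$idx[di] - 1L) * 50000L,
                    (dt$idx[di] - 1L) * 50000L + 20000L)
          hit <- which(seg_start >= span[1] & seg_end <= span[2])
          if (stats::runif(1) < p_event) {
            amp <- dt$direction[di] == "gain"
            mean_val[hit] <- (if (amp) 0.7 else -0.7) +
              stats::rnorm(length(hit), 0, 0.1)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[si], chrom = ch, start = seg_start, end = seg_end,
        n_markers = pmax(1L, (seg_end - seg_start) %/% 50000L),
        seg_mean = round(mean_val, 4), stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  rownames(seg) <- NULL
  list(seg = seg, labels = labels)
}

# Pooled shRNA dropout screen over all human genes.  Background scores are
# N(0, 1); each planted driver's shRNAs are strongly depleted (N(-4, 0.5))
# in screen_essential_lines randomly chosen lines.
shrna_screen <- function(cfg, gh, driver_tab) {
  lines <- sprintf("L%02d", seq_len(cfg$screen_n_lines))
  k <- cfg$screen_shrnas_per_gene
  genes <- rep(gh$gene, each = k)
  shrna <- paste0(genes, "_sh", rep(seq_len(k), nrow(gh)))
  screen <- data.frame(
    cell_line = rep(lines, each = length(genes)),
    shrna_id = rep(shrna, length(lines)),
    gene_id = rep(genes, length(lines)),
    dropout_score = stats::rnorm(length(genes) * length(lines)),
    stringsAsFactors = FALSE)
  ess <- list()
  if (!is.null(driver_tab) && nrow(driver_tab) > 0) {
    for (hgene in unique(driver_tab$human_gene)) {
      in_lines <- sample(lines, min(cfg$screen_essential_lines,
                                    length(lines)))
      ess[[hgene]] <- sort(in_lines)
      hit <- screen$gene_id == hgene & screen$cell_line %in% in_lines
      screen$dropout_score[hit] <- stats::rnorm(sum(hit), -4, 0.5)
    }
  }
  attr(screen, "essential_lines") <- ess
  screen
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "murine tumors;",
      nrow(x$human_labels), "human samples;",
      length(unique(x$screen$cell_line)), "screen lines\n")
  nd <- if (is.null(x$truth$drivers)) 0 else nrow(x$truth$drivers)
  cat("  planted drivers:", nd, "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits every component in its external format (TSV/SEG/BED), a
#' `truth.json` record of the planted elements and a `config.yaml` echo of
#' the generating configuration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_expression(cohort$expression, fp("expression.tsv"))
  write_probes(cohort$probes, fp("probes.tsv"))
  write_labels(cohort$labels, fp("labels.tsv"))
  write_mutations(cohort$mutations, fp("mutations.tsv"))
  write_svs(cohort$svs, fp("svs.tsv"))
  write_seg(cohort$human_seg, fp("human_seg.tsv"))
  write_labels(cohort$human_labels, fp("human_labels.tsv"))
  write_bed(cohort$genes_mouse, fp("genes_mouse.bed"))
  write_bed(cohort$genes_human, fp("genes_human.bed"))
  write_homologs(cohort$homologs, fp("homologs.tsv"))
  write_screen(cohort$screen, fp("screen.tsv"))
  jsonlite::write_json(cohort$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `synthetic_cohort`-shaped bundle (truth included when
#'   `truth.json` is present).
#' @export
load_cohort <- function(dir) {
  fp <- function(f) file.path(dir, f)
  truth <- if (file.exists(fp("truth.json"))) {
    jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  } else NULL
  structure(list(expression = read_expression(fp("expression.tsv")),
                 probes = read_probes(fp("probes.tsv")),
                 labels = read_labels(fp("labels.tsv")),
                 mutations = read_mutations(fp("mutations.tsv")),
                 svs = read_svs(fp("svs.tsv")),
                 human_seg = read_seg(fp("human_seg.tsv")),
                 human_labels = read_labels(fp("human_labels.tsv")),
                 genes_mouse = read_bed(fp("genes_mouse.bed")),
                 genes_human = read_bed(fp("genes_human.bed")),
                 homologs = read_homologs(fp("homologs.tsv")),
                 screen = read_screen(fp("screen.tsv")),
                 truth = truth, config = NULL),
            class = "synthetic_cohort")
}

#' Simulate a differentiation-axis cohort for D-Score validation
#'
#' Draws tumors as convex mixtures of an adult mammary stem cell (aMaSC) and
#' a mature luminal expression centroid, alpha * MatureLum +
#' (1 - alpha) * aMaSC + noise, with class-specific mixing ranges that plant
#' the ordering ClaudinLowEx < BasalEx < LuminalEx on the differentiation
#' axis (claudin-low most stem-like).  The luminal-progenitor centroid is
#' the midpoint of the two.
#'
#' @param n_per_class Tumors per class.
#' @param n_genes Centroid genes.
#' @param noise_sd Expression noise around the mixture.
#' @param seed Integer seed.
#' @param alpha_ranges Named list of c(lo, hi) mixing ranges per class.
#' @return List with `matrix`, `labels` (data.frame), `centroids` (list for
#'   [differentiation_score()]) and `alpha` (true mixing weights).
#' @export
simulate_differentiation_cohort <- function(
    n_per_class = 8, n_genes = 60, noise_sd = 0.3, seed = 1,
    alpha_ranges = list(ClaudinLowEx = c(0, 0.25), BasalEx = c(0.375, 0.625),
                        LuminalEx = c(0.75, 1))) {
  with_seed(seed, {
    genes <- sprintf("dG%03d", seq_len(n_genes))
    amasc <- stats::setNames(stats::rnorm(n_genes), genes)
    mature <- stats::setNames(stats::rnorm(n_genes), genes)
    centroids <- list(aMaSC = amasc, LumProg = (amasc + mature) / 2,
                      MatureLum = mature)
    classes <- names(alpha_ranges)
    samples <- unlist(lapply(classes, function(cl) {
      sprintf("%s_%02d", cl, seq_len(n_per_class))
    }))
    lab <- rep(classes, each = n_per_class)
    alpha <- unlist(lapply(classes, function(cl) {
      stats::runif(n_per_class, alpha_ranges[[cl]][1], alpha_ranges[[cl]][2])
    }))
    m <- vapply(seq_along(samples), function(i) {
      alpha[i] * mature + (1 - alpha[i]) * amasc +
        stats::rnorm(n_genes, 0, noise_sd)
    }, numeric(n_genes))
    dimnames(m) <- list(genes, samples)
    list(matrix = m,
         labels = data.frame(sample = samples, class = lab,
                             stringsAsFactors = FALSE),
         centroids = centroids,
         alpha = stats::setNames(alpha, samples))
  })
}
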