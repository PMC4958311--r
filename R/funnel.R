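# The candidate-drug-target filtering funnel: class-enriched copy-number
# regions -> DNA-RNA cis-correlation -> amplifications only -> human
# basal-like conservation -> shRNA essentiality, with a per-gene audit
# trail; plus the tumor treatment-response arithmetic.

#' Run the driver-candidate filtering funnel
#'
#' For each murine class, executes the five-stage cascade:
#' \enumerate{
#'   \item genes inside class-enriched copy-number regions (aCGH probe
#'     filtering, ten-probe averaging, two-class SAM at FDR 0);
#'   \item genes whose expression tracks their copy number (signed Pearson
#'     r >= `r_cutoff`);
#'   \item amplified regions only (gains; protein products of amplified
#'     genes are directly targetable, deletions are not);
#'   \item orthologs amplified preferentially in human basal-like tumors
#'     (segment calls at +/- `tau`, two-sided Fisher p < `alpha`);
#'   \item orthologs essential in at least `min_fraction` of the screen's
#'     cell lines (per-line GARP-style p < `alpha`).
#' }
#' An empty intermediate stage simply empties the downstream lists; no error
#' is raised.
#'
#' @param cohort A `synthetic_cohort` (or [load_cohort()] bundle).
#' @param target_fdr SAM target FDR for region calling (default 0).
#' @param n_permutations SAM permutations.
#' @param seed Integer seed (SAM permutations, GARP null draws).
#' @param r_cutoff DNA-RNA Pearson cutoff (default 0.5).
#' @param tau Human segmentation log2 threshold (default 0.3).
#' @param alpha Significance cut for the Fisher and per-line GARP tests.
#' @param min_fraction Essential-line fraction (default 0.05).
#' @param garp_draws Null draws per gene-line for the GARP p-value.
#' @return A `funnel_report`: per class, `stages` (five gene lists, strictly
#'   nested) and `audit` (per-gene per-stage values and pass flags), plus
#'   `regions` and the parameter set.
#' @export
run_funnel <- function(cohort, target_fdr = 0, n_permutations = 1000,
                       seed = 1, r_cutoff = 0.5, tau = 0.3, alpha = 0.05,
                       min_fraction = 0.05, garp_draws = 1000) {
  pt <- filter_probes(cohort$probes)
  fm <- ten_probe_average(pt)
  gene_cn <- gene_level_cn(fm, cohort$genes_mouse)
  classes <- sort(unique(cohort$labels$class))
  out <- list()
  all_regions <- list()
  for (cl in classes) {
    regions <- call_regions(fm, cohort$labels, cl, target_fdr = target_fdr,
                            n_permutations = n_permutations, seed = seed)
    all_regions[[cl]] <- regions
    corr <- dna_rna_correlation(gene_cn, cohort$expression, regions,
                                cohort$genes_mouse, cutoff = r_cutoff)
    audit <- corr
    names(audit)[names(audit) == "pass"] <- "pass_correlation"
    stage1 <- unique(corr$gene)
    stage2 <- unique(corr$gene[corr$pass])
    audit$pass_amplified <- audit$pass_correlation & audit$direction == "gain"
    stage3 <- unique(audit$gene[audit$pass_amplified])

    # stage 4: human basal-like conservation of the amplified orthologs
    audit$human_gene <- rep(NA_character_, nrow(audit))
    audit$conservation_p <- rep(NA_real_, nrow(audit))
    audit$pass_conserved <- rep(FALSE, nrow(audit))
    stage4 <- character(0)
    mapped <- map_murine_candidates(stage3, cohort$homologs)
    if (nrow(mapped) > 0) {
      hm_models <- cohort$genes_human[
        cohort$genes_human$gene %in% mapped$human_gene, , drop = FALSE]
      states <- call_gene_states(cohort$human_seg, hm_models,
                                 samples = cohort$human_labels$sample,
                                 tau = tau)
      cons <- basal_enrichment(states, cohort$human_labels,
                               direction = "amplified", alpha = alpha)
      mapped$p <- cons$p[match(mapped$human_gene, cons$gene)]
      mapped$conserved <- cons$conserved[match(mapped$human_gene, cons$gene)]
      by_mouse <- split(mapped, mapped$mouse_gene)
      for (mg in names(by_mouse)) {
        mm <- by_mouse[[mg]]
        best <- which.min(mm$p)
        rows <- audit$gene == mg & audit$pass_amplified
        audit$human_gene[rows] <- mm$human_gene[best]
        audit$conservation_p[rows] <- mm$p[best]
        audit$pass_conserved[rows] <- any(mm$conserved)
      }
      stage4 <- sort(unique(mapped$mouse_gene[mapped$conserved]))
    }

    # stage 5: shRNA essentiality of the conserved amplified orthologs
    audit$essential_fraction <- rep(NA_real_, nrow(audit))
    audit$pass_essential <- rep(FALSE, nrow(audit))
    stage5 <- character(0)
    if (length(stage4) > 0) {
      hgenes <- unique(audit$human_gene[audit$gene %in% stage4 &
                                          audit$pass_conserved])
      hgenes <- hgenes[hgenes %in% cohort$screen$gene_id]
      if (length(hgenes) > 0) {
        ess <- essentiality_table(cohort$screen, genes = hgenes,
                                  n_draws = garp_draws, seed = seed,
                                  alpha = alpha)
        passing <- essential_filter(ess, min_fraction = min_fraction)
        for (mg in stage4) {
          hg <- audit$human_gene[audit$gene == mg & audit$pass_conserved][1]
          fr <- ess$summary$fraction[ess$summary$gene == hg]
          rows <- audit$gene == mg & audit$pass_conserved
          audit$essential_fraction[rows] <- if (length(fr)) fr else NA_real_
          audit$pass_essential[rows] <- hg %in% passing
        }
        stage5 <- sort(unique(audit$gene[audit$pass_essential]))
      }
    }
    out[[cl]] <- list(
      stages = list(in_region = sort(stage1),
                    cis_correlated = sort(stage2),
                    amplified = sort(stage3),
                    conserved = sort(stage4),
                    essential = stage5),
      candidates = stage5,
      audit = audit)
  }
  structure(list(classes = out, regions = all_regions,
                 params = list(target_fdr = target_fdr,
                               n_permutations = n_permutations,
                               r_cutoff = r_cutoff, tau = tau, alpha = alpha,
                               min_fraction = min_fraction, seed = seed)),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("funnel_report (", length(x$classes), " classes)\n", sep = "")
  for (cl in names(x$classes)) {
    st <- x$classes[[cl]]$stages
    cat(sprintf("  %-14s %d in-region -> %d cis -> %d amplified -> %d conserved -> %d essential\n",
                cl, length(st$in_region), length(st$cis_correlated),
                length(st$amplified), length(st$conserved),
                length(st$essential)))
    if (length(st$essential) > 0) {
      cat("    candidates:", paste(st$essential, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Extract final candidates from a funnel report
#'
#' @param report A `funnel_report`.
#' @return Named list of candidate gene vectors per class.
#' @export
funnel_candidates <- function(report) {
  lapply(report$classes, function(cl) cl$candidates)
}

#' Tumor volume from caliper measurements
#'
#' Volume = width^2 x length / 2, in mm^3 for measurements in mm.
#'
#' @param width,length Tumor dimensions (mm), positive.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0)) {
    stop("tumor dimensions must be positive")
  }
  width^2 * length / 2
}

#' Percent change in tumor volume
#'
#' 100 x (v_end - v_start) / v_start; a complete regression gives -100.
#'
#' @param v_start Baseline volume (> 0).
#' @param v_end Follow-up volume (e.g. at day 14).
#' @return Percent change.
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start == 0)) stop("baseline volume must be non-zero")
  100 * (v_end - v_start) / v_start
}
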