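# Shared fixture builders.  Everything is generated in code at test time.

# A scaled-down cohort configuration for fast end-to-end tests: 3 classes x
# 6 tumors, 300 genes on 3 chromosomes, one gain amplicon with 2 drivers +
# 4 passengers, one deletion, 12 + 12 human samples.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(small_config_defaults(seed), list(...))
  do.call(cohort_config, args)
}

small_config_defaults <- function(seed) {
  list(
    seed = seed,
    n_tumors_per_class = c(BasalEx = 6, ClaudinLowEx = 6, LuminalEx = 6),
    n_genes = 300,
    n_chromosomes = 3,
    probes_per_chromosome = 100,
    planted_amplicons = list(
      list(class = "BasalEx", chrom = "chr1", start_gene = 22,
           end_gene = 27, drivers = c(23, 26), log2_gain = 1.0)
    ),
    planted_deletions = list(
      list(class = "LuminalEx", chrom = "chr2", start_gene = 42,
           end_gene = 47, drivers = 43, log2_loss = -1.0)
    ),
    planted_mutated_gene = list(class = "ClaudinLowEx", chrom = "chr3",
                                gene = 61, carrier_fraction = 0.8),
    planted_sv_gene = list(class = "BasalEx", chrom = "chr3", gene = 31,
                           carrier_fraction = 0.8),
    n_signature_genes = 15,
    human_n_basal = 12,
    human_n_nonbasal = 12
  )
}

# Minimal probe table built by hand.
make_probe_table <- function(info, ratio, ctrl = NULL, present = NULL) {
  if (is.null(ctrl)) ctrl <- matrix(100, nrow(ratio), ncol(ratio))
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(ratio), ncol(ratio))
  }
  dimnames(ctrl) <- dimnames(present) <- dimnames(ratio)
  probe_table(info = info, ratio = ratio, ctrl = ctrl, present = present)
}

random_gene_models <- function(n, chroms = c("chrA", "chrB"), seed = 1,
                               spacing = 1000L, width = 400L) {
  set.seed(seed)
  per <- split(seq_len(n), sort(rep_len(seq_along(chroms), n)))
  do.call(rbind, lapply(seq_along(chroms), function(ci) {
    idx <- per[[ci]]
    start <- (seq_along(idx) - 1L) * spacing
    data.frame(gene = sprintf("g%s_%03d", chroms[ci], seq_along(idx)),
               chrom = chroms[ci], start = start, end = start + width,
               strand = "+", stringsAsFactors = FALSE)
  }))
}
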