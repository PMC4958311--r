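test_that("mutation collapsing keeps one hit per gene and ignores silent classes", {
  cat <- data.frame(
    sample = c("S1", "S1", "S1", "S2", "S2"),
    gene = c("gA", "gA", "gA", "gA", "gB"),
    chrom = "chr1", pos = 1:5,
    classification = c("missense", "missense", "nonsense", "silent",
                       "synonymous"),
    stringsAsFactors = FALSE)
  m <- collapse_mutations(cat, samples = c("S1", "S2", "S3"))
  expect_true(m["gA", "S1"])       # 3 non-silent hits -> one TRUE
  expect_false(m["gA", "S2"])      # only silent hits
  expect_false("gB" %in% rownames(m) && m["gB", "S2"])
  expect_false(any(m[, "S3"]))

  # idempotent and row-order independent
  m2 <- collapse_mutations(cat[sample(nrow(cat)), ],
                           samples = c("S1", "S2", "S3"))
  expect_identical(m, m2)
})

test_that("SV collapsing respects half-open gene spans and matches a naive scan", {
  gm <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                   start = c(100L, 500L), end = c(200L, 600L), strand = "+",
                   stringsAsFactors = FALSE)
  cat <- data.frame(
    sample = c("S1", "S2", "S3"),
    chromA = "chr1", posA = c(100L, 200L, 599L),   # at start / at end / last base
    chromB = "chr9", posB = 1L,
    sv_type = "translocation", stringsAsFactors = FALSE)
  m <- collapse_svs(cat, gm, samples = c("S1", "S2", "S3"))
  expect_true(m["gA", "S1"])     # endpoint exactly at start is inside
  expect_false("gA" %in% rownames(m) && m["gA", "S2"])  # at end is outside
  expect_true(m["gB", "S3"])

  set.seed(14)
  gm2 <- random_gene_models(50, seed = 14)
  cat2 <- data.frame(
    sample = sample(sprintf("S%d", 1:8), 100, replace = TRUE),
    chromA = sample(c("chrA", "chrB"), 100, replace = TRUE),
    posA = sample.int(30000L, 100) - 1L,
    chromB = sample(c("chrA", "chrB"), 100, replace = TRUE),
    posB = sample.int(30000L, 100) - 1L,
    sv_type = "deletion", stringsAsFactors = FALSE)
  samples <- sort(unique(cat2$sample))
  got <- collapse_svs(cat2, gm2, samples = samples)
  oracle <- sv_collapse_oracle(cat2, gm2, samples)
  oracle <- oracle[rowSums(oracle) > 0, , drop = FALSE]
  expect_identical(got[order(rownames(got)), ],
                   oracle[order(rownames(oracle)), ])
})

test_that("class enrichment p-values match closed forms", {
  m <- matrix(FALSE, 3, 12,
              dimnames = list(c("gHit", "gNone", "gEven"),
                              sprintf("S%02d", 1:12)))
  lab <- stats::setNames(rep(c("X", "Y"), c(3, 9)), colnames(m))
  m["gHit", 1:3] <- TRUE                 # 3/3 in class, 0/9 out
  m["gEven", c(1, 2, 4, 5)] <- TRUE      # 2/3 vs 2/9 -> not the symmetric case
  et <- class_enrichment(m, lab, "X")
  expect_equal(et$p[et$gene == "gHit"], 1 / choose(12, 3), tolerance = 1e-12)
  expect_equal(et$p[et$gene == "gNone"], 1)
  expect_true(all(et$affected_in + et$affected_out + et$unaffected_in +
                    et$unaffected_out == 12))
  # symmetric 2x2 table [[2,2],[2,2]] is exchangeable: p = 1
  m2 <- matrix(FALSE, 1, 8, dimnames = list("g", sprintf("S%d", 1:8)))
  m2["g", c(1, 2, 5, 6)] <- TRUE
  lab2 <- stats::setNames(rep(c("X", "Y"), each = 4), colnames(m2))
  expect_equal(class_enrichment(m2, lab2, "X")$p, 1)
})

test_that("wgs restriction reproduces the full test on all-wgs cohorts and drops exome-only events", {
  m <- matrix(FALSE, 2, 8, dimnames = list(c("gA", "gB"), sprintf("S%d", 1:8)))
  m["gA", 1:3] <- TRUE
  labels <- data.frame(sample = colnames(m),
                       class = rep(c("ClaudinLowEx", "BasalEx"), each = 4),
                       assay = "wgs", stringsAsFactors = FALSE)
  full <- class_enrichment(m, labels, "ClaudinLowEx")
  restricted <- wgs_only_enrichment(m, labels, "ClaudinLowEx")
  expect_equal(restricted$p, full$p)

  # an SV seen only in exome samples vanishes from the restricted table
  labels$assay <- c("wgs", "wgs", "exome", "wgs", "wgs", "wgs", "exome", "wgs")
  m["gB", c(3, 7)] <- TRUE
  r2 <- wgs_only_enrichment(m, labels, "ClaudinLowEx")
  expect_equal(r2$affected_in[r2$gene == "gB"] + r2$affected_out[r2$gene == "gB"], 0)

  # an SV only detectable by whole-genome profiling looks claudin-low
  # enriched in the mixed cohort (claudin-low is all-wgs) but the
  # enrichment dissolves when the test is restricted to wgs samples
  m3 <- matrix(FALSE, 1, 16, dimnames = list("gW", sprintf("S%02d", 1:16)))
  lab3 <- data.frame(sample = colnames(m3),
                     class = rep(c("ClaudinLowEx", "BasalEx"), each = 8),
                     assay = c(rep("wgs", 8), rep("wgs", 2), rep("exome", 6)),
                     stringsAsFactors = FALSE)
  m3["gW", c(1:7, 9, 10)] <- TRUE   # 7/8 CL; both wgs basal carry it too
  full3 <- class_enrichment(m3, lab3, "ClaudinLowEx")
  res3 <- wgs_only_enrichment(m3, lab3, "ClaudinLowEx")
  expect_true(full3$significant)
  expect_false(res3$significant)

  labels$assay <- "exome"
  expect_error(wgs_only_enrichment(m, labels, "ClaudinLowEx"), "absent")
})
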