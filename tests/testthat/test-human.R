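test_that("gene-state thresholding is strict at +/-0.3", {
  gm <- data.frame(gene = sprintf("g%d", 1:4), chrom = "chr1",
                   start = c(0L, 100L, 200L, 300L) * 1000L,
                   end = c(50L, 150L, 250L, 350L) * 1000L, strand = "+",
                   stringsAsFactors = FALSE)
  seg <- data.frame(sample = "H1", chrom = "chr1",
                    start = c(0L, 100L, 200L, 300L) * 1000L,
                    end = c(100L, 200L, 300L, 400L) * 1000L,
                    n_markers = 10L,
                    seg_mean = c(0.31, 0.30, -0.31, -0.30),
                    stringsAsFactors = FALSE)
  st <- call_gene_states(seg, gm)
  expect_equal(unname(st[, "H1"]),
               c("amplified", "neutral", "deleted", "neutral"))
})

test_that("maximal-overlap segment defines the gene value", {
  gm <- data.frame(gene = "g", chrom = "chr1", start = 0L, end = 1000L,
                   strand = "+", stringsAsFactors = FALSE)
  seg <- data.frame(sample = "H1", chrom = "chr1",
                    start = c(0L, 800L), end = c(800L, 2000L),
                    n_markers = 5L, seg_mean = c(0.6, 0.0),
                    stringsAsFactors = FALSE)
  expect_equal(unname(call_gene_states(seg, gm)[, "H1"]), "amplified")
  # flip the overlap proportions: neutral segment wins
  seg$seg_mean <- c(0.0, 0.6)
  expect_equal(unname(call_gene_states(seg, gm)[, "H1"]), "neutral")
  # an uncovered gene is neutral
  gm2 <- rbind(gm, data.frame(gene = "gOut", chrom = "chr9", start = 0L,
                              end = 10L, strand = "+"))
  st <- suppressMessages(call_gene_states(seg, gm2))
  expect_equal(unname(st["gOut", "H1"]), "neutral")
})

test_that("basal enrichment matches the hypergeometric closed form", {
  st <- matrix("neutral", 2, 20,
               dimnames = list(c("gAll", "gEq"),
                               sprintf("H%02d", 1:20)))
  lab <- stats::setNames(rep(c("basal-like", "non-basal"), each = 10),
                         colnames(st))
  st["gAll", 1:10] <- "amplified"                    # 10/10 vs 0/10
  st["gEq", c(1:5, 11:15)] <- "amplified"            # equal rates
  out <- basal_enrichment(st, lab, direction = "amplified")
  # the mirrored extreme table has identical probability, so the two-sided
  # enumeration sums both tails: p = 2 / C(20,10)
  expect_equal(out$p[out$gene == "gAll"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_true(out$conserved[out$gene == "gAll"])
  expect_equal(out$p[out$gene == "gEq"], 1)
  expect_false(out$conserved[out$gene == "gEq"])
  expect_equal(out$pct_basal[out$gene == "gAll"], 100)
  expect_equal(out$pct_nonbasal[out$gene == "gAll"], 0)

  # raising tau never increases affected counts (threshold monotonicity)
  gm <- data.frame(gene = "g", chrom = "chr1", start = 0L, end = 1000L,
                   strand = "+", stringsAsFactors = FALSE)
  seg <- data.frame(sample = rep(sprintf("H%d", 1:4), each = 1),
                    chrom = "chr1", start = 0L, end = 1000L, n_markers = 5L,
                    seg_mean = c(0.2, 0.35, 0.5, -0.6),
                    stringsAsFactors = FALSE)
  n_amp <- function(tau) {
    sum(call_gene_states(seg, gm, tau = tau) == "amplified")
  }
  expect_true(n_amp(0.3) >= n_amp(0.45))
  expect_equal(n_amp(0.3), 2)
  expect_equal(n_amp(0.45), 1)
})

test_that("homolog mapping emits all pairs and audits drops", {
  map <- data.frame(mouse_gene = c("m1", "m2", "m2"),
                    human_gene = c("h1", "h2a", "h2b"),
                    stringsAsFactors = FALSE)
  out <- map_murine_candidates(c("m1", "m2", "m3"), map)
  expect_equal(nrow(out), 3)            # many-to-many cross product kept
  expect_identical(attr(out, "unmapped"), "m3")
  idmap <- data.frame(mouse_gene = "mX", human_gene = "mX",
                      stringsAsFactors = FALSE)
  expect_equal(map_murine_candidates("mX", idmap)$human_gene, "mX")
})

test_that("planted conserved drivers are flagged and murine-only events are not", {
  co <- generate_cohort(small_config(seed = 6))
  drv <- co$truth$drivers
  states <- suppressMessages(call_gene_states(co$human_seg, co$genes_human,
                                              samples = co$human_labels$sample))
  gain_h <- drv$human_gene[drv$direction == "gain"]
  out <- basal_enrichment(states[gain_h, , drop = FALSE], co$human_labels,
                          direction = "amplified")
  expect_true(all(out$conserved))
  # a random non-planted gene shows no basal enrichment
  other <- setdiff(rownames(states), drv$human_gene)[1:20]
  out2 <- basal_enrichment(states[other, , drop = FALSE], co$human_labels,
                           direction = "amplified")
  expect_true(all(!out2$conserved))
  # deletion drivers conserve in the deleted direction, not the amplified one
  del_h <- drv$human_gene[drv$direction == "loss"]
  out3 <- basal_enrichment(states[del_h, , drop = FALSE], co$human_labels,
                           direction = "deleted")
  expect_true(all(out3$conserved))
})
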