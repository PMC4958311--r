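test_that("probe filters are strict at their boundaries", {
  n_s <- 10
  info <- data.frame(probe = sprintf("p%d", 1:4), chrom = "chr1",
                     pos = c(100L, 200L, 300L, 400L), stringsAsFactors = FALSE)
  ratio <- matrix(1, 4, n_s, dimnames = list(info$probe, sprintf("s%d", 1:n_s)))
  ctrl <- matrix(100, 4, n_s, dimnames = dimnames(ratio))
  present <- matrix(TRUE, 4, n_s, dimnames = dimnames(ratio))
  # p1: intensity exactly 10 in 3 samples -> those values dropped, 7/10 = 70%
  # presence is NOT strictly greater -> probe dropped
  ctrl[1, 1:3] <- 10
  # p2: intensity 10.01 everywhere -> kept
  ctrl[2, ] <- 10.01
  # p3: absent in 2 samples -> 8/10 = 80% -> kept, missing imputed
  present[3, 1:2] <- FALSE
  ratio[3, ] <- c(9, 9, 1, 1, 1, 2, 2, 2, 3, 3)
  pt <- probe_table(info, ratio, ctrl, present)
  expect_message(out <- filter_probes(pt), "dropped 1 probe")
  expect_setequal(out$info$probe, c("p2", "p3", "p4"))
  # imputation uses the probe median over surviving values
  expect_equal(unname(out$ratio["p3", 1:2]), rep(2, 2))

  ctrl[] <- 5
  expect_error(filter_probes(probe_table(info, ratio, ctrl, present)),
               "all probes removed")
})

test_that("ten-probe averaging matches arithmetic and drops remainders", {
  info <- data.frame(probe = sprintf("p%02d", 1:10), chrom = "chr1",
                     pos = seq(100L, 1000L, by = 100L),
                     stringsAsFactors = FALSE)
  ratio <- matrix(1:10, 10, 1, dimnames = list(info$probe, "s1"))
  fm <- ten_probe_average(make_probe_table(info, ratio))
  expect_equal(nrow(fm$info), 1)
  expect_equal(unname(fm$values[1, 1]), 5.5)
  expect_equal(fm$info$n_probes, 10)

  # 23 probes -> 2 features, 3 trailing probes logged dropped
  info2 <- data.frame(probe = sprintf("p%02d", 1:23), chrom = "chr1",
                      pos = seq_len(23) * 10L, stringsAsFactors = FALSE)
  ratio2 <- matrix(rnorm(23 * 2), 23, 2,
                   dimnames = list(info2$probe, c("s1", "s2")))
  expect_message(fm2 <- ten_probe_average(make_probe_table(info2, ratio2)),
                 "dropped 3 trailing")
  expect_equal(nrow(fm2$info), 2)

  # a chromosome with < 10 probes yields no features, with a warning
  info3 <- rbind(info2,
                 data.frame(probe = "q1", chrom = "chr2", pos = 5L))
  ratio3 <- rbind(ratio2, q1 = c(0, 0))
  expect_warning(fm3 <- ten_probe_average(make_probe_table(info3, ratio3)),
                 "chr2")
  expect_equal(nrow(fm3$info), 2)
})

test_that("windowed averages equal a brute-force oracle on random tables", {
  set.seed(31)
  n <- 437
  info <- data.frame(probe = sprintf("p%04d", 1:n),
                     chrom = sample(c("chr1", "chr2", "chr3"), n,
                                    replace = TRUE),
                     pos = sample.int(1e6, n), stringsAsFactors = FALSE)
  info <- info[order(info$chrom, info$pos), ]
  ratio <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(info$probe, sprintf("s%d", 1:6)))
  fm <- suppressMessages(ten_probe_average(make_probe_table(info, ratio)))
  oracle <- ten_probe_oracle(info, ratio)
  expect_setequal(rownames(fm$values), names(oracle))
  for (f in names(oracle)) {
    expect_equal(unname(fm$values[f, ]), oracle[[f]], tolerance = 1e-12)
  }
  # feature count identity: sum over chromosomes of floor(n/10)
  expected_n <- sum(vapply(split(info$probe, info$chrom),
                           function(p) length(p) %/% 10, numeric(1)))
  expect_equal(nrow(fm$info), expected_n)
})

test_that("median class profiles equal a sort-based oracle", {
  set.seed(4)
  info <- data.frame(probe = sprintf("p%02d", 1:20), chrom = "chr1",
                     pos = seq_len(20) * 50L, stringsAsFactors = FALSE)
  ratio <- matrix(rnorm(20 * 7), 20, 7,
                  dimnames = list(info$probe, sprintf("s%d", 1:7)))
  fm <- ten_probe_average(make_probe_table(info, ratio))
  lab <- stats::setNames(c("A", "A", "A", "B", "B", "B", "B"),
                         colnames(ratio))
  prof <- median_class_profile(fm, lab)
  expect_equal(unname(prof["chr1:w1", "A"]),
               unname(sort(fm$values["chr1:w1", 1:3])[2]))
  expect_equal(unname(prof[, "B"]),
               unname(apply(fm$values[, 4:7], 1, stats::median)))
  # single-sample class returns its own values; {-1, 0, 1} -> 0
  lab1 <- stats::setNames(c("solo", rep("rest", 6)), colnames(ratio))
  expect_equal(unname(median_class_profile(fm, lab1)[, "solo"]),
               unname(fm$values[, 1]))
  expect_equal(stats::median(c(-1, 0, 1)), 0)
})

test_that("gene-level assignment picks the maximal-overlap feature", {
  info <- data.frame(probe = sprintf("p%02d", 1:20), chrom = "chr1",
                     pos = c(seq(0L, 900L, by = 100L),
                             seq(1000L, 1900L, by = 100L)),
                     stringsAsFactors = FALSE)
  ratio <- matrix(rep(c(1, 5), each = 10), 20, 1,
                  dimnames = list(info$probe, "s1"))
  fm <- ten_probe_average(make_probe_table(info, ratio))
  # feature 1 spans [0, 901); feature 2 spans [1000, 1901)
  gm <- data.frame(gene = c("nested", "straddle"), chrom = "chr1",
                   start = c(100L, 831L), end = c(300L, 1931L), strand = "+",
                   stringsAsFactors = FALSE)
  # straddle: 70 bp in feature 1, ~901 bp in feature 2 -> feature 2
  cn <- gene_level_cn(fm, gm)
  expect_equal(unname(cn["nested", "s1"]), 1)
  expect_equal(unname(cn["straddle", "s1"]), 5)

  # random layouts equal the naive exhaustive-overlap oracle
  set.seed(17)
  gm2 <- random_gene_models(60, chroms = "chr1", seed = 17,
                            spacing = 40L, width = 35L)
  got <- suppressMessages(gene_level_cn(fm, gm2))
  ora <- max_overlap_oracle(gm2, fm$info)
  keep <- !is.na(ora)
  expect_setequal(rownames(got), gm2$gene[keep])
  expect_equal(unname(got[gm2$gene[keep], "s1"]),
               unname(fm$values[ora[keep], "s1"]))
})

test_that("region calling finds planted gains and losses and skips neutral classes", {
  co <- generate_cohort(small_config(seed = 2))
  pt <- suppressMessages(filter_probes(co$probes))
  fm <- suppressMessages(ten_probe_average(pt))
  basal <- call_regions(fm, co$labels, "BasalEx", n_permutations = 200,
                        seed = 2)
  expect_true(any(basal$direction == "gain" & basal$chrom == "chr1"))
  lum <- call_regions(fm, co$labels, "LuminalEx", n_permutations = 200,
                      seed = 2)
  expect_true(any(lum$direction == "loss" & lum$chrom == "chr2"))
  cl <- call_regions(fm, co$labels, "ClaudinLowEx", n_permutations = 200,
                     seed = 2)
  expect_equal(nrow(cl), 0)   # copy-number-neutral class
})

test_that("cis-correlation filter separates drivers from passengers and is monotone", {
  co <- generate_cohort(small_config(seed = 2))
  pt <- suppressMessages(filter_probes(co$probes))
  fm <- suppressMessages(ten_probe_average(pt))
  cn <- suppressMessages(gene_level_cn(fm, co$genes_mouse))
  regions <- call_regions(fm, co$labels, "BasalEx", n_permutations = 200,
                          seed = 2)
  corr <- dna_rna_correlation(cn, co$expression, regions, co$genes_mouse)
  truth <- co$truth
  drv <- truth$drivers$gene[truth$drivers$class == "BasalEx" &
                              truth$drivers$direction == "gain"]
  pas <- truth$passengers$gene[truth$passengers$class == "BasalEx"]
  expect_true(all(drv %in% corr$gene[corr$pass]))
  expect_true(all(corr$r[corr$gene %in% drv] >= 0.5))
  expect_true(all(corr$r[corr$gene %in% pas] < 0.5))

  # raising the cutoff never adds genes
  strict <- dna_rna_correlation(cn, co$expression, regions, co$genes_mouse,
                                cutoff = 0.8)
  expect_true(all(strict$gene[strict$pass] %in% corr$gene[corr$pass]))

  # perfect and anti-correlated toy genes
  cn_toy <- matrix(c(1, 2, 3, 4), 1, 4,
                   dimnames = list("gT", sprintf("s%d", 1:4)))
  regions_toy <- data.frame(class = "X", chrom = "chrT", start = 0L,
                            end = 100L, direction = "gain", n_features = 1,
                            features = "f", stringsAsFactors = FALSE)
  gm_toy <- data.frame(gene = "gT", chrom = "chrT", start = 10L, end = 20L,
                       strand = "+", stringsAsFactors = FALSE)
  r_pos <- dna_rna_correlation(cn_toy, cn_toy, regions_toy, gm_toy)
  expect_equal(r_pos$r, 1)
  r_neg <- dna_rna_correlation(cn_toy, -cn_toy, regions_toy, gm_toy)
  expect_equal(r_neg$r, -1)
  expect_false(r_neg$pass)
})
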