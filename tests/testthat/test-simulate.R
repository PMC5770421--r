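test_that("genomes are deterministic under a seed and populate all strata", {
  g1 <- make_genome(10, seed = 5)
  g2 <- make_genome(10, seed = 5)
  expect_identical(as.data.frame(g1$target), as.data.frame(g2$target))
  expect_identical(chrom_sizes(g1$spike), chrom_sizes(g2$spike))
  g3 <- make_genome(10, seed = 6)
  expect_false(identical(as.data.frame(g1$target), as.data.frame(g3$target)))

  big <- make_genome(100, min_bp = 600, max_bp = 6000, seed = 7)
  cl <- table(length_clusters(big$target)$length_cluster)
  expect_true(all(cl[c("kb05to1", "kb1to2", "gt2kb")] > 0))
  expect_error(make_genome(0), "n_genes")

  strat <- make_genome(60, law = "stratified", seed = 8)
  cls <- table(length_clusters(strat$target)$length_cluster)
  expect_equal(as.integer(cls[c("kb05to1", "kb1to2", "gt2kb")]), rep(20L, 3))
})

test_that("annotation invariants hold for generated genomes", {
  g <- make_genome(50, seed = 9)
  for (ann in g) {
    expect_true(all(ann$start < ann$end))
    expect_true(all(ann$end <= chrom_sizes(ann)[ann$chrom]))
    expect_false(any(duplicated(ann$gene_id)))
  }
  expect_identical(genome_label(g$target), "target")
  expect_identical(genome_label(g$spike), "spike")
})

test_that("ChIP simulation is seed-deterministic and respects the design", {
  g <- make_genome(40, seed = 10)
  truth <- synthetic_truth(3, global_scale_s = 1)
  f1 <- simulate_chip(truth, g, 20000, "wt", "ip")
  f2 <- simulate_chip(truth, g, 20000, "wt", "ip")
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  f3 <- simulate_chip(synthetic_truth(4), g, 20000, "wt", "ip")
  expect_false(identical(as.data.frame(f1), as.data.frame(f3)))
  expect_equal(nrow(f1), 20000L)
  expect_error(simulate_chip(truth, g, 0, "wt", "ip"), "n_fragments")

  # with s = 1 the mutant and wild-type target fractions agree within
  # binomial error (5 sigma at n = 50000)
  flat <- synthetic_truth(3, per_gene_enrichment = setNames(
    rep(1, nrow(g$target) + nrow(g$spike)),
    c(g$target$gene_id, g$spike$gene_id)))
  pm <- genome_count(simulate_chip(flat, g, 5e4, "mut", "ip"), "target") / 5e4
  pw <- genome_count(simulate_chip(flat, g, 5e4, "wt", "ip"), "target") / 5e4
  expect_lt(abs(pm - pw), 5 * sqrt(0.5 * 0.5 / 5e4) * sqrt(2))
})

test_that("input-role fragment fractions follow length-proportional rates", {
  g <- make_genome(30, seed = 11)
  truth <- synthetic_truth(3)
  fr <- simulate_chip(truth, g, 1e5, "wt", "input")
  # expected gene fractions: length within genome, split by mixing ratio
  len_t <- g$target$end - g$target$start
  len_s <- g$spike$end - g$spike$start
  w <- c(len_t * truth$spike_mix_ratio, len_s)
  exp_frac <- w / sum(w)
  mids <- (fr$start + fr$end) %/% 2
  obs <- vapply(seq_len(nrow(g$target) + nrow(g$spike)), function(i) {
    ann <- if (i <= nrow(g$target)) g$target else g$spike
    j <- if (i <= nrow(g$target)) i else i - nrow(g$target)
    sum(fr$chrom == ann$chrom[j] & mids >= ann$start[j] & mids < ann$end[j])
  }, numeric(1))
  gof <- stats::chisq.test(obs, p = exp_frac)
  expect_gt(gof$p.value, 0.001)
})

test_that("turnover simulation boosts Flag near the TSS and obeys the null", {
  g <- make_genome(60, law = "stratified", seed = 12)
  truth <- synthetic_truth(5, turnover_params = list(tss_boost = 2,
                                                     decay_bp = 200))
  n <- 3e4
  s <- simulate_turnover(truth, g$target, n, "wt")
  expect_identical(
    as.data.frame(simulate_turnover(truth, g$target, n, "wt")$flag),
    as.data.frame(s$flag))
  ann <- g$target
  flag <- normalize_rpm(coverage_from_fragments(s$flag, ann), n)
  myc <- normalize_rpm(coverage_from_fragments(s$myc, ann), n)
  # mean Flag/Myc over the first 10% of gene bodies vs the central fifth
  first <- genome_annotation(
    transform(as.data.frame(ann),
              end = ifelse(strand == "+", start + pmax(100, 0.1 * (end - start)), end),
              start = ifelse(strand == "+", start, end - pmax(100, 0.1 * (end - start)))),
    chrom_sizes(ann))
  centr <- {
    w <- center_window(ann, 0.4)
    genome_annotation(data.frame(gene_id = w$gene_id, chrom = w$chrom,
                                 start = w$win_start, end = w$win_end,
                                 strand = ann$strand), chrom_sizes(ann))
  }
  ratio_head <- turnover_score(flag, myc, first)$turnover
  ratio_mid <- turnover_score(flag, myc, centr)$turnover
  expect_gt(mean(ratio_head), mean(ratio_mid) + 0.5)

  # longgene_delta = 0: conditions statistically indistinguishable
  mut <- simulate_turnover(truth, g$target, n, "mut")
  ctw <- center_turnover(s$flag, s$myc, ann, total_flag = n, total_myc = n)
  ctm <- center_turnover(mut$flag, mut$myc, ann, total_flag = n, total_myc = n)
  p <- group_compare(ctm$center_turnover, ctw$center_turnover)$p.value
  expect_gt(p, 0.01)
})

test_that("ATAC libraries are bimodal in length and seed-deterministic", {
  g <- make_genome(50, seed = 13)
  truth <- synthetic_truth(6)
  fr <- simulate_atac(truth, g$target, 1e5, "wt")
  expect_identical(as.data.frame(simulate_atac(truth, g$target, 1e5, "wt")),
                   as.data.frame(fr))
  len <- fragment_lengths(fr)
  h <- hist(len, breaks = seq(0, max(len) + 10, by = 10), plot = FALSE)
  dens <- h$counts
  mid <- h$mids
  # local modes near the two component means
  expect_lt(abs(mid[which.max(dens * (mid < 100))] - 60), 15)
  expect_lt(abs(mid[which.max(dens * (mid >= 100))] - 160), 15)
  # subnucleosomal fraction close to the design value
  expect_lt(abs(mean(len < 100) - truth$atac_params$sub_frac), 0.05)

  none <- synthetic_truth(6, atac_params = list(sub_frac = 0))
  fr0 <- simulate_atac(none, g$target, 1e4, "wt")
  expect_warning(sub0 <- filter_subnucleosomal(fr0), "empty")
  expect_equal(nrow(sub0), 0L)
})

test_that("a null ATAC contrast classifies essentially all genes steady", {
  g <- make_genome(50, seed = 14)
  truth <- synthetic_truth(7)
  n <- 5e5
  wt <- filter_subnucleosomal(simulate_atac(truth, g$target, n, "wt"))
  mut <- filter_subnucleosomal(simulate_atac(truth, g$target, n, "mut"))
  mk <- function(fs) normalize_rpm(coverage_from_fragments(fs, g$target), n)
  fc <- gene_accessibility_log2fc(mk(mut), mk(wt), g$target)
  calls <- classify_accessibility(fc)
  expect_gt(mean(calls$call == "steady"), 0.95)
})
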