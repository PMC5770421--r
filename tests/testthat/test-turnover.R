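test_that("exchange score is 0 on identity and antisymmetric on swap", {
  ann <- toy_ann()
  flag <- random_track(seed = 31)
  myc <- random_track(seed = 32)
  same <- turnover_score(flag, flag, ann)
  expect_equal(same$turnover, rep(0, 3))
  fm <- turnover_score(flag, myc, ann)
  mf <- turnover_score(myc, flag, ann)
  expect_equal(fm$turnover, -mf$turnover)
  # forced arithmetic: myc 0, flag 1, pseudocount 1 -> log2(2/1) = 1
  sizes <- c(chrA = 1000)
  one <- binned_track(list(chrA = rep(1, 20)), 50, sizes, "rpm")
  zero <- binned_track(list(chrA = rep(0, 20)), 50, sizes, "rpm")
  g1 <- genome_annotation(
    data.frame(gene_id = "g", chrom = "chrA", start = 0, end = 1000,
               strand = "+"), sizes)
  expect_equal(turnover_score(one, zero, g1, pseudocount = 1)$turnover, 1)
})

test_that("length clusters partition genes with right-closed boundaries", {
  sizes <- c(chrA = 30000)
  len <- c(2500, 2000, 2001, 1000, 501, 500, 400)
  start <- seq(0, by = 4000, length.out = length(len))
  ann <- genome_annotation(
    data.frame(gene_id = paste0("g", seq_along(len)), chrom = "chrA",
               start = start, end = start + len, strand = "+"), sizes)
  cl <- length_clusters(ann)
  expect_equal(as.character(cl$length_cluster),
               c("gt2kb", "kb1to2", "gt2kb", "kb05to1", "kb05to1",
                 "unassigned", "unassigned"))
  # every gene gets exactly one label, driven by length only
  expect_false(anyNA(cl$length_cluster))
  expect_equal(nrow(cl), length(len))
})

test_that("center windows drop the requested fraction from both ends", {
  sizes <- c(chrA = 10000)
  ann <- genome_annotation(
    data.frame(gene_id = c("a", "b"), chrom = "chrA",
               start = c(0, 5000), end = c(4000, 5200),
               strand = c("+", "-")), sizes)
  win <- center_window(ann, 0.25)
  expect_equal(win$win_start, c(1000, 5050))
  expect_equal(win$win_end, c(3000, 5150))
  expect_error(center_window(ann, 0.5), "0.5")
})

test_that("RPKM matches direct evaluation of the formula", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1234, 5e6), 0)
  withr::with_seed(37, {
    rc <- sample(0:1e4, 1000, replace = TRUE)
    len <- sample(100:10000, 1000, replace = TRUE)
    tot <- sample(1e5:1e8, 1000, replace = TRUE)
  })
  expect_identical(rpkm(rc, len, tot), rc * 1e9 / (as.numeric(len) * tot))
  expect_error(rpkm(10, 0, 1e6), "length_bp")
  expect_error(rpkm(10, 100, 0), "total_mapped")
})

test_that("window counting uses fragment midpoints", {
  fr <- fragment_set(tibble::tibble(
    chrom = "chrA", start = c(0, 90, 200, 395), end = c(100, 110, 300, 405)))
  win <- tibble::tibble(gene_id = "g", chrom = "chrA",
                        win_start = 50, win_end = 260)
  # midpoints 50, 100, 250, 400 -> three inside [50, 260)
  expect_equal(count_in_windows(fr, win)$n, 3L)
})

test_that("quantile stratification splits by rank with deterministic ties", {
  v <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                      value = c(5, 1, 9, 3))
  s <- stratify_genes(v, "quantile", k = 2)
  expect_equal(s$group[match(c("b", "d"), s$gene_id)], c("q1", "q1"))
  expect_equal(s$group[match(c("a", "c"), s$gene_id)], c("q2", "q2"))
  # all-equal values: split follows input order
  tie <- tibble::tibble(gene_id = c("a", "b", "c", "d"), value = 1)
  st <- stratify_genes(tie, "quantile", k = 2)
  expect_equal(st$group, c("q1", "q1", "q2", "q2"))
  expect_error(stratify_genes(tie, "quantile", k = 5), "exceeds")
  # threshold mode, right-closed
  th <- stratify_genes(tibble::tibble(gene_id = c("x", "y", "z"),
                                      value = c(1, 2, 3)),
                       "threshold", cuts = 2)
  expect_equal(th$group, c("t1", "t1", "t2"))
})

test_that("rank-sum test matches exhaustive enumeration on small groups", {
  # forced example: {1,2} vs {3,4} has U = 0 and p = 2/6
  g <- group_compare(c(1, 2), c(3, 4))
  expect_equal(g$statistic, 0)
  expect_equal(g$p.value, 1 / 3)
  # random small groups, with and without ties
  withr::with_seed(41, {
    for (i in 1:25) {
      m <- sample(2:4, 1); n <- sample(2:4, 1)
      a <- sample(1:5, m, replace = TRUE)
      b <- sample(1:5, n, replace = TRUE)
      expect_equal(group_compare(a, b)$p.value, enumerate_rank_p(a, b))
    }
  })
  # untied case cross-checked against the exact Wilcoxon distribution
  a <- c(1.1, 3.7, 5.2); b <- c(2.4, 6.9, 8.1, 9.3)
  expect_equal(group_compare(a, b)$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("rank-sum test behaves at the null and under large shifts", {
  x <- c(1, 2, 2, 5)
  expect_gte(group_compare(x, x)$p.value, 0.99)
  withr::with_seed(43, b <- rnorm(200))
  g <- group_compare(b + 10, b)
  expect_lt(g$p.value, 1e-10)
  expect_match(g$method, "normal approximation")
  expect_error(group_compare(1, c(1, 2)), "at least 2")
  td <- tidy(g); gl <- glance(g)
  expect_equal(td$p.value, g$p.value)
  expect_equal(gl$n_a, 200L)
})

test_that("count-based center turnover recovers a known density ratio", {
  sizes <- c(chrA = 40000)
  starts <- seq(0, by = 4000, length.out = 10)
  ann <- genome_annotation(
    data.frame(gene_id = paste0("g", 1:10), chrom = "chrA",
               start = starts, end = starts + 2000, strand = "+"), sizes)
  # Flag density 4x Myc density everywhere, equal library sizes
  mk <- function(per_gene) {
    pos <- unlist(lapply(starts, function(s) {
      seq(s, s + 1999, length.out = per_gene)
    }))
    fragment_set(tibble::tibble(chrom = "chrA", start = floor(pos),
                                end = floor(pos) + 1))
  }
  flag <- mk(400); myc <- mk(100)
  ct <- center_turnover(flag, myc, ann, pseudocount = 1e-6,
                        total_flag = 4000, total_myc = 4000)
  expect_equal(ct$center_turnover, rep(2, 10), tolerance = 1e-2)
})

test_that("the gene statistics table joins clusters, scores and centers", {
  ann <- toy_ann()
  flag <- random_track(seed = 51)
  myc <- random_track(seed = 52)
  fr <- random_fragments(300, seed = 53)
  tab <- gene_stat_table(ann, flag, myc, flag_frags = fr, myc_frags = fr)
  expect_setequal(tab$gene_id, ann$gene_id)
  expect_true(all(c("length_bp", "length_cluster", "turnover",
                    "center_turnover") %in% names(tab)))
  expect_equal(tab$center_turnover, rep(0, 3))  # same fragments both roles
})
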