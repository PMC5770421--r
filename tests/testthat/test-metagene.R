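test_that("a constant track gives the constant inside genes, 0 beyond TES", {
  ann <- toy_ann()  # plus1k is 1000 bp on + strand
  tr <- const_track(4)
  m <- tss_anchored_matrix(tr, ann, extent = 2000, bin_width = 100)
  row <- m$values["plus1k", ]
  expect_equal(unname(row), c(rep(4, 10), rep(0, 10)))
  # masking is exact, not approximate
  expect_identical(unname(row[11:20]), rep(0, 20 - 10))
  # genes longer than the extent are all-constant
  expect_equal(unname(m$values["minus3k", ]), rep(4, 20))
})

test_that("minus-strand rows read the genomic profile in reverse", {
  sizes <- c(chrA = 10000)
  ann <- genome_annotation(
    data.frame(gene_id = "gm", chrom = "chrA", start = 5000, end = 8000,
               strand = "-"), sizes)
  v <- numeric(200); v[101:160] <- seq_len(60)  # rising over [5000, 8000)
  tr <- binned_track(list(chrA = v), 50, sizes, "rpm")
  m <- tss_anchored_matrix(tr, ann, extent = 1000, bin_width = 50)
  expect_equal(unname(m$values["gm", ]), seq(60, 41))
})

test_that("row ordering follows the requested sort key", {
  sizes <- c(chrA = 20000)
  ann <- genome_annotation(
    data.frame(gene_id = c("a", "b", "c"), chrom = "chrA",
               start = c(0, 4000, 6000), end = c(3000, 4500, 7500),
               strand = "+"), sizes)
  tr <- const_track(1, sizes = sizes)
  m <- tss_anchored_matrix(tr, ann, 2000, 100, sort_key = "length_asc")
  expect_equal(m$gene_ids, c("b", "c", "a"))  # lengths 500, 1500, 3000

  vals <- numeric(400); vals[1:60] <- 9      # gene a has the top signal
  tr2 <- binned_track(list(chrA = vals), 50, c(chrA = 20000), "rpm")
  m2 <- tss_anchored_matrix(tr2, ann, 2000, 100, sort_key = "signal_desc")
  expect_equal(m2$gene_ids[1], "a")
})

test_that("mirroring the genome and flipping strands leaves rows unchanged", {
  size <- 10000
  ann <- genome_annotation(
    data.frame(gene_id = c("g1", "g2"), chrom = "chrA",
               start = c(1000, 6000), end = c(2500, 9000),
               strand = c("+", "-")), c(chrA = size))
  withr::with_seed(21, v <- runif(200, 0, 5))
  tr <- binned_track(list(chrA = v), 50, c(chrA = size), "rpm")
  mirror_ann <- genome_annotation(
    data.frame(gene_id = c("g1", "g2"), chrom = "chrA",
               start = size - c(2500, 9000), end = size - c(1000, 6000),
               strand = c("-", "+")), c(chrA = size))
  tr_m <- binned_track(list(chrA = rev(v)), 50, c(chrA = size), "rpm")
  m1 <- tss_anchored_matrix(tr, ann, 2000, 50)
  m2 <- tss_anchored_matrix(tr_m, mirror_ann, 2000, 50)
  expect_equal(m1$values, m2$values)
})

test_that("beyond-TES masking is exact for random tracks", {
  ann <- toy_ann()
  tr <- random_track(seed = 13)
  m <- tss_anchored_matrix(tr, ann, extent = 2000, bin_width = 50)
  d <- (seq_len(ncol(m$values)) - 0.5) * 50
  for (g in ann$gene_id) {
    len <- ann$end[ann$gene_id == g] - ann$start[ann$gene_id == g]
    expect_identical(unname(m$values[g, d >= len]),
                     rep(0, sum(d >= len)))
    expect_true(all(m$values[g, d < len] > 0))
  }
})

test_that("TSS panel equals the matrix column means exactly", {
  ann <- toy_ann()
  tr <- random_track(seed = 17)
  m <- tss_anchored_matrix(tr, ann, 2000, 50)
  prof <- two_anchor_profile(tr, ann, 2000, 50)
  expect_identical(prof$value[prof$panel == "TSS"],
                   unname(colMeans(m$values)))
})

test_that("two-anchor panels match a naive per-gene loop on many genes", {
  g <- make_genome(100, seed = 19)
  ann <- g$target
  tr <- random_track(seed = 19, sizes = chrom_sizes(ann))
  extent <- 2000; bw <- 50
  prof <- two_anchor_profile(tr, ann, extent, bw)

  vals <- split(tr$value, factor(tr$chrom, levels = names(chrom_sizes(ann))))
  nb <- extent / bw
  tss_m <- matrix(0, nrow(ann), nb)
  tes_m <- matrix(0, nrow(ann), nb)
  for (i in seq_len(nrow(ann))) {
    len <- ann$end[i] - ann$start[i]
    v <- vals[[ann$chrom[i]]]
    for (j in seq_len(nb)) {
      d <- (j - 0.5) * bw
      if (d < len) {
        pos <- if (ann$strand[i] == "+") ann$start[i] + d else ann$end[i] - d
        tss_m[i, j] <- v[floor(pos / bw) + 1]
      }
      dup <- extent - d  # distance upstream of the TES
      if (dup < len) {
        dd <- len - dup
        pos <- if (ann$strand[i] == "+") ann$start[i] + dd else ann$end[i] - dd
        tes_m[i, j] <- v[floor(pos / bw) + 1]
      }
    }
  }
  expect_equal(prof$value[prof$panel == "TSS"], colMeans(tss_m))
  expect_equal(prof$value[prof$panel == "TES"], colMeans(tes_m))
})

test_that("constant track yields flat panels when genes exceed the extent", {
  sizes <- c(chrA = 20000)
  ann <- genome_annotation(
    data.frame(gene_id = c("long1", "long2"), chrom = "chrA",
               start = c(1000, 10000), end = c(6000, 16000),
               strand = c("+", "-")), sizes)
  prof <- two_anchor_profile(const_track(3, sizes = sizes), ann, 2000, 50)
  expect_equal(prof$value, rep(3, 80))
})

test_that("gene-body means agree with a brute-force oracle", {
  tr <- random_track(seed = 23)
  expect_equal(gene_body_mean(const_track(7), "chrA", 1000, 2000), 7)
  # half 0 / half 4
  sizes <- c(chrA = 1000)
  half <- binned_track(list(chrA = rep(c(0, 4), each = 10)), 50, sizes, "rpm")
  expect_equal(gene_body_mean(half, "chrA", 0, 1000), 2)
  # oracle: bins with centers inside the gene
  ann <- toy_ann()
  v <- split(tr$value, factor(tr$chrom, levels = names(toy_sizes)))
  for (i in seq_len(nrow(ann))) {
    centers <- (seq_along(v[[ann$chrom[i]]]) - 0.5) * 50
    keep <- centers >= ann$start[i] & centers < ann$end[i]
    expect_equal(gene_body_mean(tr, ann$chrom[i], ann$start[i], ann$end[i]),
                 mean(v[[ann$chrom[i]]][keep]))
  }
  expect_error(gene_body_mean(tr, "chrA", 100, 110), "no bin center")
})

test_that("metagene matrices tidy and export to TSV", {
  ann <- toy_ann()
  m <- tss_anchored_matrix(const_track(2), ann, 1000, 50)
  td <- tidy(m)
  expect_equal(nrow(td), 3 * 20)
  expect_s3_class(autoplot(m), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metagene_tsv(m, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$gene_id, m$gene_ids)
  expect_equal(unname(as.matrix(back[, -1])), unname(m$values))
})
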