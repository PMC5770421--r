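# small in-code fixtures shared across tests

toy_sizes <- c(chrA = 10000, chrB = 6000)

toy_ann <- function() {
  genome_annotation(
    data.frame(
      gene_id = c("plus1k", "minus3k", "shortB"),
      chrom = c("chrA", "chrA", "chrB"),
      start = c(1000, 5000, 500),
      end = c(2000, 8000, 1200),
      strand = c("+", "-", "+")
    ),
    toy_sizes
  )
}

const_track <- function(value = 4, bw = 50, sizes = toy_sizes,
                        state = "rpm") {
  vals <- lapply(sizes, function(s) rep(value, ceiling(s / bw)))
  binned_track(vals, bw, sizes, norm_state = state, sample_id = "const")
}

random_track <- function(seed = 1, bw = 50, sizes = toy_sizes,
                         state = "rpm") {
  withr::with_seed(seed, {
    vals <- lapply(sizes, function(s) runif(ceiling(s / bw), 0, 10))
  })
  binned_track(vals, bw, sizes, norm_state = state, sample_id = "rand")
}

random_fragments <- function(n = 500, seed = 1, sizes = toy_sizes,
                             width = 150) {
  withr::with_seed(seed, {
    chrom <- sample(names(sizes), n, replace = TRUE)
    start <- floor(runif(n, 0, sizes[chrom] - width))
  })
  fragment_set(tibble::tibble(chrom = chrom, start = start,
                              end = start + width),
               sample_id = "randfrags")
}

# independent brute-force oracle: two-sided permutation p-value of the
# rank-sum statistic, by explicit enumeration of all group assignments
enumerate_rank_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  mu <- m * (length(pooled) + 1) / 2
  obs <- sum(r[seq_len(m)])
  idx <- utils::combn(length(pooled), m)
  sums <- apply(idx, 2, function(j) sum(r[j]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
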