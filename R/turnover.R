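#' Histone exchange score per gene
#'
#' Replication-independent histone exchange is assayed by chasing an
#' inducible Flag-tagged histone against a constitutive Myc-tagged one; the
#' per-gene score is
#' `log2((mean Flag over the gene + pseudocount) / (mean Myc + pseudocount))`
#' on rpm-normalized tracks, so sequencing depths of the two libraries
#' cancel. Swapping Flag and Myc negates every score.
#'
#' @param flag,myc rpm-normalized [binned_track]s on the same grid.
#' @param ann A [genome_annotation].
#' @param pseudocount Positive pseudocount in rpm units (default 0.1).
#' @return Tibble with columns `gene_id`, `flag_mean`, `myc_mean`,
#'   `turnover`.
#' @export
turnover_score <- function(flag, myc, ann, pseudocount = 0.1) {
  if (!same_grid(flag, myc)) abort("Flag and Myc tracks are on different grids.")
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  f <- gene_body_means(flag, ann)
  m <- gene_body_means(myc, ann)
  tibble(gene_id = ann$gene_id,
         flag_mean = f$mean_signal,
         myc_mean = m$mean_signal,
         turnover = log2((f$mean_signal + pseudocount) /
                           (m$mean_signal + pseudocount)))
}

#' Per-bin histone exchange track
#'
#' The same log2 Flag/Myc statistic computed bin-wise, for heatmaps.
#'
#' @inheritParams turnover_score
#' @return A `log2ratio` [binned_track].
#' @export
turnover_track <- function(flag, myc, pseudocount = 0.1) {
  compare_tracks(flag, myc, scale_a = 1, pseudocount = pseudocount)
}

#' Gene-length clusters
#'
#' Assigns every gene to one of the analysis strata `>2 kb`, `1-2 kb`,
#' `0.5-1 kb`, with genes of 0.5 kb or less labelled `unassigned` and
#' excluded from cluster analyses. Boundaries are left-open/right-closed:
#' a 2000 bp gene falls in `kb1to2`.
#'
#' @param ann A [genome_annotation].
#' @param cuts Increasing length cut points in bp (default
#'   `c(500, 1000, 2000)`).
#' @return Tibble with columns `gene_id`, `length_bp`, `length_cluster`
#'   (factor with levels `unassigned`, `kb05to1`, `kb1to2`, `gt2kb`).
#' @export
length_clusters <- function(ann, cuts = c(500, 1000, 2000)) {
  if (length(cuts) != 3 || is.unsorted(cuts, strictly = TRUE)) {
    abort("`cuts` must be three strictly increasing lengths.")
  }
  len <- ann$end - ann$start
  cl <- cut(len, breaks = c(-Inf, cuts, Inf),
            labels = c("unassigned", "kb05to1", "kb1to2", "gt2kb"),
            right = TRUE)
  tibble(gene_id = ann$gene_id, length_bp = len, length_cluster = cl)
}

#' Center window of a transcribed region
#'
#' Drops a fraction of the gene length from each end, keeping the central
#' portion `[start + f*L, end - f*L)`; strand-independent in genomic
#' coordinates. Used to score histone turnover away from the 5' and 3'
#' ends, where exchange is dominated by promoter dynamics.
#'
#' @param ann A [genome_annotation].
#' @param exclude_fraction Fraction of the length excluded per end, in
#'   (0, 0.5) (default 0.25).
#' @return Tibble with columns `gene_id`, `chrom`, `win_start`, `win_end`.
#' @export
center_window <- function(ann, exclude_fraction = 0.25) {
  assert_scalar_number(exclude_fraction, "exclude_fraction", positive = TRUE)
  if (exclude_fraction >= 0.5) {
    abort("`exclude_fraction` must be < 0.5 (the window would be empty).")
  }
  len <- ann$end - ann$start
  ws <- floor(ann$start + exclude_fraction * len)
  we <- ceiling(ann$end - exclude_fraction * len)
  if (any(we <= ws)) {
    abort(sprintf("empty center window for gene(s): %s",
                  paste(head(ann$gene_id[we <= ws], 5L), collapse = ", ")))
  }
  tibble(gene_id = ann$gene_id, chrom = ann$chrom,
         win_start = ws, win_end = we)
}

#' Reads per kilobase per million (RPKM)
#'
#' `read_count * 1e9 / (length_bp * total_mapped)` — reads mapped to a
#' region, scaled by region length in kb and library size in millions.
#' Vectorized over all three arguments.
#'
#' @param read_count Number of reads (fragments) mapped to the region.
#' @param length_bp Region length in bp (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(read_count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) abort("`length_bp` must be > 0.")
  if (any(total_mapped <= 0)) abort("`total_mapped` must be > 0.")
  if (any(read_count < 0)) abort("`read_count` must be >= 0.")
  read_count * 1e9 / (as.numeric(length_bp) * total_mapped)
}

#' Count fragments whose midpoints fall in windows
#'
#' @param frags A [fragment_set].
#' @param windows Tibble with columns `gene_id`, `chrom`, `win_start`,
#'   `win_end` (as from [center_window()]).
#' @return Tibble with columns `gene_id`, `n`.
#' @export
count_in_windows <- function(frags, windows) {
  mids <- split((frags$start + frags$end) %/% 2, frags$chrom)
  mids <- lapply(mids, sort)
  n <- vapply(seq_len(nrow(windows)), function(i) {
    m <- mids[[windows$chrom[i]]]
    if (is.null(m)) return(0L)
    # midpoints in [win_start, win_end): counts via sorted search
    hi <- findInterval(windows$win_end[i] - 0.5, m)
    lo <- findInterval(windows$win_start[i] - 0.5, m)
    hi - lo
  }, integer(1))
  tibble(gene_id = windows$gene_id, n = as.integer(n))
}

#' Center-of-gene histone turnover from fragment counts
#'
#' RPKM of Flag and Myc fragments within each gene's center window (the
#' printed RPKM formula, with the window length as the region length), and
#' the turnover score `log2((rpkm_flag + p) / (rpkm_myc + p))`.
#'
#' @param flag_frags,myc_frags [fragment_set]s of the two libraries.
#' @param ann A [genome_annotation].
#' @param exclude_fraction Passed to [center_window()].
#' @param pseudocount Pseudocount in RPKM units (default 0.1).
#' @param total_flag,total_myc Library sizes used in the RPKM denominator;
#'   default to the realized fragment counts. Pass the calibrated design
#'   depth when libraries were sequenced to a known common scale.
#' @return Tibble: `gene_id`, `center_rpkm_flag`, `center_rpkm_myc`,
#'   `center_turnover`.
#' @export
center_turnover <- function(flag_frags, myc_frags, ann,
                            exclude_fraction = 0.25, pseudocount = 0.1,
                            total_flag = nrow(flag_frags),
                            total_myc = nrow(myc_frags)) {
  win <- center_window(ann, exclude_fraction)
  cf <- count_in_windows(flag_frags, win)
  cm <- count_in_windows(myc_frags, win)
  wlen <- win$win_end - win$win_start
  rf <- rpkm(cf$n, wlen, total_flag)
  rm_ <- rpkm(cm$n, wlen, total_myc)
  tibble(gene_id = win$gene_id,
         center_rpkm_flag = rf, center_rpkm_myc = rm_,
         center_turnover = log2((rf + pseudocount) / (rm_ + pseudocount)))
}

#' Stratify genes by a per-gene value
#'
#' `mode = "quantile"` splits the ranked genes into `k` groups of (near)
#' equal size, lowest values first (`q1`), ties broken by gene order;
#' `mode = "threshold"` bins by user cut points, right-closed.
#'
#' @param values Tibble with columns `gene_id` and `value` (or a named
#'   numeric vector).
#' @param mode `"quantile"` or `"threshold"`.
#' @param k Number of quantile groups.
#' @param cuts Increasing numeric cut points for threshold mode; groups are
#'   `(-Inf, c1], (c1, c2], ...` labelled `t1..t(k+1)`.
#' @return Tibble with columns `gene_id`, `value`, `group`.
#' @export
stratify_genes <- function(values, mode = c("quantile", "threshold"),
                           k = 3, cuts = NULL) {
  mode <- arg_match(mode)
  if (!is.data.frame(values)) {
    values <- tibble(gene_id = names(values), value = as.numeric(values))
  }
  if (!nrow(values)) abort("`values` is empty.")
  if (mode == "quantile") {
    assert_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
    if (k > nrow(values)) abort("`k` exceeds the number of genes.")
    ord <- order(values$value, seq_len(nrow(values)))
    grp <- integer(nrow(values))
    grp[ord] <- as.integer(ceiling(seq_len(nrow(values)) * k / nrow(values)))
    out <- values
    out$group <- paste0("q", grp)
  } else {
    if (is.null(cuts) || is.unsorted(cuts, strictly = TRUE)) {
      abort("threshold mode needs strictly increasing `cuts`.")
    }
    out <- values
    out$group <- paste0("t", findInterval(values$value, cuts,
                                          left.open = TRUE) + 1L)
  }
  out
}

#' Rank-based comparison of two groups (Mann-Whitney / Wilcoxon rank sum)
#'
#' Two-sided test that the two samples come from the same distribution.
#' For small samples the exact permutation null of the rank sum (with
#' average ranks under ties) is enumerated; for larger samples the normal
#' approximation with tie correction of [stats::wilcox.test()] is used.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default enumerates when `choose(length(a) + length(b), length(a))`
#'   is at most 100000.
#' @return Object of class `rank_sum_test`: a list with `statistic` (the
#'   Mann-Whitney U of `a`), `rank_sum`, `p.value`, `n_a`, `n_b`, `method`.
#' @export
group_compare <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("both groups need at least 2 observations.")
  }
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)])
  u_obs <- w_obs - m * (m + 1) / 2
  use_exact <- exact %||% (choose(N, m) <= 1e5)
  if (use_exact) {
    mu <- m * (N + 1) / 2
    sums <- utils::combn(r, m, sum)
    p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact rank-sum permutation"
  } else {
    p <- stats::wilcox.test(a, b, alternative = "two.sided",
                            exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u_obs, rank_sum = w_obs, p.value = p,
                 n_a = m, n_b = n, method = method),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\nU = %g, W = %g, n = %d/%d, p = %.4g\n",
              x$method, x$statistic, x$rank_sum, x$n_a, x$n_b, x$p.value))
  invisible(x)
}

#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, rank_sum = x$rank_sum,
         p.value = x$p.value, method = x$method)
}

#' @method glance rank_sum_test
#' @export
glance.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n_a = x$n_a, n_b = x$n_b)
}

#' Assemble the per-gene statistics table
#'
#' Joins gene length, length cluster, gene-body turnover and
#' center-of-gene turnover into one table, one row per gene.
#'
#' @param ann A [genome_annotation].
#' @param flag,myc rpm-normalized [binned_track]s.
#' @param flag_frags,myc_frags [fragment_set]s for the count-based center
#'   RPKM (optional; center columns are omitted when absent).
#' @inheritParams center_turnover
#' @inheritParams turnover_score
#' @return Tibble keyed by `gene_id`.
#' @export
gene_stat_table <- function(ann, flag, myc, flag_frags = NULL,
                            myc_frags = NULL, exclude_fraction = 0.25,
                            pseudocount = 0.1,
                            total_flag = NULL, total_myc = NULL) {
  out <- length_clusters(ann) %>%
    left_join(turnover_score(flag, myc, ann, pseudocount), by = "gene_id")
  if (!is.null(flag_frags) && !is.null(myc_frags)) {
    ct <- center_turnover(flag_frags, myc_frags, ann,
                          exclude_fraction = exclude_fraction,
                          pseudocount = pseudocount,
                          total_flag = total_flag %||% nrow(flag_frags),
                          total_myc = total_myc %||% nrow(myc_frags))
    out <- left_join(out, ct, by = "gene_id")
  }
  out
}
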