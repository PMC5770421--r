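#' Fragment lengths of a fragment set
#' @param frags A [fragment_set].
#' @return Integer vector `end - start`.
#' @export
fragment_lengths <- function(frags) {
  as.integer(frags$end - frags$start)
}

#' Keep subnucleosomal ATAC fragments
#'
#' Retains fragments strictly shorter than `cutoff` bp (default 100 bp, the
#' conventional bound below a nucleosome footprint); these report accessible
#' DNA. Length is the interval span `end - start`; no transposase offset
#' correction is applied.
#'
#' @param frags A [fragment_set].
#' @param cutoff Strict upper bound on fragment length in bp.
#' @return A [fragment_set]; an empty result triggers a warning, not an
#'   error.
#' @export
filter_subnucleosomal <- function(frags, cutoff = 100) {
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  keep <- fragment_lengths(frags) < cutoff
  out <- frags[keep, ]
  attr(out, "sample_id") <- sample_id(frags)
  class(out) <- class(frags)
  if (!nrow(out)) {
    warn(sprintf("no fragment shorter than %d bp; empty set returned.", cutoff))
  }
  out
}

#' Per-gene accessibility log2 fold change
#'
#' Mean subnucleosomal signal over each transcribed region in mutant and
#' wild type, compared as `log2((mut + p) / (wt + p))`.
#'
#' @param mut,wt rpm-normalized [binned_track]s built from subnucleosomal
#'   fragments, on the same grid.
#' @param ann A [genome_annotation].
#' @param pseudocount Positive pseudocount in rpm units (default 0.1).
#' @return Tibble with columns `gene_id`, `mut_mean`, `wt_mean`, `log2fc`.
#' @export
gene_accessibility_log2fc <- function(mut, wt, ann, pseudocount = 0.1) {
  if (!same_grid(mut, wt)) abort("tracks are on different bin grids.")
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  mm <- gene_body_means(mut, ann)
  wm <- gene_body_means(wt, ann)
  tibble(gene_id = ann$gene_id,
         mut_mean = mm$mean_signal, wt_mean = wm$mean_signal,
         log2fc = log2((mm$mean_signal + pseudocount) /
                         (wm$mean_signal + pseudocount)))
}

#' Classify accessibility changes
#'
#' Three-way call per gene: `increased` when `log2fc > threshold`,
#' `decreased` when `log2fc < -threshold`, `steady` otherwise. Values
#' exactly at a boundary are `steady` (the intervals are open).
#'
#' @param log2fc Tibble with columns `gene_id` and `log2fc` (or a named
#'   numeric vector).
#' @param threshold Positive classification threshold (default 0.2).
#' @return Tibble with columns `gene_id`, `log2fc`, `call` (factor with
#'   levels `decreased`, `steady`, `increased`).
#' @export
classify_accessibility <- function(log2fc, threshold = 0.2) {
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  if (!is.data.frame(log2fc)) {
    log2fc <- tibble(gene_id = names(log2fc), log2fc = as.numeric(log2fc))
  }
  call <- factor(
    dplyr::case_when(log2fc$log2fc > threshold ~ "increased",
                     log2fc$log2fc < -threshold ~ "decreased",
                     TRUE ~ "steady"),
    levels = c("decreased", "steady", "increased")
  )
  out <- log2fc[c("gene_id", "log2fc")]
  out$call <- call
  out
}

#' Summarize accessibility calls
#'
#' Counts and percentages per class (the numbers behind a stacked-percent
#' plot). Counts sum to the number of genes; percentages to 100.
#'
#' @param calls Tibble from [classify_accessibility()].
#' @return Tibble with columns `call`, `n`, `pct`.
#' @export
summarize_calls <- function(calls) {
  if (!nrow(calls)) abort("no calls to summarize.")
  tab <- table(calls$call)
  tibble(call = factor(names(tab), levels = names(tab)),
         n = as.integer(tab),
         pct = 100 * as.integer(tab) / nrow(calls))
}
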