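#' TSS-anchored metagene matrix
#'
#' Samples a signal track gene by gene from the TSS downstream (5' to 3',
#' reversed on the genomic axis for `-` strand genes) onto a common distance
#' grid of `extent / bin_width` columns. Positions at distance greater than
#' or equal to the gene length — i.e. beyond the TES — are set to exactly 0,
#' so short genes contribute zeros rather than downstream signal. Rows can
#' be ordered by ascending gene length (heatmap convention) or by descending
#' mean gene-body signal.
#'
#' Column `j` holds the track value at distance `(j - 0.5) * bin_width`
#' from the TSS (bin-center sampling, matching the midpoint coverage
#' convention; a bin straddling the TES is zeroed when its center is beyond
#' it).
#'
#' @param track A [binned_track].
#' @param ann A [genome_annotation]; must be nonempty and on the track's
#'   chromosomes.
#' @param extent Distance covered downstream of the TSS, bp (default 2000).
#' @param bin_width Column width in bp; defaults to the track's bin width.
#' @param sort_key `"none"`, `"length_asc"` or `"signal_desc"`.
#' @return An object of class `metagene_matrix`: a list with `values`
#'   (genes x bins matrix, rownames = gene ids), `gene_ids`, `anchor`,
#'   `bin_width`, `extent`, `sort_key`.
#' @export
tss_anchored_matrix <- function(track, ann, extent = 2000,
                                bin_width = NULL,
                                sort_key = c("none", "length_asc", "signal_desc")) {
  sort_key <- arg_match(sort_key)
  bin_width <- bin_width %||% bin_width(track)
  assert_scalar_number(extent, "extent", positive = TRUE, integerish = TRUE)
  assert_scalar_number(bin_width, "bin_width", positive = TRUE, integerish = TRUE)
  if (extent %% bin_width != 0) {
    abort("`extent` must be a multiple of `bin_width`.")
  }
  if (!nrow(ann)) abort("empty annotation.")
  m <- anchored_values(track, ann, extent, bin_width, anchor = "tss")
  ord <- switch(sort_key,
    none = seq_len(nrow(ann)),
    length_asc = order(ann$end - ann$start, ann$gene_id),
    signal_desc = order(-gene_body_means(track, ann)$mean_signal, ann$gene_id)
  )
  structure(list(values = m[ord, , drop = FALSE],
                 gene_ids = ann$gene_id[ord],
                 anchor = "tss", bin_width = as.integer(bin_width),
                 extent = as.integer(extent), sort_key = sort_key),
            class = "metagene_matrix")
}

# genes x bins matrix of track values sampled at bin centers measured from
# the TSS (anchor = "tss": distances 0..extent downstream) or up to the TES
# (anchor = "tes": distances -extent..0); out-of-gene positions are 0.
anchored_values <- function(track, ann, extent, bin_width, anchor) {
  vals <- track_values(track)
  tw <- bin_width(track)
  ncol <- extent %/% bin_width
  d <- (seq_len(ncol) - 0.5) * bin_width  # distance into the gene, 5'->3'
  len <- ann$end - ann$start
  m <- matrix(0, nrow = nrow(ann), ncol = ncol,
              dimnames = list(ann$gene_id, NULL))
  for (i in seq_len(nrow(ann))) {
    ch <- ann$chrom[i]
    v <- vals[[ch]]
    if (is.null(v)) abort(sprintf("chromosome %s absent from track.", ch))
    if (anchor == "tss") {
      inside <- d < len[i]
      dist <- d[inside]
    } else {
      updist <- extent - d            # distance upstream of the TES
      inside <- updist < len[i]
      dist <- len[i] - updist[inside] # distance from the TSS
    }
    if (!any(inside)) next
    pos <- if (ann$strand[i] == "+") ann$start[i] + dist else ann$end[i] - dist
    idx <- floor(pos / tw) + 1
    m[i, inside] <- v[idx]
  }
  m
}

#' Two-anchor average metagene profile
#'
#' Mean signal across genes on two fixed-distance panels: one anchored at
#' the TSS (positions beyond each gene's TES contribute exactly 0) and one
#' ending at the TES (positions upstream of each gene's TSS contribute 0).
#' Both panels run 5' to 3'. The TSS panel equals the column means of
#' [tss_anchored_matrix()] bit for bit.
#'
#' @inheritParams tss_anchored_matrix
#' @return Tibble of class `metagene_profile` with columns `panel`
#'   (`"TSS"`/`"TES"`), `distance` (bp from the anchor; TES panel distances
#'   are negative, ending at 0) and `value` (mean signal).
#' @export
two_anchor_profile <- function(track, ann, extent = 2000, bin_width = NULL) {
  bin_width <- bin_width %||% bin_width(track)
  if (extent %% bin_width != 0) {
    abort("`extent` must be a multiple of `bin_width`.")
  }
  if (!nrow(ann)) abort("empty annotation.")
  m_tss <- anchored_values(track, ann, extent, bin_width, anchor = "tss")
  m_tes <- anchored_values(track, ann, extent, bin_width, anchor = "tes")
  nb <- extent %/% bin_width
  out <- bind_rows(
    tibble(panel = "TSS", distance = (seq_len(nb) - 0.5) * bin_width,
           value = colMeans(m_tss)),
    tibble(panel = "TES", distance = (seq_len(nb) - 0.5) * bin_width - extent,
           value = colMeans(m_tes))
  )
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Mean signal over one transcribed region
#'
#' Mean of the track bins whose centers lie within `[start, end)`;
#' strand-independent.
#'
#' @param track A [binned_track].
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @return Scalar mean signal.
#' @export
gene_body_mean <- function(track, chrom, start, end) {
  v <- track_values(track)[[chrom]]
  if (is.null(v)) abort(sprintf("chromosome %s absent from track.", chrom))
  bw <- bin_width(track)
  idx <- body_bin_range(start, end, bw, length(v))
  if (is.null(idx)) {
    abort(sprintf("no bin center falls inside [%s, %s).", start, end))
  }
  mean(v[idx[1]:idx[2]])
}

# indices of bins with centers in [start, end); NULL when empty
body_bin_range <- function(start, end, bw, nb) {
  lo <- max(1L, as.integer(ceiling(start / bw + 0.5 - 1e-9)))
  hi <- min(nb, as.integer(ceiling(end / bw + 0.5 - 1e-9)) - 1L)
  if (hi < lo) NULL else c(lo, hi)
}

#' Mean gene-body signal for every gene
#'
#' @param track A [binned_track].
#' @param ann A [genome_annotation].
#' @return Tibble with columns `gene_id`, `mean_signal`.
#' @export
gene_body_means <- function(track, ann) {
  vals <- track_values(track)
  bw <- bin_width(track)
  ms <- vapply(seq_len(nrow(ann)), function(i) {
    v <- vals[[ann$chrom[i]]]
    idx <- body_bin_range(ann$start[i], ann$end[i], bw, length(v))
    if (is.null(idx)) NA_real_ else mean(v[idx[1]:idx[2]])
  }, numeric(1))
  tibble(gene_id = ann$gene_id, mean_signal = ms)
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("<metagene_matrix> %d genes x %d bins (%s-anchored, %d bp bins, sort: %s)\n",
              nrow(x$values), ncol(x$values), x$anchor, x$bin_width, x$sort_key))
  invisible(x)
}

#' Turn a metagene matrix into a long tibble
#'
#' @param x A `metagene_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `row` (display order, 1 = top),
#'   `distance` (bp from the anchor, bin centers), `value`.
#' @method tidy metagene_matrix
#' @export
tidy.metagene_matrix <- function(x, ...) {
  nb <- ncol(x$values)
  tibble(
    gene_id = rep(x$gene_ids, each = nb),
    row = rep(seq_along(x$gene_ids), each = nb),
    distance = rep((seq_len(nb) - 0.5) * x$bin_width, times = length(x$gene_ids)),
    value = as.vector(t(x$values))
  )
}

#' Write a metagene matrix as TSV
#'
#' One row per gene (`gene_id` first column, then one column per distance
#' bin, named by the bin-center distance from the anchor).
#'
#' @param x A `metagene_matrix`.
#' @param path Output path.
#' @export
write_metagene_tsv <- function(x, path) {
  df <- as_tibble(x$values, .name_repair = "minimal")
  names(df) <- as.character((seq_len(ncol(x$values)) - 0.5) * x$bin_width)
  df <- dplyr::bind_cols(tibble(gene_id = x$gene_ids), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
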