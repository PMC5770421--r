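#' Write a binned track as bedGraph
#'
#' Standard four-column bedGraph (chrom, start, end, value), 0-based
#' half-open. Runs of adjacent equal-valued bins are merged into a single
#' record by default; [read_bedgraph()] re-expands them so a write/read
#' round trip reproduces the track bin for bin.
#'
#' @param track A [binned_track].
#' @param path Output path.
#' @param merge Merge adjacent equal-valued bins (default `TRUE`).
#' @export
write_bedgraph <- function(track, path, merge = TRUE) {
  recs <- lapply(names(chrom_sizes(track)), function(ch) {
    sub <- track[track$chrom == ch, ]
    if (!nrow(sub)) return(NULL)
    if (merge) {
      r <- rle(sub$value)
      last <- cumsum(r$lengths)
      first <- last - r$lengths + 1
      tibble(chrom = ch, start = sub$start[first], end = sub$end[last],
             value = r$values)
    } else {
      tibble(chrom = ch, start = sub$start, end = sub$end, value = sub$value)
    }
  })
  df <- bind_rows(recs)
  df$value <- format(df$value, trim = TRUE, digits = 15, scientific = FALSE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph into a binned track
#'
#' Records may span several bins (as written by the merging writer); they
#' are expanded back onto the fixed bin grid. Record boundaries must align
#' with the grid.
#'
#' @param path bedGraph file.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param bin_width Bin width of the grid the file was written from.
#' @param norm_state Normalization state to stamp on the result.
#' @param sample_id Library identifier (defaults to the file name).
#' @return A [binned_track]; bins not covered by any record are 0.
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_width = 50,
                          norm_state = "raw", sample_id = basename(path)) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "cddd", progress = FALSE)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown)) {
    abort(paste0("bedGraph chromosome(s) not in `chrom_sizes`: ",
                 paste(unknown, collapse = ", ")))
  }
  nb <- ceiling(chrom_sizes / bin_width)
  values <- lapply(names(chrom_sizes), function(ch) numeric(nb[[ch]]))
  names(values) <- names(chrom_sizes)
  if (nrow(df)) {
    if (any(df$start %% bin_width != 0)) {
      abort("bedGraph record start not aligned to the bin grid.")
    }
    first <- df$start %/% bin_width + 1
    last <- (df$end - 1) %/% bin_width + 1
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      values[[ch]][first[i]:last[i]] <- df$value[i]
    }
  }
  binned_track(values, bin_width, chrom_sizes, norm_state = norm_state,
               sample_id = sample_id)
}
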