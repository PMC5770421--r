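#' Construct a binned signal track
#'
#' A binned track is a tidy tibble with one row per fixed-width bin
#' (`chrom`, `start`, `end`, `value`), covering every chromosome of
#' `chrom_sizes` completely (the last bin of a chromosome is clipped at the
#' chromosome end). The normalization state (`"raw"`, `"rpm"` or
#' `"log2ratio"`) travels with the track so that scaling steps cannot be
#' applied twice.
#'
#' @param values Named list mapping chromosome to a numeric vector of per-bin
#'   values; each vector must have `ceiling(size / bin_width)` entries.
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param norm_state One of `"raw"`, `"rpm"`, `"log2ratio"`.
#' @param sample_id Library identifier.
#' @return A tibble of class `binned_track` with attributes `bin_width`,
#'   `norm_state`, `sample_id`, `chrom_sizes`.
#' @export
binned_track <- function(values, bin_width, chrom_sizes,
                         norm_state = c("raw", "rpm", "log2ratio"),
                         sample_id = "track") {
  norm_state <- arg_match(norm_state)
  assert_scalar_number(bin_width, "bin_width", positive = TRUE, integerish = TRUE)
  chroms <- names(chrom_sizes)
  if (!setequal(names(values), chroms)) {
    abort("`values` must have exactly one vector per chromosome in `chrom_sizes`.")
  }
  rows <- lapply(chroms, function(ch) {
    nb <- ceiling(chrom_sizes[[ch]] / bin_width)
    v <- values[[ch]]
    if (length(v) != nb) {
      abort(sprintf("chromosome %s: expected %d bins, got %d.", ch, nb, length(v)))
    }
    starts <- (seq_len(nb) - 1) * bin_width
    tibble(chrom = ch, start = starts,
           end = pmin(starts + bin_width, chrom_sizes[[ch]]),
           value = as.numeric(v))
  })
  df <- bind_rows(rows)
  if (norm_state %in% c("raw", "rpm") && any(df$value < 0)) {
    abort(sprintf("%s track values must be nonnegative.", norm_state))
  }
  structure(df, bin_width = as.integer(bin_width), norm_state = norm_state,
            sample_id = sample_id,
            chrom_sizes = setNames(as.numeric(chrom_sizes), names(chrom_sizes)),
            class = c("binned_track", class(tibble())))
}

#' @rdname binned_track
#' @param x A `binned_track`.
#' @export
bin_width <- function(x) attr(x, "bin_width")

#' @rdname binned_track
#' @export
norm_state <- function(x) attr(x, "norm_state")

# per-chromosome value vectors, in bin order
track_values <- function(track) {
  split(track$value, factor(track$chrom, levels = names(chrom_sizes(track))))
}

same_grid <- function(a, b) {
  identical(bin_width(a), bin_width(b)) &&
    identical(names(chrom_sizes(a)), names(chrom_sizes(b))) &&
    isTRUE(all.equal(chrom_sizes(a), chrom_sizes(b))) &&
    nrow(a) == nrow(b)
}

#' Extend fragments to a fixed length
#'
#' Single-end ChIP reads carry no fragment length; before coverage they are
#' extended symmetrically about their midpoint to `length` bp (strand is not
#' recorded in BED3 input, so directional 3' extension is not possible),
#' clipped to chromosome bounds when `chrom_sizes` is given.
#'
#' @param frags A [fragment_set].
#' @param length Target fragment length in bp (default 150).
#' @param chrom_sizes Optional named vector used to clip extended fragments.
#' @return A [fragment_set] with every fragment of width `length` (modulo
#'   clipping at chromosome edges).
#' @export
extend_fragments <- function(frags, length = 150, chrom_sizes = NULL) {
  assert_scalar_number(length, "length", positive = TRUE, integerish = TRUE)
  if (!nrow(frags)) return(frags)
  mid <- (frags$start + frags$end) %/% 2
  start <- pmax(mid - length %/% 2, 0)
  end <- start + length
  if (!is.null(chrom_sizes)) {
    cap <- unname(chrom_sizes[frags$chrom])
    end <- pmin(end, cap)
    start <- pmax(pmin(start, end - 1), 0)
  }
  out <- frags
  out$start <- start
  out$end <- end
  out
}

#' Bin fragment coverage over a genome
#'
#' Each fragment contributes to exactly one bin — the bin containing its
#' midpoint — so the sum over all bins equals the number of fragments placed
#' (coverage conservation). `method = "overlap"` instead spreads each
#' fragment across the bins it overlaps in proportion to the overlap length;
#' totals are still conserved but single-bin attribution is lost.
#'
#' @param frags A [fragment_set]; every fragment chromosome must appear in
#'   the annotation's `chrom_sizes`.
#' @param ann A [genome_annotation] supplying the chromosome sizes (and the
#'   genome label used to select fragments when the set is mixed-species).
#' @param bin_width Bin width in bp (default 50).
#' @param method `"midpoint"` (default) or `"overlap"`.
#' @return A raw [binned_track].
#' @export
coverage_from_fragments <- function(frags, ann, bin_width = 50,
                                    method = c("midpoint", "overlap")) {
  method <- arg_match(method)
  assert_scalar_number(bin_width, "bin_width", positive = TRUE, integerish = TRUE)
  sizes <- chrom_sizes(ann)
  df <- as_tibble(frags)
  lab <- genome_label(ann)
  if (!is.null(lab) && "genome_label" %in% names(df)) {
    keep <- df$genome_label == lab
    # a single-genome fragment file may carry a different label; only filter
    # when the annotation's label is actually present in the set
    if (any(keep)) df <- df[keep, ]
  }
  unknown <- setdiff(unique(df$chrom), names(sizes))
  if (length(unknown)) {
    abort(paste0("fragment chromosome(s) not in annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  nb <- ceiling(sizes / bin_width)
  values <- lapply(names(sizes), function(ch) numeric(nb[[ch]]))
  names(values) <- names(sizes)
  if (nrow(df)) {
    if (method == "midpoint") {
      mid <- (df$start + df$end) %/% 2
      idx <- pmin(mid %/% bin_width + 1, nb[df$chrom])
      for (ch in unique(df$chrom)) {
        sel <- df$chrom == ch
        values[[ch]] <- values[[ch]] +
          tabulate(idx[sel], nbins = nb[[ch]])
      }
    } else {
      for (ch in unique(df$chrom)) {
        sel <- which(df$chrom == ch)
        v <- numeric(nb[[ch]])
        s <- df$start[sel]; e <- pmin(df$end[sel], sizes[[ch]])
        w <- e - s
        first <- s %/% bin_width + 1
        last <- pmin((e - 1) %/% bin_width + 1, nb[[ch]])
        for (k in seq_along(sel)) {
          bins <- first[k]:last[k]
          bs <- (bins - 1) * bin_width
          ov <- pmin(e[k], bs + bin_width) - pmax(s[k], bs)
          v[bins] <- v[bins] + ov / w[k]
        }
        values[[ch]] <- v
      }
    }
  }
  binned_track(values, bin_width, sizes, norm_state = "raw",
               sample_id = sample_id(frags) %||% "coverage")
}

#' Normalize a raw track to reads per million
#'
#' Scales every bin by `1e6 / total_mapped`. Refuses to renormalize an
#' already normalized track.
#'
#' @param track A raw [binned_track].
#' @param total_mapped Total mapped fragment count of the library
#'   (defaults to the sum of the track's bins).
#' @return An `rpm` [binned_track].
#' @export
normalize_rpm <- function(track, total_mapped = sum(track$value)) {
  if (!identical(norm_state(track), "raw")) {
    abort(sprintf("track is already %s-normalized; refusing to normalize twice.",
                  norm_state(track)))
  }
  assert_scalar_number(total_mapped, "total_mapped", positive = TRUE)
  out <- track
  out$value <- track$value * 1e6 / total_mapped
  attr(out, "norm_state") <- "rpm"
  out
}
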