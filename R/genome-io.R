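#' Build a genome annotation from a gene table
#'
#' A genome annotation is a tibble of oriented transcribed regions (one row
#' per gene, BED-style 0-based half-open coordinates) carrying the chromosome
#' sizes and a genome label (e.g. `"target"` for *S. cerevisiae* vs
#' `"spike"` for the *S. pombe* spike-in) as attributes.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`). Coordinates are 0-based half-open.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param genome_label Single string naming the genome.
#' @return A tibble of class `genome_annotation` with attributes
#'   `chrom_sizes` and `genome_label`.
#' @export
genome_annotation <- function(genes, chrom_sizes, genome_label = "target") {
  genes <- as_tibble(genes)
  needed <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    abort(paste0("`genes` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("`chrom_sizes` must be a named vector of chromosome lengths.")
  }
  genes <- genes[needed]
  bad <- which(!(genes$start < genes$end))
  if (length(bad)) {
    abort(sprintf("gene(s) with start >= end at row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  if (any(genes$start < 0)) abort("negative gene start coordinate.")
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown)) {
    abort(paste0("gene chromosome(s) absent from `chrom_sizes`: ",
                 paste(unknown, collapse = ", ")))
  }
  over <- genes$end > chrom_sizes[genes$chrom]
  if (any(over)) {
    abort(sprintf("gene(s) extending past chromosome end: %s",
                  paste(head(genes$gene_id[over], 5L), collapse = ", ")))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup)) {
    abort(paste0("duplicate gene_id(s): ", paste(head(dup, 5L), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("`strand` must be \"+\" or \"-\".")
  }
  structure(genes,
            chrom_sizes = setNames(as.numeric(chrom_sizes), names(chrom_sizes)),
            genome_label = genome_label,
            class = c("genome_annotation", class(tibble())))
}

#' Chromosome sizes of an annotation or track
#' @param x A `genome_annotation` or `binned_track`.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes")

#' Genome label of an annotation
#' @param x A `genome_annotation`.
#' @export
genome_label <- function(x) attr(x, "genome_label")

#' TSS coordinate of each gene
#'
#' With 0-based half-open coordinates the transcription start site is `start`
#' for a `+` strand gene and `end - 1` for a `-` strand gene.
#'
#' @param genes Data frame with `start`, `end`, `strand` columns.
#' @return Integer vector of TSS base positions.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Read chromosome sizes from two-column text
#' @param path Tab-delimited file: chromosome name, length in bp.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  setNames(df$size, df$chrom)
}

#' Read a BED6 gene annotation
#'
#' Expects tab-delimited BED6 (chrom, start, end, name, score, strand);
#' coordinates are taken as 0-based half-open per the BED standard. Lines
#' failing validation are reported with their line numbers.
#'
#' @param path BED6 file path.
#' @inheritParams genome_annotation
#' @return A [genome_annotation] tibble.
#' @export
read_genes_bed <- function(path, chrom_sizes, genome_label = "target") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    abort(sprintf("malformed BED6 line(s) (fewer than 6 fields) at line(s): %s",
                  paste(head(which(nf < 6L), 5L), collapse = ", ")))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("non-numeric coordinates at line(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  genes <- tibble(
    gene_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end,
    strand = vapply(fields, `[[`, "", 6L)
  )
  degenerate <- which(genes$start >= genes$end)
  if (length(degenerate)) {
    abort(sprintf("start >= end at line(s): %s",
                  paste(head(degenerate, 5L), collapse = ", ")))
  }
  genome_annotation(genes, chrom_sizes, genome_label)
}

#' Write a genome annotation as BED6
#' @param ann A [genome_annotation].
#' @param path Output path.
#' @export
write_genes_bed <- function(ann, path) {
  df <- tibble(chrom = ann$chrom, start = ann$start, end = ann$end,
               name = ann$gene_id, score = 0, strand = ann$strand)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write chromosome sizes as two-column text
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  df <- tibble(chrom = names(chrom_sizes), size = chrom_sizes)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Build a fragment set
#'
#' A fragment set is a tibble of aligned fragments (0-based half-open
#' intervals), each attributed to a genome by `genome_label`, with a
#' `sample_id` attribute. Mixed-species spike-in libraries put target and
#' spike fragments in the same set under different labels.
#'
#' @param fragments Data frame with columns `chrom`, `start`, `end` and
#'   optionally `genome_label` (filled with `default_label` if absent).
#' @param sample_id Single string identifying the library.
#' @param default_label Genome label used when the column is absent.
#' @return A tibble of class `fragment_set`.
#' @export
fragment_set <- function(fragments, sample_id = "sample", default_label = "target") {
  fragments <- as_tibble(fragments)
  if (!all(c("chrom", "start", "end") %in% names(fragments))) {
    abort("`fragments` needs columns chrom, start, end.")
  }
  if (!"genome_label" %in% names(fragments)) {
    fragments$genome_label <- rep_len(default_label, nrow(fragments))
  }
  fragments <- fragments[c("chrom", "start", "end", "genome_label")]
  if (nrow(fragments)) {
    if (any(fragments$start < 0)) abort("negative fragment coordinate.")
    if (any(fragments$start >= fragments$end)) {
      abort("fragment with start >= end.")
    }
  }
  structure(fragments, sample_id = sample_id,
            class = c("fragment_set", class(tibble())))
}

#' Sample identifier of a fragment set or track
#' @param x A `fragment_set` or `binned_track`.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Fragment counts per genome
#' @param frags A [fragment_set].
#' @return Tibble with columns `genome_label`, `n`; `n` sums to the total
#'   fragment count.
#' @export
count_by_genome <- function(frags) {
  if (!nrow(frags)) return(tibble(genome_label = character(), n = integer()))
  frags %>%
    as_tibble() %>%
    count(.data$genome_label, name = "n") %>%
    arrange(.data$genome_label)
}

#' Fragment count for one genome label
#' @param frags A [fragment_set].
#' @param label Genome label to count.
#' @return Integer count (0 when the label is absent).
#' @export
genome_count <- function(frags, label) {
  sum(frags$genome_label == label)
}

#' Read aligned fragments from BED3
#'
#' One interval per aligned fragment. An empty file yields an empty set with
#' a warning (not an error); negative coordinates are rejected.
#'
#' @param path BED3 (or wider; only the first three columns are used).
#' @param genome_label Genome the file's fragments are attributed to.
#' @param sample_id Library identifier (defaults to the file name).
#' @return A [fragment_set].
#' @export
read_fragments <- function(path, genome_label = "target",
                           sample_id = basename(path)) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn(sprintf("empty fragment file: %s", path))
    return(fragment_set(tibble(chrom = character(), start = numeric(),
                               end = numeric()),
                        sample_id = sample_id, default_label = genome_label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("malformed BED line(s) at: %s",
                  paste(head(which(nf < 3L), 5L), collapse = ", ")))
  }
  df <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L))
  )
  if (anyNA(df$start) || anyNA(df$end)) abort("non-numeric fragment coordinate.")
  fragment_set(df, sample_id = sample_id, default_label = genome_label)
}

#' Write fragments as BED3
#' @param frags A [fragment_set].
#' @param path Output path.
#' @param label Optional genome label filter; default writes all fragments.
#' @export
write_fragments_bed <- function(frags, path, label = NULL) {
  df <- as_tibble(frags)
  if (!is.null(label)) df <- df[df$genome_label == label, ]
  readr::write_tsv(df[c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
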