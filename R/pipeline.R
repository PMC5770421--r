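#' Pipeline configuration
#'
#' A validated bag of inputs and parameters shared by the recipe runners.
#' Inputs may be in-memory objects ([genome_annotation], [fragment_set],
#' [binned_track]) or file paths (BED6 genes + chrom sizes, BED3 fragments,
#' bedGraph tracks); paths are loaded at run time.
#'
#' @param genes A [genome_annotation] or BED6 path.
#' @param chrom_sizes Named vector or two-column file path (required when
#'   `genes` is a path).
#' @param tracks Named list of [binned_track]s or bedGraph paths.
#' @param fragments Named list of [fragment_set]s or BED3 paths.
#' @param spike_genes Optional spike-genome [genome_annotation].
#' @param bin_width Coverage bin width, bp.
#' @param pseudocount_compare Pseudocount for raw-count track comparison.
#' @param pseudocount Pseudocount for rpm-scale ratios.
#' @param extent Metagene extent per anchor, bp.
#' @param exclude_fraction Center-window exclusion per gene end.
#' @param length_cuts Length-cluster cut points, bp.
#' @param atac_cutoff Strict subnucleosomal length bound, bp.
#' @param atac_threshold Accessibility classification threshold.
#' @param design_depth Calibrated library depth used when rpm-normalizing
#'   depth-matched libraries; `NULL` uses realized totals.
#' @param target_label,spike_label Genome labels in mixed fragment sets.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Output directory; `NULL` returns results without writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes = NULL, chrom_sizes = NULL, tracks = list(),
                            fragments = list(), spike_genes = NULL,
                            bin_width = 50, pseudocount_compare = 1,
                            pseudocount = 0.1, extent = 2000,
                            exclude_fraction = 0.25,
                            length_cuts = c(500, 1000, 2000),
                            atac_cutoff = 100, atac_threshold = 0.2,
                            design_depth = NULL,
                            target_label = "target", spike_label = "spike",
                            seed = 1, out_dir = NULL) {
  structure(list(genes = genes, chrom_sizes = chrom_sizes, tracks = tracks,
                 fragments = fragments, spike_genes = spike_genes,
                 bin_width = bin_width,
                 pseudocount_compare = pseudocount_compare,
                 pseudocount = pseudocount, extent = extent,
                 exclude_fraction = exclude_fraction,
                 length_cuts = length_cuts, atac_cutoff = atac_cutoff,
                 atac_threshold = atac_threshold,
                 design_depth = design_depth, target_label = target_label,
                 spike_label = spike_label, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Collects every failure (missing files, out-of-range parameters, missing
#' inputs for the requested recipe) instead of stopping at the first.
#'
#' @param config A [pipeline_config].
#' @param recipe Recipe name the config is intended for, or `NULL` for the
#'   shared checks only.
#' @return Character vector of failure messages (empty when valid).
#' @export
validate_config <- function(config, recipe = NULL) {
  bad <- character()
  need_path <- function(x, what) {
    if (is.character(x) && !file.exists(x)) {
      sprintf("%s file not found: %s", what, x)
    } else character()
  }
  bad <- c(bad, need_path(config$genes, "genes"))
  bad <- c(bad, need_path(config$chrom_sizes, "chrom sizes"))
  for (nm in names(config$tracks)) {
    bad <- c(bad, need_path(config$tracks[[nm]], paste("track", nm)))
  }
  for (nm in names(config$fragments)) {
    bad <- c(bad, need_path(config$fragments[[nm]], paste("fragments", nm)))
  }
  if (is.character(config$genes) && is.null(config$chrom_sizes)) {
    bad <- c(bad, "`chrom_sizes` is required when `genes` is a file path.")
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) msg else character()
  bad <- c(bad, chk(config$bin_width > 0, "`bin_width` must be > 0."))
  bad <- c(bad, chk(config$pseudocount > 0, "`pseudocount` must be > 0."))
  bad <- c(bad, chk(config$pseudocount_compare > 0,
                    "`pseudocount_compare` must be > 0."))
  bad <- c(bad, chk(config$extent > 0 &&
                      config$extent %% config$bin_width == 0,
                    "`extent` must be a positive multiple of `bin_width`."))
  bad <- c(bad, chk(config$exclude_fraction > 0 && config$exclude_fraction < 0.5,
                    "`exclude_fraction` must be in (0, 0.5)."))
  bad <- c(bad, chk(config$atac_cutoff > 0, "`atac_cutoff` must be > 0."))
  bad <- c(bad, chk(config$atac_threshold > 0, "`atac_threshold` must be > 0."))
  needed <- switch(recipe %||% "none",
    fig1_metagene = list(tracks = "signal", fragments = character()),
    fig3_spikein = list(tracks = character(),
                        fragments = c("ip_mut", "input_mut", "ip_wt", "input_wt")),
    fig5_turnover = list(tracks = character(),
                         fragments = c("flag_wt", "myc_wt", "flag_mut", "myc_mut")),
    fig6_atac = list(tracks = character(), fragments = c("mut", "wt")),
    NULL)
  if (!is.null(needed)) {
    if (is.null(config$genes)) bad <- c(bad, "`genes` is required.")
    mt <- setdiff(needed$tracks, names(config$tracks))
    mf <- setdiff(needed$fragments, names(config$fragments))
    if (length(mt)) bad <- c(bad, paste0("missing track(s): ",
                                         paste(mt, collapse = ", ")))
    if (length(mf)) bad <- c(bad, paste0("missing fragment set(s): ",
                                         paste(mf, collapse = ", ")))
  }
  bad
}

load_genes <- function(config) {
  if (inherits(config$genes, "genome_annotation")) return(config$genes)
  sizes <- if (is.character(config$chrom_sizes)) {
    read_chrom_sizes(config$chrom_sizes)
  } else {
    config$chrom_sizes
  }
  read_genes_bed(config$genes, sizes, genome_label = config$target_label)
}

load_frags <- function(config, name, label = config$target_label) {
  x <- config$fragments[[name]]
  if (inherits(x, "fragment_set")) x else read_fragments(x, genome_label = label)
}

load_track <- function(config, name, sizes, norm_state = "raw") {
  x <- config$tracks[[name]]
  if (inherits(x, "binned_track")) {
    x
  } else {
    read_bedgraph(x, sizes, bin_width = config$bin_width,
                  norm_state = norm_state)
  }
}

write_log <- function(config, recipe, steps, path) {
  params <- config[c("bin_width", "pseudocount", "pseudocount_compare",
                     "extent", "exclude_fraction", "atac_cutoff",
                     "atac_threshold", "seed")]
  lines <- c(
    sprintf("recipe: %s", recipe),
    sprintf("chromexch_version: %s",
            as.character(utils::packageVersion("chromexch"))),
    sprintf("length_cuts: %s", paste(config$length_cuts, collapse = ",")),
    vapply(names(params), function(p) {
      sprintf("%s: %s", p, paste(format(params[[p]]), collapse = ","))
    }, character(1)),
    steps
  )
  writeLines(lines, path)
}

#' Run a figure-level analysis recipe
#'
#' End-to-end deterministic runs of the four analyses:
#' * `fig1_metagene` — TSS-anchored matrix (sorted by ascending length) and
#'   the two-anchor average profile of one signal track.
#' * `fig3_spikein` — spike-in calibration of a mutant/wild-type IP pair:
#'   genome counts, E^IP values, scale factor N, and the calibrated
#'   per-bin log2 mutant-over-wild-type track.
#' * `fig5_turnover` — Flag/Myc exchange scores per condition, gene-length
#'   clusters, center-of-gene turnover, and per-cluster mutant-versus-wild-
#'   type comparison (median difference + rank-sum p).
#' * `fig6_atac` — subnucleosomal filtering, per-gene accessibility log2
#'   fold change, three-way classification and the stacked-percentage
#'   summary.
#'
#' Given identical inputs and configuration, outputs are byte-identical
#' across runs. When `config$out_dir` is set, TSV/bedGraph outputs and a
#' `run_log.txt` recording every parameter and filtering count are written
#' there; results are also returned invisibly as tibbles.
#'
#' @param name Recipe name.
#' @param config A [pipeline_config].
#' @return (Invisibly) a named list of result tibbles/tracks.
#' @export
run_recipe <- function(name = c("fig1_metagene", "fig3_spikein",
                                "fig5_turnover", "fig6_atac"),
                       config) {
  name <- arg_match(name)
  problems <- validate_config(config, recipe = name)
  if (length(problems)) {
    abort(c("invalid configuration:", set_names(problems, "x")))
  }
  ann <- load_genes(config)
  sizes <- chrom_sizes(ann)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      readr::write_tsv(df, file.path(out_dir, file), progress = FALSE)
    }
  }
  steps <- character()
  note <- function(fmt, ...) steps <<- c(steps, sprintf(fmt, ...))

  res <- switch(name,
    fig1_metagene = {
      track <- load_track(config, "signal", sizes, norm_state = "rpm")
      mat <- tss_anchored_matrix(track, ann, extent = config$extent,
                                 bin_width = config$bin_width,
                                 sort_key = "length_asc")
      prof <- two_anchor_profile(track, ann, extent = config$extent,
                                 bin_width = config$bin_width)
      note("genes: %d", nrow(ann))
      if (!is.null(out_dir)) {
        write_metagene_tsv(mat, file.path(out_dir, "matrix.tsv"))
      }
      emit(prof, "profile.tsv")
      list(matrix = mat, profile = prof)
    },
    fig3_spikein = {
      fr <- lapply(c("ip_mut", "input_mut", "ip_wt", "input_wt"),
                   function(nm) load_frags(config, nm))
      names(fr) <- c("ip_mut", "input_mut", "ip_wt", "input_wt")
      report <- spikein_factors(fr$ip_mut, fr$input_mut, fr$ip_wt, fr$input_wt,
                                target_label = config$target_label,
                                spike_label = config$spike_label)
      cov <- lapply(fr[c("ip_mut", "ip_wt")], coverage_from_fragments,
                    ann = ann, bin_width = config$bin_width)
      ratio <- compare_tracks(cov$ip_mut, cov$ip_wt,
                              scale_a = report$n_factor,
                              pseudocount = config$pseudocount_compare)
      body <- gene_body_means(ratio, ann) %>%
        rename(log2fc = "mean_signal")
      for (nm in names(fr)) note("%s fragments: %d", nm, nrow(fr[[nm]]))
      note("n_factor: %s", format(report$n_factor))
      emit(report, "spikein_report.tsv")
      emit(body, "gene_log2fc.tsv")
      if (!is.null(out_dir)) {
        write_bedgraph(ratio, file.path(out_dir, "log2ratio.bedgraph"))
      }
      list(report = report, ratio_track = ratio, gene_log2fc = body)
    },
    fig5_turnover = {
      fr <- lapply(c("flag_wt", "myc_wt", "flag_mut", "myc_mut"),
                   function(nm) load_frags(config, nm))
      names(fr) <- c("flag_wt", "myc_wt", "flag_mut", "myc_mut")
      depth <- config$design_depth
      mk_rpm <- function(fs) {
        normalize_rpm(coverage_from_fragments(fs, ann,
                                              bin_width = config$bin_width),
                      total_mapped = depth %||% max(1, nrow(fs)))
      }
      tab <- lapply(c(wt = "wt", mut = "mut"), function(cond) {
        gene_stat_table(ann,
                        flag = mk_rpm(fr[[paste0("flag_", cond)]]),
                        myc = mk_rpm(fr[[paste0("myc_", cond)]]),
                        flag_frags = fr[[paste0("flag_", cond)]],
                        myc_frags = fr[[paste0("myc_", cond)]],
                        exclude_fraction = config$exclude_fraction,
                        pseudocount = config$pseudocount,
                        total_flag = depth %||% nrow(fr[[paste0("flag_", cond)]]),
                        total_myc = depth %||% nrow(fr[[paste0("myc_", cond)]]))
      })
      joined <- left_join(
        tab$wt, tab$mut,
        by = c("gene_id", "length_bp", "length_cluster"),
        suffix = c("_wt", "_mut"))
      comparison <- joined %>%
        filter(.data$length_cluster != "unassigned") %>%
        group_by(.data$length_cluster) %>%
        summarise(
          n = dplyr::n(),
          median_delta = median(.data$center_turnover_mut -
                                  .data$center_turnover_wt),
          p_value = group_compare(.data$center_turnover_mut,
                                  .data$center_turnover_wt)$p.value,
          .groups = "drop")
      for (nm in names(fr)) note("%s fragments: %d", nm, nrow(fr[[nm]]))
      emit(joined, "turnover_table.tsv")
      emit(comparison, "cluster_compare.tsv")
      list(table = joined, comparison = comparison)
    },
    fig6_atac = {
      mut <- load_frags(config, "mut")
      wt <- load_frags(config, "wt")
      mut_sub <- filter_subnucleosomal(mut, cutoff = config$atac_cutoff)
      wt_sub <- filter_subnucleosomal(wt, cutoff = config$atac_cutoff)
      depth <- config$design_depth
      mk <- function(fs) {
        normalize_rpm(coverage_from_fragments(fs, ann,
                                              bin_width = config$bin_width),
                      total_mapped = depth %||% max(1, nrow(fs)))
      }
      fc <- gene_accessibility_log2fc(mk(mut_sub), mk(wt_sub), ann,
                                      pseudocount = config$pseudocount)
      calls <- classify_accessibility(fc, threshold = config$atac_threshold)
      summary <- summarize_calls(calls)
      note("mut fragments: %d (subnucleosomal: %d)", nrow(mut), nrow(mut_sub))
      note("wt fragments: %d (subnucleosomal: %d)", nrow(wt), nrow(wt_sub))
      emit(calls, "calls.tsv")
      emit(summary, "summary.tsv")
      list(log2fc = fc, calls = calls, summary = summary)
    })
  if (!is.null(out_dir)) {
    write_log(config, name, steps, file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}

#' Read a pipeline configuration from YAML
#'
#' Plain key/value YAML matching [pipeline_config()]'s arguments; `tracks`
#' and `fragments` are maps from sample name to file path.
#'
#' @param path YAML file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the `yaml` package is required to read YAML configs.")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}
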