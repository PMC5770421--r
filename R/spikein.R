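#' Spike-in enrichment ratio E^IP
#'
#' For a ChIP library prepared from a mix of target-species and spike-in
#' species chromatin, the enrichment ratio is
#' \deqn{E^{IP} = \frac{IP_{target}/input_{target}}{IP_{spike}/input_{spike}}}
#' computed from whole-library mapped fragment counts. Because the amount of
#' spike-in chromatin is constant across samples, E^IP places IP efficiency
#' on a common quantitative scale.
#'
#' @param ip_target,ip_spike Mapped fragment counts of the IP library on the
#'   target and spike-in genomes.
#' @param input_target,input_spike The same for the matched input library.
#' @return The enrichment ratio (positive finite scalar).
#' @export
spike_ratio <- function(ip_target, ip_spike, input_target, input_spike) {
  counts <- c(ip_target = ip_target, ip_spike = ip_spike,
              input_target = input_target, input_spike = input_spike)
  zero <- names(counts)[counts <= 0]
  if (length(zero)) {
    abort(paste0("spike-in calibration needs positive counts; offending: ",
                 paste(zero, collapse = ", ")))
  }
  (ip_target / input_target) / (ip_spike / input_spike)
}

#' Mutant-versus-wild-type scale factor N
#'
#' The factor `N` that puts the mutant IP library on the wild-type scale,
#' defined by the proportion
#' \eqn{N \cdot c_{mut} : c_{wt} = E^{IP}_{mut} : E^{IP}_{wt}}
#' where `c` are the target-genome mapped fragment counts of the two IP
#' libraries; hence \eqn{N = (E_{mut} c_{wt}) / (E_{wt} c_{mut})}. Applied
#' downstream as scale `N:1` on (mutant, wild-type).
#'
#' @param e_mut,e_wt Enrichment ratios of the two samples ([spike_ratio]).
#' @param ip_count_mut,ip_count_wt Target-genome mapped fragment counts of
#'   the two IP libraries.
#' @return The scale factor N (positive scalar).
#' @export
norm_factor <- function(e_mut, e_wt, ip_count_mut, ip_count_wt) {
  vals <- c(e_mut = e_mut, e_wt = e_wt,
            ip_count_mut = ip_count_mut, ip_count_wt = ip_count_wt)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    abort(paste0("`", paste(bad, collapse = "`, `"), "` must be positive."))
  }
  (e_mut * ip_count_wt) / (e_wt * ip_count_mut)
}

#' Spike-in calibration report for a mutant/wild-type ChIP pair
#'
#' Counts fragments per genome in the four libraries, computes both
#' enrichment ratios and the scale factor N.
#'
#' @param ip_mut,input_mut,ip_wt,input_wt [fragment_set]s of the four
#'   libraries, each mixing target- and spike-genome fragments.
#' @param target_label,spike_label Genome labels used in the fragment sets.
#' @return One-row tibble: the eight genome counts, `e_ip_mut`, `e_ip_wt`,
#'   `n_factor`.
#' @export
spikein_factors <- function(ip_mut, input_mut, ip_wt, input_wt,
                            target_label = "target", spike_label = "spike") {
  cnt <- function(fs) {
    c(target = genome_count(fs, target_label),
      spike = genome_count(fs, spike_label))
  }
  im <- cnt(ip_mut); nm <- cnt(input_mut)
  iw <- cnt(ip_wt); nw <- cnt(input_wt)
  e_mut <- spike_ratio(im[["target"]], im[["spike"]],
                       nm[["target"]], nm[["spike"]])
  e_wt <- spike_ratio(iw[["target"]], iw[["spike"]],
                      nw[["target"]], nw[["spike"]])
  tibble(
    ip_mut_target = im[["target"]], ip_mut_spike = im[["spike"]],
    input_mut_target = nm[["target"]], input_mut_spike = nm[["spike"]],
    ip_wt_target = iw[["target"]], ip_wt_spike = iw[["spike"]],
    input_wt_target = nw[["target"]], input_wt_spike = nw[["spike"]],
    e_ip_mut = e_mut, e_ip_wt = e_wt,
    n_factor = norm_factor(e_mut, e_wt, im[["target"]], iw[["target"]])
  )
}

#' Per-bin log2 comparison of two tracks
#'
#' Computes `log2((scale_a * a + pseudocount) / (b + pseudocount))` bin by
#' bin. With raw tracks and `scale_a = N` this is the spike-in calibrated
#' mutant-over-wild-type comparison; with rpm tracks and `scale_a = 1` it is
#' the library-size normalized one. The output is itself a track
#' (`norm_state = "log2ratio"`), so comparisons compose — e.g. a
#' mutant-over-wild-type comparison of two per-genotype H4ac-over-H3
#' comparisons.
#'
#' @param a,b [binned_track]s on the same bin grid and in the same
#'   normalization state.
#' @param scale_a Scale applied to `a` before the ratio (default 1).
#' @param pseudocount Positive pseudocount keeping empty bins finite
#'   (default 1 raw count per bin).
#' @return A `log2ratio` [binned_track].
#' @export
compare_tracks <- function(a, b, scale_a = 1, pseudocount = 1) {
  if (!same_grid(a, b)) abort("tracks are on different bin grids.")
  if (!identical(norm_state(a), norm_state(b))) {
    abort("tracks must share a normalization state.")
  }
  assert_scalar_number(scale_a, "scale_a", positive = TRUE)
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  out <- a
  out$value <- log2((scale_a * a$value + pseudocount) / (b$value + pseudocount))
  attr(out, "norm_state") <- "log2ratio"
  attr(out, "sample_id") <- paste0(sample_id(a), "_vs_", sample_id(b))
  out
}
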