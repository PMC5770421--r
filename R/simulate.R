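#' Ground truth for the synthetic fragment generator
#'
#' Bundles every parameter the generators draw from, so a simulated dataset
#' is fully described by one object plus a seed. Each generator derives its
#' own RNG stream from `(seed, operation, condition, role)`, so adding a
#' sample never perturbs an existing one, and a fixed seed reproduces every
#' fragment byte for byte.
#'
#' @param seed Integer master seed.
#' @param global_scale_s Mutant/wild-type occupancy ratio on the target
#'   genome (IP only); 1 means no genotype effect.
#' @param spike_mix_ratio Target:spike cell-mixing ratio (default 5, i.e.
#'   five parts target chromatin per part spike-in).
#' @param per_gene_enrichment Optional named vector of per-gene IP
#'   enrichment rates; drawn log-normally per genome when `NULL`.
#' @param turnover_params List: `baseline_log2` (log2 Flag/Myc far from the
#'   TSS), `tss_boost` (extra log2 units at the TSS), `decay_bp`
#'   (exponential decay length of the boost), `longgene_delta` (log2 shift
#'   applied to genes > 2 kb in the mutant condition only).
#' @param atac_params List: `sub_frac` (subnucleosomal weight of the
#'   library), `sub_len_mean`/`sub_len_sd` and `nuc_len_mean`/`nuc_len_sd`
#'   (fragment-length normals, bp; subnucleosomal lengths truncated at
#'   >= 20 bp), `per_gene_multiplier` (named vector of mutant accessibility
#'   multipliers, default 1).
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed,
                            global_scale_s = 1,
                            spike_mix_ratio = 5,
                            per_gene_enrichment = NULL,
                            turnover_params = list(),
                            atac_params = list()) {
  assert_scalar_number(seed, "seed", integerish = TRUE)
  assert_scalar_number(global_scale_s, "global_scale_s", positive = TRUE)
  assert_scalar_number(spike_mix_ratio, "spike_mix_ratio", positive = TRUE)
  tp <- utils::modifyList(
    list(baseline_log2 = 0, tss_boost = 1, decay_bp = 300, longgene_delta = 0),
    turnover_params)
  ap <- utils::modifyList(
    list(sub_frac = 0.35, sub_len_mean = 60, sub_len_sd = 15,
         nuc_len_mean = 160, nuc_len_sd = 20, per_gene_multiplier = NULL),
    atac_params)
  if (ap$sub_frac < 0 || ap$sub_frac >= 1) abort("`sub_frac` must be in [0, 1).")
  structure(list(seed = as.integer(seed), global_scale_s = global_scale_s,
                 spike_mix_ratio = spike_mix_ratio,
                 per_gene_enrichment = per_gene_enrichment,
                 turnover_params = tp, atac_params = ap),
            class = "synthetic_truth")
}

#' Generate a toy target + spike-in genome pair
#'
#' Lays `n_genes` genes head to tail over `n_chrom` chromosomes with fixed
#' intergenic gaps; gene lengths are log-uniform over `[min_bp, max_bp]` so
#' that all three length strata (>2 kb, 1-2 kb, 0.5-1 kb) are populated.
#' The spike genome is a scaled-down second annotation (one fifth the gene
#' count by default, mirroring a 5:1 mixing design) on its own
#' chromosomes.
#'
#' @param n_genes Number of target-genome genes (>= 1).
#' @param min_bp,max_bp Gene length bounds (bp); `min_bp` >= 100.
#' @param law `"loguniform"` (default) draws lengths log-uniformly over
#'   `[min_bp, max_bp]`; `"stratified"` draws equal numbers of genes
#'   log-uniformly within each length stratum (0.5-1 kb, 1-2 kb,
#'   2 kb-`max_bp`), giving balanced cluster sizes for stratified designs.
#' @param intergenic_bp Gap between consecutive genes (bp).
#' @param n_chrom Number of target chromosomes.
#' @param spike_fraction Spike gene count as a fraction of `n_genes`.
#' @param seed Integer seed; the same seed reproduces the genomes exactly.
#' @return List with elements `target` and `spike`, each a
#'   [genome_annotation].
#' @export
make_genome <- function(n_genes, min_bp = 600, max_bp = 6000,
                        law = "loguniform", intergenic_bp = 200,
                        n_chrom = 2, spike_fraction = 0.2, seed = 1) {
  assert_scalar_number(n_genes, "n_genes", positive = TRUE, integerish = TRUE)
  if (min_bp < 100) abort("`min_bp` must be >= 100.")
  if (max_bp <= min_bp) abort("`max_bp` must exceed `min_bp`.")
  law <- arg_match(law, c("loguniform", "stratified"))
  if (law == "stratified" && max_bp <= 2000) {
    abort("stratified law needs `max_bp` > 2000.")
  }
  draw_len <- function(n) {
    if (law == "loguniform") {
      round(exp(runif(n, log(min_bp), log(max_bp))))
    } else {
      strata <- list(c(501, 1000), c(1001, 2000), c(2001, max_bp))
      per <- diff(round(seq(0, n, length.out = 4)))
      unlist(lapply(seq_along(strata), function(i) {
        round(exp(runif(per[i], log(strata[[i]][1]), log(strata[[i]][2]))))
      }), use.names = FALSE)
    }
  }
  build <- function(n, prefix, chrom_prefix, nchr, sd) {
    withr::with_seed(sd, {
      len <- draw_len(n)
      strand <- sample(c("+", "-"), n, replace = TRUE)
    })
    chrom_of <- rep(seq_len(nchr), length.out = n)
    genes <- vector("list", nchr)
    sizes <- numeric(nchr)
    for (c_i in seq_len(nchr)) {
      sel <- which(chrom_of == c_i)
      l <- len[sel]
      start <- intergenic_bp + c(0, cumsum(l + intergenic_bp))[seq_along(l)]
      genes[[c_i]] <- tibble(
        gene_id = sprintf("%s%04d", prefix, sel),
        chrom = paste0(chrom_prefix, c_i),
        start = start, end = start + l,
        strand = strand[sel])
      sizes[c_i] <- max(genes[[c_i]]$end) + intergenic_bp
    }
    genome_annotation(bind_rows(genes),
                      setNames(sizes, paste0(chrom_prefix, seq_len(nchr))),
                      genome_label = if (prefix == "g") "target" else "spike")
  }
  n_spike <- max(1L, as.integer(round(n_genes * spike_fraction)))
  list(
    target = build(n_genes, "g", "tchr", n_chrom,
                   derive_seed(seed, "genome", "target")),
    spike = build(n_spike, "s", "schr", 1L,
                  derive_seed(seed, "genome", "spike"))
  )
}

# per-gene enrichment for one annotation, drawn or taken from truth
gene_enrichment <- function(truth, ann) {
  if (!is.null(truth$per_gene_enrichment)) {
    e <- truth$per_gene_enrichment[ann$gene_id]
    e[is.na(e)] <- 1
    return(unname(e))
  }
  sd <- derive_seed(truth$seed, "enrichment", genome_label(ann))
  withr::with_seed(sd, exp(rnorm(nrow(ann), 0, 0.5)))
}

# uniform fragment midpoints within genes picked by `counts`, emitted as
# fixed-length fragments clipped to [0, chrom size)
fragments_from_counts <- function(ann, counts, frag_len, sizes) {
  idx <- rep(seq_len(nrow(ann)), counts)
  if (!length(idx)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  genome_label = character()))
  }
  mid <- floor(ann$start[idx] +
                 runif(length(idx)) * (ann$end[idx] - ann$start[idx]))
  start <- pmax(mid - frag_len %/% 2, 0)
  end <- pmin(start + frag_len, unname(sizes[ann$chrom[idx]]))
  tibble(chrom = ann$chrom[idx], start = start, end = end,
         genome_label = rep_len(genome_label(ann), length(idx)))
}

#' Simulate a spike-in ChIP library
#'
#' Draws `n_fragments` fragments multinomially over the genes of the mixed
#' target + spike genome. Per-gene weights are `enrichment x length` for
#' the IP role and `length` (flat density) for input; the target genome's
#' weight carries the cell-mixing ratio, and — for the IP of the mutant
#' condition only — the global occupancy scale `s`. Spike-genome rates are
#' identical across conditions, which is what makes the spike-in a valid
#' calibrator.
#'
#' @param truth A [synthetic_truth].
#' @param genomes List with `target` and `spike` annotations (from
#'   [make_genome()]).
#' @param n_fragments Library size (> 0).
#' @param condition `"wt"` or `"mut"`.
#' @param role `"ip"` or `"input"`.
#' @param frag_len Emitted fragment length (bp, default 150).
#' @return A [fragment_set] mixing both genome labels.
#' @export
simulate_chip <- function(truth, genomes, n_fragments,
                          condition = c("wt", "mut"), role = c("ip", "input"),
                          frag_len = 150) {
  condition <- arg_match(condition); role <- arg_match(role)
  assert_scalar_number(n_fragments, "n_fragments", positive = TRUE,
                       integerish = TRUE)
  tgt <- genomes$target; spk <- genomes$spike
  len_t <- tgt$end - tgt$start
  len_s <- spk$end - spk$start
  w_t <- len_t * (if (role == "ip") gene_enrichment(truth, tgt) else 1)
  w_s <- len_s * (if (role == "ip") gene_enrichment(truth, spk) else 1)
  s <- if (condition == "mut" && role == "ip") truth$global_scale_s else 1
  w <- c(w_t * s * truth$spike_mix_ratio, w_s)
  sd <- derive_seed(truth$seed, "chip", condition, role)
  withr::with_seed(sd, {
    counts <- as.vector(rmultinom(1, n_fragments, w))
    sizes <- c(chrom_sizes(tgt), chrom_sizes(spk))
    df <- bind_rows(
      fragments_from_counts(tgt, counts[seq_len(nrow(tgt))], frag_len,
                            chrom_sizes(tgt)),
      fragments_from_counts(spk, counts[nrow(tgt) + seq_len(nrow(spk))],
                            frag_len, chrom_sizes(spk))
    )
  })
  fragment_set(df, sample_id = paste("chip", condition, role, sep = "_"))
}

# per-gene 25 bp lattice of (gene row, bin center offset from TSS, weight)
turnover_lattice <- function(ann, step = 25) {
  len <- ann$end - ann$start
  nb <- pmax(1L, as.integer(ceiling(len / step)))
  gi <- rep(seq_len(nrow(ann)), nb)
  off <- unlist(lapply(nb, function(k) (seq_len(k) - 0.5) * step),
                use.names = FALSE)
  keep <- off < rep(len, nb)
  list(gene = gi[keep], offset = off[keep], step = step)
}

#' Simulate a Flag/Myc histone-exchange library pair
#'
#' Myc (old histone) coverage is flat over genes. Flag (new histone)
#' density at offset `x` bp from the TSS follows
#' `2^(baseline_log2 + tss_boost * exp(-x / decay_bp) + delta)`, where
#' `delta = longgene_delta` for genes longer than 2 kb under the mutant
#' condition and 0 otherwise — exchange is promoter-proximal and the
#' mutant suppresses it specifically over long gene bodies. Fragment counts
#' per 25 bp lattice site are Poisson with absolute (per-cell) rates scaled
#' so the expected wild-type library size is `n_fragments_per_sample`;
#' compare conditions on a calibrated depth scale (see
#' [normalize_rpm()]'s `total_mapped`).
#'
#' @param truth A [synthetic_truth].
#' @param ann Target [genome_annotation].
#' @param n_fragments_per_sample Expected wild-type library size.
#' @param condition `"wt"` or `"mut"`.
#' @param frag_len Emitted fragment length (bp, default 150).
#' @return List with [fragment_set]s `flag` and `myc`.
#' @export
simulate_turnover <- function(truth, ann, n_fragments_per_sample,
                              condition = c("wt", "mut"), frag_len = 150) {
  condition <- arg_match(condition)
  assert_scalar_number(n_fragments_per_sample, "n_fragments_per_sample",
                       positive = TRUE, integerish = TRUE)
  tp <- truth$turnover_params
  lat <- turnover_lattice(ann)
  len <- ann$end - ann$start
  sizes <- chrom_sizes(ann)
  log2rate <- tp$baseline_log2 + tp$tss_boost * exp(-lat$offset / tp$decay_bp)
  w_wt <- 2^log2rate
  is_long <- len[lat$gene] > 2000
  w_cond <- if (condition == "mut") {
    w_wt * 2^(tp$longgene_delta * is_long)
  } else {
    w_wt
  }
  c_flag <- n_fragments_per_sample / sum(w_wt)   # calibrated to WT depth
  c_myc <- n_fragments_per_sample / length(lat$gene)
  emit <- function(weights, scale, which) {
    sd <- derive_seed(truth$seed, "turnover", condition, which)
    withr::with_seed(sd, {
      counts <- rpois(length(weights), scale * weights)
      idx <- rep(seq_along(weights), counts)
      if (!length(idx)) {
        df <- tibble(chrom = character(), start = numeric(), end = numeric(),
                     genome_label = character())
      } else {
        g <- lat$gene[idx]
        jitter <- runif(length(idx), -lat$step / 2, lat$step / 2)
        x <- pmin(pmax(lat$offset[idx] + jitter, 0.5), len[g] - 0.5)
        mid <- floor(ifelse(ann$strand[g] == "+",
                            ann$start[g] + x, ann$end[g] - x))
        start <- pmax(mid - frag_len %/% 2, 0)
        end <- pmin(start + frag_len, unname(sizes[ann$chrom[g]]))
        df <- tibble(chrom = ann$chrom[g], start = start, end = end,
                     genome_label = rep_len(genome_label(ann), length(idx)))
      }
      df
    }) -> df
    fragment_set(df, sample_id = paste("turnover", condition, which, sep = "_"))
  }
  list(flag = emit(w_cond, c_flag, "flag"),
       myc = emit(rep(1, length(lat$gene)), c_myc, "myc"))
}

#' Simulate an ATAC-seq library
#'
#' A bimodal mixture of subnucleosomal fragments (truncated normal lengths,
#' default mean 60 sd 15, floor 20 bp) and nucleosomal fragments (default
#' mean 160 sd 20). Per-gene subnucleosomal counts are Poisson with
#' absolute rates proportional to gene length times the gene's
#' accessibility multiplier (applied under the mutant condition only);
#' nucleosomal rates are proportional to length in both conditions. The
#' expected wild-type library size is `n_fragments`, of which a fraction
#' `sub_frac` is subnucleosomal.
#'
#' @param truth A [synthetic_truth].
#' @param ann Target [genome_annotation].
#' @param n_fragments Expected wild-type library size.
#' @param condition `"wt"` or `"mut"`.
#' @return A [fragment_set].
#' @export
simulate_atac <- function(truth, ann, n_fragments,
                          condition = c("wt", "mut")) {
  condition <- arg_match(condition)
  assert_scalar_number(n_fragments, "n_fragments", positive = TRUE,
                       integerish = TRUE)
  ap <- truth$atac_params
  len <- ann$end - ann$start
  sizes <- chrom_sizes(ann)
  mult <- rep(1, nrow(ann))
  if (!is.null(ap$per_gene_multiplier)) {
    m <- ap$per_gene_multiplier[ann$gene_id]
    mult <- ifelse(is.na(m), 1, unname(m))
  }
  if (condition != "mut") mult <- rep(1, nrow(ann))
  c_sub <- ap$sub_frac * n_fragments / sum(len)
  c_nuc <- (1 - ap$sub_frac) * n_fragments / sum(len)
  sd <- derive_seed(truth$seed, "atac", condition)
  withr::with_seed(sd, {
    n_sub <- rpois(nrow(ann), c_sub * len * mult)
    n_nuc <- rpois(nrow(ann), c_nuc * len)
    draw <- function(counts, lmean, lsd, lmin) {
      idx <- rep(seq_len(nrow(ann)), counts)
      if (!length(idx)) {
        return(tibble(chrom = character(), start = numeric(),
                      end = numeric(), genome_label = character()))
      }
      # inverse-CDF truncated normal keeps the stream deterministic
      p0 <- stats::pnorm(lmin, lmean, lsd)
      fl <- pmax(2, round(qnorm(runif(length(idx), p0, 1), lmean, lsd)))
      mid <- floor(ann$start[idx] + runif(length(idx)) * len[idx])
      start <- pmax(mid - fl %/% 2, 0)
      end <- pmin(start + fl, unname(sizes[ann$chrom[idx]]))
      tibble(chrom = ann$chrom[idx], start = start, end = end,
             genome_label = rep_len(genome_label(ann), length(idx)))
    }
    df <- bind_rows(
      draw(n_sub, ap$sub_len_mean, ap$sub_len_sd, 20),
      # nucleosomal lengths are floored at 100 bp: anything shorter is
      # subnucleosomal by definition, so the two components do not overlap
      draw(n_nuc, ap$nuc_len_mean, ap$nuc_len_sd, 100)
    )
  })
  fragment_set(df, sample_id = paste("atac", condition, sep = "_"))
}
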