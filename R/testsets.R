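#' Builder configuration for the three benchmark tasks
#'
#' Houses the task constants: the task-1 frequency window (5-15%), the
#' task-2 CPP frequency floor (MAF > 5%), pairing window (1 kb), DAV search
#' window (50 kb), gene window (10 kb), mixing ratios (1:1 to 100:1 by
#' default), minimum pairwise separation (1 kb) and the top-percentile
#' cutoff (10).
#'
#' @param maf_lo,maf_hi task-1 frequency window bounds.
#' @param cpp_maf_min task-2 CPP minor-allele-frequency floor (exclusive).
#' @param pair_window_bp maximum DAV-CPP pairing distance (inclusive).
#' @param search_window_bp flanking region searched for CPPs around a DAV.
#' @param gene_window_bp maximum DAV-to-gene distance for the gene-balanced
#'   subsample.
#' @param ratios non-pathogenic : pathogenic mixing ratios for task 3.
#' @param min_separation_bp minimum pairwise distance within a mixture
#'   (exclusive: members must be strictly further apart).
#' @param top_percentile task-3 short-list percentile.
#' @param distance_bin_edges upper edges (bp) of the task-2 distance bins.
#' @param freq_mode apply the task-1 window to the derived-allele frequency
#'   (`"derived"`, falling back to MAF when DAF is missing) or to MAF.
#' @param seed integer seed for the randomised choices.
#' @return a `builder_config` list.
#' @export
builder_config <- function(maf_lo = 0.05, maf_hi = 0.15, cpp_maf_min = 0.05,
                           pair_window_bp = 1000L, search_window_bp = 50000L,
                           gene_window_bp = 10000L, ratios = c(1, 2, 5, 10,
                                                               20, 50, 100),
                           min_separation_bp = 1000L, top_percentile = 10,
                           distance_bin_edges = c(10, 50, 100, 200, 500, 1000),
                           freq_mode = c("derived", "maf"), seed = 1L) {
  stopifnot(maf_lo >= 0, maf_lo < maf_hi, maf_hi <= 1,
            pair_window_bp > 0, search_window_bp > 0, gene_window_bp > 0,
            min_separation_bp > 0, all(ratios >= 1))
  structure(list(maf_lo = maf_lo, maf_hi = maf_hi, cpp_maf_min = cpp_maf_min,
                 pair_window_bp = as.integer(pair_window_bp),
                 search_window_bp = as.integer(search_window_bp),
                 gene_window_bp = as.integer(gene_window_bp),
                 ratios = ratios,
                 min_separation_bp = as.integer(min_separation_bp),
                 top_percentile = top_percentile,
                 distance_bin_edges = distance_bin_edges,
                 freq_mode = match.arg(freq_mode),
                 seed = as.integer(seed)),
            class = "builder_config")
}

builder_freq <- function(catalog, config) {
  if (config$freq_mode == "derived")
    ifelse(is.na(catalog$daf), catalog$maf, catalog$daf)
  else catalog$maf
}

#' Evolutionarily forbidden alleles at one position
#'
#' A base is forbidden when it is neither the human reference, nor observed
#' in any species of the alignment column, nor reported as an ape
#' polymorphism: across a deep species panel, such an allele has been
#' persistently removed by purifying selection.
#'
#' @param column alignment column over the non-human species panel (gaps
#'   contribute no observed base).
#' @param human_ref human reference base.
#' @param ape_polymorphisms bases segregating in great apes at this
#'   position.
#' @return character vector of forbidden bases (possibly empty).
#' @export
forbidden_alleles <- function(column, human_ref,
                              ape_polymorphisms = character()) {
  observed <- unique(column[column %in% BASES])
  setdiff(BASES, c(toupper(human_ref), observed,
                   toupper(ape_polymorphisms)))
}

#' Build the position-matched allelic test set (task 1)
#'
#' At each candidate CPP position, pairs the common (non-pathogenic) allele
#' with an evolutionarily forbidden (pathogenic) allele. Pipeline order:
#' keep CPP positions whose frequency lies in the configured window; drop
#' positions on the association blacklist; designate the highest-MAF
#' alternate as non-pathogenic; drop positions where a remaining
#' (candidate) allele is an ape polymorphism; compute the forbidden set
#' from the alignment column; drop positions with no forbidden allele;
#' choose one forbidden allele uniformly at random when several remain.
#'
#' @param catalog a [variant_catalog()]; rows labelled `CPP` are candidates.
#' @param alignment matrix over the non-human species; columns named
#'   `"chrom:pos"`.
#' @param config a [builder_config()].
#' @param association_blacklist character keys `"chrom:pos"` of positions
#'   with known trait associations (dropped).
#' @param ape_polymorphisms data frame `chrom`, `pos`, `base` of great-ape
#'   polymorphisms.
#' @return an `allele_pair_set` data frame: `chrom`, `pos`, `ref`,
#'   `pathogenic_alt`, `nonpathogenic_alt`. Positions lacking an alignment
#'   column are dropped with a logged count (`attr(, "n_no_column")`).
#' @export
build_position_matched <- function(catalog, alignment, config,
                                   association_blacklist = character(),
                                   ape_polymorphisms = NULL) {
  set.seed(config$seed)
  cpp <- catalog[catalog$label == "CPP", , drop = FALSE]
  fq <- builder_freq(cpp, config)
  cpp <- cpp[!is.na(fq) & fq >= config$maf_lo & fq <= config$maf_hi, ,
             drop = FALSE]
  keys <- pos_key(cpp$chrom, cpp$pos)
  cpp <- cpp[!(keys %in% association_blacklist), , drop = FALSE]
  # one candidate per position: the alternate with the highest MAF is the
  # non-pathogenic allele
  if (nrow(cpp)) {
    ord <- order(cpp$chrom, cpp$pos, -cpp$maf, cpp$alt)
    cpp <- cpp[ord, , drop = FALSE]
    cpp <- cpp[!duplicated(pos_key(cpp$chrom, cpp$pos)), , drop = FALSE]
  }
  ape_at <- function(chrom, pos) {
    if (is.null(ape_polymorphisms)) return(character())
    toupper(ape_polymorphisms$base[ape_polymorphisms$chrom == chrom &
                                     ape_polymorphisms$pos == pos])
  }
  out <- list(); n_no_col <- 0L
  for (i in seq_len(nrow(cpp))) {
    key <- pos_key(cpp$chrom[i], cpp$pos[i])
    if (!key %in% colnames(alignment)) { n_no_col <- n_no_col + 1L; next }
    col <- alignment[, key]
    apes <- ape_at(cpp$chrom[i], cpp$pos[i])
    remaining <- setdiff(BASES, c(cpp$ref[i], cpp$alt[i]))
    if (length(intersect(remaining, apes))) next
    cand <- setdiff(forbidden_alleles(col, cpp$ref[i], apes), cpp$alt[i])
    if (!length(cand)) next
    path <- if (length(cand) == 1L) cand else sample(cand, 1L)
    out[[length(out) + 1L]] <- data.frame(
      chrom = cpp$chrom[i], pos = cpp$pos[i], ref = cpp$ref[i],
      pathogenic_alt = path, nonpathogenic_alt = cpp$alt[i],
      stringsAsFactors = FALSE)
  }
  if (n_no_col) message("build_position_matched: dropped ", n_no_col,
                        " position(s) lacking an alignment column")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               pathogenic_alt = character(), nonpathogenic_alt = character())
  rownames(res) <- NULL
  attr(res, "n_no_column") <- n_no_col
  class(res) <- c("allele_pair_set", "data.frame")
  res
}

#' Filter candidate DAVs by evidence strength
#'
#' Three filters mirroring clinical evidence tiers: (1) the variant must
#' carry a certain disease-mutation label and functional evidence; (2) it
#' must lie inside a known regulatory element; (3) its population
#' frequency must not exceed `freq_threshold`.
#'
#' @param catalog a [variant_catalog()]; rows labelled `DAV` are candidates.
#' @param freq_threshold maximum population frequency (typical choices:
#'   0.01, 0.001, 1e-4, 0).
#' @return the surviving DAV rows.
#' @export
filter_davs <- function(catalog, freq_threshold = 0.01) {
  dav <- catalog[catalog$label == "DAV", , drop = FALSE]
  keep <- dav$dm_certain & dav$functional_evidence &
    dav$in_regulatory_element &
    (is.na(dav$maf) | dav$maf <= freq_threshold)
  out <- dav[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

matched_pair_frame <- function() {
  data.frame(dav_id = integer(), cpp_id = integer(), chrom = character(),
             dav_pos = integer(), cpp_pos = integer(),
             dav_alt = character(), cpp_alt = character(),
             distance_bp = integer(), same_ld_block = logical(),
             distance_bin = character(), stringsAsFactors = FALSE)
}

distance_bin_label <- function(d, edges) {
  lo <- c(0, head(edges, -1))
  lab <- sprintf("(%g,%g]", lo, edges)
  idx <- findInterval(d, c(lo, Inf), left.open = TRUE)
  out <- rep(NA_character_, length(d))
  ok <- idx >= 1 & idx <= length(edges)
  out[ok] <- lab[idx[ok]]
  out
}

#' Build the region-matched DAV-CPP pair set (task 2)
#'
#' Pairs each anchor DAV with every CPP that has MAF above the floor, lies
#' within the pairing window (inclusive), and has no known disease
#' association.
#'
#' @param davs filtered DAV rows (see [filter_davs()]).
#' @param cpps CPP rows of a [variant_catalog()].
#' @param config a [builder_config()].
#' @return a `matched_pair_set` data frame with per-pair distance,
#'   LD-block agreement and distance bin; `attr(, "n_unpaired_davs")`
#'   counts anchors with no qualifying CPP.
#' @export
build_region_matched <- function(davs, cpps, config) {
  cpps <- cpps[!is.na(cpps$maf) & cpps$maf > config$cpp_maf_min &
                 !cpps$has_known_association, , drop = FALSE]
  out <- list(); n_unpaired <- 0L
  for (i in seq_len(nrow(davs))) {
    hit <- which(cpps$chrom == davs$chrom[i] &
                   abs(cpps$pos - davs$pos[i]) <= config$pair_window_bp)
    if (!length(hit)) { n_unpaired <- n_unpaired + 1L; next }
    d <- abs(cpps$pos[hit] - davs$pos[i])
    out[[length(out) + 1L]] <- data.frame(
      dav_id = i, cpp_id = hit, chrom = davs$chrom[i],
      dav_pos = davs$pos[i], cpp_pos = cpps$pos[hit],
      dav_alt = davs$alt[i], cpp_alt = cpps$alt[hit],
      distance_bp = d,
      same_ld_block = !is.na(davs$ld_block[i]) &
        !is.na(cpps$ld_block[hit]) & davs$ld_block[i] == cpps$ld_block[hit],
      distance_bin = distance_bin_label(d, config$distance_bin_edges),
      stringsAsFactors = FALSE)
  }
  if (n_unpaired) message("build_region_matched: ", n_unpaired,
                          " DAV(s) had no qualifying CPP within the window")
  res <- if (length(out)) do.call(rbind, out) else matched_pair_frame()
  rownames(res) <- NULL
  attr(res, "n_unpaired_davs") <- n_unpaired
  class(res) <- c("matched_pair_set", "data.frame")
  res
}

#' Build the LD-matched DAV-CPP pair set (task 2, LD variant)
#'
#' Pairs each DAV with every qualifying CPP sharing its LD-block label.
#' Block assignment at the given r-squared threshold is an input annotation
#' (the `ld_block` field), not computed here.
#'
#' @param davs filtered DAV rows carrying `ld_block`.
#' @param cpps CPP rows carrying `ld_block`.
#' @param r2_threshold the r-squared used to define the blocks; values
#'   outside \[0.8, 0.99\] trigger a warning but proceed.
#' @param config a [builder_config()] (CPP frequency floor, bins).
#' @return a `matched_pair_set` with `same_ld_block = TRUE` throughout.
#' @export
build_ld_matched <- function(davs, cpps, r2_threshold,
                             config = builder_config()) {
  if (all(is.na(davs$ld_block)) || all(is.na(cpps$ld_block)))
    stop("LD-block annotation missing at r2 = ", r2_threshold)
  if (r2_threshold < 0.8 || r2_threshold > 0.99)
    warning("r2 threshold ", r2_threshold, " outside the usual [0.8, 0.99]")
  cpps <- cpps[!is.na(cpps$maf) & cpps$maf > config$cpp_maf_min &
                 !cpps$has_known_association & !is.na(cpps$ld_block), ,
               drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(davs))) {
    if (is.na(davs$ld_block[i])) next
    hit <- which(cpps$ld_block == davs$ld_block[i])
    if (!length(hit)) next
    d <- abs(cpps$pos[hit] - davs$pos[i])
    out[[length(out) + 1L]] <- data.frame(
      dav_id = i, cpp_id = hit, chrom = davs$chrom[i],
      dav_pos = davs$pos[i], cpp_pos = cpps$pos[hit],
      dav_alt = davs$alt[i], cpp_alt = cpps$alt[hit],
      distance_bp = d, same_ld_block = TRUE,
      distance_bin = distance_bin_label(d, config$distance_bin_edges),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else matched_pair_frame()
  rownames(res) <- NULL
  class(res) <- c("matched_pair_set", "data.frame")
  res
}

#' Gene-balanced DAV subsample
#'
#' Keeps exactly one uniformly chosen DAV per gene, dropping DAVs farther
#' than `config$gene_window_bp` from any gene (or lacking a gene
#' assignment). Counteracts the strong per-gene clustering of curated
#' disease variants.
#'
#' @param davs DAV rows with `gene` and `gene_dist_bp`.
#' @param config a [builder_config()] (window, seed).
#' @return one DAV row per represented gene.
#' @export
gene_balanced_subsample <- function(davs, config) {
  set.seed(config$seed)
  ok <- !is.na(davs$gene) & !is.na(davs$gene_dist_bp) &
    davs$gene_dist_bp <= config$gene_window_bp
  davs <- davs[ok, , drop = FALSE]
  davs <- davs[order(davs$chrom, davs$pos, davs$alt), , drop = FALSE]
  if (!nrow(davs)) return(davs)
  pick <- unlist(lapply(split(seq_len(nrow(davs)), davs$gene),
                        function(ix) if (length(ix) == 1L) ix
                        else sample(ix, 1L)))
  out <- davs[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy selection of rows pairwise separated by more than min_sep,
# scanning in the given order; returns kept row indices
greedy_separate <- function(chrom, pos, order_idx, min_sep,
                            fixed_chrom = character(), fixed_pos = integer()) {
  keep <- integer()
  kc <- fixed_chrom; kp <- fixed_pos
  for (i in order_idx) {
    near <- kc == chrom[i] & abs(kp - pos[i]) <= min_sep
    if (!any(near)) {
      keep <- c(keep, i)
      kc <- c(kc, chrom[i]); kp <- c(kp, pos[i])
    }
  }
  keep
}

#' Build mixture test sets over a range of class-imbalance ratios (task 3)
#'
#' All members of a mixture must be pairwise separated by more than
#' `config$min_separation_bp` to avoid regional score correlation. Eligible
#' DAVs are selected greedily in position order; per ratio rho, all
#' eligible DAVs enter together with `round(rho * n_dav)` CPPs sampled
#' (seeded) from the CPPs compatible with the separation constraint.
#' Ratios that cannot be satisfied are skipped with a warning.
#'
#' @param davs,cpps variant rows (positive and negative classes).
#' @param config a [builder_config()] (`ratios`, `min_separation_bp`,
#'   `seed`).
#' @return named list of `mixture_set` data frames (`chrom`, `pos`, `alt`,
#'   `pathogenic`), one per realised ratio, each carrying
#'   `attr(, "mixing_ratio")`.
#' @export
build_mixtures <- function(davs, cpps, config) {
  set.seed(config$seed)
  davs <- davs[order(davs$chrom, davs$pos, davs$alt), , drop = FALSE]
  cpps <- cpps[order(cpps$chrom, cpps$pos, cpps$alt), , drop = FALSE]
  dkeep <- greedy_separate(davs$chrom, davs$pos,
                           order(davs$chrom, davs$pos),
                           config$min_separation_bp)
  if (!length(dkeep))
    stop("no DAV survives the pairwise separation filter")
  dav_sel <- davs[dkeep, , drop = FALSE]
  ckeep <- greedy_separate(cpps$chrom, cpps$pos,
                           sample(nrow(cpps)), config$min_separation_bp,
                           fixed_chrom = dav_sel$chrom,
                           fixed_pos = dav_sel$pos)
  cpp_sel <- cpps[ckeep, , drop = FALSE]
  n_p <- nrow(dav_sel)
  out <- list()
  for (rho in config$ratios) {
    n_n <- round(rho * n_p)
    if (n_n > nrow(cpp_sel)) {
      warning("ratio ", rho, ":1 skipped: needs ", n_n, " CPPs, only ",
              nrow(cpp_sel), " eligible")
      next
    }
    cs <- cpp_sel[sample(nrow(cpp_sel), n_n), , drop = FALSE]
    mix <- data.frame(
      chrom = c(dav_sel$chrom, cs$chrom), pos = c(dav_sel$pos, cs$pos),
      alt = c(dav_sel$alt, cs$alt),
      pathogenic = rep(c(TRUE, FALSE), c(n_p, n_n)),
      stringsAsFactors = FALSE)
    rownames(mix) <- NULL
    attr(mix, "mixing_ratio") <- rho
    attr(mix, "min_separation_bp") <- config$min_separation_bp
    class(mix) <- c("mixture_set", "data.frame")
    out[[as.character(rho)]] <- mix
  }
  out
}

#' Select top association records and deduplicate by position
#'
#' Sorts records by the requested key (absolute effect size descending, or
#' association p-value ascending; `"effect_and_chosen"` additionally
#' requires the `chosen` flag), takes the top `n`, then deduplicates by
#' position keeping the first occurrence. Ties at rank `n` are broken by
#' (position, id) lexicographic order.
#'
#' @param records data frame: `id`, `chrom` (optional), `pos`,
#'   `effect_size`, `p_value`, `chosen`.
#' @param n number of records to take before deduplication.
#' @param key `"effect"`, `"p_value"` or `"effect_and_chosen"`.
#' @return data frame of unique positions (first record per position).
#' @export
select_top_records <- function(records, n,
                               key = c("effect", "p_value",
                                       "effect_and_chosen")) {
  key <- match.arg(key)
  if (is.null(records$chrom)) records$chrom <- "chr1"
  if (key == "effect_and_chosen") {
    records <- records[as.logical(records$chosen), , drop = FALSE]
    key <- "effect"
  }
  ord <- if (key == "effect")
    order(-abs(records$effect_size), records$pos, records$id)
  else
    order(records$p_value, records$pos, records$id)
  top <- records[ord, , drop = FALSE][seq_len(min(n, nrow(records))), ,
                                      drop = FALSE]
  out <- top[!duplicated(pos_key(top$chrom, top$pos)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
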