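#' Evaluation configuration
#'
#' @param auprc_target AUPRC level defining "usable" performance (task 3).
#' @param top_percentile short-list percentile (task 3).
#' @param tie_credit credit for ties in success rates; 0.5 preserves the
#'   50% random-expectation line under exchangeability.
#' @param alpha significance level reported alongside tests.
#' @return an `eval_config` list.
#' @export
eval_config <- function(auprc_target = 0.8, top_percentile = 10,
                        tie_credit = 0.5, alpha = 0.05) {
  stopifnot(auprc_target > 0, auprc_target < 1,
            tie_credit >= 0, tie_credit <= 1)
  structure(list(auprc_target = auprc_target,
                 top_percentile = top_percentile,
                 tie_credit = tie_credit, alpha = alpha),
            class = "eval_config")
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties half-credited (midrank convention).
#'
#' @param pos_scores,neg_scores numeric score vectors; `NA`s are dropped.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("auroc: empty class after removing NAs")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# DeLong structural components via the midrank formulation
delong_components <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  rp <- rank(pos, ties.method = "average")
  rn <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(np)] - rp) / nn            # per-positive
  v01 <- 1 - (all_r[np + seq_len(nn)] - rn) / np   # per-negative
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for an AUROC
#'
#' One-sample mode: estimates the variance of a single AUROC from its
#' structural components and z-tests it against `null_auc` (two-sided).
#' Paired mode (supply `pos_scores2`/`neg_scores2` from a second tool on
#' the same variants, in the same order): tests the difference of the two
#' correlated AUROCs, using the covariance of the components.
#'
#' @param pos_scores,neg_scores scores of the first tool.
#' @param null_auc null value for the one-sample test.
#' @param pos_scores2,neg_scores2 optional scores of a second tool.
#' @return list: `auc` (or `auc1`, `auc2`, `delta`), `variance`, `z`, `p`,
#'   and `degenerate = TRUE` with p = 0 when the variance collapses (e.g.
#'   perfect separation).
#' @export
delong_auc_test <- function(pos_scores, neg_scores, null_auc = 0.5,
                            pos_scores2 = NULL, neg_scores2 = NULL) {
  paired <- !is.null(pos_scores2)
  if (paired) {
    ok_p <- !is.na(pos_scores) & !is.na(pos_scores2)
    ok_n <- !is.na(neg_scores) & !is.na(neg_scores2)
    pos_scores <- pos_scores[ok_p]; pos_scores2 <- pos_scores2[ok_p]
    neg_scores <- neg_scores[ok_n]; neg_scores2 <- neg_scores2[ok_n]
  } else {
    pos_scores <- pos_scores[!is.na(pos_scores)]
    neg_scores <- neg_scores[!is.na(neg_scores)]
  }
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np < 2 || nn < 2) stop("delong_auc_test: need >= 2 per class")
  c1 <- delong_components(pos_scores, neg_scores)
  if (!paired) {
    v <- var(c1$v10) / np + var(c1$v01) / nn
    stat <- c1$auc - null_auc
    out <- list(auc = c1$auc, variance = v)
  } else {
    c2 <- delong_components(pos_scores2, neg_scores2)
    v <- var(c1$v10 - c2$v10) / np + var(c1$v01 - c2$v01) / nn
    stat <- c1$auc - c2$auc
    out <- list(auc1 = c1$auc, auc2 = c2$auc, delta = stat, variance = v)
  }
  if (v <= 0 || !is.finite(v)) {
    if (stat == 0) {
      out$z <- 0; out$p <- 1; out$degenerate <- TRUE
    } else {
      warning("DeLong variance is zero (perfect separation); p set to 0")
      out$z <- sign(stat) * Inf; out$p <- 0; out$degenerate <- TRUE
    }
  } else {
    out$z <- stat / sqrt(v)
    out$p <- 2 * pnorm(-abs(out$z))
    out$degenerate <- FALSE
  }
  out
}

#' Wilcoxon signed-rank test on paired score differences
#'
#' Exact when n (nonzero differences) <= 25 — including under ties, via
#' dynamic programming over the midrank sum (signed midranks are half
#' integers, so doubling makes the sign-flip distribution an integer
#' convolution) — with the normal approximation beyond that; zero
#' differences are dropped per convention.
#'
#' @param paired_diffs vector of pathogenic-minus-non-pathogenic score
#'   differences.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @export
wilcoxon_signed_rank <- function(paired_diffs,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- paired_diffs[!is.na(paired_diffs) & paired_diffs != 0]
  if (!length(d)) stop("wilcoxon_signed_rank: all differences are zero")
  n <- length(d)
  if (n > 25)
    return(suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE,
                  alternative = alternative)$p.value))
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks
  w2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # counts of sign assignments by doubled rank sum
  f <- numeric(tot + 1L)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(tot + 1L)] <- g[(r + 1L):(tot + 1L)] + f[1:(tot + 1L - r)]
    f <- g
  }
  f <- f / 2^n
  p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
  p_le <- sum(f[1:(w2 + 1L)])
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

#' One-sided paired t-test (pathogenic > non-pathogenic)
#'
#' @param paired_diffs pathogenic-minus-non-pathogenic score differences.
#' @return one-sided p-value for mean difference > 0.
#' @export
paired_t_one_sided <- function(paired_diffs) {
  d <- paired_diffs[!is.na(paired_diffs)]
  if (length(d) < 2) stop("paired_t_one_sided: need >= 2 differences")
  t.test(d, alternative = "greater")$p.value
}

# resolve scores for the two sides of a pair set
pair_scores <- function(pairs, scores, tool) {
  if (inherits(pairs, "allele_pair_set")) {
    s_path <- score_lookup(scores, pairs$chrom, pairs$pos,
                           pairs$pathogenic_alt, tool)
    s_non <- score_lookup(scores, pairs$chrom, pairs$pos,
                          pairs$nonpathogenic_alt, tool)
  } else {
    s_path <- score_lookup(scores, pairs$chrom, pairs$dav_pos,
                           pairs$dav_alt, tool)
    s_non <- score_lookup(scores, pairs$chrom, pairs$cpp_pos,
                          pairs$cpp_alt, tool)
  }
  list(path = s_path, non = s_non)
}

#' Matched-pair success rate
#'
#' Fraction of pairs in which the pathogenic member outscores the
#' non-pathogenic one; ties earn `config$tie_credit` (0.5 by default, so an
#' allele-invariant tool scores exactly 50% on the allelic task). Pairs
#' with either score missing count into `n_missing`. Optionally stratified
#' by a labelling vector (conservation class, context or distance bin).
#'
#' @param pairs an `allele_pair_set` or `matched_pair_set`.
#' @param scores a [score_table()].
#' @param tool tool name.
#' @param config an [eval_config()].
#' @param strata optional per-pair stratum labels.
#' @return data frame: `metric`, `stratum`, `value`, `n_used`, `n_missing`
#'   (first row is the overall rate; strata with no usable pair are omitted
#'   with a warning).
#' @export
success_rate <- function(pairs, scores, tool, config = eval_config(),
                         strata = NULL) {
  s <- pair_scores(pairs, scores, tool)
  usable <- !is.na(s$path) & !is.na(s$non)
  credit <- ifelse(s$path > s$non, 1,
                   ifelse(s$path == s$non, config$tie_credit, 0))
  rows <- data.frame(metric = "success_rate", stratum = "overall",
                     value = mean(credit[usable]),
                     n_used = sum(usable), n_missing = sum(!usable),
                     stringsAsFactors = FALSE)
  if (!is.null(strata)) {
    for (st in unique(strata[!is.na(strata)])) {
      m <- strata == st & !is.na(strata)
      if (!any(m & usable)) {
        warning("stratum '", st, "' has no usable pair; omitted")
        next
      }
      rows <- rbind(rows, data.frame(
        metric = "success_rate", stratum = st,
        value = mean(credit[m & usable]),
        n_used = sum(m & usable), n_missing = sum(m & !usable),
        stringsAsFactors = FALSE))
    }
  }
  class(rows) <- c("eval_result", "data.frame")
  rows
}

#' Pearson correlation of scores between variant pairs, by distance bin
#'
#' For every unordered pair of distinct variant positions whose genomic
#' distance falls in a bin, correlates the two scores; bins with fewer
#' than `min_pairs` pairs or degenerate (constant) scores are reported as
#' `NA`.
#'
#' @param variants data frame with `chrom`, `pos`, `alt`.
#' @param scores a [score_table()].
#' @param tool tool name.
#' @param bin_edges upper bin edges in bp (lower edge of the first bin
#'   is 0, exclusive).
#' @param min_pairs minimum pair count per bin (default 3).
#' @param cumulative when `TRUE`, bins are nested thresholds
#'   (distance <= edge) instead of disjoint intervals.
#' @return data frame: `bin`, `r`, `n_pairs`.
#' @export
score_correlation_by_distance <- function(variants, scores, tool, bin_edges,
                                          min_pairs = 3L,
                                          cumulative = FALSE) {
  sc <- score_lookup(scores, variants$chrom, variants$pos, variants$alt,
                     tool)
  ok <- which(!is.na(sc))
  v <- variants[ok, , drop = FALSE]; sc <- sc[ok]
  maxd <- max(bin_edges)
  xs <- list(); ys <- list(); ds <- list()
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    o <- i[order(v$pos[i])]
    p <- v$pos[o]
    for (a in seq_along(o)) {
      b <- a + 1L
      while (b <= length(o) && p[b] - p[a] <= maxd) {
        if (p[b] != p[a]) {
          xs[[length(xs) + 1L]] <- sc[o[a]]
          ys[[length(ys) + 1L]] <- sc[o[b]]
          ds[[length(ds) + 1L]] <- p[b] - p[a]
        }
        b <- b + 1L
      }
    }
  }
  x <- unlist(xs); y <- unlist(ys); d <- unlist(ds)
  lo <- c(0, head(bin_edges, -1))
  res <- lapply(seq_along(bin_edges), function(k) {
    inbin <- if (cumulative) d <= bin_edges[k]
    else d > lo[k] & d <= bin_edges[k]
    n <- sum(inbin)
    r <- if (n >= min_pairs && sd(x[inbin]) > 0 && sd(y[inbin]) > 0)
      cor(x[inbin], y[inbin]) else NA_real_
    data.frame(bin = if (cumulative) sprintf("<=%g", bin_edges[k])
               else sprintf("(%g,%g]", lo[k], bin_edges[k]),
               r = r, n_pairs = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Anchor-to-neighbour feature correlation by distance class
#'
#' For each anchor variant, collects neighbours within each flanking
#' distance class (nested thresholds, e.g. 10, 100, 200, 500, 1000, 10000,
#' 50000 bp) and correlates anchor and neighbour values of each predictor
#' over the pooled (anchor, neighbour) pairs. Predictors that are entirely
#' missing or constant are omitted.
#'
#' @param predictor_table data frame: `chrom`, `pos`, then one numeric
#'   column per predictor.
#' @param anchors logical vector marking anchor rows (e.g. DAV-labelled).
#' @param bin_edges distance-class thresholds in bp.
#' @return matrix predictors x distance classes of Pearson r.
#' @export
predictor_distance_correlation <- function(predictor_table, anchors,
                                           bin_edges = c(10, 100, 200, 500,
                                                         1000, 10000, 50000)) {
  feat_cols <- setdiff(names(predictor_table), c("chrom", "pos"))
  anchor_idx <- which(anchors)
  res <- matrix(NA_real_, length(feat_cols), length(bin_edges),
                dimnames = list(feat_cols, sprintf("<=%g", bin_edges)))
  keep <- logical(length(feat_cols))
  for (k in seq_along(bin_edges)) {
    ai <- list(); ni <- list()
    for (a in anchor_idx) {
      nb <- which(predictor_table$chrom == predictor_table$chrom[a] &
                    abs(predictor_table$pos - predictor_table$pos[a]) <=
                    bin_edges[k] &
                    predictor_table$pos != predictor_table$pos[a])
      if (length(nb)) {
        ai[[length(ai) + 1L]] <- rep(a, length(nb))
        ni[[length(ni) + 1L]] <- nb
      }
    }
    ai <- unlist(ai); ni <- unlist(ni)
    if (is.null(ai)) next
    for (f in seq_along(feat_cols)) {
      x <- predictor_table[[feat_cols[f]]][ai]
      y <- predictor_table[[feat_cols[f]]][ni]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        res[f, k] <- cor(x[ok], y[ok])
        keep[f] <- TRUE
      }
    }
  }
  res[keep, , drop = FALSE]
}

#' Precision-recall curve (average-precision convention)
#'
#' Thresholds descend over unique score values; tied scores enter as one
#' block.
#'
#' @param labels logical/0-1 vector (TRUE = positive).
#' @param scores numeric scores (higher = more pathogenic); `NA` pairs
#'   dropped.
#' @return data frame `recall`, `precision` at each threshold block.
#' @export
pr_curve <- function(labels, scores) {
  ok <- !is.na(scores) & !is.na(labels)
  labels <- as.logical(labels[ok]); scores <- scores[ok]
  P <- sum(labels)
  if (P == 0) stop("pr_curve: no positives")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  # last index of each unique-score block (ties processed together)
  blk_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[blk_end]
  n_at <- blk_end
  data.frame(recall = tp / P, precision = tp / n_at)
}

#' Area under the precision-recall curve (average precision)
#'
#' AP = sum over threshold blocks of (R_k - R_(k-1)) * P_k. The step
#' convention (rather than trapezoidal interpolation) avoids the known
#' overestimation of interpolated PR areas.
#'
#' @inheritParams pr_curve
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(labels, scores) {
  pr <- pr_curve(labels, scores)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Top-percentile precision
#'
#' The short list is everything at or above the (100 - p)th percentile of
#' the mixed score distribution; boundary ties are all included and
#' precision uses the realised list size.
#'
#' @param labels logical/0-1 pathogenicity labels.
#' @param scores numeric scores.
#' @param top_percentile list size as a percentage of the mixture.
#' @return fraction of the short list that is pathogenic.
#' @export
top_percentile_precision <- function(labels, scores, top_percentile = 10) {
  ok <- !is.na(scores)
  labels <- as.logical(labels[ok]); scores <- scores[ok]
  cutoff <- quantile(scores, 1 - top_percentile / 100, names = FALSE)
  sel <- scores >= cutoff
  mean(labels[sel])
}

#' Evaluate a tool across mixture test sets
#'
#' For each mixing ratio: the top-percentile precision and the AUPRC.
#'
#' @param mixtures list of `mixture_set`s from [build_mixtures()].
#' @param scores a [score_table()].
#' @param tool tool name.
#' @param config an [eval_config()].
#' @return data frame: `ratio`, `n_pos`, `n_neg`, `n_missing`,
#'   `top_precision`, `auprc`.
#' @export
mixing_sweep <- function(mixtures, scores, tool, config = eval_config()) {
  rows <- lapply(mixtures, function(mx) {
    sc <- score_lookup(scores, mx$chrom, mx$pos, mx$alt, tool)
    ok <- !is.na(sc)
    data.frame(ratio = attr(mx, "mixing_ratio"),
               n_pos = sum(mx$pathogenic[ok]),
               n_neg = sum(!mx$pathogenic[ok]),
               n_missing = sum(!ok),
               top_precision = top_percentile_precision(
                 mx$pathogenic[ok], sc[ok], config$top_percentile),
               auprc = auprc(mx$pathogenic[ok], sc[ok]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$ratio), , drop = FALSE]
}

#' Largest mixing ratio at which a tool sustains a target AUPRC
#'
#' Scans the sweep in increasing ratio order and returns the largest ratio
#' with AUPRC above the target, linearly interpolating between the last
#' ratio above and the first below. Returns 0 when the target is missed
#' already at the smallest tested ratio (the tool is excluded, as with
#' predictors that never reach the target).
#'
#' @param sweep data frame from [mixing_sweep()].
#' @param target AUPRC target (default from [eval_config()]).
#' @return the (possibly interpolated) maximum ratio.
#' @export
max_ratio_at_target <- function(sweep, target = 0.8) {
  sweep <- sweep[order(sweep$ratio), , drop = FALSE]
  above <- sweep$auprc > target
  if (!any(above)) return(0)
  if (all(above)) return(max(sweep$ratio))
  k <- max(which(above))       # last ratio above target
  if (k == nrow(sweep)) return(sweep$ratio[k])
  # interpolate between ratio[k] (above) and ratio[k+1] (below)
  r1 <- sweep$ratio[k]; r2 <- sweep$ratio[k + 1]
  a1 <- sweep$auprc[k]; a2 <- sweep$auprc[k + 1]
  r1 + (a1 - target) / (a1 - a2) * (r2 - r1)
}

#' Score cutoff maximising balanced accuracy
#'
#' Scans candidate cutoffs at the observed score values under the rule
#' "score >= cutoff is called positive" and returns the cutoff maximising
#' TPR + TNR; among maximisers, the midpoint of the optimal threshold
#' interval is returned (lowest such interval when several achieve the
#' maximum).
#'
#' @param pos_scores,neg_scores calibration scores of the two classes.
#' @return list: `cutoff`, `tpr`, `tnr`.
#' @export
balanced_accuracy_cutoff <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores))
    stop("balanced_accuracy_cutoff: empty class")
  u <- sort(unique(c(pos_scores, neg_scores)))
  j <- vapply(u, function(c0)
    mean(pos_scores >= c0) + mean(neg_scores < c0), 0)
  k <- which.max(j)
  cutoff <- if (k == 1) u[1] else (u[k - 1] + u[k]) / 2
  list(cutoff = cutoff, tpr = mean(pos_scores >= cutoff),
       tnr = mean(neg_scores < cutoff))
}

#' Sample odds ratio with Fisher's exact p-value
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `odds_ratio` (ad/bc; `NA` when a margin cell is zero) and
#'   the two-sided Fisher exact `p`.
#' @export
fisher_exact_or <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  or <- if (table[1, 2] == 0 || table[2, 1] == 0) {
    if (table[1, 1] == 0 || table[2, 2] == 0) NA_real_ else Inf
  } else (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(odds_ratio = or, p = fisher.test(table)$p.value)
}

#' One-way ANOVA F-test across groups
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list: `F`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("one_way_anova: need >= 2 groups")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(res$statistic), p = unname(res$p.value))
}
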