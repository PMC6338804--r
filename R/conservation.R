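#' Fitch small-parsimony substitution count for one site
#'
#' Computes the minimum number of substitutions on the tree consistent with
#' the observed leaf bases at one alignment column (Fitch's dynamic
#' program). Gap or ambiguous leaves, and tree tips absent from the column,
#' carry the full state set \{A,C,G,T\} (missing data) so indels never count
#' as substitutions. The tree must be binary; the count is the unrooted
#' parsimony score and does not depend on root placement.
#'
#' @param tree a rooted binary `phylo`.
#' @param column named character vector, leaf name -> symbol in
#'   A/C/G/T/`-`; names must be tree tips.
#' @return integer minimum substitution count.
#' @export
fitch_min_substitutions <- function(tree, column) {
  bad <- setdiff(names(column), tree$tip.label)
  if (length(bad))
    stop("column names not in tree: ", paste(bad, collapse = ", "))
  m <- matrix(column, nrow = length(column), ncol = 1,
              dimnames = list(names(column), NULL))
  fitch_counts(tree, m)[1]
}

# vectorised Fitch over all columns of an alignment matrix
fitch_counts <- function(tree, alignment) {
  if (!ape::is.binary(tree))
    stop("Fitch counting requires a binary tree")
  n_tip <- length(tree$tip.label)
  n_sites <- ncol(alignment)
  po <- reorder(tree, "postorder")
  n_node <- n_tip + po$Nnode
  states <- matrix(0L, n_node, n_sites)     # 0 = not yet assigned
  for (tip in seq_len(n_tip)) {
    lab <- po$tip.label[tip]
    states[tip, ] <- if (lab %in% rownames(alignment))
      encode_bases(alignment[lab, ]) else 15L
  }
  counts <- integer(n_sites)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; chd <- po$edge[e, 2L]
    cs <- states[chd, ]
    ps <- states[par, ]
    first <- ps == 0L
    if (any(first)) ps[first] <- cs[first]
    rest <- !first
    if (any(rest)) {
      inter <- bitwAnd(ps[rest], cs[rest])
      empty <- inter == 0L
      counts[rest][empty] <- counts[rest][empty] + 1L
      ps[rest] <- ifelse(empty, bitwOr(ps[rest], cs[rest]), inter)
    }
    states[par, ] <- ps
  }
  counts
}

#' Per-site absolute evolutionary rate and conservation class
#'
#' Divides the Fitch minimum substitution count by the total tree length in
#' billions of years, yielding substitutions/site/billion years, and
#' assigns the conservation class: `ultra` (rate = 0), `well`
#' (0 < rate < 2) or `least` (rate >= 2).
#'
#' @param tree a rooted binary `phylo` with branch lengths in years.
#' @param column named character vector as in [fitch_min_substitutions()].
#' @param total_length_years denominator tree length; defaults to the sum
#'   of all branch lengths of `tree` (set it explicitly to use e.g. a
#'   reduced-panel tree length).
#' @return a `conservation_call` list: `min_substitutions`, `rate`,
#'   `klass`, `gapped`.
#' @export
evolutionary_rate <- function(tree, column,
                              total_length_years = sum(tree$edge.length)) {
  if (!isTRUE(total_length_years > 0))
    stop("total_length_years must be > 0")
  subs <- fitch_min_substitutions(tree, column)
  rate <- subs / (total_length_years / 1e9)
  structure(list(min_substitutions = subs, rate = rate,
                 klass = conservation_class(rate),
                 gapped = any(!(column %in% BASES))),
            class = "conservation_call")
}

#' @export
print.conservation_call <- function(x, ...) {
  cat(sprintf("conservation call: %d substitution(s), %.4g subs/site/Gy [%s]%s\n",
              x$min_substitutions, x$rate, x$klass,
              if (x$gapped) " (gapped)" else ""))
  invisible(x)
}

#' Conservation class from an absolute rate
#'
#' @param rate substitutions/site/billion years.
#' @return `"ultra"` (rate 0), `"well"` (0 < rate < 2) or `"least"`
#'   (rate >= 2); the boundary at 2 is closed on the right.
#' @export
conservation_class <- function(rate) {
  ifelse(rate == 0, "ultra", ifelse(rate < 2, "well", "least"))
}

#' Per-site conservation table for a whole alignment
#'
#' @param tree a rooted binary `phylo`, branch lengths in years.
#' @param alignment matrix from [read_alignment()] or
#'   [simulate_alignment()].
#' @param total_length_years denominator as in [evolutionary_rate()].
#' @return data frame: `pos` (column index), `min_subs`, `rate`, `klass`,
#'   `gapped`.
#' @export
conservation_table <- function(tree, alignment,
                               total_length_years = sum(tree$edge.length)) {
  if (!isTRUE(total_length_years > 0))
    stop("total_length_years must be > 0")
  subs <- fitch_counts(tree, alignment)
  rate <- subs / (total_length_years / 1e9)
  data.frame(pos = seq_len(ncol(alignment)), min_subs = subs, rate = rate,
             klass = conservation_class(rate),
             gapped = apply(alignment, 2, function(col) any(!(col %in% BASES))),
             stringsAsFactors = FALSE)
}

#' Is an alignment column completely conserved?
#'
#' @param column named character vector over A/C/G/T/`-`.
#' @param require_no_gaps when `TRUE`, a single gap disqualifies the site;
#'   when `FALSE` gaps are treated as missing data.
#' @return `TRUE` iff all non-gap symbols are one identical base (and no
#'   gaps occur, if required). A column with no non-gap symbol is not
#'   conserved.
#' @export
completely_conserved <- function(column, require_no_gaps = TRUE) {
  isbase <- column %in% BASES
  if (require_no_gaps && any(!isbase)) return(FALSE)
  obs <- unique(column[isbase])
  length(obs) == 1L
}

#' Fraction of neutrally evolving sites that look completely conserved
#'
#' Simulates `config$n_sites` independent alignment columns under the HKY
#' model on a dated phylogeny and reports the fraction of columns whose
#' base is identical across all leaves, with its binomial Monte-Carlo
#' standard error. Under realistic mammalian rates this fraction is tiny,
#' which is what licenses treating completely conserved positions as
#' non-neutral.
#'
#' @param config a [sim_config()].
#' @param tree optional `phylo`; when `NULL` a tree is generated from
#'   `config` via [gen_tree()].
#' @return list: `fraction`, `se`, `n_sites`, `total_length_years`.
#' @export
neutral_conserved_fraction <- function(config, tree = NULL) {
  if (is.null(tree)) tree <- gen_tree(config)
  aln <- simulate_alignment(tree, config)
  same <- colSums(aln != aln[rep(1L, nrow(aln)), , drop = FALSE]) == 0L
  f <- mean(same)
  list(fraction = f, se = sqrt(f * (1 - f) / length(same)),
       n_sites = length(same),
       total_length_years = sum(tree$edge.length))
}

#' Neutral conserved-fraction grid experiment
#'
#' Runs [neutral_conserved_fraction()] over a grid of substitution rates
#' and G+C contents, holding the tree fixed.
#'
#' @param rates vector of substitution rates (per base per year).
#' @param gcs vector of stationary G+C contents.
#' @param config base [sim_config()]; its `rate`/`gc` are overridden.
#' @param tree optional fixed tree (generated from `config` when `NULL`).
#' @return data frame: `rate`, `gc`, `fraction`, `se`, `n_sites`.
#' @export
neutral_conserved_grid <- function(rates, gcs, config = sim_config(),
                                   tree = NULL) {
  if (is.null(tree)) tree <- gen_tree(config)
  grid <- expand.grid(rate = rates, gc = gcs)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$rate <- grid$rate[i]; cfg$gc <- grid$gc[i]
    ncf <- neutral_conserved_fraction(cfg, tree)
    data.frame(rate = cfg$rate, gc = cfg$gc, fraction = ncf$fraction,
               se = ncf$se, n_sites = ncf$n_sites)
  })
  do.call(rbind, res)
}
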