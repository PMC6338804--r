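#' Simulation configuration for neutral sequence evolution
#'
#' Defaults are the study conditions of the neutral conserved-site
#' experiment: a 58-taxon mammalian-like phylogeny whose branches sum to
#' 2.9 billion years, a neutral substitution rate of 2.2e-9 per base per
#' year, an HKY transition/transversion rate ratio of 3.6 and unbiased base
#' composition.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param total_length_years target total branch length, in years.
#' @param rate substitutions per base per year at stationarity.
#' @param kappa HKY transition/transversion instantaneous-rate ratio.
#' @param gc stationary G+C content, in (0, 1).
#' @param n_sites number of independent alignment columns to simulate.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 58L, total_length_years = 2.9e9,
                       rate = 2.2e-9, kappa = 3.6, gc = 0.5,
                       n_sites = 100000L, seed = 1L) {
  stopifnot(n_taxa >= 2, total_length_years > 0, rate >= 0, kappa > 0,
            gc > 0, gc < 1, n_sites >= 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 total_length_years = total_length_years,
                 rate = rate, kappa = kappa, gc = gc,
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a dated random phylogeny
#'
#' Draws an ultrametric pure-birth (Yule) topology with the requested number
#' of leaves and rescales every branch by one common factor so the total
#' branch length equals `config$total_length_years` exactly. Only the total
#' length matters for the neutral conservation argument, so the topology is
#' free while the evolutionary time budget is fixed.
#'
#' @param config a [sim_config()].
#' @return a `phylo` with branch lengths in years.
#' @export
gen_tree <- function(config) {
  set.seed(config$seed)
  if (config$n_taxa == 2L) {
    tr <- ape::read.tree(text = "(t1:1,t2:1);")
  } else {
    tr <- phytools::pbtree(n = config$n_taxa, quiet = TRUE)
  }
  tr$edge.length <- tr$edge.length *
    (config$total_length_years / sum(tr$edge.length))
  tr
}

# HKY machinery -------------------------------------------------------------

#' HKY substitution model with unit expected rate
#'
#' Builds the HKY rate matrix with stationary distribution
#' pi = ((1-gc)/2, gc/2, gc/2, (1-gc)/2) over (A, C, G, T) and
#' transition/transversion rate ratio `kappa`, scaled so the expected
#' substitution rate at stationarity is 1 per unit time. The spectral
#' decomposition (via the pi-symmetrised form, which is symmetric for any
#' reversible chain) is precomputed so transition matrices P(t) come from a
#' closed-form matrix exponential.
#'
#' @param kappa transition/transversion rate ratio.
#' @param gc stationary G+C content.
#' @return an `hky_model` list with `Q`, `pi` and eigen structure.
#' @export
hky_model <- function(kappa, gc) {
  stopifnot(kappa > 0, gc > 0, gc < 1)
  pi <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ts <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  ts["A", "G"] <- ts["G", "A"] <- ts["C", "T"] <- ts["T", "C"] <- TRUE
  Q <- outer(rep(1, 4), pi)
  Q[ts] <- Q[ts] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))        # expected substitutions per unit time
  Q <- Q / mu
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2             # symmetric up to round-off
  es <- eigen(S, symmetric = TRUE)
  structure(list(Q = Q, pi = pi, kappa = kappa, gc = gc,
                 evec = es$vectors, eval = es$values, d = d),
            class = "hky_model")
}

#' HKY transition-probability matrix P(t)
#'
#' @param model an [hky_model()].
#' @param t elapsed time in expected substitutions (i.e. rate * years when
#'   the model is normalised to unit rate).
#' @return 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
hky_transition <- function(model, t) {
  P <- diag(1 / model$d) %*% model$evec %*%
    (exp(model$eval * t) * t(model$evec)) %*% diag(model$d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Simulate a neutral alignment on a dated tree
#'
#' Sites are i.i.d.: the root base is drawn from the HKY stationary
#' distribution and each branch applies the exact transition matrix
#' P(rate * branch_length). No indels, no rate heterogeneity across sites.
#'
#' @param tree `phylo` with branch lengths in years.
#' @param config a [sim_config()]; `n_taxa`/`total_length_years` are taken
#'   from the tree, the substitution parameters and `n_sites`/`seed` from
#'   the config.
#' @return character matrix (leaves x sites) over A/C/G/T.
#' @export
simulate_alignment <- function(tree, config) {
  stopifnot(length(tree$tip.label) >= 2)
  set.seed(config$seed)
  model <- hky_model(config$kappa, config$gc)
  n_sites <- config$n_sites
  tr <- reorder(tree, "cladewise")   # parents before children
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  root <- n_tip + 1L
  states <- matrix(0L, n_node, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
    P <- hky_transition(model, config$rate * tr$edge.length[e])
    ps <- states[par, ]
    cs <- integer(n_sites)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[chd, ] <- cs
  }
  out <- matrix(BASES[states[seq_len(n_tip), , drop = FALSE]],
                n_tip, n_sites)
  rownames(out) <- tr$tip.label
  out
}

# variant catalogs -----------------------------------------------------------

#' Parameters for the synthetic variant catalog
#'
#' The generator emulates the shape of curated variant collections: DAVs
#' cluster in the 1 kb region upstream of gene transcription start sites
#' (some genes carry tens of DAVs), while CPPs fall as a homogeneous Poisson
#' process across the genome with common minor-allele frequencies.
#'
#' @param n_genes number of genes.
#' @param genome_length_bp length of the single simulated chromosome.
#' @param dav_per_gene either a single Poisson mean or an integer vector of
#'   per-gene DAV counts (recycled to `n_genes`).
#' @param cpp_density expected CPPs per bp.
#' @param maf_dist function `n -> n` CPP minor-allele frequencies; default
#'   Uniform(0.05, 0.5).
#' @param dav_maf_dist function `n -> n` DAV population frequencies;
#'   default Beta(1, 200) (rare).
#' @param gene_body_bp gene body length used for context assignment.
#' @param ld_block_bp width of the fixed LD-block tiling.
#' @param evidence_probs named probabilities for the DAV evidence flags.
#' @param seed integer seed.
#' @return a `catalog_params` list.
#' @export
catalog_params <- function(n_genes = 50L, genome_length_bp = 1e6,
                           dav_per_gene = 3, cpp_density = 5e-4,
                           maf_dist = function(n) runif(n, 0.05, 0.5),
                           dav_maf_dist = function(n) rbeta(n, 1, 200),
                           gene_body_bp = 10000L, ld_block_bp = 20000L,
                           evidence_probs = c(dm_certain = 0.8,
                                              functional_evidence = 0.7,
                                              in_regulatory_element = 0.8),
                           seed = 1L) {
  stopifnot(n_genes >= 0, genome_length_bp >= 1, cpp_density >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 genome_length_bp = as.integer(genome_length_bp),
                 dav_per_gene = dav_per_gene, cpp_density = cpp_density,
                 maf_dist = maf_dist, dav_maf_dist = dav_maf_dist,
                 gene_body_bp = as.integer(gene_body_bp),
                 ld_block_bp = as.integer(ld_block_bp),
                 evidence_probs = evidence_probs,
                 seed = as.integer(seed)),
            class = "catalog_params")
}

# context from position relative to the nearest gene (TSS at gene start,
# body extends downstream)
assign_context <- function(pos, tss, body_bp) {
  if (!length(tss)) return(rep("desert", length(pos)))
  ctx <- character(length(pos))
  for (i in seq_along(pos)) {
    d_tss <- pos[i] - tss                    # negative = upstream
    g <- which.min(abs(d_tss))
    d <- d_tss[g]
    ctx[i] <-
      if (d >= -1000 && d < 0) "promoter"
      else if (d >= 0 && d < 0.1 * body_bp) "utr5"
      else if (d >= 0.9 * body_bp && d < body_bp) "utr3"
      else if (d >= 0 && d < body_bp) "intron"
      else if (d < 0 && d >= -1e5) "upstream100k"
      else if (d >= body_bp && d < body_bp + 1e5) "downstream100k"
      else "desert"
  }
  ctx
}

#' Simulate a variant catalog
#'
#' @param params a [catalog_params()].
#' @return a [variant_catalog()] with DAV and CPP records, MAFs, evidence
#'   flags, genomic context, nearest gene and LD-block labels. Deterministic
#'   under `params$seed`.
#' @export
simulate_catalog <- function(params) {
  set.seed(params$seed)
  L <- params$genome_length_bp
  tss <- if (params$n_genes > 0)
    sort(sample.int(L, params$n_genes)) else integer()
  genes <- if (params$n_genes > 0) sprintf("g%03d", seq_along(tss)) else character()

  dcounts <- params$dav_per_gene
  if (length(dcounts) == 1L && params$n_genes > 0)
    dcounts <- rpois(params$n_genes, dcounts)
  dcounts <- as.integer(rep_len(dcounts, params$n_genes))

  rows <- list()
  for (g in seq_len(params$n_genes)) {
    k <- dcounts[g]
    if (k == 0) next
    off <- sample.int(1000L, k, replace = TRUE)       # within 1 kb upstream
    pos <- pmax(1L, tss[g] - off)
    n <- length(pos)
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    maf <- params$dav_maf_dist(n)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      daf = maf, maf = maf, label = "DAV",
      functional_evidence = runif(n) < params$evidence_probs[["functional_evidence"]],
      in_regulatory_element = runif(n) < params$evidence_probs[["in_regulatory_element"]],
      dm_certain = runif(n) < params$evidence_probs[["dm_certain"]],
      has_known_association = TRUE,
      gene = genes[g], gene_dist_bp = as.numeric(abs(pos - tss[g])),
      stringsAsFactors = FALSE)
  }

  n_cpp <- rpois(1L, params$cpp_density * L)
  if (n_cpp > 0) {
    pos <- sort(sample.int(L, n_cpp, replace = TRUE))
    n <- length(pos)
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    maf <- params$maf_dist(n)
    gdist <- if (length(tss))
      vapply(pos, function(p) min(abs(p - tss)), 0) else rep(NA_real_, n)
    gidx <- if (length(tss))
      vapply(pos, function(p) which.min(abs(p - tss)), 0L) else rep(NA_integer_, n)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      daf = maf, maf = maf, label = "CPP",
      functional_evidence = FALSE, in_regulatory_element = FALSE,
      dm_certain = FALSE,
      has_known_association = runif(n) < 0.05,
      gene = if (length(tss)) genes[gidx] else NA_character_,
      gene_dist_bp = gdist,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(variant_catalog(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character())))
  df <- do.call(rbind, rows)
  df$context <- assign_context(df$pos, tss, params$gene_body_bp)
  df$ld_block <- sprintf("%s_b%d", df$chrom,
                         df$pos %/% params$ld_block_bp)
  out <- variant_catalog(df)
  attr(out, "tss") <- setNames(tss, genes)
  out
}

# score model ----------------------------------------------------------------

#' Parameters of the synthetic score model
#'
#' The simulated score of allele `alt` at position `p` is the sum of a
#' pathogenicity shift (`delta_allelic` when the allele is truly
#' pathogenic), an allele-level Gaussian effect, a position-level Gaussian
#' effect, a regional zero-mean Gaussian process over genomic coordinates
#' with covariance `sigma_regional^2 * exp(-d / corr_length_bp)`, and white
#' noise. The regional term reproduces the distance-decaying inter-site
#' correlation observed in published predictors; `allele_specific = FALSE`
#' drops the allelic term and forces all alternates at a position to share
#' one score.
#'
#' @param delta_allelic mean score shift of a pathogenic allele, score units.
#' @param sigma_allelic,sigma_positional,sigma_regional,sigma_noise standard
#'   deviations of the four variance components (>= 0).
#' @param corr_length_bp e-folding distance of the regional autocorrelation.
#' @param allele_specific does the simulated tool resolve alleles?
#' @return a `score_model_params` list.
#' @export
score_model_params <- function(delta_allelic = 1, sigma_allelic = 1,
                               sigma_positional = 0, sigma_regional = 0,
                               sigma_noise = 0, corr_length_bp = 1000,
                               allele_specific = TRUE) {
  stopifnot(sigma_allelic >= 0, sigma_positional >= 0, sigma_regional >= 0,
            sigma_noise >= 0, corr_length_bp > 0)
  structure(list(delta_allelic = delta_allelic, sigma_allelic = sigma_allelic,
                 sigma_positional = sigma_positional,
                 sigma_regional = sigma_regional, sigma_noise = sigma_noise,
                 corr_length_bp = corr_length_bp,
                 allele_specific = isTRUE(allele_specific)),
            class = "score_model_params")
}

# exact O(n) draw of the exponential-kernel GP at sorted positions: the
# kernel is Markov, so sequential nearest-neighbour conditioning is exact
# (an AR(1) in irregular time).
gp_exponential <- function(pos, sigma, corr_length) {
  n <- length(pos)
  r <- numeric(n)
  if (n == 0 || sigma == 0) return(r)
  ord <- order(pos)
  ps <- pos[ord]
  z <- rnorm(n)
  r_s <- numeric(n)
  r_s[1] <- sigma * z[1]
  if (n > 1) {
    phi <- exp(-diff(ps) / corr_length)
    for (i in 2:n)
      r_s[i] <- phi[i - 1] * r_s[i - 1] + sigma * sqrt(1 - phi[i - 1]^2) * z[i]
  }
  r[ord] <- r_s
  r
}

#' Simulate a tool score table over a variant set
#'
#' @param variants data frame with `chrom`, `pos`, `alt` (e.g. a
#'   [variant_catalog()] or the allele list of a test set).
#' @param truth logical/0-1 vector: is each (position, alt) row truly
#'   pathogenic?
#' @param params a [score_model_params()].
#' @param seed integer seed.
#' @param tool name recorded in the output table.
#' @return a [score_table()].
#' @export
simulate_scores <- function(variants, truth, params, seed = 1L,
                            tool = "sim") {
  stopifnot(nrow(variants) == length(truth))
  set.seed(seed)
  truth <- as.numeric(truth)
  pk <- pos_key(variants$chrom, variants$pos)
  upos <- !duplicated(pk)
  uidx <- match(pk, pk[upos])            # row -> unique-position index
  n_u <- sum(upos)

  # positional and regional components live on unique positions
  p_eff <- rnorm(n_u, 0, params$sigma_positional)
  r_eff <- numeric(n_u)
  uchrom <- variants$chrom[upos]; uposn <- variants$pos[upos]
  for (ch in unique(uchrom)) {
    i <- which(uchrom == ch)
    r_eff[i] <- gp_exponential(uposn[i], params$sigma_regional,
                               params$corr_length_bp)
  }

  if (params$allele_specific) {
    a_eff <- rnorm(nrow(variants), 0, params$sigma_allelic)
    eps <- rnorm(nrow(variants), 0, params$sigma_noise)
    sc <- params$delta_allelic * truth + a_eff + p_eff[uidx] +
      r_eff[uidx] + eps
  } else {
    # one score per position: delta applies if any alternate there is
    # pathogenic; noise drawn per position
    pos_truth <- as.numeric(tapply(truth, uidx, max)[as.character(seq_len(n_u))])
    eps_u <- rnorm(n_u, 0, params$sigma_noise)
    sc_u <- params$delta_allelic * pos_truth + p_eff + r_eff + eps_u
    sc <- sc_u[uidx]
  }
  score_table(data.frame(chrom = variants$chrom, pos = variants$pos,
                         alt = variants$alt, tool = tool, score = sc,
                         stringsAsFactors = FALSE),
              setNames(params$allele_specific, tool))
}
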