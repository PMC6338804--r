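# Independent oracles used by the property tests. These deliberately take
# different computational routes than the package implementations.

# exhaustive small-parsimony count: enumerate base assignments to every
# internal node (and every missing-data leaf) and take the cheapest
brute_force_parsimony <- function(tree, column) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  fixed <- rep(NA_integer_, n_node)
  free <- (n_tip + 1L):n_node
  for (tip in seq_len(n_tip)) {
    lab <- tree$tip.label[tip]
    b <- if (lab %in% names(column)) column[[lab]] else "-"
    if (b %in% c("A", "C", "G", "T")) {
      fixed[tip] <- match(b, c("A", "C", "G", "T"))
    } else {
      free <- c(free, tip)
    }
  }
  k <- length(free)
  best <- Inf
  grid <- rep(1L, k)
  repeat {
    st <- fixed
    st[free] <- grid
    cost <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (cost < best) best <- cost
    i <- 1L
    while (i <= k && grid[i] == 4L) { grid[i] <- 1L; i <- i + 1L }
    if (i > k) break
    grid[i] <- grid[i] + 1L
  }
  best
}

# AUROC by enumerating every (positive, negative) pair
pair_count_auroc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# average precision by explicit threshold sets (one set per unique score)
threshold_set_auprc <- function(labels, scores) {
  labels <- as.logical(labels)
  P <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (c0 in thr) {
    sel <- scores >= c0
    r <- sum(labels & sel) / P
    p <- sum(labels & sel) / sum(sel)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# DeLong structural components straight from the defining double loop
brute_force_delong <- function(pos, neg) {
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y), 0)), 0)
  v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y), 0)), 0)
  list(auc = mean(v10), v10 = v10, v01 = v01,
       variance = var(v10) / m + var(v01) / n)
}

# HKY transition matrix by scaled-and-squared series exponential -- a
# different route than the package's spectral decomposition
series_expm <- function(M) {
  nsq <- 20L
  A <- M / 2^nsq
  P <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in 1:12) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(nsq)) P <- P %*% P
  P
}

hky_Q_oracle <- function(kappa, gc) {
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
      (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# per-branch jump-chain (uniformisation) simulator: an exact stochastic
# alternative to applying the closed-form P(t)
jump_chain_branch <- function(states, kappa, gc, subs_t) {
  Q <- hky_Q_oracle(kappa, gc)
  lam <- max(-diag(Q))
  R <- diag(4) + Q / lam
  n <- length(states)
  k <- rpois(n, lam * subs_t)
  out <- states
  for (i in seq_len(n)) {
    s <- out[i]
    if (k[i] > 0)
      for (j in seq_len(k[i])) s <- sample.int(4L, 1L, prob = R[s, ])
    out[i] <- s
  }
  out
}

# simulate a 2-leaf alignment entirely through the jump chain
jump_chain_two_leaf <- function(t1, t2, rate, kappa, gc, n_sites) {
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  root <- sample.int(4L, n_sites, replace = TRUE, prob = pi)
  l1 <- jump_chain_branch(root, kappa, gc, rate * t1)
  l2 <- jump_chain_branch(root, kappa, gc, rate * t2)
  cbind(l1, l2)
}

# random binary rooted tree with unit-ish branch lengths
random_tree <- function(n_tip) {
  tr <- ape::rtree(n_tip, rooted = TRUE)
  tr$tip.label <- paste0("s", seq_len(n_tip))
  tr
}

random_column <- function(tree, p_gap = 0.15) {
  syms <- c("A", "C", "G", "T")
  col <- sample(syms, length(tree$tip.label), replace = TRUE)
  gap <- runif(length(col)) < p_gap
  col[gap] <- "-"
  stats::setNames(col, tree$tip.label)
}

# tiny variant-catalog builder for the test-set tests (rbind with fill)
make_catalog <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)[cols]
  }))
  variant_catalog(df)
}

cpp_row <- function(pos, ref = "A", alt = "C", maf = 0.10, daf = maf,
                    chrom = "chr1", ld_block = NA_character_,
                    has_known_association = FALSE) {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, daf = daf, maf = maf,
       label = "CPP", has_known_association = has_known_association,
       ld_block = ld_block)
}

dav_row <- function(pos, ref = "A", alt = "G", maf = 1e-4, chrom = "chr1",
                    dm_certain = TRUE, functional_evidence = TRUE,
                    in_regulatory_element = TRUE, gene = NA_character_,
                    gene_dist_bp = NA_real_, ld_block = NA_character_) {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, daf = maf, maf = maf,
       label = "DAV", dm_certain = dm_certain,
       functional_evidence = functional_evidence,
       in_regulatory_element = in_regulatory_element,
       has_known_association = TRUE, gene = gene,
       gene_dist_bp = gene_dist_bp, ld_block = ld_block)
}

# all-reference (fully conserved) species panel over given positions
conserved_panel <- function(chrom, pos, ref, n_species = 10) {
  m <- matrix(rep(ref, each = n_species), nrow = n_species,
              dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                              paste(chrom, pos, sep = ":")))
  m
}
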