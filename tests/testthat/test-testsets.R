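test_that("forbidden alleles exclude ref, observed bases and ape alleles", {
  col <- c(s1 = "A", s2 = "A", s3 = "A")
  expect_setequal(forbidden_alleles(col, "A"), c("C", "G", "T"))
  col2 <- c(s1 = "A", s2 = "C", s3 = "G")
  expect_setequal(forbidden_alleles(col2, "A"), "T")
  expect_setequal(forbidden_alleles(col, "A", ape_polymorphisms = "T"),
                  c("C", "G"))
  # gaps contribute no observed base
  expect_setequal(forbidden_alleles(c(s1 = "A", s2 = "-"), "A"),
                  c("C", "G", "T"))
})

test_that("position-matched builder applies the frequency window,
           blacklist and ape filters in order", {
  catalog <- make_catalog(
    cpp_row(100, ref = "A", alt = "C", maf = 0.10),   # survives
    cpp_row(200, ref = "A", alt = "C", maf = 0.20),   # outside [0.05, 0.15]
    cpp_row(300, ref = "G", alt = "T", maf = 0.10),   # blacklisted
    cpp_row(400, ref = "A", alt = "C", maf = 0.10))   # ape polymorphism
  aln <- conserved_panel("chr1", c(100, 200, 300, 400),
                         c("A", "A", "G", "A"))
  cfg <- builder_config(seed = 5)
  apes <- data.frame(chrom = "chr1", pos = 400, base = "G")
  res <- build_position_matched(catalog, aln, cfg,
                                association_blacklist = "chr1:300",
                                ape_polymorphisms = apes)
  expect_s3_class(res, "allele_pair_set")
  expect_equal(res$pos, 100L)
  expect_equal(res$nonpathogenic_alt, "C")
  # pathogenic allele drawn from the two non-ref non-CPP bases
  expect_true(res$pathogenic_alt %in% c("G", "T"))
  # deterministic under the seed
  expect_identical(res, build_position_matched(
    catalog, aln, cfg, association_blacklist = "chr1:300",
    ape_polymorphisms = apes))
})

test_that("position-matched pairs never contain an observed allele", {
  set.seed(31)
  n <- 40
  pos <- sort(sample.int(100000, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  catalog <- variant_catalog(data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt, maf = 0.1,
    daf = 0.1, label = "CPP"))
  # panel with scattered extra observed bases
  aln <- conserved_panel("chr1", pos, ref, n_species = 8)
  extra <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  aln[3, ] <- extra
  res <- build_position_matched(catalog, aln, builder_config(seed = 1))
  for (i in seq_len(nrow(res))) {
    col <- aln[, paste0("chr1:", res$pos[i])]
    expect_false(res$pathogenic_alt[i] %in% col)
    expect_true(res$pathogenic_alt[i] != res$ref[i])
    expect_true(res$pathogenic_alt[i] != res$nonpathogenic_alt[i])
  }
  # positions without an alignment column are dropped and counted
  aln2 <- aln[, -1, drop = FALSE]
  suppressMessages(res2 <- build_position_matched(
    catalog, aln2, builder_config(seed = 1)))
  expect_equal(attr(res2, "n_no_column"), 1L)
})

test_that("DAV evidence filters drop uncertain, unannotated and common
           records", {
  catalog <- make_catalog(
    dav_row(10),
    dav_row(20, dm_certain = FALSE),
    dav_row(30, functional_evidence = FALSE),
    dav_row(40, in_regulatory_element = FALSE),
    dav_row(50, maf = 0.02),
    cpp_row(60))
  out <- filter_davs(catalog, freq_threshold = 0.01)
  expect_equal(out$pos, c(10L))
  # looser threshold readmits the 2% record
  expect_setequal(filter_davs(catalog, freq_threshold = 0.05)$pos,
                  c(10L, 50L))
})

test_that("region-matched pairing respects window, frequency floor and
           association flags", {
  davs <- filter_davs(make_catalog(dav_row(5000)))
  cpps <- make_catalog(
    cpp_row(5100, maf = 0.2),                        # pair
    cpp_row(4500, maf = 0.3),                        # pair
    cpp_row(6000, maf = 0.3),                        # pair (boundary 1000)
    cpp_row(6001, maf = 0.3),                        # 1001 bp: out
    cpp_row(5200, maf = 0.04),                       # below MAF floor
    cpp_row(5300, maf = 0.3, has_known_association = TRUE))
  res <- build_region_matched(davs, cpps, builder_config())
  expect_s3_class(res, "matched_pair_set")
  expect_setequal(res$cpp_pos, c(5100L, 4500L, 6000L))
  expect_equal(res$distance_bp, abs(res$cpp_pos - res$dav_pos))
  # distance bins partition the pairs
  expect_false(any(is.na(res$distance_bin)))
})

test_that("LD-matched pairing uses shared block labels", {
  davs <- filter_davs(make_catalog(dav_row(5000, ld_block = "b1")))
  cpps <- make_catalog(cpp_row(4000, maf = 0.2, ld_block = "b1"),
                       cpp_row(90000, maf = 0.2, ld_block = "b1"),
                       cpp_row(7000, maf = 0.2, ld_block = "b2"))
  res <- build_ld_matched(davs, cpps, r2_threshold = 0.9)
  expect_equal(nrow(res), 2)
  expect_true(all(res$same_ld_block))
  expect_warning(build_ld_matched(davs, cpps, r2_threshold = 0.5),
                 "outside")
  cpps_na <- cpps; cpps_na$ld_block <- NA_character_
  davs_na <- davs; davs_na$ld_block <- NA_character_
  expect_error(build_ld_matched(davs_na, cpps_na, 0.9), "annotation")
})

test_that("gene-balanced subsample keeps one DAV per gene", {
  heavy <- lapply(1:40, function(i)
    dav_row(1000 + i, gene = "g1", gene_dist_bp = i))
  others <- list(dav_row(5000, gene = "g2", gene_dist_bp = 100),
                 dav_row(9000, gene = "g3", gene_dist_bp = 900),
                 dav_row(12000, gene = "g4", gene_dist_bp = 20000))  # too far
  catalog <- do.call(make_catalog, c(heavy, others))
  davs <- filter_davs(catalog)
  out <- gene_balanced_subsample(davs, builder_config(seed = 3))
  expect_equal(nrow(out), 3)              # g1, g2, g3; g4 beyond 10 kb
  expect_equal(sum(out$gene == "g1"), 1)
  expect_identical(out, gene_balanced_subsample(davs,
                                                builder_config(seed = 3)))
})

test_that("mixtures enforce separation and hit the requested ratios", {
  davs <- do.call(make_catalog, lapply(seq(10), function(i)
    dav_row(i * 10000)))
  cpps <- do.call(make_catalog, lapply(seq(2000), function(i)
    cpp_row(200000 + i * 2000)))
  cfg <- builder_config(ratios = c(1, 100), seed = 4)
  mixes <- build_mixtures(davs, cpps, cfg)
  m1 <- mixes[["1"]]
  expect_equal(sum(m1$pathogenic), 10)
  expect_equal(sum(!m1$pathogenic), 10)
  m100 <- mixes[["100"]]
  expect_equal(nrow(m100), 10 + 1000)
  # pairwise separation within each mixture
  for (m in mixes) {
    d <- diff(sort(m$pos))
    expect_true(all(d > cfg$min_separation_bp))
  }
})

test_that("of two DAVs closer than the separation only one enters", {
  davs <- make_catalog(dav_row(10000), dav_row(10500))
  cpps <- do.call(make_catalog, lapply(seq(20), function(i)
    cpp_row(50000 + i * 2000)))
  mixes <- build_mixtures(davs, cpps, builder_config(ratios = 1, seed = 2))
  expect_equal(sum(mixes[["1"]]$pathogenic), 1)
})

test_that("unsatisfiable ratios are skipped with a warning; no DAV is an
           error", {
  davs <- make_catalog(dav_row(10000))
  cpps <- make_catalog(cpp_row(50000), cpp_row(60000))
  expect_warning(mixes <- build_mixtures(davs, cpps,
                                         builder_config(ratios = c(1, 100),
                                                        seed = 2)),
                 "skipped")
  expect_named(mixes, "1")
  expect_error(build_mixtures(davs[0, ], cpps, builder_config(seed = 2)),
               "no DAV")
})

test_that("mixture building is invariant to input row order", {
  set.seed(12)
  davs <- do.call(make_catalog, lapply(seq(8), function(i)
    dav_row(i * 20000)))
  cpps <- do.call(make_catalog, lapply(seq(300), function(i)
    cpp_row(400000 + i * 3000)))
  cfg <- builder_config(ratios = c(1, 5), seed = 9)
  a <- build_mixtures(davs, cpps, cfg)
  perm_d <- davs[sample(nrow(davs)), ]
  perm_c <- cpps[sample(nrow(cpps)), ]
  b <- build_mixtures(perm_d, perm_c, cfg)
  for (r in names(a)) {
    expect_identical(a[[r]][order(a[[r]]$pos), ]$pos,
                     b[[r]][order(b[[r]]$pos), ]$pos)
  }
})

test_that("top-record selection sorts, truncates and deduplicates", {
  rec <- data.frame(id = 1:5, pos = c(10, 20, 20, 30, 40),
                    effect_size = c(5, -4, 3, 2, 1),
                    p_value = c(0.5, 0.5, 0.5, 0.5, 0.5),
                    chosen = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # distinct positions
  out <- select_top_records(rec[c(1, 4, 5), ], n = 3, key = "effect")
  expect_equal(nrow(out), 3)
  # duplicate position inside the top-n collapses
  out2 <- select_top_records(rec, n = 3, key = "effect")
  expect_equal(out2$pos, c(10, 20))
  # all-tied p-values resolve lexicographically by (position, id)
  out3 <- select_top_records(rec, n = 2, key = "p_value")
  expect_equal(out3$id, c(1L, 2L))
  # chosen flag restricts the effect ranking
  out4 <- select_top_records(rec, n = 5, key = "effect_and_chosen")
  expect_false(3 %in% out4$id)
})
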