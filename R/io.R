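#' Read a variant catalog from TSV or VCF
#'
#' Parses biallelic SNV records into a `variant_catalog` data frame, one row
#' per (position, alternate allele). Multi-allelic VCF rows are split into
#' one record per alternate; rows whose REF or ALT is not a single base are
#' skipped and counted (indels and other non-SNVs carry no allelic contrast
#' here). All positions are 1-based, all alleles on the + strand.
#'
#' A TSV must have a header naming at least `chrom`, `pos`, `ref`, `alt`;
#' recognised optional columns are `daf`, `maf`, `label`, `context`, `gene`,
#' `gene_dist_bp`, `ld_block` and the logical evidence flags
#' `functional_evidence`, `in_regulatory_element`, `dm_certain`,
#' `has_known_association`. Leading `#key=value` metadata lines are ignored.
#' For VCF the same optional fields are looked up as INFO keys (upper-case).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A `variant_catalog` data frame; the number of skipped non-SNV
#'   rows is in `attr(, "n_skipped")`.
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

variant_columns <- c("chrom", "pos", "ref", "alt", "daf", "maf", "label",
                     "functional_evidence", "in_regulatory_element",
                     "dm_certain", "has_known_association",
                     "context", "gene", "gene_dist_bp", "ld_block")

#' Construct / validate a variant catalog
#'
#' Fills missing optional columns with defaults (frequencies `NA`, label
#' `"unlabeled"`, flags `FALSE`, context `NA`) and validates the record
#' invariants: single-base ref/alt on \{A,C,G,T\}, `ref != alt`, `pos >= 1`,
#' frequencies in \[0, 1\].
#'
#' @param df data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return the validated `variant_catalog`.
#' @export
variant_catalog <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing variant columns: ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (is.null(df$daf)) df$daf <- NA_real_
  if (is.null(df$maf)) df$maf <- NA_real_
  if (is.null(df$label)) df$label <- "unlabeled"
  for (fl in c("functional_evidence", "in_regulatory_element",
               "dm_certain", "has_known_association"))
    if (is.null(df[[fl]])) df[[fl]] <- FALSE else df[[fl]] <- as.logical(df[[fl]])
  if (is.null(df$context)) df$context <- NA_character_
  if (is.null(df$gene)) df$gene <- NA_character_
  if (is.null(df$gene_dist_bp)) df$gene_dist_bp <- NA_real_
  if (is.null(df$ld_block)) df$ld_block <- NA_character_
  bad <- which(!(df$ref %in% BASES) | !(df$alt %in% BASES))
  if (length(bad)) stop("non-SNV alleles at rows: ", paste(head(bad, 5), collapse = ", "))
  if (any(df$ref == df$alt)) stop("ref == alt in some rows")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  for (fq in c("daf", "maf")) {
    v <- df[[fq]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(fq, " must lie in [0, 1]")
  }
  badlab <- setdiff(unique(df$label), LABELS)
  if (length(badlab))
    stop("unknown label(s) ", paste(badlab, collapse = ", "),
         "; allowed: ", paste(LABELS, collapse = ", "))
  badctx <- setdiff(unique(df$context[!is.na(df$context)]), CONTEXTS)
  if (length(badctx))
    stop("unknown context(s) ", paste(badctx, collapse = ", "),
         "; allowed: ", paste(CONTEXTS, collapse = ", "))
  df <- df[c(variant_columns)]
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

read_variants_tsv <- function(path) {
  tab <- read_table(path)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("TSV header lacks column(s): ", paste(miss, collapse = ", "))
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  snv <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% BASES & tab$alt %in% BASES
  n_skip <- sum(!snv)
  if (n_skip) message("read_variants: skipped ", n_skip, " non-SNV row(s)")
  out <- variant_catalog(tab[snv, , drop = FALSE])
  attr(out, "n_skipped") <- n_skip
  out
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- variant_catalog(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  info_get <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  daf <- info_get("DAF"); maf <- info_get("MAF")
  lab <- info_get("LABEL"); ctx <- info_get("CONTEXT")
  gene <- info_get("GENE"); ldb <- info_get("LDBLOCK")
  rows <- list(); n_skip <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    if (nchar(ref) != 1L || !ref %in% BASES) { n_skip <- n_skip + 1L; next }
    dafs <- if (is.na(daf[i])) NA_character_ else
      strsplit(as.character(daf[i]), ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      a <- alts[k]
      if (nchar(a) != 1L || !a %in% BASES) { n_skip <- n_skip + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref, alt = a,
        daf = suppressWarnings(as.numeric(dafs[min(k, length(dafs))])),
        maf = suppressWarnings(as.numeric(maf[i])),
        label = if (is.na(lab[i])) "unlabeled" else lab[i],
        context = ctx[i], gene = gene[i], ld_block = ldb[i],
        stringsAsFactors = FALSE)
    }
  }
  if (n_skip) message("read_variants: skipped ", n_skip, " non-SNV allele(s)")
  out <- variant_catalog(do.call(rbind, rows))
  attr(out, "n_skipped") <- n_skip
  out
}

# score tables --------------------------------------------------------------

#' Construct a score table
#'
#' A score table holds per-(chrom, pos, alt, tool) impact scores. Missing
#' keys are representable (simply absent) and distinct from score 0;
#' [score_lookup()] returns `NA` for them. Each tool carries an
#' `allele_specific` flag: tools that score positions rather than alleles
#' report one value shared by all alternates at a position.
#'
#' @param df data frame with `chrom`, `pos`, `alt`, `tool`, `score`.
#' @param allele_specific named logical vector, one entry per tool.
#' @return a `score_table` data frame.
#' @export
score_table <- function(df, allele_specific) {
  need <- c("chrom", "pos", "alt", "tool", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing score columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  df$chrom <- as.character(df$chrom); df$pos <- as.integer(df$pos)
  df$alt <- toupper(as.character(df$alt)); df$tool <- as.character(df$tool)
  df$score <- as.numeric(df$score)
  key <- paste(df$chrom, df$pos, df$alt, df$tool)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate score key: ", dup)
  }
  tools <- unique(df$tool)
  if (is.null(names(allele_specific)) && length(allele_specific) == 1L)
    allele_specific <- setNames(rep(allele_specific, length(tools)), tools)
  miss_t <- setdiff(tools, names(allele_specific))
  if (length(miss_t))
    stop("allele_specific flag missing for tool(s): ", paste(miss_t, collapse = ", "))
  rownames(df) <- NULL
  attr(df, "allele_specific") <- allele_specific
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read a per-variant score file
#'
#' The file is TSV with a header line and a mandatory coordinate pragma
#' `#coords=0` or `#coords=1` above it declaring whether `pos` is 0-based
#' (BED dialect) or 1-based; 0-based positions are converted to 1-based on
#' read. Columns: `chrom`, `pos`, `score`, plus `alt` when
#' `allele_specific = TRUE` or `ref` when `FALSE` (the score is then
#' materialised for all three non-reference alternates at the position).
#'
#' @param path file path.
#' @param tool tool name recorded in the table.
#' @param allele_specific does the tool score individual alternates?
#' @return a [score_table()].
#' @export
read_scores <- function(path, tool, allele_specific) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  prag <- grep("^#coords=", lines, value = TRUE)
  if (!length(prag))
    stop("score file lacks the required '#coords=0|1' pragma: ", path)
  base0 <- sub("^#coords=", "", prag[1]) == "0"
  body <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "score", if (allele_specific) "alt" else "ref")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("score file lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(tab$score)) stop("non-numeric score values in ", path)
  if (base0) tab$pos <- tab$pos + 1L
  if (allele_specific) {
    out <- data.frame(chrom = tab$chrom, pos = tab$pos, alt = toupper(tab$alt),
                      tool = tool, score = tab$score, stringsAsFactors = FALSE)
  } else {
    ref <- toupper(tab$ref)
    alts <- lapply(ref, function(r) setdiff(BASES, r))
    out <- data.frame(
      chrom = rep(tab$chrom, each = 3L), pos = rep(tab$pos, each = 3L),
      alt = unlist(alts), tool = tool, score = rep(tab$score, each = 3L),
      stringsAsFactors = FALSE)
  }
  score_table(out, setNames(allele_specific, tool))
}

#' Look up scores for alleles
#'
#' @param scores a [score_table()].
#' @param chrom,pos,alt vectors identifying alleles (recycled to a common
#'   length).
#' @param tool tool name.
#' @return numeric vector of scores, `NA` where no score is recorded.
#' @export
score_lookup <- function(scores, chrom, pos, alt, tool) {
  sub <- scores[scores$tool == tool, , drop = FALSE]
  idx <- match(allele_key(chrom, pos, alt),
               allele_key(sub$chrom, sub$pos, sub$alt))
  sub$score[idx]
}

# trees and alignments ------------------------------------------------------

#' Read a Newick tree (branch lengths in years)
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths: ", path)
  tr
}

#' Read a leaf-aligned FASTA alignment
#'
#' @param path FASTA file; all sequences must be equally long.
#' @return character matrix, rows = sequences (named), columns = sites;
#'   symbols in A/C/G/T with `-` for gaps and any other symbol mapped to `-`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L)
    stop("FASTA sequences have unequal lengths: ",
         paste(range(lens), collapse = " vs "))
  m <- toupper(as.character(as.matrix(seqs)))
  m[!(m %in% BASES)] <- "-"
  m
}

#' Check that tree tips and alignment rows name the same taxa
#'
#' @param tree a `phylo`.
#' @param alignment matrix from [read_alignment()].
#' @return invisibly `TRUE`; errors listing the symmetric difference
#'   otherwise.
#' @export
check_tree_alignment <- function(tree, alignment) {
  a <- setdiff(tree$tip.label, rownames(alignment))
  b <- setdiff(rownames(alignment), tree$tip.label)
  if (length(a) || length(b))
    stop("tree/alignment taxa mismatch: {",
         paste(c(a, b), collapse = ", "), "}")
  invisible(TRUE)
}

#' Extract one alignment column
#'
#' @param alignment matrix from [read_alignment()] or
#'   [simulate_alignment()].
#' @param i column (site) index.
#' @return named character vector, leaf name -> symbol.
#' @export
column_at <- function(alignment, i) {
  setNames(alignment[, i], rownames(alignment))
}

# generic tables with metadata headers --------------------------------------

#' Write a result table as TSV with a `#key=value` metadata header
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named list recorded as `#key=value` lines (config, seed, ...).
#' @export
write_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s=%s", k, format(meta[[k]], digits = 15)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @return data frame; metadata lines are returned in `attr(, "meta")`.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in metal) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Convert between 0-based and 1-based coordinates
#'
#' @param pos integer vector of positions.
#' @param from `"0"` or `"1"`: the basis `pos` is currently expressed in.
#' @return positions in the other basis (0->1 adds one; 1->0 subtracts one).
#' @export
convert_coords <- function(pos, from = c("0", "1")) {
  from <- match.arg(from)
  if (from == "0") pos + 1L else pos - 1L
}
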