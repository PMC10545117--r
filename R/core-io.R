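#' Read biallelic SNVs from a VCF
#'
#' Loads diploid genotypes from a VCF and keeps only biallelic single
#' nucleotide variants: multiallelic records and indels are dropped (and
#' counted). An optional effect table assigns each site a functional class;
#' unmatched sites default to `"unknown"`.
#'
#' @param vcf_path path to a VCF (plain or bgzipped) with GT fields.
#' @param effect_table_path optional TSV with columns
#'   `chrom, pos, ref, alt, class`.
#' @param max_missing optional per-site missingness threshold in `[0, 1]`;
#'   sites with a higher fraction of missing genotypes are dropped. Default
#'   keeps everything.
#' @return A [surf_geno]. The drop counts are attached as attribute
#'   `drop_log`.
#' @export
read_variants <- function(vcf_path, effect_table_path = NULL,
                          max_missing = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) abort("no records in VCF")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_indel <- sum(!snv & !grepl(",", alt %||% ""), na.rm = TRUE)
  n_multi <- sum(grepl(",", alt), na.rm = TRUE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  okc <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[okc] <- as.integer(a1[okc]) + as.integer(a2[okc])

  sites <- tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    effect = "unknown", gene_id = NA_character_
  )
  if (!is.null(effect_table_path)) {
    eff <- readr::read_tsv(effect_table_path, show_col_types = FALSE,
                           progress = FALSE)
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    ek <- paste(eff$chrom, eff$pos, eff$ref, eff$alt)
    hit <- match(ek, key)
    if (anyNA(hit)) {
      warn(sprintf("%d effect rows match no retained site; skipped",
                   sum(is.na(hit))))
    }
    sites$effect[hit[!is.na(hit)]] <- eff$class[!is.na(hit)]
    if (!is.null(eff$gene_id)) {
      sites$gene_id[hit[!is.na(hit)]] <- eff$gene_id[!is.na(hit)]
    }
  }
  g <- surf_geno(t(dos), sites, samples = colnames(gt))
  if (!is.null(max_missing)) {
    miss <- colMeans(is.na(g$geno))
    g <- geno_subset(g, sites = miss <= max_missing)
  }
  attr(g, "drop_log") <- tibble(
    reason = c("multiallelic", "indel_or_other"),
    n = c(n_multi, n_indel)
  )
  g
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits an uncompressed VCF with unphased diploid GT fields. When the
#' container carries ancestral assignments (see [infer_ancestral()]) the
#' ancestral allele is written into the standard `AA` INFO tag.
#'
#' @param g a [surf_geno].
#' @param path output file.
#' @param ancestral optional character vector of ancestral bases (one per
#'   site, `NA` allowed) written as `AA=` INFO entries.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(g, path, ancestral = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt <- matrix("./.", nrow(g$geno), ncol(g$geno))
  gt[which(g$geno == 0L)] <- "0/0"
  gt[which(g$geno == 1L)] <- "0/1"
  gt[which(g$geno == 2L)] <- "1/1"
  info <- if (is.null(ancestral)) rep(".", nrow(g$sites)) else {
    ifelse(is.na(ancestral), "AA=.", paste0("AA=", ancestral))
  }
  body <- paste(
    g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt, ".", "PASS",
    info, "GT", apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load gene models from a GFF3 file
#'
#' Collects CDS segments per transcript and keeps one transcript per gene:
#' the longest spliced CDS, ties broken by lexicographic transcript id.
#' Transcripts whose spliced length (after trimming the initial phase) is not
#' a multiple of three are kept but flagged `in_frame = FALSE` and are
#' excluded from codon-based statistics downstream.
#'
#' @param gff_path path to a GFF3 file with CDS features.
#' @return Tibble with one row per gene: `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds` (list of tibbles with
#'   `start, end, phase`), `cds_len`, `in_frame`.
#' @export
load_gene_models <- function(gff_path) {
  gff <- as.data.frame(rtracklayer::readGFF(gff_path))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) abort("no CDS features in GFF")
  parent <- vapply(cds$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  cds$transcript_id <- ifelse(is.na(parent), as.character(cds$ID), parent)
  # map transcript -> gene through mRNA features when present
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- if (nrow(mrna)) {
    setNames(
      vapply(mrna$Parent, function(p) {
        if (length(p) == 0) NA_character_ else as.character(p[[1]])
      }, character(1)),
      as.character(mrna$ID)
    )
  } else c()
  cds$gene_id <- ifelse(
    cds$transcript_id %in% names(tx2gene),
    unname(tx2gene[cds$transcript_id]), cds$transcript_id
  )
  tx <- as_tibble(cds) |>
    mutate(phase = as.integer(as.character(.data$phase))) |>
    group_by(.data$gene_id, .data$transcript_id, chrom = as.character(.data$seqid),
             strand = as.character(.data$strand)) |>
    summarise(
      cds = {
        d <- dplyr::pick("start", "end", "phase")
        list(as_tibble(d[order(d$start), ]))
      },
      cds_len = sum(.data$end - .data$start + 1L),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
  out <- tx |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$cds_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  first_phase <- vapply(seq_len(nrow(out)), function(i) {
    segs <- out$cds[[i]]
    if (out$strand[i] == "-") segs <- segs[rev(seq_len(nrow(segs))), ]
    p <- segs$phase[1]
    if (is.na(p)) 0L else p
  }, integer(1))
  out$in_frame <- (out$cds_len - first_phase) %% 3L == 0L
  if (any(!out$in_frame)) {
    inform(sprintf("%d gene(s) flagged out-of-frame and excluded from codon statistics",
                   sum(!out$in_frame)))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Read a BED file into a normalized region set
#'
#' Intervals stay in BED's 0-based half-open convention; overlapping or
#' adjacent intervals sharing a label are merged.
#'
#' @param bed_path BED3+ file (no header).
#' @param label label attached to every interval (e.g. `"tetraploid"`).
#' @return Tibble `chrom, start, end, label`, sorted and merged.
#' @export
read_region_set <- function(bed_path, label = "region") {
  raw <- tryCatch(
    readr::read_tsv(bed_path, col_names = FALSE, show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) tibble()
  )
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  bed <- tibble(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
                end = as.integer(raw[[3]]))
  bad <- bed$start >= bed$end
  if (any(bad)) {
    warn(sprintf("%d BED record(s) with start >= end rejected", sum(bad)))
    bed <- bed[!bad, , drop = FALSE]
  }
  if (nrow(bed) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    bed$chrom, IRanges::IRanges(bed$start + 1L, bed$end)
  ))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = label
  ) |> arrange(.data$chrom, .data$start)
}

# ---- coding alignments -----------------------------------------------------

# coding-order genomic positions of a gene model (after phase trimming)
coding_positions <- function(gene) {
  segs <- gene$cds[[1]]
  pos <- unlist(lapply(seq_len(nrow(segs)),
                       function(i) segs$start[i]:segs$end[i]))
  if (gene$strand == "-") pos <- rev(pos)
  ph_segs <- if (gene$strand == "-") segs[rev(seq_len(nrow(segs))), ] else segs
  ph <- ph_segs$phase[1]
  if (!is.na(ph) && ph > 0) pos <- pos[-seq_len(ph)]
  pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reconstruct per-individual coding alignments from genotypes
#'
#' Rebuilds two pseudo-haplotype coding sequences per individual by
#' substituting each variant allele into the reference CDS (the classical
#' "vcf2fasta" step). Homozygous genotypes place the allele on both
#' haplotypes; unphased heterozygotes are assigned to the two haplotypes
#' uniformly at random under `seed` (frequency statistics are invariant to
#' this choice); missing genotypes become `N` on both haplotypes.
#'
#' @param genes gene-model tibble from [load_gene_models()]; out-of-frame
#'   genes are skipped.
#' @param g a [surf_geno].
#' @param ref named character vector (or `Biostrings::DNAStringSet`) of
#'   reference chromosome sequences.
#' @param seed integer seed for heterozygote assignment.
#' @return A `surf_cds_aln`: haplotype matrix (2 rows per individual) over
#'   the concatenated coding space, with a gene map and per-column genomic
#'   coordinates.
#' @export
reconstruct_cds_alignment <- function(genes, g, ref, seed = 1L) {
  if (methods::is(ref, "DNAStringSet")) ref <- as.character(ref)
  genes <- genes[genes$in_frame, , drop = FALSE]
  if (nrow(genes) == 0) abort("no in-frame genes")
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    if (!gene$chrom %in% names(ref)) {
      abort(sprintf("chromosome %s absent from reference", gene$chrom))
    }
    gpos <- coding_positions(gene)
    base <- strsplit(ref[[gene$chrom]], "")[[1]][gpos]
    if (gene$strand == "-") base <- unname(COMPLEMENT[base])
    list(gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
         gpos = gpos, base = toupper(base))
  })
  ncol_total <- sum(vapply(per_gene, function(x) length(x$gpos), integer(1)))
  n_hap <- 2L * length(g$samples)
  offsets <- cumsum(c(0L, vapply(per_gene, function(x) length(x$gpos),
                                 integer(1))))
  refrow <- unlist(lapply(per_gene, `[[`, "base"))
  seqs <- matrix(rep(refrow, each = n_hap), nrow = n_hap)
  col_chrom <- unlist(lapply(per_gene, function(x) rep(x$chrom, length(x$gpos))))
  col_gpos <- unlist(lapply(per_gene, `[[`, "gpos"))
  col_strand <- unlist(lapply(per_gene, function(x)
    rep(x$strand, length(x$gpos))))

  withr::with_seed(seed, {
    key_aln <- paste(col_chrom, col_gpos)
    key_var <- paste(g$sites$chrom, g$sites$pos)
    vcol <- match(key_var, key_aln)
    for (v in which(!is.na(vcol))) {
      cc <- vcol[v]
      ra <- g$sites$ref[v]; aa <- g$sites$alt[v]
      if (col_strand[cc] == "-") {
        ra <- unname(COMPLEMENT[ra]); aa <- unname(COMPLEMENT[aa])
      }
      if (seqs[1, cc] != ra) {
        abort(sprintf("variant %s:%d ref allele %s disagrees with reference %s",
                      g$sites$chrom[v], g$sites$pos[v], g$sites$ref[v],
                      seqs[1, cc]))
      }
      dos <- g$geno[, v]
      r1 <- 2L * seq_along(dos) - 1L
      r2 <- r1 + 1L
      seqs[r1[is.na(dos)], cc] <- "N"
      seqs[r2[is.na(dos)], cc] <- "N"
      hom <- which(!is.na(dos) & dos == 2L)
      seqs[r1[hom], cc] <- aa
      seqs[r2[hom], cc] <- aa
      het <- which(!is.na(dos) & dos == 1L)
      if (length(het)) {
        pick1 <- runif(length(het)) < 0.5
        seqs[ifelse(pick1, r1[het], r2[het]), cc] <- aa
      }
    }
  })
  structure(
    list(
      seqs = seqs,
      ref = refrow,
      samples = g$samples,
      hap_sample = rep(g$samples, each = 2L),
      gene_map = tibble(
        gene_id = vapply(per_gene, `[[`, character(1), "gene_id"),
        chrom = vapply(per_gene, `[[`, character(1), "chrom"),
        strand = vapply(per_gene, `[[`, character(1), "strand"),
        start_col = offsets[-length(offsets)] + 1L,
        end_col = offsets[-1L]
      ),
      col_chrom = col_chrom, col_gpos = col_gpos, col_strand = col_strand
    ),
    class = "surf_cds_aln"
  )
}

#' @export
print.surf_cds_aln <- function(x, ...) {
  cat(sprintf("<surf_cds_aln> %d haplotypes x %d coding positions, %d genes\n",
              nrow(x$seqs), ncol(x$seqs), nrow(x$gene_map)))
  invisible(x)
}

#' Extract the alignment of a single gene
#' @param aln a `surf_cds_aln`.
#' @param gene_id gene to extract.
#' @return Character matrix of haplotype sequences for that gene.
#' @export
aln_gene <- function(aln, gene_id) {
  i <- match(gene_id, aln$gene_map$gene_id)
  if (is.na(i)) abort(sprintf("gene %s not in alignment", gene_id))
  aln$seqs[, aln$gene_map$start_col[i]:aln$gene_map$end_col[i], drop = FALSE]
}

#' Restrict an alignment to a subset of individuals
#' @param aln a `surf_cds_aln`.
#' @param samples sample ids to keep.
#' @return A `surf_cds_aln` over those individuals.
#' @export
aln_subset <- function(aln, samples) {
  keep <- aln$hap_sample %in% samples
  aln$seqs <- aln$seqs[keep, , drop = FALSE]
  aln$hap_sample <- aln$hap_sample[keep]
  aln$samples <- intersect(aln$samples, samples)
  aln
}
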