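# Gene annotation loading (GFF3 / BED via rtracklayer) and cascade SNP-to-
# gene mapping: coding-region containment first, then a strand-aware
# 2kb-upstream / 0.5kb-downstream proximity window; plus the strand-agnostic
# 10kb gene-window SNP selection used for seeded analyses.
#
# Coordinates are 1-based inclusive internally; BED input is converted from
# 0-based half-open on import (rtracklayer does this).

#' Load gene models from a GFF3 or BED file
#'
#' GFF3: `gene` records define spans; `CDS` records define coding intervals,
#' assigned to their gene via `Parent` attributes (directly or through an
#' mRNA/transcript), with same-strand containment as fallback. BED: 12-column
#' entries use their blocks as coding intervals; 6-column entries are
#' span-only models whose whole span is treated as coding.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return a `gene_model_set`: list with `genes` (data.frame `gene_id`,
#'   `name`, `chrom`, `strand`, `start`, `end`) and `coding` (data.frame
#'   `gene_id`, `start`, `end`).
#' @export
load_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) {
                   stop("malformed ", format, " record in ", path, ": ",
                        conditionMessage(e))
                 })
  if (format == "gff3") .models_from_gff(gr) else .models_from_bed(gr)
}

.models_from_gff <- function(gr) {
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features present in annotation")
  ids <- as.character(meta$ID)
  g <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(g)$ID)
  gname <- if ("Name" %in% names(S4Vectors::mcols(g))) {
    as.character(S4Vectors::mcols(g)$Name)
  } else gid
  gname[is.na(gname)] <- gid[is.na(gname)]
  genes <- data.frame(gene_id = gid, name = gname,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      strand = as.character(GenomicRanges::strand(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene records must carry a +/- strand")
  }
  # resolve CDS -> gene: follow Parent one level (mRNA/transcript) if needed
  parent_of <- function(x) {
    p <- meta$Parent[x]
    vapply(p, function(v) if (length(v)) as.character(v[1]) else NA_character_,
           character(1))
  }
  cds_idx <- which(type == "CDS")
  coding <- NULL
  if (length(cds_idx)) {
    par <- parent_of(cds_idx)
    # hop through transcript-level parents
    hop <- match(par, ids)
    hop_par <- ifelse(!is.na(hop) & !(par %in% genes$gene_id),
                      parent_of(hop), par)
    gene_id <- ifelse(hop_par %in% genes$gene_id, hop_par,
                      ifelse(par %in% genes$gene_id, par, NA_character_))
    # containment fallback
    for (i in which(is.na(gene_id))) {
      cand <- which(genes$chrom == as.character(GenomicRanges::seqnames(gr[cds_idx[i]])) &
                      genes$strand == as.character(GenomicRanges::strand(gr[cds_idx[i]])) &
                      genes$start <= GenomicRanges::start(gr[cds_idx[i]]) &
                      genes$end >= GenomicRanges::end(gr[cds_idx[i]]))
      if (length(cand)) gene_id[i] <- genes$gene_id[cand[1]]
    }
    keep <- !is.na(gene_id)
    coding <- data.frame(gene_id = gene_id[keep],
                         start = GenomicRanges::start(gr[cds_idx][keep]),
                         end = GenomicRanges::end(gr[cds_idx][keep]))
  }
  if (is.null(coding) || nrow(coding) == 0L) {
    coding <- data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0))
  }
  .gene_model_set(genes, coding)
}

.models_from_bed <- function(gr) {
  meta <- S4Vectors::mcols(gr)
  gid <- if ("name" %in% names(meta)) as.character(meta$name) else
    paste0("bed_", seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  genes <- data.frame(gene_id = gid, name = gid,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand,
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr))
  if ("blocks" %in% names(meta)) {
    bl <- meta$blocks
    coding <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- bl[[i]]
      if (length(b) == 0L) {
        data.frame(gene_id = gid[i], start = genes$start[i],
                   end = genes$end[i])
      } else {
        data.frame(gene_id = gid[i],
                   start = genes$start[i] + IRanges::start(b) - 1L,
                   end = genes$start[i] + IRanges::end(b) - 1L)
      }
    }))
  } else {
    coding <- data.frame(gene_id = gid, start = genes$start, end = genes$end)
  }
  .gene_model_set(genes, coding)
}

.gene_model_set <- function(genes, coding) {
  stopifnot(all(genes$start <= genes$end))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  rownames(genes) <- NULL; rownames(coding) <- NULL
  structure(list(genes = genes, coding = coding), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes, %d coding intervals\n",
              nrow(x$genes), nrow(x$coding)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' @param models a `gene_model_set`.
#' @param path output GFF3.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  g <- models$genes
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id, g$name))
  cd <- models$coding
  if (nrow(cd)) {
    gi <- match(cd$gene_id, g$gene_id)
    lines <- c(lines,
               sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                       g$chrom[gi], cd$start, cd$end, g$strand[gi],
                       cd$gene_id, seq_len(nrow(cd)), cd$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Cascade-map SNPs to genes
#'
#' Stage 1: a SNP inside any gene's coding interval maps `coding_direct`
#' (distance 0) to that gene, or to all such genes when they overlap.
#' Stage 2: otherwise, genes whose strand-aware window -- `upstream` bp
#' before the gene span's 5' end or `downstream` bp past its 3' end,
#' boundaries inclusive -- contains the SNP are collected and the SNP maps
#' `proximal` to the nearest by bp distance to the gene span (ties map to
#' all tied genes). A SNP inside a gene span but outside its coding
#' intervals is proximal at distance 0. SNPs matching neither stage, or on a
#' chromosome absent from the annotation (warned), are reported `unmapped`.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (1-based), e.g. a
#'   genotype matrix's `snp_map`.
#' @param models a `gene_model_set`.
#' @param upstream,downstream window sizes in bp (defaults 2000 and 500).
#' @return data.frame: `snp_id`, `gene_id`, `class`
#'   (`coding_direct`/`proximal`/`unmapped`), `distance` (bp; 0 for
#'   coding_direct; `NA` for unmapped).
#' @export
cascade_map <- function(snps, models, upstream = 2000, downstream = 500) {
  g <- models$genes
  cd <- models$coding
  cd_chrom <- g$chrom[match(cd$gene_id, g$gene_id)]
  missing_chrom <- setdiff(unique(snps$chrom), unique(g$chrom))
  if (length(missing_chrom)) {
    warning("SNP chromosome(s) absent from annotation: ",
            paste(missing_chrom, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(snps)), function(i) {
    chrom <- snps$chrom[i]; pos <- snps$pos[i]
    hit <- which(cd_chrom == chrom & cd$start <= pos & cd$end >= pos)
    if (length(hit)) {
      return(data.frame(snp_id = snps$snp_id[i],
                        gene_id = unique(cd$gene_id[hit]),
                        class = "coding_direct", distance = 0L))
    }
    cand <- which(g$chrom == chrom)
    if (length(cand)) {
      gg <- g[cand, , drop = FALSE]
      lo <- ifelse(gg$strand == "+", gg$start - upstream, gg$start - downstream)
      hi <- ifelse(gg$strand == "+", gg$end + downstream, gg$end + upstream)
      within <- pos >= lo & pos <= hi
      if (any(within)) {
        dist <- pmax(0L, pmax(gg$start - pos, pos - gg$end))[within]
        nearest <- dist == min(dist)
        return(data.frame(snp_id = snps$snp_id[i],
                          gene_id = gg$gene_id[within][nearest],
                          class = "proximal",
                          distance = as.integer(dist[nearest])))
      }
    }
    data.frame(snp_id = snps$snp_id[i], gene_id = NA_character_,
               class = "unmapped", distance = NA_integer_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' SNPs within a symmetric window of any gene span
#'
#' Strand-agnostic selection used for seeded analyses: every SNP whose
#' position is within `window_bp` (inclusive) of any listed gene's span, on
#' either side. Implemented with GenomicRanges overlaps.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos`.
#' @param models a `gene_model_set`.
#' @param window_bp window size in bp (default 10000).
#' @return deduplicated character vector of SNP ids, in input order.
#' @export
snps_near_genes <- function(snps, models, window_bp = 10000) {
  stopifnot(window_bp >= 0)
  g <- models$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$start - window_bp),
                              g$end + window_bp))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  unique(snps$snp_id[sort(unique(S4Vectors::queryHits(hits)))])
}
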