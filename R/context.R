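CPG_CATEGORIES <- c("island", "shore", "shelf", "inter_CGI")
GENE_CATEGORIES <- c("promoter", "promoter_plus", "CDS", "intergenic")

#' CpG-island context of genomic positions
#'
#' `island` when the position falls inside a CpG island; otherwise `shore`
#' within 0-2 kb of the nearest island boundary, `shelf` within 2-4 kb,
#' and `inter_CGI` beyond. Distances are measured to the nearest island
#' edge on the same chromosome; coordinates are 0-based with half-open
#' island intervals.
#'
#' @param chrom,pos Parallel vectors of probe coordinates.
#' @param island_track Data frame `chrom`, `start`, `end`.
#' @return Character vector of categories.
#' @export
annotate_cpg_context <- function(chrom, pos, island_track) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0L) return(character(0))
  if (nrow(island_track) == 0L) return(rep("inter_CGI", length(pos)))
  lev <- unique(c(as.character(chrom), as.character(island_track$chrom)))
  pr <- GenomicRanges::GRanges(factor(chrom, lev),
                               IRanges::IRanges(pos + 1L, width = 1L))
  isl <- GenomicRanges::GRanges(factor(island_track$chrom, lev),
                                IRanges::IRanges(island_track$start + 1L,
                                                 island_track$end))
  inside <- GenomicRanges::countOverlaps(pr, isl) > 0L
  dist <- rep(Inf, length(pos))
  hits <- GenomicRanges::distanceToNearest(pr, isl)
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out <- rep("inter_CGI", length(pos))
  out[dist <= 4000] <- "shelf"
  out[dist <= 2000] <- "shore"
  out[inside] <- "island"
  out
}

.parse_blocks <- function(genes) {
  starts <- strsplit(as.character(genes$cds_starts), ",", fixed = TRUE)
  ends <- strsplit(as.character(genes$cds_ends), ",", fixed = TRUE)
  n <- lengths(starts)
  if (!all(n == lengths(ends)))
    stop("cds_starts and cds_ends block counts differ")
  data.frame(gene_idx = rep(seq_len(nrow(genes)), n),
             start = as.integer(unlist(starts)),
             end = as.integer(unlist(ends)))
}

#' Gene context of genomic positions
#'
#' `promoter` when the position lies 0-1 kb upstream (5', strand-aware) of
#' any transcription start site; else `promoter_plus` at 1-5 kb upstream;
#' else `CDS` when inside any coding-sequence interval; else `intergenic`
#' -- category precedence in that order. When several genes match the
#' assigned category the gene with the nearest TSS wins.
#'
#' @param chrom,pos Parallel vectors of probe coordinates (0-based).
#' @param gene_track Data frame `gene_id`, `chrom`, `strand`, `tss`,
#'   `cds_starts`, `cds_ends` (comma-joined half-open blocks).
#' @return Data frame `gene_category`, `nearest_gene_id`.
#' @export
annotate_gene_context <- function(chrom, pos, gene_track) {
  stopifnot(length(chrom) == length(pos))
  np <- length(pos)
  if (!all(gene_track$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-'")
  category <- rep("intergenic", np)
  nearest <- rep(NA_character_, np)
  blocks <- .parse_blocks(gene_track)

  for (ch in unique(chrom)) {
    pi <- which(chrom == ch)
    gi <- which(gene_track$chrom == ch)
    if (length(gi) == 0L) next
    tss <- gene_track$tss[gi]
    sgn <- ifelse(gene_track$strand[gi] == "+", 1L, -1L)
    # strand-aware upstream distance of each probe (rows) to each TSS (cols)
    U <- outer(pos[pi], tss, function(p, t) t - p) *
      rep(sgn, each = length(pi))
    A <- abs(outer(pos[pi], tss, "-"))
    in_prom <- U >= 1 & U <= 1000
    in_promp <- U > 1000 & U <= 5000

    bk <- blocks[blocks$gene_idx %in% gi, , drop = FALSE]
    in_cds <- matrix(FALSE, length(pi), length(gi))
    if (nrow(bk)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pos[pi] + 1L, width = 1L),
        IRanges::IRanges(bk$start + 1L, bk$end))
      in_cds[cbind(S4Vectors::queryHits(ov),
                   match(bk$gene_idx[S4Vectors::subjectHits(ov)], gi))] <- TRUE
    }

    pick <- function(mask_row, a_row) gi[which(mask_row)[
      which.min(a_row[mask_row])]]
    for (r in seq_along(pi)) {
      i <- pi[r]
      if (any(in_prom[r, ])) {
        category[i] <- "promoter"; g <- pick(in_prom[r, ], A[r, ])
      } else if (any(in_promp[r, ])) {
        category[i] <- "promoter_plus"; g <- pick(in_promp[r, ], A[r, ])
      } else if (any(in_cds[r, ])) {
        category[i] <- "CDS"; g <- pick(in_cds[r, ], A[r, ])
      } else {
        g <- gi[which.min(A[r, ])]
      }
      nearest[i] <- gene_track$gene_id[g]
    }
  }
  data.frame(gene_category = category, nearest_gene_id = nearest,
             stringsAsFactors = FALSE)
}

#' Annotate probes with both context axes
#'
#' @param feature_ids Probe ids to annotate (must exist in the manifest).
#' @param manifest [probe_manifest()].
#' @return Data frame `feature_id`, `cpg_category`, `gene_category`,
#'   `nearest_gene_id`.
#' @export
annotate_probes <- function(feature_ids, manifest) {
  idx <- match(feature_ids, manifest$probes$probe_id)
  if (anyNA(idx))
    stop("manifest is missing probe(s): ",
         paste(feature_ids[is.na(idx)][1L], collapse = ", "))
  chrom <- manifest$probes$chrom[idx]
  pos <- manifest$probes$pos[idx]
  gc <- annotate_gene_context(chrom, pos, manifest$genes)
  data.frame(feature_id = feature_ids,
             cpg_category = annotate_cpg_context(chrom, pos,
                                                 manifest$islands),
             gene_category = gc$gene_category,
             nearest_gene_id = gc$nearest_gene_id,
             stringsAsFactors = FALSE)
}

#' Annotate DMRs by their midpoint position
#'
#' @param dmrs [call_dmrs()] output.
#' @param manifest [probe_manifest()].
#' @return Data frame as in [annotate_probes()], `feature_id` =
#'   `chrom:start-end`.
#' @export
annotate_dmrs <- function(dmrs, manifest) {
  if (nrow(dmrs) == 0L)
    return(data.frame(feature_id = character(0), cpg_category = character(0),
                      gene_category = character(0),
                      nearest_gene_id = character(0),
                      stringsAsFactors = FALSE))
  mid <- (dmrs$start + dmrs$end) %/% 2L
  gc <- annotate_gene_context(dmrs$chrom, mid, manifest$genes)
  data.frame(
    feature_id = sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end),
    cpg_category = annotate_cpg_context(dmrs$chrom, mid, manifest$islands),
    gene_category = gc$gene_category,
    nearest_gene_id = gc$nearest_gene_id,
    stringsAsFactors = FALSE)
}

.integer_percents <- function(counts) {
  p <- 100 * counts / sum(counts)
  r <- floor(p + 0.5)               # round half away from zero (p >= 0)
  excess <- 100L - sum(r)
  if (excess != 0L) {
    big <- which.max(counts)
    r[big] <- r[big] + excess
  }
  r
}

#' Summarize context annotations into category fraction tables
#'
#' Per axis, reports counts and integer percentages that sum to exactly
#' 100 (nearest-integer rounding with the remainder assigned to the
#' largest category).
#'
#' @param annotations [annotate_probes()] / [annotate_dmrs()] output.
#' @return Data frame `axis`, `category`, `n`, `percent`.
#' @export
summarize_context <- function(annotations) {
  if (nrow(annotations) == 0L) stop("no annotations to summarize")
  one_axis <- function(axis, values, levels) {
    counts <- table(factor(values, levels = levels))
    data.frame(axis = axis, category = levels, n = as.integer(counts),
               percent = as.numeric(.integer_percents(as.integer(counts))),
               stringsAsFactors = FALSE)
  }
  rbind(one_axis("cpg", annotations$cpg_category, CPG_CATEGORIES),
        one_axis("gene", annotations$gene_category, GENE_CATEGORIES))
}
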