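# Classify CCGG sites into the four genomic categories (gene body, promoter,
# repeat, intergenic), attach genes and GO terms, and test GO enrichment.

#' Build strand-aware promoter intervals
#'
#' The promoter of a gene is the `promoter_length` bp immediately upstream of
#' its transcription start site: `[start - L, start)` for + strand genes and
#' `[end, end + L)` for - strand genes, clipped at position 0 (chromosome-end
#' clipping happens implicitly since sites beyond the end cannot exist).
#'
#' @param genes Gene data frame (id, chrom, start0, end0, strand).
#' @param promoter_length Promoter window in bp (default 1000).
#' @return Data frame with columns `gene_id`, `chrom`, `start0`, `end0`.
#' @examples
#' g <- data.frame(id = "g1", chrom = "c1", start0 = 5000, end0 = 8000,
#'                 strand = "+")
#' build_promoters(g)  # [4000, 5000)
#' @export
build_promoters <- function(genes, promoter_length = 1000L) {
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, pmax(0L, genes$start0 - promoter_length), genes$end0)
  end0 <- ifelse(plus, genes$start0, genes$end0 + promoter_length)
  out <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                    start0 = start0, end0 = end0, stringsAsFactors = FALSE)
  out[out$end0 > out$start0, , drop = FALSE]
}

df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0)
  )
}

#' Classify CCGG sites into genomic feature categories
#'
#' Each 4-bp CCGG site is assigned exactly one category by overlap, with
#' precedence gene_body > promoter > repeat > intergenic (gene-linked
#' evidence wins any tie; intergenic means no annotation overlaps). Promoter
#' and gene-body assignments carry the associated gene id(s); a site in two
#' genes' features gets both ids but is counted once.
#'
#' @param sites Data frame with `chrom` and `start0` of CCGG sites (or a
#'   character vector of site ids).
#' @param annotation An `msap_annotation` from [read_annotation_gff3()] (or a
#'   list with `genes`, `repeats`, `go_map`).
#' @param promoter_length Promoter window in bp (default 1000).
#' @return Data frame: `site_id`, `category` (gene_body/promoter/repeat/
#'   intergenic), `gene_ids` (comma-separated, "" if none), `go_terms`.
#' @export
classify_sites <- function(sites, annotation, promoter_length = 1000L) {
  if (is.character(sites)) sites <- parse_site_id(sites)
  ids <- site_id(sites$chrom, sites$start0)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start0 + 1L, width = 4L)
  )
  n <- length(site_gr)
  category <- rep("intergenic", n)
  gene_ids <- rep("", n)

  genes <- annotation$genes
  promoters <- build_promoters(genes, promoter_length)
  hit_list <- function(feature_df, id_col) {
    if (nrow(feature_df) == 0L) return(NULL)
    ov <- GenomicRanges::findOverlaps(site_gr, df_to_granges(feature_df))
    list(site = S4Vectors::queryHits(ov),
         id = if (is.null(id_col)) NULL else
           feature_df[[id_col]][S4Vectors::subjectHits(ov)])
  }
  collapse_ids <- function(site_idx, feat_ids, n) {
    out <- rep("", n)
    if (length(site_idx)) {
      agg <- tapply(feat_ids, site_idx, function(x) paste(unique(x), collapse = ","))
      out[as.integer(names(agg))] <- as.character(agg)
    }
    out
  }

  gb <- hit_list(genes, "id")
  pr <- hit_list(promoters, "gene_id")
  rp <- hit_list(annotation$repeats, NULL)

  gb_ids <- collapse_ids(gb$site, gb$id, n)
  pr_ids <- collapse_ids(pr$site, pr$id, n)
  in_gb <- gb_ids != ""
  in_pr <- pr_ids != ""
  in_rp <- logical(n)
  if (!is.null(rp)) in_rp[unique(rp$site)] <- TRUE

  category[in_rp] <- "repeat"
  category[in_pr] <- "promoter"
  category[in_gb] <- "gene_body"
  gene_ids[in_pr] <- pr_ids[in_pr]
  gene_ids[in_gb] <- gb_ids[in_gb]

  go_terms <- rep("", n)
  if (length(annotation$go_map)) {
    go_terms <- vapply(strsplit(gene_ids, ",", fixed = TRUE), function(gs) {
      gs <- gs[gs != ""]
      paste(unique(unlist(annotation$go_map[gs])), collapse = ",")
    }, character(1))
  }
  data.frame(site_id = ids, category = category, gene_ids = gene_ids,
             go_terms = go_terms, stringsAsFactors = FALSE)
}

#' Category distribution of annotated sites
#'
#' @param annotated Data frame from [classify_sites()] (optionally a subset,
#'   e.g. the DMS sites).
#' @return Data frame with `category`, `count` and `percent` (summing to 100)
#'   over the four categories.
#' @export
feature_distribution <- function(annotated) {
  if (nrow(annotated) == 0L) stop("no sites to summarize")
  cats <- c("gene_body", "promoter", "repeat", "intergenic")
  counts <- vapply(cats, function(c) sum(annotated$category == c), integer(1))
  data.frame(category = cats, count = counts,
             percent = 100 * counts / sum(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GO term enrichment by one-sided hypergeometric test
#'
#' For each GO term with at least one background hit, tests over-representation
#' in the foreground gene set with the upper-tail hypergeometric probability
#' P(X >= k), X ~ Hypergeom(N, K, n), followed by Benjamini-Hochberg
#' adjustment across tested terms. The natural background (universe) is the
#' set of genes with at least one MSAP-Seq site, conditioning enrichment on
#' assayability.
#'
#' @param foreground Character vector of foreground gene ids (must be a
#'   subset of `background`).
#' @param background Character vector of universe gene ids.
#' @param go_map Named list gene id -> GO terms.
#' @return Data frame: `term`, `k` (foreground hits), `n` (foreground size),
#'   `K` (background hits), `N` (background size), `p`, `q`.
#' @export
go_enrichment <- function(foreground, background, go_map) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground genes must be a subset of the background universe")
  }
  N <- length(background)
  n <- length(foreground)
  bg_terms <- go_map[intersect(names(go_map), background)]
  term_bg <- table(unlist(lapply(bg_terms, unique)))
  if (length(term_bg) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  fg_terms <- go_map[intersect(names(go_map), foreground)]
  term_fg <- table(unlist(lapply(fg_terms, unique)))
  terms <- names(term_bg)
  K <- as.integer(term_bg[terms])
  k <- as.integer(term_fg[terms])
  k[is.na(k)] <- 0L
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$p), , drop = FALSE]
}
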