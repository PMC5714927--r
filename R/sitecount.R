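# Assign filtered tags to genomic CCGG sites, count, normalize to RPM,
# apply the per-sample coverage floor.

#' Samples-by-sites count table
#'
#' Container for raw tag counts per CCGG site and sample, the per-sample
#' library sizes used as RPM denominators, and (once normalized) the RPM
#' matrix `raw * 1e6 / library_size`.
#'
#' @param raw Integer matrix (sites x samples) with site-id rownames and
#'   sample colnames.
#' @param lib_sizes Optional named numeric of per-sample library sizes; when
#'   NULL they are set at normalization time to the total counted tags per
#'   sample.
#' @return An object of class `site_count_table` with fields `raw`, `rpm`
#'   (NULL until [normalize_rpm()]), `lib_sizes`.
#' @export
site_count_table <- function(raw, lib_sizes = NULL) {
  raw <- as.matrix(raw)
  if ((nrow(raw) > 0L && is.null(rownames(raw))) || is.null(colnames(raw))) {
    stop("raw count matrix needs site-id rownames and sample colnames")
  }
  if (is.null(rownames(raw))) rownames(raw) <- character(0)
  if (any(raw < 0) || any(raw != round(raw))) {
    stop("raw counts must be non-negative integers")
  }
  storage.mode(raw) <- "integer"
  if (!is.null(lib_sizes)) {
    lib_sizes <- lib_sizes[colnames(raw)]
    if (any(is.na(lib_sizes))) stop("lib_sizes must cover every sample")
  }
  structure(list(raw = raw, rpm = NULL, lib_sizes = lib_sizes),
            class = "site_count_table")
}

#' @export
print.site_count_table <- function(x, ...) {
  cat(sprintf("<site_count_table> %d site(s) x %d sample(s)%s\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$rpm)) "" else ", RPM-normalized"))
  invisible(x)
}

#' @export
dim.site_count_table <- function(x) dim(x$raw)

# Forward (F) and reverse (R) tag contexts of each CCGG site: the genomic
# sequence a canonical tag (beginning with the CGG remnant) reads into, for
# a fragment to the right of the cut (F) and, after fill-in, to the left (R).
site_tag_contexts <- function(genome, sites, max_len) {
  chr <- genome[sites$chrom]
  s <- sites$start0
  fwd <- substr(chr, s + 2L, s + 1L + max_len)
  rev_raw <- substr(chr, pmax(1L, s + 4L - max_len), s + 3L)
  rev_ <- revcomp(rev_raw)
  ids <- site_id(sites$chrom, sites$start0)
  data.frame(
    site_id = c(ids, ids),
    orient = rep(c("F", "R"), each = length(ids)),
    context = c(fwd, rev_),
    stringsAsFactors = FALSE
  )
}

#' Built-in exact tag-to-site mapper
#'
#' Places each trimmed tag (canonical orientation, beginning with CGG) at the
#' CCGG sites whose cut remnant its leading CGG coincides with: either a
#' forward-strand match starting at `start0 + 1` or a reverse-complement
#' match ending at `start0 + 3`. Placement is exact-match over the full tag.
#' Tags with a unique placement are assigned; more than one distinct site is
#' ambiguous; none is unmapped.
#'
#' @param tags Data frame with `id` and `seq` (from [filter_reads()]).
#' @param genome An `msap_genome`.
#' @param ccgg_sites Optional precomputed site table from [find_sites()].
#' @return Data frame with columns `id`, `site_id` (NA unless assigned) and
#'   `status` in {assigned, ambiguous, unmapped}.
#' @export
map_tags_builtin <- function(tags, genome, ccgg_sites = NULL) {
  if (is.null(ccgg_sites)) ccgg_sites <- find_sites(genome, restriction_enzyme("HpaII"))
  out <- data.frame(id = tags$id, site_id = NA_character_,
                    status = "unmapped", stringsAsFactors = FALSE)
  if (nrow(tags) == 0L || nrow(ccgg_sites) == 0L) return(out)
  bad <- !startsWith(tags$seq, "CGG")
  if (any(bad)) stop("tags must begin with the CGG remnant (canonical orientation)")
  max_len <- max(nchar(tags$seq))
  ctx <- site_tag_contexts(genome, ccgg_sites, max_len)
  key_len <- min(24L, min(nchar(tags$seq)))
  ctx$key <- substr(ctx$context, 1L, key_len)
  tag_key <- substr(tags$seq, 1L, key_len)
  joined <- merge(
    data.frame(tag_row = seq_len(nrow(tags)), seq = tags$seq, key = tag_key,
               stringsAsFactors = FALSE),
    ctx, by = "key"
  )
  if (nrow(joined) > 0L) {
    ok <- substr(joined$context, 1L, nchar(joined$seq)) == joined$seq
    joined <- joined[ok, , drop = FALSE]
  }
  if (nrow(joined) > 0L) {
    hits <- tapply(joined$site_id, joined$tag_row,
                   function(s) unique(s), simplify = FALSE)
    rows <- as.integer(names(hits))
    n_hits <- lengths(hits)
    one <- n_hits == 1L
    out$status[rows[one]] <- "assigned"
    out$site_id[rows[one]] <- vapply(hits[one], `[[`, "", 1L)
    out$status[rows[n_hits > 1L]] <- "ambiguous"
  }
  out
}

# Reference span consumed by a CIGAR string (M/D/N/=/X advance the reference).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign externally produced alignments to CCGG sites
#'
#' A unique, primary alignment is assigned to the CCGG site whose cut
#' position coincides with the tag's adapter-proximal alignment terminus
#' within `tolerance` bp: forward alignments must start at `start0 + 1`,
#' reverse alignments must end at `start0 + 3`. Non-unique or non-coinciding
#' alignments are discarded and tallied.
#'
#' @param alignments Data frame from [read_alignments_sam()].
#' @param ccgg_sites Site table from [find_sites()].
#' @param tolerance Allowed distance between terminus and cut (default 0).
#' @return List with `assignments` (id, site_id, status) and `tally`
#'   (non_unique, no_site, unknown_chrom counts).
#' @export
ingest_sam <- function(alignments, ccgg_sites, tolerance = 0L) {
  site_keys <- site_id(ccgg_sites$chrom, ccgg_sites$start0)
  span <- cigar_ref_span(alignments$cigar)
  span[span == 0L] <- alignments$read_length[span == 0L]
  term_start0 <- ifelse(alignments$strand == "+",
                        alignments$pos0 - 1L,                # site start0 + 1 == pos0
                        alignments$pos0 + span - 3L)         # site start0 + 3 == end
  unknown <- !(alignments$chrom %in% ccgg_sites$chrom)
  site_hit <- rep(NA_character_, nrow(alignments))
  for (off in seq.int(-tolerance, tolerance)) {
    key <- site_id(alignments$chrom, term_start0 + off)
    found <- is.na(site_hit) & key %in% site_keys
    site_hit[found] <- key[found]
  }
  status <- rep("assigned", nrow(alignments))
  status[is.na(site_hit)] <- "no_site"
  status[unknown] <- "unknown_chrom"
  status[!alignments$is_unique] <- "non_unique"
  assignments <- data.frame(
    id = alignments$id,
    site_id = ifelse(status == "assigned", site_hit, NA_character_),
    status = ifelse(status == "assigned", "assigned", "unmapped"),
    stringsAsFactors = FALSE
  )
  list(
    assignments = assignments,
    tally = c(non_unique = sum(status == "non_unique"),
              no_site = sum(status == "no_site"),
              unknown_chrom = sum(unknown))
  )
}

#' Count assigned tags per site and sample
#'
#' @param assignments Named list (sample -> assignment data frame from
#'   [map_tags_builtin()] or [ingest_sam()]`$assignments`).
#' @return A `site_count_table` of raw counts; sites with zero counts in all
#'   samples are omitted.
#' @export
count_sites <- function(assignments) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  samples <- names(assignments)
  per_sample <- lapply(assignments, function(a) {
    a <- a[a$status == "assigned", , drop = FALSE]
    table(a$site_id)
  })
  all_sites <- sort(unique(unlist(lapply(per_sample, names))))
  raw <- matrix(0L, nrow = length(all_sites), ncol = length(samples),
                dimnames = list(all_sites, samples))
  for (s in samples) {
    t <- per_sample[[s]]
    if (length(t)) raw[names(t), s] <- as.integer(t)
  }
  site_count_table(raw)
}

#' Normalize raw counts to reads per million (RPM)
#'
#' `RPM = raw * 1e6 / library_size`. The library size defaults to the total
#' number of tags assigned to any CCGG site in that sample, so per-sample RPM
#' sums to exactly 1e6.
#'
#' @param table A `site_count_table`.
#' @return The table with its `rpm` matrix and `lib_sizes` filled in.
#' @export
normalize_rpm <- function(table) {
  stopifnot(inherits(table, "site_count_table"))
  lib <- table$lib_sizes
  if (is.null(lib)) lib <- colSums(table$raw)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(table$raw)[lib <= 0], collapse = ", "))
  }
  table$lib_sizes <- lib
  table$rpm <- sweep(table$raw, 2L, lib, function(x, n) x * 1e6 / n)
  table
}

#' Apply the per-sample minimum coverage floor
#'
#' A site is reported for a sample only when its raw count is at least
#' `min_reads` (protocol default 2); sub-floor cells are zeroed, and sites
#' below the floor in every sample are dropped. Library sizes (and hence the
#' RPM denominator) are kept from the pre-floor assignment totals.
#'
#' @param table A `site_count_table`.
#' @param min_reads Coverage floor (default 2).
#' @return Filtered `site_count_table` (RPM recomputed if present).
#' @export
apply_min_coverage <- function(table, min_reads = 2L) {
  stopifnot(inherits(table, "site_count_table"))
  if (min_reads <= 0L) return(table)
  raw <- table$raw
  raw[raw < min_reads] <- 0L
  keep <- rowSums(raw) > 0L
  raw <- raw[keep, , drop = FALSE]
  out <- site_count_table(raw, lib_sizes = table$lib_sizes)
  if (!is.null(table$rpm)) out <- normalize_rpm(out)
  out
}

#' De novo tag table (no genome required)
#'
#' Tags are keyed by the exact sequence of the first `tag_key_length` bases
#' after the CGG remnant and counted per sample, enabling quantitative
#' comparison among samples without genome mapping. Tags shorter than the key
#' are excluded and tallied.
#'
#' @param tag_sets Named list (sample -> tag data frame from [filter_reads()]).
#' @param tag_key_length Key length after CGG (default 30).
#' @return List with `table` (a `site_count_table` keyed by tag sequence) and
#'   `excluded` (named integer: tags too short per sample).
#' @export
denovo_tag_table <- function(tag_sets, tag_key_length = 30L) {
  stopifnot(is.list(tag_sets), !is.null(names(tag_sets)))
  min_needed <- 3L + tag_key_length
  keys <- lapply(tag_sets, function(t) {
    ok <- nchar(t$seq) >= min_needed
    list(keys = substr(t$seq[ok], 4L, min_needed), excluded = sum(!ok))
  })
  all_keys <- sort(unique(unlist(lapply(keys, `[[`, "keys"))))
  samples <- names(tag_sets)
  raw <- matrix(0L, nrow = length(all_keys), ncol = length(samples),
                dimnames = list(all_keys, samples))
  for (s in samples) {
    t <- table(keys[[s]]$keys)
    if (length(t)) raw[names(t), s] <- as.integer(t)
  }
  excluded <- vapply(keys, `[[`, integer(1), "excluded")
  list(table = site_count_table(raw), excluded = excluded)
}
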