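# Readers/writers for the standard formats the pipeline touches.
#
# Coordinate conventions: everything internal is 0-based half-open; GFF3 on
# disk is 1-based inclusive; BED output is 0-based half-open.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on load and validated against the {A,C,G,T,N}
#' alphabet. Internally all coordinates are 0-based half-open.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named character vector of class `msap_genome`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  as_msap_genome(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return A named character vector of class `msap_genome`.
#' @export
as_msap_genome <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("all genome sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence name(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty sequence(s) in genome")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(sequences, class = "msap_genome")
}

#' @export
print.msap_genome <- function(x, ...) {
  cat(sprintf("<msap_genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome An `msap_genome`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' @param path FASTQ path (Sanger Phred+33 qualities).
#' @param mate Mate index to record (1, 2, or NA for single-end).
#' @return Data frame with columns `id`, `seq`, `qual`, `mate`.
#' @export
read_reads_fastq <- function(path, mate = NA_integer_) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(set)$qualities)
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    seq = as.character(set),
    qual = qual,
    mate = rep(as.integer(mate), length(set)),
    stringsAsFactors = FALSE
  )
}

#' Write sequencing reads to FASTQ
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to constant Q30).
#' @param path Output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- vapply(nchar(reads$seq), function(n)
    strrep(rawToChar(as.raw(63L)), n), character(1))
  stopifnot(all(nchar(qual) == nchar(reads$seq)))
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities =
                                Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read gene/repeat annotation from GFF3
#'
#' Gene features (`type == "gene"`) and repeat features (type containing
#' "repeat" or "transposable_element") are collected. On-disk GFF3 is 1-based
#' inclusive; returned coordinates are 0-based half-open. Genes without a
#' strand are excluded and counted in the `n_strandless` field.
#'
#' @param path GFF3 path.
#' @param go_path Optional two-column TSV (gene id, GO term) mapping file.
#' @return A list of class `msap_annotation` with elements `genes`
#'   (data.frame: id, chrom, start0, end0, strand), `repeats`
#'   (chrom, start0, end0), `go_map` (named list gene -> GO terms) and
#'   `n_strandless`.
#' @export
read_annotation_gff3 <- function(path, go_path = NULL) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)

  is_gene <- type == "gene"
  strandless <- is_gene & !(strand %in% c("+", "-"))
  if (any(strandless)) {
    warning(sum(strandless), " gene(s) without strand excluded")
  }
  keep <- is_gene & !strandless
  ids <- as.character(gr$ID)
  if (all(is.na(ids[keep])) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  ids[is.na(ids)] <- paste0("gene", seq_along(ids))[is.na(ids)]
  genes <- data.frame(
    id = ids[keep], chrom = chrom[keep],
    start0 = start0[keep], end0 = end0[keep], strand = strand[keep],
    stringsAsFactors = FALSE
  )
  is_repeat <- grepl("repeat", type, ignore.case = TRUE) |
    grepl("transposable_element", type, ignore.case = TRUE)
  repeats <- data.frame(
    chrom = chrom[is_repeat], start0 = start0[is_repeat], end0 = end0[is_repeat],
    stringsAsFactors = FALSE
  )
  go_map <- list()
  if (!is.null(go_path)) go_map <- read_go_map(go_path)
  structure(
    list(genes = genes, repeats = repeats, go_map = go_map,
         n_strandless = sum(strandless)),
    class = "msap_annotation"
  )
}

#' @export
print.msap_annotation <- function(x, ...) {
  cat(sprintf("<msap_annotation> %d genes, %d repeats, GO terms for %d genes\n",
              nrow(x$genes), nrow(x$repeats), length(x$go_map)))
  invisible(x)
}

#' Read a two-column gene-to-GO mapping file
#'
#' @param path TSV with two columns: gene id, GO term id (no header).
#' @return Named list mapping gene id to a character vector of GO terms.
#' @export
read_go_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("gene", "go"))
  split(tab$go, tab$gene)
}

#' Read alignments from a SAM file
#'
#' A minimal text SAM reader for the fields the counting step needs. Only the
#' subset of the format required here is interpreted: FLAG bits 0x10 (reverse
#' strand), 0x100 (secondary) and 0x4 (unmapped); POS is converted to 0-based.
#' Multi-mapping is flagged when an alignment is secondary or reports
#' alternative hits (`XS:i` tag with `AS:i <= XS:i`, or `NH:i > 1`).
#'
#' @param path SAM path.
#' @return Data frame with columns `id`, `chrom`, `pos0`, `strand`, `cigar`,
#'   `mapq`, `is_unique`, `read_length`.
#' @export
read_alignments_sam <- function(path) {
  if (!file.exists(path)) stop("SAM not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- sub(".*SN:([^\t]+).*", "\\1", sq)
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(rec) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      pos0 = integer(0), strand = character(0),
                      cigar = character(0), mapq = integer(0),
                      is_unique = logical(0), read_length = integer(0)))
  }
  fields <- strsplit(rec, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 11L)) {
    stop("malformed SAM record at line ",
         which(!startsWith(lines, "@") & nzchar(lines))[which(n_fields < 11L)[1L]])
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  chrom <- vapply(fields, `[[`, "", 3L)
  mapped <- bitwAnd(flag, 4L) == 0L & chrom != "*"
  unknown <- mapped & !(chrom %in% sq_names)
  if (any(unknown)) {
    stop("alignment references sequence(s) absent from @SQ header: ",
         paste(unique(chrom[unknown]), collapse = ", "))
  }
  secondary <- bitwAnd(flag, 256L) > 0L
  nh <- vapply(fields, function(f) {
    t <- grep("^NH:i:", f, value = TRUE)
    if (length(t)) as.integer(sub("NH:i:", "", t[1L])) else NA_integer_
  }, integer(1))
  as_tag <- vapply(fields, function(f) {
    t <- grep("^AS:i:", f, value = TRUE)
    if (length(t)) as.integer(sub("AS:i:", "", t[1L])) else NA_integer_
  }, integer(1))
  xs_tag <- vapply(fields, function(f) {
    t <- grep("^XS:i:", f, value = TRUE)
    if (length(t)) as.integer(sub("XS:i:", "", t[1L])) else NA_integer_
  }, integer(1))
  multi <- secondary |
    (!is.na(nh) & nh > 1L) |
    (!is.na(as_tag) & !is.na(xs_tag) & xs_tag >= as_tag)
  out <- data.frame(
    id = vapply(fields, `[[`, "", 1L),
    chrom = chrom,
    pos0 = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = vapply(fields, `[[`, "", 6L),
    mapq = as.integer(vapply(fields, `[[`, "", 5L)),
    is_unique = !multi,
    read_length = nchar(vapply(fields, `[[`, "", 10L)),
    stringsAsFactors = FALSE
  )
  out[mapped, , drop = FALSE]
}

#' Write and read site-count tables
#'
#' Tab-separated with a `site_id` key column (format `"chrom:start0"`),
#' `chrom`, `start0`, one `<sample>.raw` column per sample and, when
#' normalized, one `<sample>.rpm` column per sample. Write-then-read
#' round-trips values to at least 10 significant digits.
#'
#' @param table A `site_count_table`.
#' @param path Output/input path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a `site_count_table`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "site_count_table"))
  df <- data.frame(site_id = rownames(table$raw), stringsAsFactors = FALSE)
  coords <- tryCatch(parse_site_id(df$site_id), error = function(e) NULL)
  if (!is.null(coords)) {
    df$chrom <- coords$chrom
    df$start0 <- coords$start0
  }
  for (s in colnames(table$raw)) df[[paste0(s, ".raw")]] <- table$raw[, s]
  if (!is.null(table$rpm)) {
    for (s in colnames(table$rpm)) {
      df[[paste0(s, ".rpm")]] <- format(table$rpm[, s], digits = 12)
    }
  }
  lib_line <- paste0("#lib_sizes\t",
                     paste(names(table$lib_sizes), table$lib_sizes,
                           sep = "=", collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lib_line, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  first <- readLines(path, n = 1L)
  lib_sizes <- NULL
  skip <- 0L
  if (startsWith(first, "#lib_sizes")) {
    parts <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
    kv <- strsplit(parts, "=", fixed = TRUE)
    lib_sizes <- setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                          vapply(kv, `[[`, "", 1L))
    skip <- 1L
  }
  df <- read.delim(path, skip = skip, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"site_id" %in% names(df)) stop("count table lacks a site_id column")
  raw_cols <- grep("\\.raw$", names(df), value = TRUE)
  if (length(raw_cols) == 0L) stop("count table lacks sample .raw columns")
  raw <- as.matrix(df[, raw_cols, drop = FALSE])
  colnames(raw) <- sub("\\.raw$", "", raw_cols)
  rownames(raw) <- df$site_id
  storage.mode(raw) <- "integer"
  tab <- site_count_table(raw, lib_sizes = lib_sizes)
  rpm_cols <- grep("\\.rpm$", names(df), value = TRUE)
  if (length(rpm_cols) > 0L) {
    rpm <- as.matrix(df[, rpm_cols, drop = FALSE])
    colnames(rpm) <- sub("\\.rpm$", "", rpm_cols)
    rownames(rpm) <- df$site_id
    storage.mode(rpm) <- "double"
    tab$rpm <- rpm
  }
  tab
}

#' Export differential-methylation calls to BED
#'
#' BED intervals are 0-based half-open over the 4-bp CCGG site; the name field
#' carries the direction call and the score column the |log2 FC| scaled to
#' 0-1000.
#'
#' @param dms Data frame of DMS records (from the `call_dms_*` functions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dms_bed <- function(dms, path) {
  coords <- parse_site_id(dms$site_id)
  score <- pmin(1000L, as.integer(round(100 * abs(dms$log2_fc))))
  score[is.na(score)] <- 0L
  bed <- data.frame(coords$chrom, coords$start0, coords$start0 + 4L,
                    ifelse(is.na(dms$direction), ".", dms$direction),
                    score,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MSRE-qPCR Cp table
#'
#' @param path TSV with header columns: region, sample, condition, replicate,
#'   cp_digested, cp_mock, efficiency.
#' @return Data frame.
#' @export
read_qpcr_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "condition", "replicate", "cp_digested", "cp_mock",
            "efficiency")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("qPCR table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}
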