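# Read filtering: HpaII-adapter detection, trimming, CGG-terminus rule,
# minimum length. Only reads that carry the HpaII-related adapter followed by
# the CGG restriction remnant are countable MSAP-Seq tags.

#' Detect the HpaII-related adapter in a read
#'
#' Searches the read 5' prefix for the adapter tail and the read 3' suffix for
#' its reverse complement (a tag sequenced from the other strand), allowing up
#' to `max_mismatches` substitutions. The default query is the HpaII primer
#' tail without the CGG remnant and selective bases: `GATGAGTCTAGAA`.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter_query Adapter sequence searched for.
#' @param max_mismatches Maximum substitutions tolerated (default 1).
#' @return Data frame with columns `side` (`"5p"`, `"3p"` or NA when absent)
#'   and `offset` (1-based position at which the adapter ends, from the
#'   matched side).
#' @examples
#' detect_hpaii_adapter("GATGAGTCTAGAACGGTGACGTACGT")$side  # "5p"
#' @export
detect_hpaii_adapter <- function(seqs, adapter_query = "GATGAGTCTAGAA",
                                 max_mismatches = 1L) {
  n <- nchar(adapter_query)
  rc <- revcomp(adapter_query)
  len <- nchar(seqs)
  pre <- substr(seqs, 1L, n)
  suf <- substr(seqs, pmax(1L, len - n + 1L), len)
  d5 <- hamming_to(pre, adapter_query)
  d3 <- hamming_to(suf, rc)
  side <- rep(NA_character_, length(seqs))
  offset <- rep(NA_integer_, length(seqs))
  hit5 <- d5 <= max_mismatches
  hit3 <- !hit5 & d3 <= max_mismatches
  side[hit5] <- "5p"
  offset[hit5] <- n
  side[hit3] <- "3p"
  offset[hit3] <- n
  data.frame(side = side, offset = offset, stringsAsFactors = FALSE)
}

#' Trim a detected adapter from reads
#'
#' Removes the adapter bases while RETAINING the CGG remnant and selective
#' bases (the downstream filter requires CGG on the retained read, and the
#' selective bases are genomic-matching). Qualities are trimmed in register.
#' Reads whose `match$side` is NA are returned unchanged.
#'
#' @param reads Data frame with `seq` and optionally `qual`.
#' @param match Data frame from [detect_hpaii_adapter()] (same row order).
#' @return `reads` with trimmed `seq`/`qual` and an added `adapter_side`
#'   column.
#' @examples
#' r <- data.frame(seq = "GATGAGTCTAGAACGGTGACGT")
#' trim_adapter(r, detect_hpaii_adapter(r$seq))$seq  # "CGGTGACGT"
#' @export
trim_adapter <- function(reads, match) {
  stopifnot(nrow(reads) == nrow(match))
  len <- nchar(reads$seq)
  off <- match$offset
  if (any(!is.na(off) & off > len)) stop("adapter match offset beyond read length")
  seq <- reads$seq
  qual <- reads$qual
  i5 <- which(!is.na(match$side) & match$side == "5p")
  i3 <- which(!is.na(match$side) & match$side == "3p")
  seq[i5] <- substring(seq[i5], off[i5] + 1L)
  seq[i3] <- substr(seq[i3], 1L, len[i3] - off[i3])
  if (!is.null(qual)) {
    qual[i5] <- substring(qual[i5], off[i5] + 1L)
    qual[i3] <- substr(qual[i3], 1L, len[i3] - off[i3])
    reads$qual <- qual
  }
  reads$seq <- seq
  reads$adapter_side <- match$side
  reads
}

#' Filter reads to countable MSAP-Seq tags
#'
#' A read is retained iff the HpaII-related adapter is found, the trimmed read
#' carries the CGG remnant at the adapter-proximal terminus, and the trimmed
#' length is at least `min_length` (protocol default 50 bp). Retained tags are
#' reported in canonical orientation (beginning with CGG; 3'-side matches are
#' reverse-complemented), together with the filter funnel statistics.
#'
#' @param reads Data frame with columns `id`, `seq`, optionally `qual`.
#' @param adapter_query Adapter searched for (see [detect_hpaii_adapter()]).
#' @param min_length Minimum trimmed tag length (default 50).
#' @param max_mismatches Adapter mismatch tolerance (default 1).
#' @return List with `tags` (data.frame: id, seq (canonical, begins CGG),
#'   qual, side, original_length, trimmed_length) and `stats` (one-row
#'   data.frame: input, with_adapter, with_cgg, length_pass,
#'   retained_fraction).
#' @export
filter_reads <- function(reads, adapter_query = "GATGAGTCTAGAA",
                         min_length = 50L, max_mismatches = 1L) {
  n_input <- nrow(reads)
  # Idempotence: a stream of already-filtered tags (adapter removed, canonical
  # CGG orientation, side recorded) passes through unchanged.
  if (n_input > 0L && all(c("side", "trimmed_length") %in% names(reads)) &&
      all(startsWith(reads$seq, "CGG"))) {
    keep <- nchar(reads$seq) >= min_length
    stats <- data.frame(input = n_input, with_adapter = n_input,
                        with_cgg = n_input, length_pass = sum(keep),
                        retained_fraction = sum(keep) / n_input)
    return(list(tags = reads[keep, , drop = FALSE], stats = stats))
  }
  if (n_input == 0L) {
    tags <- data.frame(id = character(0), seq = character(0),
                       qual = character(0), side = character(0),
                       original_length = integer(0), trimmed_length = integer(0))
    stats <- data.frame(input = 0L, with_adapter = 0L, with_cgg = 0L,
                        length_pass = 0L, retained_fraction = NA_real_)
    return(list(tags = tags, stats = stats))
  }
  match <- detect_hpaii_adapter(reads$seq, adapter_query, max_mismatches)
  has_adapter <- !is.na(match$side)
  trimmed <- trim_adapter(reads, match)
  tlen <- nchar(trimmed$seq)

  cgg_ok <- has_adapter & (
    (match$side == "5p" & startsWith(trimmed$seq, "CGG")) |
      (match$side == "3p" & endsWith(trimmed$seq, "CCG"))
  )
  cgg_ok[is.na(cgg_ok)] <- FALSE
  len_ok <- cgg_ok & tlen >= min_length

  keep <- which(len_ok)
  seqs <- trimmed$seq[keep]
  quals <- if (!is.null(trimmed$qual)) trimmed$qual[keep] else NA_character_
  flip <- match$side[keep] == "3p"
  if (any(flip)) {
    seqs[flip] <- revcomp(seqs[flip])
    if (!all(is.na(quals))) {
      quals[flip] <- vapply(strsplit(quals[flip], "", fixed = TRUE),
                            function(q) paste(rev(q), collapse = ""), character(1))
    }
  }
  tags <- data.frame(
    id = reads$id[keep],
    seq = seqs,
    qual = quals,
    side = match$side[keep],
    original_length = nchar(reads$seq)[keep],
    trimmed_length = tlen[keep],
    stringsAsFactors = FALSE
  )
  stats <- data.frame(
    input = n_input,
    with_adapter = sum(has_adapter),
    with_cgg = sum(cgg_ok),
    length_pass = sum(len_ok),
    retained_fraction = sum(len_ok) / n_input
  )
  list(tags = tags, stats = stats)
}
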