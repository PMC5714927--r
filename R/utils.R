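#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree hclust median p.adjust phyper
#'   rnorm runif setNames t.test as.dist
#' @importFrom utils read.delim write.table head
NULL

# Vectorized reverse complement of plain character vectors.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length strings x and a single pattern.
hamming_to <- function(x, pattern) {
  n <- nchar(pattern)
  xs <- strsplit(x, "", fixed = TRUE)
  ps <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  vapply(xs, function(ch) {
    if (length(ch) != n) return(n + 1L)
    sum(ch != ps)
  }, integer(1))
}

#' Format and parse canonical CCGG site identifiers
#'
#' A site is keyed as `"chrom:start0"` where `start0` is the 0-based offset
#' of the first C of the CCGG recognition sequence on the forward strand
#' (CCGG is palindromic, so one key identifies the site on both strands).
#'
#' @param chrom Chromosome names.
#' @param start0 0-based start offsets.
#' @return `site_id()` returns a character vector; `parse_site_id()` a
#'   data.frame with columns `chrom` and `start0`.
#' @examples
#' site_id("c1", 99)
#' parse_site_id("c1:99")
#' @export
site_id <- function(chrom, start0) {
  paste0(chrom, ":", as.integer(start0))
}

#' @rdname site_id
#' @param id Character vector of site identifiers.
#' @export
parse_site_id <- function(id) {
  pos <- regexpr(":[0-9]+$", id)
  if (any(pos < 0L)) {
    stop("malformed site id(s): ", paste(head(id[pos < 0L]), collapse = ", "))
  }
  data.frame(
    chrom = substr(id, 1L, pos - 1L),
    start0 = as.integer(substring(id, pos + 1L)),
    stringsAsFactors = FALSE
  )
}

# Derive a per-stage/per-sample 32-bit seed from a single global seed.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt_num <- sum(utf8ToInt(as.character(salt)) * 131^(seq_len(nchar(as.character(salt))) %% 7))
  as.integer((as.numeric(seed) * 48271 + salt_num) %% 2147483629) + 1L
}
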