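#' Restriction enzyme model
#'
#' MSAP-Seq uses a double digest with the rare-cutting, methylation-insensitive
#' EcoRI (GAATTC, cut G^AATTC) and the frequent-cutting, methylation-sensitive
#' HpaII (CCGG, cut C^CGG). HpaII is blocked when the internal CG of its
#' recognition site is methylated on both strands, which is the signal the
#' assay reads out.
#'
#' @param name Enzyme name; `"HpaII"` and `"EcoRI"` have built-in defaults.
#' @param recognition Recognition sequence on the forward strand (A/C/G/T).
#' @param cut_offset Top-strand cut position within the recognition sequence
#'   (0 = before the first base).
#' @param methylation_sensitive Logical; is cleavage blocked by methylation?
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HpaII")
#' restriction_enzyme("EcoRI")
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL,
                               methylation_sensitive = NULL) {
  defaults <- list(
    HpaII = list(recognition = "CCGG", cut_offset = 1L, methylation_sensitive = TRUE),
    EcoRI = list(recognition = "GAATTC", cut_offset = 1L, methylation_sensitive = FALSE)
  )
  if (name %in% names(defaults)) {
    d <- defaults[[name]]
    if (is.null(recognition)) recognition <- d$recognition
    if (is.null(cut_offset)) cut_offset <- d$cut_offset
    if (is.null(methylation_sensitive)) methylation_sensitive <- d$methylation_sensitive
  }
  if (is.null(recognition) || is.null(cut_offset) || is.null(methylation_sensitive)) {
    stop("unknown enzyme '", name, "': supply recognition, cut_offset and ",
         "methylation_sensitive explicitly")
  }
  if (!grepl("^[ACGT]+$", recognition)) {
    stop("recognition sequence must be over {A,C,G,T}")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within the recognition sequence")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset,
         methylation_sensitive = isTRUE(methylation_sensitive)),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s %s^%s%s\n", x$name,
              substr(x$recognition, 1, x$cut_offset),
              substring(x$recognition, x$cut_offset + 1L),
              if (x$methylation_sensitive) " (methylation-sensitive)" else ""))
  invisible(x)
}

# Double-stranded recognition-site "reach" of the remnant on the fragment to
# the LEFT of a cut: after overhang fill-in that fragment's bottom strand
# carries genomic bases up to start0 + left_reach. C^CGG leaves a 2-nt CG
# overhang -> reach 3; G^AATTC leaves AATT -> reach 5.
enzyme_left_reach <- function(enzyme) {
  nchar(enzyme$recognition) - enzyme$cut_offset
}

# The remnant read inward from a cut end (bases of the recognition site that
# the amplified fragment end starts with): "CGG" for HpaII, "AATTC" for EcoRI.
enzyme_remnant <- function(enzyme) {
  substring(enzyme$recognition, enzyme$cut_offset + 1L)
}

#' Double-stranded adapter model (protocol defaults)
#'
#' Defaults are the EcoRI and HpaII adapters used in the MSAP-Seq protocol:
#' EcoRI `CTCGTAGACTGCGTACC` / `AATTGGTACGCAGTCTAC`, HpaII
#' `GACGATGAGTCTAGAA` / `CGTTCTAGACTCATC`.
#'
#' @param end_type `"EcoRI"` or `"HpaII"`.
#' @param strand1,strand2 The two oligo strands; defaults per `end_type`.
#' @return An object of class `msap_adapter`.
#' @export
msap_adapter <- function(end_type = c("EcoRI", "HpaII"),
                         strand1 = NULL, strand2 = NULL) {
  end_type <- match.arg(end_type)
  defaults <- list(
    EcoRI = c("CTCGTAGACTGCGTACC", "AATTGGTACGCAGTCTAC"),
    HpaII = c("GACGATGAGTCTAGAA", "CGTTCTAGACTCATC")
  )
  if (is.null(strand1)) strand1 <- defaults[[end_type]][1L]
  if (is.null(strand2)) strand2 <- defaults[[end_type]][2L]
  structure(list(end_type = end_type, strand1 = strand1, strand2 = strand2),
            class = "msap_adapter")
}

#' Selective amplification primer model
#'
#' An MSAP/AFLP primer is the adapter-derived tail followed by the restriction
#' remnant and 0-3 selective nucleotides that must match the genomic bases
#' adjacent to the cut. The protocol defaults reproduce the published primer
#' pair: E-AC `GACTGCGTACCAATTCAC` and H-TG `GATGAGTCTAGAACGGTG`.
#'
#' @param end_type `"EcoRI"` or `"HpaII"`.
#' @param selective Selective nucleotides (0-3 bases over A/C/G/T).
#' @return An object of class `msap_primer` with fields `end_type`, `tail`
#'   (adapter-derived 5' part), `remnant`, `selective` and `sequence`
#'   (the full primer).
#' @examples
#' msap_primer("HpaII", "TG")$sequence  # "GATGAGTCTAGAACGGTG"
#' msap_primer("EcoRI", "AC")$sequence  # "GACTGCGTACCAATTCAC"
#' @export
msap_primer <- function(end_type = c("EcoRI", "HpaII"), selective = "") {
  end_type <- match.arg(end_type)
  if (nchar(selective) > 3L) {
    stop("selective bases longer than 3 are not supported")
  }
  if (nchar(selective) > 0L && !grepl("^[ACGT]+$", selective)) {
    stop("selective bases must be over {A,C,G,T}")
  }
  tails <- c(EcoRI = "GACTGCGTACC", HpaII = "GATGAGTCTAGAA")
  remnants <- c(EcoRI = "AATTC", HpaII = "CGG")
  tail <- unname(tails[end_type])
  remnant <- unname(remnants[end_type])
  structure(
    list(end_type = end_type, tail = tail, remnant = remnant,
         selective = selective,
         sequence = paste0(tail, remnant, selective)),
    class = "msap_primer"
  )
}

#' @export
print.msap_primer <- function(x, ...) {
  cat(sprintf("<msap_primer> %s-%s %s (tail %s + remnant %s + selective '%s')\n",
              substr(x$end_type, 1, 1), x$selective, x$sequence,
              x$tail, x$remnant, x$selective))
  invisible(x)
}

#' Enumerate selective-nucleotide combinations
#'
#' With `k` selective nucleotides on a primer there are `4^k` possible primer
#' variants; two selective nucleotides give the 16 primer combinations used to
#' tune library complexity.
#'
#' @param k Number of selective nucleotides (0-3).
#' @return Character vector of all length-`k` sequences over A/C/G/T.
#' @examples
#' length(selective_combinations(2))  # 16
#' @export
selective_combinations <- function(k) {
  k <- as.integer(k)
  if (k < 0L || k > 3L) stop("k must be between 0 and 3")
  if (k == 0L) return("")
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(replicate(k, bases, simplify = FALSE), stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}
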