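# In-silico MSAP-Seq experiment: methylation-aware double digestion,
# selective amplification, sonication and read synthesis, with ground truth.

#' Locate restriction recognition sites in a genome
#'
#' Reports all exact forward-strand matches of the recognition sequence
#' (CCGG and GAATTC are palindromic, so forward matches cover both strands).
#' Matches overlapping an N are never reported (undefined cleavage).
#'
#' @param genome An `msap_genome`.
#' @param enzyme A `restriction_enzyme`.
#' @return Data frame with columns `chrom` and `start0` (0-based offset of
#'   the first recognition base), sorted by chromosome and position.
#' @examples
#' g <- as_msap_genome(c(c1 = "ACCGGT"))
#' find_sites(g, restriction_enzyme("HpaII"))  # start0 = 1
#' @export
find_sites <- function(genome, enzyme) {
  stopifnot(inherits(genome, "msap_genome"), inherits(enzyme, "restriction_enzyme"))
  pat <- Biostrings::DNAString(enzyme$recognition)
  res <- lapply(names(genome), function(ch) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(genome[[ch]]),
                                  fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(chrom = ch, start0 = Biostrings::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(chrom = character(0), start0 = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start0), , drop = FALSE]
}

# Internal: per-chromosome fragment construction from realized cut positions.
# cuts: data.frame(pos (0-based cut position), type, site) sorted by pos.
fragments_from_cuts <- function(chrom, chrom_len, cuts, molecule = NA_integer_) {
  bounds <- c(0L, cuts$pos, chrom_len)
  n <- length(bounds) - 1L
  data.frame(
    chrom = rep(chrom, n),
    start0 = bounds[-length(bounds)],
    end0 = bounds[-1L],
    left_type = c("terminus", cuts$type),
    right_type = c(cuts$type, "terminus"),
    left_site = c(NA_integer_, cuts$site),
    right_site = c(cuts$site, NA_integer_),
    molecule = rep(molecule, n),
    stringsAsFactors = FALSE
  )
}

#' Methylation-aware in-silico double digestion
#'
#' EcoRI cuts every GAATTC; HpaII cuts a CCGG site only when it is
#' unmethylated. In `"deterministic"` mode the methylome must be binary
#' (m in {0,1}): m = 1 sites are never cut, m = 0 sites always are. In
#' `"molecules"` mode each of `n_molecules` genome copies cuts each HpaII
#' site independently with probability 1 - m, modeling a cell-population
#' mixture with methylated fraction m. Fragments tile each chromosome
#' exactly in every molecule.
#'
#' @param genome An `msap_genome`.
#' @param methylome Named numeric vector: CCGG site id -> methylated fraction
#'   m in [0,1]. Sites absent from the map are unmethylated.
#' @param mode `"deterministic"` or `"molecules"`.
#' @param n_molecules Number of genome copies in `"molecules"` mode.
#' @param seed RNG seed for `"molecules"` mode.
#' @param enzymes List of `restriction_enzyme` objects (default EcoRI + HpaII).
#' @return Data frame of fragments: `chrom`, `start0`, `end0`, `left_type`,
#'   `right_type` (enzyme name or `"terminus"`), `left_site`, `right_site`
#'   (start0 of the flanking recognition site, NA at termini) and `molecule`
#'   (NA in deterministic mode).
#' @export
digest <- function(genome, methylome = numeric(0),
                   mode = c("deterministic", "molecules"),
                   n_molecules = 1L, seed = NULL,
                   enzymes = list(restriction_enzyme("EcoRI"),
                                  restriction_enzyme("HpaII"))) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "msap_genome"))
  sens <- vapply(enzymes, function(e) e$methylation_sensitive, logical(1))
  if (sum(sens) != 1L) stop("exactly one methylation-sensitive enzyme expected")
  enz_h <- enzymes[[which(sens)]]
  site_tabs <- lapply(enzymes, function(e) {
    s <- find_sites(genome, e)
    s$type <- rep(e$name, nrow(s))
    s$cut <- s$start0 + e$cut_offset
    s
  })
  all_sites <- do.call(rbind, site_tabs)
  h_ids <- site_id(all_sites$chrom[all_sites$type == enz_h$name],
                   all_sites$start0[all_sites$type == enz_h$name])
  if (length(methylome)) {
    unknown <- setdiff(names(methylome), h_ids)
    if (length(unknown)) {
      stop("methylome keys are not ", enz_h$name, " sites of the genome: ",
           paste(head(unknown), collapse = ", "))
    }
    if (any(methylome < 0 | methylome > 1)) stop("methylated fractions must be in [0,1]")
  }
  m_of <- setNames(rep(0, length(h_ids)), h_ids)
  m_of[names(methylome)] <- methylome

  if (mode == "deterministic") {
    if (any(!m_of %in% c(0, 1))) {
      stop("deterministic digestion requires a binary methylome (m in {0,1}); ",
           "use mode = 'molecules' for fractional methylation")
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    n_molecules <- as.integer(n_molecules)
    stopifnot(n_molecules >= 1L)
  }

  out <- vector("list", length(genome) * max(1L, n_molecules))
  k <- 0L
  for (ch in names(genome)) {
    s <- all_sites[all_sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$cut), , drop = FALSE]
    is_h <- s$type == enz_h$name
    m <- ifelse(is_h, m_of[site_id(s$chrom, s$start0)], 0)
    L <- nchar(genome[[ch]])
    if (mode == "deterministic") {
      keep <- m == 0
      k <- k + 1L
      out[[k]] <- fragments_from_cuts(
        ch, L, data.frame(pos = s$cut[keep], type = s$type[keep],
                          site = s$start0[keep]))
    } else {
      for (mol in seq_len(n_molecules)) {
        keep <- !is_h | (runif(nrow(s)) < 1 - m)
        k <- k + 1L
        out[[k]] <- fragments_from_cuts(
          ch, L, data.frame(pos = s$cut[keep], type = s$type[keep],
                            site = s$start0[keep]), molecule = mol)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# Observed selective context at each fragment end.
#  - Left end of a fragment (right of a cut at site s): the forward-strand
#    bases immediately past the recognition sequence, genome[s+rl, s+rl+k).
#  - Right end (left of a cut at site s): reverse complement of the bases
#    immediately upstream of the recognition site, revcomp(genome[s-k, s)).
# Both read the end's inward 5'->3' strand just past the remnant.
end_selective_context <- function(genome, chrom, s, enzyme, side, k) {
  if (k == 0L) return(rep("", length(s)))
  seq <- genome[chrom]
  rl <- nchar(enzyme$recognition)
  if (side == "left") {
    substr(seq, s + rl + 1L, s + rl + k)
  } else {
    ctx <- substr(seq, s - k + 1L, s)
    ctx[s - k < 0L] <- ""
    bad <- nchar(ctx) != k | grepl("[^ACGT]", ctx)
    ctx[!bad] <- revcomp(ctx[!bad])
    ctx
  }
}

#' Selective amplification of digestion fragments
#'
#' A fragment end is amplifiable when it is a cut end (not a chromosome
#' terminus) and its inward-reading strand begins with the matching primer's
#' restriction remnant followed by that primer's selective bases. By default
#' only EcoRI-HpaII and HpaII-HpaII amplicon classes are retained (an
#' EcoRI-EcoRI product carries no HpaII adapter and can never pass the
#' downstream tag filter) and the insert length (without adapters) must lie
#' in `size_range`.
#'
#' @param fragments Fragment data frame from [digest()].
#' @param genome The `msap_genome` the fragments came from.
#' @param primer_e,primer_h `msap_primer` objects for the EcoRI and HpaII ends.
#' @param size_range Insert length window, default `c(50, 1000)`.
#' @param classes Retained amplicon classes.
#' @return The amplifiable subset of `fragments` with an added `class`
#'   column and a `seq` column holding the amplifiable-orientation sequence
#'   (HpaII/EcoRI adapter tail + insert + reverse-complemented right tail).
#' @export
select_amplicons <- function(fragments, genome, primer_e = msap_primer("EcoRI", "AC"),
                             primer_h = msap_primer("HpaII", "TG"),
                             size_range = c(50, 1000),
                             classes = c("EcoRI-HpaII", "HpaII-HpaII")) {
  stopifnot(inherits(genome, "msap_genome"))
  if (nchar(primer_e$selective) > 3L || nchar(primer_h$selective) > 3L) {
    stop("selective bases longer than 3 are not supported")
  }
  fr <- fragments[fragments$left_type != "terminus" &
                    fragments$right_type != "terminus", , drop = FALSE]
  if (nrow(fr) == 0L) return(cbind(fr, class = character(0), seq = character(0)))
  len <- fr$end0 - fr$start0
  fr <- fr[len >= size_range[1L] & len <= size_range[2L], , drop = FALSE]
  if (nrow(fr) == 0L) return(cbind(fr, class = character(0), seq = character(0)))

  cls <- paste(pmin(fr$left_type, fr$right_type),
               pmax(fr$left_type, fr$right_type), sep = "-")
  fr <- fr[cls %in% classes, , drop = FALSE]
  cls <- cls[cls %in% classes]
  if (nrow(fr) == 0L) return(cbind(fr, class = character(0), seq = character(0)))

  primer_of <- function(type) if (type == "EcoRI") primer_e else primer_h
  enz_of <- function(type) restriction_enzyme(type)
  match_end <- function(types, sites, side) {
    ok <- logical(nrow(fr))
    for (type in unique(types)) {
      idx <- which(types == type)
      p <- primer_of(type)
      if (p$end_type != type) {
        stop("primer end-type mismatch: ", p$end_type, " primer at a ", type, " end")
      }
      obs <- end_selective_context(genome, fr$chrom[idx], sites[idx],
                                   enz_of(type), side, nchar(p$selective))
      ok[idx] <- obs == p$selective
    }
    ok
  }
  keep <- match_end(fr$left_type, fr$left_site, "left") &
    match_end(fr$right_type, fr$right_site, "right")
  fr <- fr[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(fr) == 0L) return(cbind(fr, class = character(0), seq = character(0)))
  fr$class <- cls
  fr$seq <- amplicon_sequences(fr, genome, primer_e, primer_h)
  rownames(fr) <- NULL
  fr
}

# Full amplifiable-orientation sequence of each amplicon: left adapter tail,
# genomic span from the left cut through the right end's filled-in remnant,
# then the reverse complement of the right adapter tail. Computed once per
# distinct amplicon and recycled across molecules.
amplicon_sequences <- function(amplicons, genome, primer_e, primer_h) {
  tail_of <- c(EcoRI = primer_e$tail, HpaII = primer_h$tail)
  reach_of <- c(EcoRI = enzyme_left_reach(restriction_enzyme("EcoRI")),
                HpaII = enzyme_left_reach(restriction_enzyme("HpaII")))
  key <- paste(amplicons$chrom, amplicons$left_site, amplicons$right_site,
               amplicons$left_type, amplicons$right_type)
  u <- !duplicated(key)
  a <- amplicons[u, , drop = FALSE]
  gstart <- a$left_site + 2L                     # 1-based: first base after cut
  gend <- a$right_site + reach_of[a$right_type]  # 1-based inclusive
  insert <- substr(genome[a$chrom], gstart, gend)
  seqs <- paste0(tail_of[a$left_type], insert, revcomp(tail_of[a$right_type]))
  unname(seqs[match(key, key[u])])
}

#' Sonication: shear amplicons into sequencing-sized pieces
#'
#' Piece lengths follow a normal distribution with the given mean and sd,
#' truncated to `[1, amplicon length]`; an amplicon no longer than
#' `mean_size` is left as a single unsheared piece. Pieces partition each
#' amplicon molecule exactly, and terminal pieces retain the ligated
#' adapter-tail sequence on their outer end. Runs are bit-reproducible for a
#' fixed seed.
#'
#' @param amplicons Amplicon data frame from [select_amplicons()] (one row
#'   per molecule; must carry a `seq` column).
#' @param mean_size Target mean piece length (>= 50); the protocol sonication
#'   aims at 300 bp.
#' @param sd Standard deviation of the piece-length distribution.
#' @param seed RNG seed.
#' @return Data frame of pieces with columns `amp_index` (row of `amplicons`),
#'   `molecule`, `seq`, `from`, `to` (1-based position within the amplicon
#'   sequence), `left_terminal`, `right_terminal`.
#' @export
fragment_amplicons <- function(amplicons, mean_size = 300, sd = 100, seed = NULL) {
  stopifnot(mean_size >= 50)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(amplicons) == 0L) {
    return(data.frame(amp_index = integer(0), molecule = integer(0),
                      seq = character(0), from = integer(0), to = integer(0),
                      left_terminal = logical(0), right_terminal = logical(0)))
  }
  lens <- nchar(amplicons$seq)
  amp_idx <- list(); mol <- list(); from <- list(); to <- list()
  for (i in seq_len(nrow(amplicons))) {
    L <- lens[i]
    if (L <= mean_size) {
      cuts <- integer(0)
    } else {
      pieces <- integer(0)
      remaining <- L
      while (remaining > 0L) {
        l <- as.integer(round(rnorm(1L, mean_size, sd)))
        l <- max(1L, min(l, remaining))
        if (remaining - l < 1L) l <- remaining
        pieces <- c(pieces, l)
        remaining <- remaining - l
      }
      cuts <- cumsum(pieces[-length(pieces)])
    }
    bounds <- c(0L, cuts, L)
    np <- length(bounds) - 1L
    amp_idx[[i]] <- rep(i, np)
    mol[[i]] <- rep(amplicons$molecule[i], np)
    from[[i]] <- bounds[-length(bounds)] + 1L
    to[[i]] <- bounds[-1L]
  }
  amp_index <- unlist(amp_idx)
  from <- unlist(from)
  to <- unlist(to)
  data.frame(
    amp_index = amp_index,
    molecule = unlist(mol),
    seq = substr(amplicons$seq[amp_index], from, to),
    from = from, to = to,
    left_terminal = from == 1L,
    right_terminal = to == lens[amp_index],
    stringsAsFactors = FALSE
  )
}

#' Synthesize sequencing reads from sheared pieces
#'
#' One read is taken from each end of each piece: a forward read from the
#' piece 5' end and a reverse-complement read from its 3' end (in paired mode
#' these become mates /1 and /2 of one pair). In single-end mode a piece no
#' longer than the read length is fully covered by its forward read, so only
#' that one read is emitted (its reverse-complement twin would duplicate the
#' same molecule observation). Reads from the outer ends of terminal pieces
#' begin with the ligated adapter tail followed by the restriction remnant
#' (for HpaII ends: `GATGAGTCTAGAA` + `CGG` + selective bases); short pieces
#' sequenced through to the far adapter carry it reverse-complemented at the
#' read 3' end, as on a real instrument. Substitution errors are applied per
#' base at `error_rate`; qualities are constant Q30.
#'
#' @param pieces Piece data frame from [fragment_amplicons()].
#' @param amplicons The amplicon data frame the pieces refer to (for
#'   provenance: end types and flanking sites).
#' @param read_length Read length (>= 36); shorter pieces yield shorter reads.
#' @param paired Emit mate pairs (`/1`, `/2`) instead of independent reads.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param id_prefix Read id prefix.
#' @return List with `reads` (data.frame: id, seq, qual, mate) and
#'   `provenance` (data.frame: id, amp_index, end, end_type, site_chrom,
#'   site_start0 - NA for internal, adapter-free read starts).
#' @export
synthesize_reads <- function(pieces, amplicons, read_length = 75L,
                             paired = FALSE, error_rate = 0, seed = NULL,
                             id_prefix = "sim") {
  stopifnot(read_length >= 36L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pieces)
  if (n == 0L) {
    reads <- data.frame(id = character(0), seq = character(0),
                        qual = character(0), mate = integer(0))
    return(list(reads = reads, provenance = reads[, "id", drop = FALSE]))
  }
  L <- nchar(pieces$seq)
  fwd <- substr(pieces$seq, 1L, pmin(L, read_length))
  rev_ <- revcomp(substr(pieces$seq, pmax(1L, L - read_length + 1L), L))
  base_id <- sprintf("%s_%06d", id_prefix, seq_len(n))

  end_info <- function(which_end) {
    terminal <- if (which_end == "left") pieces$left_terminal else pieces$right_terminal
    type_col <- if (which_end == "left") "left_type" else "right_type"
    site_col <- if (which_end == "left") "left_site" else "right_site"
    data.frame(
      amp_index = pieces$amp_index,
      end = rep(which_end, n),
      end_type = ifelse(terminal, amplicons[[type_col]][pieces$amp_index],
                        NA_character_),
      site_chrom = ifelse(terminal, amplicons$chrom[pieces$amp_index],
                          NA_character_),
      site_start0 = ifelse(terminal, amplicons[[site_col]][pieces$amp_index],
                           NA_integer_),
      stringsAsFactors = FALSE
    )
  }
  if (paired) {
    ids <- c(paste0(base_id, "/1"), paste0(base_id, "/2"))
    seqs <- c(fwd, rev_)
    mate <- rep(c(1L, 2L), each = n)
    prov <- rbind(end_info("left"), end_info("right"))
    prov <- cbind(id = ids, prov, stringsAsFactors = FALSE)
  } else {
    # a fully covered piece is represented once, by its forward read
    full <- L <= read_length
    ids_l <- paste0(base_id, ifelse(full, ":F", ":L"))
    ids <- c(ids_l, paste0(base_id, ":R")[!full])
    seqs <- c(fwd, rev_[!full])
    mate <- rep(NA_integer_, length(ids))
    prov_l <- cbind(id = ids_l, end_info("left"), stringsAsFactors = FALSE)
    prov_r <- cbind(id = ids_l, end_info("right"), stringsAsFactors = FALSE)
    prov_r2 <- cbind(id = paste0(base_id, ":R")[!full],
                     end_info("right")[!full, , drop = FALSE],
                     stringsAsFactors = FALSE)
    # forward reads of full pieces represent both ends; longer pieces split
    # their two ends across the :L and :R reads
    prov <- rbind(prov_l, prov_r[full, , drop = FALSE], prov_r2)
  }

  if (error_rate > 0) {
    seqs <- apply_substitution_errors(seqs, error_rate)
  }
  qual <- strrep("?", nchar(seqs))  # constant Q30, Phred+33
  reads <- data.frame(id = ids, seq = seqs, qual = qual, mate = mate,
                      stringsAsFactors = FALSE)
  list(reads = reads, provenance = prov)
}

# Independent per-base substitution errors (substitute with one of the three
# other bases uniformly).
apply_substitution_errors <- function(seqs, error_rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- runif(length(flat)) < error_rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(flat[hit], function(b) sample(setdiff(bases, b), 1L),
                   character(1))
    flat[hit] <- repl
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste0, character(1),
         collapse = "")
}

#' Generate a synthetic genome with planted restriction sites
#'
#' Builds a random background free of CCGG and GAATTC, then plants recognition
#' sites at controlled spacings with flanking bases that either match the
#' selective primers (with probability `p_context_match` per fragment end) or
#' deliberately mismatch them. About one EcoRI site is planted per
#' `ecori_every` CCGG sites, mimicking a rare/frequent cutter pair.
#'
#' @param n_sites Total number of planted recognition sites.
#' @param spacing Two-element range of inter-site gaps in bp (default
#'   200-900, bracketing the 300 bp sonication target).
#' @param ecori_every Plant an EcoRI site every this many sites (default 8).
#' @param primer_e,primer_h The selective primers contexts are matched to.
#' @param p_context_match Probability that each flank of a planted site
#'   matches its primer's selective bases.
#' @param chrom_name Name of the single chromosome generated.
#' @param seed RNG seed.
#' @return List with `genome` (an `msap_genome`) and `planted` (data.frame:
#'   site_id, enzyme, left_context_match, right_context_match).
#' @export
simulate_genome <- function(n_sites = 1000L, spacing = c(200L, 900L),
                            ecori_every = 8L,
                            primer_e = msap_primer("EcoRI", "AC"),
                            primer_h = msap_primer("HpaII", "TG"),
                            p_context_match = 0.8, chrom_name = "chr1",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  bases <- c("A", "C", "G", "T")
  bg <- function(n) {
    s <- paste0(sample(bases, n, replace = TRUE), collapse = "")
    # destroy accidental recognition sites in the background
    repeat {
      hits <- c(unlist(gregexpr("CCGG", s, fixed = TRUE)),
                unlist(gregexpr("GAATTC", s, fixed = TRUE)))
      hits <- hits[hits > 0L]
      if (length(hits) == 0L) break
      for (h in hits) substr(s, h + 1L, h + 1L) <- sample(bases, 1L)
    }
    s
  }
  mismatch_for <- function(match_bases) {
    if (nchar(match_bases) == 0L) return("")
    cand <- chartr("ACGT", "TTAA", match_bases)  # never equal to the match
    cand
  }
  is_e <- (seq_len(n_sites) %% as.integer(ecori_every)) == 0L
  gaps <- as.integer(round(runif(n_sites + 1L, spacing[1L], spacing[2L])))
  parts <- character(0)
  pos <- 0L
  planted <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    seg <- bg(gaps[i] )
    if (is_e[i]) {
      p <- primer_e; motif <- "GAATTC"
      up_match <- revcomp(p$selective)
    } else {
      p <- primer_h; motif <- "CCGG"
      up_match <- revcomp(p$selective)
    }
    left_ok <- runif(1L) < p_context_match
    right_ok <- runif(1L) < p_context_match
    up <- if (left_ok) up_match else mismatch_for(up_match)
    down <- if (right_ok) p$selective else mismatch_for(p$selective)
    block <- paste0(up, motif, down)
    start0 <- pos + nchar(seg) + nchar(up)
    parts <- c(parts, seg, block)
    pos <- pos + nchar(seg) + nchar(block)
    planted[[i]] <- data.frame(
      chrom = chrom_name, start0 = start0,
      enzyme = if (is_e[i]) "EcoRI" else "HpaII",
      left_context_match = left_ok, right_context_match = right_ok,
      stringsAsFactors = FALSE
    )
  }
  parts <- c(parts, bg(gaps[n_sites + 1L]))
  seq <- paste0(parts, collapse = "")
  planted <- do.call(rbind, planted)
  planted$site_id <- site_id(planted$chrom, planted$start0)

  # junctions between blocks may have created spurious sites; repair them
  # without touching planted windows
  protect <- unlist(lapply(seq_len(nrow(planted)), function(i) {
    rl <- if (planted$enzyme[i] == "EcoRI") 6L else 4L
    (planted$start0[i] - 2L):(planted$start0[i] + rl + 1L)
  }))
  repeat {
    hits1 <- unlist(gregexpr("CCGG", seq, fixed = TRUE))
    hits1 <- hits1[hits1 > 0L]
    hits1 <- hits1[!((hits1 - 1L) %in% planted$start0[planted$enzyme == "HpaII"])]
    hits2 <- unlist(gregexpr("GAATTC", seq, fixed = TRUE))
    hits2 <- hits2[hits2 > 0L]
    hits2 <- hits2[!((hits2 - 1L) %in% planted$start0[planted$enzyme == "EcoRI"])]
    spans <- c(lapply(hits1, function(h) h:(h + 3L)),
               lapply(hits2, function(h) h:(h + 5L)))
    if (length(spans) == 0L) break
    for (span in spans) {
      editable <- setdiff(span - 1L, protect)  # 0-based editable positions
      if (length(editable) == 0L) next
      pos1 <- editable[1L] + 1L
      cur <- substr(seq, pos1, pos1)
      substr(seq, pos1, pos1) <- sample(setdiff(bases, cur), 1L)
    }
  }
  g <- as_msap_genome(setNames(seq, chrom_name))
  list(genome = g, planted = planted)
}

#' Generate a random methylome over the CCGG sites of a genome
#'
#' @param genome An `msap_genome`.
#' @param p_methylated Probability a site is methylated.
#' @param fractional If TRUE, methylated sites get a fractional level drawn
#'   uniformly from `levels`; otherwise m = 1.
#' @param levels Candidate fractional methylation levels.
#' @param seed RNG seed.
#' @return Named numeric vector site_id -> m, covering every CCGG site.
#' @export
random_methylome <- function(genome, p_methylated = 0.5, fractional = FALSE,
                             levels = c(0.25, 0.5, 0.75, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- find_sites(genome, restriction_enzyme("HpaII"))
  ids <- site_id(sites$chrom, sites$start0)
  m <- numeric(length(ids))
  meth <- runif(length(ids)) < p_methylated
  m[meth] <- if (fractional) sample(levels, sum(meth), replace = TRUE) else 1
  setNames(m, ids)
}

#' Simulate a complete MSAP-Seq experiment
#'
#' Composes digestion, selective amplification, sonication and read synthesis
#' for each sample, and records the ground truth: the realized HpaII-adapter
#' end abundance per CCGG site and molecule (proportional to (1 - m) times
#' amplicon multiplicity), plus a site-level table of which sites are
#' amplifiable at all under the chosen primers and size window.
#'
#' @param config A list with elements: `genome` (an `msap_genome` or FASTA
#'   path), `samples` (list of lists with `name`, `methylome` (named numeric),
#'   `n_molecules`, `seed`), and optionally `primers` (list with `E` and `H`
#'   `msap_primer`s), `size_range`, `classes`, `mean_size`, `sd`,
#'   `read_length`, `paired`, `error_rate`, `out_dir`.
#' @return List with `samples` (per sample: `reads`, `provenance`),
#'   `truth` (data.frame: sample, site_id, expected_abundance),
#'   `sites` (data.frame: site_id, amplifiable, fragment_length) and
#'   `fastq_paths` when `out_dir` was given.
#' @export
simulate_experiment <- function(config) {
  problems <- character(0)
  if (is.null(config$genome)) problems <- c(problems, "missing 'genome'")
  if (is.null(config$samples) || length(config$samples) == 0L) {
    problems <- c(problems, "missing 'samples'")
  } else {
    for (i in seq_along(config$samples)) {
      smp <- config$samples[[i]]
      if (is.null(smp$name)) problems <- c(problems, sprintf("sample %d: missing 'name'", i))
      if (is.null(smp$seed)) problems <- c(problems, sprintf("sample %d: missing 'seed'", i))
    }
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "))
  }
  genome <- config$genome
  if (!inherits(genome, "msap_genome")) genome <- read_genome_fasta(genome)
  primer_e <- if (!is.null(config$primers$E)) config$primers$E else msap_primer("EcoRI", "AC")
  primer_h <- if (!is.null(config$primers$H)) config$primers$H else msap_primer("HpaII", "TG")
  size_range <- if (!is.null(config$size_range)) config$size_range else c(50, 1000)
  classes <- if (!is.null(config$classes)) config$classes else c("EcoRI-HpaII", "HpaII-HpaII")
  mean_size <- if (!is.null(config$mean_size)) config$mean_size else 300
  sd <- if (!is.null(config$sd)) config$sd else 100
  read_length <- if (!is.null(config$read_length)) config$read_length else 75L
  paired <- isTRUE(config$paired)
  error_rate <- if (!is.null(config$error_rate)) config$error_rate else 0

  # site-level candidate amplifiability: all sites unmethylated
  cand <- select_amplicons(digest(genome, numeric(0), mode = "deterministic"),
                           genome, primer_e, primer_h, size_range, classes)
  h_sites <- find_sites(genome, restriction_enzyme("HpaII"))
  h_ids <- site_id(h_sites$chrom, h_sites$start0)
  amp_end_sites <- c(site_id(cand$chrom, cand$left_site)[cand$left_type == "HpaII"],
                     site_id(cand$chrom, cand$right_site)[cand$right_type == "HpaII"])
  frag_len <- c(setNames(cand$end0 - cand$start0, site_id(cand$chrom, cand$left_site)),
                setNames(cand$end0 - cand$start0, site_id(cand$chrom, cand$right_site)))
  sites_tab <- data.frame(
    site_id = h_ids,
    amplifiable = h_ids %in% amp_end_sites,
    fragment_length = unname(frag_len[h_ids]),
    stringsAsFactors = FALSE
  )

  sample_out <- list()
  truth <- list()
  fastq_paths <- list()
  for (smp in config$samples) {
    n_mol <- if (!is.null(smp$n_molecules)) as.integer(smp$n_molecules) else 30L
    methylome <- if (!is.null(smp$methylome)) smp$methylome else numeric(0)
    frs <- digest(genome, methylome, mode = "molecules", n_molecules = n_mol,
                  seed = derive_seed(smp$seed, "digest"))
    amps <- select_amplicons(frs, genome, primer_e, primer_h, size_range, classes)
    pieces <- fragment_amplicons(amps, mean_size = mean_size, sd = sd,
                                 seed = derive_seed(smp$seed, "shear"))
    synth <- synthesize_reads(pieces, amps, read_length = read_length,
                              paired = paired, error_rate = error_rate,
                              seed = derive_seed(smp$seed, "reads"),
                              id_prefix = smp$name)
    sample_out[[smp$name]] <- synth

    h_end <- c(site_id(amps$chrom, amps$left_site)[amps$left_type == "HpaII"],
               site_id(amps$chrom, amps$right_site)[amps$right_type == "HpaII"])
    tab <- table(h_end)
    truth[[smp$name]] <- data.frame(
      sample = rep(smp$name, length(tab)),
      site_id = names(tab),
      expected_abundance = as.integer(tab),
      stringsAsFactors = FALSE
    )
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      if (paired) {
        p1 <- file.path(config$out_dir, paste0(smp$name, "_R1.fastq"))
        p2 <- file.path(config$out_dir, paste0(smp$name, "_R2.fastq"))
        write_reads_fastq(synth$reads[synth$reads$mate == 1L, ], p1)
        write_reads_fastq(synth$reads[synth$reads$mate == 2L, ], p2)
        fastq_paths[[smp$name]] <- c(p1, p2)
      } else {
        p <- file.path(config$out_dir, paste0(smp$name, ".fastq"))
        write_reads_fastq(synth$reads, p)
        fastq_paths[[smp$name]] <- p
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(samples = sample_out, truth = truth, sites = sites_tab)
  if (!is.null(config$out_dir)) {
    write.table(truth, file.path(config$out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$fastq_paths <- fastq_paths
  }
  out
}
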