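test_that("find_sites enumerates all forward-strand matches in order", {
  g <- as_msap_genome(c(c1 = "ACCGGT"))
  s <- find_sites(g, restriction_enzyme("HpaII"))
  expect_identical(s$start0, 1L)

  g2 <- as_msap_genome(c(c1 = "CCGGCCGG"))
  s2 <- find_sites(g2, restriction_enzyme("HpaII"))
  expect_identical(s2$start0, c(0L, 4L))

  # no recognition site may overlap an N
  g3 <- as_msap_genome(c(c1 = "CCNGGCCGG"))
  s3 <- find_sites(g3, restriction_enzyme("HpaII"))
  expect_identical(s3$start0, 5L)
})

test_that("site offsets mirror exactly under reverse complementation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 400
    seq <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    g <- as_msap_genome(c(c1 = seq))
    grc <- as_msap_genome(c(
      c1 = as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))))
    for (enz in list(restriction_enzyme("HpaII"), restriction_enzyme("EcoRI"))) {
      fwd <- find_sites(g, enz)$start0
      rev_ <- find_sites(grc, enz)$start0
      L <- nchar(seq)
      rl <- nchar(enz$recognition)
      expect_setequal(rev_, L - rl - fwd)
    }
  }
})

test_that("digestion cuts at stated positions and honours methylation", {
  g <- ex_digest_genome()  # EcoRI at 2, CCGG at 11
  fr <- digest(g)
  expect_identical(fr$start0, c(0L, 3L, 12L))
  expect_identical(fr$end0, c(3L, 12L, 17L))
  expect_identical(fr$left_type, c("terminus", "EcoRI", "HpaII"))

  fr_m <- digest(g, c("c1:11" = 1))
  expect_identical(fr_m$start0, c(0L, 3L))
  expect_identical(fr_m$end0, c(3L, 17L))

  expect_error(digest(g, c("c1:11" = 0.5)), "binary")
  expect_error(digest(g, c("c1:3" = 1)), "not HpaII sites")
})

test_that("digest fragments tile every chromosome exactly in all modes", {
  set.seed(23)
  for (rep in 1:4) {
    sg <- simulate_genome(n_sites = 30, seed = 100 + rep)
    meth <- random_methylome(sg$genome, p_methylated = 0.5,
                             fractional = rep %% 2 == 0, seed = 200 + rep)
    mode <- if (rep %% 2 == 0) "molecules" else "deterministic"
    fr <- if (mode == "molecules") {
      digest(sg$genome, meth, mode = "molecules", n_molecules = 3, seed = 5)
    } else {
      digest(sg$genome, round(meth))
    }
    for (mol in unique(fr$molecule)) {
      sub <- if (is.na(mol)) fr else fr[fr$molecule %in% mol, ]
      for (ch in unique(sub$chrom)) {
        f <- sub[sub$chrom == ch, ]
        f <- f[order(f$start0), ]
        expect_identical(f$start0[1], 0L)
        expect_identical(f$end0[nrow(f)], nchar(sg$genome[[ch]]))
        expect_identical(f$start0[-1], f$end0[-nrow(f)])  # contiguous
      }
    }
  }
})

test_that("selective amplification retains exactly the matching fragments", {
  g <- ex_amplicon_genome()  # GAATTC at 2, CCGG at 15
  fr <- digest(g)
  amp <- select_amplicons(fr, g, primer_E_AC(), primer_H_TG(),
                          size_range = c(1, 1000))
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$start0, 3L)
  expect_identical(amp$end0, 16L)
  expect_identical(amp$class, "EcoRI-HpaII")

  # selective mismatch: H-AA never matches the TG context
  amp2 <- select_amplicons(fr, g, primer_E_AC(), msap_primer("HpaII", "AA"),
                           size_range = c(1, 1000))
  expect_identical(nrow(amp2), 0L)

  # empty selective bases match vacuously
  amp3 <- select_amplicons(fr, g, msap_primer("EcoRI", ""), msap_primer("HpaII", ""),
                           size_range = c(1, 1000))
  expect_identical(nrow(amp3), 1L)
})

test_that("amplicon sequence begins with the full primer tail context", {
  g <- ex_amplicon_genome()
  amp <- select_amplicons(digest(g), g, primer_E_AC(), primer_H_TG(),
                          size_range = c(1, 1000))
  # EcoRI-ended left: E tail + AATTC + AC...
  expect_true(startsWith(amp$seq, "GACTGCGTACCAATTCAC"))
  # reading the HpaII end inward: H primer sequence exactly
  expect_true(startsWith(revcomp_chr(amp$seq), "GATGAGTCTAGAACGGTG"))
})

test_that("shearing partitions amplicons and is seed-reproducible", {
  g <- ex_amplicon_genome()
  amp <- select_amplicons(digest(g), g, primer_E_AC(), primer_H_TG(),
                          size_range = c(1, 1000))
  # shorter than mean size: single unsheared piece
  p <- fragment_amplicons(amp, mean_size = 300, sd = 100, seed = 1)
  expect_identical(nrow(p), 1L)
  expect_identical(p$seq, amp$seq)
  expect_true(p$left_terminal && p$right_terminal)

  # long amplicons: pieces partition, reproducibly
  long_amp <- data.frame(molecule = 1:50,
                         seq = strrep("ACGT", 1250),  # 5 kb
                         stringsAsFactors = FALSE)
  p1 <- fragment_amplicons(long_amp, mean_size = 300, sd = 60, seed = 7)
  p2 <- fragment_amplicons(long_amp, mean_size = 300, sd = 60, seed = 7)
  expect_identical(p1, p2)
  recon <- tapply(seq_len(nrow(p1)), p1$amp_index, function(i)
    paste0(p1$seq[i], collapse = ""))
  expect_true(all(recon == long_amp$seq))
})

test_that("shear lengths follow the truncated-normal model", {
  long_amp <- data.frame(molecule = seq_len(600),
                         seq = strrep("ACGT", 1250),  # 5 kb each
                         stringsAsFactors = FALSE)
  p <- fragment_amplicons(long_amp, mean_size = 300, sd = 60, seed = 99)
  lens <- nchar(p$seq)
  expect_gt(length(lens), 9000)
  expect_lt(abs(mean(lens) - 300), 10)
})

test_that("reads from HpaII-adapter piece ends carry the primer prefix", {
  g <- ex_amplicon_genome()
  amp <- select_amplicons(digest(g), g, primer_E_AC(), primer_H_TG(),
                          size_range = c(1, 1000))
  p <- fragment_amplicons(amp, seed = 1)
  synth <- synthesize_reads(p, amp, read_length = 36, error_rate = 0, seed = 1)
  prov <- synth$provenance
  h_ids <- prov$id[!is.na(prov$end_type) & prov$end_type == "HpaII"]
  h_reads <- synth$reads[synth$reads$id %in% h_ids, ]
  is_h_prefix <- startsWith(h_reads$seq, "GATGAGTCTAGAACGGTG") |
    endsWith(h_reads$seq, revcomp_chr("GATGAGTCTAGAACGGTG"))
  expect_true(all(is_h_prefix))
})

test_that("paired mode yields matched /1 and /2 mates", {
  g <- ex_amplicon_genome()
  amp <- select_amplicons(digest(g), g, primer_E_AC(), primer_H_TG(),
                          size_range = c(1, 1000))
  p <- fragment_amplicons(amp, seed = 1)
  synth <- synthesize_reads(p, amp, read_length = 36, paired = TRUE, seed = 1)
  r1 <- synth$reads[synth$reads$mate == 1L, ]
  r2 <- synth$reads[synth$reads$mate == 2L, ]
  expect_identical(sub("/1$", "", r1$id), sub("/2$", "", r2$id))
})

test_that("substitution errors appear at the configured rate", {
  piece <- data.frame(amp_index = 1L, molecule = 1L,
                      seq = strrep("ACGT", 5000), from = 1L, to = 20000L,
                      left_terminal = FALSE, right_terminal = FALSE)
  amp <- data.frame(chrom = "c1", left_type = "HpaII", right_type = "HpaII",
                    left_site = NA_integer_, right_site = NA_integer_)
  clean <- synthesize_reads(piece, amp, read_length = 10000, error_rate = 0,
                            seed = 3)$reads
  noisy <- synthesize_reads(piece, amp, read_length = 10000, error_rate = 0.01,
                            seed = 3)$reads
  mism <- sum(strsplit(clean$seq[1], "")[[1]] != strsplit(noisy$seq[1], "")[[1]])
  n <- nchar(clean$seq[1])
  expect_lt(abs(mism / n - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("simulated experiments are deterministic given seeds", {
  sg <- simulate_genome(n_sites = 40, seed = 5)
  meth <- random_methylome(sg$genome, seed = 6)
  cfg <- list(genome = sg$genome,
              samples = list(list(name = "a", methylome = meth,
                                  n_molecules = 10, seed = 77),
                             list(name = "b", methylome = meth,
                                  n_molecules = 10, seed = 77)))
  sim <- simulate_experiment(cfg)
  ra <- sim$samples$a$reads
  rb <- sim$samples$b$reads
  expect_identical(ra$seq, rb$seq)
  expect_identical(ra$qual, rb$qual)
})

test_that("fully methylated sites are absent from the truth table", {
  sg <- simulate_genome(n_sites = 60, seed = 15)
  meth <- random_methylome(sg$genome, p_methylated = 0.5, seed = 16)
  cfg <- list(genome = sg$genome,
              samples = list(list(name = "s", methylome = meth,
                                  n_molecules = 15, seed = 8)))
  sim <- simulate_experiment(cfg)
  blocked <- names(meth)[meth == 1]
  expect_length(intersect(sim$truth$site_id, blocked), 0L)
})

test_that("a half-methylated site recovers about half its reads", {
  sg <- simulate_genome(n_sites = 120, p_context_match = 1, seed = 25)
  ids <- names(random_methylome(sg$genome, p_methylated = 0))
  n_mol <- 200L
  run_with_m <- function(target, m) {
    meth <- setNames(numeric(length(ids)), ids)
    meth[target] <- m
    cfg <- list(genome = sg$genome,
                samples = list(list(name = "s", methylome = meth,
                                    n_molecules = n_mol, seed = 31)))
    sim <- simulate_experiment(cfg)
    ab <- sim$truth$expected_abundance[sim$truth$site_id == target]
    if (length(ab)) ab else 0L
  }
  target <- ids[20]
  ab0 <- run_with_m(target, 0)
  ab_half <- run_with_m(target, 0.5)
  expect_gt(ab0, 0)
  # only the target site's cut probability changed: its abundance is thinned
  # Binomial(n_molecules, 0.5); allow 3 binomial sd around one half
  expect_lt(abs(ab_half / ab0 - 0.5), 3 * 0.5 / sqrt(n_mol))
})

test_that("raising methylation at a site never increases its abundance", {
  sg <- simulate_genome(n_sites = 50, seed = 55)
  ids <- names(random_methylome(sg$genome, p_methylated = 0))
  target <- ids[10]
  prev <- Inf
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    meth <- setNames(rep(0, length(ids)), ids)
    meth[target] <- m
    cfg <- list(genome = sg$genome,
                samples = list(list(name = "s", methylome = meth,
                                    n_molecules = 60, seed = 99)))
    sim <- simulate_experiment(cfg)
    ab <- sim$truth$expected_abundance[sim$truth$site_id == target]
    ab <- if (length(ab)) ab else 0L
    expect_lte(ab, prev)
    prev <- ab
  }
})

test_that("reverse-complementing the genome mirrors the amplicon pool", {
  sg <- simulate_genome(n_sites = 40, spacing = c(60, 200), seed = 65)
  seq <- sg$genome[[1]]
  L <- nchar(seq)
  grc <- as_msap_genome(c(
    chr1 = as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))))
  amp_f <- select_amplicons(digest(sg$genome), sg$genome,
                            primer_E_AC(), primer_H_TG())
  amp_r <- select_amplicons(digest(grc), grc, primer_E_AC(), primer_H_TG())
  # the physical molecules are strand-symmetric: the full adapter-flanked
  # sequences mirror as reverse complements
  expect_identical(sort(revcomp_chr(amp_f$seq)), sort(amp_r$seq))
  # HpaII-end site ids mirror: start0 -> L - 4 - start0
  h_ends <- function(a) c(a$left_site[a$left_type == "HpaII"],
                          a$right_site[a$right_type == "HpaII"])
  expect_identical(sort(L - 4L - h_ends(amp_f)), sort(h_ends(amp_r)))
})

test_that("config validation enumerates schema violations", {
  expect_error(simulate_experiment(list()), "missing 'genome'")
  expect_error(
    simulate_experiment(list(genome = ex_digest_genome(),
                             samples = list(list(name = "x")))),
    "missing 'seed'")
})
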