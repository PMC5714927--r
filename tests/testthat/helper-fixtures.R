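# Shared fixtures, built in code at test time.

# Worked micro-genomes used across modules:
#   ex_digest: EcoRI site at 2, CCGG at 11 -> cuts at 3 and 12
#   ex_amplicon: GAATTC at 2, CCGG at 15; E-AC / H-TG contexts both match
ex_digest_genome <- function() as_msap_genome(c(c1 = "TTGAATTCAAACCGGTT"))
ex_amplicon_genome <- function() as_msap_genome(c(c1 = "TTGAATTCACGGGCACCGGTT"))

primer_E_AC <- function() msap_primer("EcoRI", "AC")
primer_H_TG <- function() msap_primer("HpaII", "TG")

# Random genome without any CCGG/GAATTC, for negative controls.
random_clean_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    hits <- c(unlist(gregexpr("CCGG", s, fixed = TRUE)),
              unlist(gregexpr("GAATTC", s, fixed = TRUE)))
    hits <- hits[hits > 0]
    if (length(hits) == 0) break
    for (h in hits) substr(s, h + 1, h + 1) <- sample(c("A", "C", "G", "T"), 1)
  }
  s
}

# Small simulated experiment shared by tagfilter/sitecount tests.
small_simulation <- function(n_sites = 80, seed = 42, p_methylated = 0.5,
                             n_molecules = 20, ...) {
  sg <- simulate_genome(n_sites = n_sites, seed = derive(seed, 1))
  meth <- random_methylome(sg$genome, p_methylated = p_methylated,
                           seed = derive(seed, 2))
  cfg <- list(genome = sg$genome,
              samples = list(list(name = "s1", methylome = meth,
                                  n_molecules = n_molecules,
                                  seed = derive(seed, 3))),
              ...)
  sim <- simulate_experiment(cfg)
  list(genome = sg$genome, planted = sg$planted, methylome = meth, sim = sim)
}

derive <- function(seed, salt) as.integer(seed * 1000L + salt)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Poisson count tables for two conditions with optional spiked fold changes.
make_count_tables <- function(n_sites, n_reps, mean_count, spike_idx = integer(0),
                              spike_fold = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("c1:%d", seq_len(n_sites) * 10L)
  lam_a <- rep(mean_count, n_sites)
  lam_b <- lam_a
  lam_b[spike_idx] <- lam_b[spike_idx] * spike_fold
  raw_a <- matrix(rpois(n_sites * n_reps, lam_a), n_sites, n_reps,
                  dimnames = list(ids, paste0("A", seq_len(n_reps))))
  raw_b <- matrix(rpois(n_sites * n_reps, lam_b), n_sites, n_reps,
                  dimnames = list(ids, paste0("B", seq_len(n_reps))))
  list(a = site_count_table(raw_a), b = site_count_table(raw_b))
}
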