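test_that("the built-in mapper assigns simulated tags to provenance sites", {
  fx <- small_simulation(seed = 201)
  reads <- fx$sim$samples$s1$reads
  prov <- fx$sim$samples$s1$provenance
  tags <- filter_reads(reads)$tags
  asn <- map_tags_builtin(tags, fx$genome)
  expect_true(all(asn$status == "assigned"))
  h_prov <- prov[!is.na(prov$end_type) & prov$end_type == "HpaII", ]
  truth_site <- setNames(site_id(h_prov$site_chrom, h_prov$site_start0),
                         h_prov$id)
  expect_identical(asn$site_id, unname(truth_site[asn$id]))
})

test_that("tags matching two CCGG contexts are ambiguous, absent ones unmapped", {
  # duplicate context: the same sequence follows two different CCGG sites
  ctx <- random_clean_sequence(70, seed = 31)
  spacer <- random_clean_sequence(100, seed = 32)
  g <- as_msap_genome(c(c1 = paste0("AA", "CCGG", ctx, spacer, "CCGG", ctx, "AA")))
  tag_dup <- data.frame(id = "t1", seq = paste0("CGG", substr(ctx, 1, 60)),
                        stringsAsFactors = FALSE)
  asn <- map_tags_builtin(tag_dup, g)
  expect_identical(asn$status, "ambiguous")
  expect_true(is.na(asn$site_id))

  tag_none <- data.frame(id = "t2",
                         seq = paste0("CGG", random_clean_sequence(60, seed = 33)),
                         stringsAsFactors = FALSE)
  expect_identical(map_tags_builtin(tag_none, g)$status, "unmapped")
})

test_that("SAM ingestion applies cut-coincidence and uniqueness rules", {
  sites <- data.frame(chrom = "c1", start0 = c(99L, 500L))
  al <- data.frame(
    id = c("fwd_ok", "off_by_5", "secondary", "rev_ok"),
    chrom = "c1",
    pos0 = c(100L, 105L, 100L, 450L),
    strand = c("+", "+", "+", "-"),
    cigar = c("60M", "60M", "60M", "53M"),
    mapq = 60L,
    is_unique = c(TRUE, TRUE, FALSE, TRUE),
    read_length = c(60L, 60L, 60L, 53L),
    stringsAsFactors = FALSE
  )
  res <- ingest_sam(al, sites)
  a <- res$assignments
  expect_identical(a$site_id[a$id == "fwd_ok"], "c1:99")
  expect_identical(a$status[a$id == "off_by_5"], "unmapped")
  expect_identical(a$status[a$id == "secondary"], "unmapped")
  expect_identical(a$site_id[a$id == "rev_ok"], "c1:500")
  expect_identical(unname(res$tally["non_unique"]), 1L)

  # with tolerance the off-by-5 forward alignment is recovered
  res5 <- ingest_sam(al, sites, tolerance = 5L)
  expect_identical(res5$assignments$site_id[res5$assignments$id == "off_by_5"],
                   "c1:99")
})

test_that("SAM ingestion agrees with the built-in mapper on simulated tags", {
  fx <- small_simulation(seed = 205)
  tags <- filter_reads(fx$sim$samples$s1$reads)$tags
  builtin <- map_tags_builtin(tags, fx$genome)
  # write a SAM fixture from the built-in placements (exact matches: the
  # alignment an external aligner would report), then re-ingest it
  sites <- find_sites(fx$genome, restriction_enzyme("HpaII"))
  coords <- parse_site_id(builtin$site_id)
  sam <- withr::local_tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6",
             paste0("@SQ\tSN:", names(fx$genome), "\tLN:", nchar(fx$genome)))
  fwd_ctx <- substr(fx$genome[coords$chrom], coords$start0 + 2L,
                    coords$start0 + 1L + nchar(tags$seq))
  is_fwd <- fwd_ctx == tags$seq
  pos1 <- ifelse(is_fwd, coords$start0 + 2L,
                 coords$start0 + 4L - nchar(tags$seq))
  lines <- c(lines, paste(builtin$id,
                          ifelse(is_fwd, 0L, 16L),
                          coords$chrom, pos1, 60L,
                          paste0(nchar(tags$seq), "M"),
                          "*", 0L, 0L,
                          ifelse(is_fwd, tags$seq, revcomp_chr(tags$seq)),
                          strrep("?", nchar(tags$seq)), sep = "\t"))
  writeLines(lines, sam)
  ing <- ingest_sam(read_alignments_sam(sam), sites)
  merged <- merge(builtin, ing$assignments, by = "id")
  expect_identical(merged$site_id.x, merged$site_id.y)
})

test_that("counting is additive and drops all-zero sites", {
  a1 <- data.frame(id = c("r1", "r2", "r3", "r4"),
                   site_id = c("c1:5", "c1:5", "c1:9", NA),
                   status = c("assigned", "assigned", "assigned", "unmapped"),
                   stringsAsFactors = FALSE)
  tab <- count_sites(list(s1 = a1))
  expect_identical(tab$raw["c1:5", "s1"], 2L)
  expect_identical(tab$raw["c1:9", "s1"], 1L)

  # merging two runs of the same sample adds counts
  tab2 <- count_sites(list(s1 = rbind(a1, a1)))
  expect_identical(tab2$raw[, "s1"], tab$raw[, "s1"] * 2L)

  empty <- count_sites(list(s1 = a1[0, ]))
  expect_identical(nrow(empty$raw), 0L)
})

test_that("RPM normalization conserves one million per sample", {
  raw <- matrix(c(2L, 8L), 2, 1, dimnames = list(c("c1:1", "c1:5"), "s1"))
  tab <- normalize_rpm(site_count_table(raw))
  expect_equal(unname(tab$rpm[, 1]), c(200000, 800000))
  expect_equal(unname(colSums(tab$rpm)), 1e6)

  # doubling raw counts leaves RPM unchanged
  tab2 <- normalize_rpm(site_count_table(raw * 2L))
  expect_equal(tab2$rpm, tab$rpm)

  zero <- site_count_table(matrix(0L, 1, 1, dimnames = list("c1:1", "s1")))
  expect_error(normalize_rpm(zero), "zero library size")
})

test_that("the coverage floor is per sample with any-sample retention", {
  raw <- matrix(c(1L, 1L,   # below floor everywhere -> dropped
                  2L, 0L,   # kept; the zero stays zero
                  1L, 5L),  # kept; the 1 is masked
                nrow = 3, byrow = TRUE,
                dimnames = list(c("c1:1", "c1:5", "c1:9"), c("s1", "s2")))
  tab <- apply_min_coverage(site_count_table(raw), min_reads = 2L)
  expect_identical(rownames(tab$raw), c("c1:5", "c1:9"))
  expect_identical(unname(tab$raw["c1:5", ]), c(2L, 0L))
  expect_identical(unname(tab$raw["c1:9", ]), c(0L, 5L))

  # min_reads 0 is the identity
  tab0 <- apply_min_coverage(site_count_table(raw), min_reads = 0L)
  expect_identical(tab0$raw, raw)
})

test_that("de novo tag counting matches mapped counts on unique contexts", {
  fx <- small_simulation(seed = 207)
  tags <- filter_reads(fx$sim$samples$s1$reads)$tags
  mapped <- normalize_rpm(count_sites(list(
    s1 = map_tags_builtin(tags, fx$genome))))
  dn <- denovo_tag_table(list(s1 = tags), tag_key_length = 30L)
  expect_identical(unname(dn$excluded), 0L)
  expect_identical(sum(dn$table$raw), sum(mapped$raw))
  # contexts are unique by construction: each site's mapped count equals the
  # sum of its two orientation keys (30-mer after CGG, forward and reverse)
  coords <- parse_site_id(rownames(mapped$raw))
  chr <- fx$genome[coords$chrom]
  key_f <- substr(chr, coords$start0 + 5L, coords$start0 + 34L)
  key_r <- revcomp_chr(substr(chr, coords$start0 - 29L, coords$start0))
  dn_of <- function(k) {
    v <- dn$table$raw[match(k, rownames(dn$table$raw)), 1]
    ifelse(is.na(v), 0L, v)
  }
  expect_identical(unname(mapped$raw[, 1]),
                   as.integer(dn_of(key_f) + dn_of(key_r)))

  # two identical tags in one sample count twice under one key
  t2 <- data.frame(id = c("a", "b"),
                   seq = rep(paste0("CGG", random_clean_sequence(40, seed = 3)), 2),
                   stringsAsFactors = FALSE)
  dn2 <- denovo_tag_table(list(s = t2), tag_key_length = 30L)
  expect_identical(unname(dn2$table$raw[1, 1]), 2L)

  # key longer than every tag: empty table, full exclusion tally
  dn3 <- denovo_tag_table(list(s = t2), tag_key_length = 60L)
  expect_identical(nrow(dn3$table$raw), 0L)
  expect_identical(unname(dn3$excluded), 2L)
})
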