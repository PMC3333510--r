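test_that("index construction validates input and uppercases sequences", {
  genome <- random_genome(1000L, seed = 3L)
  idx <- build_index(genome, k = 12)
  expect_s3_class(idx, "ref_index")
  expect_equal(reference_lengths(idx), c(`1` = 1000L))

  lower <- setNames(tolower(genome), names(genome))
  idx2 <- build_index(lower)
  expect_equal(idx2$chromosomes[["1"]]$seq, genome[[1]])

  expect_error(build_index(c(`1` = "ACGTX")), class = "usnp_alignment_error")
  expect_error(build_index(genome, k = 3), class = "usnp_alignment_error")
  # FASTA path input, with "chr" prefixes stripped from record names
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  write_genome_fasta(setNames(genome, "chr1 synthetic"), fa)
  expect_equal(build_index(fa)$names, "1")
})

test_that("exact, reverse-complement and over-budget reads behave as contracted", {
  genome <- random_genome(5000L, seed = 13L)
  idx <- build_index(genome)
  read <- substr(genome[[1]], 501, 576)

  hit <- align_read(idx, read)
  expect_equal(hit$start[1], 501L)
  expect_equal(hit$strand[1], "+")
  expect_equal(hit$mismatches[1], 0L)

  rc_hit <- align_read(idx, oracle_revcomp(read))
  expect_equal(rc_hit$start[1], 501L)
  expect_equal(rc_hit$strand[1], "-")
  expect_equal(rc_hit$mismatches[1], 0L)

  withr::with_seed(17L, {
    worse <- mutate_read(read, 4L)
    expect_equal(nrow(align_read(idx, worse, max_mismatch = 3)), 0L)
    expect_gte(nrow(align_read(idx, worse, max_mismatch = 4)), 1L)
  })

  expect_error(align_read(idx, "ACG"), class = "usnp_length_error")
  expect_error(align_read(idx, strrep("A", 1025)), class = "usnp_length_error")
})

test_that("hit sets equal the exhaustive Hamming-scan oracle", {
  genome <- random_genome(10000L, seed = 101L)
  idx <- build_index(genome)
  withr::with_seed(202L, {
    for (rep in 1:50) {
      L <- sample(c(35L, 76L, 128L, 512L), 1L)
      start <- sample.int(10000L - L + 1L, 1L)
      read <- substr(genome[[1]], start, start + L - 1L)
      read <- mutate_read(read, sample(0:4, 1L))
      if (runif(1) < 0.5) read <- oracle_revcomp(read)
      got <- align_read(idx, read, max_mismatch = 3, max_hits = Inf)
      want <- oracle_align(genome, read, max_mismatch = 3)
      expect_equal(got[, c("chrom", "start", "strand", "mismatches")], want)
    }
  })
})

test_that("the oracle also agrees when a free (marked-site) offset is excluded", {
  genome <- random_genome(6000L, seed = 303L)
  idx <- build_index(genome)
  withr::with_seed(404L, {
    for (rep in 1:15) {
      L <- sample(c(35L, 76L, 128L), 1L)
      start <- sample.int(6000L - L + 1L, 1L)
      read <- substr(genome[[1]], start, start + L - 1L)
      k <- sample.int(L, 1L)
      substr(read, k, k) <- "N"          # marked variant site
      read <- mutate_read(read, sample(0:3, 1L), protect = k)
      got <- align_read(idx, read, max_mismatch = 3, max_hits = Inf,
                        free_offsets = k)
      want <- oracle_align(genome, read, max_mismatch = 3, free_offsets = k)
      expect_equal(got[, c("chrom", "start", "strand", "mismatches")], want)
    }
  })
})

test_that("N matches nothing, in query or reference", {
  genome <- c(`1` = paste0(strrep("ACGT", 30), "NNNN", strrep("TTGA", 30)))
  idx <- build_index(genome)
  # a read overlapping the N block pays one mismatch per N, even for N vs N
  read <- substr(genome[[1]], 119, 142)  # covers positions 121..124 (NNNN)
  hits <- align_read(idx, read, max_mismatch = 4, max_hits = Inf)
  self <- hits[hits$start == 119L & hits$strand == "+", ]
  expect_equal(self$mismatches, 4L)
})

test_that("raising the mismatch budget never shrinks the hit set", {
  genome <- random_genome(8000L, seed = 550L)
  idx <- build_index(genome)
  withr::with_seed(551L, {
    for (rep in 1:10) {
      start <- sample.int(8000L - 76L, 1L)
      read <- mutate_read(substr(genome[[1]], start, start + 75L), sample(0:3, 1L))
      sets <- lapply(0:4, function(mm) {
        h <- align_read(idx, read, max_mismatch = mm, max_hits = Inf)
        paste(h$chrom, h$start, h$strand)
      })
      for (j in 2:5) expect_true(all(sets[[j - 1L]] %in% sets[[j]]))
    }
  })
})

test_that("ties break deterministically: fewest mismatches, chromosome, leftmost, + first", {
  seg <- paste(withr::with_seed(7L, sample(c("A", "C", "G", "T"), 40, TRUE)),
               collapse = "")
  pad <- function(n, seed) paste(withr::with_seed(seed, sample(c("A", "C", "G", "T"), n, TRUE)),
                                 collapse = "")
  genome <- c(`1` = paste0(pad(50, 8), seg, pad(50, 9), seg, pad(50, 10)),
              `2` = paste0(pad(30, 11), seg, pad(30, 12)))
  idx <- build_index(genome)
  hits <- align_read(idx, seg, max_hits = Inf)
  expect_equal(hits$chrom, c("1", "1", "2"))
  expect_equal(hits$start, c(51L, 141L, 31L))
  # capped at the default two best hits
  expect_equal(nrow(align_read(idx, seg)), 2L)
})

# ---- variant localization --------------------------------------------------

test_that("a planted substitution localizes to its exact locus with ref allele leftmost", {
  genome <- random_genome(10000L, seed = 23L)
  idx <- build_index(genome)
  locus <- 5000L
  ref <- substr(genome[[1]], locus, locus)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rec <- flanking_record("q", substr(genome[[1]], locus - 37L, locus - 1L),
                         substr(genome[[1]], locus + 1L, locus + 38L),
                         "substitution", c(alt, ref))   # observed alt-first
  loc <- localize_variant(idx, rec)
  expect_equal(loc$status, "ok")
  expect_equal(loc$name$locus, 5000L)
  expect_equal(loc$name$alleles, c(ref, alt))           # reference moved leftmost
  expect_equal(loc$hit$mismatches, 0L)                  # marked site is budget-free
  expect_false(loc$reference_mismatch)

  # strand invariance: the reverse-complemented record gives the same name
  loc_rc <- localize_variant(idx, rc_flanking(rec))
  expect_equal(format_usnp(loc_rc$name), format_usnp(loc$name))
  expect_equal(loc_rc$hit$strand, "-")
})

test_that("insertion localization follows the displaced-base convention", {
  genome <- random_genome(8000L, seed = 29L)
  idx <- build_index(genome)
  p <- 1234L   # the inserted base is written at p; the old base moves to p+1
  rec <- flanking_record("ins_q", substr(genome[[1]], p - 38L, p - 1L),
                         substr(genome[[1]], p, p + 37L),
                         "insertion", "T")
  loc <- localize_variant(idx, rec)
  expect_equal(loc$status, "ok")
  expect_equal(loc$name$variant_class, "insertion")
  expect_equal(loc$name$locus, 1234L)
  expect_equal(displaced_reference_position(loc$name), 1235L)
  # the displaced reference base is the first base of the 3' flank
  expect_equal(substr(genome[[1]], loc$name$locus, loc$name$locus),
               substr(rec$three_prime, 1L, 1L))
  loc_rc <- localize_variant(idx, rc_flanking(rec))
  expect_equal(format_usnp(loc_rc$name), format_usnp(loc$name))
})

test_that("deletion localization recovers the deleted base at its locus", {
  genome <- random_genome(8000L, seed = 37L)
  idx <- build_index(genome)
  p <- 4321L
  del <- substr(genome[[1]], p, p)
  rec <- flanking_record("del_q", substr(genome[[1]], p - 38L, p - 1L),
                         substr(genome[[1]], p + 1L, p + 38L),
                         "deletion", del)
  loc <- localize_variant(idx, rec)
  expect_equal(loc$name$locus, p)
  expect_equal(loc$name$alleles, del)
  expect_false(loc$reference_mismatch)
  loc_rc <- localize_variant(idx, rc_flanking(rec))
  expect_equal(format_usnp(loc_rc$name), format_usnp(loc$name))
})

test_that("unplaceable and ambiguous queries are reported as such", {
  genome <- random_genome(6000L, seed = 41L)
  idx <- build_index(genome)
  alien <- flanking_record("alien", strrep("AC", 20), strrep("GT", 20),
                           "substitution", c("G", "A"))
  withr::with_seed(42L, {
    # a random 80-mer almost surely has no 3-mismatch placement in 6 kb
    alien$five_prime <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    alien$three_prime <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  })
  loc <- localize_variant(idx, alien)
  expect_equal(loc$status, "not_aligned")
  expect_null(loc$name)

  # duplicated segment: the same flanks occur at two loci -> ambiguous
  seg <- substr(genome[[1]], 1001L, 1100L)
  dup <- genome
  substr(dup[[1]], 4001L, 4100L) <- seg
  idx_dup <- build_index(dup)
  mid <- 1050L
  ref <- substr(genome[[1]], mid, mid)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rec <- flanking_record("dup_q", substr(dup[[1]], mid - 37L, mid - 1L),
                         substr(dup[[1]], mid + 1L, mid + 38L),
                         "substitution", c(ref, alt))
  loc2 <- localize_variant(idx_dup, rec)
  expect_equal(loc2$status, "ambiguous")
  expect_equal(nrow(loc2$hits), 2L)
  expect_setequal(loc2$hits$locus, c(1050L, 4050L))
})

test_that("a read whose observed alleles exclude the reference base is flagged", {
  genome <- random_genome(5000L, seed = 43L)
  idx <- build_index(genome)
  locus <- 2500L
  others <- setdiff(c("A", "C", "G", "T"), substr(genome[[1]], locus, locus))
  rec <- flanking_record("q", substr(genome[[1]], locus - 37L, locus - 1L),
                         substr(genome[[1]], locus + 1L, locus + 38L),
                         "substitution", others[1:2])
  loc <- localize_variant(idx, rec)
  expect_equal(loc$status, "ok")
  expect_true(loc$reference_mismatch)
  expect_equal(loc$name$alleles, others[1:2])   # observed alleles kept
})

test_that("batch annotation joins localization with the snapshot and renders negatives", {
  spec <- fixture_spec(genome_length = 12000, n_snps = 60, indel_fraction = 0.2,
                       xref_fraction = 0.5, seed = 19)
  genome <- generate_genome(spec)
  planted <- plant_snps(genome, spec)
  idx <- build_index(genome)
  reads <- emit_flanking_reads(genome, planted$truth, 76, error_rate = 0, seed = 20)
  alien <- flanking_record("alien", strrep("ACGTT", 8), strrep("GGATC", 8),
                           "substitution", c("G", "A"))
  res <- align_batch(idx, c(reads, list(alien)), store = planted$xref)
  expect_equal(nrow(res), 61L)
  expect_equal(names(res)[1:11],
               c("query_id", "chrom", "position", "strand", "mismatches",
                 "alleles", "usnp_id", "rs", "jsnp", "hapmap", "gwas"))
  planted_rows <- res[seq_len(60L), ]
  expect_equal(planted_rows$usnp_id, planted$truth$usnp_id)
  # identifiers come back where the snapshot has them, "none" elsewhere
  in_store <- planted$truth$locus %in% planted$xref$records$pos
  expect_true(all(planted_rows$rs[!in_store] == "none"))
  expect_true(any(planted_rows$rs != "none"))
  # the unplaceable read renders as Not Aligned
  expect_equal(res$usnp_id[61L], "Not Aligned")
  expect_equal(res$status[61L], "Not Aligned")
})
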