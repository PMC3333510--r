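test_that("genome generation is deterministic, sized and compositionally uniform", {
  spec <- fixture_spec(genome_length = 10000, n_snps = 50, seed = 1)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[[1]]), 10000L)

  spec2 <- fixture_spec(genome_length = 4000, n_chromosomes = 2, n_snps = 50, seed = 1)
  expect_equal(names(generate_genome(spec2)), c("1", "2"))

  # GC fraction of a 100 kb genome within 0.5 +/- 0.02 (binomial bound)
  big <- generate_genome(fixture_spec(genome_length = 100000, n_snps = 100, seed = 2))
  gc <- sum(strsplit(big[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("planted variants sit at distinct loci with reference-consistent alleles", {
  spec <- fixture_spec(genome_length = 10000, n_snps = 100, indel_fraction = 0.2,
                       seed = 4)
  genome <- generate_genome(spec)
  truth <- plant_snps(genome, spec)$truth
  expect_equal(nrow(truth), 100L)
  expect_equal(anyDuplicated(truth[, c("chrom", "locus")]), 0L)
  for (i in seq_len(nrow(truth))) {
    ref <- substr(genome[[truth$chrom[i]]], truth$locus[i], truth$locus[i])
    cls <- truth$variant_class[i]
    if (cls == "substitution") {
      alleles <- strsplit(truth$alleles[i], "/", fixed = TRUE)[[1]]
      expect_equal(alleles[1], ref)         # leftmost allele is the reference base
      expect_false(alleles[2] == ref)
    } else if (cls == "deletion") {
      expect_equal(sub("^del", "", truth$alleles[i]), ref)
    }
  }

  all_subs <- plant_snps(genome, fixture_spec(genome_length = 10000, n_snps = 80,
                                              indel_fraction = 0, seed = 4))$truth
  expect_true(all(all_subs$variant_class == "substitution"))

  expect_error(plant_snps(genome, fixture_spec(genome_length = 10000, n_snps = 1100,
                                               seed = 4)),
               class = "usnp_fixture_error")
})

test_that("the snapshot covers about the configured fraction of variants per namespace", {
  spec <- fixture_spec(genome_length = 40000, n_snps = 400, xref_fraction = 0.5,
                       seed = 6)
  genome <- generate_genome(spec)
  xref <- plant_snps(genome, spec)$xref$records
  # each namespace is an independent Binomial(400, 0.5): allow 5 sigma (+/-50)
  for (col in c("rs", "jsnp", "hapmap", "gwas")) {
    expect_lt(abs(sum(!is.na(xref[[col]])) - 200), 50)
  }
})

test_that("error-free reads match the genome exactly; errored reads at the stated rate", {
  spec <- fixture_spec(genome_length = 30000, n_snps = 200, indel_fraction = 0,
                       seed = 8)
  genome <- generate_genome(spec)
  truth <- plant_snps(genome, spec)$truth
  clean <- emit_flanking_reads(genome, truth, 76, error_rate = 0, seed = 9)
  n_mismatch <- function(rec, row) {
    plus <- rec
    # reads are emitted from either strand; compare in plus orientation
    a <- localization_mismatches(genome, plus, row)
    b <- localization_mismatches(genome, rc_flanking(plus), row)
    min(a, b)
  }
  localization_mismatches <- function(genome, rec, row) {
    five_ref <- substr(genome[[row$chrom]], row$locus - nchar(rec$five_prime), row$locus - 1L)
    three_ref <- substr(genome[[row$chrom]], row$locus + 1L,
                        row$locus + nchar(rec$three_prime))
    sum(strsplit(paste0(rec$five_prime, rec$three_prime), "")[[1]] !=
        strsplit(paste0(five_ref, three_ref), "")[[1]])
  }
  total_clean <- sum(vapply(seq_along(clean), function(i) {
    n_mismatch(clean[[i]], truth[i, ])
  }, numeric(1)))
  expect_equal(total_clean, 0)

  noisy <- emit_flanking_reads(genome, truth, 76, error_rate = 0.01, seed = 10)
  total_noisy <- sum(vapply(seq_along(noisy), function(i) {
    n_mismatch(noisy[[i]], truth[i, ])
  }, numeric(1)))
  # 200 reads x 75 flank bases x 0.01 = 150 expected errors; allow 5 sigma
  expect_lt(abs(total_noisy - 150), 5 * sqrt(150))
  expect_gt(total_noisy, 0)
})

test_that("the full pipeline recovers the truth table exactly on error-free reads", {
  spec <- fixture_spec(genome_length = 15000, n_snps = 120, indel_fraction = 0.2,
                       seed = 12)
  genome <- generate_genome(spec)
  planted <- plant_snps(genome, spec)
  idx <- build_index(genome)
  for (L in c(35L, 128L)) {
    reads <- emit_flanking_reads(genome, planted$truth, L, error_rate = 0,
                                 seed = 13L + L)
    expect_true(all(!vapply(reads, `[[`, logical(1), "truncated")))
    res <- align_batch(idx, reads, store = planted$xref)
    expect_equal(res$usnp_id, planted$truth$usnp_id,
                 info = sprintf("read length %d", L))
    # and mapping the recovered names against the snapshot is consistent
    for (i in head(which(!is.na(planted$xref$records$rs)), 5L)) {
      rs <- planted$xref$records$rs[i]
      expect_equal(map_name(planted$xref, rs)$status, "ok")
    }
  }
})

test_that("fixture file sets are byte-identical across reruns with the same seed", {
  spec <- fixture_spec(genome_length = 5000, n_snps = 30, read_lengths = c(35L, 76L),
                       seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(spec, d1)
  write_fixtures(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  write_fixtures(fixture_spec(genome_length = 5000, n_snps = 30,
                              read_lengths = c(35L, 76L), seed = 15), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("the duplicated-segment knob produces genuinely ambiguous reads", {
  spec <- fixture_spec(genome_length = 20000, n_snps = 50,
                       duplicate_segment_length = 400, seed = 16)
  genome <- generate_genome(spec)
  seg <- attr(genome, "duplicated_segment")
  expect_false(is.null(seg))
  expect_equal(substr(genome[[1]], seg["from"], seg["from"] + seg["length"] - 1L),
               substr(genome[[1]], seg["to"], seg["to"] + seg["length"] - 1L))
  idx <- build_index(genome)
  mid <- seg[["from"]] + 200L
  ref <- substr(genome[[1]], mid, mid)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rec <- flanking_record("dup", substr(genome[[1]], mid - 37L, mid - 1L),
                         substr(genome[[1]], mid + 1L, mid + 38L),
                         "substitution", c(ref, alt))
  expect_equal(localize_variant(idx, rec)$status, "ambiguous")
})
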