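# Independent brute-force alignment oracle: exhaustive Hamming scan over
# every offset of every chromosome, both strands, on plain character
# vectors. Kept free of the package's integer encoding and seeding logic so
# it can stand as a reference for align_read. N matches nothing.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_mismatch_profile <- function(genome_chars, query_chars, free = integer(0)) {
  L <- length(query_chars)
  n_off <- length(genome_chars) - L + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (i in seq_len(L)) {
    if (i %in% free) next
    g <- genome_chars[i:(i + n_off - 1L)]
    mm <- mm + (g != query_chars[i] | g == "N" | query_chars[i] == "N")
  }
  mm
}

# All placements with <= max_mismatch mismatches, sorted the way align_read
# sorts (mismatches, chromosome order, start, + before -).
oracle_align <- function(genome, read, max_mismatch = 3L, free_offsets = integer(0)) {
  genome_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  L <- nchar(read)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else oracle_revcomp(read)
    free <- if (strand == "+") free_offsets else L + 1L - free_offsets
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    for (cn in names(genome)) {
      mm <- oracle_mismatch_profile(genome_chars[[cn]], qc, free)
      ok <- which(mm <= max_mismatch)
      if (length(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, start = ok, strand = strand, mismatches = mm[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mismatches, match(out$chrom, names(genome)), out$start,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random genome for tests that do not need the fixture module itself.
random_genome <- function(lengths, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- as.character(seq_along(lengths))
    seqs
  })
}

random_valid_usnp <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cls <- sample(c("substitution", "insertion", "deletion"), 1L,
                    prob = c(0.7, 0.15, 0.15))
      alleles <- if (cls == "substitution") {
        sample(c("A", "C", "G", "T", "N"), sample(2:4, 1L))
      } else {
        sample(c("A", "C", "G", "T", "N"), 1L)
      }
      usnp_name(sample(c(18L, 19L, 38L), 1L),
                sample(c(as.character(1:22), "X", "Y"), 1L),
                sample.int(250000000L, 1L), cls, alleles)
    })
  })
}

# Corrupt n_mut distinct positions of a read (never the positions in
# `protect`) to a different base.
mutate_read <- function(read, n_mut, protect = integer(0)) {
  if (n_mut == 0L) return(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  idx <- sample(setdiff(seq_along(chars), protect), n_mut)
  for (j in idx) chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
  paste(chars, collapse = "")
}
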