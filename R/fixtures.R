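# Synthetic study material: a random reference genome, planted SNPs with a
# truth table, a cross-reference snapshot covering a configurable subset of
# the planted variants, and simulated flanking reads with a uniform per-base
# substitution error. These stand in for a real reference genome, database
# dumps and read simulation; everything is reproducible from the seed.

fixture_stop <- function(message, field = NULL) {
  stop(errorCondition(message, field = field,
                      class = c("usnp_fixture_error", "usnp_error")))
}

#' Specification of a synthetic fixture set
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: a 50 kb single-chromosome genome with 500 planted variants, the
#' four read lengths 35/76/128/512, a 1% uniform flank substitution error,
#' a 10% indel fraction and a 70% chance that a planted variant carries any
#' given database identifier in the snapshot (so roughly a third of
#' identifier fields exercise the `"none"` rendering).
#'
#' @param genome_length Length of each chromosome (recycled to
#'   `n_chromosomes`).
#' @param n_chromosomes Number of chromosomes (named `1`, `2`, ...).
#' @param n_snps Number of planted variants (at most genome length / 10).
#' @param read_lengths Flanking-read lengths to simulate.
#' @param substitution_error_rate Per-base probability of a flank
#'   sequencing error, in `[0, 1)`.
#' @param indel_fraction Fraction of planted variants that are single-base
#'   indels (split evenly between insertions and deletions).
#' @param xref_fraction Per-namespace probability that a planted variant is
#'   recorded in the snapshot.
#' @param duplicate_segment_length If positive, a segment of this length is
#'   copied to a second location of chromosome 1, creating genuinely
#'   ambiguous placements to exercise the `ambiguous` flag.
#' @param seed Integer seed; every fixture output is a pure function of the
#'   spec including this seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 50000L, n_chromosomes = 1L,
                         n_snps = 500L, read_lengths = c(35L, 76L, 128L, 512L),
                         substitution_error_rate = 0.01, indel_fraction = 0.1,
                         xref_fraction = 0.7, duplicate_segment_length = 0L,
                         seed = 1L) {
  spec <- list(
    genome_length = rep_len(as.integer(genome_length), as.integer(n_chromosomes)),
    n_chromosomes = as.integer(n_chromosomes),
    n_snps = as.integer(n_snps),
    read_lengths = as.integer(read_lengths),
    substitution_error_rate = substitution_error_rate,
    indel_fraction = indel_fraction,
    xref_fraction = xref_fraction,
    duplicate_segment_length = as.integer(duplicate_segment_length),
    seed = as.integer(seed))
  if (any(spec$genome_length < 1L) || spec$n_chromosomes < 1L || spec$n_snps < 1L) {
    fixture_stop("all counts must be positive")
  }
  if (spec$n_chromosomes > 22L) fixture_stop("at most 22 numbered chromosomes")
  if (spec$substitution_error_rate < 0 || spec$substitution_error_rate >= 1) {
    fixture_stop("substitution_error_rate must be in [0, 1)")
  }
  if (spec$indel_fraction < 0 || spec$indel_fraction > 1) {
    fixture_stop("indel_fraction must be in [0, 1]")
  }
  if (any(spec$read_lengths < 20L)) fixture_stop("read lengths must be >= 20")
  if (is.na(spec$seed)) fixture_stop("seed must be an integer")
  structure(spec, class = "fixture_spec")
}

#' Generate a random reference genome
#'
#' Uniform i.i.d. A/C/G/T sequences (no repeat structure, GC = 0.5 in
#' expectation), one per chromosome, deterministic under the spec's seed.
#' With `duplicate_segment_length > 0` a segment of chromosome 1 is copied
#' to a distant location to create multi-hit reads.
#'
#' @param spec A [fixture_spec()].
#' @return Named character vector of chromosome sequences (`"1"`, `"2"`, ...).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_chromosomes), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$genome_length[i], replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- as.character(seq_len(spec$n_chromosomes))
    d <- spec$duplicate_segment_length
    if (d > 0L) {
      len1 <- spec$genome_length[1]
      if (len1 < 4L * d) fixture_stop("chromosome 1 too short for segment duplication")
      from <- sample.int(len1 %/% 4L, 1L)
      to <- len1 %/% 2L + sample.int(len1 %/% 4L, 1L)
      segment <- substr(seqs[[1]], from, from + d - 1L)
      substr(seqs[[1]], to, to + d - 1L) <- segment
      attr(seqs, "duplicated_segment") <- c(from = from, to = to, length = d)
    }
    seqs
  })
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @param width Line wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Plant variants on a genome
#'
#' Chooses distinct loci (kept clear of the contig ends so that reads at
#' the longest configured length need no truncation), assigns each a
#' variant: a substitution to a random non-reference base, or -- for the
#' configured indel fraction -- a single-base insertion or deletion. Also
#' fabricates the cross-reference snapshot: each variant gets a numeric
#' identity, and each of the four identifier namespaces records it
#' independently with probability `xref_fraction` (dbSNP-style `rs<k>`,
#' JSNP-style `IMS-JST<k>`, HapMap listing the rs identifier, GWAS-style
#' `HGVM<k>`). A variant recorded by no namespace is absent from the
#' snapshot entirely, as a genuinely novel SNP would be.
#'
#' @param genome Named character vector from [generate_genome()].
#' @param spec The [fixture_spec()].
#' @return A list with `truth` (data.frame: `id, chrom, locus,
#'   variant_class, alleles, usnp_id`) and `xref` (an `xref_store`).
#' @export
plant_snps <- function(genome, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  total <- sum(nchar(genome))
  if (spec$n_snps > total %/% 10L) {
    fixture_stop(sprintf("too dense: %d variants on a %d bp genome (max 1 per 10 bp)",
                         spec$n_snps, total))
  }
  margin <- max(spec$read_lengths) %/% 2L + 2L
  withr::with_seed(spec$seed + 1L, {
    lens <- nchar(genome)
    usable <- pmax(0L, lens - 2L * margin)
    if (sum(usable) < spec$n_snps) fixture_stop("genome too short for the margins required")
    n_per <- as.integer(round(spec$n_snps * usable / sum(usable)))
    n_per[length(n_per)] <- spec$n_snps - sum(n_per[-length(n_per)])
    rows <- list()
    for (ci in seq_along(genome)) {
      if (n_per[ci] <= 0L) next
      loci <- sort(sample(seq.int(margin + 1L, lens[ci] - margin), n_per[ci]))
      rows[[ci]] <- data.frame(chrom = names(genome)[ci], locus = loci,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    n <- nrow(truth)
    is_indel <- runif(n) < spec$indel_fraction
    cls <- ifelse(is_indel, sample(c("insertion", "deletion"), n, replace = TRUE),
                  "substitution")
    bases <- c("A", "C", "G", "T")
    ref <- substring(genome[truth$chrom], truth$locus, truth$locus)
    allele_txt <- character(n)
    for (i in seq_len(n)) {
      allele_txt[i] <- switch(cls[i],
        substitution = paste(ref[i], sample(setdiff(bases, ref[i]), 1L), sep = "/"),
        insertion    = paste0("ins", sample(bases, 1L)),
        deletion     = paste0("del", ref[i]))
    }
    truth$variant_class <- cls
    truth$alleles <- allele_txt
    truth$id <- sprintf("var%05d", seq_len(n))
    truth$usnp_id <- sprintf("HG19.%s:%d:%s", truth$chrom, truth$locus, truth$alleles)
    truth <- truth[, c("id", "chrom", "locus", "variant_class", "alleles", "usnp_id")]

    id_num <- 100000L + sample.int(899999L, n)
    has <- matrix(runif(4L * n) < spec$xref_fraction, nrow = n)
    colnames(has) <- XREF_ID_COLUMNS
    xref <- data.frame(
      chrom = truth$chrom, pos = truth$locus, alleles = truth$alleles,
      rs     = ifelse(has[, "rs"],     sprintf("rs%d", id_num), NA_character_),
      jsnp   = ifelse(has[, "jsnp"],   sprintf("IMS-JST%d", id_num), NA_character_),
      hapmap = ifelse(has[, "hapmap"], sprintf("rs%d", id_num), NA_character_),
      gwas   = ifelse(has[, "gwas"],   sprintf("HGVM%d", id_num), NA_character_),
      stringsAsFactors = FALSE)
    xref <- xref[rowSums(has) > 0L, , drop = FALSE]
    rownames(xref) <- NULL
    list(truth = truth, xref = new_xref_store(xref))
  })
}

#' Simulate flanking reads for planted variants
#'
#' Emits one bracket-marked flanking record per truth row: a window of
#' `read_length` reference bases centered on the variant with the site
#' written as an allele bracket (substitutions list the reference allele
#' first). Flank bases (never the bracket) are corrupted independently at
#' `error_rate` to a uniformly random different base, and each read is
#' emitted from a uniformly random strand, reverse-complemented accordingly.
#' A variant closer to a contig end than half the read length yields a
#' truncated, flagged read.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param truth Truth table from [plant_snps()].
#' @param read_length Total query length (flanks plus the one marked base
#'   for substitutions/deletions).
#' @param error_rate Per-base flank substitution error probability.
#' @param seed Integer seed.
#' @return List of [flanking_record()] objects (field `truncated` flags
#'   reads cut short at a contig end).
#' @export
emit_flanking_reads <- function(genome, truth, read_length, error_rate = 0,
                                seed = 1L) {
  read_length <- as.integer(read_length)
  if (read_length < 20L) fixture_stop("read_length must be >= 20")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nrow(truth)), function(i) {
      row <- truth[i, ]
      chrom_seq <- genome[[row$chrom]]
      len <- nchar(chrom_seq)
      allele <- parse_allele_field(row$alleles)
      if (allele$variant_class == "insertion") {
        f_len <- read_length %/% 2L
        t_len <- read_length - f_len
        from5 <- row$locus - f_len; to5 <- row$locus - 1L
        from3 <- row$locus; to3 <- row$locus + t_len - 1L
      } else {
        f_len <- (read_length - 1L) %/% 2L
        t_len <- read_length - 1L - f_len
        from5 <- row$locus - f_len; to5 <- row$locus - 1L
        from3 <- row$locus + 1L; to3 <- row$locus + t_len
      }
      truncated <- from5 < 1L || to3 > len
      five <- substr(chrom_seq, max(1L, from5), to5)
      three <- substr(chrom_seq, from3, min(len, to3))
      if (error_rate > 0) {
        five <- corrupt_bases(five, error_rate, bases)
        three <- corrupt_bases(three, error_rate, bases)
      }
      rec <- flanking_record(
        query_id = sprintf("%s_L%d", row$id, read_length),
        five_prime = five, three_prime = three,
        variant_class = allele$variant_class, alleles = allele$alleles,
        truncated = truncated)
      if (runif(1) < 0.5) rc_flanking(rec) else rec
    })
  })
}

corrupt_bases <- function(seq, rate, bases) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < rate)
  for (j in hit) chars[j] <- sample(setdiff(bases, chars[j]), 1L)
  paste(chars, collapse = "")
}

#' Write a complete fixture set to a directory
#'
#' Materializes the four fixture artifacts: `genome.fa` (reference FASTA),
#' `truth.tsv` (planted-variant truth table), `xref.tsv` (cross-reference
#' snapshot) and one `reads_L<length>.fa` bracket-FASTA per configured read
#' length.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(spec)
  planted <- plant_snps(genome, spec)
  paths <- list(genome = file.path(dir, "genome.fa"),
                truth = file.path(dir, "truth.tsv"),
                xref = file.path(dir, "xref.tsv"))
  write_genome_fasta(genome, paths$genome)
  write.table(planted$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_xref(planted$xref, paths$xref)
  for (L in spec$read_lengths) {
    reads <- emit_flanking_reads(genome, planted$truth, L,
                                 error_rate = spec$substitution_error_rate,
                                 seed = spec$seed + 2L + L)
    p <- file.path(dir, sprintf("reads_L%d.fa", L))
    write_flanking(reads, p)
    paths[[sprintf("reads_L%d", L)]] <- p
  }
  invisible(paths)
}
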