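# Flanking-sequence IO. A query read carries the bases surrounding a variant
# site plus a marker for the site itself. The on-disk marker is the
# bracket-allele dialect used by dbSNP's rs_fasta dumps:
#   ACGT[G/A]TTCA   substitution, observed alleles G and A
#   ACGT[-/T]TTCA   insertion of T between the flanks
#   ACGT[T/-]TTCA   deletion of the T between the flanks
# FASTQ cannot carry in-sequence markers, so FASTQ records are plain reads
# unless the description line carries `variant_at=<k>;alleles=<X/Y>`.

ALLOWED_EXTENSIONS <- c("fa", "fas", "fast", "fasta", "fq", "fastq")
FASTQ_EXTENSIONS <- c("fq", "fastq")

flank_stop <- function(message, class = "usnp_format_error", field = NULL) {
  stop(errorCondition(message, field = field,
                      class = c(class, "usnp_io_error", "usnp_error")))
}

#' Construct a flanking-sequence record
#'
#' @param query_id Read identifier.
#' @param five_prime,three_prime Flank sequences (A/C/G/T/N; at least one
#'   non-empty; combined length at most 1024, the supported query cap).
#' @param variant_class `"substitution"`, `"insertion"`, `"deletion"`, or
#'   `NA` for a plain read with no marked site (alignable, but not
#'   localizable).
#' @param alleles Observed alleles at the site: 2-4 distinct bases for a
#'   substitution, one base for an indel, `NULL` for a plain read.
#' @param quality Optional per-base quality string, carried opaquely.
#' @param truncated Whether a flank was cut short at a contig end.
#' @return An object of class `flanking_record`.
#' @export
flanking_record <- function(query_id, five_prime, three_prime,
                            variant_class = NA_character_, alleles = NULL,
                            quality = NA_character_, truncated = FALSE) {
  five_prime <- toupper(five_prime)
  three_prime <- toupper(three_prime)
  if (grepl("[^ACGTN]", five_prime) || grepl("[^ACGTN]", three_prime)) {
    flank_stop(sprintf("record '%s': flanks may contain only A/C/G/T/N", query_id))
  }
  if (!nzchar(five_prime) && !nzchar(three_prime)) {
    flank_stop(sprintf("record '%s': both flanks are empty", query_id))
  }
  if (nchar(five_prime) + nchar(three_prime) > 1024L) {
    flank_stop(sprintf("record '%s': combined flank length exceeds 1024", query_id),
               class = "usnp_length_error")
  }
  if (!is.na(variant_class)) {
    if (!variant_class %in% VARIANT_CLASSES) {
      flank_stop(sprintf("record '%s': unknown variant class '%s'", query_id, variant_class))
    }
    alleles <- toupper(as.character(alleles))
    if (!all(alleles %in% VALID_NUCLEOTIDES)) {
      flank_stop(sprintf("record '%s': illegal allele character", query_id))
    }
    if (variant_class == "substitution" &&
        (length(alleles) < 2L || length(alleles) > 4L || anyDuplicated(alleles))) {
      flank_stop(sprintf("record '%s': substitution needs 2-4 distinct alleles", query_id))
    }
    if (variant_class != "substitution" && length(alleles) != 1L) {
      flank_stop(sprintf("record '%s': %s carries exactly one allele",
                         query_id, variant_class))
    }
  } else {
    alleles <- NULL
  }
  structure(
    list(query_id = as.character(query_id), five_prime = five_prime,
         three_prime = three_prime, variant_class = variant_class,
         alleles = alleles, quality = quality, truncated = isTRUE(truncated)),
    class = "flanking_record")
}

#' @export
print.flanking_record <- function(x, ...) {
  cat(sprintf("<flanking_record> %s: %s%s%s\n", x$query_id, x$five_prime,
              if (is.na(x$variant_class)) "" else bracket_token(x),
              x$three_prime))
  invisible(x)
}

bracket_token <- function(rec) {
  switch(rec$variant_class,
    substitution = sprintf("[%s]", paste(rec$alleles, collapse = "/")),
    insertion    = sprintf("[-/%s]", rec$alleles),
    deletion     = sprintf("[%s/-]", rec$alleles)
  )
}

# Reverse-complement a flanking record: flanks swap and reverse-complement,
# alleles complement in place. Localization must be invariant under this.
#' Reverse-complement a flanking record
#'
#' Swaps and reverse-complements the flanks and complements the marked
#' alleles, i.e. the same physical variant read from the opposite strand.
#' [localize_variant()] is invariant under this transformation.
#'
#' @param rec A `flanking_record`.
#' @return The reverse-complemented `flanking_record`.
#' @export
rc_flanking <- function(rec) {
  stopifnot(inherits(rec, "flanking_record"))
  flanking_record(
    query_id = rec$query_id,
    five_prime = revcomp(rec$three_prime),
    three_prime = revcomp(rec$five_prime),
    variant_class = rec$variant_class,
    alleles = if (is.null(rec$alleles)) NULL else
      chartr("ACGTN", "TGCAN", rec$alleles),
    quality = rec$quality,
    truncated = rec$truncated)
}

parse_bracket_group <- function(txt, query_id) {
  tokens <- strsplit(txt, "/", fixed = TRUE)[[1]]
  tokens <- toupper(tokens)
  if (length(tokens) == 2L && tokens[1] == "-" && tokens[2] != "-") {
    return(list(variant_class = "insertion", alleles = tokens[2]))
  }
  if (length(tokens) == 2L && tokens[2] == "-" && tokens[1] != "-") {
    return(list(variant_class = "deletion", alleles = tokens[1]))
  }
  if (any(tokens == "-") || length(tokens) < 2L || length(tokens) > 4L ||
      any(nchar(tokens) != 1L) || !all(tokens %in% VALID_NUCLEOTIDES) ||
      anyDuplicated(tokens)) {
    flank_stop(sprintf("record '%s': malformed allele bracket [%s]", query_id, txt))
  }
  list(variant_class = "substitution", alleles = tokens)
}

check_batch_file <- function(path, max_bytes) {
  if (!file.exists(path)) flank_stop(sprintf("file not found: %s", path),
                                     class = "usnp_io_error")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% ALLOWED_EXTENSIONS) {
    flank_stop(
      sprintf("only files with extensions %s are allowed (got '%s')",
              paste(ALLOWED_EXTENSIONS, collapse = ", "), basename(path)),
      class = "usnp_extension_error")
  }
  if (!is.null(max_bytes) && file.size(path) > max_bytes) {
    flank_stop(sprintf("input exceeds the maximum upload size of %d bytes", max_bytes),
               class = "usnp_batch_size_error")
  }
  ext
}

#' Read flanking sequences
#'
#' Reads a batch of query reads from FASTA (including the bracket-allele
#' dialect above) or FASTQ. Each sequence may carry at most one variant
#' marker; a sequence with none is a plain read, accepted for raw alignment
#' but not for localization. Extension and batch-size gates are applied
#' before parsing: only `fa, fas, fast, fasta, fq, fastq` files are accepted
#' and the default batch cap is 5 MB.
#'
#' @param path Input file.
#' @param format `"auto"` (from extension), `"fasta"` or `"fastq"`.
#' @param max_bytes Batch size cap in bytes (default 5 MB); `NULL` disables.
#' @return A list of [flanking_record()] objects.
#' @export
read_flanking <- function(path, format = c("auto", "fasta", "fastq"),
                          max_bytes = 5L * 1024L^2) {
  format <- match.arg(format)
  ext <- check_batch_file(path, max_bytes)
  if (format == "auto") {
    format <- if (ext %in% FASTQ_EXTENSIONS) "fastq" else "fasta"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") parse_bracket_fasta(lines) else parse_marked_fastq(lines)
}

parse_bracket_fasta <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    flank_stop("not a FASTA file: first line must start with '>'")
  }
  header_idx <- which(startsWith(lines, ">"))
  bounds <- c(header_idx, length(lines) + 1L)
  records <- vector("list", length(header_idx))
  for (i in seq_along(header_idx)) {
    id <- sub("^>\\s*", "", lines[header_idx[i]])
    id <- strsplit(id, "[ \t]")[[1]][1]
    from <- header_idx[i] + 1L
    to <- bounds[i + 1L] - 1L
    seq <- if (from > to) "" else paste(lines[from:to], collapse = "")
    seq <- gsub("[ \t]", "", seq)
    records[[i]] <- flanking_from_sequence(id, seq)
  }
  records
}

flanking_from_sequence <- function(id, seq) {
  m <- gregexpr("\\[[^][]*\\]", seq)[[1]]
  n_groups <- if (m[1] == -1L) 0L else length(m)
  if (n_groups == 0L) {
    if (grepl("[][]", seq)) flank_stop(sprintf("record '%s': unbalanced bracket", id))
    return(flanking_record(id, seq, ""))
  }
  if (n_groups > 1L) {
    flank_stop(sprintf("record '%s': more than one allele bracket", id))
  }
  start <- m[1]
  len <- attr(m, "match.length")[1]
  group <- substr(seq, start + 1L, start + len - 2L)
  five <- substr(seq, 1L, start - 1L)
  three <- substr(seq, start + len, nchar(seq))
  if (grepl("[][]", paste0(five, three))) {
    flank_stop(sprintf("record '%s': stray bracket outside allele group", id))
  }
  spec <- parse_bracket_group(group, id)
  flanking_record(id, five, three, spec$variant_class, spec$alleles)
}

parse_marked_fastq <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 4L != 0L || !all(startsWith(lines[seq(1, length(lines), 4)], "@"))) {
    flank_stop("not a FASTQ file: expected 4-line records starting with '@'")
  }
  n <- length(lines) %/% 4L
  records <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- sub("^@", "", lines[4L * i - 3L])
    seq <- toupper(gsub("[ \t]", "", lines[4L * i - 2L]))
    qual <- lines[4L * i]
    id <- strsplit(hdr, "[ \t]")[[1]][1]
    desc <- sub("^\\S+\\s*", "", hdr)
    ann <- regmatches(desc,
      regexec("variant_at=([0-9]+);alleles=([ACGTNacgtn](?:/[ACGTNacgtn]){1,3})", desc))[[1]]
    if (length(ann) == 3L) {
      k <- as.integer(ann[2])
      if (k < 1L || k > nchar(seq)) {
        flank_stop(sprintf("record '%s': variant_at=%d outside the read", id, k))
      }
      alleles <- toupper(strsplit(ann[3], "/", fixed = TRUE)[[1]])
      records[[i]] <- flanking_record(
        id, substr(seq, 1L, k - 1L), substr(seq, k + 1L, nchar(seq)),
        "substitution", alleles, quality = qual)
    } else {
      records[[i]] <- flanking_record(id, seq, "", quality = qual)
    }
  }
  records
}

#' Write flanking records in the bracket-FASTA dialect
#'
#' Inverse of [read_flanking()] for FASTA input: every record re-serializes
#' to an equivalent bracket-FASTA entry (plain reads serialize without a
#' bracket).
#'
#' @param records List of `flanking_record` objects.
#' @param path Output path (use an allowed extension if the file is to be
#'   read back).
#' @export
write_flanking <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    body <- if (is.na(r$variant_class)) {
      paste0(r$five_prime, r$three_prime)
    } else {
      paste0(r$five_prime, bracket_token(r), r$three_prime)
    }
    c(paste0(">", r$query_id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- SAM export ------------------------------------------------------------

#' Write alignments as SAM
#'
#' Emits a minimal, standard-conformant SAM v1 file: `@HD`/`@SQ` headers,
#' one line per alignment with FLAG 16 for minus-strand hits (SEQ emitted
#' reverse-complemented, per SAM convention), `NM:i:` mismatch-count tags,
#' full-length match CIGAR (the aligner is gapless), and FLAG 4 records for
#' unaligned reads.
#'
#' @param hits A data.frame with columns `query_id`, `chrom`, `start`,
#'   `strand`, `mismatches`, `seq` (the aligned query, plus-strand
#'   orientation of the read as submitted). Unaligned reads have `NA`
#'   `chrom`.
#' @param reference_lengths Named integer vector: chromosome name -> length.
#' @param path Output path.
#' @export
write_sam <- function(hits, reference_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(reference_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(reference_lengths[[nm]])), con)
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (is.na(h$chrom)) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", h$query_id, h$seq), con)
      next
    }
    flag <- if (h$strand == "-") 16L else 0L
    seq <- if (h$strand == "-") revcomp(h$seq) else h$seq
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       h$query_id, flag, h$chrom, as.integer(h$start),
                       nchar(seq), seq, as.integer(h$mismatches)), con)
  }
  invisible(path)
}
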