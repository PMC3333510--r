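# Gapless, mismatch-tolerant placement of flanking sequences on a reference
# genome, and projection of the marked variant site to a genomic coordinate.
#
# The aligner is seed-and-extend over a k-mer hash of the reference. For a
# query of length L aligned under a raw mismatch budget b, (b+1) disjoint
# k-mer seeds are taken from the query; by pigeonhole at least one seed is
# exact in any placement with <= b mismatches, so the candidate set is
# complete whenever L >= (b+1)*k. Shorter queries fall back to an exhaustive
# scan of every offset on both strands. Alignment is strictly gapless
# (Hamming distance); indel *variants* are handled by how the query is
# constructed, not by gapped dynamic programming.
#
# N never matches anything -- an N in the query or the reference always
# counts as a mismatch. The marked variant site of a substitution query is
# written as N and its position is excluded from the reported mismatch
# count, so a clean substitution read aligns with 0 counted mismatches.

align_stop <- function(message, class = "usnp_alignment_error", field = NULL) {
  stop(errorCondition(message, field = field, class = c(class, "usnp_error")))
}

encode_ref <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L   # reference N: matches nothing
  codes
}

encode_query <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L   # query N: matches nothing, not even reference N
  codes
}

#' Build a k-mer index over a reference genome
#'
#' Indexes every exact k-mer occurrence (k-mers containing N are skipped) of
#' each chromosome. Only the forward strand is indexed; minus-strand queries
#' are handled at query time by reverse-complementing the query. Chromosome
#' names are taken from the FASTA headers after stripping an optional `chr`
#' prefix and any description.
#'
#' @param reference A FASTA path, a named character vector of sequences, or
#'   a [Biostrings::DNAStringSet].
#' @param k Seed length (default 12, minimum 4). The default guarantees a
#'   complete candidate set for reads of at least 48 bases at the default
#'   3-mismatch budget; shorter reads are scanned exhaustively.
#' @return An object of class `ref_index`.
#' @export
build_index <- function(reference, k = 12L) {
  k <- as.integer(k)
  if (is.na(k) || k < 4L) align_stop("seed length k must be >= 4", field = "k")
  if (is.character(reference) && length(reference) == 1L && file.exists(reference) &&
      is.null(names(reference))) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference) && !is.null(names(reference))) {
    seqs <- reference
  } else {
    align_stop("reference must be a FASTA path, a named character vector or a DNAStringSet")
  }
  if (!length(seqs)) align_stop("reference contains no sequences")
  names(seqs) <- sub("^[Cc][Hh][Rr]", "", vapply(strsplit(names(seqs), "[ \t]"),
                                                 `[[`, character(1), 1L))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    align_stop("reference contains non-nucleotide characters (only A/C/G/T/N allowed)")
  }
  chroms <- lapply(seqs, function(s) {
    n <- nchar(s)
    kmap <- new.env(hash = TRUE, parent = emptyenv())
    if (n >= k) {
      starts <- seq_len(n - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("N", kmers, fixed = TRUE)
      if (any(ok)) {
        kmap <- list2env(split(starts[ok], kmers[ok]), hash = TRUE)
      }
    }
    list(seq = s, code = encode_ref(s), length = n, kmap = kmap)
  })
  structure(list(k = k, chromosomes = chroms, names = names(seqs)),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  lens <- vapply(x$chromosomes, `[[`, integer(1), "length")
  cat(sprintf("<ref_index> k=%d, %d chromosome(s), %s bp total\n",
              x$k, length(lens), format(sum(lens), big.mark = ",")))
  invisible(x)
}

#' @export
#' @rdname build_index
reference_lengths <- function(index) {
  stopifnot(inherits(index, "ref_index"))
  vapply(index$chromosomes, `[[`, integer(1), "length")
}

# Mismatch counts for a query placed at every offset of one chromosome
# (exhaustive scan). Vectorized over offsets: one pass per query position.
hamming_profile <- function(code_ref, code_q, free_idx = integer(0)) {
  L <- length(code_q)
  n_off <- length(code_ref) - L + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (i in seq_len(L)) {
    if (i %in% free_idx) next
    mm <- mm + (code_ref[i:(i + n_off - 1L)] != code_q[i])
  }
  mm
}

mismatches_at <- function(code_ref, code_q, start, keep_idx) {
  sum(code_q[keep_idx] != code_ref[start + keep_idx - 1L])
}

# Disjoint seed start offsets: one per of n roughly equal query segments.
seed_starts <- function(L, k, n_seeds) {
  1L + as.integer(floor((seq_len(n_seeds) - 1L) * L / n_seeds))
}

#' Align a read against the reference index
#'
#' Places the read on both strands, gaplessly, reporting up to `max_hits`
#' placements with at most `max_mismatch` mismatches, sorted by ascending
#' mismatch count with deterministic tie-breaking (chromosome order in the
#' index, then leftmost start, then `+` strand before `-`). An empty result
#' is the "Not Aligned" outcome.
#'
#' @param index A `ref_index`.
#' @param read Query sequence (A/C/G/T/N, length 4-1024).
#' @param max_mismatch Maximum mismatches per reported hit (default 3).
#' @param max_hits Maximum number of hits reported (default 2). `Inf`
#'   reports every qualifying placement.
#' @param chromosomes Optional character vector restricting the search.
#' @param free_offsets 1-based query positions excluded from the mismatch
#'   count (used by [localize_variant()] for the marked variant site, which
#'   must not consume mismatch budget).
#' @param query_id Identifier attached to the hits.
#' @return A data.frame with columns `query_id`, `chrom`, `start` (1-based
#'   leftmost reference position), `strand`, `mismatches`; zero rows when
#'   the read does not place anywhere within the budget.
#' @export
align_read <- function(index, read, max_mismatch = 3L, max_hits = 2L,
                       chromosomes = NULL, free_offsets = integer(0),
                       query_id = "query") {
  stopifnot(inherits(index, "ref_index"))
  read <- toupper(read)
  L <- nchar(read)
  if (L < 4L || L > 1024L) {
    align_stop(sprintf("read length must be between 4 and 1024 (got %d)", L),
               class = "usnp_length_error", field = "read")
  }
  if (grepl("[^ACGTN]", read)) {
    align_stop("read contains non-nucleotide characters", field = "read")
  }
  max_mismatch <- as.integer(max_mismatch)
  chrom_names <- index$names
  if (!is.null(chromosomes)) {
    chromosomes <- sub("^[Cc][Hh][Rr]", "", toupper(as.character(chromosomes)))
    chrom_names <- chrom_names[chrom_names %in% chromosomes]
  }
  raw_budget <- max_mismatch + length(free_offsets)
  k <- index$k
  n_seeds <- raw_budget + 1L
  seeded <- L >= n_seeds * k

  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    free <- if (strand == "+") free_offsets else L + 1L - free_offsets
    code_q <- encode_query(q)
    keep_idx <- setdiff(seq_len(L), free)
    for (cn in chrom_names) {
      chr <- index$chromosomes[[cn]]
      if (chr$length < L) next
      if (seeded) {
        starts <- integer(0)
        for (s in seed_starts(L, k, n_seeds)) {
          kmer <- substr(q, s, s + k - 1L)
          if (grepl("N", kmer, fixed = TRUE)) next
          hits <- chr$kmap[[kmer]]
          if (!is.null(hits)) starts <- c(starts, hits - s + 1L)
        }
        starts <- unique(starts)
        starts <- starts[starts >= 1L & starts <= chr$length - L + 1L]
        if (!length(starts)) next
        mm <- vapply(starts, function(st) mismatches_at(chr$code, code_q, st, keep_idx),
                     integer(1))
      } else {
        mm <- hamming_profile(chr$code, code_q, free)
        starts <- seq_along(mm)
      }
      ok <- mm <= max_mismatch
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          query_id = query_id, chrom = cn, start = starts[ok], strand = strand,
          mismatches = mm[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  ord <- order(hits$mismatches, match(hits$chrom, index$names), hits$start,
               match(hits$strand, c("+", "-")))
  hits <- hits[ord, , drop = FALSE]
  if (is.finite(max_hits)) hits <- utils::head(hits, as.integer(max_hits))
  rownames(hits) <- NULL
  hits
}

# ---- variant localization --------------------------------------------------

# Build the alignable query for a marked record. The substitution site is
# written as N (excluded from the mismatch count); a deletion query carries
# the deleted base (it is present on the reference); an insertion query is
# the two flanks joined (the inserted base is absent from the reference).
localization_query <- function(rec) {
  f <- nchar(rec$five_prime)
  switch(rec$variant_class,
    substitution = list(query = paste0(rec$five_prime, "N", rec$three_prime),
                        free = f + 1L, f = f),
    deletion     = list(query = paste0(rec$five_prime, rec$alleles, rec$three_prime),
                        free = integer(0), f = f),
    insertion    = list(query = paste0(rec$five_prime, rec$three_prime),
                        free = integer(0), f = f)
  )
}

# Project the marked site of a placed query to a genomic locus, with the
# alleles as observed on the reference (+) strand.
project_variant <- function(rec, hit, qlen) {
  f <- nchar(rec$five_prime)
  if (hit$strand == "+") {
    locus <- hit$start + f
    alleles <- rec$alleles
  } else {
    locus <- if (rec$variant_class == "insertion") {
      hit$start + qlen - f
    } else {
      hit$start + qlen - 1L - f
    }
    alleles <- chartr("ACGTN", "TGCAN", rec$alleles)
  }
  list(locus = as.integer(locus), alleles = alleles)
}

#' Localize a marked variant on the reference genome
#'
#' Aligns a flanking record's query to the reference and projects the marked
#' site to a genomic coordinate, returning the universal name of the
#' variant. For substitutions the reference base at the projected locus is
#' read off the genome and placed leftmost in the allele list (the
#' convention that the leftmost allele is the reference base); if the
#' reference base is not among the observed alleles the name keeps the
#' observed alleles and is flagged `reference_mismatch`. On minus-strand
#' placements the locus is mirrored through the placement and alleles are
#' reverse-complemented, so localization is invariant under
#' [rc_flanking()]. An insertion's locus is the position the inserted base
#' is written at; the displaced reference base sits at locus + 1.
#'
#' @param index A `ref_index`.
#' @param rec A `flanking_record` with a marked variant site.
#' @param max_mismatch,max_hits,chromosomes Passed to [align_read()].
#' @param build Genome build for the resulting name (default 19).
#' @return An object of class `localization`: a list with `status`
#'   (`"ok"`, `"ambiguous"`, or `"not_aligned"`), `query_id`, `name` (a
#'   `usnp_name`, or `NULL` when not aligned), `hit` (the best placement),
#'   `hits` (every reported placement with its projected locus),
#'   `reference_mismatch` (logical) and `query` (the aligned query string).
#' @export
localize_variant <- function(index, rec, max_mismatch = 3L, max_hits = 2L,
                             chromosomes = NULL, build = 19L) {
  stopifnot(inherits(index, "ref_index"), inherits(rec, "flanking_record"))
  if (is.na(rec$variant_class)) {
    align_stop(sprintf("record '%s' has no marked variant site", rec$query_id),
               class = "usnp_no_marker_error")
  }
  lq <- localization_query(rec)
  hits <- align_read(index, lq$query, max_mismatch = max_mismatch,
                     max_hits = max_hits, chromosomes = chromosomes,
                     free_offsets = lq$free, query_id = rec$query_id)
  res <- structure(
    list(status = "not_aligned", query_id = rec$query_id, name = NULL,
         hit = NULL, hits = hits, reference_mismatch = FALSE, query = lq$query),
    class = "localization")
  if (!nrow(hits)) return(res)

  qlen <- nchar(lq$query)
  proj <- lapply(seq_len(nrow(hits)), function(i) project_variant(rec, hits[i, ], qlen))
  hits$locus <- vapply(proj, `[[`, integer(1), "locus")
  best <- hits[1, ]
  res$hits <- hits
  res$hit <- best
  ambiguous <- nrow(hits) >= 2L &&
    any(hits$mismatches[-1L] == best$mismatches &
        (hits$chrom[-1L] != best$chrom | hits$locus[-1L] != best$locus))
  res$status <- if (ambiguous) "ambiguous" else "ok"

  alleles <- proj[[1L]]$alleles
  locus <- best$locus
  chrom_seq <- index$chromosomes[[best$chrom]]$seq
  if (rec$variant_class == "substitution") {
    ref_base <- substr(chrom_seq, locus, locus)
    nm <- usnp_name(build, best$chrom, locus, "substitution", alleles)
    nm <- withCallingHandlers(
      canonicalize_alleles(nm, ref_base),
      usnp_reference_mismatch = function(w) invokeRestart("muffleWarning"))
    res$reference_mismatch <- isTRUE(attr(nm, "reference_mismatch"))
    attr(nm, "reference_mismatch") <- NULL
    res$name <- nm
  } else {
    if (rec$variant_class == "deletion" &&
        substr(chrom_seq, locus, locus) != alleles) {
      res$reference_mismatch <- TRUE
    }
    res$name <- usnp_name(build, best$chrom, locus, rec$variant_class, alleles)
  }
  res
}

#' @export
print.localization <- function(x, ...) {
  if (x$status == "not_aligned") {
    cat(sprintf("%s\tNot Aligned\n", x$query_id))
  } else {
    cat(sprintf("%s\t%s\t%s%s\n", x$query_id, format_usnp(x$name), x$status,
                if (x$reference_mismatch) " (reference/allele disagreement)" else ""))
  }
  invisible(x)
}

#' Localize and cross-reference a batch of flanking records
#'
#' Runs [localize_variant()] on every record and joins the result against a
#' cross-reference snapshot by position. One row per record in the fixed
#' column order `query_id, chrom, position, strand, mismatches, alleles,
#' usnp_id, rs, jsnp, hapmap, gwas`, plus a trailing `status` column
#' (`ok`/`ambiguous`/`Not Aligned`). Missing per-database identifiers render
#' as `"none"`; reads that place nowhere render as `Not Aligned` with `-`
#' in the positional columns.
#'
#' @param index A `ref_index`.
#' @param records List of `flanking_record` objects.
#' @param store Optional `xref_store` for identifier lookup.
#' @param max_mismatch,max_hits,chromosomes Passed to [localize_variant()].
#' @param build Genome build (default 19).
#' @return A data.frame, one row per input record, with attribute
#'   `localizations` holding the full `localization` objects.
#' @export
align_batch <- function(index, records, store = NULL, max_mismatch = 3L,
                        max_hits = 2L, chromosomes = NULL, build = 19L) {
  locs <- lapply(records, function(rec) {
    localize_variant(index, rec, max_mismatch = max_mismatch,
                     max_hits = max_hits, chromosomes = chromosomes,
                     build = build)
  })
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    loc <- locs[[i]]
    allele_txt <- if (is.na(rec$variant_class)) "-" else {
      switch(rec$variant_class,
             substitution = paste(rec$alleles, collapse = "/"),
             insertion = paste0("ins", rec$alleles),
             deletion = paste0("del", rec$alleles))
    }
    if (loc$status == "not_aligned") {
      return(data.frame(
        query_id = rec$query_id, chrom = "-", position = "-", strand = "-",
        mismatches = "-", alleles = allele_txt, usnp_id = "Not Aligned",
        rs = "none", jsnp = "none", hapmap = "none", gwas = "none",
        status = "Not Aligned", stringsAsFactors = FALSE))
    }
    ids <- c(rs = "none", jsnp = "none", hapmap = "none", gwas = "none")
    if (!is.null(store)) {
      recs <- lookup_by_position(store, loc$name$chromosome, loc$name$locus)
      for (col in names(ids)) {
        vals <- recs[[col]][!is.na(recs[[col]])]
        if (length(vals)) ids[[col]] <- paste(unique(vals), collapse = ",")
      }
    }
    data.frame(
      query_id = rec$query_id, chrom = loc$name$chromosome,
      position = as.character(loc$name$locus), strand = loc$hit$strand,
      mismatches = as.character(loc$hit$mismatches), alleles = allele_txt,
      usnp_id = format_usnp(loc$name),
      rs = ids[["rs"]], jsnp = ids[["jsnp"]], hapmap = ids[["hapmap"]],
      gwas = ids[["gwas"]], status = loc$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "localizations") <- locs
  out
}

#' SAM rows for a batch of localizations
#'
#' Converts the localizations produced by [align_batch()] into the hit table
#' [write_sam()] consumes (best placement per read; unaligned reads as
#' FLAG-4 rows).
#'
#' @param locs List of `localization` objects (the `localizations` attribute
#'   of an [align_batch()] result).
#' @return A data.frame with columns `query_id, chrom, start, strand,
#'   mismatches, seq`.
#' @export
sam_hits <- function(locs) {
  rows <- lapply(locs, function(loc) {
    if (loc$status == "not_aligned") {
      data.frame(query_id = loc$query_id, chrom = NA_character_, start = NA_integer_,
                 strand = "+", mismatches = NA_integer_, seq = loc$query,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(query_id = loc$query_id, chrom = loc$hit$chrom,
                 start = loc$hit$start, strand = loc$hit$strand,
                 mismatches = loc$hit$mismatches, seq = loc$query,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
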