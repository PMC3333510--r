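# Bridge between universal names and genomic-level (g.) HGVS names.
#
# HGVS names place a variant on an accessioned reference sequence
# (e.g. NT_021937.19:g.7871183G>A); the same SNP therefore has one legal HGVS
# name per covering accession. Translating to the genome-wide nomenclature
# needs an explicit accession -> chromosome placement, supplied by the user
# as an accession map (HGVS itself carries no such mapping).

hgvs_stop <- function(message, class, field = NULL) {
  stop(errorCondition(message, field = field,
                      class = c(class, "usnp_hgvs_error", "usnp_error")))
}

new_hgvs_g <- function(accession, version, position, variant_class, ref, alt) {
  structure(
    list(accession = accession, version = as.integer(version),
         position = as.integer(position), variant_class = variant_class,
         ref = ref, alt = alt),
    class = "hgvs_g_name"
  )
}

#' Parse a genomic-level HGVS name
#'
#' Accepts single-base genomic (`g.`) names of the forms
#' `ACC.V:g.<pos><REF>><ALT>`, `ACC.V:g.<pos>ins<BASE>` and
#' `ACC.V:g.<pos>del<BASE>`. The `>` symbol reads "changed to". Coding,
#' protein, mitochondrial and RNA coordinates (`c.`, `p.`, `m.`, `n.`, `r.`)
#' and multi-base or range (`_`) payloads are recognized but rejected with an
#' `hgvs_unsupported_error`, distinct from `hgvs_syntax_error` for strings
#' that are not HGVS-shaped at all.
#'
#' @param text A single HGVS name string.
#' @return An `hgvs_g_name` object with fields `accession`, `version`,
#'   `position` (1-based on the accession), `variant_class`, `ref`, `alt`
#'   (for indels `alt` holds the inserted/deleted base and `ref` is `NA`).
#' @examples
#' parse_hgvs_g("NT_021937.19:g.7871183G>A")
#' @export
parse_hgvs_g <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    hgvs_stop("HGVS name must be a single non-empty string", "hgvs_syntax_error")
  }
  text <- trimws(text)
  m <- regexec("^([A-Za-z][A-Za-z0-9_]*)\\.([0-9]+):([a-z])\\.(.+)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 5L) {
    hgvs_stop(sprintf("not an HGVS name: '%s'", text), "hgvs_syntax_error")
  }
  if (parts[4] != "g") {
    hgvs_stop(
      sprintf("only genomic (g.) coordinates are supported, not '%s.'", parts[4]),
      "hgvs_unsupported_error", field = "sequence_type")
  }
  payload <- parts[5]
  if (grepl("_", payload, fixed = TRUE)) {
    hgvs_stop("range (_) payloads are not supported; single-base variants only",
              "hgvs_unsupported_error", field = "payload")
  }
  base <- "[ACGTNacgtn]"
  if (grepl(sprintf("^([0-9]+)%s>%s$", base, base), payload)) {
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", payload))
    bases <- toupper(substring(payload, nchar(payload) - c(2L, 0L),
                               nchar(payload) - c(2L, 0L)))
    cls <- "substitution"; ref <- bases[1]; alt <- bases[2]
  } else if (grepl(sprintf("^([0-9]+)(ins|del)%s$", base), payload)) {
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", payload))
    cls <- if (grepl("ins", payload, fixed = TRUE)) "insertion" else "deletion"
    ref <- NA_character_
    alt <- toupper(substring(payload, nchar(payload)))
  } else if (grepl(sprintf("^[0-9]+(%s{2,}>|%s>%s{2,}|(ins|del)%s{2,})", base, base, base, base),
                   payload)) {
    hgvs_stop("multi-base payloads are not supported; single-base variants only",
              "hgvs_unsupported_error", field = "payload")
  } else {
    hgvs_stop(sprintf("cannot parse g. payload '%s'", payload), "hgvs_syntax_error",
              field = "payload")
  }
  if (pos < 1L) {
    hgvs_stop("HGVS g. positions are 1-based (position >= 1)",
              "hgvs_syntax_error", field = "position")
  }
  if (cls == "substitution" && ref == alt) {
    hgvs_stop("reference and alternate base of a substitution must differ",
              "hgvs_syntax_error", field = "payload")
  }
  new_hgvs_g(parts[2], parts[3], pos, cls, ref, alt)
}

#' @export
format.hgvs_g_name <- function(x, ...) {
  payload <- switch(x$variant_class,
    substitution = sprintf("%d%s>%s", x$position, x$ref, x$alt),
    insertion    = sprintf("%dins%s", x$position, x$alt),
    deletion     = sprintf("%ddel%s", x$position, x$alt)
  )
  sprintf("%s.%d:g.%s", x$accession, x$version, payload)
}

#' @export
print.hgvs_g_name <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' Read an accession map
#'
#' The accession map places accessioned reference sequences (RefSeq contigs
#' and the like) on the genome: one row per `accession.version`, giving the
#' chromosome, the 1-based genome position of the accession's first base
#' (`genome_start`), the strand the accession runs on, and its length. A
#' minus-strand accession is the reverse complement of the genome segment it
#' covers.
#'
#' File format: tab-separated with header
#' `accession  version  chromosome  genome_start  strand  length`;
#' lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `accession_map`.
#' @export
read_accession_map <- function(path) {
  if (!file.exists(path)) {
    hgvs_stop(sprintf("accession map not found: %s", path), "hgvs_io_error")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("accession", "version", "chromosome", "genome_start", "strand", "length")
  if (!all(required %in% names(df))) {
    hgvs_stop(sprintf("accession map must have columns: %s",
                      paste(required, collapse = ", ")), "hgvs_io_error")
  }
  df$chromosome <- toupper(as.character(df$chromosome))
  df$key <- paste0(df$accession, ".", df$version)
  if (anyDuplicated(df$key)) {
    hgvs_stop("duplicate accession.version entries in accession map", "hgvs_io_error")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    hgvs_stop("strand must be '+' or '-'", "hgvs_io_error", field = "strand")
  }
  if (!all(df$chromosome %in% VALID_CHROMOSOMES)) {
    hgvs_stop("accession map contains an invalid chromosome token",
              "hgvs_io_error", field = "chromosome")
  }
  if (any(df$genome_start < 1) || any(df$length < 1)) {
    hgvs_stop("genome_start and length must be >= 1", "hgvs_io_error")
  }
  class(df) <- c("accession_map", "data.frame")
  df
}

#' Build an accession map in memory
#'
#' Programmatic counterpart of [read_accession_map()], mostly used by the
#' fixture generator and tests.
#'
#' @param accession,version,chromosome,genome_start,strand,length Parallel
#'   vectors, one element per accession placement.
#' @return A data.frame of class `accession_map`.
#' @export
accession_map <- function(accession, version, chromosome, genome_start, strand, length) {
  df <- data.frame(
    accession = as.character(accession), version = as.integer(version),
    chromosome = toupper(as.character(chromosome)),
    genome_start = as.integer(genome_start),
    strand = as.character(strand), length = as.integer(length),
    stringsAsFactors = FALSE
  )
  df$key <- paste0(df$accession, ".", df$version)
  class(df) <- c("accession_map", "data.frame")
  df
}

#' Translate an HGVS genomic name to the universal nomenclature
#'
#' Looks the name's `accession.version` up in the map and shifts the position
#' onto genome coordinates. On the minus strand the position is mirrored
#' through the accession's span (accession base 1 sits at the *end* of the
#' covered genome segment) and bases are reverse-complemented; an insertion
#' additionally shifts by one because the inserted base is written at the
#' position left of the insertion gap on the genome strand.
#'
#' @param h An `hgvs_g_name` (or a string, parsed first).
#' @param map An `accession_map`.
#' @param build Genome build for the resulting name (default 19).
#' @return A `usnp_name`. Substitution alleles are ordered (reference,
#'   alternate).
#' @examples
#' m <- accession_map("NT_x", 1, "1", 901, "+", 500)
#' format(hgvs_to_usnp("NT_x.1:g.100G>A", m))   # "HG19.1:1000:G/A"
#' @export
hgvs_to_usnp <- function(h, map, build = 19L) {
  if (is.character(h)) h <- parse_hgvs_g(h)
  stopifnot(inherits(h, "hgvs_g_name"), inherits(map, "accession_map"))
  key <- paste0(h$accession, ".", h$version)
  i <- match(key, map$key)
  if (is.na(i)) {
    hgvs_stop(sprintf("accession %s is not in the accession map", key),
              "hgvs_unmapped_accession_error", field = "accession")
  }
  row <- map[i, ]
  if (h$position > row$length) {
    hgvs_stop(sprintf("position %d exceeds accession length %d", h$position, row$length),
              "hgvs_position_error", field = "position")
  }
  if (row$strand == "+") {
    locus <- row$genome_start - 1L + h$position
    ref <- h$ref; alt <- h$alt
  } else {
    locus <- row$genome_start + row$length - h$position
    if (h$variant_class == "insertion") locus <- locus + 1L
    ref <- if (is.na(h$ref)) NA_character_ else revcomp(h$ref)
    alt <- revcomp(h$alt)
  }
  alleles <- if (h$variant_class == "substitution") c(ref, alt) else alt
  usnp_name(build, row$chromosome, locus, h$variant_class, alleles)
}

#' Translate a universal name to HGVS genomic names
#'
#' The reverse mapping is one-to-many: each accession whose placement covers
#' the name's locus yields one legal HGVS name (a SNP commonly has several
#' legal HGVS names on different reference sequences). A substitution with k
#' alternate alleles yields k names per covering accession, the leftmost
#' allele serving as the HGVS reference base. An empty list is a valid
#' outcome (no covering accession).
#'
#' @param u A `usnp_name`.
#' @param map An `accession_map`.
#' @return A list of `hgvs_g_name` objects (possibly empty).
#' @export
usnp_to_hgvs <- function(u, map) {
  stopifnot(inherits(u, "usnp_name"), inherits(map, "accession_map"))
  covering <- map[map$chromosome == u$chromosome &
                  map$genome_start <= u$locus &
                  u$locus <= map$genome_start + map$length - 1L, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(covering))) {
    row <- covering[i, ]
    if (row$strand == "+") {
      pos <- u$locus - row$genome_start + 1L
      if (u$variant_class == "substitution") {
        for (alt in u$alleles[-1L]) {
          out[[length(out) + 1L]] <-
            new_hgvs_g(row$accession, row$version, pos, "substitution",
                       u$alleles[1L], alt)
        }
      } else {
        out[[length(out) + 1L]] <-
          new_hgvs_g(row$accession, row$version, pos, u$variant_class,
                     NA_character_, u$alleles)
      }
    } else {
      pos <- row$genome_start + row$length - u$locus
      if (u$variant_class == "insertion") pos <- pos + 1L
      if (pos < 1L || pos > row$length) next
      if (u$variant_class == "substitution") {
        for (alt in u$alleles[-1L]) {
          out[[length(out) + 1L]] <-
            new_hgvs_g(row$accession, row$version, pos, "substitution",
                       revcomp(u$alleles[1L]), revcomp(alt))
        }
      } else {
        out[[length(out) + 1L]] <-
          new_hgvs_g(row$accession, row$version, pos, u$variant_class,
                     NA_character_, revcomp(u$alleles))
      }
    }
  }
  out
}
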