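# Local cross-reference snapshot: one row per known SNP linking a genomic
# position to the identifiers the major databases assigned it (dbSNP rs#,
# JSNP IMS-JST id, HapMap id, GWAS/HGVbaseG2P HGVM id). Stands in for a live
# multi-database join: lookups are by exact (chromosome, locus) -- alleles
# are deliberately NOT compared, so a record whose recorded alleles differ
# from the query's is still returned.

XREF_COLUMNS <- c("chrom", "pos", "alleles", "rs", "jsnp", "hapmap", "gwas")
XREF_ID_COLUMNS <- c("rs", "jsnp", "hapmap", "gwas")

xref_stop <- function(message, field = NULL) {
  stop(errorCondition(message, field = field,
                      class = c("usnp_xref_error", "usnp_error")))
}

new_xref_store <- function(records) {
  structure(list(records = records), class = "xref_store")
}

#' Load a cross-reference snapshot
#'
#' Reads the tab-separated snapshot dialect: columns
#' `chrom  pos  alleles  rs  jsnp  hapmap  gwas`, `-` marking an absent
#' field, an optional header row, and an optional coordinate directive line
#' `#coord=0based` or `#coord=1based` (default `1based`). Dump files from
#' some databases are 0-based; when the directive says so every position is
#' converted with [to_one_based()] at load time, so the store is always
#' 1-based internally. Other `#` lines are comments. Identical duplicate
#' rows are dropped silently; a row carrying no identifier at all is an
#' error, as is any malformed row (reported with its line number).
#'
#' @param tsv_path Path to the snapshot TSV.
#' @return An `xref_store`.
#' @export
load_xref <- function(tsv_path) {
  if (!file.exists(tsv_path)) xref_stop(sprintf("xref file not found: %s", tsv_path))
  lines <- readLines(tsv_path, warn = FALSE)
  coord <- "1based"
  directive <- grepl("^#\\s*coord\\s*=", lines)
  if (any(directive)) {
    val <- sub("^#\\s*coord\\s*=\\s*", "", lines[directive][1])
    val <- trimws(val)
    if (!val %in% c("0based", "1based")) {
      xref_stop(sprintf("unknown coordinate directive '#coord=%s'", val))
    }
    coord <- val
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  body <- lines[keep]
  if (length(body) && grepl("^chrom\\b", body[1])) {
    body <- body[-1]
    line_no <- line_no[-1]
  }
  if (!length(body)) {
    return(new_xref_store(empty_xref_records()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(XREF_COLUMNS))
  if (length(bad)) {
    xref_stop(sprintf("malformed xref row at line %d: expected %d tab-separated fields",
                      line_no[bad[1]], length(XREF_COLUMNS)))
  }
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- XREF_COLUMNS
  df[df == "-"] <- NA_character_
  df$chrom <- toupper(df$chrom)
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos))
  if (length(bad)) {
    xref_stop(sprintf("malformed position at line %d", line_no[bad[1]]))
  }
  df$pos <- if (coord == "0based") to_one_based(pos) else pos
  if (any(df$pos < 1L)) xref_stop("xref positions must be >= 1")
  if (!all(df$chrom %in% VALID_CHROMOSOMES)) {
    bad <- which(!df$chrom %in% VALID_CHROMOSOMES)[1]
    xref_stop(sprintf("invalid chromosome token at line %d", line_no[bad]))
  }
  no_id <- rowSums(!is.na(df[XREF_ID_COLUMNS])) == 0L
  if (any(no_id)) {
    xref_stop(sprintf("xref row at line %d carries no identifier", line_no[which(no_id)[1]]))
  }
  df <- unique(df)
  rownames(df) <- NULL
  new_xref_store(df)
}

empty_xref_records <- function() {
  df <- data.frame(matrix(character(0), ncol = length(XREF_COLUMNS)),
                   stringsAsFactors = FALSE)
  names(df) <- XREF_COLUMNS
  df$pos <- integer(0)
  df
}

#' Write a cross-reference snapshot
#'
#' Re-serializes a store in the snapshot TSV dialect. Writing the `0based`
#' dialect subtracts 1 from every position and records the
#' `#coord=0based` directive, so a load/export/reload cycle through either
#' dialect reproduces the store exactly.
#'
#' @param store An `xref_store`.
#' @param path Output path.
#' @param coord `"1based"` (default) or `"0based"`.
#' @export
write_xref <- function(store, path, coord = c("1based", "0based")) {
  coord <- match.arg(coord)
  stopifnot(inherits(store, "xref_store"))
  df <- store$records
  out <- df
  out$pos <- if (coord == "0based") to_zero_based(df$pos) else df$pos
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "-"
    col
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#coord=%s", coord), con)
  writeLines(paste(XREF_COLUMNS, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' @export
print.xref_store <- function(x, ...) {
  cat(sprintf("<xref_store> %d records on chromosome(s) %s\n",
              nrow(x$records),
              paste(sort(unique(x$records$chrom)), collapse = ", ")))
  invisible(x)
}

#' Look up cross-reference records by genomic position
#'
#' Returns every record at exactly (chromosome, locus). Alleles are not
#' compared: cross-referencing asks only whether some SNP is recorded at the
#' same locus, so records whose stored alleles differ from the query's are
#' still reported.
#'
#' @param store An `xref_store`.
#' @param chromosome Chromosome token (case-insensitive, `chr` prefix allowed).
#' @param locus 1-based position.
#' @return A data.frame of matching records (zero rows when none).
#' @export
lookup_by_position <- function(store, chromosome, locus) {
  stopifnot(inherits(store, "xref_store"))
  chromosome <- toupper(sub("^[Cc][Hh][Rr]", "", as.character(chromosome)))
  locus <- as.integer(locus)
  if (is.na(locus) || locus < 1L) {
    usnp_stop("locus must be >= 1", "usnp_locus_error", field = "locus")
  }
  df <- store$records
  df[df$chrom == chromosome & df$pos == locus, , drop = FALSE]
}

# Parse the allele field of a name or snapshot row ("G/A", "insA", "delT")
# into (variant_class, alleles). Returns NULL if unparseable.
parse_allele_field <- function(txt) {
  if (is.null(txt) || is.na(txt) || !nzchar(txt)) return(NULL)
  low <- tolower(txt)
  if (grepl("^(ins|del)[acgtn]$", low)) {
    return(list(
      variant_class = if (startsWith(low, "ins")) "insertion" else "deletion",
      alleles = toupper(substring(txt, 4L))
    ))
  }
  if (grepl("^[acgtn](/[acgtn]){1,3}$", low)) {
    return(list(variant_class = "substitution",
                alleles = toupper(strsplit(txt, "/", fixed = TRUE)[[1]])))
  }
  NULL
}

#' Universal name for a cross-reference record
#'
#' Builds the universal name from a snapshot record when chromosome, locus
#' and alleles are all recoverable; returns `NULL` otherwise (a record
#' without allele information cannot be named, since the alleles are part of
#' the name).
#'
#' @param record A one-row data.frame or list with fields `chrom`, `pos`,
#'   `alleles`.
#' @param build Genome build (default 19).
#' @return A `usnp_name`, or `NULL`.
#' @export
xref_usnp_name <- function(record, build = 19L) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  allele <- parse_allele_field(record$alleles)
  if (is.null(allele) || is.null(record$chrom) || is.na(record$chrom) ||
      is.null(record$pos) || is.na(record$pos)) {
    return(NULL)
  }
  dup <- allele$variant_class == "substitution" && anyDuplicated(allele$alleles)
  if (dup) return(NULL)
  tryCatch(
    usnp_name(build, record$chrom, record$pos, allele$variant_class, allele$alleles),
    usnp_validation_error = function(e) NULL
  )
}

# ---- name mapping ----------------------------------------------------------

# Lenient normalization of genome-browser style positional names:
# "Chr19:11,087,877-11,087,877 G/T" or "Chr19:11087877 G/T".
parse_browser_style <- function(text) {
  text <- gsub(",", "", trimws(text), fixed = TRUE)
  m <- regexec(
    "^[Cc][Hh][Rr]([0-9XYxy]+):([0-9]+)(-([0-9]+))?[ \t]+([ACGTNacgtn](/[ACGTNacgtn]){1,3})$",
    text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L) return(NULL)
  start <- as.integer(parts[3])
  end <- if (nzchar(parts[5])) as.integer(parts[5]) else start
  if (end != start) return(NULL)  # single-base scope only
  list(chromosome = toupper(parts[2]), locus = start,
       alleles = toupper(strsplit(parts[6], "/", fixed = TRUE)[[1]]))
}

detect_namespace <- function(text) {
  text <- trimws(text)
  if (grepl("^rs[0-9]+@", text)) return("pharmgkb")
  if (grepl("^rs[0-9]+$", text)) return("rs")
  if (grepl("^ss[0-9]+$", text)) return("ss")
  if (grepl("^IMS-JST[0-9]+$", text, ignore.case = TRUE)) return("jsnp")
  if (grepl("^HGVM[0-9]+$", text, ignore.case = TRUE)) return("gwas")
  if (grepl("^[Hh][Gg][0-9]+\\.", text)) return("usnp")
  if (!is.null(parse_browser_style(text))) return("browser")
  NA_character_
}

render_none <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "none"
  x
}

#' Map an existing SNP name onto every known namespace
#'
#' Takes a SNP name from any supported namespace -- dbSNP `rs#`/`ss#`, JSNP
#' `IMS-JST...`, GWAS `HGVM...`, HapMap, PharmGKB's `rs#@chr:pos` style, a
#' universal name, or the lenient genome-browser style
#' `Chr19:11,087,877 G/T` -- resolves it against the snapshot, and reports
#' the identifier every database assigned the same position. A per-database
#' identifier that is missing renders as the literal string `"none"`; an
#' input whose namespace cannot be recognized, or an identifier the snapshot
#' does not contain, gives a report with status `"None"` (the whole-name
#' negative), never an exception.
#'
#' @param store An `xref_store`.
#' @param name_text The SNP name to map.
#' @param build Genome build for generated universal names (default 19).
#' @return A `mapping_report`: list with `status` (`"ok"` or `"None"`),
#'   `query`, `namespace`, `usnp` (canonical universal name string or
#'   `"none"`), `records` (matched snapshot rows, possibly zero), and
#'   `table` (rendered rows with `"none"` fill, one per matched record).
#' @examples
#' \dontrun{
#' map_name(store, "rs3737965")
#' map_name(store, "Chr19:11,087,877 G/T")
#' }
#' @export
map_name <- function(store, name_text, build = 19L) {
  stopifnot(inherits(store, "xref_store"))
  ns <- if (is.character(name_text) && length(name_text) == 1L && !is.na(name_text)) {
    detect_namespace(name_text)
  } else NA_character_
  report <- structure(
    list(status = "None", query = as.character(name_text)[1], namespace = ns,
         usnp = "none", records = empty_xref_records(), table = NULL),
    class = "mapping_report")
  if (is.na(ns)) return(report)

  df <- store$records
  query_name <- NULL   # usnp_name recovered from the query itself, if any
  if (ns %in% c("rs", "ss", "jsnp", "gwas", "pharmgkb")) {
    id <- trimws(name_text)
    if (ns == "pharmgkb") id <- sub("@.*$", "", id)
    hit <- rep(FALSE, nrow(df))
    for (col in XREF_ID_COLUMNS) {
      hit <- hit | (!is.na(df[[col]]) & toupper(df[[col]]) == toupper(id))
    }
    records <- df[hit, , drop = FALSE]
  } else if (ns == "usnp") {
    query_name <- tryCatch(parse_usnp(name_text), usnp_error = function(e) NULL)
    if (is.null(query_name)) return(report)
    records <- lookup_by_position(store, query_name$chromosome, query_name$locus)
  } else { # browser style
    b <- parse_browser_style(name_text)
    query_name <- tryCatch(
      usnp_name(build, b$chromosome, b$locus, "substitution", b$alleles),
      usnp_validation_error = function(e) NULL)
    if (is.null(query_name)) return(report)
    records <- lookup_by_position(store, b$chromosome, b$locus)
  }

  if (nrow(records) == 0L && is.null(query_name)) {
    return(report)   # identifier namespace recognized but unknown to the store
  }
  usnp_txt <- if (!is.null(query_name)) {
    format_usnp(query_name)
  } else {
    nm <- xref_usnp_name(records[1, ], build)
    if (is.null(nm)) "none" else format_usnp(nm)
  }
  tab <- if (nrow(records)) {
    data.frame(
      chrom = records$chrom, pos = records$pos,
      alleles = render_none(records$alleles),
      usnp = vapply(seq_len(nrow(records)), function(i) {
        nm <- xref_usnp_name(records[i, ], build)
        if (is.null(nm)) usnp_txt else format_usnp(nm)
      }, character(1)),
      rs = render_none(records$rs), jsnp = render_none(records$jsnp),
      hapmap = render_none(records$hapmap), gwas = render_none(records$gwas),
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = query_name$chromosome, pos = query_name$locus,
               alleles = paste(query_name$alleles, collapse = "/"),
               usnp = usnp_txt, rs = "none", jsnp = "none",
               hapmap = "none", gwas = "none", stringsAsFactors = FALSE)
  }
  report$status <- "ok"
  report$usnp <- usnp_txt
  report$records <- records
  report$table <- tab
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  if (x$status != "ok") {
    cat("None\n")
    return(invisible(x))
  }
  cat(sprintf("query: %s  [%s]\n", x$query, x$namespace))
  cat(sprintf("universal name: %s\n", x$usnp))
  print(x$table, row.names = FALSE)
  invisible(x)
}
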