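VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y")
VALID_NUCLEOTIDES <- c("A", "C", "G", "T", "N")
VARIANT_CLASSES   <- c("substitution", "insertion", "deletion")

new_usnp_name <- function(build, chromosome, locus, variant_class, alleles) {
  structure(
    list(
      build = as.integer(build),
      chromosome = as.character(chromosome),
      locus = as.integer(locus),
      variant_class = variant_class,
      alleles = as.character(alleles)
    ),
    class = "usnp_name"
  )
}

#' Construct and validate a universal SNP name
#'
#' A universal SNP name pins a single-nucleotide variant to one point of the
#' human reference genome: `HG<build>.<chromosome>:<locus>:<alleles>`, e.g.
#' `HG19.1:11789038:G/A`. The locus is 1-based. Substitutions list 2-4
#' distinct alleles separated by `/`; single-base insertions and deletions are
#' written `insX` / `delX`. For an insertion the inserted base is written *at*
#' the locus, so the pre-existing reference base is displaced to `locus + 1`
#' (see [displaced_reference_position()]).
#'
#' `usnp_name()` takes the pivot features that define a SNP (genome build,
#' chromosome, position, alleles) and performs strict validation, the same
#' rule set the parser applies to name strings. This is the programmatic
#' entry point of the name generator.
#'
#' @param build Integer human reference genome version (e.g. `19` for HG19).
#' @param chromosome Chromosome token, one of `1`-`22`, `X`, `Y` (a leading
#'   `chr` prefix is not part of the canonical name and is rejected here; the
#'   lenient mapper strips it, see [map_name()]).
#' @param locus 1-based genomic position (integer, >= 1).
#' @param variant_class One of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param alleles Character vector of single nucleotides from `A,C,G,T,N`:
#'   2-4 pairwise distinct bases for a substitution, exactly one base for an
#'   insertion or deletion.
#'
#' @return An object of class `usnp_name` (a validated list with fields
#'   `build`, `chromosome`, `locus`, `variant_class`, `alleles`).
#'
#' @section Errors:
#' Failures raise conditions subclassing `usnp_validation_error` with a
#' field-specific class: `usnp_chromosome_error`, `usnp_locus_error`,
#' `usnp_allele_error` (illegal character), `usnp_allele_count_error`
#' (wrong number of alleles or duplicated substitution alleles),
#' `usnp_class_error`.
#'
#' @examples
#' usnp_name(19, "1", 11789038, "substitution", c("G", "A"))
#' format(usnp_name(19, "Y", 5, "deletion", "T"))
#' @seealso [parse_usnp()], [format_usnp()], [validate_descriptor()]
#' @export
usnp_name <- function(build, chromosome, locus, variant_class, alleles) {
  if (length(build) != 1L || is.na(suppressWarnings(as.integer(build))) ||
      as.integer(build) < 1L) {
    usnp_stop("genome build must be a single positive integer",
              "usnp_build_error", field = "build")
  }
  chromosome <- toupper(as.character(chromosome))
  if (length(chromosome) != 1L || !chromosome %in% VALID_CHROMOSOMES) {
    usnp_stop(
      sprintf("chromosome must be one of 1-22, X, Y (got '%s')", chromosome),
      "usnp_chromosome_error", field = "chromosome")
  }
  if (length(locus) != 1L || is.na(suppressWarnings(as.numeric(locus))) ||
      as.numeric(locus) != trunc(as.numeric(locus))) {
    usnp_stop("locus must be a single integer", "usnp_locus_error", field = "locus")
  }
  if (as.numeric(locus) < 1) {
    usnp_stop("locus must be >= 1 (positions are 1-based)",
              "usnp_locus_error", field = "locus")
  }
  if (length(variant_class) != 1L || !variant_class %in% VARIANT_CLASSES) {
    usnp_stop("variant_class must be substitution, insertion or deletion",
              "usnp_class_error", field = "variant_class")
  }
  alleles <- toupper(as.character(alleles))
  if (length(alleles) == 0L || any(nchar(alleles) != 1L) ||
      !all(alleles %in% VALID_NUCLEOTIDES)) {
    usnp_stop("alleles must be single characters from A, C, G, T, N",
              "usnp_allele_error", field = "alleles")
  }
  if (variant_class == "substitution") {
    if (length(alleles) < 2L || length(alleles) > 4L) {
      usnp_stop("a substitution lists 2-4 alleles",
                "usnp_allele_count_error", field = "alleles")
    }
    if (anyDuplicated(alleles)) {
      usnp_stop("substitution alleles must be pairwise distinct",
                "usnp_allele_count_error", field = "alleles")
    }
  } else if (length(alleles) != 1L) {
    usnp_stop(sprintf("an %s carries exactly one allele", variant_class),
              "usnp_allele_count_error", field = "alleles")
  }
  new_usnp_name(build, chromosome, locus, variant_class, alleles)
}

#' Validate a variant descriptor (pivot features) into a universal name
#'
#' A descriptor is the unvalidated, structured form of a SNP's pivot
#' features: build, chromosome, 1-based locus, variant class and alleles.
#' Validation applies exactly the parser's rule set and returns the
#' corresponding `usnp_name`, or raises the same field-level conditions.
#'
#' @param d A list (or `usnp_name`) with fields `build`, `chromosome`,
#'   `locus`, `variant_class`, `alleles`.
#' @return A validated `usnp_name`.
#' @examples
#' d <- list(build = 19, chromosome = "1", locus = 11789038,
#'           variant_class = "substitution", alleles = c("G", "A"))
#' format(validate_descriptor(d))
#' @export
validate_descriptor <- function(d) {
  required <- c("build", "chromosome", "locus", "variant_class", "alleles")
  if (!is.list(d) || !all(required %in% names(d))) {
    usnp_stop("descriptor must carry build, chromosome, locus, variant_class, alleles",
              "usnp_descriptor_error", field = "descriptor")
  }
  usnp_name(d$build, d$chromosome, d$locus, d$variant_class, d$alleles)
}

#' Parse a universal SNP name string
#'
#' Parses `HG<build>.<chromosome>:<locus>:<alleles>` into its components.
#' Parsing is case-insensitive on the `HG` prefix, nucleotides and the
#' `ins`/`del` keywords; re-rendering with [format_usnp()] is canonical
#' (upper-case nucleotides, lower-case `ins`/`del`).
#'
#' @param name_string A single non-empty character string.
#' @return A validated `usnp_name`.
#' @section Errors:
#' `usnp_syntax_error` for a malformed string; otherwise the field-level
#' conditions documented in [usnp_name()].
#' @examples
#' parse_usnp("HG19.1:11789038:G/A")
#' parse_usnp("hg19.x:1:insa")   # case-insensitive input
#' @export
parse_usnp <- function(name_string) {
  if (!is.character(name_string) || length(name_string) != 1L ||
      is.na(name_string) || !nzchar(name_string)) {
    usnp_stop("name must be a single non-empty string",
              "usnp_syntax_error", field = "name")
  }
  m <- regexec("^[Hh][Gg]([0-9]+)\\.([0-9A-Za-z]+):([0-9]+):([A-Za-z/]+)$",
               trimws(name_string))
  parts <- regmatches(trimws(name_string), m)[[1]]
  if (length(parts) != 5L) {
    usnp_stop(
      sprintf("not a universal SNP name: '%s' (expected HG<build>.<chrom>:<locus>:<alleles>)",
              name_string),
      "usnp_syntax_error", field = "name")
  }
  build <- as.integer(parts[2])
  chromosome <- toupper(parts[3])
  locus <- suppressWarnings(as.numeric(parts[4]))
  allele_txt <- parts[5]

  low <- tolower(allele_txt)
  if (startsWith(low, "ins")) {
    variant_class <- "insertion"
    alleles <- substring(allele_txt, 4L)
  } else if (startsWith(low, "del")) {
    variant_class <- "deletion"
    alleles <- substring(allele_txt, 4L)
  } else {
    variant_class <- "substitution"
    alleles <- strsplit(allele_txt, "/", fixed = TRUE)[[1]]
    if (grepl("^/|/$|//", allele_txt)) {
      usnp_stop("empty allele slot in substitution",
                "usnp_syntax_error", field = "alleles")
    }
  }
  if (variant_class != "substitution" && nchar(alleles) != 1L) {
    usnp_stop(sprintf("%s payload must be a single base", variant_class),
              "usnp_syntax_error", field = "alleles")
  }
  usnp_name(build, chromosome, locus, variant_class, alleles)
}

#' Render a universal SNP name in canonical form
#'
#' The canonical string is `HG<build>.<chromosome>:<locus>:<alleles>` with
#' upper-case nucleotides, `X/Y[/Z...]` for substitutions and lower-case
#' `ins`/`del` prefixes for single-base indels. `parse_usnp(format_usnp(x))`
#' reproduces `x` field-for-field.
#'
#' @param name A validated `usnp_name`.
#' @return A character string.
#' @examples
#' format_usnp(usnp_name(19, 1, 11789038, "substitution", c("G", "A")))
#' @export
format_usnp <- function(name) {
  stopifnot(inherits(name, "usnp_name"))
  allele_txt <- switch(name$variant_class,
    substitution = paste(name$alleles, collapse = "/"),
    insertion    = paste0("ins", name$alleles),
    deletion     = paste0("del", name$alleles)
  )
  sprintf("HG%d.%s:%d:%s", name$build, name$chromosome, name$locus, allele_txt)
}

#' @export
format.usnp_name <- function(x, ...) format_usnp(x)

#' @export
print.usnp_name <- function(x, ...) {
  cat(format_usnp(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.usnp_name <- function(x, ...) format_usnp(x)

#' Put the reference (or major) allele in the leftmost slot
#'
#' The leftmost allele of a substitution name is by convention the reference
#' genome base (more generally the major allele). Given the reference base at
#' the name's locus, this reorders the allele list so that base comes first,
#' preserving the relative order of the remaining alleles. Without a
#' reference base the name is returned untouched: allele frequencies are not
#' modeled, so no other reordering is defensible. The operation is idempotent
#' and never changes the allele multiset.
#'
#' If the supplied reference base is not among the recorded alleles the name
#' is returned unchanged with attribute `reference_mismatch = TRUE` and a
#' `usnp_reference_mismatch` warning: allele observations are population- and
#' assay-dependent, so a disagreement with the reference genome is suspicious
#' but not illegal.
#'
#' @param name A substitution `usnp_name`.
#' @param reference_base A single nucleotide, or `NULL` when no reference
#'   information is available.
#' @return The (possibly reordered) `usnp_name`.
#' @examples
#' n <- usnp_name(19, 1, 100, "substitution", c("A", "G"))
#' format(canonicalize_alleles(n, "G"))   # "HG19.1:100:G/A"
#' @export
canonicalize_alleles <- function(name, reference_base = NULL) {
  stopifnot(inherits(name, "usnp_name"))
  if (name$variant_class != "substitution") {
    usnp_stop("allele canonicalization applies to substitution names only",
              "usnp_class_error", field = "variant_class")
  }
  if (is.null(reference_base)) {
    return(name)
  }
  reference_base <- toupper(as.character(reference_base))
  if (length(reference_base) != 1L || !reference_base %in% VALID_NUCLEOTIDES) {
    usnp_stop("reference_base must be a single nucleotide",
              "usnp_allele_error", field = "reference_base")
  }
  i <- match(reference_base, name$alleles)
  if (is.na(i)) {
    usnp_warn(
      sprintf("reference base %s is not among recorded alleles %s; name left unchanged",
              reference_base, paste(name$alleles, collapse = "/")),
      "usnp_reference_mismatch")
    attr(name, "reference_mismatch") <- TRUE
    return(name)
  }
  name$alleles <- c(name$alleles[i], name$alleles[-i])
  name
}

#' Position of the reference base displaced by an insertion
#'
#' An insertion name writes the inserted base *at* its locus: `1234insT`
#' means `T` occupies position 1234 and the base formerly at 1234 now sits at
#' position 1235. This returns that displaced position, `locus + 1`, for
#' insertion names and `NA` for substitutions and deletions, where the
#' convention does not apply.
#'
#' @param name A `usnp_name`.
#' @return Integer position, or `NA_integer_` for non-insertions.
#' @examples
#' displaced_reference_position(parse_usnp("HG19.1:1234:insT"))  # 1235
#' @export
displaced_reference_position <- function(name) {
  stopifnot(inherits(name, "usnp_name"))
  if (name$variant_class != "insertion") {
    return(NA_integer_)
  }
  name$locus + 1L
}

#' Convert between 1-based and 0-based genomic coordinates
#'
#' The nomenclature is 1-based throughout, but database dump files are often
#' 0-based (dbSNP's dumps are, while its web display and JSNP's dumps are
#' 1-based). These helpers make the off-by-one explicit and range-checked:
#' `to_one_based(to_zero_based(p)) == p`.
#'
#' @param locus_1based Integer position >= 1.
#' @param locus_0based Integer position >= 0.
#' @return The converted integer position(s).
#' @examples
#' to_zero_based(11789038)  # 11789037
#' to_one_based(0)          # 1
#' @export
to_zero_based <- function(locus_1based) {
  p <- as.integer(locus_1based)
  if (any(is.na(p)) || any(p < 1L)) {
    usnp_stop("1-based positions must be >= 1", "usnp_locus_error", field = "locus")
  }
  p - 1L
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(locus_0based) {
  p <- as.integer(locus_0based)
  if (any(is.na(p)) || any(p < 0L)) {
    usnp_stop("0-based positions must be >= 0", "usnp_locus_error", field = "locus")
  }
  p + 1L
}
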