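#' Parse a peptide query file
#'
#' One query per line, whitespace-separated; the input mode is inferred from
#' the field count and modes can be mixed in one file:
#' \describe{
#'   \item{2 fields}{`name peptide` — peptide mode: every possible coding
#'     sequence is searched.}
#'   \item{3 fields}{`name peptide mcs` — MCS mode: only the given coding
#'     sequence is searched.}
#'   \item{5 fields}{`name peptide mcs chrom:start-end strand` — manual mode:
#'     the given coding sequence is verified and counted at the stated
#'     location only.  Coordinates are 1-based inclusive; strand `+` or `-`.}
#' }
#'
#' @param path Path to the query file.  Blank lines and `#` comments are
#'   ignored.
#' @return Data frame with columns `name`, `peptide`, `mode`, `mcs`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
parse_peptides <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("No queries in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    n <- length(f)
    if (!n %in% c(2L, 3L, 5L))
      stop("Line ", i, ": expected 2 (peptide), 3 (MCS) or 5 (manual) fields, got ", n)
    pep <- toupper(f[2])
    if (!grepl("^[A-Z]+$", pep))
      stop("Line ", i, ": invalid peptide sequence '", f[2], "'")
    if (nchar(pep) < 8L || nchar(pep) > 11L)
      stop("Line ", i, ": peptide '", pep, "' outside the 8-11 residue range")
    check_peptide_chars(pep)
    out <- data.frame(name = f[1], peptide = pep, mode = "peptide",
                      mcs = NA_character_, chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, stringsAsFactors = FALSE)
    if (n >= 3L) {
      mcs <- toupper(f[3])
      tp <- tryCatch(translate_mcs(mcs), error = function(e) conditionMessage(e))
      if (!identical(tp, pep))
        stop("Line ", i, ": MCS does not translate to '", pep, "' (", tp, ")")
      out$mode <- "mcs"
      out$mcs <- mcs
    }
    if (n == 5L) {
      m <- regmatches(f[4], regexec("^([^:]+):([0-9]+)-([0-9]+)$", f[4]))[[1]]
      if (length(m) != 4L)
        stop("Line ", i, ": bad location '", f[4], "', expected chrom:start-end")
      if (!f[5] %in% c("+", "-"))
        stop("Line ", i, ": strand must be + or -, got '", f[5], "'")
      out$mode <- "manual"
      out$chrom <- m[2]
      out$start <- as.integer(m[3])
      out$end <- as.integer(m[4])
      out$strand <- f[5]
      if (out$end - out$start + 1L != nchar(out$mcs))
        stop("Line ", i, ": location span ", out$end - out$start + 1L,
             " nt does not match MCS length ", nchar(out$mcs))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name))
    stop("Duplicate query name(s): ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  out
}
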