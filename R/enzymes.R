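# Restriction enzymes: recognition motifs with a top-strand cut offset.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Define a restriction enzyme
#'
#' A restriction enzyme is a named IUPAC recognition motif together with the
#' 0-based position of the top-strand cut within the motif (e.g. EcoRI,
#' \code{G^AATTC}, has site \code{"GAATTC"} and \code{cut_offset = 1}).
#' Only palindromic sites (motif equals its IUPAC-aware reverse complement)
#' are accepted, so that a single top-strand scan finds every cut.
#'
#' @param name Short identifier, e.g. \code{"EcoRI"}.
#' @param site Recognition motif as an IUPAC string, length >= 4.
#' @param cut_offset Integer in \code{0..nchar(site)}: bases to the left of
#'   the top-strand cut, counted from the start of the motif.
#' @return An object of class \code{"restriction_enzyme"}.
#' @examples
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  site <- toupper(site)
  letters <- strsplit(site, "")[[1]]
  if (nchar(site) < 4L || !all(letters %in% IUPAC_CODES)) {
    stop("invalid recognition site '", site,
         "': must be >= 4 IUPAC nucleotide codes", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie in 0..", nchar(site), call. = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (rc != site) {
    stop("non-palindromic site '", site, "' for ", name,
         ": only palindromic enzymes are supported", call. = FALSE)
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cut <- paste0(substr(x$site, 1, x$cut_offset), "^",
                substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat(sprintf("Restriction enzyme %s: %s\n", x$name, cut))
  invisible(x)
}

#' Built-in enzyme catalogue
#'
#' The nine enzymes commonly screened for ddRAD library design:
#' AvaII (G^GWCC), EcoRI (G^AATTC), MseI (T^TAA), MspI (C^CGG),
#' NlaIII (CATG^), PstI (CTGCA^G), SbfI (CCTGCA^GG), SphI (GCATG^C),
#' MluCI (^AATT).
#'
#' @param names Optional character vector restricting (and ordering) the
#'   returned enzymes; unknown names are an error.
#' @return Named list of \code{restriction_enzyme} objects.
#' @export
enzyme_catalogue <- function(names = NULL) {
  tab <- list(
    AvaII = c("GGWCC", 1), EcoRI = c("GAATTC", 1), MseI  = c("TTAA", 1),
    MspI  = c("CCGG", 1),  NlaIII = c("CATG", 4),  PstI  = c("CTGCAG", 5),
    SbfI  = c("CCTGCAGG", 6), SphI = c("GCATGC", 5), MluCI = c("AATT", 0)
  )
  cat_full <- lapply(names(tab), function(nm)
    restriction_enzyme(nm, tab[[nm]][1], as.integer(tab[[nm]][2])))
  names(cat_full) <- names(tab)
  if (is.null(names)) return(cat_full)
  missing <- setdiff(names, base::names(cat_full))
  if (length(missing)) {
    stop("unknown enzyme(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cat_full[names]
}

#' Read an enzyme catalogue from a TSV file
#'
#' Expects columns \code{name}, \code{site}, \code{cut_offset}.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of \code{restriction_enzyme} objects.
#' @export
read_enzyme_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "site", "cut_offset")
  if (!all(need %in% names(df))) {
    stop("enzyme table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i)
    restriction_enzyme(df$name[i], df$site[i], df$cut_offset[i]))
  names(out) <- df$name
  out
}

#' Find all cut positions of an enzyme on a sequence
#'
#' Scans the top strand for exact IUPAC-aware occurrences of the recognition
#' motif and reports between-base cut positions (0-based: a cut at position
#' p falls between bases p and p+1 of the 1-based sequence). Ambiguity codes
#' are honoured in the motif only; any non-ACGT character in the genome
#' (e.g. N) never matches.
#'
#' @param sequence A single character string or \code{Biostrings::DNAString}.
#' @param enzyme A \code{restriction_enzyme}.
#' @return Strictly increasing integer vector of 0-based cut positions.
#' @examples
#' eco <- enzyme_catalogue("EcoRI")[[1]]
#' scan_cut_sites("AAGAATTCAA", eco)  # 3
#' @export
scan_cut_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  subject <- if (inherits(sequence, "DNAString")) sequence else {
    if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
      stop("sequence must be a non-empty string or DNAString", call. = FALSE)
    Biostrings::DNAString(toupper(sequence))
  }
  if (length(subject) < nchar(enzyme$site)) return(integer(0))
  # fixed = "subject": IUPAC codes expanded in the pattern, genome letters
  # taken literally, so genomic N can never satisfy a motif position.
  m <- Biostrings::matchPattern(enzyme$site, subject, fixed = "subject")
  starts0 <- Biostrings::start(m) - 1L      # 0-based motif starts
  if (length(starts0)) {
    # a window containing any non-ACGT genome character never matches, even
    # where the ambiguity codes would nominally be compatible
    ok <- !grepl("[^ACGT]", as.character(m))
    starts0 <- starts0[ok]
  }
  sort(unique(starts0 + enzyme$cut_offset))
}
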