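#' Construct a primer pair
#'
#' @param name Assay label.
#' @param forward,reverse Primer sequences, 5'->3', length >= 15, over
#'   the IUPAC DNA alphabet.
#' @param expected_amplicon_bp Optional expected product size in bp.
#' @return A one-row tibble of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_amplicon_bp = NULL) {
  for (s in list(forward, reverse)) {
    validate_dna(s)
    if (nchar(s) < 15) abort("primer sequences must be at least 15 nt")
  }
  out <- tibble::tibble(
    name = name,
    forward = toupper(forward),
    reverse = toupper(reverse),
    expected_amplicon_bp = expected_amplicon_bp %||% NA_integer_
  )
  class(out) <- c("primer_pair", class(out))
  out
}

validate_dna <- function(seq, iupac = TRUE) {
  if (length(seq) != 1 || !is.character(seq) || nchar(seq) == 0) {
    abort("sequence must be a single non-empty string")
  }
  alphabet <- if (iupac) Biostrings::DNA_ALPHABET else c("A", "C", "G", "T")
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    abort(paste0("invalid character '", chars[bad[1]], "' at position ",
                 bad[1]))
  }
  invisible(seq)
}

#' Diagnostic COI primer pairs bundled with the package
#'
#' The three species-specific assays targeting the mitochondrial
#' cytochrome oxidase I region of *H. variegata* (104 bp product),
#' *C. septempunctata* (108 bp) and *A. gossypii* (263 bp), shipped as a
#' plain-text table in `inst/extdata/coi_primers.csv`.
#'
#' @return Tibble with `name`, `forward`, `reverse`,
#'   `expected_amplicon_bp`.
#' @export
coi_primers <- function() {
  path <- system.file("extdata", "coi_primers.csv", package = "igpsim",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a FASTA file
#'
#' Blank interleaved lines are tolerated; sequences are uppercased and
#' record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with `name` (header line without `>`) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- trimws(lines) != ""
  lines <- lines[keep]
  if (length(lines) == 0) abort(paste0("empty FASTA file: ", path))
  if (!startsWith(lines[1], ">")) {
    abort(paste0("malformed FASTA at line ", which(keep)[1],
                 ": expected a '>' header"))
  }
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  set <- Biostrings::readDNAStringSet(tmp)
  tibble::tibble(
    name = names(set),
    sequence = unname(toupper(as.character(set)))
  )
}

#' Reverse complement of a DNA sequence
#'
#' Involution: applying it twice returns the input. IUPAC degeneracy
#' codes are complemented according to their standard pairing.
#'
#' @param seq A single DNA string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  validate_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Predict in-silico PCR amplicon lengths
#'
#' Finds forward-primer sites on the template strand and reverse-primer
#' sites as the reverse complement of the reverse primer downstream of
#' each forward site. A product is reported for every (forward, reverse)
#' site pair whose reverse site starts at or after the forward site's
#' end; its length is counted inclusively of both primers (end of the
#' reverse site minus start of the forward site, plus one). Matching is
#' Hamming-only (no indels), with up to `max_mismatches` mismatches per
#' primer; IUPAC degeneracy in the primers is honoured.
#'
#' @param template A single DNA string, at least as long as the combined
#'   primer lengths.
#' @param pair A [primer_pair()] (or any list/one-row table with
#'   `forward` and `reverse` elements).
#' @param max_mismatches Maximum mismatches per primer site (default 0).
#' @param both_strands Also scan the reverse complement of the template
#'   (default `FALSE`: primers as printed target one strand).
#' @return Integer vector of product lengths, sorted ascending; empty if
#'   no product.
#' @export
amplicon_lengths <- function(template, pair, max_mismatches = 0,
                             both_strands = FALSE) {
  validate_dna(template)
  fwd <- toupper(pair$forward[[1]])
  rev <- toupper(pair$reverse[[1]])
  validate_dna(fwd)
  validate_dna(rev)
  template <- toupper(template)
  if (nchar(template) < nchar(fwd) + nchar(rev)) {
    abort("template is shorter than the combined primer lengths")
  }
  scan_one <- function(tmpl) {
    subj <- Biostrings::DNAString(tmpl)
    f_hits <- Biostrings::matchPattern(
      Biostrings::DNAString(fwd), subj,
      max.mismatch = max_mismatches, fixed = FALSE
    )
    r_hits <- Biostrings::matchPattern(
      Biostrings::DNAString(reverse_complement(rev)), subj,
      max.mismatch = max_mismatches, fixed = FALSE
    )
    if (length(f_hits) == 0 || length(r_hits) == 0) return(integer())
    f_start <- Biostrings::start(f_hits)
    r_start <- Biostrings::start(r_hits)
    r_end <- Biostrings::end(r_hits)
    lens <- unlist(lapply(f_start, function(fs) {
      ok <- r_start >= fs + nchar(fwd)
      r_end[ok] - fs + 1L
    }))
    as.integer(lens)
  }
  out <- scan_one(template)
  if (both_strands) {
    out <- c(out, scan_one(reverse_complement(template)))
  }
  sort(out)
}
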