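# Low-level DNA helpers shared by the scanner and the simulators.
# Sequences are plain uppercase character strings at the API surface;
# internally the scanner works on integer codes over the IUPAC alphabet.

DNA_BASES <- c("A", "C", "G", "T")

# Full IUPAC alphabet accepted in genomic input; protospacers must be ACGT.
IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

seq_to_codes <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, IUPAC_LETTERS)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort(sprintf("invalid %s character(s): %s", what,
                  paste(bad, collapse = ", ")))
  }
  codes
}

codes_to_seq <- function(codes) {
  paste(IUPAC_LETTERS[codes], collapse = "")
}

check_protospacer <- function(protospacer) {
  chars <- strsplit(toupper(protospacer), "", fixed = TRUE)[[1]]
  if (!all(chars %in% DNA_BASES)) {
    abort("protospacer must contain only A/C/G/T")
  }
  n <- length(chars)
  if (n < 17 || n > 23) {
    abort(sprintf("protospacer length must be 17-23 nt, got %d", n))
  }
  invisible(toupper(protospacer))
}

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. `R` -> `Y`).
#'
#' @param seq A DNA character string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# For a pattern character, the set of genome letters it accepts.  Pattern N
# accepts anything (including genomic ambiguity codes); other pattern
# letters accept exactly the unambiguous bases in their IUPAC set.
pam_allowed_codes <- function(pattern_char) {
  if (pattern_char == "N") return(seq_along(IUPAC_LETTERS))
  match(IUPAC_SETS[[pattern_char]], IUPAC_LETTERS)
}

check_pam_pattern <- function(pam) {
  pam <- toupper(pam)
  chars <- strsplit(pam, "", fixed = TRUE)[[1]]
  if (length(chars) != 3 || !all(chars %in% IUPAC_LETTERS)) {
    abort(sprintf("PAM pattern must be exactly 3 IUPAC characters, got '%s'",
                  pam))
  }
  pam
}

# IUPAC 3-mer pattern to a regular expression character-class string.
pam_pattern_regex <- function(pam) {
  chars <- strsplit(toupper(pam), "", fixed = TRUE)[[1]]
  paste0(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (ch == "N") "." else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Coerce a genome argument (named character vector, DNAStringSet, or a
# FASTA file path) to a named character vector of contig sequences.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome))) {
    abort("genome must be a named character vector, DNAStringSet, or FASTA path with unique contig names")
  }
  if (length(genome) == 0) abort("genome is empty")
  # FASTA descriptions: keep the first word as the contig name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}
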