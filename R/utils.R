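# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency of the simulator and
#' aligner.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, uppercase).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases, vectorised, no reversal
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# genome can be a DNAStringSet or a named character vector; normalise to
# a named character vector (uppercase)
as_genome_chr <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- genome
  } else if (is.list(genome) && !is.null(genome$genome)) {
    return(as_genome_chr(genome$genome))
  } else {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == "")) {
    stop("genome contigs must be named")
  }
  toupper(g)
}

check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGTN symbols (first offender: %s)",
                 what, x[which(bad)[1L]]))
  }
  invisible(TRUE)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be in [0, 1]", name))
  }
  invisible(TRUE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("%s must be > 0", name))
  }
  invisible(TRUE)
}

# deterministic child seeds below 2^31, derived from a user seed
derive_seed <- function(seed, index) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + 7919 * as.numeric(index)) %% 2147483647)
}

# substring of one contig, 1-based closed coordinates
contig_substr <- function(genome_chr, contig, start, end) {
  substring(genome_chr[[contig]], start, end)
}
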