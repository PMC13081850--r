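# Codon-usage utilities for codon-aware operations.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Load a codon-usage table
#'
#' @param path Tab-separated file with columns `codon`, `aa`, `freq`
#'   (relative usage; any consistent scale such as per-thousand works).
#'   `NULL` loads the packaged human table.
#' @return Data frame with columns `codon`, `aa`, `freq`, covering all 64
#'   codons of the standard code.
#' @export
load_codon_usage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_usage_human.tsv",
                        package = "oligopool", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "aa", "freq")
  if (!all(need %in% names(tab))) {
    stop("codon usage table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gc <- genetic_code()
  if (!setequal(tab$codon, names(gc))) {
    stop("codon usage table must cover all 64 codons", call. = FALSE)
  }
  bad <- tab$codon[gc[tab$codon] != tab$aa]
  if (length(bad)) {
    stop("codon/amino-acid mismatch vs the standard code: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab
}

# Named vector: amino acid -> its most frequently used codon.
top_codons <- function(usage) {
  sp <- split(usage, usage$aa)
  vapply(sp, function(d) d$codon[which.max(d$freq)], character(1))
}

#' Encode a peptide with most-frequent codons
#'
#' @param peptide Amino-acid string (single-letter codes, `*` allowed).
#' @param usage Codon-usage table from [load_codon_usage()]; default
#'   packaged human table.
#' @return DNA string of length `3 * nchar(peptide)`.
#' @export
#' @examples
#' translate_dna(encode_peptide("MG"))  # "MG"
encode_peptide <- function(peptide, usage = NULL) {
  usage <- usage %||% load_codon_usage()
  top <- top_codons(usage)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(top))
  if (length(bad)) {
    stop("unknown amino acid(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(top[aa], collapse = "")
}
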