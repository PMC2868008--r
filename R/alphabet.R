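#' Sequence alphabets
#'
#' The package works over two residue alphabets: the 4-letter DNA alphabet
#' `A,C,G,T` (with `N` as the masking/ambiguity letter) and the 20-letter
#' protein alphabet (with `X` as the masking letter). Positions whose
#' width-`w` window contains a masking letter contribute neither prior mass
#' nor likelihood: they are never selected as motif sites.
#'
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list with elements `name`, `letters`, `size`, `ambiguity`, and
#'   (DNA only) `complement`, the index permutation mapping each letter to its
#'   Watson-Crick complement.
#' @examples
#' alphabet_spec("dna")$letters
#' @export
alphabet_spec <- function(alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    list(name = "dna", letters = c("A", "C", "G", "T"), size = 4L,
         complement = c(4L, 3L, 2L, 1L), ambiguity = "N")
  } else {
    list(name = "protein",
         letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
         size = 20L, complement = NULL, ambiguity = "X")
  }
}

## Encode an uppercase residue string as 1-based letter indices, NA for the
## ambiguity letter. Errors (naming `id` and the 1-based offset) on anything
## else.
encode_residues <- function(residues, abc, id = "<sequence>") {
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, abc$letters)
  bad <- which(is.na(idx) & chars != abc$ambiguity)
  if (length(bad) > 0) {
    stop(sprintf("record '%s': residue '%s' at offset %d is not in the %s alphabet",
                 id, chars[bad[1]], bad[1], abc$name), call. = FALSE)
  }
  idx
}

decode_residues <- function(enc, abc) {
  out <- abc$letters[enc]
  out[is.na(enc)] <- abc$ambiguity
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x a character string over `A,C,G,T,N`.
#' @return The reverse-complemented string.
#' @examples revcomp_string("ACGTN")
#' @export
revcomp_string <- function(x) {
  abc <- alphabet_spec("dna")
  enc <- encode_residues(toupper(x), abc)
  decode_residues(rev(abc$complement[enc]), abc)
}
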