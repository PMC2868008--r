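#' Construct a sequence set
#'
#' A `seqset` holds an ordered collection of named sequences over a common
#' alphabet, the container for the motif-discovery input \eqn{X = \{X_1,
#' \dots, X_n\}}. Residues are folded to upper case and validated against the
#' alphabet; the ambiguity letter (`N` for DNA, `X` for protein) is kept and
#' treated as a mask.
#'
#' @param residues character vector of sequences.
#' @param ids unique sequence identifiers; defaults to names of `residues` or
#'   `seq_1`, `seq_2`, ...
#' @param alphabet `"dna"` or `"protein"`.
#' @return An object of class `seqset`: a list with `ids`, `seqs` (uppercase
#'   strings), `enc` (integer encodings, `NA` at masked residues) and
#'   `alphabet`.
#' @examples
#' x <- sequence_set(c(a = "acgt", b = "TTGACA"))
#' seq_lengths(x)
#' @export
sequence_set <- function(residues, ids = NULL, alphabet = c("dna", "protein")) {
  abc <- alphabet_spec(match.arg(alphabet))
  if (is.null(ids)) {
    ids <- names(residues)
    if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(residues))
  }
  stopifnot(length(ids) == length(residues))
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  seqs <- toupper(as.character(residues))
  enc <- mapply(encode_residues, seqs, MoreArgs = list(abc = abc),
                id = ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(list(ids = as.character(ids), seqs = unname(seqs), enc = enc,
                 alphabet = abc$name), class = "seqset")
}

#' @rdname sequence_set
#' @param x a `seqset`.
#' @export
seq_lengths <- function(x) {
  stopifnot(inherits(x, "seqset"))
  lengths(x$enc)
}

#' @export
length.seqset <- function(x) length(x$ids)

#' @export
print.seqset <- function(x, ...) {
  cat(sprintf("seqset: %d %s sequence(s), lengths %s\n", length(x$ids),
              x$alphabet, paste(range(seq_lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Record order is preserved, wrapped sequence lines are concatenated and
#' lower-case residues are folded to upper case. A residue outside the
#' alphabet (plus its ambiguity letter) is an error naming the record and
#' offset; an empty file yields an empty set with a warning.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    if (file.size(path) == 0) NULL else stop(e)
                  })
  if (is.null(set) || length(set) == 0) {
    warning("FASTA file '", path, "' contains no sequences", call. = FALSE)
    return(sequence_set(character(0), ids = character(0), alphabet = alphabet))
  }
  ids <- sub("\\s.*$", "", names(set))
  sequence_set(as.character(set), ids = ids, alphabet = alphabet)
}

#' Write a sequence set to FASTA
#'
#' @param x a `seqset`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "seqset"))
  set <- Biostrings::BStringSet(stats::setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## Concatenated layout shared by the discovery internals: global 0-based
## offsets into the single encoded vector plus, per width, the matrices of
## window letter indices on both strands.
seq_offsets <- function(seqs) {
  len <- seq_lengths(seqs)
  list(len = len, off = cumsum(c(0L, len[-length(len)])),
       total = sum(len))
}

## Per-width site layout: one row per legal start position (window fully
## inside its sequence). `valid` marks windows free of masked residues.
site_layout <- function(seqs, w, both_strands = TRUE) {
  abc <- alphabet_spec(seqs$alphabet)
  if (both_strands && is.null(abc$complement))
    stop("double-stranded mode is only defined for DNA", call. = FALSE)
  geo <- seq_offsets(seqs)
  n <- length(seqs)
  m <- pmax(geo$len - w + 1L, 0L)
  site_seq <- rep.int(seq_len(n), m)
  site_j <- unlist(lapply(m, seq_len), use.names = FALSE)     # local 1-based
  site_g <- geo$off[site_seq] + site_j                        # global 1-based
  xcat <- unlist(seqs$enc, use.names = FALSE)
  nsite <- length(site_g)
  Wf <- matrix(xcat[rep(site_g, w) + rep(0:(w - 1L), each = nsite)],
               nrow = nsite, ncol = w)
  valid <- rowSums(is.na(Wf)) == 0L
  Wr <- NULL
  if (both_strands) {
    Wr <- matrix(abc$complement[Wf[, w:1, drop = FALSE]], nrow = nsite)
  }
  list(abc = abc, n = n, w = w, len = geo$len, off = geo$off, m = m,
       xcat = xcat, site_seq = site_seq, site_j = site_j, site_g = site_g,
       nsite = nsite, Wf = Wf, Wr = Wr, valid = valid,
       both_strands = both_strands)
}
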