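#' Position-specific probability matrices
#'
#' A PSPM is the motif model \eqn{\theta}: a column-stochastic matrix
#' \eqn{f_{a,k}} giving the probability of letter `a` at motif position `k`,
#' `k = 1..w`. Rows are letters (alphabet order), columns are positions.
#'
#' @param mat numeric matrix, `size x w`, columns summing to 1 (tolerance
#'   1e-9), entries non-negative.
#' @param alphabet `"dna"` or `"protein"`.
#' @param nsites optional number of sites the motif was built from.
#' @param evalue optional motif E-value annotation.
#' @return An object of class `pspm` (a matrix with attributes).
#' @examples
#' pspm(matrix(0.25, 4, 6))
#' @export
pspm <- function(mat, alphabet = c("dna", "protein"), nsites = NULL,
                 evalue = NULL) {
  abc <- alphabet_spec(match.arg(alphabet))
  mat <- as.matrix(mat)
  if (nrow(mat) != abc$size)
    stop(sprintf("PSPM must have %d rows for the %s alphabet", abc$size,
                 abc$name), call. = FALSE)
  if (any(mat < -1e-12)) stop("PSPM entries must be non-negative", call. = FALSE)
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9))
    stop("PSPM columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")", call. = FALSE)
  rownames(mat) <- abc$letters
  colnames(mat) <- NULL
  structure(mat, class = c("pspm", "matrix"), alphabet = abc$name,
            nsites = nsites, evalue = evalue)
}

#' @export
print.pspm <- function(x, digits = 3, ...) {
  abc <- alphabet_spec(attr(x, "alphabet"))
  cons <- paste(abc$letters[apply(unclass(x), 2, which.max)], collapse = "")
  cat(sprintf("pspm: width %d (%s), consensus %s", ncol(x),
              attr(x, "alphabet"), cons))
  if (!is.null(attr(x, "nsites"))) cat(sprintf(", nsites %s", attr(x, "nsites")))
  if (!is.null(attr(x, "evalue"))) cat(sprintf(", E-value %.3g", attr(x, "evalue")))
  cat("\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Width of a motif
#'
#' @param theta a `pspm`.
#' @return The number of motif columns.
#' @export
motif_width <- function(theta) {
  stopifnot(inherits(theta, "pspm"))
  ncol(theta)
}

#' Reverse complement of a DNA motif
#'
#' @param theta a DNA `pspm`.
#' @return The `pspm` of the reverse-complement motif.
#' @export
revcomp_pspm <- function(theta) {
  stopifnot(inherits(theta, "pspm"))
  abc <- alphabet_spec(attr(theta, "alphabet"))
  if (is.null(abc$complement))
    stop("reverse complement is only defined for DNA motifs", call. = FALSE)
  m <- unclass(theta)[abc$complement, ncol(theta):1, drop = FALSE]
  pspm(m, alphabet = abc$name, nsites = attr(theta, "nsites"),
       evalue = attr(theta, "evalue"))
}

#' Starting PSPM from a subsequence
#'
#' Converts a word of the data into the "starting" motif model used to seed
#' EM: column `k` puts probability `beta` on the word's letter `k` and spreads
#' `1 - beta` evenly over the remaining letters.
#'
#' @param word character string over the alphabet (no masked letters), or an
#'   integer encoding.
#' @param beta probability assigned to the word letter (default 0.55; must be
#'   strictly between `1/size` and 1 for the start to be informative).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `pspm` of width `nchar(word)`.
#' @examples
#' subsequence_to_pspm("A")[, 1]  # 0.55, 0.15, 0.15, 0.15
#' @export
subsequence_to_pspm <- function(word, beta = 0.55,
                                alphabet = c("dna", "protein")) {
  abc <- alphabet_spec(match.arg(alphabet))
  enc <- if (is.character(word)) encode_residues(toupper(word), abc, id = word)
         else as.integer(word)
  if (anyNA(enc)) stop("starting word may not contain masked letters", call. = FALSE)
  stopifnot(beta > 0, beta <= 1)
  w <- length(enc)
  m <- matrix((1 - beta) / (abc$size - 1), nrow = abc$size, ncol = w)
  m[cbind(enc, seq_len(w))] <- beta
  pspm(m, alphabet = abc$name)
}

#' Likelihood of a site under a motif model
#'
#' The probability of the width-`w` window starting at `j` (1-based) under
#' \eqn{\theta}: the product over motif positions of \eqn{f_{x_k,k}}, with the
#' window reverse-complemented first for `strand = "-"`. Windows containing a
#' masked letter have likelihood 0.
#'
#' @param theta a `pspm`.
#' @param seq a character string or integer-encoded sequence.
#' @param j 1-based start position; the window must lie inside the sequence.
#' @param strand `"+"` or `"-"` (DNA only).
#' @return The site probability.
#' @export
site_likelihood <- function(theta, seq, j, strand = c("+", "-")) {
  strand <- match.arg(strand)
  abc <- alphabet_spec(attr(theta, "alphabet"))
  enc <- if (is.character(seq)) encode_residues(toupper(seq), abc) else as.integer(seq)
  w <- ncol(theta)
  if (j < 1 || j + w - 1 > length(enc))
    stop(sprintf("window [%d, %d] is outside the sequence (length %d)", j,
                 j + w - 1, length(enc)), call. = FALSE)
  win <- enc[j:(j + w - 1)]
  if (anyNA(win)) return(0)
  if (strand == "-") {
    if (is.null(abc$complement))
      stop("strand '-' is only defined for DNA", call. = FALSE)
    win <- rev(abc$complement[win])
  }
  prod(unclass(theta)[cbind(win, seq_len(w))])
}

## weighted letter counts c_{a,k} of an aligned site set
site_counts <- function(seqs, sites, w, weights = rep(1, nrow(sites))) {
  abc <- alphabet_spec(seqs$alphabet)
  stopifnot(nrow(sites) == length(weights))
  counts <- matrix(0, nrow = abc$size, ncol = w)
  for (r in seq_len(nrow(sites))) {
    enc <- seqs$enc[[sites$seq[r]]]
    j <- sites$pos[r]
    win <- enc[j:(j + w - 1)]
    if (!is.null(sites$strand) && sites$strand[r] == "-")
      win <- rev(abc$complement[win])
    if (anyNA(win)) stop("site window contains a masked residue", call. = FALSE)
    counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + weights[r]
  }
  counts
}

#' Weighted log-likelihood ratio of a site set
#'
#' Builds weighted letter counts \eqn{c_{a,k}} by adding each site's weight
#' \eqn{b_{i,j}} to the count of its letter at each motif column, forms
#' frequencies \eqn{f_{a,k} = c_{a,k}/N_{wt}}, and returns
#' \deqn{\sum_k \sum_a c_{a,k} \log_2 (f_{a,k} / p_a)}
#' in bits, with the convention \eqn{0 \log 0 = 0}. With unit weights this is
#' the ordinary LLR of the aligned sites. The weights come from the prior,
#' scaled per sequence so the largest prior in each sequence is 1, so
#' high-prior sites contribute more to the counts.
#'
#' @param seqs a [sequence_set()].
#' @param sites data frame with columns `seq` (index), `pos` (1-based start),
#'   and optionally `strand` (`"+"`/`"-"`).
#' @param w motif width.
#' @param bg a `background_model`; only its zero-order marginals \eqn{p_a}
#'   enter the LLR.
#' @param weights per-site weights in `(0, 1]` (default all 1).
#' @return The weighted LLR in bits.
#' @export
weighted_llr <- function(seqs, sites, w, bg,
                         weights = rep(1, nrow(sites))) {
  stopifnot(nrow(sites) >= 1, all(weights > 0), all(weights <= 1))
  counts <- site_counts(seqs, sites, w, weights)
  nwt <- sum(weights)
  if (nwt <= 0) stop("total site weight is zero", call. = FALSE)
  f <- counts / nwt
  p <- bg$p
  pos <- counts > 0
  sum(counts[pos] * log2(f[pos] / p[row(counts)[pos]]))
}

#' Information content of a motif
#'
#' Returns the maximum, over all `window` consecutive motif columns, of the
#' mean per-column information content
#' \eqn{\sum_a f_{a,k} \log_2(f_{a,k}/p_a)} in bits. Used by the evaluation
#' filter that rejects reported motifs lacking a width-6 region of mean IC of
#' at least 1 bit.
#'
#' @param theta a `pspm`.
#' @param bg a `background_model`, or `NULL` for a uniform background.
#' @param window window length; if it exceeds the motif width the whole motif
#'   is used as the window, with a warning.
#' @return Maximum mean per-column IC in bits.
#' @export
information_content <- function(theta, bg = NULL, window = ncol(theta)) {
  stopifnot(inherits(theta, "pspm"))
  abc <- alphabet_spec(attr(theta, "alphabet"))
  p <- if (is.null(bg)) rep(1 / abc$size, abc$size) else bg$p
  w <- ncol(theta)
  if (window > w) {
    warning("IC window exceeds the motif width; using the whole motif",
            call. = FALSE)
    window <- w
  }
  f <- unclass(theta)
  term <- f * log2(f / p)
  term[f == 0] <- 0
  colic <- colSums(term)
  cum <- cumsum(c(0, colic))
  max((cum[(window + 1):(w + 1)] - cum[1:(w - window + 1)]) / window)
}

#' Write a motif block (with optional site list)
#'
#' Emits a minimal text motif block: width, number of sites, E-value and the
#' letter-probability matrix (one row per motif position, 6 decimals, letters
#' in alphabet order), followed by a `SITES` section of BED-like lines
#' (`sequence id`, 0-based half-open interval, strand). [read_motif()] reads
#' it back with matrix entries reproduced to within 5e-7.
#'
#' @param motif a `pspm`.
#' @param sites optional data frame with columns `id`, `start` (0-based),
#'   `end`, `strand`.
#' @param evalue motif E-value (printed in scientific notation).
#' @param path output path (or connection).
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, sites = NULL, evalue = NULL, path, name = "motif_1") {
  stopifnot(inherits(motif, "pspm"))
  nsites <- if (is.null(sites)) attr(motif, "nsites") else nrow(sites)
  if (is.null(nsites)) nsites <- 0L
  if (is.null(evalue)) evalue <- attr(motif, "evalue")
  lines <- c(
    sprintf("MOTIF %s", name),
    sprintf("alphabet= %s width= %d nsites= %d evalue= %s",
            attr(motif, "alphabet"), ncol(motif), nsites,
            if (is.null(evalue)) "NA" else sprintf("%.6e", evalue)),
    apply(unclass(motif), 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
    "SITES")
  if (!is.null(sites) && nrow(sites) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", sites$id, as.integer(sites$start),
                              as.integer(sites$end), sites$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif block written by [write_motif()]
#'
#' @param path path to the motif file.
#' @return A `pspm` with `nsites`/`evalue` attributes and, if present, a
#'   `sites` attribute (data frame `id`, `start`, `end`, `strand`).
#' @export
read_motif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^MOTIF ", lines[1])) stop("not a motif block: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  kv <- stats::setNames(hdr[seq(2, length(hdr), 2)],
                        sub("=$", "", hdr[seq(1, length(hdr), 2)]))
  w <- as.integer(kv[["width"]])
  nsites <- as.integer(kv[["nsites"]])
  evalue <- suppressWarnings(as.numeric(kv[["evalue"]]))
  rows <- lapply(strsplit(trimws(lines[3:(2 + w)]), "\\s+"), as.numeric)
  m <- t(do.call(rbind, rows))           # letters x positions
  m <- sweep(m, 2, colSums(m), "/")      # absorb 6-decimal rounding
  out <- pspm(m, alphabet = kv[["alphabet"]], nsites = nsites,
              evalue = if (is.na(evalue)) NULL else evalue)
  site_at <- which(lines == "SITES")
  if (length(site_at) == 1 && site_at < length(lines)) {
    rows <- strsplit(lines[(site_at + 1):length(lines)], "\t")
    attr(out, "sites") <- data.frame(
      id = vapply(rows, `[[`, "", 1L),
      start = as.integer(vapply(rows, `[[`, "", 2L)),
      end = as.integer(vapply(rows, `[[`, "", 3L)),
      strand = vapply(rows, `[[`, "", 4L), stringsAsFactors = FALSE)
  }
  out
}
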