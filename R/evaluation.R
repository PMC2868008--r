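#' Scaled Euclidean distance between width-matched motifs
#'
#' \deqn{D(f, g) = \frac{1}{w} \sum_{i=1}^{w}
#'   \frac{\sqrt{\sum_a (f_{a,i} - g_{a,i})^2}}{\sqrt{2}},}
#' the per-column Euclidean distance scaled so the maximum attainable
#' distance (disjoint point-mass columns) is 1 and the minimum (identical
#' motifs) is 0.
#'
#' @param f,g `pspm`s of equal width.
#' @return The distance in `[0, 1]`.
#' @examples
#' a <- pspm(matrix(c(1, 0, 0, 0), 4, 8))
#' t_ <- pspm(matrix(c(0, 0, 0, 1), 4, 8))
#' scaled_distance(a, t_)  # 1
#' @export
scaled_distance <- function(f, g) {
  stopifnot(inherits(f, "pspm"), inherits(g, "pspm"))
  if (ncol(f) != ncol(g))
    stop("widths differ (", ncol(f), " vs ", ncol(g),
         "); use aligned_distance() for unequal widths", call. = FALSE)
  d <- unclass(f) - unclass(g)
  mean(sqrt(colSums(d^2)) / sqrt(2))
}

## distance over the overlap columns only (mean per overlap column)
overlap_distance <- function(fm, gm, offset) {
  wf <- ncol(fm); wg <- ncol(gm)
  lo <- max(1L, 1L + offset); hi <- min(wg, wf + offset)
  fcols <- (lo - offset):(hi - offset)
  gcols <- lo:hi
  d <- fm[, fcols, drop = FALSE] - gm[, gcols, drop = FALSE]
  mean(sqrt(colSums(d^2)) / sqrt(2))
}

#' Minimum scaled distance over alignments and strands
#'
#' Slides motif `f` (and, for DNA, its reverse complement) along motif `g`
#' over every offset where the overlap is at least the width of the shorter
#' motif, computing the scaled Euclidean distance over the aligned columns,
#' and returns the minimum. When `ic_filter` is on and the reported motif `f`
#' lacks a width-6 window with mean information content of at least 1 bit
#' against a uniform background, the maximum distance 1.0 is returned -- this
#' rejects low-complexity "motifs" that would otherwise align well by chance.
#'
#' @param f the reported `pspm`.
#' @param g the known/reference `pspm`.
#' @param ic_filter apply the width-6, 1-bit information-content filter to
#'   `f`?
#' @return A list of class `motif_distance`: `distance`, `offset` (position of
#'   `f` column 1 relative to `g` column 1), `strand` (`"+"` or `"-"`),
#'   `columns` (overlap length).
#' @export
aligned_distance <- function(f, g, ic_filter = TRUE) {
  stopifnot(inherits(f, "pspm"), inherits(g, "pspm"))
  abc <- alphabet_spec(attr(f, "alphabet"))
  if (ic_filter) {
    win <- min(6L, ncol(f))
    if (information_content(f, bg = NULL, window = win) < 1) {
      return(structure(list(distance = 1.0, offset = NA_integer_,
                            strand = NA_character_, columns = 0L),
                       class = "motif_distance"))
    }
  }
  wf <- ncol(f); wg <- ncol(g)
  minov <- min(wf, wg)
  cand <- list(`+` = unclass(f))
  if (!is.null(abc$complement)) cand[["-"]] <- unclass(revcomp_pspm(f))
  best <- NULL
  gm <- unclass(g)
  for (s in names(cand)) {
    fm <- cand[[s]]
    for (offset in (minov - wf):(wg - minov)) {
      d <- overlap_distance(fm, gm, offset)
      if (is.null(best) || d < best$distance) {
        best <- list(distance = d, offset = offset, strand = s,
                     columns = min(wg, wf + offset) - max(1L, 1L + offset) + 1L)
      }
    }
  }
  structure(best, class = "motif_distance")
}

#' @export
print.motif_distance <- function(x, ...) {
  cat(sprintf("motif_distance: D = %.4f (offset %s, strand %s, %d columns)\n",
              x$distance, x$offset, x$strand, x$columns))
  invisible(x)
}

#' Successful motif discovery
#'
#' A reported motif counts as a successful discovery of a known motif when
#' the minimum aligned scaled Euclidean distance (with the width-6 / 1-bit
#' information-content filter applied to the reported motif) is strictly
#' below 0.25.
#'
#' @param reported,known `pspm`s.
#' @param threshold success threshold (default 0.25, strict).
#' @return Logical.
#' @export
motif_success <- function(reported, known, threshold = 0.25) {
  aligned_distance(reported, known, ic_filter = TRUE)$distance < threshold
}

#' Average motif affinity (AMA) of a sequence
#'
#' The mean, over every legal site position (and both strands in
#' double-strand mode), of the likelihood ratio of the width-`w` window under
#' the motif versus under the background model (window probabilities chain
#' the order-`k` background conditionals within the window). An AMA of 1
#' means the sequence looks exactly like background to the motif; larger
#' values indicate binding affinity. Windows containing masked residues
#' contribute 0.
#'
#' @param theta a `pspm`.
#' @param seq a character string or a `seqset` (in which case a vector of
#'   scores is returned).
#' @param bg a `background_model`.
#' @param strand_mode `"double"` or `"single"`.
#' @return The AMA score (or vector of scores).
#' @export
ama_score <- function(theta, seq, bg, strand_mode = c("double", "single")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(theta, "pspm"))
  if (inherits(seq, "seqset")) {
    return(vapply(seq$seqs, function(s)
      ama_score(theta, s, bg, strand_mode), 0, USE.NAMES = FALSE))
  }
  abc <- alphabet_spec(attr(theta, "alphabet"))
  both <- strand_mode == "double" && !is.null(abc$complement)
  enc <- if (is.character(seq)) encode_residues(toupper(seq), abc) else as.integer(seq)
  w <- ncol(theta)
  L <- length(enc)
  if (L < w) stop("sequence shorter than the motif width", call. = FALSE)
  m <- L - w + 1L
  tot <- 0
  for (j in seq_len(m)) {
    win <- enc[j:(j + w - 1L)]
    if (anyNA(win)) next
    lbg <- bg_window_logprob(bg, win)
    tot <- tot + site_likelihood(theta, enc, j, "+") / exp(lbg)
    if (both) tot <- tot + site_likelihood(theta, enc, j, "-") / exp(lbg)
  }
  unname(tot / (m * (if (both) 2 else 1)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank);
#' the motif-quality statistic correlating motif-based affinity scores with
#' ChIP-based binding scores.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return The correlation in `[-1, 1]`, or `NA` with a warning if either
#'   vector is constant (the correlation is undefined).
#' @export
spearman_cc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: constant input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Paired sign test
#'
#' Two-sided exact binomial test that wins and losses (ties excluded
#' beforehand) are equally likely; used to decide whether one motif-discovery
#' configuration beats another over repeated paired samples.
#'
#' @param wins,losses non-negative counts, `wins + losses >= 1`.
#' @return The two-sided p-value (capped at 1).
#' @examples
#' sign_test(10, 0)  # 2 * 0.5^10
#' @export
sign_test <- function(wins, losses) {
  stopifnot(wins >= 0, losses >= 0, wins + losses >= 1)
  min(1, stats::binom.test(wins, wins + losses, p = 0.5,
                           alternative = "two.sided")$p.value)
}
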