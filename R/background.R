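#' Background Markov models
#'
#' An order-`k` Markov background model stores, for every word length
#' `1..k+1`, the marginal probability of each word; conditional letter
#' probabilities are derived by normalizing within each length-`k` context.
#' The zero-order marginals \eqn{p_a} are what the motif log-likelihood ratio
#' is computed against; the full-order conditionals are used for
#' sequence-level null likelihoods (E-step denominators, AMA window
#' probabilities).
#'
#' @name background
NULL

new_background <- function(marginal, alphabet) {
  abc <- alphabet_spec(alphabet)
  order <- length(marginal) - 1L
  cond <- vector("list", length(marginal))
  for (k in seq_along(marginal)) {
    pk <- marginal[[k]]
    if (k == 1L) {
      cond[[k]] <- pk / sum(pk)
    } else {
      mat <- matrix(pk, nrow = abc$size)           # rows: last letter
      tot <- rep(colSums(mat), each = abc$size)
      cond[[k]] <- as.numeric(mat / tot)
    }
  }
  p <- cond[[1L]]
  names(p) <- abc$letters
  if (any(p <= 0)) stop("zero-order background probabilities must be positive",
                        call. = FALSE)
  structure(list(order = order, marginal = marginal, cond = cond, p = p,
                 alphabet = abc$name), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: order %d (%s); p = [%s]\n", x$order,
              x$alphabet, paste(sprintf("%s %.3f", names(x$p), x$p),
                                collapse = ", ")))
  invisible(x)
}

word_index <- function(letters_mat, size) {
  ## code of each row of an integer letter matrix, columns = word positions
  k <- ncol(letters_mat)
  idx <- letters_mat[, 1L]
  if (k > 1L) for (d in 2:k) idx <- (idx - 1L) * size + letters_mat[, d]
  idx
}

all_words <- function(k, abc) {
  grid <- do.call(expand.grid, rep(list(abc$letters), k))[, k:1, drop = FALSE]
  apply(grid, 1L, paste, collapse = "")
}

#' Read a background model file
#'
#' The file lists one word and one probability per line ("`k`-mer
#' probability"), for every word of every length `1..order+1` (orders `0..K`);
#' `#` comments and blank lines are ignored. Within an order, a missing word
#' is an error, and probabilities not summing to ~1 are renormalized with a
#' warning. Conditional probabilities are obtained by normalizing within each
#' context.
#'
#' @param path path to the background file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `background_model`.
#' @export
read_background <- function(path, alphabet = c("dna", "protein")) {
  abc <- alphabet_spec(match.arg(alphabet))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty background file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\\s+")
  words <- toupper(vapply(parts, `[[`, "", 1L))
  probs <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(probs)) stop("malformed probability in background file", call. = FALSE)
  ks <- nchar(words)
  marginal <- vector("list", max(ks))
  for (k in seq_len(max(ks))) {
    expect <- all_words(k, abc)
    have <- words[ks == k]
    pk <- probs[ks == k][match(expect, have)]
    if (anyNA(pk)) {
      stop(sprintf("background file is missing %d-mer '%s' (order %d)",
                   k, expect[which(is.na(pk))[1L]], k - 1L), call. = FALSE)
    }
    s <- sum(pk)
    if (abs(s - 1) > 1e-3) {
      warning(sprintf("order-%d background probabilities sum to %.6f; renormalizing",
                      k - 1L, s), call. = FALSE)
    }
    marginal[[k]] <- stats::setNames(pk / s, expect)
  }
  new_background(marginal, abc$name)
}

#' Write a background model file
#'
#' @param bg a `background_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_model"))
  out <- unlist(lapply(bg$marginal, function(pk) {
    sprintf("%s %.10g", names(pk), pk)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Estimate a background model from sequences
#'
#' Counts words of lengths `1..order+1` over the sequences (skipping windows
#' with masked residues). In double-stranded DNA mode both strands are
#' counted, making the null strand-symmetric. A pseudocount of
#' `pseudocount * total / cells` is added to every cell of each order so no
#' probability is zero.
#'
#' @param seqs a [sequence_set()].
#' @param order Markov order, >= 0.
#' @param double_strand count both strands (DNA only)?
#' @param pseudocount pseudocount scale (default 0.01).
#' @return A `background_model`.
#' @examples
#' estimate_background(sequence_set("ACGT"), 0)$p
#' @export
estimate_background <- function(seqs, order = 0L, double_strand = TRUE,
                                pseudocount = 0.01) {
  stopifnot(inherits(seqs, "seqset"), order >= 0)
  abc <- alphabet_spec(seqs$alphabet)
  if (is.null(abc$complement)) double_strand <- FALSE
  if (sum(seq_lengths(seqs)) == 0)
    stop("cannot estimate a background from an empty sequence set", call. = FALSE)
  enc <- seqs$enc
  if (double_strand) enc <- c(enc, lapply(enc, function(e) rev(abc$complement[e])))
  marginal <- vector("list", order + 1L)
  for (k in seq_len(order + 1L)) {
    counts <- numeric(abc$size^k)
    total <- 0
    for (e in enc) {
      L <- length(e)
      if (L < k) next
      nwin <- L - k + 1L
      Wm <- matrix(e[rep(seq_len(nwin), k) + rep(0:(k - 1L), each = nwin)],
                   nrow = nwin)
      ok <- rowSums(is.na(Wm)) == 0L
      if (!any(ok)) next
      idx <- word_index(Wm[ok, , drop = FALSE], abc$size)
      tab <- tabulate(idx, nbins = abc$size^k)
      counts <- counts + tab
      total <- total + sum(tab)
    }
    if (k > 1 && total > 0 && mean(counts == 0) > 0.5) {
      warning(sprintf("order %d: more than half of all %d-mers are unseen; pseudocounts dominate",
                      k - 1L, k), call. = FALSE)
    }
    counts <- counts + pseudocount * max(total, 1) / length(counts)
    marginal[[k]] <- stats::setNames(counts / sum(counts), all_words(k, abc))
  }
  new_background(marginal, abc$name)
}

## log P(letter at each global position | preceding context within its
## sequence), under the full-order conditionals. NA (masked) positions get 0;
## contexts containing a mask are truncated to start after it.
bg_position_logprob <- function(bg, seqs) {
  abc <- alphabet_spec(seqs$alphabet)
  K <- bg$order
  out <- vector("list", length(seqs$enc))
  for (i in seq_along(seqs$enc)) {
    e <- seqs$enc[[i]]
    L <- length(e)
    lp <- numeric(L)
    for (t in seq_len(L)) {
      if (is.na(e[t])) next
      k <- min(K, t - 1L)
      while (k > 0L && anyNA(e[(t - k):(t - 1L)])) k <- k - 1L
      word <- e[(t - k):t]
      idx <- word[1L]
      if (k > 0L) for (d in seq_len(k)) idx <- (idx - 1L) * abc$size + word[d + 1L]
      lp[t] <- log(bg$cond[[k + 1L]][idx])
    }
    out[[i]] <- lp
  }
  unlist(out, use.names = FALSE)
}

## log background probability of a window of encoded letters, chaining the
## conditionals within the window (context capped at the window start).
bg_window_logprob <- function(bg, window_enc) {
  abc <- alphabet_spec(bg$alphabet)
  if (anyNA(window_enc)) return(-Inf)
  lp <- 0
  for (t in seq_along(window_enc)) {
    k <- min(bg$order, t - 1L)
    word <- window_enc[(t - k):t]
    idx <- word[1L]
    if (k > 0L) for (d in seq_len(k)) idx <- (idx - 1L) * abc$size + word[d + 1L]
    lp <- lp + log(bg$cond[[k + 1L]][idx])
  }
  lp
}

#' Uniform background model
#'
#' @param alphabet `"dna"` or `"protein"`.
#' @param order Markov order (all conditionals uniform).
#' @return A `background_model` with all probabilities equal.
#' @export
uniform_background <- function(alphabet = c("dna", "protein"), order = 0L) {
  abc <- alphabet_spec(match.arg(alphabet))
  marginal <- lapply(seq_len(order + 1L), function(k) {
    stats::setNames(rep(1 / abc$size^k, abc$size^k), all_words(k, abc))
  })
  new_background(marginal, abc$name)
}
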