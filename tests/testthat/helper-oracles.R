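# Independent reference implementations used as oracles. These deliberately
# use naive loops and enumerate exhaustively; they must stay independent of
# the package internals they check.

uniform_bg <- uniform_background("dna")

random_pspm <- function(w, alpha = 1) {
  m <- matrix(rgamma(4 * w, shape = alpha), nrow = 4)
  pspm(sweep(m, 2, colSums(m), "/"))
}

## tail probability of the column LLR by summing over all 4^t ordered columns
brute_column_pvalue <- function(counts, t, p) {
  obs <- sum(ifelse(counts == 0, 0, counts * log2((counts / t) / p)))
  cols <- as.matrix(expand.grid(rep(list(1:4), t)))
  tot <- 0
  for (r in seq_len(nrow(cols))) {
    cnt <- tabulate(cols[r, ], 4)
    llr <- sum(ifelse(cnt == 0, 0, cnt * log2((cnt / t) / p)))
    if (llr >= obs - 1e-9) tot <- tot + prod(p[cols[r, ]])
  }
  tot
}

## every composition of t into 4 parts, by brute force
all_count_vectors <- function(t) {
  g <- expand.grid(a = 0:t, c = 0:t, g = 0:t)
  g <- g[rowSums(g) <= t, ]
  cbind(g$a, g$c, g$g, t - rowSums(g))
}

## minimum scaled distance by direct loops over strands and offsets
brute_aligned_distance <- function(f, g) {
  fm <- unclass(f); gm <- unclass(g)
  comp <- c(4, 3, 2, 1)
  variants <- list(fm, fm[comp, ncol(fm):1, drop = FALSE])
  wf <- ncol(fm); wg <- ncol(gm); minov <- min(wf, wg)
  best <- Inf
  for (v in variants) {
    for (off in -(wf - 1):(wg - 1)) {
      cols <- 0
      tot <- 0
      for (k in 1:wf) {
        gk <- k + off
        if (gk >= 1 && gk <= wg) {
          tot <- tot + sqrt(sum((v[, k] - gm[, gk])^2)) / sqrt(2)
          cols <- cols + 1
        }
      }
      if (cols >= minov) best <- min(best, tot / cols)
    }
  }
  best
}

## rank Pearson correlation with midranks, from first principles
brute_rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## reference phase 1: slow direct implementation for tiny fixtures
reference_phase1 <- function(seqs, prior, bg, w, model, beta = 0.55,
                             t_schedule = NULL, both = FALSE) {
  n <- length(seqs)
  len <- seq_lengths(seqs)
  weights <- lapply(seq_len(n), function(i) {
    pr <- prior[[i]]
    if (max(pr) > 0) pr / max(pr) else pr
  })
  if (is.null(t_schedule))
    t_schedule <- if (model == "oops") n else
      sort(unique(pmin(c(2^(1:10), n), n)))
  best <- list()
  for (wi in seq_len(n)) for (wj in seq_len(len[wi] - w + 1)) {
    word <- substr(seqs$seqs[wi], wj, wj + w - 1)
    th <- subsequence_to_pspm(word, beta = beta)
    ## best site per sequence by likelihood x prior
    sel <- list()
    for (i in seq_len(n)) {
      m <- len[i] - w + 1
      post <- rep(-1, m * (1 + both))
      for (j in seq_len(m)) {
        post[j] <- site_likelihood(th, seqs$seqs[i], j, "+") * prior[[i]][j]
        if (both) post[m + j] <- site_likelihood(th, seqs$seqs[i], j, "-") *
            prior[[i]][j]
      }
      k <- which.max(post)   # ties: smallest index, '+' block first
      if (post[k] <= 0) next
      sel[[length(sel) + 1]] <- list(
        seq = i, pos = if (k > m) k - m else k,
        strand = if (k > m) "-" else "+", post = post[k],
        b = weights[[i]][if (k > m) k - m else k])
    }
    if (length(sel) == 0) next
    posts <- vapply(sel, `[[`, 0, "post")
    ord <- if (model == "oops") seq_along(sel) else order(-posts)
    for (t in t_schedule) {
      if (model == "oops") t <- length(sel)
      if (t > length(sel)) next
      take <- sel[ord[seq_len(t)]]
      sites <- data.frame(seq = vapply(take, `[[`, 0, "seq"),
                          pos = vapply(take, `[[`, 0, "pos"),
                          strand = vapply(take, `[[`, "", "strand"))
      sc <- weighted_llr(seqs, sites, w, bg,
                         weights = vapply(take, `[[`, 0, "b"))
      key <- as.character(t)
      if (is.null(best[[key]]) || sc > best[[key]]$score + 1e-12) {
        best[[key]] <- list(word = word, score = sc, t = t, sites = sites)
      }
      if (model == "oops") break
    }
  }
  best
}

revcomp_seqset <- function(seqs) {
  sequence_set(vapply(seqs$seqs, revcomp_string, ""), ids = seqs$ids)
}
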