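## ---- column-LLR null distributions -------------------------------------
##
## The significance of a motif is based on the LLR of each aligned column of
## its sites. Under the null, a column is `nsites` i.i.d. draws from the
## zero-order background p_a; the LLR of a composition (c_1..c_A) is
## sum_a c_a log2((c_a/n)/p_a). For moderate nsites the exact distribution is
## obtained by enumerating letter compositions (multinomial tail); for large
## nsites the distribution is accumulated on a discretized score lattice.

.llr_cache <- new.env(parent = emptyenv())

composition_matrix <- function(t, A) {
  ## all length-A non-negative integer compositions of t, one per row
  if (A == 1) return(matrix(t, 1, 1))
  if (A == 4) {  # vectorized fast path for DNA
    c1 <- 0:t
    n1 <- t - c1 + 1L
    c1a <- rep.int(c1, n1)
    c2a <- sequence(n1) - 1L
    n2 <- t - c1a - c2a + 1L
    c1b <- rep.int(c1a, n2)
    c2b <- rep.int(c2a, n2)
    c3b <- sequence(n2) - 1L
    return(cbind(c1b, c2b, c3b, t - c1b - c2b - c3b, deparse.level = 0))
  }
  first <- 0:t
  sub <- lapply(first, function(c1) {
    m <- composition_matrix(t - c1, A - 1L)
    cbind(rep.int(c1, nrow(m)), m)
  })
  do.call(rbind, sub)
}

comp_llr <- function(comp, t, p) {
  term <- comp * log2(sweep(comp / t, 2, p, "/"))
  term[comp == 0] <- 0
  rowSums(term)
}

llr_dist_enum <- function(t, p) {
  comp <- composition_matrix(t, length(p))
  llr <- comp_llr(comp, t, p)
  logprob <- lgamma(t + 1) - rowSums(lgamma(comp + 1)) +
    comp %*% log(p)
  o <- order(llr, decreasing = TRUE)
  llr <- llr[o]
  prob <- exp(logprob[o])
  tail <- cumsum(prob)
  first <- which(!duplicated(round(llr, 12)))
  last <- c(first[-1] - 1L, length(llr))
  list(llr = llr[first], tail = tail[last])
}

llr_dist_lattice <- function(t, p, nbins = 2048L) {
  ## DP over letters; state = (sites assigned, discretized LLR so far).
  A <- length(p)
  score_of <- function(c, pa) ifelse(c == 0, 0, c * log2((c / t) / pa))
  lo <- sum(vapply(p, function(pa) min(score_of(0:t, pa)), 0))
  hi <- t * log2(1 / min(p))
  delta <- (hi - lo) / (nbins - 1L)
  bin_of <- function(s) pmin(nbins, pmax(1L, as.integer(round((s - lo) / delta)) + 1L))
  dp <- matrix(0, nrow = t + 1L, ncol = nbins)   # rows: sites assigned (0..t)
  dp[1L, bin_of(0)] <- 1
  for (a in seq_len(A - 1L)) {
    new <- matrix(0, nrow = t + 1L, ncol = nbins)
    for (cc in 0:t) {
      sc <- score_of(cc, p[a])
      shift <- as.integer(round(sc / delta))
      jmax <- t - cc
      rows <- 1:(jmax + 1L)
      wt <- exp(lchoose(t - (rows - 1L), cc) + cc * log(p[a]))
      s1 <- max(1L, 1L - shift)
      s2 <- min(nbins, nbins - shift)
      if (s2 < s1) next
      src <- s1:s2
      block <- dp[rows, src, drop = FALSE] * wt
      if (any(block > 0))
        new[rows + cc, src + shift] <- new[rows + cc, src + shift] + block
    }
    dp <- new
  }
  ## last letter takes the remainder
  final <- numeric(nbins)
  for (j in 0:t) {
    cc <- t - j
    rowv <- dp[j + 1L, ]
    if (all(rowv == 0)) next
    sc <- score_of(cc, p[A])
    shift <- as.integer(round(sc / delta))
    s1 <- max(1L, 1L - shift)
    s2 <- min(nbins, nbins - shift)
    if (s2 < s1) next
    src <- s1:s2
    final[src + shift] <- final[src + shift] + rowv[src] * exp(cc * log(p[A]))
  }
  llr <- lo + (seq_len(nbins) - 1L) * delta
  keep <- final > 0
  llr <- rev(llr[keep])
  tail <- cumsum(rev(final[keep]))
  list(llr = llr, tail = pmin(tail, 1))
}

llr_column_distribution <- function(nsites, p, exact_limit = 200L) {
  key <- sprintf("%d|%s", nsites, paste(signif(p, 12), collapse = ","))
  hit <- .llr_cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- length(p)
  ncomp <- choose(nsites + A - 1, A - 1)
  d <- if (nsites <= exact_limit && ncomp <= 3e6) llr_dist_enum(nsites, p)
       else llr_dist_lattice(nsites, p)
  .llr_cache[[key]] <- d
  d
}

#' P-value of a column log-likelihood ratio
#'
#' Computes \eqn{\Pr(\mathrm{LLR} \ge \mathrm{observed})} for one aligned
#' motif column of `nsites` letters under the null that the column is
#' `nsites` i.i.d. draws from the zero-order background \eqn{p_a}
#' (the Hertz-Stormo column significance). Exact multinomial-composition
#' enumeration is used for `nsites <= 200`; above that the distribution is
#' accumulated on a discretized score lattice (2048 bins).
#'
#' @param counts integer letter counts of the column (length = alphabet size,
#'   summing to `nsites`).
#' @param nsites number of sites in the column.
#' @param bg a `background_model` (zero-order marginals are used).
#' @param log_p return the natural log of the p-value?
#' @return The (possibly log) p-value; `nsites = 0` gives 1.
#' @examples
#' bgu <- uniform_background()
#' column_pvalue(c(2, 0, 0, 0), 2, bgu)  # 0.25
#' @export
column_pvalue <- function(counts, nsites, bg, log_p = FALSE) {
  stopifnot(sum(counts) == nsites)
  if (nsites == 0) return(if (log_p) 0 else 1)
  p <- bg$p
  obs <- sum(ifelse(counts == 0, 0, counts * log2((counts / nsites) / p)))
  d <- llr_column_distribution(nsites, p)
  ## d$llr is decreasing; tail[k] = P(LLR >= llr[k])
  k <- findInterval(-(obs - 1e-9), -d$llr)   # last llr >= obs - tol
  pv <- if (k <= 0) d$tail[1] else d$tail[k]
  pv <- min(max(pv, 0), 1)
  if (log_p) log(pv) else pv
}

## log of P(prod of k uniforms <= exp(logp)) = logp + log(sum (−logp)^i / i!)
log_product_tail <- function(logp, k) {
  if (k == 0 || logp >= 0) return(0)
  i <- 0:(k - 1L)
  lx <- log(-logp)
  terms <- i * lx - lgamma(i + 1)
  m <- max(terms)
  min(0, logp + m + log(sum(exp(terms - m))))
}

#' P-value of a product of p-values
#'
#' Given `k` independent p-values with product \eqn{\rho}, the probability
#' that a product of `k` independent uniforms is at most \eqn{\rho} is
#' \deqn{\rho \sum_{i=0}^{k-1} \frac{(\ln 1/\rho)^i}{i!},}
#' computed in log space. This converts the product of per-column LLR
#' p-values into a single motif p-value.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @param log_p return the natural log of the result?
#' @return The (possibly log) p-value of the product; an empty input gives 1.
#' @examples
#' product_pvalue(c(0.01, 0.01))  # 1e-4 * (1 + log(1e4))
#' @export
product_pvalue <- function(pvalues, log_p = FALSE) {
  k <- length(pvalues)
  if (k == 0) return(if (log_p) 0 else 1)
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  lp <- log_product_tail(sum(log(pvalues)), k)
  if (log_p) lp else exp(lp)
}

## log p-value of one column given its counts, via the cached distribution
column_logp <- function(counts, nsites, p) {
  obs <- sum(ifelse(counts == 0, 0, counts * log2((counts / nsites) / p)))
  d <- llr_column_distribution(nsites, p)
  k <- findInterval(-(obs - 1e-9), -d$llr)
  log(if (k <= 0) d$tail[1] else d$tail[k])
}

## log10 E-values of every prefix of an ordered ZOOPS site list (or of the
## full OOPS set), computed incrementally: identical to calling
## motif_evalue() on each prefix.
prefix_log10_evalues <- function(seqs, best, w, bg, model, strand_mode,
                                 tmin = 2L) {
  n <- length(seqs)
  s <- if (strand_mode == "double") 2 else 1
  m <- pmax(seq_lengths(seqs) - w + 1L, 0L)
  p <- bg$p
  tmax <- nrow(best)
  tmin <- min(tmin, tmax)
  counts <- matrix(0, nrow = length(p), ncol = w)
  log_npos <- 0
  out <- rep(NA_real_, tmax)
  abc <- alphabet_spec(seqs$alphabet)
  for (t in seq_len(tmax)) {
    enc <- seqs$enc[[best$seq[t]]]
    j <- best$pos[t]
    win <- enc[j:(j + w - 1L)]
    if (best$strand[t] == "-") win <- rev(abc$complement[win])
    counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
    log_npos <- log_npos + log(s * m[best$seq[t]])
    if (t < tmin) next
    colp <- vapply(seq_len(w), function(k) column_logp(counts[, k], t, p), 0)
    log_pv <- log_product_tail(sum(colp), w)
    log_nways <- if (model == "oops") sum(log(s * m)) else lchoose(n, t) + log_npos
    out[t] <- (log_pv + log_nways) / log(10)
  }
  out
}

#' E-value of a motif site alignment
#'
#' Scores a set of aligned sites: per-column Hertz-Stormo p-values are
#' multiplied, the p-value of the product is computed, and the result is
#' multiplied by the number of possible ways to place that many sites in the
#' sequence set -- for ZOOPS with `t` sites, \eqn{\binom{n}{t} \prod_{i \in
#' \mathrm{chosen}} (s\, m_i)}; for OOPS, \eqn{\prod_i (s\, m_i)} -- with `s`
#' the number of strands searched and \eqn{m_i = L_i - w + 1}. All
#' computation is in log space.
#'
#' @param seqs a [sequence_set()].
#' @param sites data frame with columns `seq`, `pos`, and optionally `strand`.
#' @param w motif width.
#' @param bg a `background_model`.
#' @param model `"zoops"` or `"oops"`.
#' @param strand_mode `"double"` or `"single"`.
#' @return A list with `log10_evalue`, `evalue`, `log_pvalue` (natural log of
#'   the motif p-value) and `column_pvalues`.
#' @export
motif_evalue <- function(seqs, sites, w, bg, model = c("zoops", "oops"),
                         strand_mode = c("double", "single")) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  t <- nrow(sites)
  stopifnot(t >= 1)
  counts <- site_counts(seqs, sites, w)
  colp <- vapply(seq_len(w), function(k)
    column_pvalue(counts[, k], t, bg, log_p = TRUE), 0)
  log_pv <- log_product_tail(sum(colp), w)
  s <- if (strand_mode == "double") 2 else 1
  m <- pmax(seq_lengths(seqs) - w + 1L, 0L)
  log_nways <- if (model == "oops") sum(log(s * m))
               else lchoose(length(seqs), t) + sum(log(s * m[sites$seq]))
  log10_e <- (log_pv + log_nways) / log(10)
  list(log10_evalue = log10_e, evalue = 10^min(log10_e, 300),
       log_pvalue = log_pv, column_pvalues = exp(colp))
}
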