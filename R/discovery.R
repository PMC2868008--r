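#' Phase I: starting-point search
#'
#' Converts every mask-free subsequence of the data into a starting motif
#' model (probability `beta` on the word letter) and, for each, scores every
#' legal site by its likelihood under that model times its positional prior.
#' Under OOPS the best site per sequence is kept and the full set scored;
#' under ZOOPS the per-sequence best sites are ranked by posterior and the
#' top-`t` prefixes scored for each `t` in the schedule. Site sets are scored
#' by the weighted LLR, the per-site weights being the priors scaled so the
#' largest prior in each sequence is 1. The top-scoring starting point per
#' `t` is returned.
#'
#' @param seqs a [sequence_set()].
#' @param psp a `psp` (renormalized internally to width `w`).
#' @param bg a `background_model`.
#' @param w motif width.
#' @param model `"zoops"` or `"oops"`.
#' @param strand_mode `"double"` or `"single"`.
#' @param erasure optional erasure weights from [new_erasure()].
#' @param beta starting-PSPM letter probability (default 0.55).
#' @param t_schedule site-count schedule for ZOOPS; defaults to powers of two
#'   capped at `n`, with `n` always included. OOPS always uses `t = n`.
#' @return A list of candidate starting points, each of class
#'   `candidate_start`: `word` (source subsequence), `seq`/`pos` (its
#'   location), `w`, `t` (scheduled site count), `nsites` (sites actually
#'   scored), `score` (weighted LLR, bits), `theta0` (starting `pspm`).
#' @export
phase1_search <- function(seqs, psp, bg, w, model = c("zoops", "oops"),
                          strand_mode = c("double", "single"), erasure = NULL,
                          beta = 0.55, t_schedule = NULL) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  abc <- alphabet_spec(seqs$alphabet)
  both <- strand_mode == "double"
  geo <- seq_offsets(seqs)
  n <- length(seqs)
  eff <- effective_site_prior(seqs, psp, w, strand_mode, model, erasure)
  if (all(eff$prior == 0))
    stop("no legal sites: all positional priors are zero", call. = FALSE)
  ## per-sequence weight normalization: largest prior in each sequence is 1
  wt <- numeric(geo$total)
  for (i in seq_len(n)) {
    sel <- (geo$off[i] + 1L):(geo$off[i] + geo$len[i])
    mx <- max(eff$prior[sel])
    if (mx > 0) wt[sel] <- eff$prior[sel] / mx
  }
  if (is.null(t_schedule)) {
    t_schedule <- if (model == "oops") n else default_t_schedule(n)
  }
  t_schedule <- sort(unique(as.integer(t_schedule)))
  if (model == "oops") t_schedule <- n
  res <- cpp_phase1(unlist(seqs$enc, use.names = FALSE), geo$off, geo$len,
                    as.integer(w), abc$size, eff$prior, wt, unname(bg$p),
                    beta, model == "oops", t_schedule, both,
                    if (is.null(abc$complement)) integer(0) else abc$complement)
  out <- list()
  for (k in seq_along(res$t)) {
    if (is.na(res$word_g[k])) next
    g <- res$word_g[k]
    i <- findInterval(g, geo$off + 1L)
    j <- g - geo$off[i]
    word <- substr(seqs$seqs[i], j, j + w - 1L)
    out[[length(out) + 1L]] <- structure(
      list(word = word, seq = i, pos = j, w = w, t = res$t[k],
           nsites = res$nsites[k], score = res$score[k],
           theta0 = subsequence_to_pspm(word, beta = beta,
                                        alphabet = seqs$alphabet)),
      class = "candidate_start")
  }
  out
}

#' @export
print.candidate_start <- function(x, ...) {
  cat(sprintf("candidate_start: word %s (seq %d pos %d), w=%d t=%d, weighted LLR %.2f bits\n",
              x$word, x$seq, x$pos, x$w, x$t, x$score))
  invisible(x)
}

#' Erasure weights for multiple-motif discovery
#'
#' After a motif is reported its sites are "probabilistically erased": each
#' position's retention weight is multiplied by \eqn{\prod_d (1 - Z_{i,j-d})}
#' over the sites of the reported motif that cover it, so positions certainly
#' inside a reported site can no longer contribute prior mass to later
#' motifs. Weights start at 1 and are non-increasing across discoveries.
#'
#' @param seqs a [sequence_set()].
#' @return An `erasure` object (retention weight per position, all 1).
#' @export
new_erasure <- function(seqs) {
  geo <- seq_offsets(seqs)
  structure(list(u = rep(1, geo$total), off = geo$off, len = geo$len),
            class = "erasure")
}

#' @rdname new_erasure
#' @param erasure an `erasure` object.
#' @param zmat the final `zmatrix` of the reported motif.
#' @return The updated `erasure`.
#' @export
erase_motif <- function(erasure, zmat) {
  stopifnot(inherits(erasure, "erasure"), inherits(zmat, "zmatrix"))
  w <- zmat$w
  zs <- zmat$zf
  if (!is.null(zmat$zr)) zs <- zs + zmat$zr
  ## z mass at each global start position
  zg <- numeric(length(erasure$u))
  g <- erasure$off[zmat$site_seq] + zmat$site_j
  zg[g] <- zs
  u <- erasure$u
  for (i in seq_along(erasure$len)) {
    span <- (erasure$off[i] + 1L):(erasure$off[i] + erasure$len[i])
    zi <- zg[span]
    ui <- u[span]
    for (d in 0:(w - 1L)) {
      shifted <- c(rep(0, d), zi)[seq_along(zi)]
      ui <- ui * pmax(0, 1 - shifted)
    }
    u[span] <- ui
  }
  erasure$u <- u
  erasure
}

#' Select the sites of a candidate motif
#'
#' The sites of a candidate motif are the positions with the largest final
#' posterior probabilities: under OOPS the argmax per sequence (ties broken
#' toward the smallest position, forward strand first); under ZOOPS the
#' per-sequence best sites sorted by decreasing posterior (at most one site
#' per sequence), from which every prefix of length `2..n` is a candidate
#' site set -- the motif finally reported is the prefix with the smallest
#' E-value.
#'
#' @param zmat a `zmatrix`.
#' @param model `"zoops"` or `"oops"`.
#' @return For OOPS, a list with one data frame of sites (`seq`, `pos`,
#'   `strand`, `z`); for ZOOPS, a list of prefix data frames in increasing
#'   prefix length.
#' @export
ranked_sites <- function(zmat, model) {
  z <- zmat$zf
  strand <- rep("+", length(z))
  if (!is.null(zmat$zr)) {
    take_rev <- zmat$zr > zmat$zf          # strict: '+' wins ties
    z <- ifelse(take_rev, zmat$zr, zmat$zf)
    strand[take_rev] <- "-"
  }
  ## per-sequence best, ties toward smallest j then '+' (site order is
  ## (seq, j) with '+' preferred already)
  best <- data.frame(seq = integer(0), pos = integer(0), strand = character(0),
                     z = numeric(0))
  o <- order(zmat$site_seq, -z, zmat$site_j)
  first <- o[!duplicated(zmat$site_seq[o])]
  best <- data.frame(seq = zmat$site_seq[first], pos = zmat$site_j[first],
                     strand = strand[first], z = z[first],
                     stringsAsFactors = FALSE)
  best <- best[best$z > 0, , drop = FALSE]
  if (model == "oops") {
    best <- best[order(best$seq), , drop = FALSE]
  } else {
    best <- best[order(-best$z, best$seq, best$pos), , drop = FALSE]
  }
  rownames(best) <- NULL
  best
}

select_sites <- function(zmat, model = c("zoops", "oops")) {
  model <- match.arg(model)
  stopifnot(inherits(zmat, "zmatrix"))
  best <- ranked_sites(zmat, model)
  if (model == "oops") return(list(best))
  tmax <- nrow(best)
  tmin <- min(2L, tmax)
  lapply(tmin:tmax, function(t) best[seq_len(t), , drop = FALSE])
}

## ZOOPS site-count schedule: powers of two capped at n, n always included
default_t_schedule <- function(n) {
  ts <- 2^seq_len(max(1, floor(log2(max(n, 2)))))
  sort(unique(pmin(c(ts, n), n)))
}

#' Discover motifs
#'
#' The full three-phase search: for every width in `minw..maxw` the prior is
#' renormalized to that width and starting points found (phase I); EM is run
#' from the best starting point for each candidate site count (phase II); the
#' converged candidates are scored by E-value over their best site sets
#' (phase III), and the candidate with the smallest E-value is reported. Its
#' sites are then probabilistically erased and the search repeated for the
#' next motif. The procedure is deterministic given its inputs: ties are
#' broken toward the smaller width, smaller site count, and earlier sequence
#' position.
#'
#' @param seqs a [sequence_set()].
#' @param psp optional `psp`; when `NULL` the uniform prior is used (this is
#'   exactly equivalent to supplying [make_uniform_psp()] output).
#' @param bg optional `background_model`; defaults to a zero-order model
#'   estimated from the sequences.
#' @param model `"zoops"` or `"oops"`.
#' @param minw,maxw inclusive motif width range.
#' @param nmotifs number of motifs to report.
#' @param strand_mode `"double"` (sites on either DNA strand) or `"single"`.
#' @param beta starting-PSPM letter probability.
#' @param max_iter,tol EM controls (see [run_em()]).
#' @param pseudocount M-step Dirichlet scale.
#' @param t_schedule optional ZOOPS site-count schedule.
#' @param seed unused; the search is deterministic. Accepted so callers can
#'   treat all entry points uniformly.
#' @return An object of class `motif_discovery`: a list with `motifs` (each
#'   having `pspm`, `sites` -- a BED-like data frame with 0-based half-open
#'   intervals --, `width`, `nsites`, `log10_evalue`, `evalue`, `model`,
#'   `em_trace`, `start`), and the call settings.
#' @export
discover_motifs <- function(seqs, psp = NULL, bg = NULL,
                            model = c("zoops", "oops"), minw = 7L, maxw = 12L,
                            nmotifs = 1L, strand_mode = c("double", "single"),
                            beta = 0.55, max_iter = 50L, tol = 1e-3,
                            pseudocount = 0.01, t_schedule = NULL, seed = NULL) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(seqs, "seqset"))
  if (minw > maxw) stop("empty width range: minw > maxw", call. = FALSE)
  n <- length(seqs)
  if (is.null(bg)) bg <- estimate_background(seqs, 0L,
                                             double_strand = strand_mode == "double")
  if (is.null(psp)) psp <- make_uniform_psp(seqs, minw, model = model,
                                            strand_mode = strand_mode)
  erasure <- new_erasure(seqs)
  motifs <- list()
  for (round in seq_len(nmotifs)) {
    best <- NULL
    for (w in minw:maxw) {
      if (any(seq_lengths(seqs) < w)) next
      cands <- phase1_search(seqs, psp, bg, w, model = model,
                             strand_mode = strand_mode, erasure = erasure,
                             beta = beta, t_schedule = t_schedule)
      ctx <- em_context(seqs, psp, bg, w, model, strand_mode, erasure)
      for (cand in cands) {
        gamma0 <- min(1, max(1 / n, cand$nsites / n))
        em <- run_em_core(ctx, cand$theta0, psp, gamma0, max_iter = max_iter,
                          tol = tol, pseudocount = pseudocount,
                          erasure = erasure)
        ranked <- ranked_sites(em$z, model)
        if (nrow(ranked) == 0) next
        ev <- prefix_log10_evalues(seqs, ranked, w, bg, model, strand_mode,
                                   tmin = if (model == "oops") nrow(ranked) else 2L)
        tstar <- which.min(ev)
        if (is.null(best) || ev[tstar] < best$log10_evalue) {
          best <- list(em = em, sites = ranked[seq_len(tstar), , drop = FALSE],
                       width = w, t = cand$t, start = cand,
                       log10_evalue = ev[tstar],
                       evalue = 10^min(ev[tstar], 300))
        }
      }
    }
    if (is.null(best)) stop("no candidate motif could be scored", call. = FALSE)
    counts <- site_counts(seqs, best$sites, best$width)
    nsites <- nrow(best$sites)
    delta <- pseudocount * bg$p
    theta_rep <- pspm(sweep(counts + delta, 2, nsites + sum(delta), "/"),
                      alphabet = seqs$alphabet, nsites = nsites,
                      evalue = best$evalue)
    sites_bed <- data.frame(
      id = seqs$ids[best$sites$seq],
      start = best$sites$pos - 1L,
      end = best$sites$pos - 1L + best$width,
      strand = best$sites$strand,
      z = best$sites$z,
      stringsAsFactors = FALSE)
    motifs[[round]] <- list(
      pspm = theta_rep, em_pspm = best$em$params$theta, sites = sites_bed,
      width = best$width, nsites = nsites,
      log10_evalue = best$log10_evalue, evalue = best$evalue,
      gamma = best$em$params$gamma, model = model,
      em_trace = best$em$trace, converged = best$em$converged,
      start = list(word = best$start$word, t = best$start$t,
                   score = best$start$score))
    erasure <- erase_motif(erasure, best$em$z)
  }
  structure(list(motifs = motifs, model = model, strand_mode = strand_mode,
                 minw = minw, maxw = maxw, nmotifs = nmotifs),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf("motif_discovery: %d motif(s), %s model, %s-strand, widths %d-%d\n",
              length(x$motifs), x$model, x$strand_mode, x$minw, x$maxw))
  for (k in seq_along(x$motifs)) {
    m <- x$motifs[[k]]
    abc <- alphabet_spec(attr(m$pspm, "alphabet"))
    cons <- paste(abc$letters[apply(unclass(m$pspm), 2, which.max)], collapse = "")
    cat(sprintf("  motif %d: width %d, %d sites, consensus %s, log10 E-value %.2f\n",
                k, m$width, m$nsites, cons, m$log10_evalue))
  }
  invisible(x)
}
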