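#' Sequence-model parameters
#'
#' Bundles everything the E-step conditions on: the motif PSPM
#' \eqn{\theta}, the site frequency \eqn{\gamma} (probability that a random
#' sequence contains a site; fixed at 1 under OOPS), the position-specific
#' prior (held fixed by EM), the sequence model, the strand mode, the
#' background model and optional erasure weights from previously reported
#' motifs.
#'
#' @param theta a `pspm`.
#' @param gamma site frequency in `[0, 1]` (forced to 1 for OOPS).
#' @param psp a `psp`; it is renormalized to the motif width internally.
#' @param model `"zoops"` or `"oops"`.
#' @param bg a `background_model`.
#' @param strand_mode `"double"` or `"single"`.
#' @param erasure optional erasure weights from [new_erasure()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(theta, gamma, psp, model = c("zoops", "oops"), bg,
                         strand_mode = c("double", "single"), erasure = NULL) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(theta, "pspm"), inherits(psp, "psp"),
            inherits(bg, "background_model"), gamma >= 0, gamma <= 1)
  if (model == "oops") gamma <- 1
  structure(list(theta = theta, gamma = gamma, psp = psp, model = model,
                 bg = bg, strand_mode = strand_mode, erasure = erasure),
            class = "model_params")
}

## Effective positional site prior at width w: the input prior renormalized
## to w, masked at windows containing ambiguity letters, multiplied by the
## erasure retention weights, and rescaled per sequence so positional mass is
## again 1 - P0. Returns the prior as one vector over global positions.
effective_site_prior <- function(seqs, psp, w, strand_mode, model,
                                 erasure = NULL) {
  pw <- renormalize_psp(psp, w)
  lay <- site_layout(seqs, w, both_strands = FALSE)
  pr <- numeric(sum(lay$len))
  pr[lay$site_g] <- unlist(lapply(seq_along(pw$prior), function(i)
    pw$prior[[i]][seq_len(lay$m[i])]), use.names = FALSE)
  pr[lay$site_g[!lay$valid]] <- 0
  if (!is.null(erasure)) pr <- pr * erasure$u
  p0 <- pw$p0
  ssum <- numeric(lay$n)
  agg <- rowsum(pr[lay$site_g], lay$site_seq)
  ssum[as.integer(rownames(agg))] <- agg[, 1]
  for (i in seq_len(lay$n)) {
    target <- 1 - p0[i]
    if (ssum[i] > 0) {
      sel <- lay$site_g[lay$site_seq == i]
      pr[sel] <- pr[sel] * (target / ssum[i])
    } else if (target > 0) {
      if (model == "oops")
        stop(sprintf("sequence '%s' has no position with positive prior mass",
                     seqs$ids[i]), call. = FALSE)
      p0[i] <- 1
    }
  }
  list(prior = pr, p0 = p0, w = w)
}

## Context shared by the EM steps at a fixed width: site layout, background
## window log-probabilities, effective prior.
em_context <- function(seqs, psp, bg, w, model, strand_mode, erasure = NULL) {
  both <- strand_mode == "double"
  lay <- site_layout(seqs, w, both_strands = both)
  eff <- effective_site_prior(seqs, psp, w, strand_mode, model, erasure)
  lpos <- bg_position_logprob(bg, seqs)
  cs <- cumsum(c(0, ifelse(is.na(lpos), 0, lpos)))
  logbgw <- cs[lay$site_g + w] - cs[lay$site_g]
  q <- eff$prior[lay$site_g] / pmax(1 - eff$p0[lay$site_seq], .Machine$double.eps)
  q[eff$p0[lay$site_seq] >= 1] <- 0
  ## precomputed linear indices into the (A x w) theta array
  A <- lay$abc$size
  koff <- rep((0:(w - 1L)) * A, each = lay$nsite)
  WfI <- lay$Wf
  WfI[is.na(WfI)] <- 1L
  idxF <- as.vector(WfI) + koff
  idxR <- NULL
  if (both) {
    WrI <- lay$Wr
    WrI[is.na(WrI)] <- 1L
    idxR <- as.vector(WrI) + koff
  }
  ## per-sequence run boundaries in the site arrays (site_seq is sorted)
  ends <- cumsum(lay$m[lay$m > 0])
  seq_present <- which(lay$m > 0)
  list(lay = lay, prior_pos = q, p0 = eff$p0, logbgw = logbgw, both = both,
       model = model, bg = bg, seqs = seqs, idxF = idxF, idxR = idxR,
       grp_ends = ends, grp_seq = seq_present)
}

## sum of x within each per-sequence run (x ordered like the site arrays)
seq_group_sums <- function(ctx, x) {
  cs <- cumsum(x)
  s <- cs[ctx$grp_ends]
  diff(c(0, s))
}

site_logliks <- function(ctx, theta_log) {
  lay <- ctx$lay
  llf <- .rowSums(theta_log[ctx$idxF], lay$nsite, lay$w)
  llf[!lay$valid] <- -Inf
  llr <- NULL
  if (ctx$both) {
    llr <- .rowSums(theta_log[ctx$idxR], lay$nsite, lay$w)
    llr[!lay$valid] <- -Inf
  }
  list(f = llf, r = llr)
}

estep_core <- function(ctx, theta, gamma) {
  lay <- ctx$lay
  ll <- site_logliks(ctx, log(pmax(unclass(theta), 1e-300)))
  odds_f <- exp(ll$f - ctx$logbgw)
  odds_f[!lay$valid] <- 0
  pri <- gamma * ctx$prior_pos
  if (ctx$both) pri <- pri / 2
  uf <- pri * odds_f
  ur <- NULL
  if (ctx$both) {
    odds_r <- exp(ll$r - ctx$logbgw)
    odds_r[!lay$valid] <- 0
    ur <- pri * odds_r
  }
  u0 <- if (ctx$model == "oops") rep(0, lay$n) else rep(1 - gamma, lay$n)
  tot <- if (ctx$both) uf + ur else uf
  denom <- u0
  denom[ctx$grp_seq] <- denom[ctx$grp_seq] + seq_group_sums(ctx, tot)
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)[1]
    stop(sprintf("sequence '%s': total posterior site mass is zero",
                 ctx$seqs$ids[bad]), call. = FALSE)
  }
  zf <- uf / denom[lay$site_seq]
  zr <- if (ctx$both) ur / denom[lay$site_seq] else NULL
  z0 <- u0 / denom
  structure(list(zf = zf, zr = zr, z0 = z0, w = lay$w, n = lay$n,
                 site_seq = lay$site_seq, site_j = lay$site_j,
                 both_strands = ctx$both, loglik = sum(log(denom)),
                 iter = NA_integer_),
            class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("zmatrix: %d sequence(s), width %d, %s-strand; mean Z0 = %.3f\n",
              x$n, x$w, if (x$both_strands) "double" else "single", mean(x$z0)))
  invisible(x)
}

#' E-step: posterior site probabilities
#'
#' Computes the expectations of the missing site indicators \eqn{Z_{i,j}}
#' given the current model: the prior probability of a site at `(i, j)` is
#' \eqn{\gamma \, P_{i,j} / (1 - P_{i,0})} (halved per strand in
#' double-strand mode) and of no site \eqn{1 - \gamma}; posteriors are
#' proportional to prior times the likelihood ratio of the window under the
#' motif versus the background, normalized per sequence (over both strands
#' when double-stranded). Under OOPS, \eqn{\gamma = 1} and
#' \eqn{Z_{i,0} = 0}.
#'
#' @param seqs a [sequence_set()].
#' @param params a [model_params()].
#' @return A `zmatrix`: per-site posteriors `zf` (forward), `zr` (reverse, if
#'   double-stranded) and per-sequence no-site posteriors `z0`, with every
#'   sequence's total equal to 1.
#' @export
e_step <- function(seqs, params) {
  stopifnot(inherits(params, "model_params"))
  ctx <- em_context(seqs, params$psp, params$bg, ncol(params$theta),
                    params$model, params$strand_mode, params$erasure)
  estep_core(ctx, params$theta, params$gamma)
}

mstep_core <- function(ctx, zmat, pseudocount = 0.01) {
  lay <- ctx$lay
  A <- lay$abc$size
  w <- lay$w
  delta <- pseudocount * ctx$bg$p
  cv <- cpp_weighted_bincount(ctx$idxF, zmat$zf, A * w, 1L)
  if (ctx$both) cv <- cv + cpp_weighted_bincount(ctx$idxR, zmat$zr, A * w, 1L)
  counts <- matrix(cv, nrow = A, ncol = w)
  ztot <- colSums(counts)
  theta <- sweep(counts + delta, 2, ztot + sum(delta), "/")
  gamma <- if (ctx$model == "oops") 1
           else min(1, max(1 / lay$n, mean(1 - zmat$z0)))
  list(theta = pspm(theta, alphabet = ctx$seqs$alphabet), gamma = gamma,
       counts = counts)
}

#' M-step: re-estimate the motif model
#'
#' Re-estimates the PSPM from the posterior site probabilities with a
#' background-proportional Dirichlet pseudocount,
#' \eqn{\theta_{a,k} = (c_{a,k} + \delta_a) / (\sum Z + \sum_a \delta_a)}
#' with \eqn{\delta_a = 0.01\, p_a} by default, and (ZOOPS) the site
#' frequency \eqn{\gamma = \frac{1}{n}\sum_i (1 - Z_{i,0})}, clamped to
#' `[1/n, 1]`. The position-specific prior is held fixed.
#'
#' @param seqs a [sequence_set()].
#' @param zmat a `zmatrix` from [e_step()].
#' @param model `"zoops"` or `"oops"`.
#' @param bg a `background_model`.
#' @param psp the `psp` (held fixed; carried into the returned parameters).
#' @param strand_mode `"double"` or `"single"`.
#' @param pseudocount Dirichlet scale (default 0.01).
#' @param erasure optional erasure weights.
#' @return A [model_params()] with the updated `theta` and `gamma`.
#' @export
m_step <- function(seqs, zmat, model = c("zoops", "oops"), bg, psp,
                   strand_mode = c("double", "single"), pseudocount = 0.01,
                   erasure = NULL) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  ctx <- em_context(seqs, psp, bg, zmat$w, model, strand_mode, erasure)
  up <- mstep_core(ctx, zmat, pseudocount)
  model_params(up$theta, up$gamma, psp, model, bg, strand_mode, erasure)
}

#' Run EM from a starting point
#'
#' Alternates [e_step()] and [m_step()] until the largest absolute change in
#' any PSPM entry falls below `tol` or `max_iter` iterations are reached.
#' The log posterior of the model (sequence-set log likelihood plus the
#' Dirichlet log prior on \eqn{\theta}, up to a constant) is recorded at each
#' iteration; EM guarantees it is non-decreasing.
#'
#' @param theta0 starting `pspm`.
#' @param seqs a [sequence_set()].
#' @param psp a `psp` (renormalized internally to the motif width).
#' @param bg a `background_model`.
#' @param model `"zoops"` or `"oops"`.
#' @param gamma0 starting site frequency (ZOOPS).
#' @param strand_mode `"double"` or `"single"`.
#' @param max_iter iteration cap (default 50).
#' @param tol convergence tolerance on `max |d theta|` (default 1e-3;
#'   `tol = Inf` performs exactly one iteration).
#' @param pseudocount M-step Dirichlet scale.
#' @param erasure optional erasure weights.
#' @return A list: `params` (final [model_params()]), `z` (final `zmatrix`,
#'   consistent with the final `theta`), `trace` (per-iteration log
#'   posterior), `converged`, `iterations`.
#' @export
run_em <- function(theta0, seqs, psp, bg, model = c("zoops", "oops"),
                   gamma0 = 0.5, strand_mode = c("double", "single"),
                   max_iter = 50L, tol = 1e-3, pseudocount = 0.01,
                   erasure = NULL) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(theta0, "pspm"))
  ctx <- em_context(seqs, psp, bg, ncol(theta0), model, strand_mode, erasure)
  run_em_core(ctx, theta0, psp, gamma0, max_iter, tol, pseudocount, erasure)
}

run_em_core <- function(ctx, theta0, psp, gamma0, max_iter = 50L, tol = 1e-3,
                        pseudocount = 0.01, erasure = NULL) {
  seqs <- ctx$seqs
  bg <- ctx$bg
  model <- ctx$model
  strand_mode <- if (ctx$both) "double" else "single"
  delta <- pseudocount * bg$p
  theta <- theta0
  gamma <- if (model == "oops") 1 else min(1, max(1 / ctx$lay$n, gamma0))
  trace <- numeric(0)
  converged <- FALSE
  zmat <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    zmat <- estep_core(ctx, theta, gamma)
    zmat$iter <- it
    logprior <- sum(delta * log(pmax(unclass(theta), 1e-300)))
    trace <- c(trace, zmat$loglik + logprior)
    up <- mstep_core(ctx, zmat, pseudocount)
    dmax <- max(abs(unclass(up$theta) - unclass(theta)))
    theta <- up$theta
    gamma <- up$gamma
    if (dmax < tol) { converged <- TRUE; break }
  }
  zmat <- estep_core(ctx, theta, gamma)
  zmat$iter <- it
  trace <- c(trace, zmat$loglik +
               sum(delta * log(pmax(unclass(theta), 1e-300))))
  params <- model_params(theta, gamma, psp, model, bg, strand_mode, erasure)
  list(params = params, z = zmat, trace = trace, converged = converged,
       iterations = it)
}
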