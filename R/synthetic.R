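## deterministic local RNG: run `expr` under a seed without disturbing the
## caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

sample_background_seq <- function(L, bg, abc) {
  e <- integer(L)
  for (t in seq_len(L)) {
    k <- min(bg$order, t - 1L)
    if (k == 0L) {
      e[t] <- sample.int(abc$size, 1L, prob = bg$cond[[1L]])
    } else {
      ctx <- e[(t - k):(t - 1L)]
      idx0 <- ctx[1L]
      if (k > 1L) for (d in 2:k) idx0 <- (idx0 - 1L) * abc$size + ctx[d]
      block <- bg$cond[[k + 1L]][((idx0 - 1L) * abc$size + 1L):(idx0 * abc$size)]
      e[t] <- sample.int(abc$size, 1L, prob = block)
    }
  }
  e
}

#' Generate a planted-motif dataset
#'
#' Emulates a ChIP-derived positive sequence set: `n` background sequences of
#' length `len`, a fraction `site_frac` of which receive exactly one motif
#' site at a uniformly random legal position. Site letters are sampled from
#' the motif PSPM and then mutated (replaced by one of the other letters,
#' uniformly) with probability `mutation_rate` per position, so the
#' *effective* planted motif -- returned as the ground truth for distance
#' evaluation -- is \eqn{f' = (1-\mu) f + (\mu/3)(1 - f)}. With the default
#' consensus `TGACTCAG` and `mutation_rate = 0.16` the planted motif has a
#' mean per-column information content of about 1.1 bits: a deliberately weak
#' motif, the regime where positional priors matter.
#'
#' @param n number of sequences.
#' @param len sequence length.
#' @param motif a `pspm` or a consensus string (converted to a point-mass
#'   PSPM).
#' @param site_frac fraction of sequences receiving a site (`floor(n *
#'   site_frac)` sequences, chosen at random).
#' @param mutation_rate per-position probability that a sampled site letter is
#'   replaced by a different letter.
#' @param bg a `background_model` for the background residues (default
#'   uniform).
#' @param strand_policy `"both"` (each site is planted on a random strand) or
#'   `"forward"`.
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @return A list: `seqs` (a [sequence_set()]), `sites` (data frame `seq`,
#'   `pos` -- 1-based leftmost forward coordinate --, `strand`), `motif` (the
#'   effective planted `pspm`).
#' @export
generate_dataset <- function(n = 50L, len = 200L, motif = "TGACTCAG",
                             site_frac = 0.5, mutation_rate = 0.16,
                             bg = NULL, strand_policy = c("both", "forward"),
                             seed = NULL) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(site_frac >= 0, site_frac <= 1, mutation_rate >= 0,
            mutation_rate <= 1)
  if (is.character(motif)) motif <- subsequence_to_pspm(motif, beta = 1)
  stopifnot(inherits(motif, "pspm"))
  abc <- alphabet_spec(attr(motif, "alphabet"))
  if (is.null(bg)) bg <- uniform_background(abc$name)
  w <- ncol(motif)
  if (len < w) stop("sequences shorter than the motif width", call. = FALSE)
  f <- unclass(motif)
  eff <- (1 - mutation_rate) * f + (mutation_rate / (abc$size - 1)) * (1 - f)
  with_seed(seed, {
    enc <- lapply(seq_len(n), function(i) sample_background_seq(len, bg, abc))
    nplant <- floor(site_frac * n)
    which_seq <- sort(sample.int(n, nplant))
    pos <- integer(nplant)
    strand <- character(nplant)
    for (r in seq_along(which_seq)) {
      j <- sample.int(len - w + 1L, 1L)
      site <- vapply(seq_len(w), function(k)
        sample.int(abc$size, 1L, prob = f[, k]), 0L)
      mut <- stats::runif(w) < mutation_rate
      if (any(mut)) {
        site[mut] <- vapply(site[mut], function(a)
          sample(setdiff(seq_len(abc$size), a), 1L), 0L)
      }
      s <- if (strand_policy == "both" && !is.null(abc$complement) &&
               stats::runif(1) < 0.5) "-" else "+"
      if (s == "-") site <- rev(abc$complement[site])
      enc[[which_seq[r]]][j:(j + w - 1L)] <- site
      pos[r] <- j
      strand[r] <- s
    }
    seqs <- sequence_set(
      vapply(enc, decode_residues, "", abc = abc),
      ids = sprintf("seq_%03d", seq_len(n)), alphabet = abc$name)
    list(seqs = seqs,
         sites = data.frame(seq = which_seq, pos = pos, strand = strand,
                            stringsAsFactors = FALSE),
         motif = pspm(eff, alphabet = abc$name))
  })
}

#' Generate an informative position-specific prior from planted sites
#'
#' Stands in for an externally derived prior (e.g. a discriminative
#' conservation prior): for each sequence with a true site, prior mass
#' `concentration` is placed on the true start, spread over positions
#' `j-1, j, j+1` by a triangular kernel (weights 1:2:1, clipped to the legal
#' range and renormalized), with the remaining mass uniform over legal
#' positions. Sequences without sites get a uniform prior and, under ZOOPS, a
#' no-site mass \eqn{P_{i,0}} equal to `concentration`. `concentration = 0`
#' reproduces the uniform prior exactly.
#'
#' @param truth site data frame from [generate_dataset()] (`seq`, `pos`).
#' @param seqs the [sequence_set()].
#' @param w0 prior width.
#' @param concentration informativeness in `[0, 1]`.
#' @param model `"zoops"` or `"oops"`.
#' @param strand_mode `"double"` or `"single"`.
#' @return A `psp` that satisfies [validate_psp()].
#' @export
generate_psp <- function(truth, seqs, w0, concentration,
                         model = c("zoops", "oops"),
                         strand_mode = c("double", "single")) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(concentration >= 0, concentration <= 1)
  out <- make_uniform_psp(seqs, w0, model = model, strand_mode = strand_mode)
  if (concentration == 0) return(out)
  len <- seq_lengths(seqs)
  has_site <- seq_along(out$prior) %in% truth$seq
  for (i in seq_along(out$prior)) {
    m <- len[i] - w0 + 1L
    if (has_site[i]) {
      j <- truth$pos[match(i, truth$seq)]
      kern_pos <- (j - 1L):(j + 1L)
      kern_wt <- c(1, 2, 1)
      ok <- kern_pos >= 1L & kern_pos <= m
      kern_pos <- kern_pos[ok]
      kern_wt <- kern_wt[ok] / sum(kern_wt[ok])
      pr <- rep((1 - concentration) / m, len[i])
      pr[seq_len(len[i]) > m] <- 0
      pr[kern_pos] <- pr[kern_pos] + concentration * kern_wt
      out$prior[[i]] <- pr
      out$p0[i] <- 0
    } else if (model == "zoops") {
      pr <- rep((1 - concentration) / m, len[i])
      pr[seq_len(len[i]) > m] <- 0
      out$prior[[i]] <- pr
      out$p0[i] <- concentration
    }
  }
  out
}
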