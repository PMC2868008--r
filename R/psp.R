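#' Position-specific priors
#'
#' A position-specific prior (PSP) encodes, for a motif width `w0`, the prior
#' probability \eqn{P_{i,j}} that a motif site starts at position `j` of
#' sequence `i`, plus a per-sequence no-site mass \eqn{P_{i,0}}. Constraints:
#' all values in `[0,1]`; \eqn{P_{i,j} = 0} for `j > L_i - w0 + 1` (a site
#' must fit inside the sequence); \eqn{P_{i,0} + \sum_j P_{i,j} = 1} per
#' sequence; and \eqn{P_{i,0} = 0} under the OOPS model, which assumes every
#' sequence has a site. In double-stranded mode the prior is symmetric by
#' construction: only the forward array is stored and a reverse-strand site is
#' assigned the prior of its leftmost forward coordinate, realizing
#' \eqn{P_{i,j} = P_{i,-j}} without duplicate storage.
#'
#' @param prior list of per-sequence numeric vectors (`prior[[i]][j]` =
#'   \eqn{P_{i,j}}, length `L_i`).
#' @param p0 numeric vector of per-sequence no-site masses \eqn{P_{i,0}}.
#' @param w0 the motif width the prior is designed for.
#' @param ids sequence identifiers (parallel to `prior`).
#' @param strand_mode `"double"` or `"single"`.
#' @return An object of class `psp`.
#' @export
new_psp <- function(prior, p0, w0, ids, strand_mode = c("double", "single")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.list(prior), length(prior) == length(p0),
            length(prior) == length(ids), w0 >= 1)
  structure(list(ids = as.character(ids), prior = lapply(prior, as.numeric),
                 p0 = as.numeric(p0), w0 = as.integer(w0),
                 strand_mode = strand_mode), class = "psp")
}

#' @export
print.psp <- function(x, ...) {
  cat(sprintf("psp: %d sequence(s), w0 = %d, strand mode %s, mean P0 = %.3f\n",
              length(x$ids), x$w0, x$strand_mode, mean(x$p0)))
  invisible(x)
}

#' Uniform position-specific prior
#'
#' The default prior when none is supplied: every legal start position of
#' every sequence is equally likely, \eqn{P_{i,j} = 1/m_i} with
#' \eqn{m_i = L_i - w0 + 1}, and \eqn{P_{i,0} = 0}. With this prior every
#' stage of discovery reduces to the classic uniform site assumption.
#'
#' @param seqs a [sequence_set()].
#' @param w0 motif width (every sequence must be at least this long).
#' @param model `"zoops"` or `"oops"` (both give \eqn{P_{i,0} = 0}; under
#'   ZOOPS the site frequency is carried by the model parameter gamma, not the
#'   prior).
#' @param strand_mode `"double"` or `"single"`.
#' @return A `psp`.
#' @examples
#' make_uniform_psp(sequence_set("ACGTACGTAC"), 8)$prior[[1]]
#' @export
make_uniform_psp <- function(seqs, w0, model = c("zoops", "oops"),
                             strand_mode = c("double", "single")) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(seqs, "seqset"), w0 >= 1)
  len <- seq_lengths(seqs)
  short <- which(len < w0)
  if (length(short) > 0) {
    stop(sprintf("sequence '%s' (length %d) is shorter than the prior width %d",
                 seqs$ids[short[1]], len[short[1]], w0), call. = FALSE)
  }
  prior <- lapply(len, function(L) {
    m <- L - w0 + 1L
    c(rep(1 / m, m), rep(0, w0 - 1L))
  })
  new_psp(prior, rep(0, length(len)), w0, seqs$ids, strand_mode)
}

#' Validate a position-specific prior
#'
#' Checks every PSP constraint and returns a diagnostics object rather than
#' erroring: value range, zero tail (no site may overhang the sequence end),
#' per-sequence total mass \eqn{P_{i,0} + \sum_j P_{i,j} = 1 \pm 10^{-6}},
#' and, under OOPS, \eqn{P_{i,0} = 0}.
#'
#' @param psp a `psp`.
#' @param model `"zoops"` or `"oops"`.
#' @return A list of class `psp_diagnostics` with `ok` (logical) and
#'   `violations` (data frame: `seq`, `rule`, `detail`).
#' @export
validate_psp <- function(psp, model = c("zoops", "oops")) {
  model <- match.arg(model)
  stopifnot(inherits(psp, "psp"))
  v <- list()
  add <- function(seq, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(seq = seq, rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  for (i in seq_along(psp$prior)) {
    pr <- psp$prior[[i]]
    L <- length(pr)
    id <- psp$ids[i]
    if (any(pr < 0 | pr > 1) || psp$p0[i] < 0 || psp$p0[i] > 1)
      add(id, "range", "prior value outside [0, 1]")
    tail_idx <- seq_len(L)[seq_len(L) > L - psp$w0 + 1L]
    if (any(pr[tail_idx] != 0))
      add(id, "tail", sprintf("nonzero prior in the last %d positions", psp$w0 - 1L))
    tot <- psp$p0[i] + sum(pr)
    if (abs(tot - 1) > 1e-6)
      add(id, "sum", sprintf("P0 + sum of positional priors = %.8f, not 1", tot))
    if (model == "oops" && psp$p0[i] != 0)
      add(id, "oops_p0", "nonzero no-site mass under the OOPS model")
  }
  violations <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(seq = character(0), rule = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "psp_diagnostics")
}

#' @export
print.psp_diagnostics <- function(x, ...) {
  if (x$ok) cat("psp_diagnostics: all constraints satisfied\n")
  else {
    cat(sprintf("psp_diagnostics: %d violation(s)\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Renormalize a prior to a different motif width
#'
#' A PSP is tied to the width `w0` it was designed for. For a wider motif
#' (`w > w0`) the prior of a width-`w` site is the geometric mean of the
#' priors of the first `c = min(w - w0 + 1, w0)` width-`w0` sites it fully
#' contains; the positional values are then rescaled by a per-sequence
#' constant so that \eqn{P_{i,0}} is preserved and the total mass is again 1.
#' For a narrower motif (`w < w0`) the prior is used as-is, so the last
#' `w0 - w` newly-legal start positions keep prior 0 (the input prior carries
#' no information about sites starting there). At `w = w0` this is the
#' identity.
#'
#' @param psp a `psp`.
#' @param w target motif width.
#' @return A `psp` tied to width `w` (so the operation is idempotent at fixed
#'   `w`). If every renormalized positional value of a sequence is zero, that
#'   sequence falls back to a uniform prior over its legal positions, scaled
#'   to `1 - P0`, with a warning.
#' @examples
#' s <- sequence_set("ACGTA")
#' p <- new_psp(list(c(0.1, 0.4, 0.4, 0.1, 0)), 0, 2, s$ids)
#' renormalize_psp(p, 3)$prior[[1]]  # (0.25, 0.5, 0.25, 0, 0)
#' @export
renormalize_psp <- function(psp, w) {
  stopifnot(inherits(psp, "psp"), w >= 1)
  w <- as.integer(w)
  if (w == psp$w0) return(psp)
  out <- psp
  if (w < psp$w0) {
    out$w0 <- w
    return(out)
  }
  cc <- min(w - psp$w0 + 1L, psp$w0)
  for (i in seq_along(psp$prior)) {
    pr <- psp$prior[[i]]
    L <- length(pr)
    mw <- L - w + 1L
    new <- rep(0, L)
    if (mw >= 1L) {
      raw <- rep(1, mw)
      for (d in 0:(cc - 1L)) raw <- raw * pr[(1L + d):(mw + d)]
      raw <- raw^(1 / cc)
      pos_mass <- 1 - psp$p0[i]
      s <- sum(raw)
      if (s <= 0) {
        if (pos_mass > 0) {
          warning(sprintf("sequence '%s': all renormalized priors are zero; falling back to a uniform prior",
                          psp$ids[i]), call. = FALSE)
          raw <- rep(1 / mw, mw)
          s <- 1
        } else s <- 1
      }
      new[seq_len(mw)] <- raw * (pos_mass / s)
    }
    out$prior[[i]] <- new
  }
  out$w0 <- w
  out
}

#' Prior of a reverse-strand site
#'
#' In double-stranded mode the prior is required to be strand-symmetric, so a
#' reverse-strand site occupying forward interval `[j, j + w - 1]` has the
#' prior of its leftmost forward coordinate, \eqn{P_{i,j}}.
#'
#' @param psp a `psp` with `strand_mode = "double"`.
#' @param w motif width (the prior is renormalized to `w` if needed).
#' @param i sequence index.
#' @param j 1-based forward start coordinate of the site.
#' @return The prior probability; 0 when `j` is outside the legal range.
#' @export
reverse_strand_prior <- function(psp, w, i, j) {
  stopifnot(inherits(psp, "psp"))
  if (psp$strand_mode != "double")
    stop("reverse_strand_prior is only defined in double-strand mode", call. = FALSE)
  pr <- renormalize_psp(psp, w)$prior[[i]]
  if (j < 1 || j > length(pr) - w + 1) return(0)
  pr[j]
}

#' Read a position-specific prior file
#'
#' File dialect: each record is a header line `>seqID w0` followed by
#' whitespace-separated decimal values (free line wrapping), exactly `L_i`
#' values for sequence `i` -- one per 1-based start position, the last
#' `w0 - 1` of which must be 0. An optional leading token of the form
#' `p0=<value>` gives the no-site mass \eqn{P_{i,0}}; if absent it defaults to
#' `1 - sum(values)` (clamped to 0 when the positional values already sum to 1
#' within `1e-6`). All records must declare the same `w0`. Sequences present
#' in `seqs` but absent from the file receive the uniform prior.
#'
#' @param path path to the PSP file.
#' @param seqs the [sequence_set()] the prior refers to.
#' @param model `"zoops"` or `"oops"`, used for validation.
#' @param strand_mode `"double"` or `"single"`.
#' @return A validated `psp`.
#' @export
read_psp <- function(path, seqs, model = c("zoops", "oops"),
                     strand_mode = c("double", "single")) {
  model <- match.arg(model)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(seqs, "seqset"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no records in PSP file: ", path, call. = FALSE)
  len <- seq_lengths(seqs)
  w0 <- NA_integer_
  rec_id <- character(0)
  rec_vals <- list()
  rec_p0 <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (r in seq_along(hdr)) {
    head_tok <- strsplit(trimws(sub("^>", "", lines[hdr[r]])), "\\s+")[[1]]
    if (length(head_tok) != 2)
      stop("malformed PSP header: ", lines[hdr[r]], call. = FALSE)
    id <- head_tok[1]
    wr <- as.integer(head_tok[2])
    if (is.na(w0)) w0 <- wr
    else if (wr != w0)
      stop(sprintf("PSP record '%s' declares w0 = %d but earlier records use %d",
                   id, wr, w0), call. = FALSE)
    i <- match(id, seqs$ids)
    if (is.na(i))
      stop(sprintf("PSP record '%s' does not match any sequence id", id),
           call. = FALSE)
    body <- lines[(hdr[r] + 1L):(bounds[r + 1L] - 1L)]
    toks <- unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE)
    toks <- toks[nzchar(toks)]
    p0 <- NA_real_
    if (length(toks) > 0 && grepl("^p0=", toks[1])) {
      p0 <- as.numeric(sub("^p0=", "", toks[1]))
      toks <- toks[-1]
    }
    vals <- as.numeric(toks)
    if (anyNA(vals))
      stop(sprintf("PSP record '%s': non-numeric prior value", id), call. = FALSE)
    if (length(vals) != len[i])
      stop(sprintf("PSP record '%s': expected %d values, found %d", id, len[i],
                   length(vals)), call. = FALSE)
    bad <- which(vals < 0 | vals > 1)
    if (length(bad) > 0)
      stop(sprintf("PSP record '%s': value %.6g at position %d is outside [0, 1]",
                   id, vals[bad[1]], bad[1]), call. = FALSE)
    s <- sum(vals)
    if (s > 1 + 1e-6)
      stop(sprintf("PSP record '%s': positional priors sum to %.8f > 1", id, s),
           call. = FALSE)
    if (is.na(p0)) p0 <- if (abs(1 - s) <= 1e-6) 0 else 1 - s
    rec_id <- c(rec_id, id)
    rec_vals[[id]] <- vals
    rec_p0[[id]] <- p0
  }
  unif <- make_uniform_psp(seqs, w0, model = model, strand_mode = strand_mode)
  prior <- unif$prior
  p0 <- unif$p0
  for (id in rec_id) {
    i <- match(id, seqs$ids)
    prior[[i]] <- rec_vals[[id]]
    p0[i] <- rec_p0[[id]]
  }
  out <- new_psp(prior, p0, w0, seqs$ids, strand_mode)
  diag <- validate_psp(out, model = model)
  if (!diag$ok) {
    stop("PSP file violates prior constraints:\n",
         paste(sprintf("  %s: %s", diag$violations$seq, diag$violations$detail),
               collapse = "\n"), call. = FALSE)
  }
  out
}

#' Write a position-specific prior file
#'
#' Emits the dialect read by [read_psp()]; values are printed with enough
#' digits that a read-back reproduces them to 1e-9 or better.
#'
#' @param psp a `psp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psp <- function(psp, path) {
  stopifnot(inherits(psp, "psp"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(psp$ids)) {
    writeLines(sprintf(">%s %d", psp$ids[i], psp$w0), con)
    toks <- sprintf("%.12g", psp$prior[[i]])
    if (psp$p0[i] != 0) toks <- c(sprintf("p0=%.12g", psp$p0[i]), toks)
    writeLines(paste(toks, collapse = " "), con)
  }
  invisible(path)
}
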