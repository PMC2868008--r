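test_that("uniform priors spread mass over legal positions", {
  s <- sequence_set(c(a = "ACGTACGTAC"))        # L = 10
  p <- make_uniform_psp(s, 8)
  expect_equal(p$prior[[1]], c(rep(1 / 3, 3), rep(0, 7)))
  expect_equal(p$p0, 0)

  s2 <- sequence_set(c(a = "ACGTACGT"))         # L = w0
  p2 <- make_uniform_psp(s2, 8)
  expect_equal(p2$prior[[1]][1], 1)
  expect_equal(sum(p2$prior[[1]]), 1)

  expect_error(make_uniform_psp(sequence_set(c(short = "ACGTACG")), 8), "short")
})

test_that("validation enforces the prior constraints per model", {
  s <- sequence_set(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  u <- make_uniform_psp(s, 8)
  expect_true(validate_psp(u, "zoops")$ok)
  expect_true(validate_psp(u, "oops")$ok)

  p <- new_psp(list(c(0.35, 0.35, 0, rep(0, 7)), u$prior[[2]]),
               c(0.3, 0), 8, s$ids)
  d <- validate_psp(p, "oops")
  expect_false(d$ok)
  expect_true("oops_p0" %in% d$violations$rule)
  expect_true(validate_psp(p, "zoops")$ok)  # 0.7 + 0.3 sums to 1

  bad <- new_psp(list(c(0.5, 0.1, 0, rep(0, 7)), u$prior[[2]]),
                 c(0, 0), 8, s$ids)
  expect_false(validate_psp(bad, "zoops")$ok)
})

test_that("renormalization follows the geometric-mean rule", {
  s <- sequence_set(c(a = "ACGTA"))
  p <- new_psp(list(c(0.1, 0.4, 0.4, 0.1, 0)), 0, 2, s$ids)
  r <- renormalize_psp(p, 3)
  expect_equal(r$prior[[1]], c(0.25, 0.5, 0.25, 0, 0), tolerance = 1e-12)
  expect_equal(r$w0, 3L)

  expect_identical(renormalize_psp(p, 2), p)               # identity at w0
  expect_equal(renormalize_psp(r, 3), r)                   # idempotent

  ## w < w0: values pass through, so late legal positions keep prior 0
  s20 <- sequence_set(c(a = strrep("ACGTA", 4)))           # L = 20
  u8 <- make_uniform_psp(s20, 8)
  r7 <- renormalize_psp(u8, 7)
  expect_equal(r7$prior[[1]][14], 0)                       # last legal for w=7
  expect_true(all(r7$prior[[1]][1:13] > 0))

  ## uniform maps to uniform
  u <- make_uniform_psp(s20, 4)
  ru <- renormalize_psp(u, 6)
  vals <- ru$prior[[1]][1:15]
  expect_equal(vals, rep(1 / 15, 15), tolerance = 1e-12)
})

test_that("renormalization preserves total mass and is monotone", {
  set.seed(5)
  for (rep in 1:10) {
    L <- sample(12:30, 1)
    w0 <- sample(3:6, 1)
    s <- sequence_set(paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
    m <- L - w0 + 1
    v <- rgamma(m, 1)
    p0 <- runif(1, 0, 0.4)
    p <- new_psp(list(c((1 - p0) * v / sum(v), rep(0, w0 - 1))), p0, w0, s$ids)
    for (w in (w0):(min(L, w0 + 4))) {
      r <- renormalize_psp(p, w)
      expect_equal(r$p0 + sum(r$prior[[1]]), 1, tolerance = 1e-9)
      expect_true(all(r$prior[[1]][seq_len(L) > L - w + 1] == 0))
    }
    ## raising the priors under a window never lowers the raw value
    w <- w0 + 1
    cc <- min(w - w0 + 1, w0)
    j <- sample(seq_len(L - w + 1), 1)
    p_hi <- p
    p_hi$prior[[1]][j:(j + cc - 1)] <- pmin(1, p_hi$prior[[1]][j:(j + cc - 1)] * 2)
    raw <- function(pp) prod(pp$prior[[1]][j:(j + cc - 1)])^(1 / cc)
    expect_gte(raw(p_hi), raw(p))
  }
})

test_that("renormalization falls back to uniform when all values vanish", {
  s <- sequence_set(c(a = "ACGTACGTAC"))
  ## alternating zeros so that every width-3 product is zero
  p <- new_psp(list(c(0.5, 0, 0.5, 0, 0, 0, 0, 0, 0, 0)), 0, 2, s$ids)
  expect_warning(r <- renormalize_psp(p, 3), "uniform")
  expect_equal(sum(r$prior[[1]]), 1, tolerance = 1e-9)
})

test_that("reverse-strand priors realize the symmetry constraint", {
  s <- sequence_set(c(a = "ACGTACGTACGT"))
  p <- make_uniform_psp(s, 6, strand_mode = "double")
  expect_equal(reverse_strand_prior(p, 6, 1, 3), p$prior[[1]][3])
  expect_equal(reverse_strand_prior(p, 6, 1, 100), 0)
  ps <- make_uniform_psp(s, 6, strand_mode = "single")
  expect_error(reverse_strand_prior(ps, 6, 1, 1), "single|double")

  ## symmetry survives renormalization
  set.seed(9)
  v <- rgamma(7, 1)
  p2 <- new_psp(list(c(v / sum(v), rep(0, 5))), 0, 6, s$ids,
                strand_mode = "double")
  r <- renormalize_psp(p2, 8)
  for (j in 1:5) expect_equal(reverse_strand_prior(p2, 8, 1, j), r$prior[[1]][j])
})
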