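toy_seqs <- function() sequence_set(c(a = "ACGTA", b = "GGTAC"))

test_that("E-step posteriors are symmetric when the motif equals background", {
  seqs <- toy_seqs()
  psp <- make_uniform_psp(seqs, 3, strand_mode = "single")
  th <- pspm(matrix(0.25, 4, 3))
  par <- model_params(th, 1, psp, "oops", uniform_bg, "single")
  z <- e_step(seqs, par)
  expect_equal(z$zf, rep(1 / 3, 6))
  expect_equal(z$z0, c(0, 0))
})

test_that("a point-mass prior pins the posterior regardless of the motif", {
  seqs <- toy_seqs()
  psp <- new_psp(list(c(0, 1, 0, 0, 0), c(1, 0, 0, 0, 0)), c(0, 0), 3,
                 seqs$ids, strand_mode = "single")
  set.seed(6)
  for (rep in 1:3) {
    par <- model_params(random_pspm(3), 1, psp, "oops", uniform_bg, "single")
    z <- e_step(seqs, par)
    expect_equal(z$zf, c(0, 1, 0, 1, 0, 0))
  }
})

test_that("ZOOPS posteriors equal brute-force enumeration of the joint", {
  seqs <- toy_seqs()
  psp <- make_uniform_psp(seqs, 3, strand_mode = "single")
  set.seed(10)
  th <- random_pspm(3)
  gamma <- 0.5
  par <- model_params(th, gamma, psp, "zoops", uniform_bg, "single")
  z <- e_step(seqs, par)
  for (i in 1:2) {
    s <- seqs$seqs[i]
    bgl <- 0.25^5
    joint_no <- (1 - gamma) * bgl
    joint_site <- vapply(1:3, function(j) {
      gamma * (1 / 3) * site_likelihood(th, s, j) * 0.25^2   # bg off-site
    }, 0)
    tot <- joint_no + sum(joint_site)
    expect_equal(z$z0[i], joint_no / tot, tolerance = 1e-12)
    expect_equal(z$zf[(i - 1) * 3 + 1:3], joint_site / tot, tolerance = 1e-12)
  }
  ## normalization invariant
  expect_equal(z$z0 + c(sum(z$zf[1:3]), sum(z$zf[4:6])), c(1, 1),
               tolerance = 1e-12)
})

test_that("M-step recovers point-mass motifs and clamps gamma", {
  seqs <- sequence_set(c(a = "ACGTT", b = "TACGT", c = "GACGA"))
  psp <- make_uniform_psp(seqs, 4, strand_mode = "single")
  th <- pspm(matrix(0.25, 4, 4))
  par <- model_params(th, 0.5, psp, "zoops", uniform_bg, "single")
  z <- e_step(seqs, par)
  ## pin Z on the shared word ACG* at positions 1, 2, 2
  z$zf[] <- 0
  z$zf[c(1, 4, 6)] <- 1
  z$z0[] <- 0
  up <- m_step(seqs, z, "zoops", uniform_bg, psp, "single",
               pseudocount = 1e-12)
  expect_equal(unname(unclass(up$theta)[cbind(c(1, 2, 3), 1:3)]), rep(1, 3),
               tolerance = 1e-6)
  expect_equal(up$gamma, 1)

  z$zf[] <- 0
  z$z0[] <- 1
  up0 <- m_step(seqs, z, "zoops", uniform_bg, psp, "single")
  expect_equal(up0$gamma, 1 / 3)   # clamped at the floor

  ## random Z: counts match independent accumulation
  set.seed(14)
  z$zf <- runif(6)
  z$z0 <- runif(3)
  tot <- z$z0 + c(sum(z$zf[1:2]), sum(z$zf[3:4]), sum(z$zf[5:6]))
  z$zf <- z$zf / tot[rep(1:3, each = 2)]
  z$z0 <- z$z0 / tot
  up2 <- m_step(seqs, z, "zoops", uniform_bg, psp, "single", pseudocount = 0.01)
  counts <- matrix(0, 4, 4)
  r <- 0
  for (i in 1:3) for (j in 1:2) {
    r <- r + 1
    win <- seqs$enc[[i]][j:(j + 3)]
    for (k in 1:4) counts[win[k], k] <- counts[win[k], k] + z$zf[r]
  }
  delta <- 0.01 * uniform_bg$p
  expect_equal(unclass(up2$theta),
               unname(sweep(counts + delta, 2, sum(z$zf) + sum(delta), "/")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("sequences with no admissible site are reported by name", {
  seqs <- toy_seqs()
  psp <- new_psp(list(rep(0, 5), c(1, 0, 0, 0, 0)), c(1, 0), 3, seqs$ids,
                 strand_mode = "single")
  th <- pspm(matrix(0.25, 4, 3))
  ## under OOPS a sequence whose prior mass is all zero cannot host its site
  expect_error(e_step(seqs, model_params(th, 1, psp, "oops", uniform_bg,
                                         "single")), "a")
})

test_that("EM is stable at a planted fixed point and honors tol = Inf", {
  ## noiseless planted data: every sequence contains the same word
  seqs <- sequence_set(vapply(1:6, function(i)
    paste0(strrep("C", i), "TGACTCAG", strrep("A", 7 - i)), ""))
  psp <- make_uniform_psp(seqs, 8, strand_mode = "single")
  truth <- subsequence_to_pspm("TGACTCAG", beta = 1 - 1e-9)
  em <- run_em(truth, seqs, psp, uniform_bg, "oops", strand_mode = "single",
               tol = 1e-3)
  expect_lte(em$iterations, 2)
  expect_lt(max(abs(unclass(em$params$theta) - unclass(truth))), 0.02)

  em1 <- run_em(truth, seqs, psp, uniform_bg, "oops", strand_mode = "single",
                tol = Inf)
  expect_equal(em1$iterations, 1L)
})

test_that("the EM objective is non-decreasing from random starts", {
  set.seed(33)
  d <- generate_dataset(n = 12, len = 60, seed = 17)
  psp <- make_uniform_psp(d$seqs, 6)
  bg <- estimate_background(d$seqs, 0)
  for (rep in 1:6) {
    word <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    model <- if (rep %% 2 == 0) "zoops" else "oops"
    em <- run_em(subsequence_to_pspm(word), d$seqs, psp, bg, model,
                 gamma0 = 0.4)
    expect_true(all(diff(em$trace) >= -1e-8 * pmax(1, abs(em$trace[-1]))))
    tot <- em$z$z0 + motifem:::seq_group_sums(
      motifem:::em_context(d$seqs, psp, bg, 6, model, "double"),
      em$z$zf + em$z$zr)
    expect_equal(tot, rep(1, 12), tolerance = 1e-9)
  }
})
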