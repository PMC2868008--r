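test_that("starting PSPMs put beta on the word letters", {
  th <- subsequence_to_pspm("A", beta = 0.55)
  expect_equal(unname(th[, 1]), c(0.55, 0.15, 0.15, 0.15))
  set.seed(2)
  for (rep in 1:5) {
    word <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    th <- subsequence_to_pspm(word, beta = runif(1, 0.3, 0.9))
    expect_equal(unname(colSums(th)), rep(1, 6))
  }
  th1 <- subsequence_to_pspm("ACGT", beta = 1)
  expect_equal(unname(diag(unclass(th1))), rep(1, 4))
})

test_that("site likelihoods multiply column probabilities per strand", {
  u <- pspm(matrix(0.25, 4, 5))
  expect_equal(site_likelihood(u, "ACGTACGTA", 2), 0.25^5)
  pm <- pspm(matrix(c(1, 0, 0, 0), 4, 4))
  expect_equal(site_likelihood(pm, "AAAA", 1), 1)
  expect_error(site_likelihood(pm, "AAAA", 2), "outside")

  ## strand '-' likelihood equals '+' likelihood under the reverse complement
  set.seed(4)
  for (rep in 1:10) {
    th <- random_pspm(4)
    s <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    j <- sample(1:9, 1)
    expect_equal(site_likelihood(th, s, j, "-"),
                 site_likelihood(revcomp_pspm(th), s, j, "+"),
                 tolerance = 1e-12)
  }
})

test_that("weighted LLR matches direct arithmetic and reduces to plain LLR", {
  seqs <- sequence_set(c(s1 = "AA", s2 = "AC"))
  sites <- data.frame(seq = 1:2, pos = c(1L, 1L), strand = c("+", "+"))
  got <- weighted_llr(seqs, sites, 2, uniform_bg, weights = c(1, 0.5))
  expect_equal(got, 1.5 * log2(4) +
                 (log2((1 / 1.5) / 0.25) + 0.5 * log2((0.5 / 1.5) / 0.25)),
               tolerance = 1e-10)

  ## unit weights equal the per-site sum of column log-odds of empirical f
  set.seed(8)
  seqs2 <- sequence_set(vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), ""))
  sites2 <- data.frame(seq = 1:6, pos = sample(1:7, 6, TRUE),
                       strand = sample(c("+", "-"), 6, TRUE))
  w <- 4
  counts <- matrix(0, 4, w)
  comp <- c(4, 3, 2, 1)
  for (r in 1:6) {
    enc <- seqs2$enc[[r]][sites2$pos[r]:(sites2$pos[r] + w - 1)]
    if (sites2$strand[r] == "-") enc <- rev(comp[enc])
    for (k in 1:w) counts[enc[k], k] <- counts[enc[k], k] + 1
  }
  f <- counts / 6
  manual <- sum(ifelse(counts == 0, 0, counts * log2(f / 0.25)))
  expect_equal(weighted_llr(seqs2, sites2, w, uniform_bg), manual,
               tolerance = 1e-10)

  ## empirical frequencies equal to background give LLR 0
  seqs0 <- sequence_set(c(a = "AG", b = "CT", c = "GA", d = "TC"))
  sites0 <- data.frame(seq = 1:4, pos = 1L, strand = "+")
  expect_equal(weighted_llr(seqs0, sites0, 2, uniform_bg), 0)

  ## LLR of empirical frequencies is never negative (Gibbs inequality)
  for (rep in 1:5) {
    sites3 <- data.frame(seq = 1:6, pos = sample(1:7, 6, TRUE), strand = "+")
    expect_gte(weighted_llr(seqs2, sites3, 4, uniform_bg), -1e-12)
  }
})

test_that("information content scans windows for the densest region", {
  u <- pspm(matrix(0.25, 4, 8))
  expect_equal(information_content(u, window = 6), 0)
  pm <- pspm(matrix(c(1, 0, 0, 0), 4, 8))
  expect_equal(information_content(pm, window = 6), 2)

  set.seed(13)
  th <- random_pspm(9, alpha = 0.5)
  for (win in c(3, 6, 9)) {
    f <- unclass(th)
    colic <- apply(f, 2, function(col) sum(ifelse(col == 0, 0, col * log2(col / 0.25))))
    brute <- max(vapply(1:(9 - win + 1), function(j) mean(colic[j:(j + win - 1)]), 0))
    expect_equal(information_content(th, window = win), brute, tolerance = 1e-12)
  }
  expect_warning(ic <- information_content(th, window = 12), "whole motif")
  expect_equal(ic, information_content(th, window = 9))
})
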