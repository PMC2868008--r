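test_that("scaled distance attains its analytic bounds and hand values", {
  A <- pspm(matrix(c(1, 0, 0, 0), 4, 8))
  Tm <- pspm(matrix(c(0, 0, 0, 1), 4, 8))
  expect_equal(scaled_distance(A, Tm), 1)
  set.seed(51)
  f <- random_pspm(8)
  expect_equal(scaled_distance(f, f), 0)

  one_f <- pspm(matrix(c(1, 0, 0, 0), 4, 1))
  one_g <- pspm(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(scaled_distance(one_f, one_g), 0.5)

  expect_error(scaled_distance(A, pspm(matrix(0.25, 4, 5))), "aligned_distance")

  ## triangle inequality on width-matched motifs
  for (rep in 1:10) {
    x <- random_pspm(5); y <- random_pspm(5); z <- random_pspm(5)
    expect_lte(scaled_distance(x, z),
               scaled_distance(x, y) + scaled_distance(y, z) + 1e-12)
  }
})

test_that("aligned distance searches offsets and strands", {
  set.seed(53)
  g <- random_pspm(10)
  f <- pspm(unclass(g)[, 3:8])          # contiguous sub-motif
  r <- aligned_distance(f, g, ic_filter = FALSE)
  expect_equal(r$distance, 0)
  expect_equal(r$offset, 2)

  rc <- aligned_distance(revcomp_pspm(g), g, ic_filter = FALSE)
  expect_equal(rc$distance, 0)
  expect_equal(rc$strand, "-")

  for (rep in 1:10) {
    f <- random_pspm(sample(4:8, 1))
    g <- random_pspm(sample(4:8, 1))
    expect_equal(aligned_distance(f, g, ic_filter = FALSE)$distance,
                 brute_aligned_distance(f, g), tolerance = 1e-12)
    ## symmetry without the filter
    expect_equal(aligned_distance(f, g, ic_filter = FALSE)$distance,
                 aligned_distance(g, f, ic_filter = FALSE)$distance,
                 tolerance = 1e-12)
  }
})

test_that("the information-content filter rejects diffuse motifs", {
  set.seed(55)
  g <- random_pspm(8)
  u <- pspm(matrix(0.25, 4, 8))
  expect_equal(aligned_distance(u, g, ic_filter = TRUE)$distance, 1.0)
  expect_false(motif_success(u, u))
  sharp <- subsequence_to_pspm("ACGTACGT", beta = 1)
  expect_true(motif_success(sharp, sharp))
  ## strict inequality at the threshold
  expect_false(motif_success(sharp, sharp, threshold = 0))
})

test_that("AMA scores are background-calibrated odds ratios", {
  u <- pspm(matrix(0.25, 4, 4))
  expect_equal(ama_score(u, "ACGTACGTAC", uniform_bg, "double"), 1)
  expect_equal(ama_score(u, "ACGTACGTAC", uniform_bg, "single"), 1)

  th <- subsequence_to_pspm("ACGT", beta = 0.7)
  ## L = w: single site odds ratio
  expect_equal(ama_score(th, "ACGT", uniform_bg, "single"),
               site_likelihood(th, "ACGT", 1) / 0.25^4)
  expect_error(ama_score(th, "ACG", uniform_bg), "shorter")

  ## direct arithmetic on a toy sequence with an order-0 skewed background
  skew <- motifem:::new_background(
    list(stats::setNames(c(0.4, 0.3, 0.2, 0.1), c("A", "C", "G", "T"))), "dna")
  th2 <- subsequence_to_pspm("CA", beta = 0.6)
  s <- "CATG"
  hand <- mean(vapply(1:3, function(j) {
    win <- substr(s, j, j + 1)
    pbg <- prod(skew$p[strsplit(win, "")[[1]]])
    (site_likelihood(th2, s, j, "+") + site_likelihood(th2, s, j, "-")) / (2 * pbg)
  }, 0))
  expect_equal(ama_score(th2, s, skew, "double"), hand, tolerance = 1e-12)

  ## reverse-complement invariance in double-strand mode
  set.seed(57)
  for (rep in 1:5) {
    th3 <- random_pspm(5)
    sq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    expect_equal(ama_score(th3, sq, uniform_bg, "double"),
                 ama_score(revcomp_pspm(th3), revcomp_string(sq),
                           uniform_bg, "double"),
                 tolerance = 1e-12)
  }
})

test_that("rank correlation matches first-principles midrank Pearson", {
  expect_equal(spearman_cc(1:10, 1:10), 1)
  expect_equal(spearman_cc(1:10, 10:1), -1)
  expect_equal(spearman_cc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  expect_warning(r <- spearman_cc(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  set.seed(59)
  for (rep in 1:10) {
    x <- rnorm(20)
    y <- rnorm(20) + 0.5 * x
    got <- spearman_cc(x, y)
    expect_equal(got, brute_rank_pearson(x, y), tolerance = 1e-12)
    expect_true(got >= -1 && got <= 1)
    ## ties handled by midranks
    xt <- round(x)
    expect_equal(spearman_cc(xt, y), brute_rank_pearson(xt, y),
                 tolerance = 1e-12)
  }
})

test_that("the sign test is exact, symmetric and capped", {
  expect_equal(sign_test(5, 5), 1)
  expect_equal(sign_test(10, 0), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(sign_test(0, 10), sign_test(10, 0))
  expect_equal(sign_test(8, 2), 2 * pbinom(2, 10, 0.5), tolerance = 1e-12)
})
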