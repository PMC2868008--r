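test_that("column p-values match exhaustive enumeration for small columns", {
  skew <- motifem:::new_background(
    list(stats::setNames(c(0.4, 0.3, 0.2, 0.1), c("A", "C", "G", "T"))), "dna")
  for (bg in list(uniform_bg, skew)) {
    for (t in 1:4) {
      cnts <- all_count_vectors(t)
      for (r in seq_len(nrow(cnts))) {
        expect_equal(column_pvalue(cnts[r, ], t, bg),
                     brute_column_pvalue(cnts[r, ], t, bg$p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("column p-value degenerate cases", {
  expect_equal(column_pvalue(c(0, 0, 0, 0), 0, uniform_bg), 1)
  ## single draw: every column has LLR 2 bits
  for (a in 1:4) {
    cnt <- integer(4); cnt[a] <- 1L
    expect_equal(column_pvalue(cnt, 1, uniform_bg), 1)
  }
  expect_equal(column_pvalue(c(2, 0, 0, 0), 2, uniform_bg), 0.25)
  ## the minimum-LLR composition has p-value 1
  expect_equal(column_pvalue(c(1, 1, 1, 1), 4, uniform_bg), 1)
})

test_that("the lattice approximation agrees with enumeration", {
  t <- 210L
  p <- uniform_bg$p
  enum <- motifem:::llr_dist_enum(t, p)
  latt <- motifem:::llr_dist_lattice(t, p)
  for (obs in c(5, 15, 30, 60)) {
    pe <- enum$tail[max(1, findInterval(-(obs - 1e-9), -enum$llr))]
    pl <- latt$tail[max(1, findInterval(-(obs - 1e-9), -latt$llr))]
    expect_equal(log(pl), log(pe), tolerance = 0.15)
  }
})

test_that("product p-values follow the uniform-product tail", {
  expect_equal(product_pvalue(0.37), 0.37)
  expect_equal(product_pvalue(c(1, 1, 1)), 1)
  expect_equal(product_pvalue(c(0.01, 0.01)), 1e-4 * (1 + log(1e4)),
               tolerance = 1e-12)
  ## oracle: the tail of a Gamma(k, 1) of -log(product)
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(1:10, 1)
    ps <- runif(k)^2
    expect_equal(product_pvalue(ps),
                 pgamma(-sum(log(ps)), shape = k, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("motif E-values chain columns, product and placement count", {
  ## single sequence, single site, single placement: E equals the product
  ## p-value of the columns (N_ways = 1)
  seqs1 <- sequence_set(c(a = "AC"))
  s1 <- data.frame(seq = 1L, pos = 1L, strand = "+")
  got <- motif_evalue(seqs1, s1, 2, uniform_bg, "oops", "single")
  expect_equal(got$log10_evalue, 0)  # both columns have p-value 1 at nsites 1

  ## toy alignment of 3 identical width-2 sites: step-by-step recomputation
  seqs3 <- sequence_set(c(a = "AG", b = "AG", c = "AG"))
  s3 <- data.frame(seq = 1:3, pos = 1L, strand = "+")
  got3 <- motif_evalue(seqs3, s3, 2, uniform_bg, "zoops", "single")
  colp <- c(column_pvalue(c(3, 0, 0, 0), 3, uniform_bg),
            column_pvalue(c(0, 0, 3, 0), 3, uniform_bg))
  hand <- log10(product_pvalue(colp)) + log10(choose(3, 3) * 1 * 1 * 1)
  expect_equal(got3$log10_evalue, hand, tolerance = 1e-10)

  ## doubling every m_i adds t * log10(2) to the log E-value
  sA <- data.frame(seq = 1:2, pos = 1L, strand = "+")
  seqs_m2 <- sequence_set(c(a = "AGA", b = "AGC"))
  seqs_m4 <- sequence_set(c(a = "AGATC", b = "AGCTC"))
  e2 <- motif_evalue(seqs_m2, sA, 2, uniform_bg, "zoops", "single")$log10_evalue
  e4 <- motif_evalue(seqs_m4, sA, 2, uniform_bg, "zoops", "single")$log10_evalue
  expect_equal(e4 - e2, 2 * log10(2), tolerance = 1e-10)
})

test_that("prefix E-values equal per-prefix motif_evalue calls", {
  set.seed(31)
  d <- generate_dataset(n = 8, len = 40, seed = 5)
  bg <- estimate_background(d$seqs, 0)
  best <- data.frame(seq = 1:8, pos = sample(1:30, 8, TRUE),
                     strand = sample(c("+", "-"), 8, TRUE), z = runif(8))
  best <- best[order(-best$z), ]
  ev <- motifem:::prefix_log10_evalues(d$seqs, best, 8, bg, "zoops", "double")
  for (t in 2:8) {
    expect_equal(ev[t],
                 motif_evalue(d$seqs, best[1:t, ], 8, bg, "zoops",
                              "double")$log10_evalue,
                 tolerance = 1e-10)
  }
})
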