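test_that("column frequencies are weighted sums mapped to query coordinates", {
  fam <- aligned_family(c(s1 = "MV", s2 = "MD", s3 = "MD"), "s1")
  w <- c(s1 = 0.5, s2 = 0.25, s3 = 0.25)
  prof <- column_frequencies(fam, w)
  expect_equal(unname(prof$freq[1, "M"]), 1)
  expect_equal(unname(prof$freq[2, "V"]), 0.5)
  expect_equal(unname(prof$freq[2, "D"]), 0.5)

  # query gaps are skipped; positions are ungapped query coordinates
  fam2 <- aligned_family(c(q = "M-V", a = "MDV", b = "MDV"), "q")
  prof2 <- column_frequencies(fam2, uniform_weights(fam2))
  expect_equal(prof2$position, 1:2)
  expect_equal(prof2$column, c(1L, 3L))
  expect_equal(prof2$query_residue, c("M", "V"))
})

test_that("uniform weights reduce to plain column proportions", {
  set.seed(9)
  seqs <- stats::setNames(replicate(8, random_protein(25)), paste0("s", 1:8))
  fam <- aligned_family(seqs, "s1")
  prof <- column_frequencies(fam, uniform_weights(fam))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (p in c(1, 10, 25)) {
    counts <- table(factor(chars[, p], levels = AA20)) / 8
    expect_equal(prof$freq[p, ], c(unclass(counts)), tolerance = 1e-12)
  }
})

test_that("frequencies plus gap mass sum to one on random gapped columns", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 12
    ncol_ <- 100
    mat <- matrix(sample(c(AA20, "-", "X"), n * ncol_, replace = TRUE,
                         prob = c(rep(1, 20), 3, 1)), n, ncol_)
    mat[1, ] <- sample(AA20, ncol_, replace = TRUE)  # gap-free query
    seqs <- stats::setNames(apply(mat, 1, paste, collapse = ""),
                            paste0("s", 1:n))
    fam <- aligned_family(seqs, "s1")
    w <- stats::runif(n)
    w <- stats::setNames(w / sum(w), names(seqs))
    prof <- column_frequencies(fam, w)
    sums <- rowSums(prof$freq) + prof$gap_mass
    expect_true(all(abs(sums - 1) <= 1e-9))
  }
})

test_that("candidate sites require a unique winner that beats the cutoff", {
  fam <- aligned_family(c(
    s1 = paste(rep("A", 20), collapse = ""),
    s2 = paste(rep("A", 20), collapse = ""),
    s3 = paste(rep("A", 20), collapse = ""),
    s4 = paste(rep("A", 20), collapse = "")), "s1")
  # query matches the consensus everywhere: no sites
  prof <- column_frequencies(fam, uniform_weights(fam))
  expect_equal(nrow(candidate_sites(prof)), 0L)

  # weighted winner V at 43.04% over query D at position 17 -> "D17V"
  q <- paste(c(rep("A", 16), "D", rep("A", 3)), collapse = "")
  v <- paste(c(rep("A", 16), "V", rep("A", 3)), collapse = "")
  c1 <- paste(c(rep("A", 16), "C", rep("A", 3)), collapse = "")
  g <- paste(c(rep("A", 16), "G", rep("A", 3)), collapse = "")
  fam2 <- aligned_family(c(v = v, q = q, c1 = c1, g = g), "q")
  w <- c(v = 0.4304, q = 0.3, c1 = 0.1696, g = 0.1)
  sites <- candidate_sites(column_frequencies(fam2, w), cutoff = 40)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$label, "D17V")
  expect_equal(sites$position, 17)
  expect_equal(sites$frequency_pct, 43.04, tolerance = 1e-9)
  expect_equal(sites$filter_status, "candidate")

  # below the cutoff the site disappears; at a lower cutoff it reappears
  w2 <- c(v = 0.39, q = 0.31, c1 = 0.2, g = 0.1)
  prof2 <- column_frequencies(fam2, w2)
  expect_equal(nrow(candidate_sites(prof2, cutoff = 40)), 0L)
  expect_equal(nrow(candidate_sites(prof2, cutoff = 35)), 1L)
})

test_that("an exact argmax tie emits no site", {
  fam <- aligned_family(c(a = "V", b = "D", q = "A", x = "V", y = "D"), "q")
  w <- c(a = 0.25, b = 0.25, q = 0.1, x = 0.2, y = 0.2)
  sites <- candidate_sites(column_frequencies(fam, w), cutoff = 30)
  expect_equal(nrow(sites), 0L)
})

test_that("with uniform weights and no gaps candidates equal the majority-difference list", {
  set.seed(33)
  n <- 9
  mat <- matrix(sample(AA20, n * 60, replace = TRUE, prob = c(10, rep(1, 19))),
                n, 60)
  seqs <- stats::setNames(apply(mat, 1, paste, collapse = ""), paste0("s", 1:n))
  fam <- aligned_family(seqs, "s1")
  sites <- candidate_sites(column_frequencies(fam, uniform_weights(fam)),
                           cutoff = 40)
  # oracle: direct column count
  expected <- character(0)
  for (p in 1:60) {
    tab <- sort(table(mat[, p]), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next
    winner <- names(tab)[1]
    if (winner != mat[1, p] && tab[1] / n > 0.4)
      expected <- c(expected, paste0(mat[1, p], p, winner))
  }
  expect_setequal(sites$label, expected)
})

test_that("raising the cutoff never adds candidate sites", {
  set.seed(44)
  fam <- simulate_family(balanced8(0.15), random_protein(80), rate = 2,
                         seed = 44)$family
  prof <- column_frequencies(fam, uniform_weights(fam))
  counts <- vapply(c(10, 25, 40, 55, 70, 85),
                   function(ct) nrow(candidate_sites(prof, ct)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gap mass counts against the cutoff under the default denominator", {
  # winner V holds 20% of total weight but 50% of non-gap weight
  fam <- aligned_family(c(q = "A", a = "V", b = "V", c1 = "D",
                          d = "-", e = "-", f = "-", g = "-", h = "-",
                          i = "-"), "q")
  prof <- column_frequencies(fam, uniform_weights(fam))
  expect_equal(nrow(candidate_sites(prof, cutoff = 40)), 0L)
  expect_equal(nrow(candidate_sites(prof, cutoff = 40,
                                    denominator = "nongap")), 1L)
})
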