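# Position statistic: segmentation enumeration, window counts,
# multinomial LLR, segmentation selection.

test_that("default grid yields 32 segmentations; (24, 8, 1) yields 8", {
  expect_length(enumerate_segmentations(500), 32L)
  expect_length(enumerate_segmentations(24, list(c(8, 1))), 8L)
  expect_length(enumerate_segmentations(8, list(c(8, 8))), 1L)
  expect_error(enumerate_segmentations(10, list(c(8, 3))))  # s !| w
  expect_error(enumerate_segmentations(10, list(c(4, 8))))  # s > w
})

test_that("every segmentation partitions the codons exactly once", {
  set.seed(41)
  for (L in c(1L, 5L, 24L, 100L, 500L, sample(2:600, 5))) {
    for (seg in enumerate_segmentations(L)) {
      win <- segmentation_windows(seg, L)
      expect_equal(unname(win[1, "start"]), 0L)
      expect_equal(unname(win[nrow(win), "end"]), L)
      if (nrow(win) > 1)
        expect_equal(unname(win[-1, "start"]), unname(win[-nrow(win), "end"]))
      # interior windows have length w; edge windows may be shorter
      lens <- win[, "end"] - win[, "start"]
      if (nrow(win) > 2)
        expect_true(all(lens[-c(1, nrow(win))] == seg$window_size))
    }
  }
})

test_that("window counts follow the counting mode", {
  seg <- enumerate_segmentations(16, list(c(8, 8)))[[1]]
  wc <- window_counts(c(0L, 3L, 9L), c(1, 1, 1), c(0, 0, 0), seg, 16)
  expect_equal(wc$x_case, c(2L, 1L))
  expect_equal(wc$x_ctrl, c(0L, 0L))
  # two case heterozygotes at codon 3: 2 mutations but 1 position
  wc2 <- window_counts(3L, 2, 0, seg, 16, "mutations")
  expect_equal(wc2$x_case[1], 2L)
  wc3 <- window_counts(3L, 2, 0, seg, 16, "positions")
  expect_equal(wc3$x_case[1], 1L)
  # two variants at the same codon still one mutated position
  wc4 <- window_counts(c(3L, 3L), c(1, 2), c(0, 1), seg, 16, "positions")
  expect_equal(wc4$x_case[1], 1L)
  expect_equal(wc4$x_ctrl[1], 1L)
  empty <- window_counts(integer(0), numeric(0), numeric(0), seg, 16)
  expect_equal(empty$x_pooled, c(0L, 0L))
  expect_error(window_counts(16L, 1, 0, seg, 16), "outside")
})

test_that("multinomial LLR matches the independent likelihood oracle", {
  expect_equal(multinomial_llr(c(4, 0), c(0, 4)), 8 * log(5 / 3),
               tolerance = 1e-12)
  expect_equal(multinomial_llr(c(4, 0), c(0, 4)),
               oracle_multinomial_llr(c(4, 0), c(0, 4)), tolerance = 1e-12)
  expect_identical(multinomial_llr(c(2, 2), c(2, 2)), 0)
  # equal totals (9 vs 9) but shifted placement still score positive
  expect_equal(multinomial_llr(c(6, 3), c(3, 6)), 0.9832223,
               tolerance = 1e-6)
  set.seed(51)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    xc <- rpois(K, 2); xt <- rpois(K, 2)
    expect_equal(multinomial_llr(xc, xt), oracle_multinomial_llr(xc, xt),
                 tolerance = 1e-12)
    expect_equal(multinomial_llr(xc, xt), multinomial_llr(xt, xc))
  }
  expect_error(multinomial_llr(c(1, -1), c(0, 0)))
  expect_error(multinomial_llr(c(1, 1), c(1, 1, 1)))
})

test_that("smoothed theta vectors are normalized", {
  set.seed(52)
  for (i in 1:20) {
    K <- sample(1:8, 1)
    th <- multinomial_thetas(rpois(K, 3), rpois(K, 3))
    expect_equal(sum(th$theta_case), 1, tolerance = 1e-12)
    expect_equal(sum(th$theta_ctrl), 1, tolerance = 1e-12)
    expect_equal(sum(th$theta_pooled), 1, tolerance = 1e-12)
  }
})

test_that("segmentation selection equals exhaustive search", {
  # case variants packed in one 8-codon block, controls in another: the
  # winning segmentation separates them and matches the oracle maximum
  codons <- c(0L, 2L, 5L, 16L, 18L, 21L)
  a_case <- c(2, 1, 1, 0, 0, 0)
  a_ctrl <- c(0, 0, 0, 1, 2, 1)
  got <- best_segmentation(codons, a_case, a_ctrl, 64)
  expect_equal(got$llr, oracle_best_segmentation(codons, a_case, a_ctrl, 64),
               tolerance = 1e-12)
  expect_gt(got$llr, 0)
  set.seed(61)
  for (i in 1:40) {
    L <- sample(10:120, 1)
    nv <- sample(1:10, 1)
    codons <- sample(0:(L - 1), nv, replace = TRUE)
    a_case <- rpois(nv, 1)
    a_ctrl <- rpois(nv, 1)
    expect_equal(best_segmentation(codons, a_case, a_ctrl, L)$llr,
                 oracle_best_segmentation(codons, a_case, a_ctrl, L),
                 tolerance = 1e-12)
  }
})

test_that("identical case and control placements never score positive", {
  # the pooled estimate smooths less than the per-group estimates, so a
  # gene whose cases and controls coincide can only lose likelihood;
  # exactly uniform window counts score exactly 0
  codons <- c(1L, 7L, 30L)
  r <- best_segmentation(codons, c(1, 2, 1), c(1, 2, 1), 100)
  expect_lte(r$llr, 0)
  expect_equal(r$llr,
               oracle_best_segmentation(codons, c(1, 2, 1), c(1, 2, 1), 100))
  expect_identical(multinomial_llr(c(2, 2), c(2, 2)), 0)
})

test_that("variant input order never changes counts or LLR", {
  set.seed(71)
  codons <- sample(0:99, 12, replace = TRUE)
  a_case <- rpois(12, 1); a_ctrl <- rpois(12, 1)
  r1 <- best_segmentation(codons, a_case, a_ctrl, 100)
  perm <- sample(12)
  r2 <- best_segmentation(codons[perm], a_case[perm], a_ctrl[perm], 100)
  expect_equal(r1$llr, r2$llr)
  expect_equal(r1$counts$x_case, r2$counts$x_case)
})
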