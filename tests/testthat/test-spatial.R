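test_that("binning conserves points, honours edges and bin geometry", {
  # 4 points at the corners of a square frame, bin side = half the frame:
  # the bins are the quadrants and each holds one corner
  pts <- data.frame(taxon = "a", x = c(0, 199, 0, 199), y = c(0, 0, 199, 199))
  hg <- bin_points(pts, 200, 200, pixel_area_cm2 = 1e-4, bin_area_cm2 = 1)
  expect_equal(hg$bin_side_px, 100)
  expect_equal(dim(hg$counts$a), c(2, 2))
  expect_equal(as.numeric(hg$counts$a), c(1, 1, 1, 1))
  # single point occupies exactly one bin
  hg1 <- bin_points(data.frame(taxon = "a", x = 57, y = 23), 200, 100, 1e-4, 1)
  expect_equal(sum(hg1$counts$a), 1)
  expect_equal(sum(hg1$counts$a > 0), 1)
  # conservation and order invariance for a large random pattern
  set.seed(8)
  big <- data.frame(taxon = sample(c("a", "b"), 1000, TRUE),
                    x = runif(1000, 0, 200), y = runif(1000, 0, 100))
  hgb <- bin_points(big, 200, 100, 1e-4, 1)
  expect_equal(sum(hgb$counts$a) + sum(hgb$counts$b), 1000)
  hgs <- bin_points(big[sample(1000), ], 200, 100, 1e-4, 1)
  expect_identical(hgb$counts, hgs$counts)
})

test_that("nearest-neighbour counts match hand enumeration and conserve rows", {
  pts <- data.frame(taxon = c("A", "B"), x = c(0, 1), y = 0)
  N <- nn_contingency(pts)
  expect_equal(N["A", "B"], 1L)
  expect_equal(N["B", "A"], 1L)
  col <- data.frame(taxon = c("A", "A", "B"), x = c(0, 1, 3), y = 0)
  Nc <- nn_contingency(col)
  expect_equal(Nc["A", "A"], 2L)
  expect_equal(Nc["B", "A"], 1L)
  expect_equal(Nc["A", "B"], 0L)
  set.seed(12)
  rnd <- data.frame(taxon = sample(c("A", "B", "C"), 60, TRUE),
                    x = runif(60), y = runif(60))
  Nr <- nn_contingency(rnd)
  expect_equal(rowSums(Nr), c(table(factor(rnd$taxon, levels = colnames(Nr)))))
  expect_equal(Nr, oracle_nn_counts(rnd, sort(unique(rnd$taxon))),
               ignore_attr = TRUE)
  expect_error(nn_contingency(pts[1, ]), "2 points")
})

test_that("tied nearest neighbours break to the lowest record index", {
  # point 3 is equidistant from 1 and 2; the lower index must win
  pts <- data.frame(taxon = c("A", "B", "C"), x = c(-1, 1, 0), y = c(0, 0, 0))
  N <- nn_contingency(pts)
  expect_equal(N["C", "A"], 1L)
  expect_equal(N["C", "B"], 0L)
})

test_that("expected counts follow the random-labelling formulas", {
  E <- expected_counts(c(A = 3, B = 3))
  expect_equal(E["A", "A"], 1.2)
  expect_equal(E["A", "B"], 1.8)
  # single taxon: every neighbour is conspecific by necessity
  expect_equal(expected_counts(c(Z = 9))[1, 1], 9)
  # monotonicity: larger abundance, larger conspecific expectation
  E2 <- expected_counts(c(rare = 4, mid = 10, abundant = 40))
  expect_true(E2["rare", "rare"] < E2["mid", "mid"])
  expect_true(E2["mid", "mid"] < E2["abundant", "abundant"])
  # expectations conserve the total neighbour count
  expect_equal(sum(E2), 54)
  expect_error(expected_counts(c(A = 1)), ">= 2")
})

test_that("segregation index is zero at expected odds and matches the hand oracle", {
  # n = (4, 3): S_AA = 0 exactly when N_AA = 2
  obs <- matrix(c(2L, 2L, 2L, 1L), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  S <- segregation_index(obs, c(A = 4, B = 3))
  expect_equal(S$S["A", "A"], 0)
  expect_equal(S$S, oracle_segregation(obs, c(A = 4, B = 3)))
  # conspecific excess -> S > 0; heterospecific deficit -> S < 0
  obs2 <- matrix(c(30L, 10L, 10L, 30L), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  S2 <- segregation_index(obs2, c(A = 40, B = 40))
  expect_gt(S2$S["A", "A"], 0)
  expect_lt(S2$S["A", "B"], 0)
  # collinear 3-point configuration against the first-principles oracle
  col <- data.frame(taxon = c("A", "A", "B"), x = c(0, 1, 3), y = 0)
  N <- nn_contingency(col)
  S3 <- segregation_index(N, c(A = 2, B = 1))
  expect_equal(S3$S, oracle_segregation(N, c(A = 2, B = 1)))
  expect_false(all(S3$finite))   # degenerate odds flagged, not hidden
  expect_error(segregation_index(obs, c(A = 5, B = 3)), "row sums")
})

test_that("pooling over frames: single frame reduces, identical frames double", {
  pts <- segregated_points(1)
  one <- nn_segregation(pts)
  Sdir <- segregation_index(nn_contingency(pts),
                            table(factor(pts$taxon, levels = c("A", "B", "C"))))
  expect_equal(one$S, Sdir$S)
  two <- rbind(pts, transform(pts, frame = 2))
  pooled <- nn_segregation(two)
  expect_equal(pooled$observed, 2 * one$observed)
  expect_equal(pooled$expected, 2 * one$expected)
  expect_equal(pooled$S, one$S)   # odds are scale-free under exact doubling
})

test_that("a segregated 3-taxon pattern reproduces the conspecific-positive sign structure", {
  pts <- segregated_points(100)
  seg <- nn_segregation(pts)
  expect_equal(unname(rowSums(seg$observed)), unname(seg$abundances))
  expect_true(all(diag(seg$S) > 0))
  off <- seg$S[row(seg$S) != col(seg$S)]
  expect_true(all(off < 0))
  # random labelling drives S toward zero
  set.seed(99)
  mean_abs <- mean(abs(seg$S))
  shuf <- replicate(200, {
    p2 <- pts
    p2$taxon <- ave(p2$taxon, p2$frame, FUN = sample)
    mean(abs(nn_segregation(p2)$S))
  })
  expect_lt(mean(shuf), mean_abs)
})

test_that("frames with fewer than two points are skipped with a warning", {
  pts <- rbind(segregated_points(2),
               data.frame(frame = 3, taxon = "A", x = 1, y = 1))
  expect_warning(seg <- nn_segregation(pts), "skipped")
  expect_equal(unname(seg$n_frames), c(2L, 3L))
})
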