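test_that("cumulative DVH matches counting oracles", {
  sh <- c(10, 10, 1)
  mask <- array(TRUE, sh)
  # uniform 2 Gy: step function
  dvh <- compute_dvh(array(2, sh), mask, bin_width = 0.1)
  expect_equal(dvh$volume_fraction[dvh$dose_axis <= 2],
               rep(1, sum(dvh$dose_axis <= 2)))
  expect_equal(dvh$volume_fraction[dvh$dose_axis > 2],
               rep(0, sum(dvh$dose_axis > 2)))
  # half at 1 Gy, half at 3 Gy: volume_fraction(2) = 0.5
  d <- array(c(rep(1, 50), rep(3, 50)), sh)
  dvh2 <- compute_dvh(d, mask, bin_width = 0.05)
  expect_equal(dvh2$volume_fraction[which.min(abs(dvh2$dose_axis - 2))], 0.5)
  # monotone non-increasing for random grids
  set.seed(2)
  dvh3 <- compute_dvh(array(rexp(100), sh), mask)
  expect_true(all(diff(dvh3$volume_fraction) <= 0))
  expect_error(compute_dvh(d, array(FALSE, sh)), "empty")
  expect_error(compute_dvh(d, mask, bin_width = 0), "positive")
})

test_that("Dx follows the sorted-voxel quantile oracle", {
  doses <- sample(1:100)      # 100 voxels, doses 1..100
  expect_equal(dx_values(doses, 5), 96)   # hottest 5 voxels are 96..100
  expect_equal(dx_values(doses, 50), 51)
  expect_equal(dx_values(doses, 95), 6)
  # brute-force bracket on random vectors: the interpolated quantile lies
  # between the min over the hottest ceil(x% n) voxels and the min over the
  # hottest floor(x% n) voxels
  set.seed(3)
  v <- rexp(57)
  s <- sort(v, decreasing = TRUE)
  for (x in c(5, 33, 75)) {
    lo <- min(s[seq_len(ceiling(x / 100 * 57))])
    hi <- min(s[seq_len(max(1, floor(x / 100 * 57)))])
    expect_gte(dx_values(v, x), lo - 1e-12)
    expect_lte(dx_values(v, x), hi + 1e-12)
  }
  # uniform dose: Dx = u for every x
  expect_equal(dx_values(rep(2.5, 40), c(5, 50, 95)), rep(2.5, 3))
  # ordering: D5 >= D95
  expect_gte(dx_values(v, 5), dx_values(v, 95))
  expect_error(dx_values(v, 0), "between 0 and 100")
  # curve-based accessor agrees with the raw-voxel quantile
  dvh <- compute_dvh(array(doses, c(10, 10, 1)), array(TRUE, c(10, 10, 1)))
  expect_equal(dx(dvh, 5), 96)
})

test_that("full-treatment tables scale linearly with fraction number", {
  case <- small_case("D")
  sh <- case$grid$shape
  set.seed(4)
  plan <- list(bio = array(runif(prod(sh), 0, 2), sh))
  t1 <- full_treatment_table(plan, case$structures,
                             list(n_fractions = 1))
  t28 <- full_treatment_table(plan, case$structures,
                              list(n_fractions = 28))
  t56 <- full_treatment_table(plan, case$structures,
                              list(n_fractions = 56))
  num <- setdiff(names(t1), "roi")
  expect_equal(as.matrix(t28[num]), 28 * as.matrix(t1[num]))
  expect_equal(as.matrix(t56[num]), 2 * as.matrix(t28[num]))
  # Dx non-increasing in x within each ROI
  for (i in seq_len(nrow(t28))) {
    expect_true(all(diff(as.numeric(t28[i, num])) <= 1e-12))
  }
})

test_that("difference tables subtract elementwise with the stated sign", {
  t1 <- data.frame(roi = c("ptv", "oar"), D5 = c(57, 30), D95 = c(50, 5))
  class(t1) <- c("dx_table", "data.frame")
  t2 <- data.frame(roi = c("ptv", "oar"), D5 = c(56, 33), D95 = c(51, 2))
  class(t2) <- c("dx_table", "data.frame")
  d <- dvh_difference_table(t1, t2)
  expect_equal(d$D5, c(1, -3))
  expect_equal(d$D95, c(-1, 3))
  # A = B -> zeros; antisymmetry
  z <- dvh_difference_table(t1, t1)
  expect_true(all(as.matrix(z[-1]) == 0))
  d2 <- dvh_difference_table(t2, t1)
  expect_equal(as.matrix(d2[-1]), -as.matrix(d[-1]))
  t3 <- t2; t3$roi <- c("ptv", "other")
  expect_error(dvh_difference_table(t1, t3), "mismatch")
})

test_that("dose-level masks are nested at the six standard thresholds", {
  sh <- c(8, 8, 2)
  # uniform dose equal to prescription: all masks full except the 107% one
  m <- dose_level_masks(array(54, sh), 54)
  for (nm in c(">10%", ">20%", ">50%", ">80%", ">95%")) {
    expect_true(all(m[[nm]]))
  }
  expect_false(any(m[[">107%"]]))
  # nesting + counting oracle on a random grid
  set.seed(6)
  d <- array(runif(prod(sh), 0, 70), sh)
  m2 <- dose_level_masks(d, 54)
  lv <- c(10, 20, 50, 80, 95, 107)
  for (k in seq_along(lv)) {
    expect_equal(sum(m2[[k]]), sum(d > lv[k] / 100 * 54))
    if (k > 1) expect_true(all(m2[[k]] <= m2[[k - 1]]))
  }
  expect_error(dose_level_masks(d, 0), "positive")
})

test_that("dose-difference maps threshold each overdose direction", {
  sh <- c(6, 6, 2)
  a <- array(10, sh); b <- a
  m0 <- dose_difference_map(a, b)
  expect_false(any(unlist(m0)))
  # A = B + 7: levels 3 and 6 full, rest empty; reverse map empty
  m7 <- dose_difference_map(a + 7, a)
  expect_true(all(m7$a_minus_b[[">3Gy(RBE)"]]))
  expect_true(all(m7$a_minus_b[[">6Gy(RBE)"]]))
  for (nm in c(">9Gy(RBE)", ">12Gy(RBE)", ">15Gy(RBE)", ">18Gy(RBE)")) {
    expect_false(any(m7$a_minus_b[[nm]]))
  }
  expect_false(any(unlist(m7$b_minus_a)))
  # disjoint supports on random grids
  set.seed(7)
  a2 <- array(runif(prod(sh), 0, 30), sh)
  b2 <- array(runif(prod(sh), 0, 30), sh)
  mr <- dose_difference_map(a2, b2)
  expect_false(any(mr$a_minus_b[[1]] & mr$b_minus_a[[1]]))
  expect_error(dose_difference_map(a2, array(0, c(2, 2, 2))), "shapes")
})

test_that("Dx tables round-trip through CSV bit-exactly", {
  set.seed(8)
  tab <- data.frame(roi = c("ptv", "brain_stem"),
                    D5 = runif(2) * 57, D50 = runif(2) * 50,
                    D95 = runif(2) * 45)
  class(tab) <- c("dx_table", "data.frame")
  path <- file.path(tempdir(), "dx_roundtrip.csv")
  write_dx_table(tab, path)
  back <- read_dx_table(path)
  expect_identical(back$D5, tab$D5)
  expect_identical(back$D50, tab$D50)
  expect_identical(back$D95, tab$D95)
  expect_identical(back$roi, tab$roi)
})

test_that("difference tables render with a configurable decimal mark", {
  tab <- data.frame(roi = "ptv", D5 = -1.25, D95 = 0.949)
  class(tab) <- c("dx_table", "data.frame")
  eu <- render_diff_table(tab, dec = ",")
  expect_equal(eu$D5, "-1,2")
  expect_equal(eu$D95, "0,9")
  us <- render_diff_table(tab, dec = ".")
  expect_equal(us$D5, "-1.2")
})
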