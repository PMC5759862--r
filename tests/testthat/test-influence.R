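test_that("a single spot's dose column reproduces the depth-dose curve", {
  wc <- water_case()
  model <- ion_beam_model("proton")
  infl <- compute_influence(wc$grid, wc$structures, wc$beams, model)
  # central spot: lateral position closest to the axis, mid energy layer
  sp <- infl$spots
  mid_r <- sort(unique(sp$range_w))[ceiling(length(unique(sp$range_w)) / 2)]
  cand <- which(sp$range_w == mid_r)
  j <- cand[which.min(sp$v[cand]^2 + sp$z[cand]^2)]
  col <- array(as.numeric(infl$D[, j]), dim = wc$grid$shape)
  curve <- bragg_curve("proton", mid_r)
  co <- grid_coords(wc$grid)
  # oracle: dose = curve(WED) x normalized lateral Gaussian; uniform water
  # phantom, so WED = distance from the upstream face
  sel <- which(col > 1e-3 * max(col))
  wed <- co$x[sel] - (wc$grid$origin[1] - 0.5)
  sig <- sigma_lateral("proton", wed, mid_r, sigma0 = 3)
  r2 <- (co$y[sel] - sp$v[j])^2 + (co$z[sel] - sp$z[j])^2
  expected <- approx(curve$depth, curve$dose, wed)$y *
    exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2)
  expect_equal(col[sel], expected, tolerance = 0.05)
})

test_that("accumulation is linear in the spot weights", {
  wc <- water_case()
  infl <- compute_influence(wc$grid, wc$structures, wc$beams,
                            ion_beam_model("proton"))
  n <- ncol(infl$D)
  expect_true(all(accumulate(infl, rep(0, n))$dose == 0))
  set.seed(1)
  w <- runif(n)
  g1 <- accumulate(infl, w)
  g2 <- accumulate(infl, 2 * w)
  expect_equal(g2$dose, 2 * g1$dose, tolerance = 1e-12)
  # doubling one spot's weight doubles its own contribution
  w2 <- w; w2[5] <- 2 * w[5]
  g3 <- accumulate(infl, w2)
  spot5 <- array(as.numeric(infl$D[, 5]), dim = wc$grid$shape)
  expect_equal(g3$dose - g1$dose, w[5] * spot5, tolerance = 1e-12)
})

test_that("mixed-field composition is the dose-weighted mean", {
  # one voxel, two spots of equal dose with LET 2 and 4 -> let_d = 3
  toy <- make_toy_influence(matrix(c(1, 1), 1, 2), c(2, 4), c(1, 1, 1))
  g <- accumulate(toy, c(1, 1))
  expect_equal(as.numeric(g$let_d), 3)
  # unequal doses: hand-computed dose-weighted mean
  g2 <- accumulate(toy, c(3, 1))
  expect_equal(as.numeric(g2$let_d), (3 * 2 + 1 * 4) / 4)
  # single component: voxel let_d equals the spot's own LET
  g3 <- accumulate(toy, c(1, 0))
  expect_equal(as.numeric(g3$let_d), 2)
  expect_equal(as.numeric(g3$alpha_ratio), 1 + 0.08 * 2 / 3.7)
})

test_that("LET and alpha grids match a brute-force per-voxel loop", {
  set.seed(42)
  shape <- c(4, 3, 2)
  nvox <- prod(shape); nspot <- 6
  D <- matrix(runif(nvox * nspot), nvox, nspot) *
    matrix(rbinom(nvox * nspot, 1, 0.6), nvox, nspot)
  lets <- runif(nspot, 1, 10)
  toy <- make_toy_influence(D, lets, shape, abx = 2.0, lambda = 0.08)
  w <- runif(nspot)
  g <- accumulate(toy, w)
  for (v in seq_len(nvox)) {
    contrib <- D[v, ] * w
    if (sum(contrib) > 0) {
      expect_equal(as.numeric(g$let_d)[v],
                   sum(contrib * lets) / sum(contrib), tolerance = 1e-12)
      expect_equal(as.numeric(g$alpha_ratio)[v],
                   sum(contrib * (1 + 0.08 * lets / 2)) / sum(contrib),
                   tolerance = 1e-12)
      # mixture bound: within the contributing spots' LET range
      rng <- range(lets[contrib > 0])
      expect_gte(as.numeric(g$let_d)[v], rng[1] - 1e-12)
      expect_lte(as.numeric(g$let_d)[v], rng[2] + 1e-12)
    } else {
      expect_equal(as.numeric(g$let_d)[v], 0)
    }
  }
})

test_that("invalid weights and degenerate setups are rejected", {
  toy <- make_toy_influence(matrix(c(1, 1), 1, 2), c(2, 4), c(1, 1, 1))
  expect_error(accumulate(toy, c(-1, 1)), "non-negative")
  expect_error(accumulate(toy, c(1, 1, 1)), "number of spots")
  # a case whose PTV the beam cannot reach is rejected with a diagnostic
  wc <- water_case()
  wc$grid$rsp[] <- 0          # nothing stops the beam: zero WED everywhere
  expect_error(
    compute_influence(wc$grid, wc$structures, wc$beams,
                      ion_beam_model("proton")),
    "PTV")
})

test_that("influence triplet serialization round-trips through disk", {
  toy <- make_toy_influence(matrix(c(1, 0.5, 0, 2), 2, 2), c(2, 4),
                            c(2, 1, 1))
  stem <- file.path(tempdir(), "toy_infl")
  files <- write_influence(toy, stem)
  expect_true(all(file.exists(files)))
  trip <- read.csv(files[1])
  D2 <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$d,
                             dims = dim(toy$D))
  expect_equal(as.matrix(D2), as.matrix(toy$D), ignore_attr = TRUE)
  meta <- jsonlite::read_json(files[3])
  expect_equal(meta$ion, "proton")
})
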