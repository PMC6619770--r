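test_that("water-voxel assignment uses half-open boxes", {
  # voxel centers at 0.5..3.5 so voxel i covers [i-1, i)
  geom <- list(origin = c(0.5, 0.5, 0.5), spacing = 1, shape = c(4L, 4L, 4L))
  mkframe <- function(o) {
    o <- matrix(o, ncol = 3, byrow = TRUE)
    n <- nrow(o)
    new("WaterFrameSet",
        frames = list(list(O = o,
                           H1 = o + rep(c(0.757, 0, 0.586), each = n),
                           H2 = o + rep(c(-0.757, 0, 0.586), each = n))),
        region = c(0, 4, 0, 4, 0, 4))
  }
  asg <- assignWaters(mkframe(c(0, 0.5, 0.5)), geom)   # exact lower corner
  expect_equal(asg$counts[1, 1, 1], 1L)
  asg2 <- assignWaters(mkframe(c(1, 0.5, 0.5)), geom)  # boundary -> voxel 2
  expect_equal(asg2$counts[2, 1, 1], 1L)
  expect_equal(asg2$counts[1, 1, 1], 0L)
  # outside the grid: unassigned
  asg3 <- assignWaters(mkframe(c(7, 0.5, 0.5)), geom)
  expect_true(is.na(asg3$index[[1]][1]))
  expect_equal(sum(asg3$counts), 0L)
  # containment count: uniform points, grid interior to the region
  set.seed(21)
  o <- matrix(stats::runif(3000, 0, 4), ncol = 3)
  fr <- mkframe(as.vector(t(o)))
  asg4 <- assignWaters(fr, geom)
  inside <- colSums(apply(o, 1, function(p) p >= 0 & p < 4)) == 3
  expect_equal(sum(asg4$counts), sum(inside))
})

test_that("translational entropy density matches its closed form", {
  rho0 <- 0.0334
  g <- array(c(1, 2, 0, 0.5), c(4, 1, 1))
  ds <- translationalEntropy(g, rho0)
  kB <- 0.0019872041
  expect_equal(ds[1, 1, 1], 0)                       # g = 1
  expect_equal(ds[3, 1, 1], 0)                       # empty voxel
  expect_equal(ds[2, 1, 1], -kB * rho0 * 2 * log(2))
  # printed check with the voxel volume: g=2, Vk = 0.125
  expect_equal(ds[2, 1, 1] * 0.125, -kB * 0.0334 * 2 * log(2) * 0.125)
  expect_equal(ds[4, 1, 1], -kB * rho0 * 0.5 * log(0.5))
  expect_gt(ds[4, 1, 1], 0)  # sub-bulk voxels contribute positive density
})

test_that("ideal-gas frames recover the null GIST signature", {
  # interior grid (6 A cube inside an 10 A box) so every voxel is fully
  # covered by the sampling region
  reg <- c(0, 10, 0, 10, 0, 10)
  nw <- 300; nf <- 200
  fr <- makeFrames("ideal_gas", nFrames = nf, nWaters = nw, region = reg,
                   seed = 42)
  geom <- alignGrid(c(5, 5, 5), 2, c(3L, 3L, 3L))
  rho0 <- nw / 1000
  res <- runGIST(fr, geom, model = waterModel(), rho0 = rho0,
                 minOrientSamples = 100)
  # occupancy ~ 1 with binomial sampling error
  nExp <- nf * rho0 * 8
  seG <- sqrt(nExp * (1 - 8 / 1000)) / nExp
  expect_true(all(abs(res@g - 1) < 4 * seG))
  # entropies vanish within 3 standard errors: compare across voxels
  expect_lt(abs(mean(res@dStrans)) ,
            3 * stats::sd(res@dStrans) / sqrt(length(res@dStrans)) + 1e-6)
  expect_lt(max(abs(res@dSorient)), 5e-4)
  # no interactions configured in the fixture run below: zero energies
  w0 <- buildCTIP3P(chargeO = 0, epsilonO = 0, epsilonH = 0)
  en <- gistEnergies(fr, assignWaters(fr, geom), w0)
  expect_equal(max(abs(en$dEsw)), 0)
  expect_equal(max(abs(en$dEww)), 0)
})

test_that("half-box frames recover g = 2 and the g ln g entropy", {
  reg <- c(0, 8, 0, 8, 0, 8)
  nw <- 200; nf <- 400
  fr <- makeFrames("half_box", nFrames = nf, nWaters = nw, region = reg,
                   seed = 17)
  # occupied half is x in [0, 4); grid voxels interior to each half
  geom <- alignGrid(c(4, 4, 4), 1, c(6L, 6L, 6L))   # centers 1.5..6.5
  rho0 <- nw / 512
  res <- runGIST(fr, geom, model = waterModel(), rho0 = rho0,
                 minOrientSamples = 1e9)
  occ <- res@g[1:2, , ]        # centers 1.5, 2.5: fully occupied half
  emp <- res@g[5:6, , ]        # centers 5.5, 6.5: empty half
  nExp <- nf * rho0 * 2
  se <- sqrt(nExp) / nExp * 2
  expect_equal(mean(occ), 2, tolerance = 3 * se / sqrt(length(occ)) * 2)
  expect_equal(max(emp), 0)
  kB <- 0.0019872041
  target <- -kB * rho0 * 2 * log(2)
  # small Jensen bias of g ln g at finite per-voxel counts: allow 5%
  expect_equal(mean(res@dStrans[1:2, , ]), target, tolerance = 0.05)
  # empty voxels carry zeros
  expect_equal(max(abs(res@dStrans[5:6, , ])), 0)
})

test_that("first-order translational entropy is non-positive in expectation", {
  # Gibbs: E[g ln g] >= (E g) ln (E g) = 0 for any occupancy distribution;
  # average over voxels and seeds
  reg <- c(0, 8, 0, 8, 0, 8)
  geom <- alignGrid(c(4, 4, 4), 2, c(3L, 3L, 3L))
  tots <- vapply(1:4, function(s) {
    fr <- makeFrames("ideal_gas", nFrames = 80, nWaters = 100, region = reg,
                     seed = 100 + s)
    res <- runGIST(fr, geom, model = waterModel(), rho0 = 100 / 512,
                   minOrientSamples = 1e9)
    mean(res@dStrans)
  }, 0)
  expect_lt(mean(tots), 0)
})

test_that("orientational NN estimator matches the quadrature oracle", {
  set.seed(31)
  kappa <- 8
  Q <- quatConcentrated(4000, kappa)
  D <- solvmap:::.nnOrientationKL(Q)
  Doracle <- orientationKLOracle(kappa)
  expect_equal(D, Doracle, tolerance = 0.1 * Doracle)
  # histogram estimator agrees at coarse accuracy
  Dh <- solvmap:::.histOrientationKL(Q)
  expect_equal(Dh, Doracle, tolerance = 0.2 * Doracle)
  # uniform orientations: KL ~ 0 (NN estimator is unbiased around 0)
  Qu <- quatUniform(4000)
  expect_lt(abs(solvmap:::.nnOrientationKL(Qu)), 0.1)
  # literally identical orientations: KL far above any physical value --
  # the estimator floor set by the distance clamp (for the k = 1
  # Kozachenko-Leonenko form the floor recedes like log(n-1), so more
  # samples give a slightly smaller, still enormous, estimate)
  qid <- quatUniform(1)
  D200 <- solvmap:::.nnOrientationKL(qid[rep(1, 200), ])
  D800 <- solvmap:::.nnOrientationKL(qid[rep(1, 800), ])
  expect_gt(D200, 10)
  expect_gt(D800, 10)
  expect_equal(D200 - D800, log(799 / 199), tolerance = 1e-6)
})

test_that("voxels with too few orientation samples are flagged", {
  reg <- c(0, 6, 0, 6, 0, 6)
  fr <- makeFrames("ideal_gas", nFrames = 5, nWaters = 20, region = reg,
                   seed = 3)
  geom <- alignGrid(c(3, 3, 3), 2, c(2L, 2L, 2L))
  asg <- assignWaters(fr, geom)
  or <- orientationalEntropy(fr, asg, rho0 = 20 / 216, minSamples = 1e6)
  expect_equal(max(abs(or$density)), 0)
  expect_gt(or$nFlagged, 0)
})

test_that("pair energies match the hand-evaluated dimer oracle", {
  w <- waterModel()
  q0 <- c(1, 0, 0, 0)
  w1 <- solvmap:::.buildWaters(matrix(c(0, 0, 0), 1), matrix(q0, 1), w)
  w2 <- solvmap:::.buildWaters(matrix(c(2.76, 0.3, -0.2), 1),
                               matrix(c(0.8, 0.1, -0.5,
                                        sqrt(1 - 0.8^2 - 0.1^2 - 0.5^2)),
                                      1), w)
  eOracle <- waterPairEnergyOracle(
    list(O = w1$O[1, ], H1 = w1$H1[1, ], H2 = w1$H2[1, ]),
    list(O = w2$O[1, ], H1 = w2$H1[1, ], H2 = w2$H2[1, ]), w)
  fr <- new("WaterFrameSet",
            frames = list(list(O = rbind(w1$O, w2$O),
                               H1 = rbind(w1$H1, w2$H1),
                               H2 = rbind(w1$H2, w2$H2))),
            region = c(-10, 10, -10, 10, -10, 10))
  geom <- alignGrid(c(0, 0, 0), 20, c(1L, 1L, 1L))
  asg <- assignWaters(fr, geom)
  en <- gistEnergies(fr, asg, w)
  # both half-contributions fall in the single voxel: total = full pair
  expect_equal(en$dEww[1, 1, 1] * 20^3, eOracle, tolerance = 1e-10)
  # Ebulk reference shifts each water by -Ebulk
  en2 <- gistEnergies(fr, asg, w, Ebulk = 1.5)
  expect_equal(en2$dEww[1, 1, 1] * 20^3, eOracle - 2 * 1.5,
               tolerance = 1e-10)
  # solute energies vanish without a solute
  expect_equal(max(abs(en$dEsw)), 0)
  # and match a direct site sum with one
  sol <- makeToySolute("lj_sphere", sigma = 3.0, epsilon = 0.2,
                       center = c(1, 1, 1))
  en3 <- gistEnergies(fr, asg, w, solute = sol)
  expect_true(is.finite(en3$dEsw[1, 1, 1]) && en3$dEsw[1, 1, 1] != 0)
})

test_that("per-voxel standard errors shrink like sqrt(n_frames)", {
  reg <- c(0, 8, 0, 8, 0, 8)
  geom <- alignGrid(c(4, 4, 4), 2, c(3L, 3L, 3L))
  gsd <- function(nf, seed) {
    fr <- makeFrames("ideal_gas", nFrames = nf, nWaters = 150, region = reg,
                     seed = seed)
    res <- runGIST(fr, geom, model = waterModel(), rho0 = 150 / 512,
                   minOrientSamples = 1e9)
    stats::sd(res@g)      # scatter of g around 1 across 27 voxels
  }
  s1 <- mean(vapply(1:3, function(s) gsd(60, 200 + s), 0))
  s2 <- mean(vapply(1:3, function(s) gsd(240, 300 + s), 0))
  # quadrupling the frames should halve the error (allow wide slack)
  expect_equal(s1 / s2, 2, tolerance = 0.4)
})
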