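test_that("area_per_lipid is exact arithmetic", {
  f1 <- frame(matrix(0, 1, 3), c(64, 64, 70))
  f2 <- frame(matrix(0, 1, 3), c(60, 70, 70))
  expect_equal(area_per_lipid(list(f1), 128)$series, 64)
  expect_equal(area_per_lipid(list(f2), 128)$series, 65.625)
  expect_error(area_per_lipid(list(f1), 127), "even")
  ## fluctuating boxes vs an independent two-pass statistics oracle
  set.seed(3)
  L <- 64 + rnorm(50, 0, 0.5)
  frames <- lapply(L, function(l) frame(matrix(0, 1, 3), c(l, l, 70)))
  r <- area_per_lipid(frames, 128)
  oracle <- L^2 / 64
  expect_equal(r$series, oracle, tolerance = 1e-12)
  expect_equal(r$mean, sum(oracle) / 50, tolerance = 1e-12)
  expect_equal(r$sd, sqrt(sum((oracle - mean(oracle))^2) / 49),
               tolerance = 1e-12)
})

test_that("volume_per_lipid is exact arithmetic and validates inputs", {
  ## 200000 A^3 box, 5120 waters x 30 A^3, 128 lipids -> 362.5
  f <- frame(matrix(0, 1, 3), c(50, 50, 80))
  expect_equal(volume_per_lipid(list(f), 5120, 30, 128)$series, 362.5)
  expect_equal(volume_per_lipid(list(f), 0, 30, 128)$series, 200000 / 128)
  expect_error(volume_per_lipid(list(f), 10000, 30, 128), "water_volume")
  ## randomized series against direct arithmetic
  set.seed(8)
  frames <- lapply(1:20, function(i) {
    frame(matrix(0, 1, 3), c(runif(1, 58, 62), runif(1, 58, 62),
                             runif(1, 75, 85)))
  })
  r <- volume_per_lipid(frames, 4000, 30.5, 128)
  oracle <- sapply(frames, function(f) (prod(f$box) - 4000 * 30.5) / 128)
  expect_equal(r$series, oracle, tolerance = 1e-12)
})

test_that("density_profile: single-atom electron weight, symmetry, oracle", {
  ## one carbon (Z = 6, q = -0.1) in one bin
  tr <- toy_trajectory(matrix(c(10, 10, 5), 1), box = c(40, 40, 60),
                       element = "C", charge = -0.1)
  p <- density_profile(tr, weighting = "electron", bin_width = 0.5)
  expect_equal(sum(p$value > 0), 1)
  expect_equal(max(p$value), 6.1 / (40 * 40 * 0.5))
  ## number-density integral returns the selected atom count
  set.seed(12)
  xyz <- cbind(runif(500, 0, 40), runif(500, 0, 40), runif(500, -25, 25))
  tr2 <- toy_trajectory(xyz, box = c(40, 40, 60))
  pn <- density_profile(tr2, weighting = "number", bin_width = 0.25)
  expect_equal(sum(pn$value) * 0.25 * 40 * 40, 500, tolerance = 1e-6)
  ## independent histogram oracle (centre of mass removed, same bins)
  com <- mean(xyz[, 3])
  zc <- xyz[, 3] - com
  half <- ceiling(30 / 0.25) * 0.25
  counts <- table(cut(zc, breaks = seq(-half, half, 0.25), right = FALSE))
  oracle <- as.numeric(counts) / (40 * 40 * 0.25)
  expect_equal(pn$value, oracle, tolerance = 1e-12)
  ## mirror-image leaflets give a symmetric profile
  zs <- c(seq(5.1, 20.1, by = 0.5))
  xyzm <- rbind(cbind(5, 5, zs), cbind(5, 5, -zs))
  trm <- toy_trajectory(xyzm, box = c(30, 30, 60))
  pm <- density_profile(trm, weighting = "number", bin_width = 0.5)
  expect_equal(pm$value, rev(pm$value), tolerance = 1e-12)
  expect_error(density_profile(tr, bin_width = 0), "positive")
})

test_that("dhh_from_profile measures peak separation", {
  expect_equal(dhh_from_profile(two_peak_profile(c(-19, 19))), 38,
               tolerance = 0.25 + 1e-9)
  expect_equal(dhh_from_profile(two_peak_profile(c(-18.5, 20.5))), 39,
               tolerance = 0.25 + 1e-9)
  ## noisy profile within one bin of the noiseless answer
  noiseless <- dhh_from_profile(two_peak_profile(c(-19, 19)))
  noisy <- dhh_from_profile(two_peak_profile(c(-19, 19), noise_sd = 0.005,
                                             seed = 3))
  expect_lte(abs(noisy - noiseless), 0.25)
  ## monotone profile has no straddling maxima
  z <- seq(-29.875, 29.875, by = 0.25)
  mono <- structure(list(z = z, value = seq_along(z) * 1e-3),
                    class = "density_profile", bin_width = 0.25)
  expect_error(dhh_from_profile(mono), "maxima")
})

test_that("order_parameters hits the axial/planar/isotropic limits", {
  ## geometry: C at origin-ish, H displaced along a chosen direction
  build <- function(dirs) {
    n <- nrow(dirs)
    c_xyz <- cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, -10, 10))
    xyz <- rbind(c_xyz, c_xyz + 1.09 * dirs)
    tr <- toy_trajectory(xyz, box = c(30, 30, 40),
                         element = c(rep("C", n), rep("H", n)))
    pairs <- data.frame(carbon = seq_len(n), hydrogen = n + seq_len(n),
                        chain = "sn-1", carbon_index = 1L)
    order_parameters(tr, pairs)
  }
  set.seed(19)
  ## axial: all C-H along z
  ax <- build(matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE))
  expect_equal(ax$scd_abs, 1.0, tolerance = 1e-12)
  expect_equal(ax$scd_signed, 1.0, tolerance = 1e-12)
  ## planar: all C-H in the xy-plane
  phi <- runif(50, 0, 2 * pi)
  pl <- build(cbind(cos(phi), sin(phi), 0))
  expect_equal(pl$scd_signed, -0.5, tolerance = 1e-12)
  expect_equal(pl$scd_abs, 0.5, tolerance = 1e-12)
  ## isotropic: 1e5 uniform orientations -> |S_CD| <= 0.01
  u <- runif(1e5, -1, 1); ph2 <- runif(1e5, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  iso <- build(cbind(s * cos(ph2), s * sin(ph2), u))
  expect_lte(iso$scd_abs, 0.01)
  ## zero-length C-H vector errors
  xyz <- matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  tr0 <- toy_trajectory(xyz, element = c("C", "H"))
  expect_error(order_parameters(tr0, data.frame(
    carbon = 1, hydrogen = 2, chain = "sn-1", carbon_index = 1)),
    "zero-length")
})

test_that("order_parameters is invariant under rigid rotation about z", {
  set.seed(23)
  n <- 200
  dirs <- cbind(rnorm(n), rnorm(n), rnorm(n))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  c_xyz <- cbind(runif(n, 5, 25), runif(n, 5, 25), runif(n, -10, 10))
  make_tr <- function(rot) {
    xyz <- rbind(c_xyz %*% t(rot), (c_xyz + 1.09 * dirs) %*% t(rot))
    toy_trajectory(xyz, box = c(60, 60, 40),
                   element = c(rep("C", n), rep("H", n)))
  }
  pairs <- data.frame(carbon = 1:n, hydrogen = n + 1:n, chain = "sn-1",
                      carbon_index = 1L)
  a <- pi / 5
  rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  s0 <- order_parameters(make_tr(diag(3)), pairs)
  s1 <- order_parameters(make_tr(rot), pairs)
  expect_equal(s1$scd_signed, s0$scd_signed, tolerance = 1e-12)
})

test_that("xray_form_factor: zero contrast, Gaussian pair, F(0), linearity", {
  z <- seq(-29.875, 29.875, by = 0.25)
  flat <- structure(list(z = z, value = rep(0.333, length(z))),
                    class = "density_profile", bin_width = 0.25)
  expect_true(all(xray_form_factor(flat)$magnitude == 0))
  ## Gaussian contrast against the analytic Fourier pair
  A <- 0.08; sg <- 2.5
  gp <- structure(list(z = z, value = 0.333 + A * exp(-z^2 / (2 * sg^2))),
                  class = "density_profile", bin_width = 0.25)
  ff <- xray_form_factor(gp)
  closed <- A * sg * sqrt(2 * pi) * exp(-ff$q^2 * sg^2 / 2)
  expect_lt(max(abs(ff$magnitude - closed)) / max(closed), 0.005)
  ## F(0) equals the trapezoid integral of the contrast
  contrast <- gp$value - 0.333
  f0_oracle <- sum(diff(z) * (contrast[-1] + contrast[-length(z)]) / 2)
  expect_equal(ff$magnitude[1], f0_oracle, tolerance = 1e-12)
  ## linearity: doubling contrast doubles |F|
  gp2 <- structure(list(z = z, value = 0.333 + 2 * A * exp(-z^2 / (2 * sg^2))),
                   class = "density_profile", bin_width = 0.25)
  expect_equal(xray_form_factor(gp2)$magnitude, 2 * ff$magnitude,
               tolerance = 1e-12)
  expect_error(xray_form_factor(gp, q_grid = numeric(0)), "q_grid")
})

test_that("neutron_form_factor: zero contrast, boxcar transform, D2O switch", {
  z <- seq(-29.875, 29.875, by = 0.25)
  sol <- 6.4e-6
  flat <- structure(list(z = z, value = rep(sol, length(z))),
                    class = "density_profile", bin_width = 0.25)
  expect_true(all(neutron_form_factor(flat, solvent_sld = sol)$magnitude == 0))
  ## boxcar contrast: 2 dr sin(qw/2)/q; half-height edge samples make
  ## the trapezoid rule agree with the closed form
  w <- 20; dr <- 2e-6
  val <- ifelse(abs(z) < w / 2, dr, 0)
  val[abs(abs(z) - w / 2) < 0.125] <- dr / 2
  box <- structure(list(z = z, value = val),
                   class = "density_profile", bin_width = 0.25)
  q <- seq(0.01, 0.8, by = 0.005)
  fn <- neutron_form_factor(box, solvent_sld = 0, q_grid = q)
  closed <- abs(2 * dr * sin(q * w / 2) / q)
  expect_lt(max(abs(fn$magnitude - closed)) / max(closed), 0.005)
  ## d2o_fraction changes only water-hydrogen terms: a lipid-only
  ## trajectory yields the same SLD profile at 0 and 100 percent D2O
  g <- make_bilayer_traj(n_lipids = 16, n_frames = 1, seed = 2)
  f0 <- neutron_form_factor(g$traj, d2o_fraction = 0, solvent_sld = 0)
  f1 <- neutron_form_factor(g$traj, d2o_fraction = 1, solvent_sld = 0)
  expect_equal(f0$magnitude, f1$magnitude, tolerance = 1e-12)
  ## unknown element is named
  tr <- toy_trajectory(matrix(0, 1, 3))
  tr$topology$element <- "XX"
  expect_error(neutron_form_factor(tr), "XX")
})

test_that("cholesterol_tilt: zero tilt, constructed 13 degrees, sampling", {
  build_tilt <- function(angles_deg) {
    n <- length(angles_deg)
    o <- cbind(runif(n, 0, 30), runif(n, 0, 30), 15)
    phi <- runif(n, 0, 2 * pi)
    v <- 5 * cbind(sin(angles_deg * pi / 180) * cos(phi),
                   sin(angles_deg * pi / 180) * sin(phi),
                   -cos(angles_deg * pi / 180))
    xyz <- rbind(o, o + v)
    tr <- toy_trajectory(xyz, box = c(30, 30, 60),
                         element = c(rep("O", n), rep("C", n)))
    cholesterol_tilt(tr, seq_len(n), n + seq_len(n))
  }
  set.seed(29)
  ## all vectors along z
  r0 <- build_tilt(rep(0, 40))
  expect_lt(r0$mode_deg, 1)
  ## exactly 13 degrees: mode bin contains 13
  r13 <- build_tilt(rep(13, 40))
  expect_lte(abs(r13$mode_deg - 13), 1)
  ## wrapped-normal around 20 degrees: mode within one bin
  rn <- build_tilt(abs(rnorm(4000, 20, 1.5)))
  expect_lte(abs(rn$mode_deg - 20), 1)
  ## coincident atoms are skipped with a warning
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 4))
  tr <- toy_trajectory(xyz, element = c("O", "C", "O", "C"))
  expect_warning(rs <- cholesterol_tilt(tr, c(1, 3), c(2, 4)), "skipped")
  expect_equal(rs$n_skipped, 1L)
})

test_that("transit_events: band logic, classification, edge handling", {
  ## never enters the band
  expect_equal(transit_events(rep(15, 100))$total, 0)
  ## single crossing is one flip-flop
  r <- transit_events(c(15, 1, -15))
  expect_equal(r$total, 1)
  expect_equal(r$events$kind, "flip_flop")
  ## scripted series entering the band 3 times: flip, visit, flip
  z <- c(15, 10, 1, -1, -10, -15,       # flip
         -15, -8, -1.5, -0.5, -1.5, -9, -15,   # transient visit
         -15, -4, 0.5, 4, 15)           # flip
  r3 <- transit_events(z)
  expect_equal(r3$total, 3)
  expect_equal(r3$events$kind,
               c("flip_flop", "transient_visit", "flip_flop"))
  ## hand-traced run boundaries for the first event
  expect_equal(r3$events$start[1], 3)
  expect_equal(r3$events$end[1], 4)
  expect_equal(r3$events$start_leaflet[1], 1L)
  ## runs touching the series boundary are unresolved -> transient
  rb <- transit_events(c(1, 5, 15))
  expect_equal(rb$events$kind, "transient_visit")
  ## multi-molecule input
  rm <- transit_events(list(a = c(15, 1, -15), b = rep(9, 3)))
  expect_equal(rm$total, 1)
  expect_equal(rm$events$molecule, "a")
  expect_error(transit_events(numeric(0)), "empty")
})

test_that("transit counting is invariant to subsampling preserving visits", {
  zp <- make_z_paths(list(list(start_leaflet = 1,
                               visits = c("flip", "visit", "flip"))),
                     pad = 40, seed = 31)
  z <- zp$z[[1]]
  full <- transit_events(z)
  sub <- transit_events(z[seq(1, length(z), by = 2)])
  expect_equal(sub$total, full$total)
  expect_equal(sub$events$kind, full$events$kind)
  ## documented limitation: subsampling that skips a whole visit
  ## changes the count (drop the frames of the transient visit)
  visit_evt <- full$events[full$events$kind == "transient_visit", ]
  drop <- setdiff(seq_along(z), visit_evt$start:visit_evt$end)
  fewer <- transit_events(z[drop])
  expect_lt(fewer$total, full$total)
})

test_that("melting_point finds logistic midpoints and rejects degeneracy", {
  g319 <- make_heating_scan(midpoint = 319, sigma = 0)
  expect_lte(abs(melting_point(g319$scan, 128)$tm - 319), 0.5)
  g335 <- make_heating_scan(midpoint = 335, sigma = 0)
  expect_lte(abs(melting_point(g335$scan, 128)$tm - 335), 0.5)
  ## linear APL: constant derivative -> no distinct inflection
  tm <- seq(0, 100, by = 0.05)
  lin <- data.frame(time = tm, temperature = 300 + 0.5 * tm,
                    Lx = sqrt((50 + 0.1 * tm) * 64),
                    Ly = sqrt((50 + 0.1 * tm) * 64))
  expect_error(melting_point(lin, 128), "inflection|constant")
  ## non-monotone temperature rejected
  bad <- g319$scan
  bad$temperature[10] <- bad$temperature[30]
  expect_error(melting_point(bad, 128), "monotone|non-decreasing")
  ## noisy recovery envelope: median error <= 1 K over 10 seeds
  errs <- vapply(0:9, function(s) {
    gs <- make_heating_scan(midpoint = 327.3, sigma = 0.5, seed = s)
    abs(melting_point(gs$scan, 128)$tm - 327.3)
  }, numeric(1))
  expect_lte(median(errs), 1)
  expect_lte(max(errs), 2)
})

test_that("two-column writer emits parseable SIMtoEXP-style text", {
  p <- two_peak_profile()
  f <- tempfile()
  write_two_column(p, f)
  back <- read.table(f)
  expect_equal(back$V1, p$z, tolerance = 1e-5)
  expect_equal(back$V2, p$value, tolerance = 1e-6)
  ff <- xray_form_factor(p)
  write_two_column(ff, f)
  expect_equal(nrow(read.table(f)), nrow(ff))
})
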