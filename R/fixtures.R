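## Synthetic-fixture generators: every input class the fitting and
## analysis modules consume, built with known ground truth so the whole
## pipeline is testable without quantum chemistry or molecular
## dynamics. Fixture geometries are deliberately non-physical (no
## sterics); they carry the exact statistical structure the analysers
## measure. Every generator is deterministic under a fixed seed.

## Smooth nuisance background standing in for the non-torsion MM energy
## of a conformer (bonded + nonbonded terms other than the fitted
## torsions).
nuisance_background <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  1.1 * cos(th + 0.7) + 0.4 * cos(2 * th - 1.3)
}

#' Generate a synthetic torsion fit dataset from a known ground truth
#'
#' Samples conformer torsion angles, builds a smooth zeroed-MM
#' background, and sets
#' `e_qm = e_zeroed + truth torsion energy + offset + noise`,
#' emulating conformer sets extracted from a simulation and evaluated
#' by QM single points. With `sigma = 0` the truth reproduces the data
#' exactly (up to the constant offset, which the fitness aligns away).
#'
#' @param truth Named list mapping torsion label to a
#'   [torsion_series()] (the ground truth).
#' @param n Number of conformers (default 1000).
#' @param sigma Gaussian noise sd on `e_qm`, kcal/mol (default 0).
#' @param offset Constant added to `e_qm`, emulating the unrelated
#'   absolute energy scales of QM and MM (default -97.3).
#' @param seed Integer seed.
#' @return List with `dataset` (a [fit_dataset()]), `truth`, `sigma`,
#'   `offset`, `seed`.
#' @export
make_fit_dataset <- function(truth, n = 1000, sigma = 0, offset = -97.3,
                             seed = 1) {
  stop_unless(is.list(truth) && length(truth) >= 1 &&
                !is.null(names(truth)), "truth must be a named list")
  for (s in truth) stop_unless(inherits(s, "torsion_series"),
                               "truth entries must be torsion_series")
  stop_unless(is_number(sigma) && sigma >= 0, "sigma must be >= 0")
  with_seed(seed, {
    angles <- as.data.frame(lapply(names(truth), function(l) {
      stats::runif(n, -180, 180)
    }))
    colnames(angles) <- names(truth)
    e_zeroed <- Reduce(`+`, lapply(names(truth), function(l) {
      nuisance_background(angles[[l]])
    }))
    e_torsion <- Reduce(`+`, lapply(names(truth), function(l) {
      torsion_energy(truth[[l]], angles[[l]])
    }))
    e_qm <- e_zeroed + e_torsion + offset + stats::rnorm(n, 0, sigma)
    list(dataset = fit_dataset(angles, e_zeroed, e_qm),
         truth = truth, sigma = sigma, offset = offset, seed = seed)
  })
}

#' Generate a synthetic 1D harmonic angle scan
#'
#' A scan from `range_deg[1]` to `range_deg[2]` in 1 degree steps with
#' `e_qm - e_zeroed = K (theta - theta0)^2 + offset + noise`
#' (deviation in radians), emulating a QM angle scan.
#'
#' @param K Force constant, kcal/mol/rad^2 (default 120).
#' @param theta0 Equilibrium angle, degrees (default 112).
#' @param offset Constant energy offset (default -3.1).
#' @param sigma Gaussian noise sd, kcal/mol (default 0).
#' @param range_deg Scan endpoints, degrees (default `c(90, 150)`).
#' @param seed Integer seed.
#' @return List with `scan` (data frame `theta`, `e_zeroed`, `e_qm`)
#'   and the truth parameters.
#' @export
make_angle_scan <- function(K = 120, theta0 = 112, offset = -3.1,
                            sigma = 0, range_deg = c(90, 150), seed = 1) {
  stop_unless(K > 0 && theta0 > range_deg[1] && theta0 < range_deg[2],
              "theta0 must lie inside the scan range")
  stop_unless(sigma >= 0, "sigma must be >= 0")
  with_seed(seed, {
    theta <- seq(range_deg[1], range_deg[2], by = 1)
    e_zeroed <- 0.3 * sin(theta / 15)
    e_qm <- e_zeroed + K * deg2rad(theta - theta0)^2 + offset +
      stats::rnorm(length(theta), 0, sigma)
    list(scan = data.frame(theta = theta, e_zeroed = e_zeroed, e_qm = e_qm),
         K = K, theta0 = theta0, offset = offset, sigma = sigma, seed = seed)
  })
}

#' Generate a synthetic per-conformer charge ensemble
#'
#' A base charge set summing exactly to `target_net`, perturbed per
#' member with zero-sum Gaussian noise, emulating RESP fits to many
#' conformers of one fragment.
#'
#' @param n_members Ensemble size (default 200, the standard
#'   conformer-ensemble size for implicitly polarised charges).
#' @param n_atoms Atoms per fragment (default 10).
#' @param target_net Integer fragment charge (default 0).
#' @param sigma Per-atom noise sd, e units (default 0.05).
#' @param fragment_label Fragment name.
#' @param seed Integer seed.
#' @return List with `ensemble` (a [charge_ensemble()]) and `base`
#'   (the true mean charges).
#' @export
make_charge_ensemble <- function(n_members = 200, n_atoms = 10,
                                 target_net = 0L, sigma = 0.05,
                                 fragment_label = "FRAG", seed = 1) {
  stop_unless(n_members >= 1 && n_atoms >= 2, "need >= 1 member, >= 2 atoms")
  with_seed(seed, {
    base <- stats::rnorm(n_atoms, 0, 0.4)
    base <- base - (sum(base) - target_net) / n_atoms
    names <- sprintf("A%d", seq_len(n_atoms))
    members <- lapply(seq_len(n_members), function(i) {
      q <- base + stats::rnorm(n_atoms, 0, sigma)
      q <- q - (sum(q) - target_net) / n_atoms   # each member sums exactly
      charge_set(names, q, fragment_label, target_net)
    })
    list(ensemble = charge_ensemble(members), base = base, seed = seed)
  })
}

## Draw C-H direction cosines realising E[(3 cos^2 theta - 1)/2] = s_cd
## via a two-point mixture on cos theta: axial (|cos| = 1) with
## probability p = (s_cd + 1/2)/(3/2), planar (cos = 0) otherwise.
sample_ch_dirs <- function(n, s_cd) {
  stop_unless(s_cd >= -0.5 && s_cd <= 1,
              "target S_CD must lie in [-0.5, 1]")
  p <- (s_cd + 0.5) / 1.5
  axial <- stats::runif(n) < p
  phi <- stats::runif(n, 0, 2 * pi)
  sign <- ifelse(stats::runif(n) < 0.5, 1, -1)
  dir <- cbind(ifelse(axial, 0, cos(phi)),
               ifelse(axial, 0, sin(phi)),
               ifelse(axial, sign, 0))
  dir
}

#' Generate an idealised bilayer trajectory with known ground truth
#'
#' Places simplified two-leaflet lipids: one phosphorus-like headgroup
#' atom per lipid at `z = +/- d_hh/2` (plus jitter), a chain of carbons
#' descending toward the midplane, each carbon carrying `n_h` explicit
#' hydrogens whose orientations are drawn from a two-point mixture
#' solving `<(3 cos^2 theta - 1)/2> = scd_target` per carbon.
#' Optionally adds two-atom cholesterol-like probes (O and chain-
#' connecting C, 5 Angstrom apart) with a prescribed tilt distribution,
#' and uniform water beyond the headgroup planes.
#'
#' @param n_lipids Total lipids, even (default 128).
#' @param n_frames Frames (default 4).
#' @param apl Area per lipid used to size the box, Angstrom^2
#'   (default 64).
#' @param d_hh True head-to-head thickness, Angstrom (default 38).
#' @param head_sd Jitter sd of headgroup z positions, Angstrom
#'   (default 0.8).
#' @param n_carbons Chain carbons per lipid (default 6).
#' @param n_h Hydrogens per carbon (default 2).
#' @param scd_target Target order parameter per carbon (recycled;
#'   default 0.2).
#' @param n_chol Cholesterol-like probes (default 0).
#' @param tilt_deg Tilt angle(s): a scalar gives a delta distribution;
#'   `tilt_sd` > 0 adds wrapped-Gaussian spread (default 13).
#' @param tilt_sd Tilt spread sd in degrees (default 0).
#' @param n_waters Water molecules (3 atoms each) beyond the headgroup
#'   region (default 0).
#' @param lz Box height, Angstrom (default `d_hh + 30`).
#' @param seed Integer seed.
#' @return List with `traj` (a [bilayer_trajectory()]), `ch_pairs`
#'   (for [order_parameters()]), `o_atoms`/`c_atoms` (for
#'   [cholesterol_tilt()]), and `truth` (d_hh, scd per carbon, tilt).
#' @export
make_bilayer_traj <- function(n_lipids = 128, n_frames = 4, apl = 64,
                              d_hh = 38, head_sd = 0.8, n_carbons = 6,
                              n_h = 2, scd_target = 0.2, n_chol = 0,
                              tilt_deg = 13, tilt_sd = 0, n_waters = 0,
                              lz = d_hh + 30, seed = 1) {
  stop_unless(n_lipids %% 2 == 0 && n_lipids >= 2,
              "n_lipids must be even and >= 2")
  scd <- rep_len(scd_target, n_carbons)
  for (s in scd) stop_unless(s >= -0.5 && s <= 1,
                             "target S_CD must lie in [-0.5, 1]")
  L <- sqrt(apl * n_lipids / 2)
  atoms_per_lipid <- 1L + n_carbons * (1L + n_h)
  ch_spacing <- min(1.27, (d_hh / 2 - 2) / max(n_carbons, 1))

  with_seed(seed, {
    build_frame <- function(t) {
      xyz <- list(); nm <- c(); el <- c(); res <- c(); rnm <- c(); rl <- c()
      rid <- 0L
      for (i in seq_len(n_lipids)) {
        rid <- rid + 1L
        leaf <- if (i <= n_lipids / 2) 1 else -1
        hx <- stats::runif(1, 0, L); hy <- stats::runif(1, 0, L)
        hz <- leaf * d_hh / 2 + stats::rnorm(1, 0, head_sd)
        xyz[[length(xyz) + 1L]] <- c(hx, hy, hz)
        nm <- c(nm, "P"); el <- c(el, "P")
        res <- c(res, rid); rnm <- c(rnm, "LIP"); rl <- c(rl, "lipid")
        for (k in seq_len(n_carbons)) {
          cz <- hz - leaf * k * ch_spacing
          cpos <- c(hx, hy, cz)
          xyz[[length(xyz) + 1L]] <- cpos
          nm <- c(nm, sprintf("C%d", k)); el <- c(el, "C")
          res <- c(res, rid); rnm <- c(rnm, "LIP"); rl <- c(rl, "lipid")
          dirs <- sample_ch_dirs(n_h, scd[k])
          for (h in seq_len(n_h)) {
            xyz[[length(xyz) + 1L]] <- cpos + 1.09 * dirs[h, ]
            nm <- c(nm, sprintf("H%d%d", k, h)); el <- c(el, "H")
            res <- c(res, rid); rnm <- c(rnm, "LIP"); rl <- c(rl, "lipid")
          }
        }
      }
      for (i in seq_len(n_chol)) {
        rid <- rid + 1L
        leaf <- if (i <= max(n_chol / 2, 1)) 1 else -1
        ox <- stats::runif(1, 0, L); oy <- stats::runif(1, 0, L)
        oz <- leaf * (d_hh / 2 - 2)
        tilt <- tilt_deg[((i - 1L) %% length(tilt_deg)) + 1L]
        if (tilt_sd > 0) tilt <- tilt + stats::rnorm(1, 0, tilt_sd)
        tilt <- abs(wrap_angle(tilt))
        phi <- stats::runif(1, 0, 2 * pi)
        v <- 5 * c(sin(deg2rad(tilt)) * cos(phi),
                   sin(deg2rad(tilt)) * sin(phi),
                   -leaf * cos(deg2rad(tilt)))
        xyz[[length(xyz) + 1L]] <- c(ox, oy, oz)
        nm <- c(nm, "O3"); el <- c(el, "O")
        res <- c(res, rid); rnm <- c(rnm, "CHL"); rl <- c(rl, "lipid")
        xyz[[length(xyz) + 1L]] <- c(ox, oy, oz) + v
        nm <- c(nm, "C17"); el <- c(el, "C")
        res <- c(res, rid); rnm <- c(rnm, "CHL"); rl <- c(rl, "lipid")
      }
      for (i in seq_len(n_waters)) {
        rid <- rid + 1L
        wx <- stats::runif(1, 0, L); wy <- stats::runif(1, 0, L)
        side <- if (stats::runif(1) < 0.5) 1 else -1
        wz <- side * stats::runif(1, d_hh / 2 + 3, lz / 2 - 1)
        o <- c(wx, wy, wz)
        xyz[[length(xyz) + 1L]] <- o
        nm <- c(nm, "OW"); el <- c(el, "O")
        res <- c(res, rid); rnm <- c(rnm, "WAT"); rl <- c(rl, "water")
        for (h in 1:2) {
          xyz[[length(xyz) + 1L]] <- o + stats::rnorm(3, 0, 0.5)
          nm <- c(nm, sprintf("HW%d", h)); el <- c(el, "H")
          res <- c(res, rid); rnm <- c(rnm, "WAT"); rl <- c(rl, "water")
        }
      }
      list(xyz = do.call(rbind, xyz), nm = nm, el = el, res = res,
           rnm = rnm, rl = rl)
    }

    frames <- list()
    first <- NULL
    for (t in seq_len(n_frames)) {
      fr <- build_frame(t)
      if (is.null(first)) first <- fr
      frames[[t]] <- frame(fr$xyz, c(L, L, lz), time = t - 1)
    }
    znum <- ELEMENT_DATA$atomic_number[match(first$el, ELEMENT_DATA$element)]
    top <- topology(first$nm, first$el, znum,
                    partial_charge = rep(0, length(first$nm)),
                    residue_id = first$res, residue_name = first$rnm,
                    role = first$rl)
    traj <- bilayer_trajectory(frames, top)

    ## C-H pair table (same layout in every frame)
    pair_rows <- list()
    for (i in seq_len(n_lipids)) {
      base <- (i - 1L) * atoms_per_lipid
      for (k in seq_len(n_carbons)) {
        cidx <- base + 1L + (k - 1L) * (1L + n_h) + 1L
        for (h in seq_len(n_h)) {
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            carbon = cidx, hydrogen = cidx + h, chain = "sn-1",
            carbon_index = k)
        }
      }
    }
    ch_pairs <- do.call(rbind, pair_rows)
    chol_base <- n_lipids * atoms_per_lipid
    o_atoms <- if (n_chol > 0) chol_base + 2L * seq_len(n_chol) - 1L else
      integer(0)
    c_atoms <- if (n_chol > 0) chol_base + 2L * seq_len(n_chol) else
      integer(0)
    list(traj = traj, ch_pairs = ch_pairs, o_atoms = o_atoms,
         c_atoms = c_atoms,
         truth = list(d_hh = d_hh, scd = scd, tilt_deg = tilt_deg,
                      apl = apl, n_lipids = n_lipids),
         seed = seed)
  })
}

#' Generate a synthetic heating scan with a known melting midpoint
#'
#' A logistic area-per-lipid curve between a gel and a fluid plateau,
#' sampled along a linear heating ramp, with optional Gaussian noise:
#' `APL(T) = gel + (fluid - gel) / (1 + exp(-(T - midpoint)/width))`.
#'
#' @param midpoint True transition temperature, K (default 319).
#' @param t_start,t_end Temperature ramp endpoints, K (default
#'   300-350).
#' @param rate Heating rate, K/ns (default 0.5).
#' @param dt Sampling interval, ns (default 0.05).
#' @param gel,fluid APL plateaus, Angstrom^2 (defaults 48 and 62, the
#'   typical gel and fluid values for a saturated PC bilayer).
#' @param width Logistic width, K (default 2.5).
#' @param sigma APL noise sd, Angstrom^2 (default 0).
#' @param n_lipids Lipid count used to back out box lengths
#'   (default 128).
#' @param seed Integer seed.
#' @return List with `scan` (data frame `time`, `temperature`, `Lx`,
#'   `Ly`) and `truth` (the midpoint).
#' @export
make_heating_scan <- function(midpoint = 319, t_start = 300, t_end = 350,
                              rate = 0.5, dt = 0.05, gel = 48, fluid = 62,
                              width = 2.5, sigma = 0, n_lipids = 128,
                              seed = 1) {
  stop_unless(rate > 0, "heating rate must be positive")
  stop_unless(midpoint > t_start && midpoint < t_end,
              "midpoint must lie inside the temperature range")
  stop_unless(sigma >= 0, "sigma must be >= 0")
  with_seed(seed, {
    time <- seq(0, (t_end - t_start) / rate, by = dt)
    temp <- t_start + rate * time
    apl <- gel + (fluid - gel) * stats::plogis((temp - midpoint) / width) +
      stats::rnorm(length(time), 0, sigma)
    Lh <- sqrt(pmax(apl, 1) * n_lipids / 2)
    list(scan = data.frame(time = time, temperature = temp,
                           Lx = Lh, Ly = Lh),
         truth = list(midpoint = midpoint, gel = gel, fluid = fluid,
                      width = width, rate = rate),
         seed = seed)
  })
}

#' Generate scripted per-molecule z paths with a known event list
#'
#' Builds piecewise z(t) series executing scripted midplane visits and
#' crossings. Noise is clipped so the trajectory is inside the
#' detection band (|z| < 2) exactly during scripted visits and safely
#' outside (|z| >= 2.6) otherwise, making the sidecar event list exact.
#'
#' @param script List, one entry per molecule: `list(start_leaflet =
#'   +1 or -1, visits = character vector of "flip" / "visit")`.
#' @param pad Frames between events (default 40).
#' @param sigma Noise sd, Angstrom (default 0.2).
#' @param seed Integer seed.
#' @return List with `z` (named list of series), `truth` (data frame
#'   `molecule`, `kind` in event order) and `total`.
#' @export
make_z_paths <- function(script, pad = 40L, sigma = 0.2, seed = 1) {
  stop_unless(is.list(script) && length(script) >= 1,
              "script must be a non-empty list")
  with_seed(seed, {
    z <- list()
    truth_rows <- list()
    for (m in seq_along(script)) {
      sc <- script[[m]]
      s <- if (is.null(sc$start_leaflet)) 1 else sc$start_leaflet
      stop_unless(s %in% c(-1, 1), "start_leaflet must be +1 or -1")
      visits <- if (is.null(sc$visits)) character(0) else sc$visits
      stop_unless(all(visits %in% c("flip", "visit")),
                  "visits must be 'flip' or 'visit'")
      zi <- rep(s * 15, pad)
      for (v in visits) {
        approach <- seq(15, 2.8, length.out = 10) * s
        inside <- if (v == "flip") {
          s2 <- -s
          seq(1.5, -1.5, length.out = 6) * s
        } else {
          s2 <- s
          c(1.5, 0.8, 0.4, 0.8, 1.5) * s
        }
        exit <- seq(2.8, 15, length.out = 10) * s2
        zi <- c(zi, approach, inside, exit, rep(s2 * 15, pad))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          molecule = sprintf("mol%d", m),
          kind = if (v == "flip") "flip_flop" else "transient_visit",
          stringsAsFactors = FALSE)
        s <- s2
      }
      if (sigma > 0) {
        noise <- stats::rnorm(length(zi), 0, sigma)
        inside_band <- abs(zi) < 2
        zn <- zi + noise
        ## clip so scripted structure is preserved exactly
        zn[inside_band] <- sign(zi[inside_band] + 1e-9) *
          pmin(abs(zn[inside_band]), 1.8)
        out_idx <- !inside_band
        zn[out_idx] <- sign(zi[out_idx]) * pmax(abs(zn[out_idx]), 2.6)
        zi <- zn
      }
      z[[sprintf("mol%d", m)]] <- zi
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(molecule = character(), kind = character(),
                 stringsAsFactors = FALSE)
    list(z = z, truth = truth, total = nrow(truth), seed = seed)
  })
}
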