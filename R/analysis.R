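## Structural observables of lipid bilayer trajectories: area/volume
## per lipid, electron-density profiles and head-to-head thickness,
## C-H (deuterium NMR) order parameters, X-ray/neutron scattering form
## factors, cholesterol tilt, midplane transit events and melting-point
## detection from heating scans.

#' Area per lipid from box dimensions
#'
#' Per frame, \eqn{A = L_x L_y / (n_{lipids}/2)}: the lateral box area
#' divided by the lipids per leaflet.
#'
#' @param traj A [bilayer_trajectory()], or a list of [frame()]s.
#' @param n_lipids Total lipid count; must be even (two leaflets).
#' @return List with `series` (A^2 per frame), `mean` and `sd`.
#' @export
area_per_lipid <- function(traj, n_lipids) {
  frames <- if (inherits(traj, "bilayer_trajectory")) traj$frames else traj
  stop_unless(is_number(n_lipids) && n_lipids > 0 && n_lipids %% 2 == 0,
              "n_lipids must be a positive even integer (two leaflets)")
  apl <- vapply(frames, function(f) f$box[1] * f$box[2] / (n_lipids / 2),
                numeric(1))
  list(series = apl, mean = mean(apl), sd = stats::sd(apl))
}

#' Volume per lipid from box volume and water content
#'
#' Per frame, \eqn{V = (L_x L_y L_z - n_w V_w) / n_{lipids}} where
#' \eqn{V_w} is the average volume of a water molecule of the chosen
#' water model at the target temperature.
#'
#' @inheritParams area_per_lipid
#' @param n_waters Number of water molecules.
#' @param water_volume Average single-water volume, Angstrom^3
#'   (e.g. ~30.5 for TIP3P near ambient conditions).
#' @return List with `series`, `mean` and `sd` (Angstrom^3).
#' @export
volume_per_lipid <- function(traj, n_waters, water_volume, n_lipids) {
  frames <- if (inherits(traj, "bilayer_trajectory")) traj$frames else traj
  stop_unless(is_number(n_lipids) && n_lipids > 0, "n_lipids must be positive")
  stop_unless(is_number(water_volume) && water_volume >= 0 &&
                is_number(n_waters) && n_waters >= 0,
              "n_waters and water_volume must be non-negative")
  vpl <- vapply(frames, function(f) {
    v <- prod(f$box) - n_waters * water_volume
    if (v <= 0) {
      stop("non-positive lipid volume: box smaller than the water volume ",
           "(check water_volume)", call. = FALSE)
    }
    v / n_lipids
  }, numeric(1))
  list(series = vpl, mean = mean(vpl), sd = stats::sd(vpl))
}

## Per-frame z of the bilayer centre: mass-weighted mean z of
## lipid-role atoms.
bilayer_center_z <- function(f, top) {
  sel <- top$role == "lipid"
  m <- element_mass(top$element[sel])
  sum(m * f$xyz[sel, 3]) / sum(m)
}

#' z-binned density profile across the bilayer
#'
#' Per frame the profile is recentred on the lipid centre of mass
#' (z = 0 at the bilayer midplane), selected atoms are binned along z,
#' each with weight 1 (`"number"`), atomic number minus partial charge
#' (`"electron"`, the convention that distributes electrons according
#' to partial charges), atomic number only (`"electron_z"`), or a
#' user-supplied per-atom weight (`"custom"`). Counts are divided by
#' the bin volume \eqn{L_x L_y \Delta z} and averaged over frames.
#'
#' @param traj A [bilayer_trajectory()].
#' @param selection Integer or logical atom index vector (default: all
#'   atoms).
#' @param bin_width Bin width in Angstrom (default 0.25).
#' @param weighting `"number"`, `"electron"`, `"electron_z"` or
#'   `"custom"`.
#' @param weights Per-selected-atom weights for `weighting = "custom"`.
#' @param species Label stored on the profile.
#' @return A `density_profile` object: data frame fields `z` (bin
#'   centres) and `value`, plus attributes `bin_width` and `species`.
#' @export
density_profile <- function(traj, selection = NULL, bin_width = 0.25,
                            weighting = c("number", "electron",
                                          "electron_z", "custom"),
                            weights = NULL, species = "") {
  stop_unless(inherits(traj, "bilayer_trajectory"),
              "traj must be a bilayer_trajectory")
  stop_unless(is_number(bin_width) && bin_width > 0,
              "bin_width must be positive")
  weighting <- match.arg(weighting)
  top <- traj$topology
  sel <- if (is.null(selection)) seq_len(nrow(top)) else {
    if (is.logical(selection)) which(selection) else as.integer(selection)
  }
  stop_unless(length(sel) >= 1, "selection is empty")
  w <- switch(weighting,
    number = rep(1, length(sel)),
    electron = top$atomic_number[sel] - top$partial_charge[sel],
    electron_z = as.numeric(top$atomic_number[sel]),
    custom = {
      stop_unless(!is.null(weights) && length(weights) == length(sel),
                  "custom weighting needs one weight per selected atom")
      as.numeric(weights)
    })

  lz_max <- max(vapply(traj$frames, function(f) f$box[3], numeric(1)))
  half <- ceiling((lz_max / 2) / bin_width) * bin_width
  edges <- seq(-half, half, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- numeric(length(centers))
  for (f in traj$frames) {
    zc <- f$xyz[sel, 3] - bilayer_center_z(f, top)
    zc <- zc - f$box[3] * round(zc / f$box[3])      # minimum image in z
    idx <- pmin(pmax(floor((zc + half) / bin_width) + 1L, 1L),
                length(centers))
    binned <- numeric(length(centers))
    tb <- tapply(w, idx, sum)
    binned[as.integer(names(tb))] <- tb
    acc <- acc + binned / (f$box[1] * f$box[2] * bin_width)
  }
  structure(list(z = centers, value = acc / length(traj$frames)),
            class = "density_profile", bin_width = bin_width,
            species = species, weighting = weighting)
}

#' Symmetrise a density profile about the midplane
#'
#' Replaces the profile with the average of \eqn{\rho(z)} and
#' \eqn{\rho(-z)}, the standard pre-step before form-factor transforms.
#'
#' @param profile A `density_profile`.
#' @return A symmetrised `density_profile`.
#' @export
symmetrize_profile <- function(profile) {
  stop_unless(inherits(profile, "density_profile"),
              "profile must be a density_profile")
  v <- (profile$value + rev(profile$value)) / 2
  structure(list(z = profile$z, value = v), class = "density_profile",
            bin_width = attr(profile, "bin_width"),
            species = attr(profile, "species"),
            weighting = attr(profile, "weighting"))
}

#' Head-to-head bilayer thickness from an electron density profile
#'
#' \eqn{D_{HH}} is the distance between the two electron-density maxima
#' (the electron-dense phosphate planes) on either side of the bilayer
#' centre: the highest local maximum at z < 0 and at z > 0.
#'
#' @param profile A `density_profile` (electron weighting).
#' @return Thickness in Angstrom.
#' @export
dhh_from_profile <- function(profile) {
  stop_unless(inherits(profile, "density_profile"),
              "profile must be a density_profile")
  v <- profile$value
  z <- profile$z
  n <- length(v)
  stop_unless(n >= 3, "profile too short")
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
                v[2:(n - 1)] >= v[3:n], FALSE)
  left <- which(is_max & z < 0)
  right <- which(is_max & z > 0)
  if (!length(left) || !length(right)) {
    stop("profile lacks two local maxima straddling z = 0; cannot ",
         "determine a head-to-head thickness", call. = FALSE)
  }
  zl <- z[left[which.max(v[left])]]
  zr <- z[right[which.max(v[right])]]
  zr - zl
}

#' C-H (deuterium) order parameters
#'
#' \eqn{S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle} with
#' \eqn{\theta} the angle between each C-H bond vector and the bilayer
#' normal (z axis), averaged over frames, molecules and equivalent
#' hydrogens. NMR experiments report the magnitude, so both the signed
#' mean and its absolute value are returned per carbon.
#'
#' @param traj A [bilayer_trajectory()].
#' @param ch_pairs Data frame with columns `carbon`, `hydrogen` (atom
#'   indices, 1-based), `chain` (e.g. `"sn-1"`) and `carbon_index`.
#' @return Data frame with one row per (chain, carbon_index):
#'   `scd_signed`, `scd_abs`, `sd` (sd of the per-sample quantity) and
#'   `n` samples.
#' @export
order_parameters <- function(traj, ch_pairs) {
  stop_unless(inherits(traj, "bilayer_trajectory"),
              "traj must be a bilayer_trajectory")
  ch_pairs <- as.data.frame(ch_pairs)
  stop_unless(all(c("carbon", "hydrogen", "chain", "carbon_index") %in%
                    colnames(ch_pairs)),
              "ch_pairs needs columns carbon, hydrogen, chain, carbon_index")
  n_atoms <- nrow(traj$topology)
  stop_unless(all(ch_pairs$carbon >= 1 & ch_pairs$carbon <= n_atoms &
                    ch_pairs$hydrogen >= 1 & ch_pairs$hydrogen <= n_atoms),
              "ch_pairs indexes atoms outside the topology")
  samples <- lapply(traj$frames, function(f) {
    v <- f$xyz[ch_pairs$hydrogen, , drop = FALSE] -
      f$xyz[ch_pairs$carbon, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    if (any(len == 0)) {
      stop("zero-length C-H vector encountered", call. = FALSE)
    }
    cost <- v[, 3] / len
    (3 * cost^2 - 1) / 2
  })
  s <- do.call(cbind, samples)               # pairs x frames
  key <- interaction(ch_pairs$chain, ch_pairs$carbon_index, drop = TRUE)
  agg <- t(vapply(levels(key), function(k) {
    vals <- as.vector(s[key == k, , drop = FALSE])
    c(mean(vals), stats::sd(vals), length(vals))
  }, numeric(3)))
  first <- match(levels(key), key)
  out <- data.frame(chain = ch_pairs$chain[first],
                    carbon_index = ch_pairs$carbon_index[first],
                    scd_signed = agg[, 1],
                    scd_abs = abs(agg[, 1]),
                    sd = agg[, 2],
                    n = as.integer(agg[, 3]),
                    row.names = NULL)
  out[order(out$chain, out$carbon_index), ]
}

## Trapezoidal integral on a (possibly non-uniform) grid.
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' X-ray scattering form factor from an electron density profile
#'
#' \eqn{|F(q)| = |\int (\rho_e(z) - \rho_w) \cos(qz)\, dz|} over the
#' profile support (the symmetric part of the contrast profile is what
#' scattering measures), by trapezoidal integration on the bin grid.
#'
#' @param profile A `density_profile` in electrons/Angstrom^3,
#'   symmetric or pre-symmetrised (see [symmetrize_profile()]).
#' @param water_density Bulk water electron density subtracted as the
#'   solvent background, e/Angstrom^3 (default 0.333, liquid water near
#'   ambient conditions).
#' @param q_grid Scattering vector grid in inverse Angstrom (default
#'   0 to 0.8 by 0.005).
#' @return A `form_factor` data frame with columns `q` and `magnitude`
#'   (e/Angstrom^2).
#' @export
xray_form_factor <- function(profile, water_density = 0.333,
                             q_grid = seq(0, 0.8, by = 0.005)) {
  stop_unless(inherits(profile, "density_profile"),
              "profile must be a density_profile")
  stop_unless(length(q_grid) >= 1 && all(q_grid >= 0) &&
                !is.unsorted(q_grid, strictly = TRUE),
              "q_grid must be non-empty, non-negative, strictly increasing")
  contrast <- profile$value - water_density
  mag <- vapply(q_grid, function(q) {
    abs(trapz(profile$z, contrast * cos(q * profile$z)))
  }, numeric(1))
  structure(data.frame(q = q_grid, magnitude = mag), class =
              c("form_factor", "data.frame"))
}

#' Neutron scattering form factor
#'
#' Builds (or accepts) a scattering-length-density profile and applies
#' the same cosine transform as the X-ray route against the solvent
#' scattering-length density. When built from a trajectory, each atom
#' contributes its bound coherent scattering length; hydrogens of
#' water-role atoms are interpolated between H and D according to
#' `d2o_fraction` (lipid hydrogens are treated as non-exchangeable).
#'
#' @param x A [bilayer_trajectory()], or a precomputed `density_profile`
#'   whose values are scattering-length density (Angstrom^-2).
#' @param d2o_fraction Fraction of heavy water in the solvent, in
#'   `[0, 1]` (default 1 = 100 percent D2O).
#' @param q_grid Scattering vector grid, inverse Angstrom.
#' @param solvent_sld Solvent scattering-length density to subtract;
#'   default computed from `d2o_fraction` and a 30.0 Angstrom^3 water
#'   volume.
#' @param bin_width Bin width when building the profile from a
#'   trajectory.
#' @return A `form_factor` data frame (`q`, `magnitude`).
#' @export
neutron_form_factor <- function(x, d2o_fraction = 1,
                                q_grid = seq(0, 0.8, by = 0.005),
                                solvent_sld = NULL, bin_width = 0.25) {
  stop_unless(is_number(d2o_fraction) && d2o_fraction >= 0 &&
                d2o_fraction <= 1, "d2o_fraction must be in [0, 1]")
  if (is.null(solvent_sld)) {
    bh <- (1 - d2o_fraction) * NEUTRON_B[["H"]] + d2o_fraction * NEUTRON_B[["D"]]
    solvent_sld <- (2 * bh + NEUTRON_B[["O"]]) / 30.0
  }
  profile <- if (inherits(x, "density_profile")) x else {
    stop_unless(inherits(x, "bilayer_trajectory"),
                "x must be a bilayer_trajectory or density_profile")
    top <- x$topology
    b <- neutron_scattering_length(top$element)
    waterH <- top$role == "water" & top$element == "H"
    b[waterH] <- (1 - d2o_fraction) * NEUTRON_B[["H"]] +
      d2o_fraction * NEUTRON_B[["D"]]
    density_profile(x, bin_width = bin_width, weighting = "custom",
                    weights = b, species = "sld")
  }
  contrast <- profile$value - solvent_sld
  mag <- vapply(q_grid, function(q) {
    abs(trapz(profile$z, contrast * cos(q * profile$z)))
  }, numeric(1))
  structure(data.frame(q = q_grid, magnitude = mag),
            class = c("form_factor", "data.frame"))
}

#' Cholesterol tilt-angle distribution
#'
#' For each cholesterol and frame, takes the vector from the hydroxyl
#' oxygen to the sterol carbon that connects the acyl chain and
#' computes its angle against the bilayer normal, folded to `[0, 90]`
#' degrees so the result is leaflet-independent. Returns the histogram
#' over all molecules and frames and the most probable tilt (the mode
#' bin centre).
#'
#' @param traj A [bilayer_trajectory()].
#' @param o_atoms,c_atoms Equal-length atom index vectors: per
#'   cholesterol, the oxygen and the chain-connecting carbon.
#' @param bin_width_deg Histogram bin width in degrees (default 1).
#' @return List with `histogram` (data frame `angle`, `count`,
#'   `density`), `mode_deg` and `n_skipped` (frames x molecules skipped
#'   for coincident atoms).
#' @export
cholesterol_tilt <- function(traj, o_atoms, c_atoms, bin_width_deg = 1) {
  stop_unless(inherits(traj, "bilayer_trajectory"),
              "traj must be a bilayer_trajectory")
  stop_unless(length(o_atoms) == length(c_atoms) && length(o_atoms) >= 1,
              "o_atoms and c_atoms must be equal-length and non-empty")
  stop_unless(is_number(bin_width_deg) && bin_width_deg > 0,
              "bin_width_deg must be positive")
  angles <- c()
  skipped <- 0L
  for (f in traj$frames) {
    v <- f$xyz[c_atoms, , drop = FALSE] - f$xyz[o_atoms, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    bad <- len == 0
    skipped <- skipped + sum(bad)
    if (any(bad)) {
      v <- v[!bad, , drop = FALSE]
      len <- len[!bad]
    }
    angles <- c(angles, rad2deg(acos(pmin(abs(v[, 3]) / len, 1))))
  }
  if (skipped > 0) {
    warning(sprintf("%d molecule-frames skipped (coincident atoms)", skipped),
            call. = FALSE)
  }
  stop_unless(length(angles) > 0, "no usable tilt vectors")
  edges <- seq(0, 90 + bin_width_deg, by = bin_width_deg)
  counts <- graphics::hist(angles, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  hist_df <- data.frame(angle = centers, count = counts,
                        density = counts / sum(counts) / bin_width_deg)
  list(histogram = hist_df, mode_deg = centers[which.max(counts)],
       n_skipped = skipped)
}

#' Detect midplane transit events in a z trajectory
#'
#' Any maximal contiguous run of frames with \eqn{|z| <}
#' `band_halfwidth` (default 2 Angstrom: the band -2 < z < 2 around the
#' bilayer centre) is one event. An event is a `flip_flop` when the
#' leaflet sign after the run differs from the sign before it, else a
#' `transient_visit`; runs touching the start or end of the series
#' cannot be resolved and are classified `transient_visit`.
#'
#' @param z Numeric z series for one molecule (Angstrom, centred on the
#'   midplane), or a named list of such series (one per molecule).
#' @param band_halfwidth Half-width of the detection band, Angstrom.
#' @return List with `events` (data frame `molecule`, `start`, `end`,
#'   `kind`, `start_leaflet`) and `total` count.
#' @export
transit_events <- function(z, band_halfwidth = 2) {
  stop_unless(is_number(band_halfwidth) && band_halfwidth > 0,
              "band_halfwidth must be positive")
  series <- if (is.list(z)) z else list(mol = z)
  if (is.null(names(series))) names(series) <- seq_along(series)
  rows <- list()
  for (mol in names(series)) {
    zi <- series[[mol]]
    stop_unless(is.numeric(zi) && length(zi) >= 1,
                "z series for molecule %s is empty", mol)
    inside <- abs(zi) < band_halfwidth
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sgn <- ifelse(zi >= 0, 1L, -1L)
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      at_edge <- s == 1L || e == length(zi)
      before <- if (s > 1L) sgn[s - 1L] else NA_integer_
      after <- if (e < length(zi)) sgn[e + 1L] else NA_integer_
      kind <- if (at_edge || before == after) "transient_visit" else
        "flip_flop"
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = mol, start = s, end = e, kind = kind,
        start_leaflet = before, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule = character(), start = integer(), end = integer(),
               kind = character(), start_leaflet = integer(),
               stringsAsFactors = FALSE)
  list(events = events, total = nrow(events))
}

#' Melting point from a heating scan
#'
#' Computes the area per lipid along a heating scan, applies a centred
#' running average with the given time window, maps the smoothed curve
#' onto temperature, and returns the temperature at the maximum of the
#' centrally differenced slope dAPL/dT — the inflection of the
#' sigmoidal gel-to-fluid melting curve. The central difference uses a
#' stencil of two windows on either side and the slope is smoothed
#' with the same window, which keeps the numerical derivative above
#' the smoothed noise floor without biasing the peak position.
#'
#' @param scan Data frame with columns `time` (ns), `temperature` (K,
#'   monotone non-decreasing) and `Lx`, `Ly` (Angstrom).
#' @param n_lipids Total lipid count (even).
#' @param window Running-average window in the same time units as
#'   `time` (default 1 ns); must span at least 2 frame intervals.
#' @return List with `tm` (transition temperature, K), `apl_smooth`
#'   (data frame `temperature`, `apl`) and `slope` (data frame
#'   `temperature`, `dapl_dt`).
#' @export
melting_point <- function(scan, n_lipids, window = 1) {
  scan <- as.data.frame(scan)
  stop_unless(all(c("time", "temperature", "Lx", "Ly") %in% colnames(scan)),
              "scan needs columns time, temperature, Lx, Ly")
  stop_unless(nrow(scan) >= 5, "scan too short")
  if (is.unsorted(scan$temperature)) {
    stop("temperature must be monotone non-decreasing", call. = FALSE)
  }
  stop_unless(is_number(n_lipids) && n_lipids %% 2 == 0,
              "n_lipids must be even")
  dt <- stats::median(diff(scan$time))
  stop_unless(window >= 2 * dt, "window must span at least 2 frame intervals")
  apl <- scan$Lx * scan$Ly / (n_lipids / 2)
  k <- max(3L, 2L * floor(window / dt / 2) + 1L)
  sm <- running_mean(apl, k)
  h <- max(1L, as.integer(round(2 * window / dt)))
  n <- length(sm)
  half <- (k - 1L) %/% 2L
  ## evaluate only where the running mean used a full window, so an
  ## exactly linear scan yields an exactly constant slope
  lo <- h + half + 1L
  hi <- n - h - half
  if (hi - lo < 2L) stop("window too wide for the scan length",
                         call. = FALSE)
  i <- lo:hi
  dT <- scan$temperature[i + h] - scan$temperature[i - h]
  if (any(dT <= 0)) {
    stop("temperature not strictly increasing at window resolution",
         call. = FALSE)
  }
  slope <- running_mean((sm[i + h] - sm[i - h]) / dT, k)
  Tm_grid <- scan$temperature[i]
  rng <- diff(range(slope))
  if (rng <= 1e-9 * max(1, abs(mean(slope)))) {
    stop("no distinct inflection: dAPL/dT is constant over the scan",
         call. = FALSE)
  }
  list(tm = Tm_grid[which.max(slope)],
       apl_smooth = data.frame(temperature = scan$temperature, apl = sm),
       slope = data.frame(temperature = Tm_grid, dapl_dt = slope))
}

#' Write a profile or form factor as two-column whitespace text
#'
#' SIMtoEXP-compatible layout: `z value` for profiles, `q magnitude`
#' for form factors, one pair per line.
#'
#' @param x A `density_profile` or `form_factor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_column <- function(x, path) {
  if (inherits(x, "density_profile")) {
    lines <- sprintf("%12.5f %15.8g", x$z, x$value)
  } else if (inherits(x, "form_factor")) {
    lines <- sprintf("%12.5f %15.8g", x$q, x$magnitude)
  } else {
    stop("x must be a density_profile or form_factor", call. = FALSE)
  }
  atomic_write(lines, path)
  invisible(path)
}
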