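## Shared fixture builders for the test suite. Everything is generated
## in code; no binary files.

## Independent term-by-term torsion summation oracle (deliberately
## written against the formula, not the package implementation).
oracle_torsion_energy <- function(coefs, theta_deg) {
  total <- 0
  for (i in seq_len(nrow(coefs))) {
    total <- total + coefs$barrier[i] *
      (1 + cos((coefs$periodicity[i] * theta_deg - coefs$phase[i]) * pi / 180))
  }
  total
}

## A small three-term series used across tests.
example_series <- function(label = "cD-cD-cD-cD") {
  torsion_series(list(torsion_term(1, 1.2, 0),
                      torsion_term(2, 0.4, 180),
                      torsion_term(3, 0.9, 0)), label)
}

## Tiny hand-buildable fit dataset: given a candidate and angles,
## construct e_qm so the candidate is exact (fitness zero).
perfect_dataset <- function(series, angles, e_zeroed = NULL, offset = 0) {
  if (is.null(e_zeroed)) e_zeroed <- seq_along(angles) * 0.37
  e_qm <- e_zeroed + torsion_energy(series, angles) + offset
  fit_dataset(data.frame(T1 = angles), e_zeroed, e_qm)
}

## Gaussian two-peak electron-density profile on a bin grid.
two_peak_profile <- function(peaks = c(-19, 19), sigma = 1.5,
                             bin_width = 0.25, amplitude = 0.2,
                             base = 0.25, half = 30, noise_sd = 0,
                             seed = NULL) {
  z <- seq(-half + bin_width / 2, half - bin_width / 2, by = bin_width)
  v <- base + amplitude * (exp(-(z - peaks[1])^2 / (2 * sigma^2)) +
                             exp(-(z - peaks[2])^2 / (2 * sigma^2)))
  if (noise_sd > 0) {
    v <- with_seed_test(seed, v + rnorm(length(v), 0, noise_sd))
  }
  structure(list(z = z, value = v), class = "density_profile",
            bin_width = bin_width, species = "test", weighting = "electron")
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

## One-frame trajectory with fully specified coordinates (n x 3) and
## per-atom metadata, for constructed analysis tests.
toy_trajectory <- function(xyz, box = c(50, 50, 80), element = "C",
                           charge = 0, role = "lipid", n_frames = 1) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  element <- rep_len(element, n)
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15)[element]
  top <- topology(name = sprintf("A%d", seq_len(n)), element = element,
                  atomic_number = z, partial_charge = rep_len(charge, n),
                  residue_id = seq_len(n), residue_name = rep("LIP", n),
                  role = rep_len(role, n))
  frames <- lapply(seq_len(n_frames), function(i) frame(xyz, box, i - 1))
  bilayer_trajectory(frames, top)
}
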