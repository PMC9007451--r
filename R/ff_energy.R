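## Force-field functional forms used in parameter fitting: the AMBER
## cosine-series torsion potential, the harmonic valence angle, and the
## scaled 1-4 Lennard-Jones pair term, plus the QM-vs-MM least-squares
## fitness these are fitted against.

#' Create a single torsion (dihedral) cosine term
#'
#' One term of the AMBER torsion potential
#' \eqn{E(\theta) = \sum_n V_n (1 + \cos(n\theta - \gamma_n))}.
#'
#' @param periodicity Integer multiplicity \eqn{n \ge 1}.
#' @param barrier Barrier height \eqn{V_n} in kcal/mol; must be
#'   non-negative (the search space is non-negative, sign information is
#'   carried by the phase).
#' @param phase Phase shift \eqn{\gamma_n} in degrees, in `[0, 360)`.
#' @return A `torsion_term` object.
#' @export
torsion_term <- function(periodicity, barrier, phase) {
  stop_unless(is_number(periodicity) && periodicity >= 1 &&
                periodicity == round(periodicity),
              "periodicity must be a positive integer, got %s",
              format(periodicity))
  stop_unless(is_number(barrier) && barrier >= 0,
              "barrier must be a non-negative number (kcal/mol)")
  stop_unless(is_number(phase) && phase >= 0 && phase < 360,
              "phase must lie in [0, 360) degrees, got %s", format(phase))
  structure(list(periodicity = as.integer(periodicity),
                 barrier = as.numeric(barrier),
                 phase = as.numeric(phase)),
            class = "torsion_term")
}

#' Create a torsion cosine series for one dihedral type
#'
#' @param terms List of [torsion_term()] objects; periodicities must be
#'   distinct. May be empty (the zero potential).
#' @param label Dihedral type name, e.g. `"cD-cD-cD-cD"`.
#' @return A `torsion_series` object.
#' @export
torsion_series <- function(terms = list(), label = "") {
  stop_unless(is.list(terms), "terms must be a list of torsion_term")
  for (t in terms) {
    stop_unless(inherits(t, "torsion_term"),
                "every element of terms must be a torsion_term")
  }
  n <- vapply(terms, `[[`, integer(1), "periodicity")
  stop_unless(!anyDuplicated(n),
              "duplicate periodicity in series '%s': n = %d",
              label, if (length(n)) n[anyDuplicated(n)] else 0L)
  structure(list(terms = terms, label = as.character(label)),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("Torsion series '%s' (%d term%s)\n", x$label,
              length(x$terms), if (length(x$terms) == 1) "" else "s"))
  for (t in x$terms) {
    cat(sprintf("  n = %d  V = %8.4f kcal/mol  gamma = %6.1f deg\n",
                t$periodicity, t$barrier, t$phase))
  }
  invisible(x)
}

## Internal: coefficient view of a series as a data.frame.
series_coefs <- function(series) {
  data.frame(
    periodicity = vapply(series$terms, `[[`, integer(1), "periodicity"),
    barrier = vapply(series$terms, `[[`, numeric(1), "barrier"),
    phase = vapply(series$terms, `[[`, numeric(1), "phase")
  )
}

#' Evaluate a torsion cosine series
#'
#' Computes \eqn{\sum_n V_n (1 + \cos(n\theta - \gamma_n))}. Periodic in
#' the angle with period 360 degrees; an empty series evaluates to 0.
#'
#' @param series A [torsion_series()].
#' @param angle Dihedral angle(s) in degrees (any real value).
#' @return Energy in kcal/mol, vectorised over `angle`.
#' @export
torsion_energy <- function(series, angle) {
  stop_unless(inherits(series, "torsion_series"),
              "series must be a torsion_series")
  stop_unless(is.numeric(angle), "angle must be numeric (degrees)")
  e <- numeric(length(angle))
  for (t in series$terms) {
    e <- e + t$barrier *
      (1 + cos(deg2rad(t$periodicity * angle - t$phase)))
  }
  e
}

#' Create a harmonic valence-angle parameter
#'
#' @param force_constant \eqn{K} in kcal/mol/rad^2; must be positive.
#' @param equilibrium Equilibrium angle \eqn{\theta_0} in degrees,
#'   strictly inside (0, 180).
#' @return A `harmonic_angle_param` object.
#' @export
harmonic_angle_param <- function(force_constant, equilibrium) {
  stop_unless(is_number(force_constant) && force_constant > 0,
              "force_constant must be positive (kcal/mol/rad^2)")
  stop_unless(is_number(equilibrium) && equilibrium > 0 && equilibrium < 180,
              "equilibrium angle must lie in (0, 180) degrees")
  structure(list(force_constant = as.numeric(force_constant),
                 equilibrium = as.numeric(equilibrium)),
            class = "harmonic_angle_param")
}

#' Harmonic valence-angle energy
#'
#' \eqn{E = K (\theta - \theta_0)^2} with the deviation converted to
#' radians, the AMBER convention for angle force constants.
#'
#' @param param A [harmonic_angle_param()].
#' @param theta Angle(s) in degrees, each in (0, 180).
#' @return Energy in kcal/mol.
#' @export
harmonic_angle_energy <- function(param, theta) {
  stop_unless(inherits(param, "harmonic_angle_param"),
              "param must be a harmonic_angle_param")
  stop_unless(is.numeric(theta) && all(is.finite(theta)),
              "theta must be numeric (degrees)")
  if (any(theta <= 0 | theta >= 180)) {
    stop("theta must lie strictly inside (0, 180) degrees", call. = FALSE)
  }
  param$force_constant * deg2rad(theta - param$equilibrium)^2
}

#' Scaled 1-4 Lennard-Jones pair energy
#'
#' \eqn{E = (A/r^{12} - B/r^6) / \mathrm{scnb}}. The SCNB divisor is the
#' AMBER convention for attenuating 1-4 (three-bonds-apart) Lennard-Jones
#' interactions: `scnb = 2` gives the standard 0.5 scaling, `scnb = 6`
#' gives 0.167 scaling as used to tune acyl-chain melting behaviour.
#'
#' @param r Pair distance in Angstrom; must be positive.
#' @param A Repulsive coefficient, kcal mol^-1 A^12.
#' @param B Attractive coefficient, kcal mol^-1 A^6.
#' @param scnb Positive dimensionless scaling divisor (default 2).
#' @return Energy in kcal/mol.
#' @export
lj14_energy <- function(r, A, B, scnb = 2) {
  stop_unless(is.numeric(r) && all(is.finite(r)) && all(r > 0),
              "r must be positive (Angstrom)")
  stop_unless(is_number(scnb) && scnb > 0, "scnb must be positive")
  (A / r^12 - B / r^6) / scnb
}

#' Build a conformer fit dataset
#'
#' Pairs per-conformer dihedral angles with the zeroed-torsion MM energy
#' and the QM reference energy. The zeroed MM energy is the molecular
#' mechanics energy evaluated with the barrier heights of the fitted
#' torsions set to zero, so the residual `e_qm - e_zeroed` is what the
#' new torsion terms must explain.
#'
#' @param angles Data frame or named list/matrix with one column per
#'   fitted torsion label, values in degrees.
#' @param e_zeroed Numeric vector, zeroed-torsion MM energies (kcal/mol).
#' @param e_qm Numeric vector, QM reference energies (kcal/mol).
#' @param weight Optional non-negative per-conformer weights (default 1).
#' @return A `fit_dataset` object with fields `angles` (data frame),
#'   `e_zeroed`, `e_qm`, `weight` and `fitted_labels`.
#' @export
fit_dataset <- function(angles, e_zeroed, e_qm, weight = NULL) {
  angles <- as.data.frame(angles)
  n <- nrow(angles)
  stop_unless(ncol(angles) >= 1, "at least one fitted torsion label required")
  stop_unless(length(e_zeroed) == n && length(e_qm) == n,
              "e_zeroed/e_qm length must match the number of conformers (%d)", n)
  stop_unless(all(is.finite(e_zeroed)) && all(is.finite(e_qm)),
              "energies must be finite")
  if (is.null(weight)) weight <- rep(1, n)
  stop_unless(length(weight) == n && all(weight >= 0),
              "weight must be non-negative and match the number of conformers")
  ## at least two distinct angle configurations
  stop_unless(nrow(unique(angles)) >= 2,
              "dataset must contain at least 2 distinct angle configurations")
  structure(list(angles = angles,
                 e_zeroed = as.numeric(e_zeroed),
                 e_qm = as.numeric(e_qm),
                 weight = as.numeric(weight),
                 fitted_labels = colnames(angles)),
            class = "fit_dataset")
}

#' @export
print.fit_dataset <- function(x, ...) {
  cat(sprintf("Fit dataset: %d conformers, %d fitted torsion label(s): %s\n",
              nrow(x$angles), length(x$fitted_labels),
              paste(x$fitted_labels, collapse = ", ")))
  invisible(x)
}

## Internal: total fitted-torsion energy per conformer for a candidate
## (named list label -> torsion_series).
candidate_torsion_energy <- function(candidate, dataset) {
  e <- numeric(nrow(dataset$angles))
  for (lab in dataset$fitted_labels) {
    if (is.null(candidate[[lab]])) {
      stop("candidate is missing a torsion series for label '", lab, "'",
           call. = FALSE)
    }
    e <- e + torsion_energy(candidate[[lab]], dataset$angles[[lab]])
  }
  e
}

#' Least-squares QM-vs-MM fitness
#'
#' The objective minimised during torsion fitting:
#' \eqn{\sum_i w_i (E_{QM,i} - E_{MM,i} - c)^2} where
#' \eqn{E_{MM,i}} is the zeroed MM energy plus the candidate torsion
#' energy, and \eqn{c} is the weighted mean residual when
#' `align_offset = TRUE` (QM and MM energy zeros are unrelated, so only
#' relative energies are compared) and 0 otherwise.
#'
#' @param candidate Named list mapping each fitted label to a
#'   [torsion_series()].
#' @param dataset A [fit_dataset()].
#' @param align_offset Fit the optimal constant offset analytically
#'   (default `TRUE`).
#' @return Non-negative scalar fitness (kcal^2/mol^2).
#' @export
fitness <- function(candidate, dataset, align_offset = TRUE) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  resid <- dataset$e_qm - dataset$e_zeroed -
    candidate_torsion_energy(candidate, dataset)
  w <- dataset$weight
  c0 <- if (align_offset) sum(w * resid) / sum(w) else 0
  sum(w * (resid - c0)^2)
}

#' Fit diagnostics: RMSE and squared Pearson correlation
#'
#' Compares offset-aligned model energies (`e_zeroed` + candidate torsion
#' energy + optimal constant) against the QM reference.
#'
#' @inheritParams fitness
#' @return List with `rmse` (kcal/mol) and `r_squared` (`NA` when either
#'   series has zero variance, rather than a misleading 0).
#' @export
fit_diagnostics <- function(candidate, dataset) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  stop_unless(nrow(dataset$angles) >= 3, "diagnostics require N >= 3 conformers")
  pred <- dataset$e_zeroed + candidate_torsion_energy(candidate, dataset)
  resid <- dataset$e_qm - pred
  w <- dataset$weight
  c0 <- sum(w * resid) / sum(w)
  pred <- pred + c0
  rmse <- sqrt(sum(w * (dataset$e_qm - pred)^2) / sum(w))
  r2 <- if (stats::var(pred) == 0 || stats::var(dataset$e_qm) == 0) {
    NA_real_
  } else {
    stats::cor(pred, dataset$e_qm)^2
  }
  list(rmse = rmse, r_squared = r2)
}

#' Read / write a fit dataset as CSV
#'
#' The CSV layout has one column per fitted torsion label (degrees), then
#' `e_zeroed`, `e_qm` and optionally `weight`. Round-trips are lossless
#' to better than 1e-9 (full precision is printed).
#'
#' @param dataset A [fit_dataset()].
#' @param path File path.
#' @return `read_fit_dataset` returns a [fit_dataset()];
#'   `write_fit_dataset` returns `path` invisibly.
#' @export
write_fit_dataset <- function(dataset, path) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  df <- dataset$angles
  df$e_zeroed <- dataset$e_zeroed
  df$e_qm <- dataset$e_qm
  if (!all(dataset$weight == 1)) df$weight <- dataset$weight
  txt <- utils::capture.output(
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     row.names = FALSE, quote = FALSE)
  )
  atomic_write(txt, path)
  invisible(path)
}

#' @rdname write_fit_dataset
#' @export
read_fit_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  reserved <- c("e_zeroed", "e_qm", "weight")
  labs <- setdiff(colnames(df), reserved)
  stop_unless(length(labs) >= 1, "no torsion-angle columns found in %s", path)
  stop_unless(all(c("e_zeroed", "e_qm") %in% colnames(df)),
              "CSV must contain e_zeroed and e_qm columns")
  fit_dataset(df[labs], df$e_zeroed, df$e_qm,
              weight = if ("weight" %in% colnames(df)) df$weight else NULL)
}

#' @rdname write_fit_dataset
#' @export
write_fit_dataset_json <- function(dataset, path) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  obj <- list(fitted_labels = dataset$fitted_labels,
              angles = as.list(dataset$angles),
              e_zeroed = dataset$e_zeroed,
              e_qm = dataset$e_qm,
              weight = dataset$weight)
  atomic_write(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE), path)
  invisible(path)
}

#' @rdname write_fit_dataset
#' @export
read_fit_dataset_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ang <- data.frame(obj$angles, check.names = FALSE)
  fit_dataset(ang[, obj$fitted_labels, drop = FALSE],
              obj$e_zeroed, obj$e_qm, weight = obj$weight)
}
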