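## Genetic-algorithm fitting of torsion barrier heights and phases to
## QM reference energies, with an exhaustive grid-search oracle for
## validation, and least-squares fitting of harmonic angle parameters
## to 1D scans.

#' Phase-shift constraint policy
#'
#' Controls the discrete values the phase shift gamma_n may take during
#' fitting: `"binary_0_180"` restricts to {0, 180} degrees (hydrocarbon
#' torsions), `"increments_60"` to {0, 60, ..., 300} degrees (headgroup
#' torsions, accommodating stereochemistry), `"fixed"` to user-supplied
#' per-label sets.
#'
#' @param mode One of `"binary_0_180"`, `"increments_60"`, `"fixed"`.
#' @param fixed_values For `mode = "fixed"`: named list mapping torsion
#'   label to a vector of allowed phases (degrees in `[0, 360)`).
#' @return A `phase_policy` object.
#' @export
phase_policy <- function(mode = c("binary_0_180", "increments_60", "fixed"),
                         fixed_values = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stop_unless(is.list(fixed_values) && length(fixed_values) > 0 &&
                  !is.null(names(fixed_values)),
                "mode 'fixed' requires a named fixed_values list")
    for (v in fixed_values) {
      stop_unless(is.numeric(v) && length(v) > 0 && all(v >= 0 & v < 360),
                  "fixed phase values must lie in [0, 360)")
    }
  }
  structure(list(mode = mode, fixed_values = fixed_values),
            class = "phase_policy")
}

phases_for_label <- function(policy, label) {
  switch(policy$mode,
    binary_0_180 = c(0, 180),
    increments_60 = seq(0, 300, by = 60),
    fixed = {
      v <- policy$fixed_values[[label]]
      if (is.null(v)) stop("phase policy has no entry for label '", label,
                           "'", call. = FALSE)
      v
    })
}

#' Periodicity constraint policy
#'
#' `"scan_1to5"` allows n = 1..5 (1D torsion scans), `"ensemble_1to3"`
#' allows n = 1..3 (ensembles of glyceride/ceramide/PC conformations),
#' `"retain_from_start"` keeps user-supplied per-label periodicity sets
#' (e.g. those of the starting force field, possibly with extra terms).
#'
#' @param mode One of `"scan_1to5"`, `"ensemble_1to3"`,
#'   `"retain_from_start"`.
#' @param retained For `retain_from_start`: named list mapping label to
#'   an integer vector of periodicities.
#' @return A `periodicity_policy` object.
#' @export
periodicity_policy <- function(mode = c("ensemble_1to3", "scan_1to5",
                                        "retain_from_start"),
                               retained = NULL) {
  mode <- match.arg(mode)
  if (mode == "retain_from_start") {
    stop_unless(is.list(retained) && length(retained) > 0 &&
                  !is.null(names(retained)),
                "mode 'retain_from_start' requires a named retained list")
    for (v in retained) {
      stop_unless(is.numeric(v) && length(v) > 0 && all(v >= 1) &&
                    all(v == round(v)) && !anyDuplicated(v),
                  "retained periodicities must be distinct positive integers")
    }
  }
  structure(list(mode = mode, retained = retained),
            class = "periodicity_policy")
}

periodicities_for_label <- function(policy, label) {
  n <- switch(policy$mode,
    scan_1to5 = 1:5,
    ensemble_1to3 = 1:3,
    retain_from_start = {
      v <- policy$retained[[label]]
      if (is.null(v)) stop("periodicity policy has no entry for label '",
                           label, "'", call. = FALSE)
      as.integer(v)
    })
  if (length(n) == 0) stop("empty allowed-periodicity set for label '",
                           label, "'", call. = FALSE)
  n
}

#' Genetic-algorithm configuration
#'
#' @param population_size Number of individuals (default 200).
#' @param generations Number of generations (default 500).
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.05).
#' @param elitism_count Individuals copied unchanged into the next
#'   generation (default 2); must be below `population_size`.
#' @param barrier_upper_bound Upper bound for barrier genes, kcal/mol
#'   (default 10; lower bound is 0).
#' @param seed Integer seed; identical seed and inputs reproduce the
#'   identical result.
#' @param mutation_sigma,mutation_sigma_final Gaussian mutation width on
#'   barrier genes, kcal/mol, annealed geometrically from
#'   `mutation_sigma` to `mutation_sigma_final` across generations so
#'   late generations refine barrier heights below the fitting
#'   tolerance. Phase genes mutate by uniform resampling from the
#'   policy set.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 200L, generations = 500L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      elitism_count = 2L, barrier_upper_bound = 10,
                      seed = 1L, mutation_sigma = 0.3,
                      mutation_sigma_final = 0.01) {
  stop_unless(is_number(population_size) && population_size >= 2,
              "population_size must be >= 2")
  stop_unless(is_number(generations) && generations >= 1,
              "generations must be >= 1")
  stop_unless(is_number(crossover_rate) && crossover_rate >= 0 &&
                crossover_rate <= 1, "crossover_rate must be in [0,1]")
  stop_unless(is_number(mutation_rate) && mutation_rate >= 0 &&
                mutation_rate <= 1, "mutation_rate must be in [0,1]")
  stop_unless(is_number(elitism_count) && elitism_count >= 0 &&
                elitism_count < population_size,
              "elitism_count must be non-negative and < population_size")
  stop_unless(is_number(barrier_upper_bound) && barrier_upper_bound > 0,
              "barrier_upper_bound must be positive")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 barrier_upper_bound = barrier_upper_bound,
                 seed = as.integer(seed),
                 mutation_sigma = mutation_sigma,
                 mutation_sigma_final = mutation_sigma_final),
            class = "ga_config")
}

## ---- internal fitness machinery ------------------------------------

## Gene table: one row per (label, periodicity); phases[[g]] holds the
## allowed phase set of gene g.
build_genes <- function(dataset, phase_pol, period_pol) {
  rows <- list()
  phases <- list()
  for (lab in dataset$fitted_labels) {
    ns <- periodicities_for_label(period_pol, lab)
    ph <- phases_for_label(phase_pol, lab)
    for (n in ns) {
      rows[[length(rows) + 1L]] <- data.frame(label = lab, periodicity = n,
                                              stringsAsFactors = FALSE)
      phases[[length(phases) + 1L]] <- ph
    }
  }
  list(table = do.call(rbind, rows), phases = phases)
}

## Precompute cos/sin basis matrices: N x G.
build_basis <- function(dataset, genes) {
  G <- nrow(genes$table)
  N <- nrow(dataset$angles)
  C <- matrix(0, N, G)
  S <- matrix(0, N, G)
  for (g in seq_len(G)) {
    th <- deg2rad(genes$table$periodicity[g] *
                    dataset$angles[[genes$table$label[g]]])
    C[, g] <- cos(th)
    S[, g] <- sin(th)
  }
  list(C = C, S = S,
       d = dataset$e_qm - dataset$e_zeroed,
       w = dataset$weight)
}

## Vectorised fitness of a population: V and phase are P x G matrices
## (phase in degrees). Returns length-P vector of weighted, offset-
## aligned sums of squares.
batch_fitness <- function(V, phase, basis, align_offset = TRUE) {
  g <- deg2rad(phase)
  Vc <- V * cos(g)
  Vs <- V * sin(g)
  ## torsion energy: sum_g V_g (1 + cos(n theta - gamma))
  T <- basis$C %*% t(Vc) + basis$S %*% t(Vs)
  T <- sweep(T, 2L, rowSums(V), `+`)
  resid <- basis$d - T                      # N x P
  w <- basis$w
  if (align_offset) {
    c0 <- colSums(w * resid) / sum(w)
    resid <- sweep(resid, 2L, c0, `-`)
  }
  colSums(w * resid^2)
}

genes_to_candidate <- function(V, phase, genes) {
  out <- list()
  for (lab in unique(genes$table$label)) {
    idx <- which(genes$table$label == lab)
    terms <- lapply(idx, function(g) {
      torsion_term(genes$table$periodicity[g], V[g], phase[g] %% 360)
    })
    out[[lab]] <- torsion_series(terms, label = lab)
  }
  out
}

## ---- GA ------------------------------------------------------------

#' Fit torsion parameters with a real-coded genetic algorithm
#'
#' Minimises the offset-aligned least-squares [fitness()] between QM and
#' MM energies over barrier heights (continuous, in
#' `[0, barrier_upper_bound]`) and phase shifts (categorical, from the
#' phase policy), one gene pair per allowed periodicity per fitted
#' label; multi-label datasets are fitted simultaneously on one
#' chromosome. Selection is binary tournament; crossover is uniform;
#' barrier genes mutate by annealed Gaussian steps and phase genes by
#' resampling. Elitism guarantees a non-increasing best-fitness history.
#' Equal-fitness ties are broken toward the lowest total barrier
#' (parsimony).
#'
#' @param dataset A [fit_dataset()].
#' @param phase_pol A [phase_policy()].
#' @param period_pol A [periodicity_policy()].
#' @param config A [ga_config()].
#' @param test_set Optional held-out [fit_dataset()] for validation
#'   metrics.
#' @return A `fit_result` list: `fitted` (named list of
#'   [torsion_series()]), `train_rmse`, `train_r2`, `test_rmse`,
#'   `test_r2` (NA without a test set), `fitness`, `history` (best
#'   fitness per generation, non-increasing), `seed`.
#' @export
run_ga_fit <- function(dataset, phase_pol, period_pol, config = ga_config(),
                       test_set = NULL) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  stop_unless(inherits(phase_pol, "phase_policy"),
              "phase_pol must be a phase_policy")
  stop_unless(inherits(period_pol, "periodicity_policy"),
              "period_pol must be a periodicity_policy")
  stop_unless(inherits(config, "ga_config"), "config must be a ga_config")

  genes <- build_genes(dataset, phase_pol, period_pol)
  basis <- build_basis(dataset, genes)
  G <- nrow(genes$table)
  P <- config$population_size
  ub <- config$barrier_upper_bound
  n_phase <- vapply(genes$phases, length, integer(1))

  with_seed(config$seed, {
    V <- matrix(stats::runif(P * G, 0, ub), P, G)
    phidx <- vapply(seq_len(G), function(g) {
      sample.int(n_phase[g], P, replace = TRUE)
    }, integer(P))
    phidx <- matrix(phidx, P, G)
    phase_of <- function(idx) {
      matrix(vapply(seq_len(G), function(g) genes$phases[[g]][idx[, g]],
                    numeric(nrow(idx))), nrow(idx), G)
    }

    history <- numeric(config$generations)
    sig0 <- config$mutation_sigma
    sigf <- config$mutation_sigma_final
    best <- NULL

    for (gen in seq_len(config$generations)) {
      fit <- batch_fitness(V, phase_of(phidx), basis)
      ord <- order(fit, rowSums(V))      # parsimony tie-break
      if (is.null(best) || fit[ord[1]] < best$fitness ||
          (fit[ord[1]] == best$fitness &&
             sum(V[ord[1], ]) < sum(best$V))) {
        best <- list(fitness = fit[ord[1]], V = V[ord[1], , drop = TRUE],
                     phidx = phidx[ord[1], , drop = TRUE])
      }
      history[gen] <- best$fitness
      if (gen == config$generations) break

      ## elitism
      nel <- config$elitism_count
      eliteV <- V[ord[seq_len(nel)], , drop = FALSE]
      eliteP <- phidx[ord[seq_len(nel)], , drop = FALSE]

      ## binary tournament selection
      n_off <- P - nel
      a <- sample.int(P, n_off, replace = TRUE)
      b <- sample.int(P, n_off, replace = TRUE)
      win <- ifelse(fit[a] < fit[b], a, b)
      newV <- V[win, , drop = FALSE]
      newP <- phidx[win, , drop = FALSE]

      ## uniform crossover on consecutive pairs
      npair <- n_off %/% 2L
      if (npair > 0) {
        do_cx <- stats::runif(npair) < config$crossover_rate
        for (k in which(do_cx)) {
          i <- 2L * k - 1L; j <- 2L * k
          mask <- stats::runif(G) < 0.5
          if (any(mask)) {
            tmp <- newV[i, mask]; newV[i, mask] <- newV[j, mask]
            newV[j, mask] <- tmp
            tmp <- newP[i, mask]; newP[i, mask] <- newP[j, mask]
            newP[j, mask] <- tmp
          }
        }
      }

      ## mutation: annealed Gaussian on barriers, resampling on phases
      sig <- if (config$generations > 1) {
        sig0 * (sigf / sig0)^((gen - 1) / (config$generations - 1))
      } else sig0
      mmask <- matrix(stats::runif(n_off * G) < config$mutation_rate, n_off, G)
      if (any(mmask)) {
        newV[mmask] <- pmin(pmax(newV[mmask] +
                                   stats::rnorm(sum(mmask), 0, sig), 0), ub)
      }
      pmask <- matrix(stats::runif(n_off * G) < config$mutation_rate, n_off, G)
      for (g in which(colSums(pmask) > 0)) {
        k <- sum(pmask[, g])
        newP[pmask[, g], g] <- sample.int(n_phase[g], k, replace = TRUE)
      }

      V <- rbind(eliteV, newV)
      phidx <- rbind(eliteP, newP)
    }

    fitted <- genes_to_candidate(
      best$V, vapply(seq_len(G), function(g) genes$phases[[g]][best$phidx[g]],
                     numeric(1)), genes)
    train <- fit_diagnostics(fitted, dataset)
    test <- if (!is.null(test_set)) fit_diagnostics(fitted, test_set) else
      list(rmse = NA_real_, r_squared = NA_real_)
    structure(list(fitted = fitted,
                   fitness = best$fitness,
                   train_rmse = train$rmse, train_r2 = train$r_squared,
                   test_rmse = test$rmse, test_r2 = test$r_squared,
                   history = history, seed = config$seed,
                   genes = genes$table),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("GA torsion fit (seed %d): fitness %.6g, train RMSE %.4f\n",
              x$seed, x$fitness, x$train_rmse))
  if (!is.na(x$test_rmse)) cat(sprintf("  test RMSE %.4f\n", x$test_rmse))
  for (s in x$fitted) print(s)
  invisible(x)
}

#' Exhaustive grid-search oracle for torsion fitting
#'
#' Enumerates every combination of barrier values (from `barrier_grid`)
#' and allowed phases per gene and returns the global minimiser of the
#' same fitness the GA optimises. Intended as an independent validation
#' oracle on small problems.
#'
#' @inheritParams run_ga_fit
#' @param barrier_grid Numeric vector of candidate barrier heights
#'   (kcal/mol).
#' @param max_combinations Safety cap on the enumeration size
#'   (default 1e7).
#' @return List with `candidate` (named list of [torsion_series()]) and
#'   `fitness`.
#' @export
ga_oracle_fit <- function(dataset, phase_pol, period_pol, barrier_grid,
                          max_combinations = 1e7) {
  stop_unless(inherits(dataset, "fit_dataset"), "dataset must be a fit_dataset")
  stop_unless(is.numeric(barrier_grid) && length(barrier_grid) >= 1 &&
                all(barrier_grid >= 0), "barrier_grid must be non-negative")
  genes <- build_genes(dataset, phase_pol, period_pol)
  basis <- build_basis(dataset, genes)
  G <- nrow(genes$table)
  per_gene <- vapply(genes$phases, function(p) {
    length(barrier_grid) * length(p)
  }, numeric(1))
  total <- prod(per_gene)
  if (total > max_combinations) {
    stop(sprintf(paste("grid enumeration of %.3g combinations exceeds the",
                       "cap of %.3g; use a coarser barrier_grid"),
                 total, max_combinations), call. = FALSE)
  }

  ## per-gene option tables (V, phase)
  opts <- lapply(seq_len(G), function(g) {
    expand.grid(V = barrier_grid, phase = genes$phases[[g]],
                KEEP.OUT.ATTRS = FALSE)
  })
  idx_grid <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))),
                          KEEP.OUT.ATTRS = FALSE)

  best_fit <- Inf
  best_V <- NULL
  best_ph <- NULL
  chunk <- 20000L
  for (start in seq(1L, nrow(idx_grid), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(idx_grid))
    V <- matrix(0, length(rows), G)
    ph <- matrix(0, length(rows), G)
    for (g in seq_len(G)) {
      o <- opts[[g]][idx_grid[rows, g], ]
      V[, g] <- o$V
      ph[, g] <- o$phase
    }
    f <- batch_fitness(V, ph, basis)
    ord <- order(f, rowSums(V))
    i <- ord[1]
    if (f[i] < best_fit ||
        (f[i] == best_fit && sum(V[i, ]) < sum(best_V))) {
      best_fit <- f[i]
      best_V <- V[i, ]
      best_ph <- ph[i, ]
    }
  }
  list(candidate = genes_to_candidate(best_V, best_ph, genes),
       fitness = best_fit)
}

#' Fit a harmonic angle parameter to a 1D scan
#'
#' Least-squares fit of \eqn{K (\theta - \theta_0)^2 + c} (deviation in
#' radians) to `e_qm - e_zeroed` over an angle scan. The model is a
#' quadratic in the angle, so the fit is a linear regression on
#' \eqn{(\theta, \theta^2)}; curvature and vertex give \eqn{K} and
#' \eqn{\theta_0}.
#'
#' @param scan Data frame with columns `theta` (degrees), `e_zeroed`,
#'   `e_qm` (kcal/mol); at least 5 points spanning an interior minimum.
#' @return List with `param` ([harmonic_angle_param()]), `offset` (the
#'   fitted energy at the minimum, kcal/mol) and `rmse`.
#' @export
fit_harmonic_angle <- function(scan) {
  scan <- as.data.frame(scan)
  stop_unless(all(c("theta", "e_zeroed", "e_qm") %in% colnames(scan)),
              "scan needs columns theta, e_zeroed, e_qm")
  stop_unless(nrow(scan) >= 5, "scan needs at least 5 points")
  e <- scan$e_qm - scan$e_zeroed
  th <- scan$theta
  if (stats::var(e) == 0) {
    stop("scan is flat: no interior minimum to fit", call. = FALSE)
  }
  fit <- stats::lm(e ~ th + I(th^2))
  a <- unname(stats::coef(fit)[3])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(a) || a <= 0) {
    stop("scan has no interior minimum (non-positive curvature)",
         call. = FALSE)
  }
  theta0 <- -b / (2 * a)
  if (theta0 <= min(th) || theta0 >= max(th)) {
    stop(sprintf("fitted minimum (%.2f deg) lies outside the scan range",
                 theta0), call. = FALSE)
  }
  K <- a / deg2rad(1)^2                     # kcal/mol/deg^2 -> kcal/mol/rad^2
  offset <- unname(stats::coef(fit)[1]) - b^2 / (4 * a)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  list(param = harmonic_angle_param(K, theta0), offset = offset, rmse = rmse)
}

#' Train/test split report for a torsion fit
#'
#' Summarises train vs held-out metrics and flags a test RMSE above
#' twice the training RMSE as an overfitting warning.
#'
#' @param fit A `fit_result` from [run_ga_fit()] carrying test metrics.
#' @param path Optional file path; when given the report is written as
#'   JSON (atomically).
#' @return The report as a list (invisibly when written to file).
#' @export
train_test_split_report <- function(fit, path = NULL) {
  stop_unless(inherits(fit, "fit_result"), "fit must be a fit_result")
  stop_unless(!is.na(fit$test_rmse), "fit carries no test metrics")
  report <- list(
    labels = names(fit$fitted),
    terms = lapply(fit$fitted, series_coefs),
    train = list(rmse = fit$train_rmse, r2 = fit$train_r2),
    test = list(rmse = fit$test_rmse, r2 = fit$test_r2),
    generations = length(fit$history),
    seed = fit$seed,
    overfitting_warning = isTRUE(fit$test_rmse > 2 * fit$train_rmse)
  )
  if (report$overfitting_warning) {
    warning(sprintf("possible overfitting: test RMSE %.4f > 2 x train RMSE %.4f",
                    fit$test_rmse, fit$train_rmse), call. = FALSE)
  }
  if (!is.null(path)) {
    atomic_write(jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE,
                                  dataframe = "columns"), path)
    return(invisible(report))
  }
  report
}
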