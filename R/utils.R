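#' @keywords internal
"_PACKAGE"

## degree/radian helpers; all user-facing angles are degrees,
## trigonometry is done in radians.
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, then
## restore the caller's stream. Keeps every stochastic routine free of
## global side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Scalar validation helpers used by the constructors.
stop_unless <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Atomic masses (u) and atomic numbers for the elements that occur in
## lipid systems; used for centre-of-mass and density bookkeeping.
ELEMENT_DATA <- data.frame(
  element = c("H", "D", "C", "N", "O", "P", "S", "K", "NA", "CL", "CA", "MG"),
  atomic_number = c(1, 1, 6, 7, 8, 15, 16, 19, 11, 17, 20, 12),
  mass = c(1.008, 2.014, 12.011, 14.007, 15.999, 30.974, 32.06,
           39.098, 22.990, 35.45, 40.078, 24.305),
  stringsAsFactors = FALSE
)

## Bound coherent neutron scattering lengths, in Angstrom (1 fm = 1e-5 A).
## Values from the standard Sears tabulation.
NEUTRON_B <- c(
  H  = -3.7390e-5, D = 6.671e-5, C = 6.6460e-5, N = 9.36e-5,
  O  = 5.803e-5,  P = 5.13e-5,  S = 2.847e-5,  K = 3.67e-5,
  `NA` = 3.63e-5, CL = 9.577e-5, CA = 4.70e-5, MG = 5.375e-5
)

element_mass <- function(element) {
  i <- match(toupper(element), ELEMENT_DATA$element)
  if (anyNA(i)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  ELEMENT_DATA$mass[i]
}

neutron_scattering_length <- function(element, d2o_fraction = 0) {
  b <- NEUTRON_B[toupper(element)]
  if (anyNA(b)) {
    bad <- unique(element[is.na(b)])
    stop("no coherent scattering length tabulated for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(b)
}

## Atomic file writer: write to a temp file in the same directory, then
## rename, so interrupted runs never leave truncated output behind.
atomic_write <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

running_mean <- function(x, k) {
  ## centred running mean with window of k points (k odd); edges use the
  ## available partial window.
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
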