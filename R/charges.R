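## Ensemble averaging of per-conformer RESP charge sets and the modular
## head/tail neutrality bookkeeping of fragment-based lipid force
## fields (each head or tail unit carries an integer target charge so
## fragments can be combined freely).

#' Create a partial-charge set for one fragment
#'
#' @param atom_names Character vector of atom labels (ordered).
#' @param charges Numeric vector of partial charges (elementary-charge
#'   units), same length as `atom_names`.
#' @param fragment_label Head/tail unit name (e.g. `"PC"`, `"OL"`).
#' @param target_net Integer total charge of the fragment (0 for
#'   zwitterionic heads and tails, -1 for anionic heads such as PG/PS).
#' @return A `charge_set` object.
#' @export
charge_set <- function(atom_names, charges, fragment_label = "",
                       target_net = 0L) {
  stop_unless(length(atom_names) == length(charges) && length(charges) >= 1,
              "atom_names and charges must be equal-length, non-empty")
  stop_unless(is.numeric(charges) && all(is.finite(charges)),
              "charges must be finite numbers")
  stop_unless(is_number(target_net) && target_net == round(target_net),
              "target_net must be an integer")
  structure(list(atom_names = as.character(atom_names),
                 charges = as.numeric(charges),
                 fragment_label = as.character(fragment_label),
                 target_net = as.integer(target_net)),
            class = "charge_set")
}

#' Create a charge ensemble
#'
#' A collection of per-conformer [charge_set()]s for the same fragment,
#' congruent in atom names and ordering (the workflow extracts many
#' conformers from a bilayer simulation, fits charges to each, and
#' averages to obtain implicitly polarised, Boltzmann-averaged charges).
#'
#' @param members List of [charge_set()] objects.
#' @return A `charge_ensemble` object.
#' @export
charge_ensemble <- function(members) {
  stop_unless(is.list(members) && length(members) >= 1,
              "ensemble needs at least one member")
  ref <- members[[1]]
  for (i in seq_along(members)) {
    m <- members[[i]]
    stop_unless(inherits(m, "charge_set"),
                "ensemble member %d is not a charge_set", i)
    mismatch <- which(m$atom_names != ref$atom_names)
    if (length(m$atom_names) != length(ref$atom_names) || length(mismatch)) {
      bad <- if (length(m$atom_names) != length(ref$atom_names)) {
        "atom count differs"
      } else {
        sprintf("first mismatching atom '%s' vs '%s'",
                m$atom_names[mismatch[1]], ref$atom_names[mismatch[1]])
      }
      stop(sprintf("ensemble member %d incongruent with member 1: %s",
                   i, bad), call. = FALSE)
    }
    stop_unless(m$target_net == ref$target_net,
                "ensemble member %d has a different target_net", i)
  }
  structure(list(members = members), class = "charge_ensemble")
}

#' Average a charge ensemble into a final charge set
#'
#' Takes the per-atom arithmetic mean over all members, then removes
#' any residual difference between the mean total and the integer
#' target net charge by uniform redistribution across all atoms, so the
#' returned set sums to `target_net` exactly (to double precision).
#'
#' @param ensemble A [charge_ensemble()].
#' @return A [charge_set()] with the averaged charges; attribute
#'   `residual_before_fix` records the redistributed residual.
#' @export
average_charges <- function(ensemble) {
  stop_unless(inherits(ensemble, "charge_ensemble"),
              "ensemble must be a charge_ensemble")
  ref <- ensemble$members[[1]]
  mat <- do.call(rbind, lapply(ensemble$members, `[[`, "charges"))
  mean_q <- colMeans(mat)
  residual <- sum(mean_q) - ref$target_net
  fixed <- mean_q - residual / length(mean_q)
  out <- charge_set(ref$atom_names, fixed, ref$fragment_label, ref$target_net)
  attr(out, "residual_before_fix") <- residual
  attr(out, "n_members") <- length(ensemble$members)
  out
}

#' Validate a modular head + tails charge assembly
#'
#' Sums the integer target charges of a head fragment and its tail
#' fragments and checks the combined lipid net charge against the
#' declared species charge (0 for zwitterionic, -1 for anionic lipids).
#'
#' @param head A [charge_set()] for the headgroup fragment.
#' @param tails List of [charge_set()]s for the acyl-chain fragments.
#' @param declared_net Declared integer net charge of the assembled
#'   lipid.
#' @return List with `net` (combined integer charge) and `pass`
#'   (logical); a failing assembly also carries a `message`.
#' @export
validate_modular_assembly <- function(head, tails, declared_net) {
  stop_unless(inherits(head, "charge_set"), "head must be a charge_set")
  stop_unless(is.list(tails), "tails must be a list of charge_set")
  stop_unless(is_number(declared_net) && declared_net == round(declared_net),
              "declared_net must be an integer")
  nets <- c(head$target_net,
            vapply(tails, function(t) {
              stop_unless(inherits(t, "charge_set"),
                          "every tail must be a charge_set")
              t$target_net
            }, integer(1)))
  net <- sum(nets)
  pass <- net == declared_net
  out <- list(net = net, pass = pass)
  if (!pass) {
    out$message <- sprintf(
      "assembled net charge %+d does not match declared species charge %+d",
      net, as.integer(declared_net))
  }
  out
}

#' Read / write charge ensembles and charge tables
#'
#' The ensemble CSV layout has one row per member and one column per
#' atom (header row = atom names). `write_charge_set` emits a
#' two-column `atom,charge` table (6 decimals, residual redistributed
#' after rounding so the printed total is exact) plus a JSON sidecar
#' with fragment metadata.
#'
#' @param path CSV path.
#' @param fragment_label,target_net Fragment metadata for the ensemble.
#' @param set A [charge_set()].
#' @param sidecar Logical; write the JSON sidecar next to `path`.
#' @return `read_charge_ensemble` returns a [charge_ensemble()].
#' @export
read_charge_ensemble <- function(path, fragment_label = "", target_net = 0L) {
  df <- utils::read.csv(path, check.names = FALSE)
  stop_unless(nrow(df) >= 1 && ncol(df) >= 1, "empty ensemble CSV")
  members <- lapply(seq_len(nrow(df)), function(i) {
    charge_set(colnames(df), as.numeric(df[i, ]), fragment_label, target_net)
  })
  charge_ensemble(members)
}

#' @rdname read_charge_ensemble
#' @export
write_charge_set <- function(set, path, sidecar = TRUE) {
  stop_unless(inherits(set, "charge_set"), "set must be a charge_set")
  q <- round(set$charges, 6)
  ## re-apply neutrality after rounding so the printed column sums to
  ## target_net at printed precision
  resid <- sum(q) - set$target_net
  n <- length(q)
  adj <- round(resid * 1e6)                  # in 1e-6 e units
  if (adj != 0) {
    per <- adj %/% n
    extra <- adj - per * n
    q <- q - per / 1e6
    if (extra != 0) {
      q[seq_len(abs(extra))] <- q[seq_len(abs(extra))] - sign(extra) / 1e6
    }
  }
  lines <- c("atom,charge",
             sprintf("%s,%.6f", set$atom_names, q))
  atomic_write(lines, path)
  if (sidecar) {
    meta <- list(fragment_label = set$fragment_label,
                 n_members = attr(set, "n_members"),
                 target_net = set$target_net,
                 residual_before_fix = attr(set, "residual_before_fix"))
    atomic_write(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                  null = "null"),
                 paste0(path, ".json"))
  }
  invisible(path)
}
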