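## Containers and file I/O for bilayer trajectories: an atom-metadata
## topology table plus a list of coordinate frames with per-frame
## orthorhombic boxes. Formats: multi-model PDB (CRYST1 boxes) with a
## CSV metadata sidecar, and a plain-text long-format frames CSV.

#' Create a topology table
#'
#' @param name Atom names.
#' @param element Element symbols (used for masses and scattering
#'   lengths).
#' @param atomic_number Integer atomic numbers (>= 1).
#' @param partial_charge Partial charges in elementary-charge units.
#' @param residue_id Integer residue numbers (1-based, as in PDB files).
#' @param residue_name Residue names.
#' @param role One of `"lipid"`, `"water"`, `"ion"` per atom; used for
#'   selections and bilayer centring.
#' @param leaflet Optional leaflet hint (`+1`/`-1`/`NA`).
#' @return A `topology` data frame.
#' @export
topology <- function(name, element, atomic_number, partial_charge,
                     residue_id, residue_name, role, leaflet = NA) {
  n <- length(name)
  stop_unless(all(lengths(list(element, atomic_number, partial_charge,
                               residue_id, residue_name, role)) == n),
              "all topology columns must have the same length")
  stop_unless(all(atomic_number >= 1), "atomic_number must be >= 1")
  stop_unless(all(role %in% c("lipid", "water", "ion")),
              "role must be one of lipid/water/ion for every atom")
  df <- data.frame(name = as.character(name),
                   element = toupper(as.character(element)),
                   atomic_number = as.integer(atomic_number),
                   partial_charge = as.numeric(partial_charge),
                   residue_id = as.integer(residue_id),
                   residue_name = as.character(residue_name),
                   role = as.character(role),
                   leaflet = if (length(leaflet) == n) leaflet else
                     rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("topology", class(df))
  df
}

#' Create a coordinate frame
#'
#' @param xyz Numeric n x 3 matrix of coordinates in Angstrom.
#' @param box Orthorhombic box lengths `c(Lx, Ly, Lz)` in Angstrom.
#' @param time Frame time in ps.
#' @return A `frame` object.
#' @export
frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  stop_unless(ncol(xyz) == 3 && nrow(xyz) >= 1, "xyz must be an n x 3 matrix")
  stop_unless(length(box) == 3 && all(box > 0),
              "box must be three positive lengths (Angstrom)")
  structure(list(xyz = xyz, box = as.numeric(box), time = as.numeric(time)),
            class = "frame")
}

#' Create a bilayer trajectory
#'
#' @param frames List of [frame()] objects; every frame must have the
#'   same atom count as the topology.
#' @param top A [topology()] table.
#' @return A `bilayer_trajectory` object.
#' @export
bilayer_trajectory <- function(frames, top) {
  stop_unless(is.list(frames) && length(frames) >= 1,
              "at least one frame required")
  stop_unless(inherits(top, "topology"), "top must be a topology")
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    stop_unless(inherits(f, "frame"), "frames[[%d]] is not a frame", i)
    if (nrow(f$xyz) != nrow(top)) {
      stop(sprintf("frame %d has %d atoms but the topology has %d",
                   i, nrow(f$xyz), nrow(top)), call. = FALSE)
    }
  }
  structure(list(frames = frames, topology = top),
            class = "bilayer_trajectory")
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat(sprintf("Bilayer trajectory: %d frames, %d atoms (%d lipid, %d water, %d ion)\n",
              length(x$frames), nrow(x$topology),
              sum(x$topology$role == "lipid"),
              sum(x$topology$role == "water"),
              sum(x$topology$role == "ion")))
  invisible(x)
}

## ---- PDB I/O -------------------------------------------------------

#' Read a trajectory from a multi-model PDB (plus metadata sidecar)
#'
#' Parses `ATOM`/`HETATM` records per `MODEL`, with per-frame boxes from
#' `CRYST1` lines (a single leading `CRYST1` applies to all models).
#' Element symbols come from PDB columns 77-78 when present, otherwise
#' from the atom name. Atomic numbers, partial charges and roles come
#' from the CSV sidecar (`atomic_number,partial_charge,role[,leaflet]`,
#' one row per atom); without a sidecar charges default to 0 and roles
#' to `"lipid"`.
#'
#' @param path PDB file path, or a frames CSV written by
#'   [write_trajectory_csv()] (dispatch on extension).
#' @param meta_path Optional metadata CSV sidecar.
#' @return A [bilayer_trajectory()].
#' @export
read_trajectory <- function(path, meta_path = NULL) {
  stop_unless(file.exists(path), "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  traj <- if (ext == "pdb") read_trajectory_pdb(path) else
    if (ext == "csv") read_trajectory_csv(path) else
      stop("unsupported trajectory format: .", ext,
           " (use multi-model PDB or frames CSV)", call. = FALSE)
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path)
    if (nrow(meta) != nrow(traj$topology)) {
      stop(sprintf("metadata has %d rows but trajectory has %d atoms",
                   nrow(meta), nrow(traj$topology)), call. = FALSE)
    }
    for (col in c("atomic_number", "partial_charge", "role", "leaflet")) {
      if (col %in% colnames(meta)) traj$topology[[col]] <- meta[[col]]
    }
    stop_unless(all(traj$topology$role %in% c("lipid", "water", "ion")),
                "metadata roles must be lipid/water/ion")
  }
  traj
}

read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines)
  parse_box <- function(ln) {
    b <- c(as.numeric(substr(ln, 7, 15)), as.numeric(substr(ln, 16, 24)),
           as.numeric(substr(ln, 25, 33)))
    stop_unless(all(is.finite(b)) && all(b > 0), "bad CRYST1 record")
    b
  }
  if (length(cryst) == 0) {
    stop("PDB has no CRYST1 record: box is required", call. = FALSE)
  }
  model_starts <- grep("^MODEL", lines)
  atom_re <- "^(ATOM  |HETATM)"
  split_models <- if (length(model_starts) == 0) {
    list(grep(atom_re, lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    stop_unless(length(ends) == length(model_starts),
                "unbalanced MODEL/ENDMDL records")
    lapply(seq_along(model_starts), function(i) {
      rng <- model_starts[i]:ends[i]
      rng[grepl(atom_re, lines[rng])]
    })
  }
  parse_atoms <- function(idx) {
    ln <- lines[idx]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    stop_unless(all(is.finite(xyz)), "malformed coordinates in PDB")
    list(
      xyz = xyz,
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      resid = as.integer(substr(ln, 23, 26)),
      element = trimws(substr(ln, 77, 78))
    )
  }
  first <- parse_atoms(split_models[[1]])
  n_atoms <- nrow(first$xyz)
  element <- first$element
  guess <- toupper(gsub("[^A-Za-z].*$", "", first$name))
  guess <- ifelse(nchar(guess) > 1 &
                    !(guess %in% ELEMENT_DATA$element),
                  substr(guess, 1, 1), guess)
  element <- ifelse(element == "" | is.na(element), guess, toupper(element))
  znum <- ELEMENT_DATA$atomic_number[match(element, ELEMENT_DATA$element)]
  znum[is.na(znum)] <- 1L

  frames <- vector("list", length(split_models))
  for (i in seq_along(split_models)) {
    at <- if (i == 1) first else parse_atoms(split_models[[i]])
    if (nrow(at$xyz) != n_atoms) {
      stop(sprintf("frame %d has %d atoms, expected %d",
                   i, nrow(at$xyz), n_atoms), call. = FALSE)
    }
    box_line <- cryst[cryst < if (length(model_starts)) model_starts[i] else
      Inf]
    box_in_model <- if (length(model_starts)) {
      within <- cryst[cryst > model_starts[i] &
                        cryst < grep("^ENDMDL", lines)[i]]
      if (length(within)) within[1] else NA
    } else NA
    bl <- if (!is.na(box_in_model)) box_in_model else
      if (length(box_line)) box_line[length(box_line)] else cryst[1]
    frames[[i]] <- frame(at$xyz, parse_box(lines[bl]), time = i - 1)
  }
  top <- topology(first$name, element, znum,
                  partial_charge = rep(0, n_atoms),
                  residue_id = first$resid, residue_name = first$resname,
                  role = rep("lipid", n_atoms))
  bilayer_trajectory(frames, top)
}

#' Write a trajectory as a multi-model PDB
#'
#' Emits one `CRYST1` + `MODEL`/`ENDMDL` block per frame, atomically.
#'
#' @param traj A [bilayer_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stop_unless(inherits(traj, "bilayer_trajectory"),
              "traj must be a bilayer_trajectory")
  top <- traj$topology
  n <- nrow(top)
  out <- character(0)
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    out <- c(out,
             sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     f$box[1], f$box[2], f$box[3], 90, 90, 90),
             sprintf("MODEL     %4d", i),
             sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     pmin(seq_len(n), 99999L), substr(top$name, 1, 4),
                     substr(top$residue_name, 1, 3),
                     top$residue_id %% 10000L,
                     f$xyz[, 1], f$xyz[, 2], f$xyz[, 3], 1, 0,
                     substr(top$element, 1, 2)),
             "ENDMDL")
  }
  out <- c(out, "END")
  atomic_write(out, path)
  invisible(path)
}

#' Write the topology metadata sidecar CSV
#'
#' @param traj A [bilayer_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology_meta <- function(traj, path) {
  top <- traj$topology
  lines <- c("atomic_number,partial_charge,role,leaflet",
             sprintf("%d,%.17g,%s,%s", top$atomic_number, top$partial_charge,
                     top$role, ifelse(is.na(top$leaflet), "",
                                      format(top$leaflet))))
  atomic_write(lines, path)
  invisible(path)
}

## ---- frames CSV (text stand-in for binary coordinate formats) ------

#' Read / write a trajectory as a long-format frames CSV
#'
#' Plain-text alternative to binary coordinate formats: columns
#' `frame,time,Lx,Ly,Lz,atom,x,y,z` (one row per atom per frame, box
#' repeated). Round-trips at full double precision.
#'
#' @param traj A [bilayer_trajectory()].
#' @param path CSV path.
#' @return `read_trajectory_csv` returns a [bilayer_trajectory()]
#'   (topology placeholder; merge a sidecar via [read_trajectory()]).
#' @export
write_trajectory_csv <- function(traj, path) {
  stop_unless(inherits(traj, "bilayer_trajectory"),
              "traj must be a bilayer_trajectory")
  rows <- lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    sprintf("%d,%.17g,%.17g,%.17g,%.17g,%d,%.17g,%.17g,%.17g",
            i, f$time, f$box[1], f$box[2], f$box[3],
            seq_len(nrow(f$xyz)), f$xyz[, 1], f$xyz[, 2], f$xyz[, 3])
  })
  atomic_write(c("frame,time,Lx,Ly,Lz,atom,x,y,z", unlist(rows)), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stop_unless(all(c("frame", "time", "Lx", "Ly", "Lz", "atom", "x", "y", "z")
                  %in% colnames(df)), "not a frames CSV: %s", path)
  ids <- sort(unique(df$frame))
  n_atoms <- sum(df$frame == ids[1])
  frames <- lapply(ids, function(i) {
    sub <- df[df$frame == i, ]
    if (nrow(sub) != n_atoms) {
      stop(sprintf("frame %d has %d atoms, expected %d", i, nrow(sub),
                   n_atoms), call. = FALSE)
    }
    sub <- sub[order(sub$atom), ]
    frame(cbind(sub$x, sub$y, sub$z),
          c(sub$Lx[1], sub$Ly[1], sub$Lz[1]), time = sub$time[1])
  })
  top <- topology(name = sprintf("X%d", seq_len(n_atoms)),
                  element = rep("C", n_atoms),
                  atomic_number = rep(6L, n_atoms),
                  partial_charge = rep(0, n_atoms),
                  residue_id = seq_len(n_atoms),
                  residue_name = rep("UNK", n_atoms),
                  role = rep("lipid", n_atoms))
  bilayer_trajectory(frames, top)
}
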