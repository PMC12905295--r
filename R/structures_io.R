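## Structure, trajectory and window-series I/O plus named atom selections.
## Everything downstream (field evaluation, WHAM) consumes these containers.

#' Construct a charged frame
#'
#' A charged frame is one environment snapshot: atom records with Cartesian
#' coordinates (Angstrom) and per-atom partial charges (elementary charge
#' units), plus a frame time in ps. It is the container the Coulomb-sum
#' field evaluation operates on.
#'
#' @param atoms data.frame with columns `serial` (positive integer),
#'   `atom_name`, `residue_name`, `residue_id` (positive integer), optional
#'   `chain` and `element`, coordinates `x`, `y`, `z` (Angstrom) and
#'   `charge` (e; may be `NA` until assigned).
#' @param frame_time frame time in ps.
#' @param require_charges if `TRUE` (default), every atom must carry a
#'   finite charge.
#' @return An object of class `charged_frame`.
#' @export
charged_frame <- function(atoms, frame_time = 0, require_charges = TRUE) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "atom_name", "residue_name", "residue_id",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"chain" %in% names(atoms)) atoms$chain <- ""
  if (!"element" %in% names(atoms))
    atoms$element <- toupper(substr(trimws(atoms$atom_name), 1L, 1L))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$residue_id < 1) || any(atoms$serial < 1))
    stop("serial and residue_id must be positive")
  key <- paste(atoms$chain, atoms$residue_id, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (residue_id, atom_name) atom keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (require_charges) {
    if (any(!is.finite(atoms$charge)))
      stop("atoms without finite charges: ",
           paste(utils::head(key[!is.finite(atoms$charge)], 5), collapse = "; "))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, frame_time = as.numeric(frame_time)),
            class = "charged_frame")
}

#' @export
print.charged_frame <- function(x, ...) {
  cat(sprintf("<charged_frame> %d atoms, %d residues, t = %g ps\n",
              nrow(x$atoms), length(unique(x$atoms$residue_id)),
              x$frame_time))
  invisible(x)
}

## Pre-validate fixed-column numeric fields of ATOM/HETATM records so a
## mangled file fails with the offending line number instead of downstream.
validate_pdb_columns <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop(sprintf("malformed fixed-column coordinate field at line %d", i))
    if (is.na(suppressWarnings(as.integer(substr(lines[i], 23, 26)))))
      stop(sprintf("malformed residue number at line %d", i))
  }
  invisible(idx)
}

#' Read a structure file into a charged frame
#'
#' Reads a fixed-column PDB (ATOM/HETATM records, 1-based residue numbering
#' as in the source file) or the package's XYZQ dialect. For PDB input,
#' charges are never guessed from elements: they must be supplied through
#' `charge_table`, keyed by (residue_name, atom_name), exactly as a
#' force-field charge set would be. Alternate locations keep the
#' highest-occupancy altloc (ties: first encountered).
#'
#' @param path file path; format chosen by extension (`.xyzq` vs PDB).
#' @param charge_table optional data.frame with columns `residue_name`,
#'   `atom_name`, `charge`, or a path to such a CSV. Required for every atom
#'   when given; an unresolvable atom is an error naming that atom.
#' @return A [charged_frame()].
#' @export
read_structure <- function(path, charge_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xyzq$", path, ignore.case = TRUE))
    return(read_xyzq(path))
  lines <- readLines(path, warn = FALSE)
  validate_pdb_columns(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  ## altloc pruning: within each (chain, resno, elety), keep the record with
  ## the highest occupancy; ties resolved toward the first encountered.
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    grp <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(ii) {
      ii[which.max(occ[ii])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  atoms <- data.frame(
    serial       = at$eleno,
    atom_name    = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_id   = at$resno,
    chain        = ifelse(is.na(at$chain), "", at$chain),
    element      = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                          toupper(substr(trimws(at$elety), 1, 1)),
                          trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(charge_table)) {
    if (is.character(charge_table))
      charge_table <- utils::read.csv(charge_table, stringsAsFactors = FALSE)
    stopifnot(all(c("residue_name", "atom_name", "charge") %in%
                    names(charge_table)))
    key_f <- paste(atoms$residue_name, atoms$atom_name)
    key_t <- paste(trimws(charge_table$residue_name),
                   trimws(charge_table$atom_name))
    m <- match(key_f, key_t)
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop(sprintf(
        "no charge-table entry for atom %s of residue %s %d",
        atoms$atom_name[bad], atoms$residue_name[bad], atoms$residue_id[bad]))
    }
    atoms$charge <- charge_table$charge[m]
  }
  charged_frame(atoms, frame_time = 0,
                require_charges = !is.null(charge_table))
}

#' Write a charged frame in the XYZQ dialect
#'
#' Extended-XYZ, self-contained frame format: a count line, a comment line
#' carrying the frame time, then one line per atom,
#' `element x y z charge residue_id residue_name atom_name`, with fixed
#' 9-decimal output so write/read round-trips to stored precision.
#'
#' @param frame a [charged_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyzq <- function(frame, path) {
  stopifnot(inherits(frame, "charged_frame"))
  a <- frame$atoms
  lines <- c(
    sprintf("%d", nrow(a)),
    sprintf("frame_time_ps=%.9f", frame$frame_time),
    sprintf("%s %.9f %.9f %.9f %.9f %d %s %s",
            a$element, a$x, a$y, a$z, a$charge,
            a$residue_id, a$residue_name, a$atom_name)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZQ frame
#'
#' @param path path to a file written by [write_xyzq()].
#' @return A [charged_frame()].
#' @export
read_xyzq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated XYZQ file: ", path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("XYZQ parse error at line 1: expected atom count")
  t_ps <- 0
  m <- regmatches(lines[2], regexec("frame_time_ps=([-0-9.eE+]+)", lines[2]))[[1]]
  if (length(m) == 2) t_ps <- as.numeric(m[2])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 8L)
  if (length(bad) > 0)
    stop(sprintf("XYZQ parse error at line %d: expected 8 fields", bad[1] + 2L))
  mat <- do.call(rbind, parts)
  atoms <- data.frame(
    serial       = seq_len(n),
    atom_name    = mat[, 8],
    residue_name = mat[, 7],
    residue_id   = as.integer(mat[, 6]),
    chain        = "",
    element      = mat[, 1],
    x = as.numeric(mat[, 2]), y = as.numeric(mat[, 3]),
    z = as.numeric(mat[, 4]),
    charge = as.numeric(mat[, 5]),
    stringsAsFactors = FALSE
  )
  charged_frame(atoms, frame_time = t_ps)
}

#' Read an umbrella-window time series
#'
#' Whitespace-delimited two-column text (time in ps, coordinate in
#' Angstrom); lines starting with `#` are ignored. Times must be strictly
#' increasing and at least two samples are required.
#'
#' @param path file path.
#' @return A data.frame of class `window_series` with columns `time`, `value`.
#' @export
read_window_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2)
    stop("insufficient data: need at least 2 samples in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(vapply(parts, length, 1L) < 2L))
    stop("format error: expected two columns (time, value) in ", path)
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  window_series(times = mat[1, ], values = mat[2, ])
}

#' Construct a window series
#'
#' @param times strictly increasing sample times, ps.
#' @param values coordinate samples, Angstrom.
#' @return A data.frame of class `window_series`.
#' @export
window_series <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (anyNA(times) || anyNA(values) || any(!is.finite(values)))
    stop("non-finite entries in window series")
  if (any(diff(times) <= 0))
    stop("format error: times must be strictly increasing")
  structure(data.frame(time = as.numeric(times), value = as.numeric(values)),
            class = c("window_series", "data.frame"))
}

#' Define a named atom selection
#'
#' Selections name atoms either by whole residue id or by
#' (residue_id, atom_name) pair, in include or exclude mode. The canonical
#' use is the field-environment rule "every protein atom except the
#' catalytic triad residues".
#'
#' @param residues integer vector of whole residue ids (optional).
#' @param atoms data.frame with columns `residue_id`, `atom_name` (optional).
#' @param mode `"include"` or `"exclude"`.
#' @return An object of class `atom_selection`.
#' @export
selection <- function(residues = integer(), atoms = NULL,
                      mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  if (!is.null(atoms))
    stopifnot(all(c("residue_id", "atom_name") %in% names(atoms)))
  structure(list(residues = as.integer(residues), atoms = atoms, mode = mode),
            class = "atom_selection")
}

#' Resolve a selection against a frame
#'
#' @param frame a [charged_frame()].
#' @param sel an [selection()].
#' @return Ascending integer indices into `frame$atoms`. Exclude mode
#'   returns the complement of the members. A member key matching no atom
#'   yields a warning, not an error, so one selection can be applied across
#'   mutated variants.
#' @export
resolve_selection <- function(frame, sel) {
  stopifnot(inherits(frame, "charged_frame"), inherits(sel, "atom_selection"))
  a <- frame$atoms
  hit <- rep(FALSE, nrow(a))
  if (length(sel$residues) > 0) {
    found <- sel$residues %in% a$residue_id
    if (!all(found))
      warning("selection residues not present in frame: ",
              paste(sel$residues[!found], collapse = ", "))
    hit <- hit | a$residue_id %in% sel$residues
  }
  if (!is.null(sel$atoms) && nrow(sel$atoms) > 0) {
    key_f <- paste(a$residue_id, a$atom_name)
    key_s <- paste(sel$atoms$residue_id, sel$atoms$atom_name)
    found <- key_s %in% key_f
    if (!all(found))
      warning("selection atoms not present in frame: ",
              paste(key_s[!found], collapse = "; "))
    hit <- hit | key_f %in% key_s
  }
  if (sel$mode == "include") which(hit) else which(!hit)
}

#' Reassemble a solvated-system atom count from its composition
#'
#' Bookkeeping helper for the standard composition statement of a solvated
#' enzyme-substrate simulation box: protein atoms + substrate atoms +
#' 3-site waters + monatomic counterions.
#'
#' @param protein_atoms,substrate_atoms atom counts.
#' @param n_waters number of water molecules (3 atoms each for a 3-site
#'   model such as TIP3P).
#' @param n_ions number of monatomic counterions.
#' @param atoms_per_water atoms per water molecule (default 3).
#' @return Total atom count (integer).
#' @export
#' @examples
#' solvated_atom_count(3848, 134, 10804, 5)  # 36399
solvated_atom_count <- function(protein_atoms, substrate_atoms, n_waters,
                                n_ions, atoms_per_water = 3L) {
  stopifnot(protein_atoms >= 0, substrate_atoms >= 0, n_waters >= 0,
            n_ions >= 0)
  as.integer(protein_atoms + substrate_atoms +
               atoms_per_water * n_waters + n_ions)
}
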