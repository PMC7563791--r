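#' Default van der Waals radii table
#'
#' United-atom (Chothia-style) radii used for all surface and gap-volume
#' computation. Values in Angstrom. Elements absent from the table receive
#' \code{default}.
#'
#' @param default radius assigned to elements not in the table (Angstrom).
#' @return named numeric vector of radii with attribute \code{default}.
#' @export
default_radii <- function(default = 1.80) {
  r <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00)
  attr(r, "default") <- default
  r
}

radius_for_element <- function(elem, radii_table) {
  def <- attr(radii_table, "default")
  if (is.null(def)) def <- 1.80
  out <- unname(radii_table[elem])
  out[is.na(out)] <- def
  out
}

#' Construct a structure object
#'
#' A structure is an ordered atom table plus free-form metadata; it is the
#' unit every geometric operation in the package works on.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{elem}, \code{resname}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z}, \code{vdw}.
#' @param metadata named list of free-form metadata.
#' @return object of class \code{md_structure}.
#' @export
md_structure <- function(atoms, metadata = list()) {
  req <- c("serial", "name", "elem", "resname", "resno", "chain",
           "x", "y", "z", "vdw")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$elem == "")) stop("empty element symbol")
  if (any(atoms$vdw <= 0)) stop("non-positive vdW radius")
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) triple: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("md_structure: %d atoms, %d chains (%s), residues %d-%d\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              min(a$resno), max(a$resno)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an \code{md_structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure an \code{md_structure}.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure an \code{md_structure}.
#' @param xyz numeric n x 3 matrix.
#' @return the structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Subset a structure by atom indices
#' @param structure an \code{md_structure}.
#' @param indices integer atom indices (1-based, in atom order).
#' @return an \code{md_structure} containing only the selected atoms.
#' @export
subset_structure <- function(structure, indices) {
  md_structure(structure$atoms[indices, , drop = FALSE], structure$metadata)
}

# ---------------------------------------------------------------------------
# PDB reading / writing

# Fixed-column PDB fields (1-based, inclusive)
.pdb_parse_atom_line <- function(line, lineno) {
  get <- function(a, b) substr(line, a, b)
  xs <- get(31, 38); ys <- get(39, 46); zs <- get(47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  if (any(is.na(c(x, y, z))))
    stop(sprintf("malformed coordinate field on line %d: '%s'", lineno, line))
  icode <- trimws(get(27, 27))
  if (icode != "")
    stop(sprintf("insertion codes are not supported (line %d)", lineno))
  list(
    record = trimws(get(1, 6)),
    serial = suppressWarnings(as.integer(trimws(get(7, 11)))),
    name = trimws(get(13, 16)),
    altloc = trimws(get(17, 17)),
    resname = trimws(get(18, 20)),
    chain = get(22, 22),
    resno = suppressWarnings(as.integer(trimws(get(23, 26)))),
    x = x, y = y, z = z,
    elem = trimws(get(77, 78))
  )
}

# Element from atom name when columns 77-78 are blank: strip digits, then
# try the two-character symbol for common metals/ions, else first letter.
.element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9']", "", name))
  two <- c("MG", "ZN", "FE", "MN", "CA", "NA", "CL", "BR", "SE", "CU", "K")
  # Within standard residues a name starting with an element letter (C,N,O,S,
  # H,P) is that element; bare two-letter names are taken as ions/metals.
  first <- substr(nm, 1, 1)
  if (first %in% c("C", "N", "O", "S", "H", "P")) {
    if (nm %in% two) return(nm)
    return(first)
  }
  if (nm %in% two) return(nm)
  if (nchar(nm) >= 1) return(first)
  stop("cannot infer element from atom name '", name, "'")
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Alternate locations other than
#' blank or 'A' are dropped; elements are taken from columns 77-78 with a
#' fallback heuristic on the atom name; van der Waals radii are assigned at
#' load time from \code{radii_table}.
#'
#' @param path path to a PDB file.
#' @param radii_table element-to-radius map (see \code{\link{default_radii}}).
#' @return an \code{md_structure}.
#' @export
read_pdb <- function(path, radii_table = default_radii()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  idx <- which(sel)
  recs <- lapply(idx, function(i) .pdb_parse_atom_line(lines[i], i))
  keep <- vapply(recs, function(r) r$altloc %in% c("", "A"), logical(1))
  recs <- recs[keep]
  if (length(recs) == 0) stop("no atoms remain after altloc filtering in ", path)
  atoms <- data.frame(
    serial  = vapply(recs, `[[`, integer(1), "serial"),
    name    = vapply(recs, `[[`, character(1), "name"),
    elem    = vapply(recs, `[[`, character(1), "elem"),
    resname = vapply(recs, `[[`, character(1), "resname"),
    resno   = vapply(recs, `[[`, integer(1), "resno"),
    chain   = vapply(recs, `[[`, character(1), "chain"),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    z = vapply(recs, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE
  )
  blank <- atoms$elem == ""
  if (any(blank))
    atoms$elem[blank] <- vapply(atoms$name[blank], .element_from_name,
                                character(1))
  atoms$elem <- toupper(atoms$elem)
  atoms$vdw <- radius_for_element(atoms$elem, radii_table)
  md_structure(atoms, metadata = list(source = path))
}

.pdb_atom_lines <- function(atoms) {
  n <- nrow(atoms)
  name4 <- ifelse(nchar(atoms$name) >= 4,
                  substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$serial %% 100000, name4, substr(atoms$resname, 1, 3),
          atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
          substr(atoms$elem, 1, 2))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records with coordinates to three decimals, a TER
#' record between chains and a terminating END.
#'
#' @param structure an \code{md_structure}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  atoms <- structure$atoms
  if (nrow(atoms) < 1) stop("refusing to write empty structure")
  if (any(abs(as.matrix(atoms[, c("x", "y", "z")])) >= 10000))
    stop("coordinate magnitude >= 10000 A does not fit PDB fixed columns")
  lines <- .pdb_atom_lines(atoms)
  # TER between consecutive atoms on different chains, and after the last
  chain_break <- which(atoms$chain[-1] != atoms$chain[-nrow(atoms)])
  out <- character(0)
  prev <- 1
  for (b in c(chain_break, nrow(atoms))) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing a single atom topology,
#' with a fixed frame interval. \code{t0_ns} records the simulated time of
#' the first stored frame (e.g. the end of an equilibration period).
#'
#' @param topology an \code{md_structure} giving atom identities.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param dt_ns frame interval in nanoseconds.
#' @param t0_ns time of the first frame in nanoseconds.
#' @return object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, frames, dt_ns, t0_ns = 0) {
  if (!inherits(topology, "md_structure")) stop("topology must be md_structure")
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(dt_ns) || dt_ns <= 0) stop("dt_ns must be positive")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3)
      stop(sprintf("frame %d atom count (%s) does not match topology (%d)",
                   i, if (is.matrix(f)) nrow(f) else "not a matrix", na))
  }
  structure(list(topology = topology, frames = frames,
                 dt_ns = dt_ns, t0_ns = t0_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, dt = %g ns, t0 = %g ns\n",
              n_frames(x), n_atoms(x$topology), x$dt_ns, x$t0_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an \code{md_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Frame times of a trajectory
#' @param trajectory an \code{md_trajectory}.
#' @return numeric vector of times in ns (t0 + (i-1) * dt).
#' @export
frame_times <- function(trajectory) {
  trajectory$t0_ns + (seq_len(n_frames(trajectory)) - 1) * trajectory$dt_ns
}

#' Extract one frame of a trajectory as a structure
#' @param trajectory an \code{md_trajectory}.
#' @param i frame index (1-based).
#' @return an \code{md_structure}.
#' @export
frame_structure <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) stop("frame index out of range: ", i)
  set_coords(trajectory$topology, trajectory$frames[[i]])
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; the topology is taken from the
#' first model. A file without MODEL records is read as a single frame.
#' Multi-model PDB carries no time information, so the frame interval is
#' supplied by the caller.
#'
#' @param path path to a (multi-model) PDB file.
#' @param dt_ns frame interval in ns.
#' @param t0_ns time of first frame in ns.
#' @param radii_table element-to-radius map.
#' @return an \code{md_trajectory}.
#' @export
read_trajectory <- function(path, dt_ns, t0_ns = 0,
                            radii_table = default_radii()) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    s <- read_pdb(path, radii_table)
    return(md_trajectory(s, list(coords(s)), dt_ns, t0_ns))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  topo <- NULL
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    block <- lines[(model_starts[m] + 1):(model_ends[m] - 1)]
    sel <- grepl("^(ATOM  |HETATM)", block)
    recs <- lapply(which(sel), function(i) .pdb_parse_atom_line(block[i], i))
    keep <- vapply(recs, function(r) r$altloc %in% c("", "A"), logical(1))
    recs <- recs[keep]
    xyz <- t(vapply(recs, function(r) c(r$x, r$y, r$z), numeric(3)))
    if (m == 1) {
      tmp <- tempfile(fileext = ".pdb")
      writeLines(c(block, "END"), tmp)
      topo <- read_pdb(tmp, radii_table)
      unlink(tmp)
      topo$metadata$source <- path
    } else if (nrow(xyz) != n_atoms(topo)) {
      stop(sprintf("model %d has %d atoms but model 1 has %d",
                   m, nrow(xyz), n_atoms(topo)))
    }
    frames[[m]] <- xyz
  }
  md_trajectory(topo, frames, dt_ns, t0_ns)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory an \code{md_trajectory}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- trajectory$topology
  for (i in seq_len(n_frames(trajectory))) {
    s <- set_coords(topo, trajectory$frames[[i]])
    atoms <- s$atoms
    if (any(abs(as.matrix(atoms[, c("x", "y", "z")])) >= 10000))
      stop("coordinate magnitude >= 10000 A does not fit PDB fixed columns")
    writeLines(sprintf("MODEL %8d", i), con)
    lines <- .pdb_atom_lines(atoms)
    chain_break <- which(atoms$chain[-1] != atoms$chain[-nrow(atoms)])
    prev <- 1
    for (b in c(chain_break, nrow(atoms))) {
      writeLines(lines[prev:b], con)
      writeLines("TER", con)
      prev <- b + 1
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selections

#' Declarative atom selection
#'
#' Describes an atom subset by chain, residue ranges (author numbering,
#' 1-based inclusive) and atom class. Atom classes: \code{"all"},
#' \code{"heavy"} (element != H), \code{"backbone"} (N, CA, C, O),
#' \code{"calpha"}, or \code{"named"} with an explicit atom-name list.
#'
#' @param chains character vector of chain identifiers, or \code{"all"}.
#' @param resid list of length-2 integer vectors (inclusive ranges), a single
#'   range, or \code{NULL} for all residues.
#' @param atoms atom class string.
#' @param names explicit atom names when \code{atoms = "named"}.
#' @return object of class \code{md_selection}.
#' @export
atom_selection <- function(chains = "all", resid = NULL, atoms = "all",
                           names = NULL) {
  atoms <- match.arg(atoms, c("all", "heavy", "backbone", "calpha", "named"))
  if (atoms == "named" && (is.null(names) || length(names) == 0))
    stop("atoms = 'named' requires a non-empty names list")
  if (!is.null(resid)) {
    if (is.numeric(resid)) resid <- list(resid)
    for (r in resid) {
      if (length(r) != 2 || r[1] > r[2])
        stop("residue ranges must be [start, end] with start <= end")
    }
  }
  structure(list(chains = chains, resid = resid, atoms = atoms, names = names),
            class = "md_selection")
}

#' Parse a selection string
#'
#' Accepts the configuration syntax
#' \code{"chain=A; resid=408-420,468-475; atoms=backbone"}. Omitted keys
#' default to all chains / all residues / all atoms. A single residue may be
#' given as \code{resid=396}.
#'
#' @param text selection string.
#' @return an \code{md_selection}.
#' @export
parse_selection <- function(text) {
  chains <- "all"; resid <- NULL; atoms <- "all"; nm <- NULL
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    p <- trimws(p)
    if (p == "") next
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse selection clause: '", p, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "chain" || key == "chains") {
      chains <- if (val == "all") "all" else
        trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "resid") {
      if (val != "all") {
        resid <- lapply(strsplit(val, ",", fixed = TRUE)[[1]], function(rr) {
          ab <- as.integer(strsplit(trimws(rr), "-", fixed = TRUE)[[1]])
          if (length(ab) == 1) ab <- c(ab, ab)
          ab
        })
      }
    } else if (key == "atoms") {
      if (val %in% c("all", "heavy", "backbone", "calpha")) {
        atoms <- val
      } else {
        atoms <- "named"
        nm <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      }
    } else stop("unknown selection key: '", key, "'")
  }
  atom_selection(chains, resid, atoms, nm)
}

#' @export
format.md_selection <- function(x, ...) {
  ch <- if (identical(x$chains, "all")) "all" else
    paste(x$chains, collapse = ",")
  rr <- if (is.null(x$resid)) "all" else
    paste(vapply(x$resid, function(r) paste0(r[1], "-", r[2]), ""),
          collapse = ",")
  at <- if (x$atoms == "named") paste(x$names, collapse = ",") else x$atoms
  sprintf("chain=%s; resid=%s; atoms=%s", ch, rr, at)
}

#' @export
print.md_selection <- function(x, ...) {
  cat("md_selection:", format(x), "\n")
  invisible(x)
}

#' Resolve a selection to atom indices
#'
#' Deterministically maps a declarative selection to the ordered list of
#' matching atom indices in a structure. Backbone means atom names
#' N, CA, C, O; heavy means element != H; residue ranges are inclusive on
#' author numbering.
#'
#' @param structure an \code{md_structure}.
#' @param spec an \code{md_selection} (or a selection string).
#' @return integer vector of atom indices in atom order.
#' @export
resolve_selection <- function(structure, spec) {
  if (is.character(spec)) spec <- parse_selection(spec)
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!identical(spec$chains, "all"))
    keep <- keep & a$chain %in% spec$chains
  if (!is.null(spec$resid)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in spec$resid)
      in_range <- in_range | (a$resno >= r[1] & a$resno <= r[2])
    keep <- keep & in_range
  }
  keep <- keep & switch(spec$atoms,
    all = TRUE,
    heavy = a$elem != "H",
    backbone = a$name %in% c("N", "CA", "C", "O"),
    calpha = a$name == "CA",
    named = a$name %in% spec$names
  )
  idx <- which(keep)
  if (length(idx) == 0)
    stop("selection resolves to zero atoms: ", format(spec))
  idx
}
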