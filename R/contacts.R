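# Heavy-atom contact maps across a chain partition, conserved-contact and
# persistence statistics, and named atom-pair distance monitors.

# integer cell key for grid-accelerated neighbour search
.cell_key <- function(ix, iy, iz) paste(ix, iy, iz, sep = ",")

.contact_pairs_brute <- function(xa, xb, cutoff) {
  # logical n_a x n_b matrix of atom pairs within cutoff
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2 <= cutoff^2 + 1e-12
}

#' Residue contact map across a chain partition
#'
#' A residue pair (one residue per side) is in contact when any heavy-atom
#' pair across the partition lies within \code{cutoff}. The default method
#' uses a cell-list spatial grid and returns results identical to the
#' brute-force all-pairs enumeration (\code{method = "brute"}, kept as an
#' independent route for verification). With \code{level = "atom"} the map
#' lists atom pairs instead.
#'
#' @param structure an \code{md_structure}.
#' @param chains_A,chains_B disjoint, non-empty chain-id sets. Alternatively
#'   \code{md_selection} objects, so that two domains of one chain can be
#'   treated as pseudo-chains.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @param level \code{"residue"} (default) or \code{"atom"}.
#' @param method \code{"grid"} (default) or \code{"brute"}.
#' @return data.frame of class \code{contact_map}: columns \code{chain_a},
#'   \code{res_a}, \code{chain_b}, \code{res_b} (plus \code{name_a},
#'   \code{name_b} at atom level), sorted, no duplicates; \code{cutoff} as
#'   attribute.
#' @export
contact_map <- function(structure, chains_A, chains_B, cutoff = 5.0,
                        level = c("residue", "atom"),
                        method = c("grid", "brute")) {
  level <- match.arg(level); method <- match.arg(method)
  a <- structure$atoms
  side_idx <- function(side) {
    if (inherits(side, "md_selection")) {
      intersect(resolve_selection(structure, side), which(a$elem != "H"))
    } else {
      which(a$elem != "H" & a$chain %in% side)
    }
  }
  ia <- side_idx(chains_A)
  ib <- side_idx(chains_B)
  if (!length(ia) || !length(ib)) stop("empty chain set in contact_map")
  if (length(intersect(ia, ib)) > 0) stop("chain sets overlap")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (method == "brute") {
    hit <- which(.contact_pairs_brute(xyz[ia, , drop = FALSE],
                                      xyz[ib, , drop = FALSE], cutoff),
                 arr.ind = TRUE)
    pa <- ia[hit[, 1]]; pb <- ib[hit[, 2]]
  } else {
    # cell list over B atoms with cell edge = cutoff; A atoms probe the
    # 27 surrounding cells
    cb <- floor(xyz[ib, , drop = FALSE] / cutoff)
    bmap <- split(ib, .cell_key(cb[, 1], cb[, 2], cb[, 3]))
    pa <- integer(0); pb <- integer(0)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (k in seq_along(ia)) {
      i <- ia[k]
      ci <- floor(xyz[i, ] / cutoff)
      keys <- .cell_key(ci[1] + off[, 1], ci[2] + off[, 2], ci[3] + off[, 3])
      cand <- unlist(bmap[keys], use.names = FALSE)
      if (is.null(cand) || length(cand) == 0) next
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      close <- cand[d2 <= cutoff^2 + 1e-12]
      if (length(close)) {
        pa <- c(pa, rep(i, length(close)))
        pb <- c(pb, close)
      }
    }
  }
  if (level == "residue") {
    df <- unique(data.frame(
      chain_a = a$chain[pa], res_a = a$resno[pa],
      chain_b = a$chain[pb], res_b = a$resno[pb],
      stringsAsFactors = FALSE))
  } else {
    df <- unique(data.frame(
      chain_a = a$chain[pa], res_a = a$resno[pa], name_a = a$name[pa],
      chain_b = a$chain[pb], res_b = a$resno[pb], name_b = a$name[pb],
      stringsAsFactors = FALSE))
  }
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cutoff") <- cutoff
  class(df) <- c("contact_map", "data.frame")
  df
}

.pair_keys <- function(cm) {
  if (nrow(cm) == 0) return(character(0))
  paste(cm$chain_a, cm$res_a, cm$chain_b, cm$res_b, sep = "|")
}

#' Conserved-contact fraction along a trajectory
#'
#' For every frame, the fraction of the reference frame's interface residue
#' pairs still present, and the total number of interface pairs — a compact
#' summary of interface remodelling (conserved fraction falling while total
#' contacts grow signals a rearranged, not dissolved, interface).
#'
#' @param trajectory an \code{md_trajectory}.
#' @param chains_A,chains_B chain sets (as in \code{\link{contact_map}}).
#' @param cutoff heavy-atom cutoff in Angstrom (default 5).
#' @param reference_frame index of the reference frame (default 1, the
#'   first production frame).
#' @return data.frame (time_ns, frame, conserved_fraction, total_contacts).
#' @export
conserved_contact_series <- function(trajectory, chains_A, chains_B,
                                     cutoff = 5.0, reference_frame = 1) {
  nf <- n_frames(trajectory)
  if (reference_frame < 1 || reference_frame > nf)
    stop("reference frame out of range")
  maps <- lapply(seq_len(nf), function(i)
    .pair_keys(contact_map(frame_structure(trajectory, i),
                           chains_A, chains_B, cutoff)))
  ref <- maps[[reference_frame]]
  if (length(ref) == 0)
    stop("reference frame has no interface contacts")
  data.frame(
    time_ns = frame_times(trajectory),
    frame = seq_len(nf),
    conserved_fraction = vapply(maps, function(k)
      length(intersect(k, ref)) / length(ref), numeric(1)),
    total_contacts = lengths(maps)
  )
}

#' Contact persistence table and persistent residues
#'
#' Fraction of frames in which each interface residue pair is present, the
#' per-residue marginal (fraction of frames the residue participates in at
#' least one interface pair), and the residues whose marginal exceeds
#' \code{threshold} strictly.
#'
#' @param trajectory an \code{md_trajectory}.
#' @param chains_A,chains_B chain sets (as in \code{\link{contact_map}}).
#' @param cutoff heavy-atom cutoff in Angstrom (default 5).
#' @param threshold persistence threshold, strict (default 0.8).
#' @return list of class \code{persistence_table}: \code{pairs} (chain_a,
#'   res_a, chain_b, res_b, fraction), \code{residues} (chain, resno, side,
#'   fraction), \code{persistent} (rows of \code{residues} with fraction >
#'   threshold), \code{threshold}.
#' @export
persistence_table <- function(trajectory, chains_A, chains_B, cutoff = 5.0,
                              threshold = 0.8) {
  nf <- n_frames(trajectory)
  maps <- lapply(seq_len(nf), function(i)
    contact_map(frame_structure(trajectory, i), chains_A, chains_B, cutoff))
  keys <- lapply(maps, .pair_keys)
  all_keys <- sort(unique(unlist(keys)))
  pair_frac <- vapply(all_keys, function(k)
    sum(vapply(keys, function(v) k %in% v, logical(1))) / nf, numeric(1))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  pairs <- data.frame(
    chain_a = vapply(parts, `[`, "", 1),
    res_a = as.integer(vapply(parts, `[`, "", 2)),
    chain_b = vapply(parts, `[`, "", 3),
    res_b = as.integer(vapply(parts, `[`, "", 4)),
    fraction = unname(pair_frac)
  )
  res_keys_frame <- lapply(maps, function(cm) {
    if (nrow(cm) == 0) return(character(0))
    unique(c(paste("A", cm$chain_a, cm$res_a, sep = "|"),
             paste("B", cm$chain_b, cm$res_b, sep = "|")))
  })
  all_res <- sort(unique(unlist(res_keys_frame)))
  res_frac <- vapply(all_res, function(k)
    sum(vapply(res_keys_frame, function(v) k %in% v, logical(1))) / nf,
    numeric(1))
  rp <- strsplit(all_res, "|", fixed = TRUE)
  residues <- data.frame(
    side = vapply(rp, `[`, "", 1),
    chain = vapply(rp, `[`, "", 2),
    resno = as.integer(vapply(rp, `[`, "", 3)),
    fraction = unname(res_frac)
  )
  structure(list(pairs = pairs, residues = residues,
                 persistent = residues[residues$fraction > threshold, ,
                                       drop = FALSE],
                 threshold = threshold),
            class = "persistence_table")
}

#' @export
print.persistence_table <- function(x, ...) {
  cat(sprintf("persistence_table: %d pairs, %d residues, %d persistent (> %.0f%%)\n",
              nrow(x$pairs), nrow(x$residues), nrow(x$persistent),
              100 * x$threshold))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Distance monitors

#' Define a distance monitor between two named atoms
#'
#' @param label monitor name.
#' @param a,b atom specs: either a list(chain, resno, name) or the string
#'   form \code{"A:LYS:1065:NZ"} (chain:resname:resno:atom; resname is
#'   checked when given, \code{*} skips the check).
#' @return list of class \code{distance_monitor_spec}.
#' @export
distance_monitor <- function(label, a, b) {
  parse_atom <- function(s) {
    if (is.list(s)) return(s)
    p <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(p) != 4) stop("bad atom spec '", s,
                             "': expected chain:resname:resno:atom")
    list(chain = p[1], resname = p[2], resno = as.integer(p[3]), name = p[4])
  }
  structure(list(label = label, a = parse_atom(a), b = parse_atom(b)),
            class = "distance_monitor_spec")
}

#' Parse a monitor definition string
#'
#' Accepts the config syntax \code{"label: A:LYS:1065:NZ -- B:ATP:1:O2G"}.
#'
#' @param text monitor string.
#' @return a \code{distance_monitor_spec}.
#' @export
parse_monitor <- function(text) {
  m <- regmatches(text, regexec("^\\s*([^:]+):\\s*(\\S+)\\s*--\\s*(\\S+)\\s*$",
                                text))[[1]]
  if (length(m) != 4) stop("cannot parse monitor: '", text, "'")
  distance_monitor(trimws(m[2]), m[3], m[4])
}

.resolve_monitor_atom <- function(structure, spec, label) {
  a <- structure$atoms
  keep <- a$chain == spec$chain & a$resno == spec$resno & a$name == spec$name
  if (!is.null(spec$resname) && spec$resname != "*")
    keep <- keep & a$resname == spec$resname
  idx <- which(keep)
  if (length(idx) == 0)
    stop(sprintf("monitor '%s': atom %s:%s:%s:%s not found", label,
                 spec$chain, if (is.null(spec$resname)) "*" else spec$resname,
                 spec$resno, spec$name))
  if (length(idx) > 1)
    stop(sprintf("monitor '%s': atom spec matches %d atoms", label,
                 length(idx)))
  idx
}

#' Evaluate distance monitors along a trajectory
#'
#' @param trajectory an \code{md_trajectory}.
#' @param monitors list of \code{distance_monitor_spec} (or monitor strings).
#' @return data.frame: time_ns plus one column per monitor label (Angstrom).
#' @export
distance_series <- function(trajectory, monitors) {
  if (inherits(monitors, "distance_monitor_spec")) monitors <- list(monitors)
  monitors <- lapply(monitors, function(m)
    if (is.character(m)) parse_monitor(m) else m)
  topo <- trajectory$topology
  out <- data.frame(time_ns = frame_times(trajectory))
  for (m in monitors) {
    ia <- .resolve_monitor_atom(topo, m$a, m$label)
    ib <- .resolve_monitor_atom(topo, m$b, m$label)
    out[[m$label]] <- vapply(trajectory$frames, function(f)
      sqrt(sum((f[ia, ] - f[ib, ])^2)), numeric(1))
  }
  out
}
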