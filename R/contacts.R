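## Aromatic-contact statistics and aromatic density maps over multi-frame
## fiber structures.  Contact criterion: at least one carbon-carbon pair at
## 5 Angstrom or less, regardless of ring orientation.

#' Read a (multi-MODEL) PDB file into a fiber trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame (a single-structure file
#' counts as one frame).  Parsing is delegated to [bio3d::read.pdb()];
#' the atom roster must be identical across frames.
#'
#' @param pdb path to a PDB file, or the PDB text itself (a character
#'   vector of lines, or a single string containing newlines).
#' @return A `fiber_trajectory` (see [gen_fiber()] for the structure).
#' @export
read_trajectory <- function(pdb) {
  if (length(pdb) > 1L || grepl("\n", pdb[1], fixed = TRUE)) {
    lines <- if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1]]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(lines, path)
  } else {
    path <- pdb
    lines <- readLines(path)
  }
  ## roster consistency check with a frame-naming error message
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) == length(starts)) {
      counts <- mapply(function(s, e) sum(grepl("^(ATOM|HETATM)",
                                                lines[s:e])), starts, ends)
      if (length(unique(counts)) > 1L) {
        bad <- which(counts != counts[1])[1]
        stop(sprintf(
          "inconsistent atom roster: frame %d has %d atoms, frame 1 has %d",
          bad, counts[bad], counts[1]))
      }
    }
  }
  pdbobj <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdbobj$atom
  element <- trimws(a$elesy)
  element[!nzchar(element) | is.na(element)] <-
    substr(trimws(a$elety[!nzchar(element) | is.na(element)]), 1, 1)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                      name = a$elety, element = element,
                      stringsAsFactors = FALSE)
  xyz <- pdbobj$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz); n_atoms <- nrow(atoms)
  coords <- array(0, dim = c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  structure(list(atoms = atoms, coords = coords, meta = list(source = "pdb")),
            class = "fiber_trajectory")
}

#' Select aromatic residues from a trajectory
#'
#' @param traj a `fiber_trajectory`.
#' @param residue_set residue names counted as aromatic (default
#'   tyrosine + phenylalanine; add `"TRP"`, `"HIS"` to widen).
#' @return Data frame with one row per selected residue: `chain`, `resno`,
#'   `resname`.
#' @export
select_aromatics <- function(traj, residue_set = c("TYR", "PHE")) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  a <- traj$atoms
  keep <- a$resname %in% residue_set
  u <- unique(a[keep, c("chain", "resno", "resname")])
  rownames(u) <- NULL
  u
}

## indices of carbon atoms of one residue
carbon_indices <- function(traj, chain, resno, ring_only = FALSE) {
  a <- traj$atoms
  idx <- which(a$chain == chain & a$resno == resno & a$element == "C")
  if (ring_only)
    idx <- idx[trimws(a$name[idx]) %in%
                 c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CH2",
                   "CD2", "CE3", "CZ2", "CZ3")]
  idx
}

min_pair_dist <- function(A, B) {
  ## A: m x 3, B: n x 3 -> minimum Euclidean distance between the sets
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Minimum carbon-carbon distance between two residues in one frame
#'
#' @param traj a `fiber_trajectory`.
#' @param resA,resB lists or one-row data frames with `chain` and `resno`.
#' @param frame frame index.
#' @param ring_only restrict to side-chain ring carbons instead of all
#'   carbon atoms.
#' @return minimum distance over all carbon pairs, Angstrom.
#' @export
min_carbon_distance <- function(traj, resA, resB, frame = 1L,
                                ring_only = FALSE) {
  ia <- carbon_indices(traj, resA$chain, resA$resno, ring_only)
  ib <- carbon_indices(traj, resB$chain, resB$resno, ring_only)
  if (!length(ia) || !length(ib))
    stop("residue without carbon atoms in this selection")
  xyz <- traj$coords[, , frame]
  min_pair_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
}

#' Census of aromatic contacts over a trajectory
#'
#' For every unordered pair of selected aromatic residues and every frame,
#' records the minimum carbon-carbon distance and whether it satisfies the
#' contact criterion (`<= cutoff`, inclusive).  Contacts are labeled
#' intramolecular (same chain/subunit) or intermolecular.  Per-subunit
#' statistics follow the convention that an intermolecular contact
#' increments both participating subunits' counts while an intramolecular
#' contact increments its subunit once; this convention is recorded in the
#' output.
#'
#' @param traj a `fiber_trajectory`.
#' @param cutoff contact cutoff, Angstrom (inclusive; default 5).
#' @param residue_set aromatic residue names (see [select_aromatics()]).
#' @param ring_only restrict the criterion to side-chain ring carbons.
#' @return An object of class `contact_census`: list with `records` (data
#'   frame: frame, chainA, resnoA, resnameA, chainB, resnoB, resnameB,
#'   min_cc_A, contact, scope), `stats` (per-subunit mean contacts per
#'   frame, overall mean contacts per subunit, per-pair occupancy,
#'   distance-distribution summary) and `params`.
#' @export
contact_census <- function(traj, cutoff = 5.0,
                           residue_set = c("TYR", "PHE"),
                           ring_only = FALSE) {
  stopifnot(inherits(traj, "fiber_trajectory"), cutoff > 0)
  aromatics <- select_aromatics(traj, residue_set)
  if (!nrow(aromatics)) stop("no aromatic residues selected")
  n_frames <- dim(traj$coords)[3]
  n_res <- nrow(aromatics)
  cidx <- lapply(seq_len(n_res), function(k)
    carbon_indices(traj, aromatics$chain[k], aromatics$resno[k], ring_only))
  if (any(!lengths(cidx)))
    stop("selected residue without carbon atoms")

  pairs <- which(upper.tri(matrix(0, n_res, n_res)), arr.ind = TRUE)
  recs <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[, , f]
    md <- vapply(seq_len(nrow(pairs)), function(p) {
      min_pair_dist(xyz[cidx[[pairs[p, 1]]], , drop = FALSE],
                    xyz[cidx[[pairs[p, 2]]], , drop = FALSE])
    }, numeric(1))
    i <- pairs[, 1]; j <- pairs[, 2]
    recs[[f]] <- data.frame(
      frame = f,
      chainA = aromatics$chain[i], resnoA = aromatics$resno[i],
      resnameA = aromatics$resname[i],
      chainB = aromatics$chain[j], resnoB = aromatics$resno[j],
      resnameB = aromatics$resname[j],
      min_cc_A = md, contact = md <= cutoff,
      scope = ifelse(aromatics$chain[i] == aromatics$chain[j],
                     "intramolecular", "intermolecular"),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)

  pair_id <- paste(records$chainA, records$resnoA, "-",
                   records$chainB, records$resnoB)
  occupancy <- stats::aggregate(contact ~ pair_id, data =
                                  cbind(records, pair_id = pair_id), FUN = mean)
  names(occupancy) <- c("pair", "occupancy")

  subunits <- sort(unique(traj$atoms$chain))
  per_subunit <- vapply(subunits, function(s) {
    hits <- records$contact & (records$chainA == s | records$chainB == s)
    sum(hits) / n_frames
  }, numeric(1))
  names(per_subunit) <- subunits

  stats <- list(per_subunit_mean_contacts = per_subunit,
                mean_contacts_per_subunit = mean(per_subunit),
                occupancy = occupancy,
                distance_summary = summary(records$min_cc_A))
  structure(list(records = records, stats = stats,
                 params = list(cutoff = cutoff, residue_set = residue_set,
                               ring_only = ring_only,
                               attribution = paste(
                                 "intermolecular contacts credit both",
                                 "subunits; intramolecular credit one"))),
            class = "contact_census")
}

#' @export
print.contact_census <- function(x, ...) {
  cat(sprintf(
    "Aromatic contact census (cutoff %.2f A, %s carbons):\n",
    x$params$cutoff, if (x$params$ring_only) "ring" else "all"))
  cat(sprintf("  %d residue pairs x %d frame(s); %d contacts\n",
              length(unique(paste(x$records$chainA, x$records$resnoA,
                                  x$records$chainB, x$records$resnoB))),
              max(x$records$frame), sum(x$records$contact)))
  cat(sprintf("  mean contacts per subunit per frame: %.3f\n",
              x$stats$mean_contacts_per_subunit))
  invisible(x)
}

#' @export
summary.contact_census <- function(object, ...) {
  object$stats
}

#' Aromatic density map on a regular 3-D grid
#'
#' Counts the atoms of the selected aromatic residues per voxel and
#' averages over frames.  The grid covers the bounding box of the selected
#' atoms in the first frame, padded by 2 Angstrom; atoms falling outside in
#' later frames are dropped and counted in `dropped`.
#'
#' @inheritParams contact_census
#' @param spacing voxel edge, Angstrom (> 0).
#' @return An object of class `density_map`: list with `grid`
#'   (3-D array of mean per-frame counts), `origin`, `spacing`, `dims`,
#'   `n_frames`, `dropped`.
#' @export
density_map <- function(traj, residue_set = c("TYR", "PHE"), spacing = 1.0) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  if (spacing <= 0) stop("spacing must be positive")
  aromatics <- select_aromatics(traj, residue_set)
  if (!nrow(aromatics)) stop("no aromatic residues selected")
  a <- traj$atoms
  key <- paste(a$chain, a$resno)
  sel <- key %in% paste(aromatics$chain, aromatics$resno)
  idx <- which(sel)
  n_frames <- dim(traj$coords)[3]
  first <- traj$coords[idx, , 1, drop = FALSE][, , 1]
  if (is.null(dim(first))) first <- matrix(first, ncol = 3)
  lo <- apply(first, 2, min) - 2
  hi <- apply(first, 2, max) + 2
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  grid <- array(0, dim = dims)
  dropped <- 0L
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[idx, , f, drop = FALSE][, , 1]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    vox <- floor(sweep(xyz, 2, lo) / spacing) + 1L
    inb <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
           vox[, 2] >= 1 & vox[, 2] <= dims[2] &
           vox[, 3] >= 1 & vox[, 3] <= dims[3]
    dropped <- dropped + sum(!inb)
    v <- vox[inb, , drop = FALSE]
    for (k in seq_len(nrow(v)))
      grid[v[k, 1], v[k, 2], v[k, 3]] <- grid[v[k, 1], v[k, 2], v[k, 3]] + 1
  }
  if (dropped > 0L)
    warning(sprintf("%d atom placements fell outside the grid and were dropped",
                    dropped))
  structure(list(grid = grid / n_frames, origin = lo, spacing = spacing,
                 dims = dims, n_frames = n_frames, dropped = dropped),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "aromatic density map: %d x %d x %d voxels (%.2f A), %d frame(s), mass %.3g\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_frames, sum(x$grid)))
  invisible(x)
}

#' Extract planar slices from a density map
#'
#' A fractional offset selects the grid plane at that fraction of the
#' bounding box along the axis normal to the requested plane (`xz` slices
#' are taken along y, and so on).
#'
#' @param map a `density_map`.
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @param offsets fractional offsets in (0, 1].
#' @return Named list of 2-D matrices, one per offset.
#' @export
slice_density <- function(map, plane = c("xz", "xy", "yz"),
                          offsets = c(0.30, 0.50, 0.70)) {
  stopifnot(inherits(map, "density_map"))
  plane <- match.arg(plane)
  axis <- switch(plane, xz = 2L, xy = 3L, yz = 1L)
  stopifnot(all(offsets > 0), all(offsets <= 1))
  out <- lapply(offsets, function(o) {
    k <- min(map$dims[axis], max(1L, as.integer(ceiling(o * map$dims[axis]))))
    switch(plane,
           xz = map$grid[, k, ],
           xy = map$grid[, , k],
           yz = map$grid[k, , ])
  })
  names(out) <- sprintf("%s_offset_%.2f", plane, offsets)
  out
}
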