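test_that("PDB round-trip: single- and multi-MODEL files parse with a consistent roster", {
  fib <- stacked_fiber(n_subunits = 3, n_frames = 1)
  tr1 <- read_trajectory(paste(fiber_pdb_text(fib), collapse = "\n"))
  expect_equal(dim(tr1$coords)[3], 1)

  fib5 <- gen_fiber(n_frames = 5, jitter_sd = 0.1, seed = 2)
  p <- tempfile(fileext = ".pdb")
  write_fiber_pdb(fib5, p)
  tr5 <- read_trajectory(p)
  expect_equal(dim(tr5$coords)[3], 5)
  expect_identical(tr5$atoms$resname, fib5$atoms$resname)

  # mismatched rosters across MODELs error with the frame named
  txt <- fiber_pdb_text(fib5)
  atom_lines <- grep("^ATOM", txt)
  bad <- txt[-atom_lines[length(atom_lines)]]   # drop an atom of frame 5
  expect_error(read_trajectory(bad), "frame 5")
})

test_that("aromatic selection counts residues and honours the residue set", {
  fib <- gen_fiber(n_subunits = 3,
                   aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                TYR = c(5, 0, 2),
                                                TYR = c(-5, 0, 4),
                                                PHE = c(0, 5, 1),
                                                PHE = c(0, -5, 3)))
  sel <- select_aromatics(fib)
  expect_equal(nrow(sel), 15)           # (3 TYR + 2 PHE) x 3 subunits
  expect_equal(nrow(select_aromatics(fib, "TYR")), 9)
  # an alanine substitution drops out of the default selection
  mut <- gen_fiber(n_subunits = 3,
                   aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                PHE = c(5, 0, 2)),
                   remove_ring_at = 1)
  expect_equal(unique(select_aromatics(mut)$resname), "PHE")
})

test_that("minimum carbon distance matches a brute-force oracle and is symmetric", {
  fib <- gen_fiber(n_subunits = 4, rise = 6, twist = 45, jitter_sd = 0.3,
                   seed = 13, n_frames = 2)
  res <- select_aromatics(fib)
  a <- res[1, ]; b <- res[4, ]
  for (f in 1:2) {
    ia <- which(fib$atoms$chain == a$chain & fib$atoms$resno == a$resno)
    ib <- which(fib$atoms$chain == b$chain & fib$atoms$resno == b$resno)
    oracle <- brute_min_dist(fib$coords[ia, , f], fib$coords[ib, , f])
    expect_equal(min_carbon_distance(fib, a, b, frame = f), oracle)
    expect_equal(min_carbon_distance(fib, b, a, frame = f),
                 min_carbon_distance(fib, a, b, frame = f))
  }
})

test_that("the 5 A criterion is inclusive and exact on planted separations", {
  # stacked rings exactly 5.00 A apart: contact (<= 5 is inclusive)
  at5 <- stacked_fiber(n_subunits = 2, rise = 5.0)
  cen5 <- contact_census(at5)
  expect_equal(cen5$records$min_cc_A, 5.0, tolerance = 1e-9)
  expect_true(all(cen5$records$contact))
  # 4.5 A planted pair
  at45 <- stacked_fiber(n_subunits = 2, rise = 4.5)
  expect_equal(contact_census(at45)$records$min_cc_A, 4.5, tolerance = 1e-6)
  # just beyond the cutoff: no contact
  at51 <- stacked_fiber(n_subunits = 2, rise = 5.01)
  expect_false(any(contact_census(at51)$records$contact))
})

test_that("contact census matches the brute-force double loop on every frame", {
  fib <- gen_fiber(n_subunits = 4, rise = 5, twist = 30,
                   aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                PHE = c(4, 0, 2.5)),
                   jitter_sd = 0.4, n_frames = 3, seed = 21)
  cen <- contact_census(fib)
  for (f in 1:3) {
    expect_equal(sum(cen$records$contact[cen$records$frame == f]),
                 brute_contact_count(fib, frame = f))
  }
})

test_that("per-subunit attribution gives WT-like ~2 vs ring-removed ~1 contacts", {
  # each interior subunit touches both neighbours -> ~2 contacts/subunit;
  # removing one of the two rings halves the contact opportunities
  wt <- stacked_fiber(n_subunits = 8, rise = 4.5, two_residues = TRUE)
  cw <- contact_census(wt)
  expect_gte(cw$stats$mean_contacts_per_subunit, 1.5)
  mut <- stacked_fiber(n_subunits = 8, rise = 4.5, two_residues = TRUE,
                       remove_ring_at = 2)
  cm <- contact_census(mut)
  expect_lte(cm$stats$mean_contacts_per_subunit,
             cw$stats$mean_contacts_per_subunit / 1.5)
  # intramolecular contacts increment one subunit; intermolecular, both
  inter <- cw$records[cw$records$scope == "intermolecular" &
                        cw$records$contact & cw$records$frame == 1, ]
  counted <- table(c(inter$chainA, inter$chainB))
  intra <- cw$records[cw$records$scope == "intramolecular" &
                        cw$records$contact & cw$records$frame == 1, ]
  if (nrow(intra)) {
    ti <- table(intra$chainA)
    for (s in names(ti))
      counted[s] <- (if (s %in% names(counted)) counted[s] else 0) + ti[[s]]
  }
  for (s in names(counted))
    expect_equal(unname(cw$stats$per_subunit_mean_contacts[s]),
                 unname(counted[s]))
})

test_that("occupancy is the fraction of frames in contact", {
  # alternate a pair across 4.9 / 5.1 A over frames -> occupancy 0.5
  f1 <- stacked_fiber(n_subunits = 2, rise = 4.9)
  f2 <- stacked_fiber(n_subunits = 2, rise = 5.1)
  traj <- f1
  traj$coords <- array(c(f1$coords, f2$coords), dim = c(nrow(f1$atoms), 3, 2))
  cen <- contact_census(traj)
  expect_equal(cen$stats$occupancy$occupancy, 0.5)
  expect_true(all(cen$stats$occupancy$occupancy >= 0 &
                    cen$stats$occupancy$occupancy <= 1))
  # no pair within cutoff: zero contacts, all occupancies 0
  far <- stacked_fiber(n_subunits = 3, rise = 12)
  cf <- contact_census(far)
  expect_equal(sum(cf$records$contact), 0)
  expect_true(all(cf$stats$occupancy$occupancy == 0))
})

test_that("census is invariant under rigid rotation + translation", {
  fib <- gen_fiber(n_subunits = 4, rise = 5, twist = 30,
                   aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                PHE = c(4, 0, 2.5)),
                   jitter_sd = 0.3, n_frames = 2, seed = 6)
  cen <- contact_census(fib)
  cen_rt <- contact_census(rigid_transform(fib))
  expect_equal(cen_rt$records$min_cc_A, cen$records$min_cc_A,
               tolerance = 1e-9)
  expect_identical(cen_rt$records$contact, cen$records$contact)
})

test_that("deleting ring carbons never increases any pairwise contact count", {
  for (seed in 1:5) {
    wt <- gen_fiber(n_subunits = 5, rise = 4.8, twist = 20,
                    aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                 PHE = c(3, 0, 2.4)),
                    jitter_sd = 0.5, n_frames = 2, seed = seed)
    mut <- gen_fiber(n_subunits = 5, rise = 4.8, twist = 20,
                     aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                  PHE = c(3, 0, 2.4)),
                     remove_ring_at = 1, jitter_sd = 0.5, n_frames = 2,
                     seed = seed)
    cw <- contact_census(wt); cm <- contact_census(mut)
    expect_lte(sum(cm$records$contact), sum(cw$records$contact))
    expect_true(all(cm$stats$per_subunit_mean_contacts <=
                      cw$stats$per_subunit_mean_contacts + 1e-12))
  }
})

test_that("density map conserves mass and slices select the right planes", {
  # single static atom: all mass in one voxel
  one <- gen_fiber(n_subunits = 2, rise = 8, twist = 0,
                   aromatics_per_subunit = list(TYR = c(0, 0, 0)))
  # reduce to a single-atom trajectory by slicing the first atom
  single <- list(atoms = one$atoms[1, , drop = FALSE],
                 coords = one$coords[1, , , drop = FALSE],
                 meta = list())
  class(single) <- "fiber_trajectory"
  m1 <- density_map(single)
  expect_equal(sum(m1$grid), 1)
  expect_equal(max(m1$grid), 1)

  # atom alternating between two voxels over 2 frames -> 0.5 each
  alt <- single
  alt$coords <- array(c(0, 0, 0, 1.5, 0, 0), dim = c(1, 3, 2))
  m2 <- density_map(alt)
  expect_equal(sort(m2$grid[m2$grid > 0]), c(0.5, 0.5))

  # conservation under jitter: mass x frames = placements in bounds
  fib <- gen_fiber(n_subunits = 3, jitter_sd = 0.4, n_frames = 4, seed = 9)
  m <- suppressWarnings(density_map(fib))
  n_aromatic_atoms <- sum(fib$atoms$resname %in% c("TYR", "PHE"))
  expect_equal(sum(m$grid) * m$n_frames + m$dropped, n_aromatic_atoms * 4)

  sl <- slice_density(m, "xz", c(0.30, 0.50, 0.70))
  expect_length(sl, 3)
  expect_equal(dim(sl[[1]]), m$dims[c(1, 3)])
  expect_error(density_map(fib, spacing = 0), "spacing")
})
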