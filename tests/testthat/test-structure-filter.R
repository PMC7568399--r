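# Coordinates in all fixtures are constructed by hand so every distance is
# known in closed form.

toy_triple <- function() {
  # GLY(1) CA at origin; ALA(2) CA at (3,4,0); SER(3) far away with OG
  data.frame(
    resno = c(1, 2, 2, 3, 3, 3),
    resid = c("GLY", "ALA", "ALA", "SER", "SER", "SER"),
    elety = c("CA", "CA", "CB", "N", "CA", "OG"),
    x = c(0, 3, 3.5, 20, 21, 22), y = c(0, 4, 4, 20, 20, 20),
    z = c(0, 0, 1, 0, 0, 0),
    elem = c("C", "C", "C", "N", "C", "O"), stringsAsFactors = FALSE)
}

test_that("structures load with a validated query mapping", {
  path <- write_toy_pdb(toy_triple())
  m <- load_structure(path, query = "GAS")
  expect_s3_class(m, "structure_model")
  expect_equal(sort(unique(m$atoms$resno)), 1:3)
  # offset-by-one numbering is caught at the first mismatching position
  expect_error(load_structure(path, query = "GAS", offset = 1),
               regexp = "position 1", class = "mapping_error")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  at <- toy_triple()
  at$alt <- ""; at$occ <- 1
  alt_a <- at[2, ]; alt_a$alt <- "A"; alt_a$occ <- 0.7
  alt_b <- at[2, ]; alt_b$alt <- "B"; alt_b$occ <- 0.3; alt_b$x <- 9
  at2 <- rbind(at[1, ], alt_a, alt_b, at[3:6, ])
  m <- load_structure(write_toy_pdb(at2))
  ca2 <- m$atoms[m$atoms$resno == 2 & m$atoms$elety == "CA", ]
  expect_equal(nrow(ca2), 1L)
  expect_equal(ca2$x, 3)   # the hand-pruned (occupancy 0.7) conformer
})

test_that("hydrogens are dropped on load", {
  at <- rbind(toy_triple(),
              data.frame(resno = 2, resid = "ALA", elety = "HB1",
                         x = 3.6, y = 4, z = 1.5, elem = "H"))
  m <- load_structure(write_toy_pdb(at))
  expect_false("HB1" %in% m$atoms$elety)
})

test_that("active-site distance is the minimum heavy-atom separation", {
  m <- load_structure(write_toy_pdb(toy_triple()))
  expect_equal(distance_to_active_site(m, 2, active_site = 1), 5)  # 3-4-5
  expect_equal(distance_to_active_site(m, 1, active_site = 1), 0)  # itself
  expect_error(distance_to_active_site(m, 2, active_site = integer(0)),
               class = "config_error")
  # ligand atoms given directly as coordinates
  lig <- data.frame(x = 0, y = 0, z = 12)
  expect_equal(distance_to_active_site(m, 1, lig), 12)
})

test_that("distances are invariant under rigid-body transforms", {
  at <- toy_triple()
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  m1 <- load_structure(write_toy_pdb(at))
  m2 <- m1   # transform the model in memory (beyond PDB coordinate precision)
  xyz <- as.matrix(m1$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -2, 7), "+")
  expect_equal(distance_to_active_site(m2, 2, 1),
               distance_to_active_site(m1, 2, 1), tolerance = 1e-6)
})

salt_bridge_pair <- function(d_nz_od = 3.8) {
  # LYS(1) with NZ at d from ASP(2) OD1; backbones far apart
  data.frame(
    resno = c(1, 1, 1, 1, 1, 2, 2, 2, 2),
    resid = c(rep("LYS", 5), rep("ASP", 4)),
    elety = c("N", "CA", "C", "O", "NZ", "N", "CA", "C", "OD1"),
    x = c(-10, -9, -8, -8, 0, 10 + d_nz_od, 11 + d_nz_od, 12 + d_nz_od, d_nz_od),
    y = c(0, 0, 0, 1, 0, 0, 0, 0, 0),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    elem = c("N", "C", "C", "O", "N", "N", "C", "C", "O"),
    stringsAsFactors = FALSE)
}

test_that("salt bridges and hydrogen bonds are detected by distance", {
  m <- load_structure(write_toy_pdb(salt_bridge_pair(3.8)))
  b <- detect_sidechain_bonds(m, 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "salt_bridge")
  expect_equal(b$distance, 3.8)
  # seen symmetrically from the carboxylate side
  b2 <- detect_sidechain_bonds(m, 2)
  expect_equal(b2$kind, "salt_bridge")

  # beyond 4 A the pair no longer qualifies (too far for an H-bond too)
  m2 <- load_structure(write_toy_pdb(salt_bridge_pair(4.2)))
  expect_equal(nrow(detect_sidechain_bonds(m2, 1)), 0L)

  # Ser OG 3.2 A from a neighbor's backbone O counts as an H-bond
  at <- data.frame(
    resno = c(1, 1, 2, 2),
    resid = c("SER", "SER", "ALA", "ALA"),
    elety = c("CA", "OG", "CA", "O"),
    x = c(-1.5, 0, 4.7, 3.2), y = 0, z = 0,
    elem = c("C", "O", "C", "O"), stringsAsFactors = FALSE)
  hb <- detect_sidechain_bonds(load_structure(write_toy_pdb(at)), 1)
  expect_equal(hb$kind, "hbond")
  expect_equal(hb$distance, 3.2)

  # glycine has no side chain: empty report
  expect_equal(nrow(detect_sidechain_bonds(
    load_structure(write_toy_pdb(toy_triple())), 1)), 0L)

  # isolated residue (no neighbor within 10 A): empty report
  expect_equal(nrow(detect_sidechain_bonds(
    load_structure(write_toy_pdb(toy_triple())), 3)), 0L)
})

test_that("structural filters set status with distance taking precedence", {
  # three CYS-like candidates at controlled distances from an active site,
  # plus a LYS/ASP salt-bridge pair beyond the distance gate
  at <- data.frame(
    resno = c(1, 2, 3, 4, 5, 6),
    resid = c("GLY", "ALA", "ALA", "THR", "LYS", "ASP"),
    elety = c("CA", "CA", "CA", "CA", "NZ", "OD1"),
    x = c(0, 5.9, 6.3, 8.0, 30, 33.8), y = 0, z = 0,
    elem = c("C", "C", "C", "C", "N", "O"), stringsAsFactors = FALSE)
  m <- load_structure(write_toy_pdb(at))
  cand <- data.frame(
    position = c(2, 3, 4, 5),
    query_residue = c("A", "A", "T", "K"),
    consensus_residue = c("V", "C", "C", "E"),
    frequency_pct = c(50, 78.1, 60, 55),
    label = c("A2V", "A3C", "T4C", "K5E"),
    filter_status = "candidate", stringsAsFactors = FALSE)
  out <- apply_structural_filters(cand, m, active_site = 1, min_distance = 6)
  expect_equal(out$filter_status,
               c("rejected_distance", "passed", "passed", "rejected_bonded"))
  expect_equal(out$active_site_distance[1:3], c(5.9, 6.3, 8.0))
  expect_equal(out$label, cand$label)  # order preserved, nothing deleted

  # tightening min_distance never converts rejected -> passed
  out2 <- apply_structural_filters(cand, m, active_site = 1, min_distance = 7)
  was_rejected <- out$filter_status != "passed"
  expect_true(all(out2$filter_status[was_rejected] != "passed"))
})
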