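test_that("PDB round trip preserves coordinates, chains, and altloc rules", {
  cx <- random_complex(seed = 5)
  all_atoms <- dplyr::bind_rows(cx$receptor, cx$ligand)
  at <- read_structure(paste(as_pdb_lines(all_atoms), collapse = "\n"))
  expect_equal(nrow(at), nrow(all_atoms))
  expect_equal(sort(unique(at$chain)), c("A", "B"))
  m <- dplyr::arrange(at, .data$serial)
  expect_equal(m$x, all_atoms$x, tolerance = 1e-3)
  expect_equal(m$resname, all_atoms$resname)
  # chain selection filters, empty selection errors
  expect_equal(unique(read_structure(as_pdb_lines(all_atoms),
                                     chains = "B")$chain), "B")
  expect_error(read_structure(as_pdb_lines(all_atoms), chains = "Z"),
               "chain")
  # a residue represented only by altloc B keeps B
  ab <- atom_row(1:2, c("CA", "CA"), "ALA", "A", 1:2, c(0, 5), 0, 0)
  ab$altloc <- c("B", "")
  at2 <- read_structure(as_pdb_lines(ab))
  expect_equal(nrow(at2), 2)
  # with an A present at the same residue, B is dropped
  ab3 <- atom_row(1:3, c("CA", "CA", "CB"), "ALA", "A", c(1, 1, 2),
                  c(0, 0.5, 5), 0, 0)
  ab3$altloc <- c("A", "B", "")
  expect_equal(nrow(read_structure(as_pdb_lines(ab3))), 2)
})

test_that("grid contact search equals the all-pairs oracle on random fixtures", {
  for (seed in 1:50) {
    cx <- random_complex(n_a = 40, n_b = 35, sep = stats::runif(1, 2, 8),
                         seed = seed)
    g <- find_contacts(cx$receptor, cx$ligand, method = "grid")
    o <- find_contacts(cx$receptor, cx$ligand, method = "all_pairs")
    expect_identical(g, o)
  }
})

test_that("contact cutoff is sharp and classification follows the atom pair", {
  a <- atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0)
  near <- atom_row(2, "CB", "LEU", "B", 1, 3.9, 0, 0)
  far <- atom_row(3, "CB", "LEU", "B", 2, 4.05, 0, 0)
  expect_equal(nrow(find_contacts(a, near)), 1)
  expect_equal(nrow(find_contacts(a, far)), 0)
  cc <- find_contacts(a, near)
  expect_equal(cc$class, "nonpolar")
  expect_equal(cc$min_dist, 3.9, tolerance = 1e-9)
  polar <- atom_row(4, "OG", "SER", "B", 3, 3.0, 0, 0)
  expect_equal(find_contacts(a, polar)$class, "polar")
  expect_error(find_contacts(a, near, cutoff = 0), "cutoff")
})

test_that("interface outputs are invariant under rigid motion", {
  cx <- random_complex(seed = 9)
  both <- list(r = cx$receptor, l = cx$ligand)
  moved <- list(r = rigid_move(cx$receptor), l = rigid_move(cx$ligand))
  c0 <- find_contacts(both$r, both$l)
  c1 <- find_contacts(moved$r, moved$l)
  expect_equal(c0$receptor_res, c1$receptor_res)
  expect_equal(c0$min_dist, c1$min_dist, tolerance = 1e-6)
  s0 <- find_salt_bridges(both$r, both$l)
  s1 <- find_salt_bridges(moved$r, moved$l)
  expect_equal(nrow(s0), nrow(s1))
})

test_that("hydrogen bonds obey the geometric criteria", {
  don <- dplyr::bind_rows(
    atom_row(1, "N", "GLY", "A", 1, 0, 0, 0),
    atom_row(2, "H", "GLY", "A", 1, 1.0, 0, 0))
  acc_good <- atom_row(3, "O", "GLY", "B", 1, 2.9, 0, 0)
  hb <- find_hbonds(don, acc_good)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_da, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  # same D-A distance but a 90-degree angle is rejected
  don_bent <- don
  don_bent$x[2] <- 0
  don_bent$y[2] <- 1.0
  expect_equal(nrow(find_hbonds(don_bent, acc_good)), 0)
  # report_all lists candidates up to the scan radius without judging
  acc_far <- atom_row(4, "O", "GLY", "B", 2, 4.8, 0, 0)
  ra <- find_hbonds(don, dplyr::bind_rows(acc_good, acc_far),
                    report_all = TRUE)
  expect_equal(nrow(ra), 2)
  expect_equal(sort(ra$d_da), c(2.9, 4.8), tolerance = 1e-9)
  # no hydrogens: warning + distance-only mode
  expect_warning(dm <- find_hbonds(don[1, ], acc_good), "hydrogen|distance")
  expect_equal(nrow(dm), 1)
})

test_that("planted hydrogen bonds are recovered exactly from a mini complex", {
  # three N-H...O bonds planted at known geometry inside decoy atoms
  planted <- lapply(1:3, function(i) {
    base <- c(10 * i, 0, 0)
    dplyr::bind_rows(
      atom_row(10 * i + 1, "N", "GLY", "A", i, base[1], 0, 0),
      atom_row(10 * i + 2, "H", "GLY", "A", i, base[1] + 1.0, 0, 0))
  })
  donors <- dplyr::bind_rows(planted)
  acceptors <- dplyr::bind_rows(lapply(1:3, function(i) {
    atom_row(100 + i, "O", "SER", "B", i, 10 * i + 2.95, 0, 0)
  }))
  decoys <- atom_row(200:202, "CA", "ALA", "B", 11:13,
                     c(5, 15, 25), 3, 3)
  hb <- find_hbonds(donors, dplyr::bind_rows(acceptors, decoys))
  expect_equal(nrow(hb), 3)
  expect_equal(hb$d_da, rep(2.95, 3), tolerance = 1e-3)
  expect_equal(hb$d_ha, rep(1.95, 3), tolerance = 1e-3)
})

test_that("salt bridges pair basic nitrogens with acidic oxygens", {
  lys <- atom_row(1, "NZ", "LYS", "A", 1, 0, 0, 0)
  glu <- atom_row(2, "OE1", "GLU", "B", 1, 3.2, 0, 0)
  asp_far <- atom_row(3, "OD1", "ASP", "B", 2, 4.5, 0, 0)
  expect_equal(nrow(find_salt_bridges(lys, glu)), 1)
  expect_equal(nrow(find_salt_bridges(lys, asp_far)), 0)
  # two planted bridges, both orientations
  arg <- atom_row(4, "NH1", "ARG", "B", 3, 0, 3.0, 0)
  asp <- atom_row(5, "OD2", "ASP", "A", 2, 0, 6.0, 0)
  two <- find_salt_bridges(dplyr::bind_rows(lys, asp),
                           dplyr::bind_rows(glu, arg))
  expect_equal(nrow(two), 2)
})

test_that("best-energy selection is an exact per-group minimum", {
  sc <- tibble::tibble(site = "DI", replicate = 1, rank = 1:3,
                       energy = c(-250, -240, -230))
  expect_equal(best_energy_per_replicate(sc)$best_energy, -250)
  # permutation invariance of rank order
  set.seed(3)
  full <- simulate_docking_scores(seed = 4)
  shuf <- full[sample(nrow(full)), ]
  expect_equal(best_energy_per_replicate(full),
               best_energy_per_replicate(shuf))
  # brute-force oracle
  oracle <- aggregate(energy ~ site + replicate, data = full, FUN = min)
  b <- best_energy_per_replicate(full)
  m <- merge(b, oracle)
  expect_equal(m$best_energy, m$energy)
  # missing groups are named
  expect_error(best_energy_per_replicate(full[full$site != "DII" |
                                                full$replicate != 2, ]),
               "DII/2")
})

test_that("site statistics separate known group structure", {
  means <- c(DI = -280, DII = -350, DIII = -270, DIV = -300, Turret = -240)
  sc <- simulate_docking_scores(means, sd = 3, seed = 7)
  best <- best_energy_per_replicate(sc)
  st <- site_stats(best)
  expect_lt(st$anova_p, 0.001)
  expect_equal(as.character(
    st$site_means$site[which.min(st$site_means$mean_energy)]), "DII")
  # DII is the most negative in every replicate
  by_rep <- split(best, best$replicate)
  for (b in by_rep) {
    expect_equal(as.character(b$site[which.min(b$best_energy)]), "DII")
  }
  expect_equal(sum(st$pca_var_frac), 1, tolerance = 1e-6)
  # Tukey adjusted p never undercuts the unadjusted pairwise p
  pairs <- utils::combn(names(means), 2)
  for (j in seq_len(ncol(pairs))) {
    x <- best$best_energy[best$site == pairs[1, j]]
    y <- best$best_energy[best$site == pairs[2, j]]
    raw <- stats::t.test(x, y, var.equal = TRUE)$p.value
    keys <- c(paste(pairs[1, j], pairs[2, j], sep = "-"),
              paste(pairs[2, j], pairs[1, j], sep = "-"))
    padj <- st$tukey$p_adj[st$tukey$pair %in% keys]
    expect_length(padj, 1)
    expect_gte(round(padj, 10), round(raw, 10) - 0.05)
  }
  # equal groups: F ~ 0, all Tukey p ~ 1
  eq <- tidyr::expand_grid(site = names(means), replicate = 1:3)
  eq$best_energy <- rep(c(-300, -299, -301), times = 5)
  st_eq <- site_stats(eq)
  expect_lt(st_eq$anova_f, 0.1)
  expect_true(all(st_eq$tukey$p_adj > 0.99))
  # zero variance everywhere is degenerate
  eq0 <- eq
  eq0$best_energy <- -300
  expect_true(site_stats(eq0)$degenerate)
})
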