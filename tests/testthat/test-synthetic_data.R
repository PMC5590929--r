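test_that("ideal peptides have ideal backbone geometry", {
  tm <- motif_templates()
  pep <- generate_ideal_peptide(tm$helix)
  cas <- do.call(rbind, lapply(pep, `[[`, "CA"))
  d <- sqrt(rowSums(diff(cas)^2))
  expect_true(all(abs(d - 3.8) < 0.05))
  # dihedrals reproduce the requested angles
  phi4 <- dihedral_angle(pep[[3]]$C, pep[[4]]$N, pep[[4]]$CA, pep[[4]]$C)
  psi4 <- dihedral_angle(pep[[4]]$N, pep[[4]]$CA, pep[[4]]$C, pep[[5]]$N)
  expect_equal(phi4, -57, tolerance = 1e-6)
  expect_equal(psi4, -47, tolerance = 1e-6)
  # noise-free siblings superimpose exactly
  a <- peptide_window_atoms(generate_ideal_peptide(tm$strand))
  b <- peptide_window_atoms(generate_ideal_peptide(tm$strand))
  expect_equal(kabsch_rmsd(a, b), 0, tolerance = 1e-9)
})

test_that("template siblings at 0.3 A noise stay well under 1 A RMSD", {
  tm <- motif_templates()
  set.seed(17)
  rmsds <- replicate(50, {
    a <- peptide_window_atoms(generate_ideal_peptide(tm$helix,
                                                     noise_sd = 0.3))
    b <- peptide_window_atoms(generate_ideal_peptide(tm$helix,
                                                     noise_sd = 0.3))
    kabsch_rmsd(a, b)
  })
  expect_gte(mean(rmsds < 1), 0.99)
})

test_that("motif templates are mutually well separated", {
  tm <- motif_templates()
  atoms <- lapply(tm, function(t)
    peptide_window_atoms(generate_ideal_peptide(t)))
  m <- pairwise_matrix(atoms)
  expect_gte(min(m[upper.tri(m)]), 3.1)
})

test_that("structure generation is deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sp <- synthetic_spec(n_proteins = 2, seed = 23)
  g1 <- generate_structure_set(sp, d1)
  g2 <- generate_structure_set(sp, d2)
  expect_identical(readLines(file.path(d1, "SYN001.pdb")),
                   readLines(file.path(d2, "SYN001.pdb")))
  expect_identical(g1$truth$sites, g2$truth$sites)
  # write -> parse -> annotate runs clean
  ch <- parse_chain(file.path(d1, "SYN001.pdb"), "A")
  expect_silent(suppressMessages(ann <- annotate_ss_rsa(ch)))
  expect_equal(nrow(ann), nchar(ch$full_sequence))
  # planted sites are S/T at the planted positions
  s1 <- g1$truth$sites[g1$truth$sites$protein_id == "SYN001", ]
  expect_true(all(substring(g1$truth$sequences["SYN001"], s1$position,
                            s1$position) %in% c("S", "T")))
})

test_that("planted motif windows cluster back to their templates", {
  d <- withr::local_tempdir()
  g <- generate_structure_set(
    synthetic_spec(n_proteins = 12, n_modified_per_protein = 2,
                   n_missing_regions = 0, seed = 29), d)
  windows <- list()
  truth <- character(0)
  for (pid in unique(g$truth$sites$protein_id)) {
    ch <- parse_chain(file.path(d, paste0(pid, ".pdb")), "A")
    rows <- g$truth$sites[g$truth$sites$protein_id == pid, ]
    for (i in seq_len(nrow(rows))) {
      w <- extract_window(ch, rows$position[i])
      if (w$backbone_complete) {
        id <- paste0(pid, "_", rows$position[i])
        windows[[id]] <- w
        truth[id] <- rows$template[i]
      }
    }
  }
  expect_gte(length(windows), 20)
  cl <- complete_linkage_clusters(pairwise_matrix(windows), 3.0)
  memb <- cl$membership[names(truth)]
  expect_gte(rand_index(unname(memb), unname(truth)), 0.99)
  expect_equal(length(cl$clusters), length(unique(truth)))
})

test_that("disorder track generation honours its probabilities and seed", {
  g1 <- generate_disorder_tracks(n_target = 50, n_background = 50,
                                 p_in = 1, p_out = 0, window = 10,
                                 seed = 3)
  tr <- g1$target_tracks[[1]]
  pos <- g1$target_sites$position[1]
  expect_true(all(classify_disordered(tr, (pos - 10):(pos + 10))))
  expect_false(any(classify_disordered(tr, 1:(pos - 11))))
  bg <- g1$background_tracks[[1]]
  expect_false(any(classify_disordered(bg, seq_along(bg$scores))))
  # determinism
  g2 <- generate_disorder_tracks(n_target = 50, n_background = 50,
                                 p_in = 1, p_out = 0, window = 10,
                                 seed = 3)
  expect_identical(g1$target_tracks[[5]]$scores,
                   g2$target_tracks[[5]]$scores)
  # p_in = p_out: flat profile
  g3 <- generate_disorder_tracks(n_target = 80, n_background = 80,
                                 p_in = 0.4, p_out = 0.4, seed = 4)
  p <- disorder_odds_profile(g3$target_tracks, g3$target_sites,
                             g3$background_tracks, g3$background_sites,
                             window = 10)
  expect_lt(max(abs(p$value)), 0.35)
  expect_true(all(p$ci_low < 0 & p$ci_high > 0) || mean(abs(p$value)) < 0.2)
})
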