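test_that("8-to-3 state reduction follows the stated rule exactly", {
  expect_equal(reduce_ss8_to_ss3(c("G", "H")), c("H", "H"))
  # the pi-helix -> strand mapping is deliberate
  expect_equal(reduce_ss8_to_ss3(c("I", "B", "E")), c("E", "E", "E"))
  expect_equal(reduce_ss8_to_ss3(c("S", "T", " ", "")), rep("C", 4))
  expect_error(reduce_ss8_to_ss3("Q"), "unknown")
  # total over all eight tokens
  expect_equal(reduce_ss8_to_ss3(c("G", "H", "I", "S", "T", "B", "E", " ")),
               c("H", "H", "E", "C", "C", "E", "E", "C"))
})

test_that("RSA normalisation and binning honour the boundary conventions", {
  expect_equal(normalise_rsa(0, "S"), 0)
  expect_equal(normalise_rsa(max_asa_table()[["S"]], "S"), 1)
  expect_equal(normalise_rsa(max_asa_table()[["S"]] / 2, "S"), 0.5)
  expect_warning(normalise_rsa(10, "X"), "max-ASA")
  # both cut-offs are inclusive on the lower bin
  expect_equal(bin_rsa(c(0.05, 0.25, 0.251, 0, 0.06)),
               c("buried", "partial", "exposed", "buried", "partial"))
  # the two scales disagree, which shifts bins
  expect_gt(normalise_rsa(60, "S", "miller1987"),
            normalise_rsa(60, "S", "tien2013"))
})

test_that("DSSP fixtures round-trip through the parser exactly", {
  dir <- withr::local_tempdir()
  resid <- data.frame(chain = "A", author_number = 1:6,
                      aa = c("M", "S", "T", "G", "K", "L"),
                      ss8 = c("H", "H", " ", "E", "G", "I"),
                      asa = c(120, 35, 0, 88, 12, 240))
  path <- file.path(dir, "fix.dssp")
  write_dssp_fixture(resid, path)
  parsed <- parse_dssp(path)
  expect_equal(parsed$aa, resid$aa)
  expect_equal(parsed$ss8, resid$ss8)
  expect_equal(parsed$asa, resid$asa)
  expect_equal(parsed$author_number, as.character(1:6))
  expect_equal(parsed$chain, rep("A", 6))
  # malformed record: hard error carrying the line number
  lines <- readLines(path)
  lines[4] <- substr(lines[4], 1, 20)
  writeLines(lines, path)
  expect_error(parse_dssp(path), "line 4")
})

test_that("sphere-sampling ASA matches the closed form for isolated atoms", {
  # residues placed far apart, with atoms pulled far from one another, so
  # every atom's full expanded sphere is accessible
  ch <- chain_from_angles(angles_for("h", 2))
  for (at in c("n", "ca", "c", "o", "cb")) {
    ch$residues[[paste0(at, "_x")]] <- ch$residues[[paste0(at, "_x")]] +
      c(0, 500)
    ch$residues[[paste0(at, "_y")]] <-
      (match(at, c("n", "ca", "c", "o", "cb")) - 1) * 50
    ch$residues[[paste0(at, "_z")]] <- 0
  }
  asa <- shrake_rupley_asa(ch)
  exp_res <- sum(4 * pi * (VDW_RADII[c("N", "C", "C", "O", "C")] + 1.4)^2)
  expect_equal(asa[1], exp_res, tolerance = 0.02)
  expect_equal(asa[2], exp_res, tolerance = 0.02)
  # additivity under non-overlap: far-separated residues score as isolated
  ch1 <- ch; ch1$residues <- ch1$residues[1, , drop = FALSE]
  ch1$full_sequence <- "A"
  expect_equal(shrake_rupley_asa(ch1)[1], asa[1], tolerance = 1e-9)
})

test_that("close atoms occlude one another", {
  spread <- chain_from_angles(angles_for("h", 2))
  tight <- chain_from_angles(angles_for("h", 2))
  ats <- c("n", "ca", "c", "o", "cb")
  for (k in seq_along(ats)) {
    at <- ats[k]
    # residue 2 parked far away in both chains
    spread$residues[[paste0(at, "_x")]] <- c((k - 1) * 100, 1e5 + k * 100)
    tight$residues[[paste0(at, "_x")]] <- c((k - 1) * 1.5, 1e5 + k * 100)
    for (ax in c("y", "z")) {
      spread$residues[[paste0(at, "_", ax)]] <- c(0, 0)
      tight$residues[[paste0(at, "_", ax)]] <- c(0, 0)
    }
  }
  a_spread <- shrake_rupley_asa(spread)[1]
  a_tight <- shrake_rupley_asa(tight)[1]
  expect_lt(a_tight, 0.7 * a_spread)
})

test_that("doubling the sample points leaves per-residue ASA converged", {
  ch <- chain_from_angles(angles_for("h", 8))
  a1 <- shrake_rupley_asa(ch, points = 960)
  a2 <- shrake_rupley_asa(ch, points = 1920)
  rel <- abs(a1 - a2) / pmax(a2, 1)
  # point-counting aliasing on partially occluded atoms caps near 2%;
  # the typical residue moves by well under 1%
  expect_true(all(rel < 0.02, na.rm = TRUE))
  expect_lt(mean(rel, na.rm = TRUE), 0.01)
})

test_that("dihedral assigner labels ideal fixtures and coils sensibly", {
  h <- chain_from_angles(angles_for("h", 12))
  expect_true(all(dihedral_ss3(h)[3:10] == "H"))
  e <- chain_from_angles(matrix(rep(c(-120, 130), each = 12), ncol = 2))
  expect_true(all(dihedral_ss3(e)[3:10] == "E"))
  # random coil: mostly C
  set.seed(11)
  coil <- chain_from_angles(cbind(runif(50, -160, -50),
                                  runif(50, -180, 40)))
  expect_gte(mean(dihedral_ss3(coil) == "C"), 0.8)
  # termini are always C
  expect_equal(dihedral_ss3(h)[c(1, 12)], c("C", "C"))
})

test_that("combined annotation records its source and scale", {
  ch <- chain_from_angles(angles_for("h", 10),
                          aa = c(rep("A", 4), "S", rep("A", 5)))
  ann <- annotate_ss_rsa(ch)
  expect_equal(attr(ann, "asa_source"), "shrake_rupley")
  expect_equal(attr(ann, "max_asa_scale"), "tien2013")
  expect_true(all(ann$ss3 %in% c("H", "E", "C")))
  expect_true(all(ann$rsa_bin[!is.na(ann$rsa_bin)] %in%
                    c("buried", "partial", "exposed")))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ssrsa.csv")
  write_ss_rsa_annotation(ann, "A", path)
  hdr <- readLines(path, n = 2)
  expect_match(hdr[1], "asa_source=shrake_rupley")
  tab <- utils::read.csv(path, comment.char = "#")
  expect_equal(names(tab), c("chain", "author_number", "aa", "ss8", "ss3",
                             "asa", "rsa", "rsa_bin"))
})
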