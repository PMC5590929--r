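test_that("flank extraction pads termini with gaps and handles exact fits", {
  # two leading gaps keep the site residue in the central (4th) slot
  expect_equal(flank7("MSTAK", 2), "--MSTAK")
  expect_equal(substr(flank7("MSTAK", 2), 4, 4), "S")
  expect_equal(flank7("MASTPQR", 4), "MASTPQR")
  expect_equal(flank7("MS", 1), "---MS--")
  expect_error(flank7("MST", 4))
})

write_catalog_fixture <- function(dir, sites, seqs) {
  site_csv <- file.path(dir, "sites.csv")
  fasta <- file.path(dir, "seqs.fasta")
  utils::write.csv(sites, site_csv, row.names = FALSE, quote = FALSE)
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta)
  list(sites = site_csv, fasta = fasta)
}

test_that("site tables load with residue filtering and error reporting", {
  dir <- withr::local_tempdir()
  seqs <- c(P1 = "MSTAKQSA", P2 = "AATSSA")
  f <- write_catalog_fixture(dir, data.frame(
    protein_id = c("P1", "P1", "P2", "P2"),
    position = c(2, 4, 4, 99)), seqs)
  expect_warning(
    expect_message(s <- load_site_table(f$sites, f$fasta, name = "MSS"),
                   "not S/T"),
    "beyond sequence")
  # P1:2 is S (kept), P1:4 is A (rejected), P2:4 is S (kept), P2:99 oob
  expect_equal(nrow(s$records), 2)
  expect_equal(s$records$flank7[1], "--MSTAK")
  expect_equal(s$records$residue, c("S", "S"))
  # missing sequence is a hard error naming the accession
  f2 <- write_catalog_fixture(dir, data.frame(protein_id = "P9",
                                              position = 1), seqs)
  expect_error(load_site_table(f2$sites, f$fasta), "P9")
})

test_that("unique-motif filtering keeps first occurrence and is idempotent", {
  seqs <- c(P1 = "AAASTAAKAAASTAAK", P2 = "GGASTAAKGG")
  rec <- data.frame(
    protein_id = c("P1", "P1", "P2"), position = c(4, 12, 4),
    residue = "S",
    flank7 = c("AASTAAK", "AASTAAK", "AASTAAK"),
    source_label = c("first", "second", "third"))
  s <- site_set(rec, seqs, name = "MSS")
  u <- filter_unique_motifs(s)
  expect_equal(nrow(u$records), 1)
  expect_equal(u$records$source_label, "first")
  expect_identical(filter_unique_motifs(u)$records, u$records)
  # empty input passes through
  e <- s; e$records <- s$records[0, ]
  expect_equal(nrow(filter_unique_motifs(e)$records), 0)
})

test_that("unmodified-set derivation enumerates exactly the other S/T", {
  s <- site_set(data.frame(protein_id = "P1", position = 1, residue = "S",
                           flank7 = flank7("SATAS", 1),
                           source_label = "x"),
                c(P1 = "SATAS"), name = "MSS")
  u <- derive_unmodified_set(s)
  expect_equal(u$records$position, c(3, 5))
  # protein with no S/T beyond the modified one contributes nothing
  s2 <- site_set(data.frame(protein_id = "P1", position = 2, residue = "T",
                            flank7 = flank7("ATAAA", 2),
                            source_label = "x"),
                 c(P1 = "ATAAA"), name = "MSS")
  expect_equal(nrow(derive_unmodified_set(s2)$records), 0)
})

test_that("modified plus derived-unmodified partition all S/T positions", {
  set.seed(41)
  # 10 proteins x 20 S/T each, one modified per protein -> 190 unmodified
  seqs <- character(0)
  recs <- list()
  for (i in 1:10) {
    pid <- paste0("P", i)
    chars <- sample(c("A", "G", "L", "V"), 60, replace = TRUE)
    st_pos <- sort(sample(60, 20))
    chars[st_pos] <- sample(c("S", "T"), 20, replace = TRUE)
    seqs[pid] <- paste(chars, collapse = "")
    mod <- sample(st_pos, 1)
    recs[[i]] <- data.frame(protein_id = pid, position = mod,
                            residue = chars[mod],
                            flank7 = flank7(seqs[pid], mod),
                            source_label = "synthetic")
  }
  s <- site_set(do.call(rbind, recs), seqs, name = "MSS")
  u <- derive_unmodified_set(s)
  expect_equal(nrow(u$records), 190)
  total_st <- sum(vapply(strsplit(seqs, ""), function(x)
    sum(x %in% c("S", "T")), integer(1)))
  expect_equal(nrow(u$records) + nrow(s$records), total_st)
  # derived records satisfy the site-set invariants
  expect_s3_class(site_set(u$records, seqs, "USS"), "site_set")
})

test_that("predictor trimming centres the window and respects margins", {
  long <- paste(rep("A", 1000), collapse = "")
  # already short enough: unchanged
  short <- paste(rep("A", 700), collapse = "")
  expect_equal(trim_for_predictor(short, 350)$new_position, 350)
  # centred window for an interior site
  tr <- trim_for_predictor(long, 500)
  expect_equal(nchar(tr$sequence), 800)
  expect_equal(tr$new_position, 400)
  expect_gte(tr$new_position, 100)
  expect_gte(nchar(tr$sequence) - tr$new_position, 100)
  # site near the N-terminus: window clamps to [1, 800]
  tr2 <- trim_for_predictor(long, 50)
  expect_equal(nchar(tr2$sequence), 800)
  expect_equal(tr2$new_position, 50)
  expect_gte(nchar(tr2$sequence) - tr2$new_position, 100)
  # sequence shorter than twice the margin: warned, unchanged
  tiny <- paste(rep("A", 150), collapse = "")
  expect_warning(tr3 <- trim_for_predictor(tiny, 75), "margin")
  expect_equal(tr3$sequence, tiny)
})
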