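make_mapping_fixture <- function(seed = 2, n_proteins = 3) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  g <- generate_structure_set(synthetic_spec(n_proteins = n_proteins,
                                             seed = seed), dir)
  s <- load_site_table(g$files[["sites"]], g$files[["fasta"]], name = "MSS")
  chains <- list()
  for (f in list.files(dir, pattern = "\\.pdb$", full.names = TRUE)) {
    ch <- parse_chain(f, "A")
    chains[[paste(ch$pdb_id, ch$chain_id, sep = ":")]] <- ch
  }
  list(g = g, sites = s, chains = chains, dir = dir)
}

test_that("table mapping enforces residue identity", {
  fx <- make_mapping_fixture(seed = 2)
  cands <- map_by_table(fx$sites, fx$g$files[["mapping"]], fx$chains)
  expect_equal(nrow(cands), nrow(fx$sites$records))
  expect_true(all(cands$method == "table"))
  # a corrupted row pointing at a non-matching residue is dropped
  tab <- utils::read.csv(fx$g$files[["mapping"]])
  pos <- tab$chain_pos[1]
  ch <- fx$chains[[paste(tab$pdb[1], "A", sep = ":")]]
  wrong <- which(strsplit(ch$full_sequence, "")[[1]] == "A")[1]
  tab$chain_pos[1] <- wrong
  expect_message(c2 <- map_by_table(fx$sites, tab, fx$chains),
                 "identity mismatch")
  expect_equal(nrow(c2), nrow(cands) - 1)
})

test_that("alignment mapping recovers planted correspondences exactly", {
  fx <- make_mapping_fixture(seed = 3)
  cands <- map_by_alignment(fx$sites, fx$chains)
  best <- select_best_candidate(cands)
  # every plantable site maps, to its own protein, at its own position
  expect_equal(nrow(best), nrow(fx$sites$records))
  expect_equal(best$pdb_id, best$protein_id)
  expect_equal(best$chain_seq_index, best$position)
  expect_true(all(best$evalue <= 1e-25))
  expect_true(all(best$identity_at_window == 1))
})

test_that("point mutations outside windows do not disturb the mapping", {
  fx <- make_mapping_fixture(seed = 4, n_proteins = 2)
  s <- fx$sites
  # mutate 5 positions of each protein sequence, away from site windows
  for (pid in names(s$sequences)) {
    seqc <- strsplit(s$sequences[[pid]], "")[[1]]
    sites_here <- s$records$position[s$records$protein_id == pid]
    blocked <- unique(unlist(lapply(sites_here, function(p)
      (p - 3):(p + 3))))
    mut <- setdiff(seq(5, length(seqc) - 5, by = 20), blocked)[1:5]
    seqc[mut] <- ifelse(seqc[mut] == "W", "F", "W")
    s$sequences[pid] <- paste(seqc, collapse = "")
  }
  # rebuild records so flanks/residues still match the mutated sequences
  s <- site_set(data.frame(
    protein_id = s$records$protein_id, position = s$records$position,
    residue = s$records$residue,
    flank7 = vapply(seq_len(nrow(s$records)), function(i)
      flank7(s$sequences[[s$records$protein_id[i]]],
             s$records$position[i]), character(1)),
    source_label = "mut"), s$sequences, name = "MSS")
  best <- select_best_candidate(map_by_alignment(s, fx$chains))
  expect_equal(nrow(best), nrow(s$records))
  expect_true(all(best$identity_at_window == 1))
  expect_equal(best$chain_seq_index, best$position)
})

test_that("weak alignments are rejected by the E-value gate", {
  fx <- make_mapping_fixture(seed = 5, n_proteins = 1)
  # unrelated random sequence: no candidate survives the gate
  set.seed(9)
  junk <- paste(sample(c("A", "G", "L", "V", "K", "E"), 60, replace = TRUE),
                collapse = "")
  junk <- sub("^(.{29}).", "\\1S", junk)  # one S at position 30
  s <- site_set(data.frame(protein_id = "JUNK1", position = 30,
                           residue = "S", flank7 = flank7(junk, 30),
                           source_label = "junk"),
                c(JUNK1 = junk), name = "user")
  cands <- map_by_alignment(s, fx$chains)
  expect_equal(nrow(cands), 0)
  # the E-value formula itself is monotone and scale-dependent
  expect_lt(karlin_altschul_evalue(300, 200, 200),
            karlin_altschul_evalue(200, 200, 200))
  expect_lt(karlin_altschul_evalue(300, 200, 200), 1e-25)
})

test_that("best-candidate selection ranks and tie-breaks deterministically", {
  base <- data.frame(protein_id = "P1", position = 10, residue = "S",
                     chain_seq_index = 10L, stringsAsFactors = FALSE)
  mk <- function(pdb, chain, method, evalue = NA, coverage = NA)
    cbind(base, pdb_id = pdb, chain_id = chain, method = method,
          evalue = evalue, coverage = coverage, identity_at_window = NA)
  cands <- rbind(mk("2xyz", "A", "table", coverage = 0.7),
                 mk("1abc", "A", "table", coverage = 0.9),
                 mk("3aaa", "A", "alignment", evalue = 1e-40,
                    coverage = 0.95))
  # table beats alignment; higher coverage wins among tables
  expect_equal(select_best_candidate(cands)$pdb_id, "1abc")
  aln <- rbind(mk("4bbb", "B", "alignment", evalue = 1e-30),
               mk("3aaa", "A", "alignment", evalue = 1e-40))
  expect_equal(select_best_candidate(aln)$pdb_id, "3aaa")
  # exact tie: lexicographically smaller (pdb, chain)
  tie <- rbind(mk("2bbb", "A", "alignment", evalue = 1e-30),
               mk("1aaa", "B", "alignment", evalue = 1e-30))
  expect_equal(select_best_candidate(tie)$pdb_id, "1aaa")
  # permutation invariance
  for (perm in list(c(2, 1), c(1, 2))) {
    expect_identical(select_best_candidate(tie[perm, ])$pdb_id, "1aaa")
  }
})

test_that("BLAST tabular input yields gated, identity-checked candidates", {
  fx <- make_mapping_fixture(seed = 6, n_proteins = 1)
  rec <- fx$sites$records[1, ]
  len <- nchar(fx$sites$sequences[[rec$protein_id]])
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hits.tsv")
  rows <- c(
    # full-length ungapped self hit, strong E-value
    paste(rec$protein_id, paste0(rec$protein_id, "_A"), 100, len, 0, 0,
          1, len, 1, len, 1e-60, 500, sep = "\t"),
    # gapped HSP: skipped with a warning
    paste(rec$protein_id, paste0(rec$protein_id, "_A"), 95, len, 2, 1,
          1, len, 1, len, 1e-50, 400, sep = "\t"),
    # weak hit: over the gate
    paste(rec$protein_id, paste0(rec$protein_id, "_A"), 40, 50, 25, 0,
          1, 50, 1, 50, 1e-10, 60, sep = "\t"))
  writeLines(rows, path)
  expect_warning(cands <- read_blast_tab(path, fx$sites, fx$chains),
                 "gapped")
  expect_equal(nrow(cands), sum(fx$sites$records$protein_id ==
                                  rec$protein_id))
  expect_true(all(cands$evalue == 1e-60))
  expect_equal(cands$chain_seq_index, cands$position)
})
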