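# Synthetic inputs with planted ground truth: ideal-geometry peptides and
# whole-chain models written as parseable PDB files, site catalogs, mapping
# tables, DSSP-style fixtures and disorder-score tracks. Every generator is
# deterministic given its seed, and the returned truth tables are sufficient
# to score downstream stages.

# Engh-Huber-style ideal backbone geometry (Angstroms / degrees); recorded in
# generated file headers.
IDEAL_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_c_ca_cb = 110.1, tor_n_c_ca_cb = -122.6,
  omega = 180)

#' Backbone phi/psi templates for planted structural motifs
#'
#' Six well-separated 7-residue conformations built from per-residue
#' phi/psi blocks: alpha-helical (-57, -47), beta-strand (-139, 135),
#' left-handed-helical (57, 47), polyproline-II-like (-75, 150) and
#' left-handed-bridge (80, 5). The block patterns were chosen to maximise
#' the minimum pairwise window superposition RMSD, which is 3.2 A for this
#' set, so complete-linkage clustering at the default 3 A cut separates the
#' motifs cleanly under the default 0.3 A coordinate noise (sibling windows
#' superimpose below ~1 A).
#'
#' @return Named list of 7 x 2 matrices (phi, psi in degrees).
#' @export
motif_templates <- function() {
  blocks <- list(h = c(-57, -47), e = c(-139, 135), l = c(57, 47),
                 p = c(-75, 150), g = c(80, 5))
  mk <- function(pat) {
    m <- do.call(rbind, blocks[strsplit(pat, "")[[1]]])
    dimnames(m) <- list(NULL, c("phi", "psi"))
    m
  }
  pats <- c(helix = "hhhhhhh", strand = "eeeeeee",
            left_coil = "lllglhe", ppii_mix = "peplgep",
            strand_left = "heeelll", bridge_mix = "glgppel")
  lapply(pats, mk)
}

#' Build an ideal-geometry peptide backbone from phi/psi angles
#'
#' Sequential placement with ideal bond lengths and angles (N-CA 1.458 A,
#' CA-C 1.525 A, C-N 1.329 A, trans omega); O and CB are placed at ideal
#' geometry. Optional isotropic Gaussian noise is added per coordinate.
#'
#' @param phi_psi n x 2 matrix of backbone dihedrals in degrees (phi of the
#'   first residue and psi of the last only affect O/CB placement).
#' @param noise_sd Gaussian noise SD per coordinate in Angstroms (default 0).
#' @param seed Optional integer seed for the noise.
#' @return List of length n; each element a list of named length-3
#'   coordinates `N`, `CA`, `C`, `O`, `CB`.
#' @export
generate_ideal_peptide <- function(phi_psi, noise_sd = 0, seed = NULL) {
  phi_psi <- as.matrix(phi_psi)
  n <- nrow(phi_psi)
  stopifnot(n >= 2, ncol(phi_psi) == 2)
  g <- IDEAL_GEOM
  res <- vector("list", n)
  # first residue laid out in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- acos(-cos(g$ang_n_ca_c * pi / 180))
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in 2:n) {
    p <- res[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n,
                     phi_psi[i - 1, 2])
    CAi <- place_atom(p$CA, p$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
    Ci <- place_atom(p$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi_psi[i, 1])
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    res[[i]]$O <- place_atom(r$N, r$CA, r$C, g$c_o, g$ang_ca_c_o,
                             phi_psi[i, 2] + 180)
    res[[i]]$CB <- place_atom(r$N, r$C, r$CA, g$ca_cb, g$ang_c_ca_cb,
                              g$tor_n_c_ca_cb)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n))
      for (a in names(res[[i]]))
        res[[i]][[a]] <- res[[i]][[a]] + stats::rnorm(3, 0, noise_sd)
  }
  res
}

#' Superposition atoms of a generated 7-residue peptide
#'
#' @param peptide Output of [generate_ideal_peptide()] with 7 residues.
#' @return 8 x 3 matrix: the 7 CA in order, then the central residue's CB.
#' @export
peptide_window_atoms <- function(peptide) {
  stopifnot(length(peptide) == 7)
  rbind(do.call(rbind, lapply(peptide, `[[`, "CA")),
        peptide[[4]]$CB)
}

#' Specification for a synthetic structure set
#'
#' Bundles the knobs of [generate_structure_set()]. Defaults emulate a
#' small set of crystal-structure-like chains: 120-residue proteins, one
#' modified S/T per protein placed on a planted backbone motif, 0.3 A
#' coordinate noise (sibling windows superimpose well under 1 A), one
#' 5-residue missing region per chain, and lognormal C-alpha B-factors.
#'
#' @param n_proteins Number of chains (default 10).
#' @param protein_length Residues per chain (default 120).
#' @param n_modified_per_protein Modified sites per chain (default 1).
#' @param motif_templates Named list of 7 x 2 phi/psi matrices (default
#'   [motif_templates()]).
#' @param coordinate_noise_sd Gaussian coordinate noise in Angstroms
#'   (default 0.3).
#' @param n_missing_regions Missing (REM465) regions per chain (default 1).
#' @param missing_region_length Length of each missing region (default 5).
#' @param disorder_enrichment List `(window, p_in, p_out)` for
#'   [generate_disorder_tracks()] (default window 15, 0.6 in, 0.3 out).
#' @param resolution Nominal resolution written to the files (default 1.8).
#' @param bfactor_meanlog,bfactor_sdlog Lognormal B-factor parameters
#'   (default log(20), 0.3).
#' @param seed Integer seed (default 1).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 10, protein_length = 120,
                           n_modified_per_protein = 1,
                           motif_templates = NULL,
                           coordinate_noise_sd = 0.3,
                           n_missing_regions = 1, missing_region_length = 5,
                           disorder_enrichment = list(window = 15,
                                                      p_in = 0.6,
                                                      p_out = 0.3),
                           resolution = 1.8,
                           bfactor_meanlog = log(20), bfactor_sdlog = 0.3,
                           seed = 1) {
  stopifnot(coordinate_noise_sd >= 0,
            disorder_enrichment$p_in >= 0, disorder_enrichment$p_in <= 1,
            disorder_enrichment$p_out >= 0, disorder_enrichment$p_out <= 1)
  if (is.null(motif_templates))
    motif_templates <- motif_templates()
  structure(as.list(environment()), class = "synthetic_spec")
}

# random coil-ish phi/psi away from the planted templates
random_coil_angles <- function(n) {
  cbind(phi = stats::runif(n, -160, -50),
        psi = stats::runif(n, 20, 170) * sample(c(1, -1), n, TRUE,
                                                prob = c(0.7, 0.3)))
}

#' Generate a synthetic structure set with planted ground truth
#'
#' Writes one PDB file per synthetic protein (ids `SYN001`, `SYN002`, ...,
#' a reserved namespace that cannot collide with real PDB codes) containing
#' SEQRES records, REMARK 465 missing regions, and backbone + CB ATOM
#' records with lognormal B-factors. Each modified site's 7-residue window
#' is built from an assigned phi/psi motif template; everything else is
#' random coil. Also writes the sequences (FASTA), a site table, a
#' SIFTS-style mapping table and truth CSVs.
#'
#' @param spec A [synthetic_spec].
#' @param out_dir Output directory (created if needed).
#' @return List with `files` (named paths), `truth` (list with `sites`,
#'   `missing`, `sequences`, `mapping` and the spec echo).
#' @export
generate_structure_set <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  tmpl <- spec$motif_templates
  n_res <- spec$protein_length
  sites <- list(); missing <- list(); seqs <- character(0)
  pdb_files <- character(0)
  for (pi in seq_len(spec$n_proteins)) {
    pid <- sprintf("SYN%03d", pi)
    aa <- sample(setdiff(AA_20, c("G", "P")), n_res, replace = TRUE)
    # modified sites: spaced, away from termini
    slots <- seq(10, n_res - 10, by = 14)
    pos <- sort(sample(slots, spec$n_modified_per_protein))
    aa[pos] <- sample(c("S", "T"), length(pos), replace = TRUE)
    tnames <- sample(names(tmpl), length(pos), replace = TRUE)
    # angles: coil everywhere, template at site windows
    ang <- random_coil_angles(n_res)
    for (k in seq_along(pos))
      ang[(pos[k] - 3):(pos[k] + 3), ] <- tmpl[[tnames[k]]]
    pep <- generate_ideal_peptide(ang, noise_sd = spec$coordinate_noise_sd)
    # missing regions, kept clear of site windows (+/- 4) and termini
    miss_idx <- integer(0)
    blocked <- unique(unlist(lapply(pos, function(p) (p - 4):(p + 4))))
    if (spec$n_missing_regions > 0) {
      cand <- setdiff(5:(n_res - spec$missing_region_length - 4), blocked)
      for (m in seq_len(spec$n_missing_regions)) {
        ok <- cand[vapply(cand, function(s)
          all((s:(s + spec$missing_region_length - 1)) %in% cand),
          logical(1))]
        if (!length(ok)) break
        s <- sample(ok, 1)
        reg <- s:(s + spec$missing_region_length - 1)
        miss_idx <- c(miss_idx, reg)
        missing[[length(missing) + 1]] <-
          data.frame(protein_id = pid, start = s,
                     length = spec$missing_region_length)
        cand <- setdiff(cand, (s - spec$missing_region_length - 1):
                          (s + 2 * spec$missing_region_length))
      }
    }
    bfac <- stats::rlnorm(n_res, spec$bfactor_meanlog, spec$bfactor_sdlog)
    path <- file.path(out_dir, paste0(pid, ".pdb"))
    write_synthetic_pdb(path, pid, "A", aa, pep, miss_idx, bfac,
                        spec$resolution)
    pdb_files <- c(pdb_files, path)
    seqs[pid] <- paste(aa, collapse = "")
    sites[[pi]] <- data.frame(protein_id = pid, position = pos,
                              residue = aa[pos], template = tnames,
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  missing <- if (length(missing)) do.call(rbind, missing)
             else data.frame(protein_id = character(), start = integer(),
                             length = integer())
  mapping <- data.frame(accession = sites$protein_id,
                        seq_pos = sites$position,
                        pdb = sites$protein_id, chain = "A",
                        chain_pos = sites$position)
  files <- c(
    fasta = file.path(out_dir, "sequences.fasta"),
    sites = file.path(out_dir, "sites.csv"),
    mapping = file.path(out_dir, "mapping.csv"),
    truth_sites = file.path(out_dir, "truth_sites.csv"),
    truth_missing = file.path(out_dir, "truth_missing.csv"))
  writeLines(paste0(">", names(seqs), "\n", seqs), files["fasta"])
  utils::write.csv(data.frame(protein_id = sites$protein_id,
                              position = sites$position,
                              residue = sites$residue,
                              source = "synthetic"),
                   files["sites"], row.names = FALSE, quote = FALSE)
  utils::write.csv(mapping, files["mapping"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sites, files["truth_sites"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(missing, files["truth_missing"], row.names = FALSE,
                   quote = FALSE)
  list(files = c(files, structures = NA, pdb = pdb_files),
       truth = list(sites = sites, missing = missing, sequences = seqs,
                    mapping = mapping, spec = spec))
}

write_synthetic_pdb <- function(path, pdb_id, chain, aa, peptide, miss_idx,
                                bfac, resolution) {
  n <- length(aa)
  lines <- c(
    sprintf("HEADER    SYNTHETIC PROTEIN                       01-JAN-26   %4s",
            substr(pdb_id, 1, 4)),
    sprintf("TITLE     SYNTHETIC MODEL %s (IDEAL ENGH-HUBER GEOMETRY)", pdb_id),
    sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution),
    "EXPDTA    X-RAY DIFFRACTION")
  if (length(miss_idx)) {
    lines <- c(lines,
               "REMARK 465 MISSING RESIDUES",
               "REMARK 465   M RES C SSSEQI",
               sprintf("REMARK 465     %3s %1s %5d", AA_1TO3[aa[miss_idx]],
                       chain, miss_idx))
  }
  res3 <- AA_1TO3[aa]
  for (i in seq_len(ceiling(n / 13))) {
    idx <- ((i - 1) * 13 + 1):min(i * 13, n)
    lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", i, chain, n,
                              paste(res3[idx], collapse = " ")))
  }
  serial <- 0L
  for (j in seq_len(n)) {
    if (j %in% miss_idx) next
    atoms <- c("N", "CA", "C", "O", "CB")
    for (a in atoms) {
      xyz <- peptide[[j]][[a]]
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, a, res3[j], chain, j, xyz[1], xyz[2], xyz[3], 1.00,
        bfac[j], substr(a, 1, 1)))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Generate disorder-score tracks with a planted enrichment
#'
#' Target proteins carry one site each; residues within `window` of the site
#' are disordered (score >= threshold) with probability `p_in` and all other
#' residues with probability `p_out`. Background proteins (globular-set
#' style) use `p_out` everywhere. The planted offset-0 log10 odds ratio is
#' `log10((p_in/(1-p_in)) / (p_out/(1-p_out)))`.
#'
#' @param n_target,n_background Numbers of target / background proteins
#'   (one site each).
#' @param protein_length Residues per protein (default 201, site centred).
#' @param window Enrichment half-width in residues (default 15).
#' @param p_in,p_out Disorder probabilities inside / outside the window.
#' @param method Track method label (default `"IUPred-Short"`).
#' @param seed Integer seed.
#' @return List with `target_tracks`, `target_sites`, `background_tracks`,
#'   `background_sites`, and `truth` (planted log10 OR and parameters).
#' @export
generate_disorder_tracks <- function(n_target = 200, n_background = 200,
                                     protein_length = 201, window = 15,
                                     p_in = 0.6, p_out = 0.3,
                                     method = "IUPred-Short", seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  set.seed(seed)
  thr <- if (method %in% names(DISORDER_THRESHOLDS))
    DISORDER_THRESHOLDS[[method]] else 0.5
  site_pos <- (protein_length + 1) %/% 2
  draw_scores <- function(p_vec) {
    dis <- stats::runif(length(p_vec)) < p_vec
    u <- stats::runif(length(p_vec))
    ifelse(dis, thr + u * (1 - thr), u * thr * 0.999)
  }
  mk_side <- function(n, prefix, enriched) {
    tracks <- list(); rows <- list()
    for (i in seq_len(n)) {
      pid <- sprintf("%s%04d", prefix, i)
      p_vec <- rep(p_out, protein_length)
      if (enriched) {
        lo <- max(1, site_pos - window); hi <- min(protein_length,
                                                   site_pos + window)
        p_vec[lo:hi] <- p_in
      }
      tracks[[pid]] <- disorder_track(pid, method, draw_scores(p_vec),
                                      threshold = thr)
      rows[[i]] <- data.frame(protein_id = pid, position = site_pos)
    }
    list(tracks = tracks, sites = do.call(rbind, rows))
  }
  tg <- mk_side(n_target, "TGT", TRUE)
  bg <- mk_side(n_background, "BGD", FALSE)
  list(target_tracks = tg$tracks, target_sites = tg$sites,
       background_tracks = bg$tracks, background_sites = bg$sites,
       truth = list(
         log10_or = log10((p_in / (1 - p_in)) / (p_out / (1 - p_out))),
         window = window, p_in = p_in, p_out = p_out, threshold = thr,
         method = method, seed = seed))
}

#' Write a classic-format DSSP fixture file
#'
#' Emits the fixed-column residue records that [parse_dssp()] reads, for
#' synthetic chains annotated by the built-in assigners. Clearly labelled
#' synthetic in the file header.
#'
#' @param residues data.frame with columns `chain`, `author_number`
#'   (integer), `aa`, `ss8` (`" "` for none), `asa`.
#' @param path Output path.
#' @export
write_dssp_fixture <- function(residues, path) {
  hdr <- c(
    "==== Synthetic secondary structure fixture (DSSP classic layout) ====",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI"))
  body <- vapply(seq_len(nrow(residues)), function(i) {
    r <- residues[i, ]
    ss <- if (is.na(r$ss8) || r$ss8 == "") " " else r$ss8
    sprintf("%5d%5d %1s %1s  %1s%17s%4d", i, as.integer(r$author_number),
            r$chain, r$aa, ss, "", as.integer(round(r$asa)))
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
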