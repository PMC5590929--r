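# End-to-end orchestration: the structural arm (map sites onto chains,
# annotate REM465 / SS / RSA / B-factors, cluster windows, bootstrap null)
# and the sequence arm (entropy profile, predicted-feature proportion
# tests, disorder score comparisons and odds-ratio profiles), each emitting
# machine-readable report tables.

#' Assemble a pipeline run configuration
#'
#' Collects input paths and the numeric thresholds of the analysis. The
#' configuration is echoed into every output file for provenance.
#'
#' @param structures Character vector of structure file paths.
#' @param site_table Path to the modified-site CSV (or a [site_set]).
#' @param fasta Path to the FASTA of full-length sequences.
#' @param mapping_table Optional path to a SIFTS-style mapping CSV.
#' @param dssp_files Optional named character vector of DSSP file paths,
#'   keyed by structure id.
#' @param out_dir Output directory for report CSVs (`NULL` = no files).
#' @param evalue_max Alignment E-value gate (default 1e-25).
#' @param rmsd_cut Complete-linkage cut in Angstroms (default 3.0).
#' @param resolution_max Maximum resolution in Angstroms (default 2.50).
#' @param min_chain_len Minimum chain length (default 31).
#' @param bootstrap_reps Bootstrap replicates for the cluster null
#'   (default 1000).
#' @param entropy_reps Bootstrap resamples for the entropy band
#'   (default 200).
#' @param profile_halfwidth Disorder profile half-width in residues
#'   (default 50).
#' @param max_asa_scale Max-ASA scale name (default `"tien2013"`).
#' @param seed Integer seed driving all randomness in the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(structures = character(), site_table = NULL,
                       fasta = NULL, mapping_table = NULL,
                       dssp_files = NULL, out_dir = NULL,
                       evalue_max = 1e-25, rmsd_cut = 3.0,
                       resolution_max = 2.50, min_chain_len = 31,
                       bootstrap_reps = 1000, entropy_reps = 200,
                       profile_halfwidth = 50,
                       max_asa_scale = "tien2013", seed = 1) {
  stopifnot(evalue_max > 0, rmsd_cut > 0, resolution_max > 0,
            min_chain_len > 0, bootstrap_reps > 0, entropy_reps > 0,
            profile_halfwidth > 0)
  structure(as.list(environment()), class = "run_config")
}

config_fingerprint <- function(config) {
  num <- config[vapply(config, function(x)
    is.numeric(x) || is.character(x) && length(x) == 1, logical(1))]
  num <- num[!names(num) %in% c("structures", "site_table", "fasta",
                                "mapping_table", "out_dir")]
  paste0("# config: ", paste(names(num), unlist(num), sep = "=",
                             collapse = "; "))
}

write_report_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_fingerprint(config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

chain_ids_in_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- lines[grepl("^ATOM  ", lines)]
  unique(substr(at, 22, 22))
}

#' Run the structural analysis arm
#'
#' Loads and deduplicates the modified-site catalog, parses and filters the
#' structure chains, maps sites (mapping table first, then alignment for the
#' remainder), and produces: the missing-residue (REM465) contingency with
#' Fisher odds ratio, a 3-state secondary-structure proportion table, the
#' RSA bin distribution and buried-site listing, the complete-linkage
#' cluster assignments with consensus secondary structure, and the
#' bootstrap null distribution of cluster counts from unmodified S/T
#' windows of the same chains.
#'
#' @param config A [run_config] with `structures`, `site_table` and `fasta`
#'   set.
#' @return Named list of report tables and result objects (also written as
#'   CSVs under `config$out_dir` when set).
#' @export
run_structural_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sites <- if (inherits(config$site_table, "site_set")) config$site_table
           else load_site_table(config$site_table, config$fasta,
                                name = "MSS")
  sites <- filter_unique_motifs(sites)

  chains <- list()
  for (f in config$structures) {
    for (cid in chain_ids_in_file(f)) {
      ch <- tryCatch(parse_chain(f, cid), error = function(e) NULL)
      if (is.null(ch)) next
      if (eligible_chain(ch, config$min_chain_len, config$resolution_max))
        chains[[chain_key(ch$pdb_id, ch$chain_id)]] <- ch
    }
  }
  if (!length(chains)) stop("structural stage: no eligible chains parsed")

  cands <- if (!is.null(config$mapping_table))
    map_by_table(sites, config$mapping_table, chains)
  else empty_candidates()
  unmapped <- setdiff(paste(sites$records$protein_id, sites$records$position),
                      paste(cands$protein_id, cands$position))
  if (length(unmapped)) {
    rest <- sites
    keep <- paste(rest$records$protein_id, rest$records$position) %in%
      unmapped
    rest$records <- rest$records[keep, , drop = FALSE]
    if (nrow(rest$records))
      cands <- rbind(cands,
                     map_by_alignment(rest, chains, config$evalue_max))
  }
  mapping <- select_best_candidate(cands)
  if (nrow(mapping) == 0) stop("structural stage: no sites mapped")
  message(nrow(mapping), " site(s) mapped onto ",
          length(unique(paste(mapping$pdb_id, mapping$chain_id))),
          " chain(s)")

  # per-chain annotations
  ann <- list()
  for (ck in unique(chain_key(mapping$pdb_id, mapping$chain_id))) {
    ch <- chains[[ck]]
    dssp <- NULL
    if (!is.null(config$dssp_files) &&
        ch$pdb_id %in% names(config$dssp_files))
      dssp <- parse_dssp(config$dssp_files[[ch$pdb_id]])
    ann[[ck]] <- annotate_ss_rsa(ch, dssp, scale = config$max_asa_scale)
  }

  mapped_key <- chain_key(mapping$pdb_id, mapping$chain_id)
  # site-level structural annotations
  site_rows <- lapply(seq_len(nrow(mapping)), function(i) {
    ck <- mapped_key[i]
    ch <- chains[[ck]]
    j <- mapping$chain_seq_index[i]
    a <- ann[[ck]]
    data.frame(mapping[i, ], rem465 = ch$residues$rem465[j],
               ss3 = a$ss3[j], rsa = a$rsa[j], rsa_bin = a$rsa_bin[j],
               bfactor_z = standardise_bfactors(ch)[j],
               stringsAsFactors = FALSE)
  })
  site_tab <- do.call(rbind, site_rows)

  # background: unmodified S/T on the same chains
  bg_rows <- list()
  for (ck in unique(mapped_key)) {
    ch <- chains[[ck]]
    a <- ann[[ck]]
    st <- which(strsplit(ch$full_sequence, "")[[1]] %in% c("S", "T"))
    st <- setdiff(st, site_tab$chain_seq_index[mapped_key == ck])
    if (!length(st)) next
    bg_rows[[ck]] <- data.frame(
      pdb_id = ch$pdb_id, chain_id = ch$chain_id, chain_seq_index = st,
      rem465 = ch$residues$rem465[st], ss3 = a$ss3[st], rsa = a$rsa[st],
      rsa_bin = a$rsa_bin[st],
      bfactor_z = standardise_bfactors(ch)[st], stringsAsFactors = FALSE)
  }
  bg_tab <- do.call(rbind, bg_rows)

  rem465_tab <- matrix(c(sum(site_tab$rem465), sum(!site_tab$rem465),
                         sum(bg_tab$rem465), sum(!bg_tab$rem465)),
                       nrow = 2, byrow = TRUE,
                       dimnames = list(c("modified", "unmodified"),
                                       c("rem465", "observed")))
  rem465_fisher <- fisher_exact_or(rem465_tab[1, 1], rem465_tab[1, 2],
                                   rem465_tab[2, 1], rem465_tab[2, 2])

  ss_table <- ss_proportion_table(site_tab$ss3, bg_tab$ss3)
  rsa_table <- rsa_bin_table(site_tab$rsa_bin, bg_tab$rsa_bin)
  buried <- site_tab[!is.na(site_tab$rsa_bin) &
                       site_tab$rsa_bin == "buried", , drop = FALSE]

  bz <- score_comparison(site_tab$bfactor_z, bg_tab$bfactor_z,
                         test = "kruskal_wallis")

  # windows and clustering
  windows <- list()
  for (i in seq_len(nrow(site_tab))) {
    ch <- chains[[mapped_key[i]]]
    w <- suppressWarnings(extract_window(ch, site_tab$chain_seq_index[i]))
    if (w$backbone_complete)
      windows[[paste0(site_tab$pdb_id[i], "_", site_tab$chain_id[i], "_",
                      site_tab$chain_seq_index[i])]] <- w
  }
  clustering <- NULL
  if (length(windows) >= 2) {
    rmsd <- pairwise_matrix(windows)
    clustering <- complete_linkage_clusters(rmsd, config$rmsd_cut)
    cons <- lapply(clustering$clusters, function(members) {
      consensus_ss(lapply(members, function(id) {
        w <- windows[[id]]
        ck <- chain_key(w$chain_ref[["pdb_id"]], w$chain_ref[["chain_id"]])
        ann[[ck]]$ss3[(w$center_seq_index - 3):(w$center_seq_index + 3)]
      }))
    })
  } else rmsd <- NULL

  # bootstrap null from unmodified windows on the same chains
  null <- NULL
  if (!is.null(bg_tab) && nrow(bg_tab) >= 2 && length(windows) >= 2) {
    bg_windows <- list()
    for (i in seq_len(nrow(bg_tab))) {
      ch <- chains[[chain_key(bg_tab$pdb_id[i], bg_tab$chain_id[i])]]
      w <- suppressWarnings(extract_window(ch, bg_tab$chain_seq_index[i]))
      if (w$backbone_complete)
        bg_windows[[paste0("bg", i)]] <- w
    }
    if (length(bg_windows) >= 2)
      null <- bootstrap_null(bg_windows, n = length(windows),
                             reps = config$bootstrap_reps,
                             threshold = config$rmsd_cut,
                             seed = config$seed)
  }

  report <- list(sites = sites, mapping = mapping, site_table = site_tab,
                 background_table = bg_tab,
                 rem465_table = rem465_tab, rem465_fisher = rem465_fisher,
                 ss_table = ss_table, rsa_table = rsa_table,
                 buried_sites = buried, bfactor_comparison = bz,
                 rmsd_matrix = rmsd, clustering = clustering,
                 consensus_ss = if (!is.null(clustering)) cons else NULL,
                 bootstrap = null, config = config)
  if (!is.null(config$out_dir)) write_structural_reports(report)
  report
}

ss_proportion_table <- function(mod_ss3, bg_ss3, states = c("C", "H", "E")) {
  mod_ss3 <- mod_ss3[!is.na(mod_ss3)]
  bg_ss3 <- bg_ss3[!is.na(bg_ss3)]
  rows <- lapply(states, function(s) {
    x1 <- sum(mod_ss3 == s); n1 <- length(mod_ss3)
    x2 <- sum(bg_ss3 == s); n2 <- length(bg_ss3)
    ci1 <- proportion_ci(x1, n1); ci2 <- proportion_ci(x2, n2)
    zt <- two_proportion_ztest(x1, n1, x2, n2)
    data.frame(state = s, mod_n = x1, mod_prop = x1 / n1,
               mod_ci_low = ci1[1], mod_ci_high = ci1[2],
               bg_n = x2, bg_prop = x2 / n2,
               bg_ci_low = ci2[1], bg_ci_high = ci2[2],
               p_value = zt$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

rsa_bin_table <- function(mod_bin, bg_bin) {
  bins <- c("buried", "partial", "exposed")
  mod_bin <- mod_bin[!is.na(mod_bin)]
  bg_bin <- bg_bin[!is.na(bg_bin)]
  data.frame(bin = bins,
             mod_n = vapply(bins, function(b) sum(mod_bin == b), integer(1)),
             mod_prop = vapply(bins, function(b) mean(mod_bin == b),
                               numeric(1)),
             bg_n = vapply(bins, function(b) sum(bg_bin == b), integer(1)),
             bg_prop = vapply(bins, function(b) mean(bg_bin == b),
                              numeric(1)),
             row.names = NULL)
}

write_structural_reports <- function(report) {
  config <- report$config
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  rt <- report$rem465_table
  write_report_csv(data.frame(group = rownames(rt), rem465 = rt[, 1],
                              observed = rt[, 2],
                              odds_ratio = report$rem465_fisher$odds_ratio,
                              p_value = report$rem465_fisher$p_value),
                   p("rem465_contingency.csv"), config)
  write_report_csv(report$ss_table, p("ss_proportions.csv"), config)
  write_report_csv(report$rsa_table, p("rsa_bins.csv"), config)
  write_report_csv(report$buried_sites, p("buried_sites.csv"), config)
  if (!is.null(report$clustering)) {
    ids <- names(report$clustering$membership)
    parts <- strsplit(ids, "_")
    info <- data.frame(PDB = vapply(parts, `[`, character(1), 1),
                       Chain = vapply(parts, `[`, character(1), 2),
                       Position = vapply(parts, `[`, character(1), 3),
                       row.names = ids)
    st <- report$site_table
    key <- paste0(st$pdb_id, "_", st$chain_id, "_", st$chain_seq_index)
    info$RSA <- round(st$rsa[match(ids, key)], 2)
    info$SS <- st$ss3[match(ids, key)]
    write_cluster_assignments(report$clustering, info,
                              p("cluster_assignments.csv"))
    write_rmsd_matrix(round(report$rmsd_matrix, 4), p("rmsd_matrix.csv"))
  }
  if (!is.null(report$bootstrap))
    write_report_csv(data.frame(
      n = report$bootstrap$n, reps = report$bootstrap$reps,
      ci_low = report$bootstrap$ci[[1]], ci_high = report$bootstrap$ci[[2]],
      mean_clusters = mean(report$bootstrap$counts),
      observed_clusters = length(report$clustering$clusters)),
      p("bootstrap_null.csv"), config)
  invisible(config$out_dir)
}

#' Run the sequence analysis arm
#'
#' Produces the sequence-level reports: the positional relative-entropy
#' profile of the modified-site flanks against the proteome background,
#' proportion tests for predicted secondary structure and accessibility
#' (either computed from per-residue prediction tracks or replicated from
#' user-supplied count tables), the per-method disorder score comparison,
#' and the per-method disorder log-odds profiles against a background set.
#'
#' @param config A [run_config]; `site_table`/`fasta` (or a [site_set])
#'   must be set.
#' @param entropy_halfwidth Half-width of the entropy profile in residues
#'   (default 7).
#' @param ss_counts Optional data.frame with columns
#'   `state,x_mod,n_mod,x_bg,n_bg`: predicted secondary-structure counts to
#'   test (replication-table path).
#' @param accessibility_counts Optional data.frame with the same layout for
#'   predicted-burial thresholds (column `state` = threshold label).
#' @param disorder Optional list with `target_tracks`, `target_sites`,
#'   `background_tracks`, `background_sites` (per method lists accepted)
#'   for score comparisons and odds profiles.
#' @return Named list of report tables (also written as CSVs under
#'   `config$out_dir` when set).
#' @export
run_sequence_analysis <- function(config, entropy_halfwidth = 7,
                                  ss_counts = NULL,
                                  accessibility_counts = NULL,
                                  disorder = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sites <- if (inherits(config$site_table, "site_set")) config$site_table
           else load_site_table(config$site_table, config$fasta,
                                name = "MSS")
  sites <- filter_unique_motifs(sites)

  bg_freqs <- aa_background_freqs(sites$sequences)
  flanks <- site_flanks(sites, entropy_halfwidth)
  entropy <- relative_entropy_profile(flanks, bg_freqs,
                                      reps = config$entropy_reps,
                                      seed = config$seed)

  count_test <- function(tab) {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      r <- tab[i, ]
      ci1 <- proportion_ci(r$x_mod, r$n_mod)
      ci2 <- proportion_ci(r$x_bg, r$n_bg)
      zt <- two_proportion_ztest(r$x_mod, r$n_mod, r$x_bg, r$n_bg)
      data.frame(state = r$state, mod_prop = r$x_mod / r$n_mod,
                 mod_ci_low = ci1[1], mod_ci_high = ci1[2],
                 bg_prop = r$x_bg / r$n_bg,
                 bg_ci_low = ci2[1], bg_ci_high = ci2[2],
                 z = zt$z, p_value = zt$p_value)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }

  ss_test <- if (!is.null(ss_counts)) count_test(ss_counts) else NULL
  acc_test <- if (!is.null(accessibility_counts))
    count_test(accessibility_counts) else NULL

  disorder_comparison <- NULL
  disorder_profiles <- NULL
  if (!is.null(disorder)) {
    # accept either one method or a named list of per-method bundles
    bundles <- if (!is.null(disorder$target_tracks)) list(disorder)
               else disorder
    site_scores <- function(tracks, sdf) {
      vapply(seq_len(nrow(sdf)), function(k) {
        tr <- tracks[[sdf$protein_id[k]]]
        if (is.null(tr)) return(NA_real_)
        tr$scores[sdf$position[k]]
      }, numeric(1))
    }
    disorder_comparison <- do.call(rbind, lapply(bundles, function(b) {
      meth <- b$target_tracks[[1]]$method
      sc <- score_comparison(site_scores(b$target_tracks, b$target_sites),
                             site_scores(b$background_tracks,
                                         b$background_sites), test = "t")
      data.frame(method = meth,
                 mean_mod = sc$means[["modified"]],
                 se_mod = sc$standard_errors[["modified"]],
                 mean_bg = sc$means[["unmodified"]],
                 se_bg = sc$standard_errors[["unmodified"]],
                 p_value = sc$p_value)
    }))
    rownames(disorder_comparison) <- NULL
    disorder_profiles <- lapply(bundles, function(b)
      disorder_odds_profile(b$target_tracks, b$target_sites,
                            b$background_tracks, b$background_sites,
                            window = config$profile_halfwidth))
    names(disorder_profiles) <- disorder_comparison$method
  }

  report <- list(sites = sites, entropy_profile = entropy,
                 ss_test = ss_test, accessibility_test = acc_test,
                 disorder_comparison = disorder_comparison,
                 disorder_profiles = disorder_profiles, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_profile(entropy, p("entropy_profile.tsv"))
    if (!is.null(ss_test))
      write_report_csv(ss_test, p("predicted_ss_tests.csv"), config)
    if (!is.null(acc_test))
      write_report_csv(acc_test, p("predicted_accessibility_tests.csv"),
                       config)
    if (!is.null(disorder_comparison))
      write_report_csv(disorder_comparison, p("disorder_comparison.csv"),
                       config)
    if (!is.null(disorder_profiles))
      for (m in names(disorder_profiles))
        write_profile(disorder_profiles[[m]],
                      p(paste0("disorder_profile_",
                               gsub("[^A-Za-z0-9]", "_", m), ".tsv")))
  }
  report
}
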