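# Structure chains: parsing, eligibility, missing-residue flags, B-factor
# standardisation and 7-residue window extraction.
#
# Windows are indexed in full-sequence (SEQRES) space so that missing
# (REM465) residues still occupy window slots; author numbering is carried
# along for reporting.

#' Parse one chain of a structure file into an annotated chain
#'
#' Reads a PDB (or mmCIF) file, reconstructs the chain's full sequence from
#' the sequence records (SEQRES), marks residues without coordinates as
#' missing (the REM465 convention), and stores backbone/CB coordinates and
#' C-alpha B-factors per residue. Alternate locations are resolved to the
#' highest-occupancy copy; only the first model of multi-model files is used.
#'
#' @param structure_file Path to a PDB or mmCIF file.
#' @param chain_id Author chain identifier.
#' @return Object of class `annotated_chain`: list with `pdb_id`, `chain_id`,
#'   `resolution` (Angstroms, `NA` if absent), `method` (experiment type),
#'   `full_sequence`, and `residues`, a data.frame with one row per
#'   full-sequence position (`seq_index`, `author_number`, `aa`, `observed`,
#'   `rem465`, `ca_bfactor` and x/y/z columns for N, CA, C, O, CB).
#' @export
parse_chain <- function(structure_file, chain_id) {
  is_cif <- grepl("\\.cif(\\.gz)?$", structure_file, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(structure_file)
         else bio3d::read.pdb(structure_file, verbose = FALSE)
  meta <- read_structure_meta(structure_file, is_cif)

  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain_id, "' not found in ",
                          structure_file)
  # resolve altlocs: keep highest occupancy per (residue, atom name)
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$resno, at$insert, at$elety)
  if (anyDuplicated(key)) {
    ord <- order(-at$o)
    at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$resno, at$insert, at$elety), unique(key))), ,
             drop = FALSE]
    message("altloc conflicts resolved to highest occupancy in ",
            basename(structure_file), " chain ", chain_id)
  }

  res_key <- paste(at$resno, at$insert)
  obs_keys <- unique(res_key)
  obs <- data.frame(
    author_number = vapply(strsplit(obs_keys, " "), function(p)
      paste0(p[1], if (length(p) > 1) p[2] else ""), character(1)),
    aa = aa_three_to_one(at$resid[match(obs_keys, res_key)]),
    stringsAsFactors = FALSE)
  obs_resno <- at$resno[match(obs_keys, res_key)]

  # full sequence from SEQRES when available
  seqres <- pdb$seqres[names(pdb$seqres) == chain_id]
  if (length(seqres) > 0) {
    full_seq <- paste(aa_three_to_one(seqres), collapse = "")
  } else {
    warning("no sequence records for chain ", chain_id,
            "; falling back to observed residues only")
    full_seq <- paste(obs$aa, collapse = "")
  }

  seq_idx <- map_observed_to_sequence(obs$aa, obs_resno, full_seq)

  n <- nchar(full_seq)
  res <- data.frame(
    seq_index = seq_len(n),
    author_number = NA_character_,
    aa = strsplit(full_seq, "")[[1]],
    observed = FALSE, rem465 = TRUE,
    ca_bfactor = NA_real_,
    stringsAsFactors = FALSE)
  for (atom in c("n", "ca", "c", "o", "cb"))
    for (ax in c("x", "y", "z"))
      res[[paste0(atom, "_", ax)]] <- NA_real_

  ok <- !is.na(seq_idx)
  res$author_number[seq_idx[ok]] <- obs$author_number[ok]
  res$observed[seq_idx[ok]] <- TRUE
  res$rem465[seq_idx[ok]] <- FALSE
  atom_names <- c(n = "N", ca = "CA", c = "C", o = "O", cb = "CB")
  for (i in which(ok)) {
    rows <- at[res_key == obs_keys[i], , drop = FALSE]
    j <- seq_idx[i]
    for (a in names(atom_names)) {
      hit <- which(rows$elety == atom_names[[a]])
      if (length(hit)) {
        res[[paste0(a, "_x")]][j] <- rows$x[hit[1]]
        res[[paste0(a, "_y")]][j] <- rows$y[hit[1]]
        res[[paste0(a, "_z")]][j] <- rows$z[hit[1]]
        if (a == "ca") res$ca_bfactor[j] <- rows$b[hit[1]]
      }
    }
  }
  # residues said to be observed must at least have CA
  no_ca <- res$observed & is.na(res$ca_x)
  if (any(no_ca)) {
    res$observed[no_ca] <- FALSE
    res$rem465[no_ca] <- TRUE
  }

  stem <- toupper(sub("\\.(pdb|ent|cif)(\\.gz)?$", "",
                      basename(structure_file), ignore.case = TRUE))
  structure(list(pdb_id = stem %||% meta$pdb_id,
                 chain_id = chain_id,
                 resolution = meta$resolution,
                 method = meta$method,
                 full_sequence = full_seq,
                 residues = res),
            class = "annotated_chain")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a

read_structure_meta <- function(path, is_cif) {
  lines <- readLines(path, warn = FALSE)
  if (is_cif) {
    res_ln <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    met_ln <- grep("_exptl\\.method", lines, value = TRUE)
    resolution <- if (length(res_ln))
      suppressWarnings(as.numeric(sub(".*\\s", "", res_ln[1]))) else NA_real_
    method <- if (length(met_ln))
      gsub("['\"]", "", sub("_exptl\\.method\\s+", "", met_ln[1])) else NA
    id_ln <- grep("^_entry\\.id", lines, value = TRUE)
    pdb_id <- if (length(id_ln)) sub(".*\\s", "", id_ln[1]) else NA
  } else {
    res_ln <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    resolution <- if (length(res_ln)) {
      m <- regmatches(res_ln[1],
                      regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)",
                              res_ln[1], perl = TRUE))
      if (length(m)) as.numeric(m) else NA_real_
    } else NA_real_
    met_ln <- grep("^EXPDTA", lines, value = TRUE)
    method <- if (length(met_ln)) trimws(sub("^EXPDTA\\s*", "", met_ln[1]))
              else NA
    hdr <- grep("^HEADER", lines, value = TRUE)
    pdb_id <- if (length(hdr) && nchar(hdr[1]) >= 66)
      trimws(substr(hdr[1], 63, 66)) else NA
  }
  list(resolution = resolution, method = method, pdb_id = pdb_id)
}

# Assign each observed residue its index in the full sequence. Tries a
# constant author-number offset first; falls back to a global-local alignment
# of the observed sequence against the full sequence.
map_observed_to_sequence <- function(obs_aa, obs_resno, full_seq) {
  n <- nchar(full_seq)
  full <- strsplit(full_seq, "")[[1]]
  if (length(obs_aa) == n && all(obs_aa == full))
    return(seq_len(n))
  # constant-offset search (author numbering is usually SEQRES index + k)
  for (off in seq(1 - min(obs_resno), n - max(obs_resno))) {
    idx <- obs_resno + off
    if (all(idx >= 1 & idx <= n) && !anyDuplicated(idx) &&
        all(full[idx] == obs_aa | obs_aa == "X"))
      return(idx)
  }
  # alignment fallback (handles insertion codes / renumbered chains)
  aln <- Biostrings::pairwiseAlignment(
    pattern = paste(obs_aa, collapse = ""), subject = full_seq,
    type = "global-local", gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  start_s <- aln@subject@range@start
  idx <- rep(NA_integer_, length(obs_aa))
  pi <- 0L; si <- start_s - 1L
  for (k in seq_along(p)) {
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-") {
      pi <- pi + 1L
      if (s[k] != "-" && (p[k] == s[k] || p[k] == "X")) idx[pi] <- si
    }
  }
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " observed residue(s) could not be placed in the full sequence")
  idx
}

#' Chain eligibility filter
#'
#' A chain is eligible when it comes from X-ray crystallography, is longer
#' than 30 residues and was determined to at most 2.50 Angstrom resolution
#' (boundary inclusive).
#'
#' @param chain An [annotated_chain][parse_chain].
#' @param min_len Minimum chain length in residues (default 31, i.e. > 30).
#' @param max_res Maximum resolution in Angstroms (default 2.50).
#' @return Logical flag.
#' @export
eligible_chain <- function(chain, min_len = 31, max_res = 2.50) {
  stopifnot(inherits(chain, "annotated_chain"))
  if (is.na(chain$resolution)) {
    warning("missing resolution for ", chain$pdb_id, " ", chain$chain_id)
    return(FALSE)
  }
  is_xray <- grepl("X[- ]?RAY", toupper(chain$method %||% ""))
  is_xray && nchar(chain$full_sequence) >= min_len &&
    chain$resolution <= max_res
}

#' Standardise C-alpha B-factors within a chain
#'
#' Z-score normalises the C-alpha B-factors over all observed residues of the
#' chain, using the population standard deviation. Unobserved residues get
#' `NA`.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @return Numeric vector, one value per full-sequence position.
#' @export
standardise_bfactors <- function(chain) {
  stopifnot(inherits(chain, "annotated_chain"))
  b <- chain$residues$ca_bfactor
  obs <- which(!is.na(b))
  if (length(obs) < 2)
    stop("need at least 2 observed residues to standardise B-factors")
  mu <- mean(b[obs])
  sdv <- sqrt(mean((b[obs] - mu)^2))
  z <- rep(NA_real_, length(b))
  if (sdv < 1e-12) {
    warning("zero B-factor variance in chain ", chain$chain_id,
            "; all Z-scores set to 0")
    z[obs] <- 0
  } else {
    z[obs] <- (b[obs] - mu) / sdv
  }
  z
}

#' Extract a 7-residue structural window around a site
#'
#' Collects the residues at offsets -3..+3 (full-sequence space) around the
#' central position, determines whether the window has a complete backbone
#' (all 7 residues observed with N, CA, C coordinates and the central residue
#' with a CB), and assembles the 8 superposition atoms: the 7 C-alphas in
#' offset order followed by the central residue's C-beta.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @param center_seq_index 1-based full-sequence index of the central residue.
#' @param require_st Warn when the central residue is not S/T (default
#'   `TRUE`; background windows may disable the warning).
#' @return Object of class `site_window` with fields `chain_ref`,
#'   `center_seq_index`, `entries` (data.frame, 7 rows), `backbone_complete`
#'   and `atoms` (8 x 3 matrix, or `NULL` when incomplete).
#' @export
extract_window <- function(chain, center_seq_index, require_st = TRUE) {
  stopifnot(inherits(chain, "annotated_chain"))
  n <- nrow(chain$residues)
  stopifnot(center_seq_index >= 1, center_seq_index <= n)
  if (require_st && !chain$residues$aa[center_seq_index] %in% c("S", "T"))
    warning("central residue at ", center_seq_index, " is ",
            chain$residues$aa[center_seq_index], ", not S/T")
  idx <- (center_seq_index - 3):(center_seq_index + 3)
  in_range <- idx >= 1 & idx <= n
  entries <- chain$residues[pmax(pmin(idx, n), 1), , drop = FALSE]
  entries$offset <- -3:3
  if (!all(in_range)) {
    entries[!in_range,
            setdiff(names(entries), "offset")] <- NA
    complete <- FALSE
  } else {
    has_bb <- entries$observed &
      !is.na(entries$n_x) & !is.na(entries$ca_x) & !is.na(entries$c_x)
    complete <- all(has_bb) && !is.na(entries$cb_x[4])
  }
  atoms <- NULL
  if (complete) {
    atoms <- rbind(as.matrix(entries[, c("ca_x", "ca_y", "ca_z")]),
                   as.numeric(entries[4, c("cb_x", "cb_y", "cb_z")]))
    dimnames(atoms) <- list(c(paste0("CA_", -3:3), "CB_0"),
                            c("x", "y", "z"))
  }
  structure(list(chain_ref = c(pdb_id = chain$pdb_id,
                               chain_id = chain$chain_id),
                 center_seq_index = center_seq_index,
                 entries = entries,
                 backbone_complete = complete,
                 atoms = atoms),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s:%s center %d (%s) backbone_complete=%s\n",
              x$chain_ref[["pdb_id"]], x$chain_ref[["chain_id"]],
              x$center_seq_index,
              paste(x$entries$aa, collapse = ""),
              x$backbone_complete))
  invisible(x)
}

#' Write per-chain residue annotation to CSV
#'
#' Columns `seq_index,author_number,aa,observed,rem465,bfactor_z`;
#' `seq_index` is 1-based in full-sequence space.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @param path Output path.
#' @export
write_chain_annotation <- function(chain, path) {
  z <- standardise_bfactors(chain)
  out <- chain$residues[, c("seq_index", "author_number", "aa",
                            "observed", "rem465")]
  out$bfactor_z <- round(z, 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# seq_index is 1-based in full-sequence (SEQRES) space",
               "# bfactor_z uses the population SD over observed C-alphas"),
             con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
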