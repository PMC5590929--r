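# Placing sequence-space sites onto structure chains, either through a
# residue-level mapping table (SIFTS-style) or by local alignment with an
# E-value gate, then selecting one best chain per site.

empty_candidates <- function() {
  data.frame(protein_id = character(), position = integer(),
             residue = character(), pdb_id = character(),
             chain_id = character(), chain_seq_index = integer(),
             method = character(), evalue = numeric(),
             coverage = numeric(), identity_at_window = numeric(),
             stringsAsFactors = FALSE)
}

chain_key <- function(pdb_id, chain_id) paste(pdb_id, chain_id, sep = ":")

#' Map sites to chains through a residue-level mapping table
#'
#' Each table row asserts that `accession` position `seq_pos` corresponds to
#' residue `chain_pos` of chain `pdb`:`chain`. Candidates whose chain
#' residue does not equal the site residue are dropped (logged).
#'
#' @param sites A [site_set].
#' @param table data.frame (or CSV path) with columns
#'   `accession,seq_pos,pdb,chain,chain_pos`.
#' @param chains Named list of [annotated_chain][parse_chain] objects keyed
#'   `"<pdb_id>:<chain_id>"`, used for the residue-identity check and for
#'   coverage (fraction of the site protein covered by the chain sequence).
#' @return data.frame of mapping candidates (`method = "table"`).
#' @export
map_by_table <- function(sites, table, chains) {
  stopifnot(inherits(sites, "site_set"))
  if (is.character(table)) table <- utils::read.csv(table,
                                                    stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "seq_pos", "pdb", "chain", "chain_pos") %in%
                  names(table)))
  rec <- sites$records
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    hit <- which(rec$protein_id == row$accession &
                   rec$position == row$seq_pos)
    if (!length(hit)) next
    ch <- chains[[chain_key(row$pdb, row$chain)]]
    if (is.null(ch)) next
    aa_chain <- substr(ch$full_sequence, row$chain_pos, row$chain_pos)
    for (h in hit) {
      if (!nzchar(aa_chain) || aa_chain != rec$residue[h]) {
        dropped <- dropped + 1L
        next
      }
      out[[length(out) + 1]] <- data.frame(
        protein_id = rec$protein_id[h], position = rec$position[h],
        residue = rec$residue[h], pdb_id = ch$pdb_id,
        chain_id = ch$chain_id,
        chain_seq_index = as.integer(row$chain_pos),
        method = "table", evalue = NA_real_,
        coverage = min(1, nchar(ch$full_sequence) /
                         nchar(sites$sequences[[rec$protein_id[h]]])),
        identity_at_window = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (dropped)
    message(dropped, " table candidate(s) dropped: residue identity mismatch")
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' E = K m n exp(-lambda S) with the default gapped BLOSUM62 parameters
#' (lambda = 0.267, K = 0.041, matching gap costs 11/1).
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject sequence lengths.
#' @param lambda,k Karlin-Altschul parameters.
#' @return Expected number of chance alignments with at least this score.
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, k = 0.041) {
  k * m * n * exp(-lambda * score)
}

#' Map sites to chains by local alignment
#'
#' Smith-Waterman alignment (BLOSUM62, affine gaps open 11 / extend 1) of
#' each site protein sequence against each chain's full sequence. Alignments
#' passing the E-value gate contribute one candidate per site whose position
#' falls in an ungapped aligned column with matching residue identity.
#'
#' @param sites A [site_set].
#' @param chains Named list of [annotated_chain][parse_chain] objects keyed
#'   `"<pdb_id>:<chain_id>"`.
#' @param evalue_max Maximum E-value (default 1e-25, a conservative gate).
#' @return data.frame of mapping candidates (`method = "alignment"`).
#' @export
map_by_alignment <- function(sites, chains, evalue_max = 1e-25) {
  stopifnot(inherits(sites, "site_set"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  rec <- sites$records
  out <- list()
  for (pid in unique(rec$protein_id)) {
    pseq <- sites$sequences[[pid]]
    prec <- rec[rec$protein_id == pid, , drop = FALSE]
    for (ck in names(chains)) {
      ch <- chains[[ck]]
      sseq <- gsub("X", "A", ch$full_sequence)  # BLOSUM62 lacks X rows
      aln <- Biostrings::pairwiseAlignment(
        pattern = pseq, subject = sseq, type = "local",
        substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1)
      ev <- karlin_altschul_evalue(Biostrings::score(aln),
                                   nchar(pseq), nchar(sseq))
      if (ev > evalue_max) next
      map <- alignment_position_map(aln)
      cover <- sum(!is.na(map$q2s)) / nchar(pseq)
      for (h in seq_len(nrow(prec))) {
        pos <- prec$position[h]
        spos <- if (pos >= 1 && pos <= length(map$q2s)) map$q2s[pos]
                else NA_integer_
        if (is.na(spos)) next
        if (substr(ch$full_sequence, spos, spos) != prec$residue[h]) next
        widx <- (pos - 3):(pos + 3)
        widx <- widx[widx >= 1 & widx <= length(map$q2s)]
        ali <- map$q2s[widx]
        idw <- mean(!is.na(ali) &
                      substring(ch$full_sequence, ali, ali) ==
                        substring(pseq, widx, widx))
        out[[length(out) + 1]] <- data.frame(
          protein_id = pid, position = pos, residue = prec$residue[h],
          pdb_id = ch$pdb_id, chain_id = ch$chain_id,
          chain_seq_index = as.integer(spos),
          method = "alignment", evalue = ev, coverage = cover,
          identity_at_window = idw, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

# Per-query-position map to subject positions (NA for gapped columns).
alignment_position_map <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qstart <- aln@pattern@range@start
  sstart <- aln@subject@range@start
  qlen <- qstart + sum(p != "-") - 1
  q2s <- rep(NA_integer_, qlen)
  qi <- qstart - 1L; si <- sstart - 1L
  for (k in seq_along(p)) {
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-") {
      qi <- qi + 1L
      if (s[k] != "-") q2s[qi] <- si
    }
  }
  list(q2s = q2s)
}

#' Read BLAST tabular output (outfmt 6) as mapping candidates
#'
#' Accepts the standard 12-column tabular format with subject ids of the
#' form `<pdb>_<chain>`. Only gap-free HSPs are converted (the tabular
#' format does not record gap placement, so positions inside gapped HSPs
#' cannot be mapped); gapped HSPs are skipped with a warning.
#'
#' @param path Path to the BLAST tabular file.
#' @param sites A [site_set] whose sites are to be mapped.
#' @param chains Named list of chains keyed `"<pdb_id>:<chain_id>"` for the
#'   identity check.
#' @param evalue_max Maximum E-value (default 1e-25).
#' @return data.frame of mapping candidates (`method = "alignment"`).
#' @export
read_blast_tab <- function(path, sites, chains, evalue_max = 1e-25) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- cols[seq_len(ncol(tab))]
  rec <- sites$records
  out <- list()
  n_gapped <- 0L
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$evalue > evalue_max) next
    if (r$gapopen > 0) { n_gapped <- n_gapped + 1L; next }
    pc <- strsplit(r$sseqid, "_")[[1]]
    ch <- chains[[chain_key(pc[1], pc[2])]]
    if (is.null(ch)) next
    hit <- which(rec$protein_id == r$qseqid &
                   rec$position >= r$qstart & rec$position <= r$qend)
    for (h in hit) {
      spos <- r$sstart + (rec$position[h] - r$qstart)
      if (substr(ch$full_sequence, spos, spos) != rec$residue[h]) next
      out[[length(out) + 1]] <- data.frame(
        protein_id = rec$protein_id[h], position = rec$position[h],
        residue = rec$residue[h], pdb_id = ch$pdb_id,
        chain_id = ch$chain_id, chain_seq_index = as.integer(spos),
        method = "alignment", evalue = r$evalue,
        coverage = (r$qend - r$qstart + 1) /
          nchar(sites$sequences[[rec$protein_id[h]]]),
        identity_at_window = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (n_gapped)
    warning(n_gapped, " gapped HSP(s) skipped (positions not mappable from ",
            "tabular output)")
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

#' Select the single best mapping candidate per site
#'
#' Table-based candidates outrank alignment-based ones. Among table
#' candidates the highest coverage wins; among alignment candidates the
#' lowest (best) E-value wins. Exact ties are broken deterministically by
#' lexicographic (pdb_id, chain_id).
#'
#' @param cands Candidate data.frame from [map_by_table()],
#'   [map_by_alignment()] or [read_blast_tab()] (rbind-able).
#' @return data.frame with one row per (protein_id, position).
#' @export
select_best_candidate <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  key <- paste(cands$protein_id, cands$position)
  picked <- lapply(split(seq_len(nrow(cands)), key), function(idx) {
    d <- cands[idx, , drop = FALSE]
    tab <- d[d$method == "table", , drop = FALSE]
    if (nrow(tab)) {
      tab <- tab[order(-tab$coverage, tab$pdb_id, tab$chain_id), ,
                 drop = FALSE]
      tab[1, , drop = FALSE]
    } else {
      d <- d[order(d$evalue, d$pdb_id, d$chain_id), , drop = FALSE]
      d[1, , drop = FALSE]
    }
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write selected mappings to CSV
#'
#' @param mapping data.frame from [select_best_candidate()].
#' @param path Output path.
#' @export
write_mapping <- function(mapping, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 1-based; chain_seq_index is in SEQRES space",
             con)
  utils::write.csv(mapping, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
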