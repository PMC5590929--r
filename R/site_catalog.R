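# Site catalogs: modified (MSS-style), unmodified (USS-style) and background
# serine/threonine site sets built from sequence-level inputs.

GAP_CHAR <- "-"

#' Construct a site set
#'
#' A site set couples a table of PTM (or background) sites with the full
#' protein sequences they live on. Positions are 1-based in sequence space
#' throughout the package.
#'
#' @param records data.frame with columns `protein_id`, `position`, `residue`,
#'   `flank7`, `source_label`.
#' @param sequences Named character vector of full amino-acid sequences,
#'   names are protein accessions.
#' @param name Set name, conventionally one of `"MSS"`, `"USS"`, `"GS"` or
#'   `"user"`.
#' @return Object of class `site_set`.
#' @export
site_set <- function(records, sequences, name = "user") {
  stopifnot(is.data.frame(records), is.character(sequences))
  needed <- c("protein_id", "position", "residue", "flank7", "source_label")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  no_seq <- setdiff(unique(records$protein_id), names(sequences))
  if (length(no_seq))
    stop("no sequence for accession(s): ", paste(no_seq, collapse = ", "))
  bad <- which(records$position < 1 |
                 records$position > nchar(sequences[records$protein_id]))
  if (length(bad))
    stop("position out of sequence range for ", length(bad), " record(s)")
  seq_res <- substr(sequences[records$protein_id],
                    records$position, records$position)
  if (any(seq_res != records$residue))
    stop("residue column disagrees with sequence for ",
         sum(seq_res != records$residue), " record(s)")
  structure(list(name = name,
                 records = records[, needed],
                 sequences = sequences),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set '%s'> %d sites on %d proteins\n",
              x$name, nrow(x$records), length(unique(x$records$protein_id))))
  invisible(x)
}

#' @export
length.site_set <- function(x) nrow(x$records)

#' Extract the 7-residue flank of a sequence position
#'
#' Positions -3..+3 around `position`; out-of-range positions are padded with
#' `"-"` so the central residue is always the 4th character.
#'
#' @param sequence Full amino-acid sequence (single string).
#' @param position 1-based site position.
#' @return 7-character string.
#' @export
flank7 <- function(sequence, position) {
  n <- nchar(sequence)
  stopifnot(position >= 1, position <= n)
  idx <- (position - 3):(position + 3)
  chars <- ifelse(idx < 1 | idx > n, GAP_CHAR,
                  substring(sequence, idx, idx))
  paste(chars, collapse = "")
}

#' Extract aligned flanks of arbitrary half-width from a site set
#'
#' Like the `flank7` column but for any half-width: windows of width
#' `2 * half_width + 1` centred on each site, gap-padded (`"-"`) at the
#' termini.
#'
#' @param s A [site_set].
#' @param half_width Residues either side of the site.
#' @return Character vector of aligned windows, one per record.
#' @export
site_flanks <- function(s, half_width = 7) {
  stopifnot(inherits(s, "site_set"), half_width >= 0)
  vapply(seq_len(nrow(s$records)), function(i) {
    seqc <- s$sequences[[s$records$protein_id[i]]]
    pos <- s$records$position[i]
    n <- nchar(seqc)
    idx <- (pos - half_width):(pos + half_width)
    paste(ifelse(idx < 1 | idx > n, GAP_CHAR, substring(seqc, idx, idx)),
          collapse = "")
  }, character(1))
}

#' Load a site table and its sequences into a site set
#'
#' Reads a CSV/TSV site table (columns `protein_id`, `position`, optionally
#' `residue` and `source`) plus a FASTA file of full-length sequences, builds
#' `flank7` windows from the sequences, and keeps only rows whose sequence
#' residue is serine or threonine (unless `restrict_st = FALSE`).
#'
#' @param path Path to the site table (comma- or tab-separated, with header).
#' @param sequences Path to a FASTA file covering every `protein_id`, or a
#'   named character vector of sequences.
#' @param name Name for the resulting set.
#' @param restrict_st Keep only S/T sites (default `TRUE`).
#' @return A [site_set]. The number of rejected rows (non-S/T residue or
#'   out-of-range position) is reported via `message()` and stored in the
#'   `n_rejected` attribute.
#' @export
load_site_table <- function(path, sequences, name = "user",
                            restrict_st = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         sep = if (grepl("\\.tsv$", path)) "\t" else ",")
  if (!all(c("protein_id", "position") %in% names(tab)))
    stop("site table must have columns protein_id and position")
  seqs <- if (is.character(sequences) && length(sequences) == 1 &&
                file.exists(sequences)) read_fasta_seqs(sequences)
          else sequences
  missing_acc <- setdiff(unique(tab$protein_id), names(seqs))
  if (length(missing_acc))
    stop("missing sequence for: ", paste(missing_acc, collapse = ", "))

  n0 <- nrow(tab)
  out_of_range <- tab$position < 1 |
    tab$position > nchar(seqs[tab$protein_id])
  if (any(out_of_range))
    warning(sum(out_of_range), " record(s) rejected: position beyond sequence")
  tab <- tab[!out_of_range, , drop = FALSE]
  res <- substr(seqs[tab$protein_id], tab$position, tab$position)
  keep <- if (restrict_st) res %in% c("S", "T") else rep(TRUE, nrow(tab))
  n_rejected <- n0 - sum(keep)
  if (any(!keep))
    message(sum(!keep), " record(s) rejected: sequence residue not S/T")
  tab <- tab[keep, , drop = FALSE]
  res <- res[keep]
  records <- data.frame(
    protein_id = tab$protein_id,
    position = as.integer(tab$position),
    residue = res,
    flank7 = vapply(seq_len(nrow(tab)), function(i)
      flank7(seqs[[tab$protein_id[i]]], tab$position[i]), character(1)),
    source_label = if ("source" %in% names(tab)) tab$source else name,
    stringsAsFactors = FALSE)
  s <- site_set(records, seqs[unique(records$protein_id)], name = name)
  attr(s, "n_rejected") <- n_rejected
  s
}

read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Keep one site per unique 7-residue motif
#'
#' Removes records whose flank has a central gap, then keeps the first
#' occurrence (stable input order) of each distinct `flank7` string.
#' Idempotent.
#'
#' @param s A [site_set].
#' @return A [site_set] with deduplicated records.
#' @export
filter_unique_motifs <- function(s) {
  stopifnot(inherits(s, "site_set"))
  rec <- s$records
  rec <- rec[substr(rec$flank7, 4, 4) != GAP_CHAR, , drop = FALSE]
  rec <- rec[!duplicated(rec$flank7), , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rec) == 0)
    return(structure(list(name = s$name, records = rec,
                          sequences = s$sequences), class = "site_set"))
  site_set(rec, s$sequences[unique(rec$protein_id)], name = s$name)
}

#' Derive the unmodified S/T background from a modified set
#'
#' Enumerates every serine/threonine position in every sequence of the
#' modified set that is not itself a modified position, mirroring the
#' construction of an "unmodified sequence sites" background from the same
#' proteins.
#'
#' @param modified A [site_set] of modified sites.
#' @param name Name for the derived set (default `"USS"`).
#' @return A [site_set] of background sites.
#' @export
derive_unmodified_set <- function(modified, name = "USS") {
  stopifnot(inherits(modified, "site_set"))
  seqs <- modified$sequences
  mod_key <- paste(modified$records$protein_id, modified$records$position)
  recs <- lapply(names(seqs), function(pid) {
    chars <- strsplit(seqs[[pid]], "")[[1]]
    pos <- which(chars %in% c("S", "T"))
    pos <- pos[!(paste(pid, pos) %in% mod_key)]
    if (!length(pos)) return(NULL)
    data.frame(protein_id = pid, position = pos, residue = chars[pos],
               flank7 = vapply(pos, function(p) flank7(seqs[[pid]], p),
                               character(1)),
               source_label = "derived_unmodified",
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, recs)
  if (is.null(rec))
    rec <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), flank7 = character(),
                      source_label = character(), stringsAsFactors = FALSE)
  structure(list(name = name, records = rec, sequences = seqs),
            class = "site_set")
}

#' Trim a sequence around a site for length-limited predictors
#'
#' Some secondary-structure predictors reject sequences longer than ~800
#' residues. This trims the sequence to at most `max_len` residues while
#' keeping the site at least `margin` residues away from each terminus
#' whenever the full sequence allows it. The window is centred on the site
#' and shifted to fit the sequence bounds.
#'
#' @param sequence Full amino-acid sequence (single string).
#' @param site_position 1-based site position within `sequence`.
#' @param max_len Maximum returned length (default 800).
#' @param margin Minimum distance from each terminus (default 100).
#' @return List with `sequence` (trimmed string) and `new_position`
#'   (1-based site index in the trimmed sequence).
#' @export
trim_for_predictor <- function(sequence, site_position,
                               max_len = 800, margin = 100) {
  n <- nchar(sequence)
  stopifnot(site_position >= 1, site_position <= n)
  if (n < 2 * margin) {
    warning("sequence shorter than twice the margin; returned unchanged")
    return(list(sequence = sequence, new_position = site_position))
  }
  if (n <= max_len)
    return(list(sequence = sequence, new_position = site_position))
  start <- site_position - (max_len %/% 2) + 1
  start <- max(1, min(start, n - max_len + 1))
  end <- start + max_len - 1
  list(sequence = substr(sequence, start, end),
       new_position = site_position - start + 1)
}

#' Write a site set to CSV
#'
#' Columns `protein_id,position,residue,flank7,source` with 1-based positions
#' (stated in a header comment line).
#'
#' @param s A [site_set].
#' @param path Output path.
#' @export
write_site_set <- function(s, path) {
  stopifnot(inherits(s, "site_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 1-based in full-sequence space", con)
  rec <- s$records
  names(rec)[names(rec) == "source_label"] <- "source"
  utils::write.csv(rec, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
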