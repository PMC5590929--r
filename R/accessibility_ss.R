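# Secondary structure and solvent accessibility: DSSP file parsing, the
# 8-state -> 3-state reduction, RSA normalisation and binning, plus built-in
# geometric fallbacks (sphere-sampling ASA and a dihedral-based 3-state
# assigner) for inputs without DSSP files.

SS8_TOKENS <- c("G", "H", "I", "S", "T", "B", "E", " ")

#' Parse a classic DSSP output file
#'
#' Reads the fixed-column residue records of a DSSP text file and returns
#' one row per residue with the 8-state secondary-structure code and the
#' absolute accessible surface area. Chain-break records (`!`) are skipped.
#'
#' @param path Path to a DSSP output file (classic text format).
#' @return data.frame with columns `chain`, `author_number`, `aa`, `ss8`
#'   (blank stored as `" "`), `asa` (square Angstroms).
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1)
    stop("not a classic DSSP file (residue header not found): ", path)
  rows <- lines[(start + 1):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[[i]]
    if (nchar(ln) < 38)
      stop("malformed DSSP record at line ", start + i, " of ", path)
    aa <- substr(ln, 14, 14)
    if (aa == "!") next  # chain break
    num <- suppressWarnings(as.integer(substr(ln, 6, 10)))
    if (is.na(num))
      stop("malformed DSSP record at line ", start + i, " of ", path)
    acc <- suppressWarnings(as.numeric(substr(ln, 35, 38)))
    if (is.na(acc))
      stop("malformed DSSP record at line ", start + i, " of ", path)
    out[[i]] <- data.frame(
      chain = substr(ln, 12, 12),
      author_number = paste0(num, trimws(substr(ln, 11, 11))),
      aa = aa,
      ss8 = substr(ln, 17, 17),
      asa = acc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Reduce 8-state secondary structure to 3 states
#'
#' G and H become helix (H); I, B and E become strand (E); everything else,
#' including residues with no assignment, becomes coil (C). Note the
#' pi-helix (I) -> strand mapping is deliberate and follows the convention
#' used by the analysis this package implements, not the more common
#' I -> helix reduction.
#'
#' @param ss8 Character vector of 8-state tokens (`G H I S T B E` or `" "`/
#'   `""` for no assignment).
#' @return Character vector of `"H"`, `"E"` or `"C"`.
#' @export
reduce_ss8_to_ss3 <- function(ss8) {
  ss8[ss8 == ""] <- " "
  bad <- !ss8 %in% SS8_TOKENS
  if (any(bad))
    stop("unknown secondary-structure token(s): ",
         paste(unique(ss8[bad]), collapse = ", "))
  out <- rep("C", length(ss8))
  out[ss8 %in% c("G", "H")] <- "H"
  out[ss8 %in% c("I", "B", "E")] <- "E"
  out
}

#' Normalise absolute accessibility to RSA
#'
#' Divides the absolute accessible surface area by the residue type's
#' maximum accessible area. Values above 1 can occur with some scales and
#' are kept (and reported via `message`).
#'
#' @param asa Absolute accessible surface area (square Angstroms).
#' @param aa One-letter residue code(s).
#' @param scale Max-ASA scale, see [max_asa_table()].
#' @return Numeric RSA (fraction); `NA` with a warning for residues not in
#'   the table.
#' @export
normalise_rsa <- function(asa, aa, scale = "tien2013") {
  tab <- max_asa_table(scale)
  mx <- tab[aa]
  unknown <- is.na(mx)
  if (any(unknown))
    warning("no max-ASA value for residue(s): ",
            paste(unique(aa[unknown]), collapse = ", "))
  rsa <- as.numeric(asa) / as.numeric(mx)
  if (any(rsa > 1, na.rm = TRUE))
    message(sum(rsa > 1, na.rm = TRUE), " RSA value(s) > 1 (kept)")
  unname(rsa)
}

#' Bin RSA into buried / partially buried / exposed
#'
#' Buried when RSA <= 0.05, partially buried when 0.05 < RSA <= 0.25,
#' exposed when RSA > 0.25 (both cut-offs boundary-inclusive on the lower
#' bin).
#'
#' @param rsa Numeric RSA values (>= 0).
#' @return Character vector in `c("buried", "partial", "exposed")`.
#' @export
bin_rsa <- function(rsa) {
  stopifnot(all(rsa >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(rsa))
  out[rsa <= 0.05] <- "buried"
  out[rsa > 0.05 & rsa <= 0.25] <- "partial"
  out[rsa > 0.25] <- "exposed"
  out
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sphere-sampling accessible surface area
#'
#' Computes per-residue solvent-accessible surface area by deterministic
#' sphere-point sampling (Shrake-Rupley) over the stored heavy atoms
#' (N, CA, C, O, CB). A surface point on an atom's solvent-expanded sphere
#' is accessible when it lies outside every other atom's expanded sphere.
#' Intended for synthetic or backbone-only models; for full-atom structures
#' supply DSSP files instead.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @param probe Probe radius in Angstroms (default 1.4, water).
#' @param points Number of sample points per atom (default 960).
#' @return Numeric vector of per-residue ASA (square Angstroms), `NA` for
#'   residues without all heavy-atom coordinates present (skipped with a
#'   warning) and for unobserved residues.
#' @export
shrake_rupley_asa <- function(chain, probe = 1.4, points = 960) {
  stopifnot(inherits(chain, "annotated_chain"))
  res <- chain$residues
  atoms <- list(n = "N", ca = "C", c = "C", o = "O", cb = "C")
  coords <- NULL; radii <- NULL; res_of <- NULL
  incomplete <- integer(0)
  for (j in seq_len(nrow(res))) {
    if (!res$observed[j]) next
    have <- vapply(names(atoms), function(a) !is.na(res[[paste0(a, "_x")]][j]),
                   logical(1))
    # glycine legitimately lacks CB
    need <- names(atoms)
    if (res$aa[j] == "G") need <- setdiff(need, "cb")
    if (!all(have[need])) {
      incomplete <- c(incomplete, j)
      next
    }
    for (a in need) {
      coords <- rbind(coords, c(res[[paste0(a, "_x")]][j],
                                res[[paste0(a, "_y")]][j],
                                res[[paste0(a, "_z")]][j]))
      radii <- c(radii, VDW_RADII[[atoms[[a]]]])
      res_of <- c(res_of, j)
    }
  }
  if (length(incomplete))
    warning(length(incomplete),
            " residue(s) skipped in ASA calculation (missing heavy atoms)")
  out <- rep(NA_real_, nrow(res))
  if (is.null(coords)) return(out)
  sphere <- fibonacci_sphere(points)
  er <- radii + probe
  na <- nrow(coords)
  asa_atom <- numeric(na)
  for (i in seq_len(na)) {
    pts <- sweep(sphere * er[i], 2, coords[i, ], `+`)
    # neighbours whose expanded sphere could occlude
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (er + er[i])^2 & seq_len(na) != i)
    acc <- rep(TRUE, points)
    for (j in nb) {
      dj2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & dj2 > er[j]^2
      if (!any(acc)) break
    }
    asa_atom[i] <- 4 * pi * er[i]^2 * mean(acc)
  }
  for (j in unique(res_of))
    out[j] <- sum(asa_atom[res_of == j])
  out[incomplete] <- NA_real_
  out
}

#' Dihedral-based 3-state secondary structure assignment
#'
#' A simple phi/psi-window assigner for models without DSSP files: a residue
#' is helix (H) when it and both neighbours have phi in [-100, -30] and psi
#' in [-80, -5] degrees; strand (E) when all three have phi in [-180, -40]
#' and psi in [90, 180]; otherwise coil (C). Chain termini and residues with
#' incomplete backbone are C. Outputs using this assigner are labelled
#' non-DSSP.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @return Character vector of `"H"`, `"E"`, `"C"` per full-sequence
#'   position.
#' @export
dihedral_ss3 <- function(chain) {
  stopifnot(inherits(chain, "annotated_chain"))
  res <- chain$residues
  n <- nrow(res)
  get <- function(j, a) c(res[[paste0(a, "_x")]][j],
                          res[[paste0(a, "_y")]][j],
                          res[[paste0(a, "_z")]][j])
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (!res$observed[j]) next
    if (j > 1 && res$observed[j - 1] &&
        !anyNA(c(get(j - 1, "c"), get(j, "n"), get(j, "ca"), get(j, "c"))))
      phi[j] <- dihedral_angle(get(j - 1, "c"), get(j, "n"),
                               get(j, "ca"), get(j, "c"))
    if (j < n && res$observed[j + 1] &&
        !anyNA(c(get(j, "n"), get(j, "ca"), get(j, "c"), get(j + 1, "n"))))
      psi[j] <- dihedral_angle(get(j, "n"), get(j, "ca"),
                               get(j, "c"), get(j + 1, "n"))
  }
  in_h <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  in_e <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -40 & psi >= 90 & psi <= 180
  ss <- rep("C", n)
  for (j in seq_len(n)) {
    if (j == 1 || j == n) next
    if (in_h[j] && in_h[j - 1] && in_h[j + 1]) ss[j] <- "H"
    else if (in_e[j] && in_e[j - 1] && in_e[j + 1]) ss[j] <- "E"
  }
  ss
}

#' Annotate a chain with SS3 and RSA
#'
#' Convenience wrapper combining a DSSP table (when given) or the built-in
#' fallbacks with RSA normalisation and binning.
#'
#' @param chain An [annotated_chain][parse_chain].
#' @param dssp Optional data.frame from [parse_dssp()] for this structure.
#' @param scale Max-ASA scale name.
#' @param probe,points Passed to [shrake_rupley_asa()] when no DSSP table is
#'   given.
#' @return data.frame with one row per full-sequence position: `seq_index`,
#'   `author_number`, `aa`, `ss8` (NA for the fallback assigner), `ss3`,
#'   `asa`, `rsa`, `rsa_bin`, plus attribute `asa_source` (`"dssp"` or
#'   `"shrake_rupley"`) and `max_asa_scale`.
#' @export
annotate_ss_rsa <- function(chain, dssp = NULL, scale = "tien2013",
                            probe = 1.4, points = 960) {
  res <- chain$residues
  out <- res[, c("seq_index", "author_number", "aa")]
  if (!is.null(dssp)) {
    d <- dssp[dssp$chain == chain$chain_id, , drop = FALSE]
    m <- match(out$author_number, d$author_number)
    out$ss8 <- d$ss8[m]
    out$ss3 <- ifelse(is.na(m), NA, reduce_ss8_to_ss3(ifelse(is.na(out$ss8),
                                                             " ", out$ss8)))
    out$asa <- d$asa[m]
    src <- "dssp"
  } else {
    out$ss8 <- NA_character_
    ss3 <- dihedral_ss3(chain)
    out$ss3 <- ifelse(res$observed, ss3, NA)
    out$asa <- shrake_rupley_asa(chain, probe = probe, points = points)
    src <- "shrake_rupley"
  }
  out$rsa <- ifelse(is.na(out$asa), NA,
                    suppressWarnings(normalise_rsa(out$asa, out$aa, scale)))
  out$rsa_bin <- ifelse(is.na(out$rsa), NA, bin_rsa(pmax(out$rsa, 0)))
  attr(out, "asa_source") <- src
  attr(out, "max_asa_scale") <- scale
  out
}

#' Write an SS/RSA annotation table to CSV
#'
#' Columns `chain,author_number,aa,ss8,ss3,asa,rsa,rsa_bin`, with the ASA
#' source and max-ASA scale recorded in header comment lines.
#'
#' @param annotation Output of [annotate_ss_rsa()].
#' @param chain_id Chain identifier for the first column.
#' @param path Output path.
#' @export
write_ss_rsa_annotation <- function(annotation, chain_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# asa_source=", attr(annotation, "asa_source")),
               paste0("# max_asa_scale=", attr(annotation, "max_asa_scale"))),
             con)
  out <- cbind(chain = chain_id,
               annotation[, c("author_number", "aa", "ss8", "ss3",
                              "asa", "rsa", "rsa_bin")])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
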