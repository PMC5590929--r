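# Positional profiles around sites: per-offset sequence relative entropy
# (sequence-logo statistic) and per-offset disorder log-odds enrichment.

new_positional_profile <- function(df, statistic_name) {
  stopifnot(all(df$ci_low <= df$value + 1e-12),
            all(df$ci_high >= df$value - 1e-12))
  attr(df, "statistic_name") <- statistic_name
  class(df) <- c("positional_profile", "data.frame")
  df
}

#' Positional relative-entropy profile of aligned site windows
#'
#' For each offset around the central residue, computes the Kullback-Leibler
#' divergence (in bits) of the column's amino-acid frequencies from a
#' background distribution:
#' \deqn{R_i = \sum_a p_{a,i} \log_2(p_{a,i} / q_a)}
#' Column frequencies are smoothed with a background-proportional Dirichlet
#' prior of total mass `pseudocount_mass` (10 by default, i.e. 0.5 per amino
#' acid under a uniform background), so a column whose observed frequencies
#' equal the background scores exactly zero. Gap-padded positions are
#' excluded from the counts. The 95% confidence band is a percentile
#' bootstrap over sites.
#'
#' @param flanks Character vector of aligned windows (equal odd width,
#'   central residue in the middle; `"-"` marks gap padding).
#' @param background_freqs Named numeric vector over the 20 amino acids,
#'   summing to 1.
#' @param reps Bootstrap resamples for the confidence band (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param pseudocount_mass Total Dirichlet prior mass (default 10).
#' @return A `positional_profile` data.frame with columns `offset`, `value`,
#'   `ci_low`, `ci_high`, `n` (usable sequences per offset);
#'   `attr(,"statistic_name")` is `"relative_entropy_bits"`.
#' @export
relative_entropy_profile <- function(flanks, background_freqs, reps = 200,
                                     seed = 1, pseudocount_mass = 10) {
  width <- unique(nchar(flanks))
  stopifnot(length(width) == 1, width %% 2 == 1)
  q <- background_freqs[AA_20]
  if (anyNA(q) || abs(sum(q) - 1) > 1e-6)
    stop("background_freqs must cover the 20 amino acids and sum to 1")
  w <- (width - 1) / 2
  mat <- do.call(rbind, strsplit(flanks, ""))

  col_entropy <- function(chars) {
    chars <- chars[chars %in% AA_20]
    n <- length(chars)
    if (n == 0) return(c(NA_real_, 0))
    counts <- table(factor(chars, levels = AA_20))
    qn <- as.numeric(q)
    p <- (as.numeric(counts) + pseudocount_mass * qn) /
      (n + pseudocount_mass)
    # KL conventions: 0 log(0/q) = 0; p > 0 against q = 0 diverges
    terms <- numeric(20)
    pos <- p > 0
    terms[pos & qn > 0] <- p[pos & qn > 0] *
      log2(p[pos & qn > 0] / qn[pos & qn > 0])
    if (any(pos & qn == 0)) return(c(Inf, n))
    c(sum(terms), n)
  }

  base <- apply(mat, 2, col_entropy)
  value <- base[1, ]
  n_col <- base[2, ]

  set.seed(seed)
  boot <- matrix(NA_real_, reps, width)
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
    boot[r, ] <- apply(mat[idx, , drop = FALSE], 2, col_entropy)[1, ]
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  keep <- !is.na(value)
  df <- data.frame(offset = (-w):w, value = value,
                   ci_low = pmin(ci[1, ], value),
                   ci_high = pmax(ci[2, ], value),
                   n = as.integer(n_col))[keep, , drop = FALSE]
  rownames(df) <- NULL
  new_positional_profile(df, "relative_entropy_bits")
}

#' Amino-acid background frequencies from sequences
#'
#' @param sequences Character vector of amino-acid sequences.
#' @return Named frequency vector over the 20 standard amino acids.
#' @export
aa_background_freqs <- function(sequences) {
  chars <- unlist(strsplit(paste(sequences, collapse = ""), ""))
  counts <- table(factor(chars[chars %in% AA_20], levels = AA_20))
  stats::setNames(as.numeric(counts) / sum(counts), AA_20)
}

#' Disorder log-odds enrichment profile around sites
#'
#' For each offset `d` in `-window..window`, classifies the residue at
#' `site position + d` of every target and background site as disordered
#' (score >= method threshold) and computes the log10 odds ratio of disorder
#' between target and background, with a Haldane +0.5 correction when a cell
#' is zero and a 95% Wald band on the log-odds scale.
#'
#' @param target_tracks,background_tracks Named lists (by `protein_id`) of
#'   [disorder_track] objects, all from the same method.
#' @param target_sites,background_sites data.frames with columns
#'   `protein_id`, `position` (1-based).
#' @param window Profile half-width in residues (default 50).
#' @return A `positional_profile` data.frame (`offset`, `value`, `ci_low`,
#'   `ci_high`, `n_target`, `n_background`); offsets with no coverage on
#'   either side are dropped. `attr(,"statistic_name")` is
#'   `"log10_odds_ratio"`.
#' @export
disorder_odds_profile <- function(target_tracks, target_sites,
                                  background_tracks, background_sites,
                                  window = 50) {
  methods <- unique(c(vapply(target_tracks, `[[`, character(1), "method"),
                      vapply(background_tracks, `[[`, character(1),
                             "method")))
  if (length(methods) != 1)
    stop("target and background tracks must come from the same method; got ",
         paste(methods, collapse = ", "))

  count_side <- function(tracks, sites, d) {
    dis <- 0L; tot <- 0L
    for (k in seq_len(nrow(sites))) {
      tr <- tracks[[sites$protein_id[k]]]
      if (is.null(tr)) next
      p <- sites$position[k] + d
      if (p < 1 || p > length(tr$scores)) next
      sc <- tr$scores[p]
      if (is.na(sc)) next
      tot <- tot + 1L
      if (sc >= tr$threshold) dis <- dis + 1L
    }
    c(dis, tot)
  }

  offs <- (-window):window
  rows <- lapply(offs, function(d) {
    t <- count_side(target_tracks, target_sites, d)
    g <- count_side(background_tracks, background_sites, d)
    if (t[2] == 0 || g[2] == 0) return(NULL)
    a <- t[1]; b <- t[2] - t[1]; cc <- g[1]; dd <- g[2] - g[1]
    if (any(c(a, b, cc, dd) == 0)) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; dd <- dd + 0.5
    }
    lor <- log10((a * dd) / (b * cc))
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd) / log(10)
    data.frame(offset = d, value = lor,
               ci_low = lor - 1.959964 * se, ci_high = lor + 1.959964 * se,
               n_target = t[2], n_background = g[2])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no offsets with coverage on both sides")
  rownames(df) <- NULL
  new_positional_profile(df, "log10_odds_ratio")
}

#' Write a positional profile to TSV
#'
#' Columns `offset,value,ci_low,ci_high` plus the per-offset counts; the
#' statistic name is recorded in a header comment.
#'
#' @param profile A `positional_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# statistic=", attr(profile, "statistic_name")), con)
  utils::write.table(profile, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
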