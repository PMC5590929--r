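# Statistics: contingency enrichment, proportion tests and intervals, score
# comparisons, and the disorder-track classification machinery.

DISORDER_THRESHOLDS <- c(
  "DisEMBL-REM465" = 0.6,
  "DisEMBL-COILS" = 0.516,
  "DisEMBL-HOTLOOPS" = 0.1204,
  "IUPred-Long" = 0.5,
  "IUPred-Short" = 0.5,
  "JRonn" = 0.5)

#' Fisher's exact test with the sample odds ratio
#'
#' For a 2x2 table (rows: modified/unmodified; columns: in-state /
#' not-in-state) returns the sample odds ratio a*d / (b*c) and the two-sided
#' exact hypergeometric p-value. When any cell is zero the Haldane +0.5
#' correction is applied to the odds ratio (flagged in the result); the
#' p-value always uses the uncorrected counts.
#'
#' @param a,b,c,d Non-negative integer counts: `a` modified in-state, `b`
#'   modified not-in-state, `c` unmodified in-state, `d` unmodified
#'   not-in-state. Alternatively `a` may be a 2x2 matrix.
#' @return List with `odds_ratio`, `p_value`, `haldane` (logical) and
#'   `table`.
#' @export
fisher_exact_or <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2, 2))) stop("contingency table must be 2x2")
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2,
                  dimnames = list(c("modified", "unmodified"),
                                  c("in_state", "not_in_state")))
  }
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = unname(or), p_value = p, haldane = haldane, table = tab)
}

#' Two-proportion z-test (pooled variance)
#'
#' Two-tailed z-score test between two proportions using the pooled variance
#' estimate, as used for the predicted secondary-structure and accessibility
#' comparisons between modified and background site sets.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is 0 or 1; test degenerate, p = 1")
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' p-hat +/- z * sqrt(p-hat (1 - p-hat) / n), clipped to [0, 1].
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

#' Compare score distributions between modified and unmodified groups
#'
#' Either a two-tailed Welch t-test (as for mean disorder-score tables) or a
#' Kruskal-Wallis two-sample test (as for standardised B-factor
#' distributions).
#'
#' @param modified_scores,unmodified_scores Numeric vectors (each length
#'   >= 2).
#' @param test `"t"` or `"kruskal_wallis"`.
#' @return List with `statistic`, `p_value`, `means` (named length-2),
#'   `standard_errors` (named length-2), `test`.
#' @export
score_comparison <- function(modified_scores, unmodified_scores,
                             test = c("t", "kruskal_wallis")) {
  test <- match.arg(test)
  x <- modified_scores[!is.na(modified_scores)]
  y <- unmodified_scores[!is.na(unmodified_scores)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (test == "t") {
    ht <- stats::t.test(x, y)
  } else {
    if (stats::sd(c(x, y)) == 0)
      stop("constant scores: Kruskal-Wallis test undefined")
    ht <- stats::kruskal.test(list(x, y))
  }
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       means = c(modified = mean(x), unmodified = mean(y)),
       standard_errors = c(modified = stats::sd(x) / sqrt(length(x)),
                           unmodified = stats::sd(y) / sqrt(length(y))),
       test = test)
}

#' Construct a per-protein disorder-score track
#'
#' @param protein_id Accession.
#' @param method One of the six supported predictor scores
#'   (`r paste(names(DISORDER_THRESHOLDS), collapse = ", ")`), or any other
#'   label if `threshold` is given explicitly.
#' @param scores Numeric per-residue scores (length = sequence length).
#' @param threshold Disorder cut-off; defaults to the method author's
#'   published value for the six known methods.
#' @return Object of class `disorder_track`.
#' @export
disorder_track <- function(protein_id, method, scores, threshold = NULL) {
  if (is.null(threshold)) {
    if (!method %in% names(DISORDER_THRESHOLDS))
      stop("unknown method '", method, "': supply a threshold")
    threshold <- DISORDER_THRESHOLDS[[method]]
  }
  structure(list(protein_id = protein_id, method = method,
                 scores = as.numeric(scores), threshold = threshold),
            class = "disorder_track")
}

#' Classify a track position as ordered or disordered
#'
#' A residue is disordered when its score is greater than or equal to the
#' method threshold (boundary inclusive).
#'
#' @param track A [disorder_track].
#' @param position 1-based residue position (vectorised).
#' @return Logical vector.
#' @export
classify_disordered <- function(track, position) {
  stopifnot(inherits(track, "disorder_track"),
            all(position >= 1), all(position <= length(track$scores)))
  sc <- track$scores[position]
  if (anyNA(sc) || any(is.nan(sc)))
    stop("NaN/NA score at requested position(s)")
  sc >= track$threshold
}

#' Read disorder tracks from CSV
#'
#' Long-format CSV with columns `protein_id,position,method,score`.
#'
#' @param path Input path.
#' @param thresholds Optional named vector overriding the per-method default
#'   thresholds.
#' @return Nested list: `tracks[[method]][[protein_id]]` is a
#'   [disorder_track].
#' @export
read_disorder_tracks <- function(path, thresholds = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("protein_id", "position", "method", "score") %in%
                  names(tab)))
  out <- list()
  for (m in unique(tab$method)) {
    sub <- tab[tab$method == m, ]
    thr <- if (!is.null(thresholds) && m %in% names(thresholds))
      thresholds[[m]] else NULL
    out[[m]] <- lapply(split(sub, sub$protein_id), function(d) {
      d <- d[order(d$position), ]
      if (!identical(d$position, seq_len(max(d$position))) &&
          !all(d$position == seq_along(d$position)))
        stop("track positions must be 1..L for ", d$protein_id[1])
      disorder_track(d$protein_id[1], m, d$score, threshold = thr)
    })
  }
  out
}

#' Write disorder tracks to CSV
#'
#' @param tracks List of [disorder_track] objects (or a nested
#'   method -> protein list as returned by [read_disorder_tracks()]).
#' @param path Output path.
#' @export
write_disorder_tracks <- function(tracks, path) {
  if (length(tracks) && inherits(tracks[[1]], "disorder_track"))
    tracks <- list(tracks)
  rows <- list()
  for (grp in tracks)
    for (tr in grp)
      rows[[length(rows) + 1]] <-
        data.frame(protein_id = tr$protein_id,
                   position = seq_along(tr$scores),
                   method = tr$method, score = tr$scores,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 1-based in full-sequence space", con)
  utils::write.csv(do.call(rbind, rows), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
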