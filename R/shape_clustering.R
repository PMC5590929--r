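# Pairwise Kabsch superposition of site windows, complete-linkage RMSD
# clustering with a cluster-diameter guarantee, consensus secondary
# structure, and the bootstrap null over background windows.

#' Minimum RMSD under rigid-body superposition (Kabsch)
#'
#' Computes the least-squares root-mean-square deviation between two
#' corresponded point sets after optimal rotation and translation. The
#' rotation is constrained to be proper (determinant +1) by sign-correcting
#' the smallest singular vector, so reflections are never used.
#'
#' @param a,b Numeric n x 3 coordinate matrices with corresponding rows
#'   (for site windows: the 7 C-alphas in offset order plus the central
#'   C-beta).
#' @return RMSD in Angstroms.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b), nrow(a) >= 3)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(bc, ac)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  br <- bc %*% t(rot)
  sqrt(sum((ac - br)^2) / nrow(a))
}

#' Pairwise RMSD matrix over site windows
#'
#' Superimposes every pair of backbone-complete windows with [kabsch_rmsd()]
#' on their 8 superposition atoms.
#'
#' @param windows List of `site_window` objects (all `backbone_complete`),
#'   or a list of n x 3 coordinate matrices. Names are used as window ids;
#'   unnamed inputs get ids `w1..wn`.
#' @return Symmetric matrix of RMSD values (Angstroms) with zero diagonal.
#' @export
pairwise_matrix <- function(windows) {
  stopifnot(length(windows) >= 2)
  coords <- lapply(windows, function(w) {
    if (inherits(w, "site_window")) {
      if (!isTRUE(w$backbone_complete))
        stop("all windows must be backbone-complete; filter upstream")
      w$atoms
    } else as.matrix(w)
  })
  ids <- names(windows)
  if (is.null(ids)) ids <- paste0("w", seq_along(windows))
  n <- length(coords)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
  m
}

#' Complete-linkage clustering of an RMSD matrix
#'
#' Cuts the complete-linkage dendrogram at `threshold`, so every resulting
#' cluster is guaranteed to have all pairwise RMSDs within the threshold
#' (diameter guarantee). Members of size-1 clusters are reported as
#' singlets. Multi-member clusters are labelled `A`, `B`, ... by descending
#' size, ties broken by the lexicographically smallest member id.
#'
#' @param m Symmetric RMSD matrix (e.g. from [pairwise_matrix()]).
#' @param threshold Cut height in Angstroms (default 3.0). Merges at height
#'   <= threshold are kept together.
#' @return Object of class `cluster_result`: list with `clusters` (named
#'   list of member-id vectors, size >= 2), `singlets` (id vector),
#'   `membership` (named vector: cluster label or `"singlet"` per id),
#'   `threshold` and `linkage`.
#' @export
complete_linkage_clusters <- function(m, threshold = 3.0) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), max(abs(m - t(m))) < 1e-9, all(m >= 0))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("w", seq_len(nrow(m)))
  if (nrow(m) == 1) {
    grp <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = "complete")
    grp <- stats::cutree(hc, h = threshold)
    names(grp) <- ids
  }
  sizes <- table(grp)
  multi <- names(sizes)[sizes >= 2]
  members <- lapply(multi, function(g) sort(ids[grp == g]))
  if (length(members)) {
    ord <- order(-vapply(members, length, integer(1)),
                 vapply(members, `[`, character(1), 1))
    members <- members[ord]
    names(members) <- LETTERS[seq_along(members)]
    if (length(members) > 26)
      names(members) <- c(LETTERS,
                          paste0("A", LETTERS))[seq_along(members)]
  } else names(members) <- character(0)
  singlets <- sort(ids[grp %in% names(sizes)[sizes == 1]])
  membership <- stats::setNames(rep("singlet", length(ids)), ids)
  for (lab in names(members)) membership[members[[lab]]] <- lab
  structure(list(clusters = members, singlets = singlets,
                 membership = membership,
                 threshold = threshold, linkage = "complete"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s) holding %d window(s), %d singlet(s), %s linkage at %.2f A\n",
    length(x$clusters), sum(lengths(x$clusters)), length(x$singlets),
    x$linkage, x$threshold))
  invisible(x)
}

#' Consensus 3-state secondary structure of a cluster
#'
#' Per window offset (-3..+3), takes the plurality vote of the members'
#' 3-state codes; ties (including the all-abstain case) give coil (C).
#' Members without an annotation at an offset abstain at that offset.
#'
#' @param members List of 7-character ss3 strings (or character vectors of
#'   length 7); `NA` positions abstain.
#' @return 7-character consensus string over `H`, `E`, `C`.
#' @export
consensus_ss <- function(members) {
  mat <- t(vapply(members, function(s) {
    if (length(s) == 1) s <- strsplit(s, "")[[1]]
    stopifnot(length(s) == 7)
    s
  }, character(7)))
  out <- vapply(seq_len(7), function(k) {
    v <- mat[, k]
    v <- v[!is.na(v) & v %in% c("H", "E", "C")]
    if (!length(v)) return("C")
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) "C" else top
  }, character(1))
  paste(out, collapse = "")
}

#' Bootstrap null distribution of cluster counts
#'
#' Repeatedly samples `n` windows with replacement from a background pool,
#' clusters each sample by complete linkage at `threshold`, and records the
#' number of multi-member clusters. The returned distribution serves as the
#' null against which the observed cluster count of the modified-site
#' windows is compared.
#'
#' @param pool Either a list of backbone-complete windows / coordinate
#'   matrices, or a precomputed pairwise RMSD matrix over the pool (the
#'   matrix form is much faster since resampled pairs reuse its entries).
#' @param n Sample size per replicate (default 132).
#' @param reps Number of replicates (default 1000).
#' @param threshold Clustering cut in Angstroms (default 3.0).
#' @param seed Integer seed; all replicates derive from it.
#' @return List with `counts` (integer vector, length `reps`), `ci`
#'   (2.5 and 97.5 percentiles) and the call parameters.
#' @export
bootstrap_null <- function(pool, n = 132, reps = 1000, threshold = 3.0,
                           seed = 1) {
  if (is.matrix(pool)) {
    m <- pool
  } else {
    m <- pairwise_matrix(pool)
  }
  pool_n <- nrow(m)
  stopifnot(pool_n >= 1)
  if (pool_n < n)
    warning("pool smaller than sample size; sampling with replacement ",
            "from ", pool_n, " windows")
  set.seed(seed)
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(pool_n, n, replace = TRUE)
    sub <- m[idx, idx, drop = FALSE]
    rownames(sub) <- colnames(sub) <- paste0("s", seq_len(n))
    cl <- complete_linkage_clusters(sub, threshold)
    counts[r] <- length(cl$clusters)
  }
  list(counts = counts,
       ci = stats::quantile(counts, c(0.025, 0.975), names = TRUE),
       n = n, reps = reps, threshold = threshold, seed = seed)
}

#' Write an RMSD matrix to CSV
#'
#' Square CSV with window ids as both header and first column.
#'
#' @param m RMSD matrix.
#' @param path Output path.
#' @export
write_rmsd_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write cluster assignments in supplementary-table layout
#'
#' One row per window with columns `PDB,Chain,Position,Cluster,RSA,SS`
#' (Cluster is `singlet` for singlets; RSA/SS optional per-window
#' annotations).
#'
#' @param result A [cluster_result][complete_linkage_clusters].
#' @param window_info data.frame keyed by window id with columns `PDB`,
#'   `Chain`, `Position` and optionally `RSA`, `SS`.
#' @param path Output path.
#' @export
write_cluster_assignments <- function(result, window_info, path) {
  ids <- names(result$membership)
  wi <- window_info[match(ids, rownames(window_info)), , drop = FALSE]
  out <- data.frame(PDB = wi$PDB, Chain = wi$Chain, Position = wi$Position,
                    Cluster = unname(result$membership),
                    RSA = if ("RSA" %in% names(wi)) wi$RSA else NA,
                    SS = if ("SS" %in% names(wi)) wi$SS else NA,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
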