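# Test helpers: an SVD-free brute-force superposition oracle, the Rand
# index, and a builder for in-memory annotated chains from phi/psi angles.

quat_rotation_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force minimum RMSD: random quaternion search plus Nelder-Mead
# refinement of the quaternion parameters. Never touches the SVD path.
oracle_min_rmsd <- function(a, b, n_start = 2000) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  f <- function(q) {
    if (sum(q^2) < 1e-12) return(Inf)
    r <- quat_rotation_matrix(q)
    sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_start), ncol = 4)
  vals <- apply(qs, 1, f)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt2 <- stats::optim(opt$par, f, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  opt2$value
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  pa <- outer(a, a, "==")
  pb <- outer(b, b, "==")
  ut <- upper.tri(pa)
  mean(pa[ut] == pb[ut])
}

# In-memory annotated chain built from phi/psi angles with ideal geometry.
chain_from_angles <- function(phi_psi, aa = NULL, noise_sd = 0, seed = NULL,
                              bfactors = NULL, resolution = 1.5,
                              method = "X-RAY DIFFRACTION",
                              unobserved = integer(0)) {
  n <- nrow(phi_psi)
  pep <- generate_ideal_peptide(phi_psi, noise_sd = noise_sd, seed = seed)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(bfactors)) bfactors <- seq(10, 30, length.out = n)
  res <- data.frame(seq_index = seq_len(n),
                    author_number = as.character(seq_len(n)), aa = aa,
                    observed = TRUE, rem465 = FALSE,
                    ca_bfactor = bfactors, stringsAsFactors = FALSE)
  for (at in c("n", "ca", "c", "o", "cb"))
    for (k in 1:3)
      res[[paste0(at, "_", c("x", "y", "z")[k])]] <-
        vapply(pep, function(r) r[[toupper(at)]][k], numeric(1))
  if (length(unobserved)) {
    res$observed[unobserved] <- FALSE
    res$rem465[unobserved] <- TRUE
    res$ca_bfactor[unobserved] <- NA
    for (col in grep("_[xyz]$", names(res), value = TRUE))
      res[[col]][unobserved] <- NA
    res$author_number[unobserved] <- NA
  }
  structure(list(pdb_id = "TST1", chain_id = "A", resolution = resolution,
                 method = method, full_sequence = paste(aa, collapse = ""),
                 residues = res),
            class = "annotated_chain")
}

angles_for <- function(code, n) {
  a <- switch(code, h = c(-57, -47), e = c(-139, 135), l = c(57, 47))
  m <- matrix(rep(a, each = n), ncol = 2)
  colnames(m) <- c("phi", "psi")
  m
}

random_point_set <- function(n = 8, spread = 3) {
  matrix(stats::rnorm(n * 3, sd = spread), ncol = 3)
}
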