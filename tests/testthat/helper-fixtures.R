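# Shared fixtures and independent oracles for the test suite.

# evenly spaced deterministic map (spacing_bp between markers, 1 chromosome
# unless n_chrom given)
make_test_map <- function(n_markers, spacing_bp = 1e5, n_chrom = 1L,
                          cm_per_mb = 1) {
  per <- n_markers %/% n_chrom
  stopifnot(per * n_chrom == n_markers)
  marker_map(rep(seq_len(n_chrom), each = per),
             rep(seq_len(per) * spacing_bp, n_chrom),
             cm_per_mb = cm_per_mb)
}

# panel from explicit haplotype matrices
make_test_panel <- function(pat, mat, map, breed = "AN", sire = NA_character_,
                            prefix = "ind") {
  n <- nrow(pat)
  haplotype_panel(
    data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
               sire = sire, dam = NA_character_, breed = breed,
               stringsAsFactors = FALSE),
    pat, mat, map
  )
}

# random panel with given allele frequencies (independent sites; only for
# design/solver tests where LD is irrelevant)
random_test_panel <- function(n, freqs, map, breed = "AN") {
  m <- length(freqs)
  draw <- function() matrix(rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  make_test_panel(draw(), draw(), map, breed = breed)
}

# Independent dense oracle for the mixed model
#   y = X beta + Z a + e,  a ~ N(0, Sigma (x) I_M),  e ~ N(0, sigma_e2 I):
# direct inversion of the joint covariance (conditional-mean BLUP), kept
# free of the package's factorized solve path.
oracle_mixed_model <- function(y, X, Zlist, Sigma, sigma_e2) {
  M <- ncol(Zlist[[1L]])
  Zb <- do.call(cbind, Zlist)
  D <- kronecker(Sigma, diag(M))
  V <- Zb %*% D %*% t(Zb) + sigma_e2 * diag(length(y))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- MASS::ginv(XtVi %*% X) %*% (XtVi %*% y)
  a <- D %*% t(Zb) %*% (Vi %*% (y - X %*% beta))
  list(beta = as.numeric(beta),
       a_hat = matrix(as.numeric(a), M, length(Zlist)))
}

# GBLUP oracle for SNP-BLUP equivalence: G = Z Z' sigma_a2, intercept by
# GLS, validation GEBVs through the genomic covariance
oracle_gblup_gebv <- function(y_ref, Z_ref, Z_val, sigma_a2, sigma_e2) {
  G_rr <- tcrossprod(Z_ref) * sigma_a2
  V <- G_rr + sigma_e2 * diag(length(y_ref))
  Vi <- solve(V)
  one <- rep(1, length(y_ref))
  beta <- sum(Vi %*% y_ref) / sum(Vi %*% one)
  w <- Vi %*% (y_ref - beta)
  as.numeric(sigma_a2 * tcrossprod(Z_val, Z_ref) %*% w)
}

# small random BOA instance for solver tests
random_boa_instance <- function(N, M, K = 2L, seed) {
  withr::with_seed(seed, {
    map <- make_test_map(M)
    pat <- matrix(rbinom(N * M, 1L, 0.5), N, M)
    mat <- matrix(rbinom(N * M, 1L, 0.5), N, M)
    opat <- matrix(sample.int(K, N * M, replace = TRUE), N, M)
    omat <- matrix(sample.int(K, N * M, replace = TRUE), N, M)
    panel <- make_test_panel(pat, mat, map)
    om <- origin_map(opat, omat, paste0("G", seq_len(K)))
    y <- rnorm(N)
    design <- build_design(panel, om, y = y)
    r <- runif(1, 0.2, 0.9)
    s2 <- runif(K, 0.05, 0.3)
    sigma <- (r + (1 - r) * diag(K)) * tcrossprod(sqrt(s2))
    list(design = design, vspec = variance_spec(sigma, runif(1, 0.3, 1.5)))
  })
}
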