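# Mixed-model machinery for the origin-split (BOA) model
#
#   y = X beta + sum_k Z_Ak a_k + e,  Cov(a) = Sigma (x) I_M,  Cov(e) = sigma_e2 I
#
# solved either through Henderson's mixed-model equations (dense, for
# KM + K systems of desk scale) or through the equivalent
# individual-space generalized-least-squares route
#   V = sum_kl sigma_kl Z_k Z_l' + sigma_e2 I,
#   beta = (X' V^-1 X)^- X' V^-1 y,  a_k = sum_l sigma_kl Z_l' V^-1 (y - X beta),
# which is cheaper whenever N < K M. Both routes give identical solutions;
# rank-deficient X is handled by a minimum-norm solution.

.solve_psd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(MASS::ginv(A) %*% b)
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

.new_model_fit <- function(beta, a_hat, kind, vspec, design, diagnostics) {
  structure(list(beta_hat = beta, a_hat = a_hat, model_kind = kind,
                 variance_spec = vspec, marker_ids = design$marker_ids,
                 group_labels = design$group_labels,
                 diagnostics = diagnostics),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s): %d markers x %d effect column(s); beta = %s\n",
              x$model_kind, nrow(x$a_hat), ncol(x$a_hat),
              paste(signif(x$beta_hat, 4), collapse = ", ")))
  invisible(x)
}

#' Solve the origin-split mixed-model equations
#'
#' Computes Henderson's BLUE/BLUP solution of the breed-origin model: the
#' coefficient matrix is `[[X'X, X'Z], [Z'X, Z'Z + sigma_e2 (Sigma^-1 (x)
#' I)]]` with `Z = [Z_A1 ... Z_AK]`, right-hand side `[X'y, Z'y]`. With
#' `method = "gls"` the equivalent individual-space system of size `N` is
#' solved instead (identical result, preferred when `N < K M`).
#'
#' @param design A `design_set` from [build_design()] with `y` present.
#' @param vspec A [variance_spec]; `sigma` must be positive definite.
#' @param method `"auto"` (default), `"mme"` or `"gls"`.
#' @return A `model_fit` with `beta_hat` (length `K`), `a_hat` (`M x K`
#'   matrix of origin-specific marker effects), the variance spec used and
#'   solver diagnostics.
#' @export
solve_boa_mme <- function(design, vspec, method = c("auto", "mme", "gls")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "design_set"), inherits(vspec, "variance_spec"))
  y <- design$y
  if (is.null(y)) stop("design has no phenotypes")
  X <- design$X
  Zl <- design$Z
  K <- length(Zl)
  M <- ncol(Zl[[1L]])
  N <- length(y)
  if (N < K) stop("need at least K observations")
  if (!identical(dim(vspec$sigma), c(K, K)) &&
      !(K == 1L && length(vspec$sigma) == 1L)) {
    stop("variance spec dimension does not match the design")
  }
  ev <- eigen(vspec$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("sigma must be strictly positive definite for the solver")
  }
  if (method == "auto") method <- if (N < K * M) "gls" else "mme"
  if (method == "mme") {
    fit <- .boa_mme_dense(y, X, Zl, vspec)
  } else {
    fit <- .boa_gls(y, X, Zl, vspec)
  }
  a_hat <- matrix(fit$a, M, K,
                  dimnames = list(design$marker_ids, design$group_labels))
  beta <- stats::setNames(as.numeric(fit$beta), colnames(X))
  .new_model_fit(beta, a_hat, "boa", vspec, design,
                 c(fit$diagnostics, list(method = method)))
}

.boa_mme_dense <- function(y, X, Zl, vspec) {
  K <- length(Zl)
  M <- ncol(Zl[[1L]])
  Z <- do.call(cbind, Zl)
  Sinv <- chol2inv(chol(vspec$sigma))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X),
                   crossprod(Z) + vspec$sigma_e2 * kronecker(Sinv, diag(M))))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- as.numeric(.solve_psd(C, rhs))
  if (!all(is.finite(sol))) stop("non-finite MME solution")
  p <- ncol(X)
  list(beta = sol[seq_len(p)], a = sol[-seq_len(p)],
       diagnostics = list(residual_norm = max(abs(C %*% sol - rhs)),
                          condition = kappa(C, exact = FALSE)))
}

.boa_gls <- function(y, X, Zl, vspec) {
  K <- length(Zl)
  N <- length(y)
  V <- diag(vspec$sigma_e2, N)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      if (vspec$sigma[k, l] != 0) {
        V <- V + vspec$sigma[k, l] * tcrossprod(Zl[[k]], Zl[[l]])
      }
    }
  }
  ch <- chol(V)
  ViX <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  Viy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  A <- crossprod(X, ViX)
  qa <- qr(A)
  beta <- if (qa$rank < ncol(X)) {
    MASS::ginv(A) %*% crossprod(X, Viy)  # minimum-norm BLUE
  } else {
    solve(A, crossprod(X, Viy))
  }
  r <- y - X %*% beta
  w <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
  a <- unlist(lapply(seq_len(K), function(k) {
    acc <- 0
    for (l in seq_len(K)) {
      if (vspec$sigma[k, l] != 0) {
        acc <- acc + vspec$sigma[k, l] * crossprod(Zl[[l]], w)
      }
    }
    as.numeric(acc)
  }))
  if (!all(is.finite(a)) || !all(is.finite(beta))) {
    stop("non-finite GLS solution")
  }
  list(beta = beta, a = a,
       diagnostics = list(residual_norm = NA_real_,
                          condition = NA_real_))
}

#' Solve standard SNP-BLUP
#'
#' The baseline model `y = beta 1 + Z_A a + e` with `Cov(a) = sigma_a2 I`
#' and a single intercept (no breed effect), used both for within-breed
#' prediction (target-breed reference only) and multi-breed prediction
#' (joined reference).
#'
#' @param y Phenotype vector.
#' @param Z `N x M` dosage matrix (0/1/2 alternative-allele counts).
#' @param sigma_a2 Marker-effect variance (> 0).
#' @param sigma_e2 Residual variance (> 0).
#' @param include_intercept Include the intercept (default `TRUE`).
#' @param method `"auto"`, `"mme"` or `"gls"` as in [solve_boa_mme()].
#' @param marker_ids Optional marker names for the fit.
#' @return A `model_fit` with a single effect column.
#' @export
solve_snp_blup <- function(y, Z, sigma_a2, sigma_e2,
                           include_intercept = TRUE,
                           method = c("auto", "mme", "gls"),
                           marker_ids = colnames(Z)) {
  method <- match.arg(method)
  if (sigma_a2 <= 0 || sigma_e2 <= 0) stop("variances must be > 0")
  N <- length(y)
  X <- if (include_intercept) matrix(1, N, 1) else matrix(0, N, 0)
  if (method == "auto") method <- if (N < ncol(Z)) "gls" else "mme"
  vs <- variance_spec(matrix(sigma_a2, 1, 1), sigma_e2)
  if (ncol(X) == 0L) X <- matrix(0, N, 1)  # degenerate column, beta -> 0
  fit <- if (method == "mme") {
    .boa_mme_dense(y, X, list(Z), vs)
  } else {
    .boa_gls(y, X, list(Z), vs)
  }
  a_hat <- matrix(fit$a, ncol(Z), 1,
                  dimnames = list(marker_ids, "a"))
  design <- list(marker_ids = marker_ids, group_labels = "a")
  .new_model_fit(stats::setNames(as.numeric(fit$beta), "intercept"),
                 a_hat, "snp_blup", vs, design,
                 c(fit$diagnostics, list(method = method)))
}

#' Genomic estimated breeding values from a model fit
#'
#' `GEBV_i = sum_m sum_k Z_Aimk a_mk` for the origin-split model, and
#' `GEBV_i = sum_m Z_Aim a_m` for the baselines. Fixed effects are not
#' part of the breeding value.
#'
#' @param fit A `model_fit`.
#' @param newdata For a BOA fit: a `design_set` (its `Z` list is used) or
#'   a list of `K` dosage matrices. For a SNP-BLUP fit: a dosage matrix or
#'   a `design_set` (origin-split counts are summed to plain dosages).
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, newdata) {
  stopifnot(inherits(fit, "model_fit"))
  if (inherits(newdata, "design_set")) {
    ids <- newdata$ids
    if (!identical(newdata$marker_ids, fit$marker_ids)) {
      stop("marker sets of fit and new data differ")
    }
    Zl <- newdata$Z
  } else if (is.list(newdata) && !is.data.frame(newdata)) {
    Zl <- newdata
    ids <- rownames(Zl[[1L]])
  } else {
    Zl <- list(newdata)
    ids <- rownames(newdata)
  }
  if (fit$model_kind == "boa") {
    if (length(Zl) != ncol(fit$a_hat)) {
      stop("group structure of fit and new data differ")
    }
    g <- 0
    for (k in seq_along(Zl)) g <- g + Zl[[k]] %*% fit$a_hat[, k]
  } else {
    Ztot <- Reduce(`+`, Zl)
    if (ncol(Ztot) != nrow(fit$a_hat)) {
      stop("marker sets of fit and new data differ")
    }
    g <- Ztot %*% fit$a_hat[, 1L]
  }
  stats::setNames(as.numeric(g), ids)
}
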