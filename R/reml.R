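# REML estimation of variance components under the animal model
#   y = X beta + a + e,  a ~ N(0, K sigma2_a),  e ~ N(0, I sigma2_e),
# with K a relationship matrix (pedigree A or single-step H). Fits use
# average-information updates in an eigen-rotated parameterisation (one
# symmetric eigendecomposition of the observed-animal block of K per
# dataset, after which every likelihood, gradient and AI evaluation is
# O(n p^2)); a damped multiplicative fallback replaces AI steps that leave
# the parameter space. Standard errors come from the inverse of the final
# average-information matrix; heritability and correlation SEs use the delta
# method.

build_fixed_design <- function(phenotypes, fixed) {
  df <- phenotypes[, fixed, drop = FALSE]
  for (f in fixed) df[[f]] <- droplevels(as.factor(df[[f]]))
  X <- stats::model.matrix(stats::reformulate(fixed), df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qx$rank)][1]
    stop_sswool("fixed-effect design is rank deficient (e.g. column %s)",
                bad %||% "?", class = "sswool_rank_error")
  }
  X
}

#' Restricted log-likelihood of the animal model (dense oracle form)
#'
#' Direct dense evaluation of
#' `-0.5 * (log|V| + log|X' V^-1 X| + y' P y)` with
#' `V = K sigma2_a + I sigma2_e`. Quadratic in memory/time; intended for
#' small problems and as the reference surface for grid checks of
#' [reml_fit()].
#'
#' @param sigma2_a,sigma2_e variance components (> 0).
#' @param phenotypes phenotype data.frame with column `animal`.
#' @param trait trait column name.
#' @param relationship relationship matrix `K` with animal dimnames.
#' @param fixed fixed-effect factor columns.
#' @return the restricted log-likelihood (additive-constant convention as
#'   above).
#' @export
reml_loglik <- function(sigma2_a, sigma2_e, phenotypes, trait, relationship,
                        fixed = c("flock", "year", "season")) {
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  dat <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  y <- dat[[trait]]
  X <- build_fixed_design(dat, fixed)
  K <- relationship[dat$animal, dat$animal]
  n <- length(y)
  V <- sigma2_a * K + diag(sigma2_e, n)
  cv <- chol(V)
  Vi <- chol2inv(cv)
  XtVi <- crossprod(X, Vi)
  C <- XtVi %*% X
  cc <- chol(C)
  beta <- backsolve(cc, forwardsolve(t(cc), XtVi %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cc))) + quad)
}

# Rotated-space engine pieces (single trait) ----------------------------------

rot_loglik_parts <- function(theta, d, ys, Xs) {
  v <- theta[1] * d + theta[2]
  w <- 1 / v
  Xw <- Xs * w
  C <- crossprod(Xs, Xw)
  Ci <- solve(C)
  beta <- Ci %*% crossprod(Xw, ys)
  r <- ys - drop(Xs %*% beta)
  Py <- w * r
  ll <- -0.5 * (sum(log(v)) + determinant(C, logarithm = TRUE)$modulus + sum(r * Py))
  list(v = v, w = w, C = C, Ci = Ci, r = r, Py = Py, ll = as.numeric(ll))
}

# Apply the projection matrix P to a vector in rotated space.
apply_P <- function(u, w, Xs, Ci) {
  wu <- w * u
  wu - w * drop(Xs %*% (Ci %*% crossprod(Xs, wu)))
}

reml_fit_single <- function(y, X, K_obs, tol, max_iter) {
  n <- length(y)
  e <- eigen(K_obs, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  vp <- stats::var(stats::lm.fit(X, y)$residuals)
  theta <- c(a = 0.5 * vp, e = 0.5 * vp)
  parts <- rot_loglik_parts(theta, d, ys, Xs)
  grad <- c(NA, NA); AI <- diag(2)
  converged <- FALSE; iter <- 0L
  derivs <- list(d, rep(1, n))
  for (iter in seq_len(max_iter)) {
    # gradient and average information
    trP <- numeric(2); yPGPy <- numeric(2); u <- vector("list", 2L)
    for (j in 1:2) {
      g <- derivs[[j]]
      M <- crossprod(Xs, Xs * (parts$w^2 * g))
      trP[j] <- sum(parts$w * g) - sum(diag(parts$Ci %*% M))
      u[[j]] <- g * parts$Py
      yPGPy[j] <- sum(u[[j]] * parts$Py)
    }
    grad <- -0.5 * (trP - yPGPy)
    for (j in 1:2) for (k in j:2) {
      AI[j, k] <- AI[k, j] <- 0.5 * sum(u[[j]] * apply_P(u[[k]], parts$w, Xs, parts$Ci))
    }
    step <- tryCatch(solve(AI, grad), error = function(e2) grad / max(diag(AI), 1))
    new_theta <- theta + step
    halvings <- 0L
    while ((any(new_theta <= 0) ||
            {p2 <- rot_loglik_parts(new_theta, d, ys, Xs); p2$ll < parts$ll - 1e-8}) &&
           halvings < 20L) {
      step <- step / 2
      new_theta <- theta + step
      halvings <- halvings + 1L
    }
    if (any(new_theta <= 0)) {
      # damped multiplicative update (fixed point of the REML equations)
      ratio <- pmin(pmax(yPGPy / pmax(trP, 1e-12), 0.25), 4)
      new_theta <- theta * sqrt(ratio)
    }
    rel <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-12))
    theta <- new_theta
    parts <- rot_loglik_parts(theta, d, ys, Xs)
    if (rel < tol) { converged <- TRUE; break }
  }
  vcov_theta <- tryCatch(solve(AI), error = function(e2) matrix(NA, 2, 2))
  list(sigma2_a = unname(theta[1]), sigma2_e = unname(theta[2]),
       vcov = vcov_theta, loglik = parts$ll, converged = converged,
       n_iterations = iter, gradient_norm = sqrt(sum(grad^2)), n = n)
}

# Bivariate engine -------------------------------------------------------------
# theta = (a11, a21, a22, e11, e21, e22); per eigen index i the 2x2 block is
# V_i = d_i * Sigma_a + Sigma_e. All sums run over eigen indices.

biv_unpack <- function(theta) {
  list(Sa = matrix(theta[c(1, 2, 2, 3)], 2), Se = matrix(theta[c(4, 5, 5, 6)], 2))
}

biv_pd <- function(theta) {
  theta[1] > 0 && theta[3] > 0 && theta[4] > 0 && theta[6] > 0 &&
    theta[2]^2 < theta[1] * theta[3] && theta[5]^2 < theta[4] * theta[6]
}

biv_parts <- function(theta, d, Y, Xs) {
  up <- biv_unpack(theta)
  v11 <- d * up$Sa[1, 1] + up$Se[1, 1]
  v12 <- d * up$Sa[1, 2] + up$Se[1, 2]
  v22 <- d * up$Sa[2, 2] + up$Se[2, 2]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0)) return(NULL)
  w11 <- v22 / det; w12 <- -v12 / det; w22 <- v11 / det
  p <- ncol(Xs)
  C <- rbind(cbind(crossprod(Xs, Xs * w11), crossprod(Xs, Xs * w12)),
             cbind(crossprod(Xs, Xs * w12), crossprod(Xs, Xs * w22)))
  Ci <- solve(C)
  xv_y <- c(crossprod(Xs, w11 * Y[, 1] + w12 * Y[, 2]),
            crossprod(Xs, w12 * Y[, 1] + w22 * Y[, 2]))
  beta <- drop(Ci %*% xv_y)
  r1 <- Y[, 1] - drop(Xs %*% beta[seq_len(p)])
  r2 <- Y[, 2] - drop(Xs %*% beta[p + seq_len(p)])
  q1 <- w11 * r1 + w12 * r2
  q2 <- w12 * r1 + w22 * r2
  ll <- -0.5 * (sum(log(det)) + determinant(C, logarithm = TRUE)$modulus +
                  sum(r1 * q1) + sum(r2 * q2))
  list(w11 = w11, w12 = w12, w22 = w22, C = C, Ci = Ci,
       r1 = r1, r2 = r2, q1 = q1, q2 = q2, ll = as.numeric(ll))
}

# V^-1 u for stacked 2-column u, then subtract projection on X.
biv_apply_P <- function(u1, u2, pt, Xs) {
  p <- ncol(Xs)
  t1 <- pt$w11 * u1 + pt$w12 * u2
  t2 <- pt$w12 * u1 + pt$w22 * u2
  xv <- c(crossprod(Xs, t1), crossprod(Xs, t2))
  gamma <- drop(pt$Ci %*% xv)
  s1 <- drop(Xs %*% gamma[seq_len(p)])
  s2 <- drop(Xs %*% gamma[p + seq_len(p)])
  list(p1 = t1 - (pt$w11 * s1 + pt$w12 * s2),
       p2 = t2 - (pt$w12 * s1 + pt$w22 * s2))
}

# d(V_i)/d(theta_j) = c_i * B_j with c_i = d_i (genetic) or 1 (residual) and
# B in {E11, E12+E21, E22}.
biv_basis <- function() {
  list(B11 = matrix(c(1, 0, 0, 0), 2), B12 = matrix(c(0, 1, 1, 0), 2),
       B22 = matrix(c(0, 0, 0, 1), 2))
}

reml_fit_bivariate <- function(Y, X, K_obs, tol, max_iter) {
  n <- nrow(Y)
  e <- eigen(K_obs, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  Ys <- crossprod(U, Y)
  Xs <- crossprod(U, X)
  R0 <- stats::cov(cbind(stats::lm.fit(X, Y[, 1])$residuals,
                         stats::lm.fit(X, Y[, 2])$residuals))
  theta <- c(0.5 * R0[1, 1], 0.5 * R0[1, 2], 0.5 * R0[2, 2],
             0.5 * R0[1, 1], 0.5 * R0[1, 2], 0.5 * R0[2, 2])
  basis <- biv_basis()
  scal <- list(d, d, d, rep(1, n), rep(1, n), rep(1, n))
  Bs <- c(basis, basis)
  pt <- biv_parts(theta, d, Ys, Xs)
  grad <- rep(NA_real_, 6L); AI <- diag(6)
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    u1 <- vector("list", 6L); u2 <- vector("list", 6L)
    trP <- numeric(6L); yPGPy <- numeric(6L)
    for (j in 1:6) {
      B <- Bs[[j]]; cvec <- scal[[j]]
      # tr(V^-1 dV): elementwise with the 2x2 inverse entries
      trVi <- cvec * (B[1, 1] * pt$w11 + 2 * B[1, 2] * pt$w12 + B[2, 2] * pt$w22)
      # M_i = V^-1 B V^-1 (2x2, symmetric), entries as series over i
      m11 <- pt$w11 * (B[1, 1] * pt$w11 + B[1, 2] * pt$w12) +
        pt$w12 * (B[1, 2] * pt$w11 + B[2, 2] * pt$w12)
      m12 <- pt$w11 * (B[1, 1] * pt$w12 + B[1, 2] * pt$w22) +
        pt$w12 * (B[1, 2] * pt$w12 + B[2, 2] * pt$w22)
      m22 <- pt$w12 * (B[1, 1] * pt$w12 + B[1, 2] * pt$w22) +
        pt$w22 * (B[1, 2] * pt$w12 + B[2, 2] * pt$w22)
      M <- rbind(cbind(crossprod(Xs, Xs * (cvec * m11)),
                       crossprod(Xs, Xs * (cvec * m12))),
                 cbind(crossprod(Xs, Xs * (cvec * m12)),
                       crossprod(Xs, Xs * (cvec * m22))))
      trP[j] <- sum(trVi) - sum(diag(pt$Ci %*% M))
      u1[[j]] <- cvec * (B[1, 1] * pt$q1 + B[1, 2] * pt$q2)
      u2[[j]] <- cvec * (B[1, 2] * pt$q1 + B[2, 2] * pt$q2)
      yPGPy[j] <- sum(u1[[j]] * pt$q1) + sum(u2[[j]] * pt$q2)
    }
    grad <- -0.5 * (trP - yPGPy)
    for (j in 1:6) {
      pu <- biv_apply_P(u1[[j]], u2[[j]], pt, Xs)
      for (k in j:6) {
        AI[j, k] <- AI[k, j] <-
          0.5 * (sum(u1[[k]] * pu$p1) + sum(u2[[k]] * pu$p2))
      }
    }
    step <- tryCatch(solve(AI, grad), error = function(e2) grad / max(diag(AI), 1))
    new_theta <- theta + step
    halvings <- 0L
    ok_new <- function(th) {
      if (!biv_pd(th)) return(FALSE)
      p2 <- biv_parts(th, d, Ys, Xs)
      !is.null(p2) && p2$ll >= pt$ll - 1e-8
    }
    while (!ok_new(new_theta) && halvings < 20L) {
      step <- step / 2
      new_theta <- theta + step
      halvings <- halvings + 1L
    }
    if (!biv_pd(new_theta)) {
      # PSD projection of both 2x2 blocks
      up <- biv_unpack(pmax(theta + step, -Inf))
      fix <- function(S) {
        ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
        ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
      }
      Sa <- fix(up$Sa); Se <- fix(up$Se)
      new_theta <- c(Sa[1, 1], Sa[1, 2], Sa[2, 2], Se[1, 1], Se[1, 2], Se[2, 2])
      if (!biv_pd(new_theta)) new_theta <- theta
    }
    rel <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-12))
    theta <- new_theta
    pt <- biv_parts(theta, d, Ys, Xs)
    if (rel < tol) { converged <- TRUE; break }
  }
  vcov_theta <- tryCatch(solve(AI), error = function(e2) matrix(NA, 6, 6))
  list(theta = theta, vcov = vcov_theta, loglik = pt$ll, converged = converged,
       n_iterations = iter, gradient_norm = sqrt(sum(grad^2)), n = n)
}

#' Fit the animal model by AI-REML
#'
#' Single-trait fits return additive and residual variances, heritability
#' and its SE; bivariate fits (two trait names) additionally return genetic
#' and residual covariances and the genetic/phenotypic correlations with
#' delta-method SEs. Bivariate fits use animals with both traits observed.
#'
#' @param phenotypes phenotype data.frame with columns `animal`, the fixed
#'   factors and the trait(s).
#' @param traits one or two trait column names.
#' @param relationship relationship matrix `K` (dense, dimnames = animal
#'   ids) covering every phenotyped animal.
#' @param fixed fixed-effect factor columns (default flock, year, season).
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum AI iterations (non-convergence flags the result
#'   and returns the last iterate).
#' @return an object of class `reml_result`.
#' @export
reml_fit <- function(phenotypes, traits, relationship,
                     fixed = c("flock", "year", "season"),
                     tol = 1e-8, max_iter = 200L) {
  stopifnot(length(traits) %in% 1:2)
  if (length(traits) == 1L) {
    dat <- phenotypes[!is.na(phenotypes[[traits]]), , drop = FALSE]
    if (nrow(dat) < 2L) stop_sswool("need >= 2 records", class = "sswool_validation_error")
    X <- build_fixed_design(dat, fixed)
    K <- relationship[dat$animal, dat$animal]
    fit <- reml_fit_single(dat[[traits]], X, K, tol, max_iter)
    h2 <- heritability(fit)
    out <- c(fit, list(traits = traits, h2 = h2["h2"], h2_se = h2["se"]))
  } else {
    ok <- !is.na(phenotypes[[traits[1]]]) & !is.na(phenotypes[[traits[2]]])
    dat <- phenotypes[ok, , drop = FALSE]
    if (nrow(dat) < 2L) stop_sswool("need >= 2 records", class = "sswool_validation_error")
    X <- build_fixed_design(dat, fixed)
    K <- relationship[dat$animal, dat$animal]
    fit <- reml_fit_bivariate(as.matrix(dat[, traits]), X, K, tol, max_iter)
    th <- fit$theta
    vc <- list(sigma2_a = th[c(1, 3)], cov_a = th[2],
               sigma2_e = th[c(4, 6)], cov_e = th[5], vcov = fit$vcov)
    rg <- genetic_correlation(vc)
    h2s <- lapply(1:2, function(t) {
      i_a <- c(1, 3)[t]; i_e <- c(4, 6)[t]
      heritability(list(sigma2_a = th[i_a], sigma2_e = th[i_e],
                        vcov = fit$vcov[c(i_a, i_e), c(i_a, i_e)]))
    })
    # phenotypic correlation from total (co)variances
    tp <- (th[1] + th[4]) * (th[3] + th[6])
    rp <- (th[2] + th[5]) / sqrt(tp)
    out <- c(fit, list(traits = traits,
                       sigma2_a = th[c(1, 3)], cov_a = th[2],
                       sigma2_e = th[c(4, 6)], cov_e = th[5],
                       h2 = c(h2s[[1]]["h2"], h2s[[2]]["h2"]),
                       h2_se = c(h2s[[1]]["se"], h2s[[2]]["se"]),
                       r_g = rg["r_g"], r_g_se = rg["se"], r_p = rp))
  }
  class(out) <- "reml_result"
  out
}

#' Heritability with delta-method standard error
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the SE propagates the sampling
#' covariance of the two components.
#'
#' @param vc list with `sigma2_a`, `sigma2_e` and optionally `vcov` (their
#'   2x2 sampling covariance).
#' @return named vector `c(h2, se)` (`se` is `NA` without `vcov`).
#' @export
heritability <- function(vc) {
  a <- vc$sigma2_a; e <- vc$sigma2_e
  tot <- a + e
  if (tot <= 0) stop_sswool("zero total variance", class = "sswool_degenerate_error")
  h2 <- a / tot
  se <- NA_real_
  if (!is.null(vc$vcov) && all(is.finite(vc$vcov))) {
    g <- c(e, -a) / tot^2
    se <- sqrt(drop(t(g) %*% vc$vcov %*% g))
  }
  c(h2 = h2, se = se)
}

#' Genetic correlation with delta-method standard error
#'
#' `r_g = cov_a / sqrt(sigma2_a1 * sigma2_a2)` from a bivariate fit.
#'
#' @param vc list with `sigma2_a` (length 2), `cov_a`, and optionally `vcov`
#'   (sampling covariance of `(a11, a21, a22, e11, e21, e22)`).
#' @return named vector `c(r_g, se)`.
#' @export
genetic_correlation <- function(vc) {
  a1 <- vc$sigma2_a[1]; a2 <- vc$sigma2_a[2]; c12 <- vc$cov_a
  if (a1 <= 0 || a2 <= 0) {
    stop_sswool("zero additive variance", class = "sswool_degenerate_error")
  }
  r <- c12 / sqrt(a1 * a2)
  se <- NA_real_
  if (!is.null(vc$vcov) && all(is.finite(vc$vcov))) {
    g <- numeric(nrow(vc$vcov))
    g[1] <- -r / (2 * a1); g[2] <- 1 / sqrt(a1 * a2); g[3] <- -r / (2 * a2)
    se <- sqrt(drop(t(g) %*% vc$vcov %*% g))
  }
  c(r_g = r, se = se)
}

#' @method print reml_result
#' @export
print.reml_result <- function(x, ...) {
  cat("AI-REML animal model fit\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  sigma2_a:", signif(x$sigma2_a, 4),
      " sigma2_e:", signif(x$sigma2_e, 4), "\n")
  cat("  h2:", signif(x$h2, 4), "(se", signif(x$h2_se, 3), ")\n")
  if (!is.null(x$r_g)) {
    cat("  r_g:", signif(x$r_g, 4), "(se", signif(x$r_g_se, 3), ")",
        " r_p:", signif(x$r_p, 4), "\n")
  }
  cat("  converged:", x$converged, "after", x$n_iterations, "iterations\n")
  invisible(x)
}
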