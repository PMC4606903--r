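# Multi-component mixed linear models by EM-REML.
#
# Model: y = X b + sum_i g_i + e,  g_i ~ N(0, s2_i G_i),  e ~ N(0, s2_e I),
# so V = sum_i s2_i G_i + s2_e I.  All quantities are on the observed scale
# (for case-control data y is 0/1); liability conversion is a separate,
# downstream step.

# normalize the GRM argument: named list of `grm` objects or plain matrices
.grm_list <- function(grms, n) {
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  mats <- lapply(grms, function(g) {
    A <- if (inherits(g, "grm")) g$A else g
    if (!is.matrix(A) || nrow(A) != ncol(A))
      stop("GRM components must be square matrices")
    if (nrow(A) != n) stop("GRM dimension ", nrow(A), " != n = ", n)
    if (max(abs(A - t(A))) > 1e-8) stop("GRM component not symmetric")
    A
  })
  if (is.null(names(mats)) || any(names(mats) == ""))
    names(mats) <- paste0("G", seq_along(mats))
  mats
}

# one evaluation of the restricted likelihood machinery at variance vector
# s2 (components first, residual last); returns logL and the pieces the EM
# update and AI matrix need
.reml_parts <- function(y, X, mats, s2) {
  n <- length(y)
  c <- length(mats)
  V <- diag(s2[c + 1], n)
  for (i in seq_len(c)) V <- V + s2[i] * mats[[i]]
  ch <- tryCatch(chol(V), error = function(e)
    stop("V not positive definite at s2 = (",
         paste(signif(s2, 4), collapse = ", "), "): ", conditionMessage(e)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e)
    stop("X'V^-1X singular (condition: check fixed-effect design): ",
         conditionMessage(e)))
  P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
  Py <- as.numeric(P %*% y)
  yPy <- sum(y * Py)
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + yPy)
  list(logL = logL, P = P, Py = Py, yPy = yPy, Vi = Vi, ViX = ViX,
       XtViX = XtViX)
}

#' Restricted log-likelihood of a multi-component mixed model
#'
#' Evaluates logL_R = -1/2 \[ log|V| + log|X'V^-1 X| + y'Py \] (constant
#' omitted) with V = sum_i s2_i G_i + s2_e I and
#' P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1.
#'
#' @param y numeric response (observed scale; 0/1 for case-control).
#' @param X fixed-effect design matrix (include the intercept column).
#' @param grms list of [compute_grm()] objects or n x n matrices (may be
#'   empty for a fixed-effects-only model).
#' @param s2 variance components, genetic components in the order of `grms`
#'   followed by the residual.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, X, grms, s2) {
  n <- length(y)
  X <- as.matrix(X)
  mats <- if (length(grms)) .grm_list(grms, n) else list()
  if (length(s2) != length(mats) + 1)
    stop("s2 must have one entry per GRM plus the residual")
  if (any(s2 < 0)) stop("variance components must be >= 0")
  .reml_parts(y, X, mats, s2)$logL
}

#' Fit a multi-component mixed model by EM-REML
#'
#' Iterates the EM update
#'   s2_i <- s2_i + (s2_i^2 / n) (y'P G_i P y - tr(P G_i))
#' (residual analogous with G = I) from the symmetric start
#' s2 = var(y)/(c+1), clamping components at a small floor, until the
#' restricted log-likelihood changes by less than `tol`.  EM guarantees a
#' non-decreasing restricted likelihood.  Standard errors come from the
#' inverse average-information matrix evaluated at the solution,
#' AI_ij = 1/2 y'P G_i P G_j P y (EM itself carries no curvature);
#' observed-scale variance fractions s2_i / s2_total get delta-method SEs.
#'
#' Fixed-effect columns (other than the intercept) are standardized
#' internally for conditioning and estimates are back-transformed.
#'
#' Convergence is declared when a plain EM step changes the restricted
#' log-likelihood by less than `tol`.  By default the EM map is accelerated
#' with SQUAREM extrapolation (Varadhan & Roland squaring scheme): each cycle
#' takes two EM steps, extrapolates along the geometric tail, and finishes
#' with a stabilizing EM step, falling back to the plain double step whenever
#' the extrapolated point does not improve the likelihood -- so the recorded
#' likelihood path is non-decreasing either way and the fixed point is the
#' same as the textbook loop (`accelerate = FALSE`), just reached in far
#' fewer likelihood evaluations.
#'
#' @inheritParams restricted_loglik
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood under one plain EM step (default 1e-4).
#' @param max_iter cap on likelihood evaluations; a non-converged fit is
#'   still returned, flagged `converged = FALSE`.
#' @param floor_frac component floor as a fraction of phenotypic variance.
#' @param par_tol optional additional convergence requirement on the largest
#'   absolute component change (`NULL` = likelihood criterion only).
#' @param accelerate use SQUAREM extrapolation between EM steps?
#' @param verbose print the likelihood path?
#' @return An object of class `reml_fit`: list with `varcomp` (data.frame
#'   source/variance/SE), `fractions` (observed-scale variance fractions of
#'   each genetic component with SEs), `beta` (fixed effects), `logLik`,
#'   `iterations`, `converged`, `n`, `m` (per-component SNP counts, when
#'   `grms` are `grm` objects), and the likelihood path `trace`.
#' @export
fit_em_reml <- function(y, X = NULL, grms, tol = 1e-4, max_iter = 10000,
                        floor_frac = 1e-6, par_tol = NULL, accelerate = TRUE,
                        verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) stop("X rows must match length(y)")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  mats <- .grm_list(grms, n)
  c <- length(mats)
  # standardize non-constant columns for conditioning; centering leaves the
  # column span (hence P and the fit) unchanged only when a constant column
  # is present, and scaling shifts logL by sum(log(scl)), which is removed
  # from every reported likelihood so logLik matches restricted_loglik() on
  # the raw design
  scl <- apply(X, 2, stats::sd)
  fixed <- scl < .Machine$double.eps
  scl[fixed] <- 1
  ctr <- if (any(fixed)) colMeans(X) else rep(0, ncol(X))
  ctr[fixed] <- 0
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xs[, fixed] <- X[, fixed]
  logl_adj <- -sum(log(scl))

  vp <- stats::var(y)
  floor <- floor_frac * vp
  s2 <- rep(vp / (c + 1), c + 1)
  trace <- numeric(0)
  iter <- 0  # counts likelihood evaluations (the unit of work)

  em_step <- function(s2, parts) {
    Py <- parts$Py
    P <- parts$P
    s2_new <- s2
    for (i in seq_len(c)) {
      GPy <- mats[[i]] %*% Py
      s2_new[i] <- s2[i] + (s2[i]^2 / n) * (sum(Py * GPy) - sum(P * mats[[i]]))
    }
    s2_new[c + 1] <- s2[c + 1] +
      (s2[c + 1]^2 / n) * (sum(Py * Py) - sum(diag(P)))
    pmax(s2_new, floor)
  }
  evaluate <- function(s2) {
    iter <<- iter + 1
    p <- .reml_parts(y, Xs, mats, s2)
    if (!is.finite(p$logL))
      stop("non-finite restricted likelihood at evaluation ", iter,
           "; s2 = (", paste(signif(s2, 4), collapse = ", "), ")")
    p
  }

  parts <- evaluate(s2)
  logL <- parts$logL
  converged <- FALSE
  while (iter < max_iter && !converged) {
    # one plain EM step; its logL change is the convergence criterion
    s2_1 <- em_step(s2, parts)
    parts_1 <- evaluate(s2_1)
    dL <- parts_1$logL - logL
    dpar <- max(abs(s2_1 - s2))
    trace <- c(trace, parts_1$logL + logl_adj)
    if (verbose) cat(sprintf("eval %4d logL %.6f dL %.2e\n", iter,
                             parts_1$logL, dL))
    if (abs(dL) < tol && (is.null(par_tol) || dpar < par_tol)) {
      s2 <- s2_1
      parts <- parts_1
      logL <- parts$logL
      converged <- TRUE
      break
    }
    if (!accelerate) {
      s2 <- s2_1
      parts <- parts_1
      logL <- parts$logL
      next
    }
    # SQUAREM cycle: second EM step, then extrapolate along the tail
    s2_2 <- em_step(s2_1, parts_1)
    r <- s2_1 - s2
    v <- (s2_2 - s2_1) - r
    alpha <- -sqrt(sum(r^2)) / max(sqrt(sum(v^2)), .Machine$double.eps)
    s2_x <- pmax(s2 - 2 * alpha * r + alpha^2 * v, floor)
    parts_x <- tryCatch(evaluate(s2_x), error = function(e) NULL)
    acc <- FALSE
    if (!is.null(parts_x) && parts_x$logL >= parts_1$logL) {
      # stabilize with one EM step from the extrapolated point
      s2_s <- em_step(s2_x, parts_x)
      parts_s <- tryCatch(evaluate(s2_s), error = function(e) NULL)
      if (!is.null(parts_s) && parts_s$logL >= parts_x$logL) {
        s2 <- s2_s
        parts <- parts_s
        acc <- TRUE
        trace <- c(trace, parts_x$logL + logl_adj, parts_s$logL + logl_adj)
      }
    }
    if (!acc) {  # fall back to the plain double EM step
      parts_2 <- evaluate(s2_2)
      if (parts_2$logL >= parts_1$logL) {
        s2 <- s2_2
        parts <- parts_2
      } else {
        s2 <- s2_1
        parts <- parts_1
      }
      trace <- c(trace, parts$logL + logl_adj)
    }
    logL <- parts$logL
  }

  # average-information matrix at the solution (components + residual)
  Py <- parts$Py
  P <- parts$P
  GPy <- c(lapply(mats, function(G) as.numeric(G %*% Py)), list(Py))
  PGPy <- lapply(GPy, function(u) as.numeric(P %*% u))
  k <- c + 1
  AI <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(GPy[[i]] * PGPy[[j]])
  covmat <- tryCatch(solve(AI), error = function(e) {
    warning("singular average-information matrix; SEs unavailable")
    matrix(NA_real_, k, k)
  })
  se <- sqrt(pmax(diag(covmat), 0))

  tot <- sum(s2)
  frac <- s2[seq_len(c)] / tot
  se_frac <- vapply(seq_len(c), function(i) {
    g <- -s2[i] / tot^2 * rep(1, k)
    g[i] <- g[i] + 1 / tot
    v <- as.numeric(t(g) %*% covmat %*% g)
    sqrt(max(v, 0))
  }, numeric(1))

  bhat_s <- solve(parts$XtViX, crossprod(Xs, parts$Vi %*% y))
  beta <- as.numeric(bhat_s) / scl
  icpt <- which(fixed)[1]
  if (!is.na(icpt))
    beta[icpt] <- beta[icpt] - sum((ctr / scl * as.numeric(bhat_s))[!fixed]) /
      X[1, icpt]
  labels <- names(mats)
  structure(list(
    varcomp = data.frame(source = c(labels, "residual"), variance = s2,
                         se = se),
    fractions = data.frame(source = labels, fraction = frac, se = se_frac),
    beta = data.frame(term = colnames(X), estimate = beta),
    logLik = logL + logl_adj, iterations = iter, converged = converged,
    n = n,
    m = vapply(if (inherits(grms, "grm") || is.matrix(grms)) list(grms) else
                 grms,
               function(g) if (inherits(g, "grm")) g$m else NA_real_,
               numeric(1)),
    floor = floor, cov_varcomp = covmat, trace = trace),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("EM-REML fit: n =", x$n, "|", nrow(x$fractions), "GRM component(s) |",
      x$iterations, "iterations |",
      if (x$converged) "converged" else "NOT converged", "\n")
  vc <- x$varcomp
  at_floor <- vc$variance <= x$floor
  vc$variance[at_floor & vc$source != "residual"] <- 0
  print(cbind(vc[1], round(vc[-1], digits)), row.names = FALSE)
  fr <- x$fractions
  cat("observed-scale fractions:\n")
  print(cbind(fr[1], round(fr[-1], digits)), row.names = FALSE)
  cat("logL_R =", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' Likelihood-ratio test for one variance component
#'
#' Refits the model without the named GRM and forms
#' lambda = 2 (logL_full - logL_reduced), clamped at 0.  Because the null
#' (s2_i = 0) lies on the boundary of the parameter space, the default null
#' distribution is the 50:50 mixture of a point mass at 0 and chi-square(1):
#' p = 1/2 P(chi2_1 > lambda), reported as 0.5 when lambda = 0.  Set
#' `mixture = FALSE` for a plain chi-square(1) null.
#'
#' @inheritParams fit_em_reml
#' @param full a fitted `reml_fit` for the full model (its `logLik` is used).
#' @param drop name of the GRM component to drop (must match `names(grms)`).
#' @param mixture use the boundary mixture null (default) or plain chi2(1)?
#' @param ... passed to [fit_em_reml()] for the reduced fit.
#' @return An object of class `lrt_result`: list with `statistic`, `p`,
#'   `dropped`, `reduced` (the reduced `reml_fit`).
#' @export
lrt_drop <- function(y, X, grms, full, drop, mixture = TRUE, ...) {
  stopifnot(inherits(full, "reml_fit"))
  if (!drop %in% names(grms))
    stop("no GRM component named '", drop, "'")
  reduced_grms <- grms[setdiff(names(grms), drop)]
  red <- if (length(reduced_grms)) fit_em_reml(y, X, reduced_grms, ...) else
    .null_reml(y, X)
  lambda <- 2 * (full$logLik - (if (inherits(red, "reml_fit")) red$logLik else red))
  lambda <- max(lambda, 0)
  p <- if (lambda == 0) {
    if (mixture) 0.5 else 1
  } else {
    pp <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
    if (mixture) 0.5 * pp else pp
  }
  structure(list(statistic = lambda, p = p, dropped = drop,
                 reduced = if (inherits(red, "reml_fit")) red else NULL),
            class = "lrt_result")
}

# restricted likelihood of the fixed-effects-only model (no GRM): closed
# form at sigma2_hat = y'Qy/(n-p) with Q the residual projector
.null_reml <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  qrx <- qr(X)
  r <- qr.resid(qrx, y)
  rss <- sum(r^2)
  s2 <- rss / (n - p)
  R <- qr.R(qrx)
  -0.5 * (n * log(s2) + log(det(crossprod(X))) - p * log(s2) + rss / s2)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT dropping '%s': lambda = %.4f, p = %.4g\n",
              x$dropped, x$statistic, x$p))
  invisible(x)
}

#' Principal components of a genetic relationship matrix
#'
#' Top-k eigenvectors of A, unit norm, with a deterministic sign convention
#' (the loading of largest magnitude is positive).  Used as fixed-effect
#' ancestry covariates.
#'
#' @param grm a [compute_grm()] result or symmetric matrix.
#' @param k number of components (k < n).
#' @return n x k matrix of PC scores (rownames = individual ids when
#'   available).  Warns when the k-th and (k+1)-th eigenvalues are nearly
#'   equal (rotationally degenerate subspace).
#' @export
pca_covariates <- function(grm, k = 2) {
  A <- if (inherits(grm, "grm")) grm$A else grm
  if (!is.matrix(A) || max(abs(A - t(A))) > 1e-8)
    stop("pca_covariates needs a symmetric matrix")
  n <- nrow(A)
  if (k >= n) stop("k must be < n")
  ee <- eigen(A, symmetric = TRUE)
  gap <- ee$values[k] - ee$values[k + 1]
  scale_ref <- max(abs(ee$values[1]), 1)
  if (gap < 1e-8 * scale_ref)
    warning("degenerate eigenvalue(s) at k = ", k,
            "; returned PCs span the subspace but are not unique")
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(k))
  rownames(V) <- rownames(A)
  V
}

#' Write a REML fit as an hsq-style summary table
#'
#' Tab-separated summary in the layout GCTA users expect: one `V(...)`
#' row per variance component with SE, `Vp` (their sum), `V(Gi)/Vp`
#' fractions, then `logL`, optional `LRT`/`df`/`Pval` rows and `n`.
#'
#' @param fit a [fit_em_reml()] result.
#' @param path output file path.
#' @param lrt optional [lrt_drop()] result to append.
#' @return `path`, invisibly.
#' @export
write_hsq <- function(fit, path, lrt = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  vc <- fit$varcomp
  lab <- ifelse(vc$source == "residual", "V(e)", paste0("V(", vc$source, ")"))
  rows <- data.frame(Source = lab,
                     Variance = sprintf("%.6f", vc$variance),
                     SE = sprintf("%.6f", vc$se))
  rows <- rbind(rows, data.frame(Source = "Vp",
                                 Variance = sprintf("%.6f", sum(vc$variance)),
                                 SE = ""))
  fr <- fit$fractions
  rows <- rbind(rows, data.frame(Source = paste0("V(", fr$source, ")/Vp"),
                                 Variance = sprintf("%.6f", fr$fraction),
                                 SE = sprintf("%.6f", fr$se)))
  rows <- rbind(rows, data.frame(Source = "logL",
                                 Variance = sprintf("%.4f", fit$logLik),
                                 SE = ""))
  if (!is.null(lrt)) {
    stopifnot(inherits(lrt, "lrt_result"))
    rows <- rbind(rows,
                  data.frame(Source = c("LRT", "df", "Pval"),
                             Variance = c(sprintf("%.4f", lrt$statistic), "1",
                                          sprintf("%.4g", lrt$p)),
                             SE = ""))
  }
  rows <- rbind(rows, data.frame(Source = "n", Variance = as.character(fit$n),
                                 SE = ""))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
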