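## Case-control region score tests with covariates: burden, SKAT and
## SKAT-O (re-implemented score machinery; Liu moment-matching tails with
## an optional characteristic-function integration).

#' Fit the logistic null model for score tests
#'
#' Maximum-likelihood logistic regression of affection on the covariate
#' design (intercept plus covariates), by iteratively reweighted least
#' squares to tolerance 1e-8 (at most 100 iterations). Returns the fitted
#' means, working variances and the projection pieces needed for score
#' variances.
#'
#' @param y 0/1 phenotype vector.
#' @param X covariate matrix without intercept (or `NULL`).
#' @param warn_small warn when n < 2000 that no small-sample moment
#'   adjustment is applied?
#' @return object of class `cc_null_model`.
#' @export
fit_null <- function(y, X = NULL, warn_small = TRUE) {
  y <- as.numeric(y)
  if (var(y) == 0) stop("phenotype is constant")
  D <- cbind(`(Intercept)` = rep(1, length(y)), X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("covariate design is rank deficient (column ",
         paste(colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]],
               collapse = ", "), ")")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(D, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(fit$coefficients) > 20)) {
    worst <- colnames(D)[which.max(abs(fit$coefficients))]
    stop("(quasi-)perfect separation in the null model; offending ",
         "covariate: ", worst)
  }
  mu <- fit$fitted.values
  v <- mu * (1 - mu)
  if (warn_small && length(y) < 2000)
    warning("n = ", length(y), " < 2000: no small-sample moment ",
            "adjustment is applied to the SKAT/SKAT-O tail approximation",
            call. = FALSE)
  structure(list(y = y, X = D, mu = mu, v = v, res = y - mu,
                 coef = fit$coefficients,
                 XtVX_inv = solve(crossprod(D, v * D))),
            class = "cc_null_model")
}

# P0 %*% Z with P0 = V - VX (X'VX)^-1 X'V
p0_mult <- function(null, Z) {
  vZ <- null$v * Z
  vZ - (null$v * null$X) %*% (null$XtVX_inv %*% crossprod(null$X, vZ))
}

impute_window <- function(Gw) {
  Gw <- as.matrix(Gw)
  storage.mode(Gw) <- "double"
  if (anyNA(Gw))
    for (j in which(colSums(is.na(Gw)) > 0)) {
      mu <- mean(Gw[, j], na.rm = TRUE)
      Gw[is.na(Gw[, j]), j] <- if (is.nan(mu)) 0 else mu
    }
  Gw
}

#' Burden score test
#'
#' Collapses the window into `c_i = sum_v w_v g_iv`; the score is
#' `U = sum_i c_i (y_i - mu_i)` with variance
#' `c'Vc - c'VX (X'VX)^-1 X'Vc`, referred to chi-square with 1 df.
#'
#' @param null a [fit_null()] model.
#' @param Gw sample-by-variant dosage matrix for the window.
#' @param weights per-variant weights (default flat).
#' @return list with `p`, `U`, `var_U`, `stat`, `degenerate`.
#' @export
burden_test <- function(null, Gw, weights = NULL) {
  Gw <- impute_window(Gw)
  if (ncol(Gw) == 0L) stop("empty window")
  w <- if (is.null(weights)) rep(1, ncol(Gw)) else weights
  cvec <- as.vector(Gw %*% w)
  U <- sum(cvec * null$res)
  varU <- sum(cvec * p0_mult(null, cvec))
  if (varU <= 1e-12)
    return(list(p = 1, U = U, var_U = varU, stat = 0, degenerate = TRUE))
  stat <- U^2 / varU
  list(p = pchisq(stat, 1, lower.tail = FALSE), U = U, var_U = varU,
       stat = stat, degenerate = FALSE)
}

# Liu-Tang-Zhang moment-matched tail of sum lambda_j chi2_1 (vectorized in q)
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(rep(1, length(q)))
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  x <- tstar * sqrt(2 * (l + 2 * delta)) + l + delta
  pchisq(pmax(x, 0), df = l, ncp = delta, lower.tail = FALSE)
}

# Liu quantile at upper-tail probability p
liu_quantile <- function(p, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  x <- qchisq(p, df = l, ncp = delta, lower.tail = FALSE)
  (x - (l + delta)) / sqrt(2 * (l + 2 * delta)) * sqrt(2 * c2) + c1
}

# Imhof-type characteristic-function inversion for P(sum lambda chi2 > q)
imhof_pvalue <- function(q, lambda) {
  th <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
  rho <- function(u)
    exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
  f <- function(u) sin(th(u)) / (u * rho(u))
  val <- integrate(f, 0, Inf, rel.tol = 1e-6, subdivisions = 500L)$value
  min(max(0.5 + val / pi, 0), 1)
}

#' SKAT variance-component score test
#'
#' `Q = sum_v w_v^2 (sum_i g_iv (y_i - mu_i))^2`; the null distribution is
#' a mixture `sum_j lambda_j chi2_1` with eigenvalues of `W Z' P0 Z W`.
#' Tail probability by Liu-type moment matching (default) or by numerical
#' characteristic-function inversion (`method = "integration"`).
#'
#' @inheritParams burden_test
#' @param method tail approximation.
#' @return list with `p`, `Q`, `lambda`, `degenerate`.
#' @export
skat_test <- function(null, Gw, weights = NULL,
                      method = c("liu", "integration")) {
  method <- match.arg(method)
  Gw <- impute_window(Gw)
  if (ncol(Gw) == 0L) stop("empty window")
  w <- if (is.null(weights)) rep(1, ncol(Gw)) else weights
  Z <- Gw %*% diag(w, ncol(Gw))
  u <- as.vector(crossprod(Z, null$res))
  Q <- sum(u^2)
  A <- crossprod(Z, p0_mult(null, Z))
  lambda <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10 & lambda > 0]
  if (!length(lambda))
    return(list(p = 1, Q = Q, lambda = numeric(0), degenerate = TRUE))
  p <- if (method == "liu") liu_pvalue(Q, lambda) else
    tryCatch(imhof_pvalue(Q, lambda),
             error = function(e) liu_pvalue(Q, lambda))
  list(p = min(max(p, .Machine$double.xmin), 1), Q = Q, lambda = lambda,
       degenerate = FALSE)
}

#' SKAT-O: optimal combination of burden and SKAT
#'
#' Evaluates `Q_rho = (1 - rho) Q_skat + rho Q_burden` over a rho grid,
#' computes each mixture p-value, and combines the minimum via the
#' one-dimensional integral of the optimal-test construction. The
#' combined p is clamped into `[min_p, n_grid * min_p]` (the Bonferroni
#' sandwich); if the integration fails the upper bound is returned with a
#' warning flag.
#'
#' @inheritParams skat_test
#' @param rho_grid mixing grid (default the standard 8-point grid).
#' @return list of class `cc_region_result`: `p_burden`, `p_skat`,
#'   `p_skato`, `rho_grid`, `p_rho`, `integration_failed`.
#' @export
skato_test <- function(null, Gw, weights = NULL,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       method = c("liu", "integration")) {
  method <- match.arg(method)
  Gw <- impute_window(Gw)
  m <- ncol(Gw)
  if (m == 0L) stop("empty window")
  w <- if (is.null(weights)) rep(1, m) else weights
  bt <- burden_test(null, Gw, w)
  st <- skat_test(null, Gw, w, method = method)
  out <- list(p_burden = bt$p, p_skat = st$p, rho_grid = rho_grid,
              integration_failed = FALSE)
  if (st$degenerate || bt$degenerate) {
    out$p_rho <- rep(1, length(rho_grid)); out$p_skato <- 1
    class(out) <- "cc_region_result"
    return(out)
  }
  Z <- Gw %*% diag(w, m)
  u <- as.vector(crossprod(Z, null$res))
  Q_skat <- sum(u^2); Q_burden <- sum(u)^2
  if (m == 1L) {
    out$p_rho <- rep(st$p, length(rho_grid)); out$p_skato <- st$p
    class(out) <- "cc_region_result"
    return(out)
  }
  # Z1 = P0^{1/2} Z via the weighted-projection factorization
  sv <- sqrt(null$v)
  Xs <- sv * null$X
  B <- solve(crossprod(Xs), crossprod(Xs, sv * Z))
  Z1 <- sv * Z - Xs %*% B
  lam_rho <- vector("list", length(rho_grid))
  Q_rho <- (1 - rho_grid) * Q_skat + rho_grid * Q_burden
  p_rho <- numeric(length(rho_grid))
  A1 <- crossprod(Z1)
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    a <- sqrt(1 - rho + m * rho); b <- sqrt(1 - rho)
    # symmetric square root of R_rho = (1-rho) I + rho 11'
    onem <- matrix(1 / m, m, m)
    Rh <- a * onem + b * (diag(m) - onem)
    K <- Rh %*% A1 %*% Rh
    lam <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > max(lam, 0) * 1e-10 & lam > 0]
    lam_rho[[i]] <- lam
    p_rho[i] <- if (length(lam)) {
      if (method == "integration")
        tryCatch(imhof_pvalue(Q_rho[i], lam),
                 error = function(e) liu_pvalue(Q_rho[i], lam))
      else liu_pvalue(Q_rho[i], lam)
    } else 1
  }
  Tmin <- min(p_rho)
  out$p_rho <- p_rho
  # optimal-test combination (one-dimensional integral over the shared
  # chi-square-1 factor)
  grid <- rho_grid
  grid[grid >= 1] <- 0.999
  zbar <- rowMeans(Z1)
  zb2 <- sum(zbar^2)
  cof <- as.vector(crossprod(zbar, Z1)) / zb2
  Z2 <- Z1 - outer(zbar, cof)
  lam0 <- eigen(crossprod(Z2), symmetric = TRUE, only.values = TRUE)$values
  lam0 <- lam0[lam0 > max(lam0, 0) * 1e-10 & lam0 > 0]
  comb <- tryCatch({
    if (!length(lam0) || zb2 <= 0) stop("degenerate decomposition")
    MuQ <- sum(lam0)
    VarQ <- 2 * sum(lam0^2) +
      4 * sum(crossprod(Z1 - Z2) * crossprod(Z2))
    Df <- 12 / (12 * sum(lam0^4) / sum(lam0^2)^2)
    tau <- (m^2 * grid + sum(cof^2) * (1 - grid)) * zb2
    qmin <- vapply(seq_along(grid), function(i)
      liu_quantile(Tmin, lam_rho[[i]]), 0)
    integrand <- function(x) {
      sapply(x, function(xx) {
        tq <- (qmin - tau * xx) / (1 - grid)
        tmin <- min(tq)
        z <- (tmin - MuQ) / sqrt(VarQ) * sqrt(2 * Df) + Df
        pchisq(max(z, 0), df = Df) * dchisq(xx, df = 1)
      })
    }
    re <- integrate(integrand, 0, 40, subdivisions = 1000L,
                    rel.tol = 1e-6)$value
    1 - re
  }, error = function(e) NA_real_)
  if (is.na(comb)) {
    out$integration_failed <- TRUE
    comb <- length(rho_grid) * Tmin
  }
  out$p_skato <- min(max(comb, Tmin), min(length(rho_grid) * Tmin, 1))
  class(out) <- "cc_region_result"
  out
}

#' Build a covariate design matrix from a covariate table
#'
#' Sequencing center becomes dummy columns (first level as reference),
#' age and sex enter linearly, and up to `n_pcs` principal-component
#' columns (`PC1`, `PC2`, ...) are included when present.
#'
#' @param covariates data.frame with `iid` and covariate columns.
#' @param n_pcs number of PC columns to use (default 4).
#' @return numeric matrix (no intercept; [fit_null()] adds it).
#' @export
cc_design <- function(covariates, n_pcs = 4) {
  parts <- list()
  if ("center" %in% names(covariates)) {
    f <- factor(covariates$center)
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0("center", levels(f)[-1])
      parts <- c(parts, list(mm))
    }
  }
  for (col in c("age", "sex"))
    if (col %in% names(covariates))
      parts <- c(parts, setNames(list(as.numeric(covariates[[col]])), col))
  pcs <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  if (length(pcs)) {
    pcs <- pcs[order(as.integer(sub("PC", "", pcs)))]
    pcs <- pcs[seq_len(min(n_pcs, length(pcs)))]
    for (col in pcs)
      parts <- c(parts, setNames(list(as.numeric(covariates[[col]])), col))
  }
  if (!length(parts)) return(NULL)
  out <- do.call(cbind, lapply(parts, as.matrix))
  nm <- unlist(lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (is.matrix(p)) colnames(p) else names(parts)[i]
  }))
  colnames(out) <- nm
  out
}

#' Scan all windows with the case-control tests
#'
#' Fits the null model once and applies the burden, SKAT and SKAT-O tests
#' per window. Monomorphic columns within a window are dropped from the
#' test (the per-window number of variants used is reported).
#'
#' @param G a [genotype_matrix()] of unrelated samples.
#' @param phenotypes data.frame (`iid`, `affection`).
#' @param covariates optional covariate table (see [cc_design()]).
#' @param windows a [build_windows()] table.
#' @param weighting `"flat"` or `"beta"`.
#' @param n_pcs PCs used from the covariate table.
#' @param method tail approximation.
#' @return data.frame with per-window `p_burden`, `p_skat`, `p_skato`,
#'   `n_used`.
#' @export
scan_cc_genome <- function(G, phenotypes, covariates = NULL, windows = NULL,
                           weighting = c("flat", "beta"), n_pcs = 4,
                           method = c("liu", "integration")) {
  weighting <- match.arg(weighting); method <- match.arg(method)
  if (is.null(windows)) windows <- build_windows(G$variants)
  ids <- rownames(G$dosage)
  y <- phenotypes$affection[match(ids, phenotypes$iid)]
  if (anyNA(y)) stop("missing phenotype for sample(s): ",
                     paste(head(ids[is.na(y)]), collapse = ", "))
  X <- if (is.null(covariates)) NULL else
    cc_design(covariates[match(ids, covariates$iid), , drop = FALSE], n_pcs)
  null <- suppressWarnings(fit_null(y, X, warn_small = FALSE))
  af <- colMeans(G$dosage, na.rm = TRUE) / 2
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    wrow <- windows[i, ]
    vidx <- wrow$vidx_start:wrow$vidx_end
    Gw <- impute_window(G$dosage[, vidx, drop = FALSE])
    use <- apply(Gw, 2, var) > 0
    if (!any(use))
      return(data.frame(window_id = wrow$window_id, p_burden = 1,
                        p_skat = 1, p_skato = 1, n_used = 0L))
    Gw <- Gw[, use, drop = FALSE]
    wts <- if (weighting == "beta") mb_weights(af[vidx][use]) else NULL
    r <- skato_test(null, Gw, weights = wts, method = method)
    data.frame(window_id = wrow$window_id, p_burden = r$p_burden,
               p_skat = r$p_skat, p_skato = r$p_skato, n_used = sum(use))
  })
  out <- cbind(windows[c("window_id", "chrom", "first_snv", "last_snv",
                         "n_variants")],
               do.call(rbind, rows)[-1])
  rownames(out) <- NULL
  out
}
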