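# Condition models: subject random intercept + factorial fixed part.
#
# lme4 supplies the (RE)ML fit; everything inferential on top of it --
# omnibus F with Satterthwaite denominator df, pairwise Sidak-adjusted
# contrasts on marginal means, omega^2 from the fixed-part ANOVA
# decomposition -- is computed here. Satterthwaite df use the analytic
# expected (REML-adjusted) information of the two variance components of
# the random-intercept model, so no numeric Hessian is needed.

# all pieces of the fitted random-intercept model the df machinery needs
ri_machinery <- function(fit, X, subject) {
  vc <- lme4::VarCorr(fit)
  sb2 <- as.numeric(vc[[1]])           # subject intercept variance
  se2 <- stats::sigma(fit)^2
  Z <- stats::model.matrix(~ 0 + factor(subject))
  n <- nrow(X)
  V <- se2 * diag(n) + sb2 * tcrossprod(Z)
  Vinv <- solve(V)
  XtVi <- crossprod(X, Vinv)
  C <- solve(XtVi %*% X)               # vcov(beta)
  P <- Vinv - t(XtVi) %*% C %*% XtVi   # REML projection
  Vd <- list(tcrossprod(Z), diag(n))   # dV/d sigma_b^2, dV/d sigma_e^2
  info <- matrix(NA_real_, 2, 2)
  PV <- lapply(Vd, function(D) P %*% D)
  for (j in 1:2) for (k in j:2)
    info[j, k] <- info[k, j] <- 0.5 * sum(t(PV[[j]]) * PV[[k]])
  A <- tryCatch(solve(info), error = function(e) MASS_ginv(info))
  # dC/d sigma_j^2 = C X' Vinv Vd_j Vinv X C
  dC <- lapply(Vd, function(D) C %*% XtVi %*% D %*% t(XtVi) %*% C)
  list(beta = lme4::fixef(fit), C = C, A = A, dC = dC,
       sb2 = sb2, se2 = se2, n = n)
}

# tiny pseudo-inverse fallback (MASS is not a dependency)
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

satt_df <- function(mach, cvec) {
  g <- drop(crossprod(cvec, mach$C %*% cvec))
  grad <- vapply(mach$dC, function(D) drop(crossprod(cvec, D %*% cvec)),
                 numeric(1))
  den <- drop(t(grad) %*% mach$A %*% grad)
  if (den <= 0) return(mach$n - length(mach$beta))
  2 * g^2 / den
}

# omnibus F for a contrast matrix L (q x p), Satterthwaite denominator df
# via the per-eigenvector recipe
f_test <- function(mach, L) {
  q <- nrow(L)
  M <- L %*% mach$C %*% t(L)
  est <- drop(L %*% mach$beta)
  Fval <- drop(crossprod(est, solve(M, est))) / q
  eig <- eigen(M, symmetric = TRUE)
  dfs <- vapply(seq_len(q), function(i)
    satt_df(mach, drop(crossprod(L, eig$vectors[, i]))), numeric(1))
  dfs <- dfs[eig$values > 1e-10 * max(eig$values)]
  dfs <- pmax(dfs, 2 + 1e-8)
  E <- sum(dfs / (dfs - 2))
  df2 <- if (E > q) 2 * E / (E - q) else 1e6
  list(F = Fval, df1 = q, df2 = df2,
       p = stats::pf(Fval, q, df2, lower.tail = FALSE))
}

#' Fit a condition model with a subject random intercept
#'
#' Fits `response ~ fixed factors (full factorial) + covariates +
#' (1 | subject)` by restricted maximum likelihood and reports, per fixed
#' term, an omnibus F test with Satterthwaite denominator degrees of
#' freedom, an omega-squared effect size from the ANOVA decomposition of
#' the fixed part (an approximation, computed by ordinary least squares on
#' the same design), FDR adjustment across terms, and Sidak-adjusted
#' pairwise contrasts of marginal means for every fixed factor.
#'
#' @param table long-format data frame, one row per subject x condition.
#' @param response name of the response column.
#' @param fixed character vector of fixed factor columns (crossed).
#' @param covariates character vector of numeric covariate columns.
#' @param subject name of the subject identifier column.
#' @return a `stat_result` list: `effects` (effect, F, df1, df2, p,
#'   p_adjusted, omega2), `contrasts` (factor, label, b, t, df, p,
#'   p_sidak), `varcomp`, `df_method`, `fit`.
#' @export
fit_condition_model <- function(table, response, fixed, covariates = NULL,
                                subject = "subject_id") {
  assert_config(length(fixed) >= 1L, "need at least one fixed factor")
  dat <- as.data.frame(table)
  dat <- dat[stats::complete.cases(dat[, c(response, fixed, covariates,
                                           subject)]), ]
  for (f in fixed) {
    dat[[f]] <- factor(dat[[f]])
    assert_config(nlevels(dat[[f]]) >= 2L,
                  "fixed factor '%s' needs >= 2 levels", f)
    # sum-to-zero coding so term-wise F tests are marginal (Type-III-style)
    # main effects even in the presence of interactions
    stats::contrasts(dat[[f]]) <- stats::contr.sum(nlevels(dat[[f]]))
  }
  rhs_fixed <- paste(fixed, collapse = " * ")
  rhs <- paste(c(rhs_fixed, covariates), collapse = " + ")
  fml_fixed <- stats::as.formula(paste(response, "~", rhs))
  X <- stats::model.matrix(fml_fixed, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    config_error("rank-deficient fixed design; aliased terms: %s",
                 paste(aliased, collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", subject, ")"))
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  mach <- ri_machinery(fit, X, dat[[subject]])

  assign <- attr(X, "assign")
  labels <- attr(stats::terms(fml_fixed), "term.labels")
  # report omnibus tests for the factor terms only; covariates are nuisance
  factor_terms <- which(!labels %in% covariates)
  eff <- list()
  for (ti in factor_terms) {
    cols <- which(assign == ti)
    L <- matrix(0, length(cols), ncol(X))
    L[cbind(seq_along(cols), cols)] <- 1
    ft <- f_test(mach, L)
    eff[[length(eff) + 1L]] <- data.frame(effect = labels[ti], F = ft$F,
                                          df1 = ft$df1, df2 = ft$df2,
                                          p = ft$p, stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, eff)
  effects$p_adjusted <- fdr_bh(effects$p)

  # omega^2 from the sequential ANOVA table of the fixed part (OLS)
  ols <- stats::lm(fml_fixed, dat)
  av <- stats::anova(ols)
  ss_total <- sum(av$`Sum Sq`)
  ms_error <- av$`Mean Sq`[nrow(av)]
  effects$omega2 <- vapply(effects$effect, function(lbl) {
    i <- match(lbl, rownames(av))
    omega_squared(av$`Sum Sq`[i], av$Df[i], ms_error, ss_total)
  }, numeric(1))

  # pairwise contrasts of marginal means per fixed factor: average the
  # prediction rows of the full factor grid (covariates at their means)
  grid <- expand.grid(lapply(dat[fixed], levels), stringsAsFactors = TRUE)
  names(grid) <- fixed
  for (f in fixed) {
    grid[[f]] <- factor(grid[[f]], levels = levels(dat[[f]]))
    stats::contrasts(grid[[f]]) <- stats::contr.sum(nlevels(grid[[f]]))
  }
  for (cv in covariates) grid[[cv]] <- mean(dat[[cv]])
  G <- stats::model.matrix(stats::delete.response(stats::terms(fml_fixed)),
                           grid)
  contrasts <- list()
  for (f in fixed) {
    lev <- levels(dat[[f]])
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    m <- length(pairs)
    for (pr in pairs) {
      c1 <- colMeans(G[grid[[f]] == pr[1], , drop = FALSE])
      c2 <- colMeans(G[grid[[f]] == pr[2], , drop = FALSE])
      cvec <- c1 - c2
      b <- drop(crossprod(cvec, mach$beta))
      se <- sqrt(drop(crossprod(cvec, mach$C %*% cvec)))
      df <- satt_df(mach, cvec)
      tval <- b / se
      p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        factor = f, label = paste(pr[1], "-", pr[2]), b = b, t = tval,
        df = df, p = p, p_sidak = sidak_adjust(p, m),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(effects = effects,
                 contrasts = do.call(rbind, contrasts),
                 varcomp = c(subject = mach$sb2, residual = mach$se2),
                 df_method = "satterthwaite", n_obs = nrow(dat),
                 formula = deparse(fml), fit = fit),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("condition model (", x$formula, ")\n", sep = "")
  cat(sprintf("variance components: subject %.4g, residual %.4g; df: %s\n",
              x$varcomp["subject"], x$varcomp["residual"], x$df_method))
  print(x$effects, row.names = FALSE, digits = 4)
  cat("post hoc contrasts (Sidak-adjusted):\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
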