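#' PLSC configuration
#'
#' @param n_perm permutations for the singular-value test (default 5000).
#' @param n_boot bootstrap resamples for salience stability (default 5000).
#' @param z_threshold robustness cutoff on |bootstrap ratio| (default 1.96).
#' @param seed integer seed.
#' @return a `plsc_config` list.
#' @export
plsc_config <- function(n_perm = 5000L, n_boot = 5000L, z_threshold = 1.96,
                        seed = 1L) {
  assert_config(n_perm >= 100L && n_boot >= 100L,
                "n_perm and n_boot must be >= 100")
  assert_config(z_threshold > 0, "z_threshold must be > 0")
  list(n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
       z_threshold = z_threshold, seed = as.integer(seed))
}

zscore <- function(x) (x - mean(x)) / stats::sd(x)

# behavior-ROI correlation row vector on z-standardized inputs
plsc_R <- function(Xz, bz) drop(crossprod(bz, Xz)) / (length(bz) - 1)

#' Fit a partial least squares correlation model
#'
#' Standardizes the ROI metric columns and the behavior vector, forms the
#' 1 x k behavior-brain correlation matrix R, and decomposes it by SVD
#' (R = U S V'). With a single behavior variable the solution is rank one:
#' the salience vector V is proportional to R and S = ||R||; this analytic
#' identity is asserted against the numeric decomposition on every fit.
#' Saliences are oriented so that the Spearman correlation between brain
#' scores (standardized metrics projected on V) and behavior is
#' non-negative. Rows with missing values are dropped listwise (logged in
#' `n_dropped`).
#'
#' @param metrics a `roi_metric_table` (or list with `metrics`, `behavior`,
#'   `group`).
#' @param config a [plsc_config()].
#' @return a `plsc_model`: `R`, `S`, `V` (saliences), `U`, `brain_scores`,
#'   `latent_r` (Spearman), `roi_r` (per-ROI Spearman correlation with
#'   behavior), `group`, `n`, `n_dropped`.
#' @export
plsc_fit <- function(metrics, config = plsc_config()) {
  X <- as.matrix(metrics$metrics)
  b <- as.numeric(metrics$behavior)
  grp <- metrics$group %||% rep("all", length(b))
  keep <- stats::complete.cases(X) & is.finite(b)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  b <- b[keep]
  grp <- grp[keep]
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 2)
    warning(sprintf("plsc_fit: n = %d < k + 2 = %d; estimates may be unstable",
                    n, k + 2))
  const <- apply(X, 2, stats::sd) == 0
  if (any(const))
    config_error("constant metric column(s): %s",
                 paste(colnames(X)[const], collapse = ", "))
  if (stats::sd(b) == 0)
    config_error("behavior vector is constant")
  Xz <- apply(X, 2, zscore)
  bz <- zscore(b)
  R <- plsc_R(Xz, bz)
  sv <- svd(matrix(R, nrow = 1))
  S <- sv$d[1]
  V <- drop(sv$v[, 1])
  U <- drop(sv$u[, 1])
  # analytic rank-one identity, asserted on every fit
  stopifnot(abs(S - sqrt(sum(R^2))) < 1e-8,
            max(abs(abs(V) - abs(R) / sqrt(sum(R^2)))) < 1e-8)
  scores <- drop(Xz %*% V)
  latent_r <- stats::cor(scores, b, method = "spearman")
  if (!is.na(latent_r) && latent_r < 0) {
    V <- -V; U <- -U; scores <- -scores; latent_r <- -latent_r
  }
  roi_r <- apply(X, 2, stats::cor, y = b, method = "spearman")
  structure(list(R = setNames(R, colnames(X)), S = S,
                 V = setNames(V, colnames(X)), U = U,
                 brain_scores = setNames(scores, rownames(X)),
                 latent_r = latent_r, roi_r = roi_r, group = grp,
                 behavior = b, Xz = Xz, n = n, n_dropped = n_dropped,
                 config = config),
            class = "plsc_model")
}

#' @export
print.plsc_model <- function(x, ...) {
  cat(sprintf("plsc_model: n = %d, k = %d ROIs, S = %.4f, latent Spearman r = %.3f\n",
              x$n, length(x$V), x$S, x$latent_r))
  print(round(rbind(salience = x$V, roi_r = x$roi_r), 3))
  invisible(x)
}

#' Permutation test of the PLSC singular value
#'
#' The behavior vector is permuted across subjects `n_perm` times, the
#' singular value recomputed each draw, and
#' `p = (1 + #\{S* >= S_obs\}) / (1 + n_perm)`.
#'
#' @param model a fitted `plsc_model`.
#' @param config a [plsc_config()] (defaults to the model's).
#' @return a `permutation_result` list: `statistic` (observed S), `p`,
#'   `n_draws`, `degenerate`, `seed`.
#' @export
plsc_perm_test <- function(model, config = model$config) {
  stopifnot(inherits(model, "plsc_model"))
  if (stats::sd(model$behavior) == 0)
    return(structure(list(statistic = NA_real_, p = 1, n_draws = 0L,
                          degenerate = TRUE, seed = config$seed),
                     class = "permutation_result"))
  bz <- zscore(model$behavior)
  n <- length(bz)
  with_seed(derive_seed(config$seed, 1L), {
    # all permuted behavior vectors at once: S* = row norms of B' Xz / (n-1)
    B <- vapply(seq_len(config$n_perm), function(i) bz[sample.int(n)],
                numeric(n))
    Rstar <- crossprod(B, model$Xz) / (n - 1)
    Sstar <- sqrt(rowSums(Rstar^2))
    p <- (1 + sum(Sstar >= model$S - 1e-12)) / (1 + config$n_perm)
    structure(list(statistic = model$S, p = p, n_draws = config$n_perm,
                   degenerate = FALSE, seed = config$seed),
              class = "permutation_result")
  })
}

#' Bootstrap ratios for PLSC saliences
#'
#' Subjects are resampled with replacement `n_boot` times; each draw's
#' salience vector is sign-aligned to the original (flipped when the dot
#' product is negative) to resolve reflection indeterminacy, and the
#' bootstrap ratio is the original salience divided by the bootstrap SD.
#' ROIs with `|BSR| > z_threshold` are flagged robust. Draws yielding a
#' constant column or constant behavior are redrawn (capped, logged).
#'
#' @param model a fitted `plsc_model`.
#' @param config a [plsc_config()] (defaults to the model's).
#' @return list: `bsr` (named vector), `robust` (logical), `boot_sd`,
#'   `n_redrawn`.
#' @export
plsc_bootstrap_bsr <- function(model, config = model$config) {
  stopifnot(inherits(model, "plsc_model"))
  n <- model$n
  k <- length(model$V)
  X <- model$Xz
  b <- model$behavior
  Vb <- matrix(NA_real_, config$n_boot, k)
  n_redrawn <- 0L
  with_seed(derive_seed(config$seed, 2L), {
    for (i in seq_len(config$n_boot)) {
      for (try in seq_len(50L)) {
        idx <- sample.int(n, replace = TRUE)
        Xs <- X[idx, , drop = FALSE]
        bs <- b[idx]
        sds <- apply(Xs, 2, stats::sd)
        if (all(sds > 0) && stats::sd(bs) > 0) break
        n_redrawn <- n_redrawn + 1L
        if (try == 50L) config_error("bootstrap draw degenerate after 50 retries")
      }
      Xsz <- scale(Xs)
      bsz <- zscore(bs)
      Rs <- plsc_R(Xsz, bsz)
      v <- Rs / sqrt(sum(Rs^2))
      if (sum(v * model$V) < 0) v <- -v
      Vb[i, ] <- v
    }
  })
  boot_sd <- apply(Vb, 2, stats::sd)
  bsr <- model$V / boot_sd
  robust <- abs(bsr) > config$z_threshold
  list(bsr = setNames(bsr, names(model$V)),
       robust = setNames(robust, names(model$V)),
       boot_sd = boot_sd, n_redrawn = n_redrawn)
}

#' Compare PLSC brain scores between two groups
#'
#' Welch two-sample t-test on the per-subject brain scores.
#'
#' @param model a fitted `plsc_model` with exactly two group labels.
#' @param groups optional group vector overriding the model's.
#' @return list: `t`, `df`, `p`, `means` (per group), `flag` (set when a
#'   group has zero variance).
#' @export
compare_brain_scores <- function(model, groups = model$group) {
  stopifnot(inherits(model, "plsc_model"))
  g <- unique(groups)
  assert_config(length(g) == 2L, "exactly two groups required, got %d",
                length(g))
  s1 <- model$brain_scores[groups == g[1]]
  s2 <- model$brain_scores[groups == g[2]]
  assert_config(length(s1) >= 3L && length(s2) >= 3L,
                "each group needs n >= 3")
  flag <- NULL
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0)
    flag <- "zero variance in a group"
  tt <- stats::t.test(s1, s2)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       means = setNames(c(mean(s1), mean(s2)), g), flag = flag)
}
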