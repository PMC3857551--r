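# Spatial ICA of the modeled-activation matrix: SVD reduction and
# whitening, fixed-point ICA with symmetric decorrelation, conversion of
# component maps to z-statistic images through a Gaussian-background
# mixture fit, and per-decomposition component statistics.

#' Reduce a modeled-activation matrix by SVD and whiten
#'
#' Works on the `e x v` experiment-by-voxel matrix (the transpose of the
#' stored MA values).  Each voxel column is centred by removing its mean
#' across experiments (the standard probabilistic-ICA preprocessing);
#' per-column variance normalization is available but off by default.  The
#' SVD is obtained from the eigendecomposition of the `e x e` Gram matrix,
#' so cost is linear in the number of voxels.
#'
#' @param ma an `ma_matrix` from [stack_corpus()], or a bare `v x e`
#'   numeric matrix.
#' @param d retained model order, `<= rank` of the centred matrix.
#' @param center remove the voxelwise mean across experiments (default
#'   TRUE).
#' @param scale_experiments z-score experiment rows before reduction
#'   (default FALSE).
#' @return List with `experiment_modes` (`e x d`, the experiment-mode
#'   singular vectors scaled by their singular values, `U_d %*% diag(s_d)`),
#'   `singular_values` (non-increasing, all retained up to rank),
#'   `whitened` (`d x v` spatial data with identity voxelwise covariance:
#'   `tcrossprod(whitened) / v = I`), and `rank`.
#' @export
reduce_svd <- function(ma, d, center = TRUE, scale_experiments = FALSE) {
  values <- if (inherits(ma, "ma_matrix")) ma$values else as.matrix(ma)
  X <- t(values)                       # e x v
  e <- nrow(X); v <- ncol(X)
  d <- as.integer(d)
  if (d < 1) stopf("'d' must be a positive integer")
  if (d > min(e, v)) stopf("d = %d exceeds min(e, v) = %d", d, min(e, v))
  if (scale_experiments) {
    sds <- apply(X, 1, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(sweep(X, 1, rowMeans(X)), 1, sds, `/`)
  }
  if (center) X <- sweep(X, 2, colMeans(X))
  G <- tcrossprod(X)                   # e x e
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  sv <- sqrt(ev)
  rank <- sum(ev > max(ev[1], 0) * 1e-12)
  if (rank == 0) stopf("matrix is identically zero after centering")
  if (d > rank)
    stopf("d = %d exceeds the achievable rank %d of the centred matrix", d, rank)
  U <- eg$vectors[, seq_len(d), drop = FALSE]
  s <- sv[seq_len(d)]
  # rows of whitened: sqrt(v)/s_i * u_i' X, so tcrossprod(whitened)/v = I
  whitened <- sweep(crossprod(U, X), 1, s / sqrt(v), `/`)
  list(
    experiment_modes = sweep(U, 2, s, `*`),
    singular_values = sv[seq_len(rank)],
    whitened = whitened,
    rank = rank
  )
}

#' Fixed-point spatial ICA on whitened data
#'
#' FastICA-style symmetric (parallel) fixed-point iteration with the
#' `tanh` contrast, on `d x v` whitened spatial data.  Sources are
#' decorrelated at every step by symmetric orthogonalization; convergence
#' is declared when the largest change in the absolute diagonal of
#' `W_new %*% t(W_old)` falls below `tol`.  Two deterministic conventions
#' are applied to the converged solution: each source is sign-flipped so
#' its skewness is non-negative (activation foci are positive-tailed), and
#' components are ordered by explained data variance, descending.
#'
#' @param red output of [reduce_svd()] (or a list with `whitened`,
#'   `experiment_modes`, `singular_values`).
#' @param d model order; must equal `nrow(red$whitened)`.
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter maximum fixed-point iterations (default 1000).
#' @param tol convergence tolerance (default 1e-6).
#' @return A `decomposition`: list with `d`, `sources` (`d x v`, unit
#'   variance over voxels), `mixing` (`d x d`; `mixing %*% sources`
#'   reconstructs the whitened data, and `experiment_modes %*% mixing`
#'   gives experiment weightings), `experiment_modes`, `singular_values`,
#'   `seed`, `iterations`, `tol_achieved`.
#' @export
fit_ica <- function(red, d = nrow(red$whitened), seed = 1L,
                    max_iter = 1000L, tol = 1e-6) {
  Y <- red$whitened
  d <- as.integer(d)
  if (d != nrow(Y))
    stopf("d = %d does not match the whitened data (%d rows); rerun reduce_svd",
          d, nrow(Y))
  v <- ncol(Y)
  W <- with_seed(substream_seed(seed, 7L), {
    qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  })
  sym_orth <- function(W) {
    S <- W %*% t(W)
    es <- eigen(S, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)), d) %*%
      t(es$vectors) %*% W
  }
  W <- sym_orth(W)
  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    WY <- W %*% Y
    G <- tanh(WY)
    gprime <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Y) / v - diag(gprime, d) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  if (delta >= tol)
    stopf("ICA did not converge after %d iterations (last delta = %.3g, tol = %.1g)",
          it, delta, tol)
  S <- W %*% Y
  # sign convention: non-negative skewness per source
  ctr <- S - rowMeans(S)
  skew <- rowMeans(ctr^3) / rowMeans(ctr^2)^1.5
  flip <- ifelse(skew < 0, -1, 1)
  S <- S * flip
  W <- W * flip
  # order by explained data variance: energy of U_d S_d W' columns
  sd_ <- red$singular_values[seq_len(d)]
  ev_contrib <- colSums((sd_ * t(W))^2)   # ||diag(s) W'[, k]||^2
  ord <- order(ev_contrib, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  S <- S[ord, , drop = FALSE]
  structure(
    list(
      d = d,
      sources = S,
      mixing = t(W),
      experiment_modes = red$experiment_modes[, seq_len(d), drop = FALSE],
      singular_values = red$singular_values,
      seed = as.integer(seed),
      iterations = it,
      tol_achieved = delta
    ),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> d = %d, %d voxels, converged in %d iterations\n",
              x$d, ncol(x$sources), x$iterations))
  invisible(x)
}

# Gaussian-background mixture fit for one source map.
# Model: background Gaussian plus positive and negative activation tails
# (each Gaussian), fitted by EM with robust median/MAD initialization.
# Voxels never touched by any modeled activation are an exact point mass
# (identical value) in every source; a continuous background cannot
# represent it, so a point mass holding > 5% of the voxels is excluded
# from the fit (detected by exact value, keeping the fit equivariant
# under affine maps of the source).
# Returns list(mu, sd, weight, converged, method).

# drop an exact point mass holding > 5% of the values, if present
strip_point_mass <- function(x) {
  dup <- x[duplicated(x)]
  if (length(dup) >= 0.05 * length(x)) {
    tab <- table(dup)
    mode_val <- as.numeric(names(tab)[which.max(tab)])
    if (sum(x == mode_val) >= 0.05 * length(x)) x <- x[x != mode_val]
  }
  x
}

fit_null_gaussian <- function(x, max_iter = 100L, tol = 1e-6) {
  x <- strip_point_mass(x)
  med <- stats::median(x)
  s0 <- stats::mad(x)
  if (s0 == 0) s0 <- stats::sd(x)
  robust <- list(mu = med, sd = s0, weight = 1, converged = FALSE,
                 method = "robust")
  if (!is.finite(s0) || s0 == 0) return(robust)
  # fit on the robustly standardized scale so the result is exactly
  # equivariant under affine maps of the source
  x <- (x - med) / s0
  mu <- c(0, 4, -4)
  sg <- c(1, 2, 2)
  w <- c(0.94, 0.03, 0.03)
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(x, mu[k], sg[k]),
                   numeric(n))
    tot <- rowSums(dens) + 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- pmax(nk / n, 1e-6)
    w <- w / sum(w)
    for (k in 1:3) {
      if (nk[k] < 1e-8) next
      mu[k] <- sum(resp[, k] * x) / nk[k]
      sg[k] <- sqrt(sum(resp[, k] * (x - mu[k])^2) / nk[k])
      sg[k] <- max(sg[k], 1e-3)
    }
    # keep the tail components on their sides of the background
    if (mu[2] < mu[1]) mu[2] <- mu[1] + 2 * sg[1]
    if (mu[3] > mu[1]) mu[3] <- mu[1] - 2 * sg[1]
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged || !is.finite(mu[1]) || !is.finite(sg[1]) || sg[1] <= 0)
    return(robust)
  list(mu = med + s0 * mu[1], sd = s0 * sg[1], weight = w[1],
       converged = TRUE, method = "mixture")
}

#' Convert component maps to z-statistic images
#'
#' Per component, a Gaussian null is fitted to the background of the
#' source-value histogram -- a three-part mixture (background Gaussian plus
#' positive and negative activation tails) fitted by EM with median/MAD
#' initialization; if the EM fit fails the robust median/MAD
#' standardization is used.  `z = (source - null mean) / null sd`.
#' Thresholding is applied downstream; `threshold` is only recorded here.
#'
#' @param decomp a `decomposition`.
#' @param threshold z threshold recorded for downstream use (default 4).
#' @param method `"mixture"` (default) or `"robust"` to force plain
#'   median/MAD standardization.
#' @return A `zmaps`: list with `zvalues` (`d x v`), `threshold`,
#'   `background_fit` (data.frame: component, mu, sd, weight, method).
#' @export
to_zmaps <- function(decomp, threshold = 4, method = c("mixture", "robust")) {
  method <- match.arg(method)
  S <- if (is.list(decomp) && !is.null(decomp$sources)) decomp$sources
       else as.matrix(decomp)
  d <- nrow(S)
  Z <- matrix(NA_real_, d, ncol(S))
  fits <- vector("list", d)
  for (k in seq_len(d)) {
    x <- S[k, ]
    if (!all(is.finite(x))) stopf("component %d contains non-finite values", k)
    if (max(x) == min(x)) stopf("component %d is constant; z-scores undefined", k)
    fit <- if (method == "robust") {
      xm <- strip_point_mass(x)
      list(mu = stats::median(xm), sd = stats::mad(xm), weight = 1,
           converged = TRUE, method = "robust")
    } else {
      fit_null_gaussian(x)
    }
    if (fit$sd <= 0) {
      fit$sd <- stats::sd(x)
      fit$method <- "sd-fallback"
    }
    Z[k, ] <- (x - fit$mu) / fit$sd
    fits[[k]] <- fit
  }
  structure(
    list(
      zvalues = Z,
      threshold = threshold,
      background_fit = data.frame(
        component = seq_len(d),
        mu = vapply(fits, `[[`, 0, "mu"),
        sd = vapply(fits, `[[`, 0, "sd"),
        weight = vapply(fits, `[[`, 0, "weight"),
        method = vapply(fits, `[[`, "", "method")
      )
    ),
    class = "zmaps"
  )
}

#' Supra-threshold component statistics
#'
#' For each component, counts voxels with `z` strictly above the recorded
#' threshold and averages `z` over them.  Components with no
#' supra-threshold voxel contribute 0 to the voxel-count mean and are
#' excluded from the mean-z summary (reported `NA` if every component is
#' sub-threshold).
#'
#' @param zmaps a `zmaps`.
#' @return A `component_stats`: list with `d`, `mean_sig_voxels`,
#'   `mean_sig_z`, and `per_component` (data.frame: component,
#'   n_sig_voxels, mean_sig_z).
#' @export
component_stats <- function(zmaps) {
  Z <- zmaps$zvalues
  thr <- zmaps$threshold
  d <- nrow(Z)
  n_sig <- integer(d)
  mz <- rep(NA_real_, d)
  for (k in seq_len(d)) {
    sup <- Z[k, ] > thr
    n_sig[k] <- sum(sup)
    if (n_sig[k] > 0) mz[k] <- mean(Z[k, sup])
  }
  structure(
    list(
      d = d,
      mean_sig_voxels = mean(n_sig),
      mean_sig_z = if (any(n_sig > 0)) mean(mz[n_sig > 0]) else NA_real_,
      per_component = data.frame(component = seq_len(d), n_sig_voxels = n_sig,
                                 mean_sig_z = mz)
    ),
    class = "component_stats"
  )
}

#' @export
print.component_stats <- function(x, ...) {
  cat(sprintf("<component_stats> d = %d: mean sig voxels %.1f, mean sig z %.3f\n",
              x$d, x$mean_sig_voxels, x$mean_sig_z))
  invisible(x)
}

#' Write per-component statistics as CSV
#'
#' Columns: d, component, n_sig_voxels, mean_sig_z.
#'
#' @param stats a `component_stats`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_stats <- function(stats, path) {
  df <- cbind(d = stats$d, stats$per_component)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write decomposition matrices as CSV files
#'
#' Writes `mixing.csv`, `experiment_modes.csv` and
#' `singular_values.csv` into `dir` (spatial sources are written as NIfTI
#' via [write_ma_nifti()] instead, being volumetric).
#'
#' @param decomp a `decomposition`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(decomp$mixing, file.path(dir, "mixing.csv"),
                   row.names = FALSE)
  utils::write.csv(decomp$experiment_modes,
                   file.path(dir, "experiment_modes.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(singular_value = decomp$singular_values),
    file.path(dir, "singular_values.csv"), row.names = FALSE
  )
  invisible(dir)
}
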