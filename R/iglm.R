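#' Incremental general linear model
#'
#' Accumulates the sufficient statistics of a least-squares fit
#' (X'X, X'y, y'y and the scan count) one volume at a time, so each
#' update costs O(p^2) regardless of history length and the estimates
#' at any scan equal a batch fit on the same prefix. `y` may be a
#' vector (one value per voxel), giving a whole-brain map from one
#' state.
#'
#' @param design_columns character labels of the regressors.
#' @param n_targets number of target series fitted jointly (voxels).
#' @return an `iglm` state with zeroed statistics.
#' @export
iglm <- function(design_columns, n_targets = 1L) {
  p <- length(design_columns)
  structure(list(xtx = matrix(0, p, p), xty = matrix(0, p, n_targets),
                 yty = numeric(n_targets), n = 0L,
                 design_columns = design_columns),
            class = "iglm")
}

#' Absorb one scan into an incremental GLM
#'
#' @param state an [iglm()] state.
#' @param x_row regressor values for this scan (length p).
#' @param y target value(s) for this scan (length `n_targets`).
#' @return the updated state.
#' @export
iglm_update <- function(state, x_row, y) {
  p <- length(state$design_columns)
  if (length(x_row) != p)
    stop("x_row must have one value per design column", call. = FALSE)
  if (length(y) != ncol(state$xty))
    stop("y must have one value per target series", call. = FALSE)
  state$xtx <- state$xtx + tcrossprod(x_row)
  state$xty <- state$xty + outer(x_row, y)
  state$yty <- state$yty + y^2
  state$n <- state$n + 1L
  state
}

#' Estimates from an incremental GLM state
#'
#' Solves the accumulated normal equations: beta = (X'X)^-1 X'y,
#' residual variance from y'y - beta' X'y with n - p degrees of
#' freedom, and a t statistic per contrast.
#'
#' @param state an [iglm()] state with `n > p`.
#' @param contrasts numeric contrast vector, or a matrix with one
#'   contrast per row; default tests the last design column.
#' @param ridge ridge fallback added to the diagonal (as a fraction of
#'   mean diagonal) when X'X is singular; `NULL` disables the fallback
#'   and singularity is an error naming the collinear columns.
#' @return list with `betas` (p x targets), `sigma2`, `df`, and `t`
#'   (contrasts x targets).
#' @export
iglm_estimates <- function(state, contrasts = NULL, ridge = NULL) {
  p <- length(state$design_columns)
  if (state$n <= p)
    stop("need more scans than design columns (n = ", state$n, ", p = ",
         p, ")", call. = FALSE)
  xtx <- state$xtx
  if (rcond(xtx) < 1e-12) {
    if (is.null(ridge)) {
      d <- svd(xtx)$d
      bad <- state$design_columns[d < max(d) * 1e-12]
      stop("singular design: collinear column(s) ",
           paste(state$design_columns, collapse = ", "),
           if (length(bad)) paste0(" (suspect: ",
                                   paste(bad, collapse = ", "), ")"),
           call. = FALSE)
    }
    message("singular X'X: ridge fallback applied")
    xtx <- xtx + ridge * mean(diag(xtx)) * diag(p)
  }
  xtx_inv <- solve(xtx)
  betas <- xtx_inv %*% state$xty
  df <- state$n - p
  rss <- pmax(state$yty - colSums(betas * state$xty), 0)
  sigma2 <- rss / df
  if (is.null(contrasts))
    contrasts <- matrix(c(rep(0, p - 1), 1), nrow = 1)
  if (!is.matrix(contrasts)) contrasts <- matrix(contrasts, nrow = 1)
  tmat <- matrix(NA_real_, nrow(contrasts), ncol(betas))
  for (i in seq_len(nrow(contrasts))) {
    cv <- contrasts[i, ]
    denom <- sqrt(sigma2 * drop(t(cv) %*% xtx_inv %*% cv))
    tmat[i, ] <- drop(cv %*% betas) / ifelse(denom > 0, denom, NA_real_)
  }
  list(betas = betas, sigma2 = sigma2, df = df, t = tmat)
}

#' @export
print.iglm <- function(x, ...) {
  cat(sprintf("<iglm> %d scan(s) absorbed, %d regressor(s) [%s], %d target(s)\n",
              x$n, length(x$design_columns),
              paste(x$design_columns, collapse = ", "), ncol(x$xty)))
  invisible(x)
}

#' @export
coef.iglm <- function(object, ...) {
  est <- iglm_estimates(object, ...)
  b <- est$betas
  rownames(b) <- object$design_columns
  drop(b)
}

# standard online design row: intercept + linear drift + convolved task
# regressor, for scan k (1-based)
design_row <- function(k, regressor) c(1, k, regressor[k])
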