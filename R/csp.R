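#' Train common spatial patterns from two window classes
#'
#' Solves the generalized eigenproblem of the two class-mean covariance
#' matrices (whitening by the composite covariance): filters at the top
#' of the spectrum maximize the Task/Rest variance ratio, those at the
#' bottom minimize it. The `n_pairs` filters from each end of the
#' spectrum are kept. Patterns (the forward model of each component) are
#' the corresponding columns of the inverse of the full filter matrix.
#'
#' @param task_windows,rest_windows lists of channels-by-samples
#'   matrices (band-passed to the feature band first).
#' @param n_pairs filters kept from each end of the eigenvalue spectrum.
#' @param shrinkage covariance shrinkage toward the scaled identity; 0
#'   requests none, but it is applied (and noted in the result) when a
#'   covariance is rank deficient.
#' @return a `csp_model`: `filters` (components x channels), `patterns`
#'   (channels x components), `eigenvalues` (full spectrum, decreasing),
#'   `n_pairs`, `shrinkage_applied`.
#' @export
train_csp <- function(task_windows, rest_windows, n_pairs = 3L,
                      shrinkage = 0) {
  if (length(task_windows) < 2L || length(rest_windows) < 2L)
    stop("need at least two windows per class", call. = FALSE)
  c1 <- class_covariance(task_windows)
  c2 <- class_covariance(rest_windows)
  nch <- nrow(c1)
  n_pairs <- min(as.integer(n_pairs), nch %/% 2L)
  comp <- c1 + c2
  shrinkage_applied <- shrinkage
  if (shrinkage == 0 && rcond(comp) < 1e-10) {
    shrinkage_applied <- 0.05
    message("rank-deficient covariance: shrinkage 0.05 applied")
  }
  if (shrinkage_applied > 0) {
    shrink <- function(C) (1 - shrinkage_applied) * C +
      shrinkage_applied * mean(diag(C)) * diag(nch)
    c1 <- shrink(c1); c2 <- shrink(c2); comp <- c1 + c2
  }
  # whiten by the composite covariance, then diagonalize class 1
  ec <- eigen(comp, symmetric = TRUE)
  pos <- ec$values > max(ec$values) * 1e-12
  P <- diag(1 / sqrt(ec$values[pos]), sum(pos)) %*% t(ec$vectors[, pos,
                                                                 drop = FALSE])
  S1 <- P %*% c1 %*% t(P)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W_full <- t(e1$vectors) %*% P             # rows = filters, eig decreasing
  # deterministic sign: largest-magnitude coefficient positive
  for (i in seq_len(nrow(W_full))) {
    j <- which.max(abs(W_full[i, ]))
    if (W_full[i, j] < 0) W_full[i, ] <- -W_full[i, ]
  }
  A_full <- solve_patterns(W_full)          # channels x components
  sel <- c(seq_len(n_pairs), nrow(W_full) - seq_len(n_pairs) + 1L)
  structure(list(filters = W_full[sel, , drop = FALSE],
                 patterns = A_full[, sel, drop = FALSE],
                 eigenvalues = e1$values,
                 n_pairs = n_pairs,
                 selected = sel,
                 shrinkage_applied = shrinkage_applied),
            class = "csp_model")
}

# Moore-Penrose pseudo-inverse of the filter matrix; its columns are
# the spatial patterns of the corresponding components
solve_patterns <- function(W) {
  sv <- svd(W)
  keep <- sv$d > max(sv$d) * 1e-12
  sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep], sum(keep)) %*%
    t(sv$u[, keep, drop = FALSE])
}

class_covariance <- function(windows) {
  covs <- lapply(windows, function(w) {
    w <- w - rowMeans(w)
    C <- w %*% t(w)
    C / sum(diag(C))
  })
  Reduce(`+`, covs) / length(covs)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filter(s) over %d channels (%d pairs)\n",
              nrow(x$filters), ncol(x$filters), x$n_pairs))
  cat("  eigenvalue spectrum:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

# separation score: how far the extreme eigenvalues sit from the
# uninformative 0.5 (0.5 = no class difference)
csp_separation <- function(model) {
  ev <- model$eigenvalues
  max(abs(ev - 0.5)) + 0.5
}

#' Band-power feature of one window under a CSP model
#'
#' Projects the (band-passed) window through the selected spatial
#' filters and returns the mean log-variance across components -- the
#' standard band-power statistic for CSP-based neurofeedback.
#'
#' @param window channels-by-samples matrix, band-passed to the model's
#'   band.
#' @param model a `csp_model` (or any components-by-channels filter
#'   matrix).
#' @param eps variance floor; zero-variance windows return `log(eps)`
#'   with a warning instead of `-Inf`.
#' @return scalar feature.
#' @export
eeg_feature <- function(window, model, eps = 1e-12) {
  W <- if (inherits(model, "csp_model")) model$filters else model
  proj <- W %*% window
  v <- apply(proj, 1, var)
  if (all(v < eps)) {
    warning("zero-variance window: feature floored at log(eps)")
    return(log(eps))
  }
  mean(log(pmax(v, eps)))
}
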