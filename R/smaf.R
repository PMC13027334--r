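#' Repeated train/test partitions of a cell population
#'
#' Randomly and independently divides cells into a training fraction and
#' a held-out remainder, repeated `n_repeats` times.  With
#' `unit = "donor"` all cells of a donor fall on one side of every split
#' (see [donor_split()]), which prevents donor identity leaking across
#' the partition.
#'
#' @param cells data frame of cell metadata with `cell_id` and (for
#'   donor mode) `donor` columns.
#' @param n_repeats number of independent partitions (default 10).
#' @param train_fraction fraction of cells in training (default 0.7).
#' @param unit "cell" or "donor".
#' @param seed integer seed; per-repeat seeds are derived from it.
#' @return list of `n_repeats` lists with elements `train` and `test`
#'   (cell-id character vectors, disjoint).
#' @export
make_partitions <- function(cells, n_repeats = 10, train_fraction = 0.7,
                            unit = c("cell", "donor"), seed = 1) {
  unit <- match.arg(unit)
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  ids <- cells$cell_id
  if (unit == "cell" && length(ids) < 10)
    stop("make_partitions: need >= 10 cells")
  if (unit == "donor" && length(unique(cells$donor)) < 2)
    stop("make_partitions: need >= 2 donors in donor mode")
  lapply(seq_len(n_repeats), function(i) {
    s <- (seed + 7919L * i) %% .Machine$integer.max
    if (unit == "cell") {
      set.seed(s)
      tr <- sample(ids, floor(train_fraction * length(ids)))
      list(train = tr, test = setdiff(ids, tr))
    } else {
      donor_split(cells, ratio = train_fraction, seed = s,
                  require_both_classes = FALSE)
    }
  })
}

## ---------------------------------------------------------------------
## sparse coding: batched greedy non-negative pursuit with support <= k
## ---------------------------------------------------------------------
## Classic orthogonal greedy pursuit per cell: at each step add the atom
## with the largest positive normalized correlation to the residual, then
## re-solve least squares on the active set with non-negativity enforced
## by active-set dropping.  Atom selection is batched across cells.
smaf_sparse_code <- function(X, U, k) {
  G <- nrow(X); N <- ncol(X); d <- ncol(U)
  W <- matrix(0, d, N)
  norms2 <- colSums(U^2)
  usable <- norms2 > 1e-12
  if (!any(usable)) return(W)
  inv_norm <- ifelse(usable, 1 / sqrt(norms2), 0)
  Gram <- crossprod(U)
  Ub <- crossprod(U, X)                 # d x N
  active <- matrix(FALSE, d, N)
  frozen <- rep(FALSE, N)
  nnls_support <- function(s, b) {
    # tiny non-negative LS on support s: unconstrained solve, drop the
    # most negative atom until feasible
    while (length(s)) {
      w <- tryCatch(solve(Gram[s, s, drop = FALSE], b[s]),
                    error = function(e) rep(0, length(s)))
      if (all(w >= -1e-12)) return(list(s = s, w = pmax(w, 0)))
      s <- s[-which.min(w)]
    }
    list(s = integer(0), w = numeric(0))
  }
  R <- X
  for (step in seq_len(k)) {
    if (all(frozen)) break
    C <- crossprod(U, R)                # d x N correlations
    score <- C * inv_norm
    score[!usable, ] <- -Inf
    score[active] <- -Inf
    j_star <- max.col(t(score), ties.method = "first")
    gain <- score[cbind(j_star, seq_len(N))]
    newly <- !frozen & gain > 1e-10
    frozen[!newly] <- TRUE
    if (!any(newly)) break
    for (i in which(newly)) {
      active[j_star[i], i] <- TRUE
      s <- which(active[, i])
      fit <- nnls_support(s, Ub[, i])
      W[, i] <- 0
      W[fit$s, i] <- fit$w
      active[, i] <- FALSE
      active[fit$s, i] <- TRUE
    }
    if (step < k) R <- X - U %*% W
  }
  W
}

#' Sparse module-activity factorization
#'
#' Factorizes a genes x cells usage matrix as `X ~ U W` with a
#' non-negative, L1-sparsified module dictionary `U` (genes x d; each
#' column one module) and a sparse activity matrix `W` (d x cells; at
#' most `k` active modules per cell).  Fitting alternates a per-cell
#' greedy non-negative pursuit with hard support limit `k` (W-step) and
#' a non-negative coordinate-descent dictionary update under an L1
#' penalty of weight `lambda_u` (U-step).  The objective
#' `0.5 ||X - UW||_F^2 + lambda_u * sum(U)` is non-increasing across
#' iterations: the W-step keeps the previous coefficients of a cell
#' whenever the new pursuit solution does not improve its residual.
#'
#' The default rank `d = 500` follows an over-complete dictionary
#' strategy (d far above the expected module count); redundant modules
#' end up empty and are pruned, and downstream stability filtering does
#' the real model selection.  Missing entries (`NA`) are imputed with
#' the gene's training mean for the factorization only; the mask should
#' be retained by callers so screening uses observed cells.
#'
#' @param X genes x cells matrix, `NA` for missing; no fully-missing
#'   rows or columns (drop them first).
#' @param d initial number of modules (default 500).
#' @param k maximum active modules per cell (default 15).
#' @param lambda_u dictionary L1 penalty weight (default 0.1).
#' @param max_iter,tol stopping rule: at most `max_iter` alternations or
#'   relative objective change below `tol`.
#' @param seed integer seed (controls the randomized part of the
#'   initialization).
#' @return object of class `smaf`: `U` (genes x m, pruned), `W`
#'   (m x cells), `module_ids`, `objective_trace`, `converged`,
#'   `n_pruned`, `gene_means` (imputation means), plus the
#'   configuration.
#' @export
fit_smaf <- function(X, d = 500, k = 15, lambda_u = 0.1,
                     max_iter = 100, tol = 1e-5, seed = 1) {
  stopifnot(is.matrix(X), d >= 1, k >= 1, lambda_u >= 0)
  if (any(rowSums(!is.na(X)) == 0) || any(colSums(!is.na(X)) == 0))
    stop("fit_smaf: X has fully-missing rows or columns; drop them first")
  G <- nrow(X); N <- ncol(X)
  gene_means <- rowMeans(X, na.rm = TRUE)
  Ximp <- X
  miss <- is.na(Ximp)
  if (any(miss)) Ximp[miss] <- gene_means[row(Ximp)[miss]]

  ## --- initialization: non-negative SVD parts, random non-negative fill
  set.seed(seed)
  r <- min(d, G, N)
  sv <- svd(Ximp, nu = r, nv = r)
  U0 <- matrix(0, G, d)
  col <- 1L
  for (j in seq_len(r)) {
    if (col > d) break
    up <- pmax(sv$u[, j], 0); un <- pmax(-sv$u[, j], 0)
    first <- if (sum(up^2) >= sum(un^2)) up else un
    second <- if (sum(up^2) >= sum(un^2)) un else up
    U0[, col] <- sqrt(sv$d[j]) * first; col <- col + 1L
    if (col <= d && sum(second^2) > 1e-12) {
      U0[, col] <- sqrt(sv$d[j]) * second; col <- col + 1L
    }
  }
  if (col <= d)
    U0[, col:d] <- matrix(abs(rnorm(G * (d - col + 1L), sd = 0.1)),
                          G, d - col + 1L)
  U <- U0
  W <- matrix(0, d, N)

  objective <- function(U, W)
    0.5 * sum((Ximp - U %*% W)^2) + lambda_u * sum(U)

  trace <- objective(U, W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## W-step with per-cell monotone guard
    W_new <- smaf_sparse_code(Ximp, U, k)
    E_new <- Ximp - U %*% W_new
    E_old <- Ximp - U %*% W
    worse <- colSums(E_new^2) > colSums(E_old^2) + 1e-12
    if (any(worse)) W_new[, worse] <- W[, worse]
    W <- W_new

    ## U-step: non-negative L1 coordinate descent (2 sweeps)
    A <- tcrossprod(W)
    B <- tcrossprod(Ximp, W)
    UA <- U %*% A
    for (sweep in 1:2) {
      for (j in seq_len(d)) {
        if (A[j, j] < 1e-12) next
        u_old <- U[, j]
        u_new <- pmax(0, (B[, j] - UA[, j] + u_old * A[j, j] - lambda_u) /
                        A[j, j])
        delta <- u_new - u_old
        if (any(delta != 0)) {
          U[, j] <- u_new
          UA <- UA + outer(delta, A[j, ])
        }
      }
    }
    obj <- objective(U, W)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fit_smaf: stopped at max_iter without meeting tol; ",
            "returning best iterate")

  ## prune empty modules (zero dictionary column or never-used activity)
  keep <- colSums(U^2) > 1e-12 & rowSums(W^2) > 1e-12
  n_pruned <- sum(!keep)
  U <- U[, keep, drop = FALSE]
  W <- W[keep, , drop = FALSE]
  module_ids <- sprintf("m%d", which(keep))
  colnames(U) <- module_ids
  rownames(W) <- module_ids
  rownames(U) <- rownames(X)
  colnames(W) <- colnames(X)

  structure(list(U = U, W = W, module_ids = module_ids,
                 d = d, k = k, lambda_u = lambda_u, seed = seed,
                 objective_trace = trace, converged = converged,
                 n_pruned = n_pruned, gene_means = gene_means),
            class = "smaf")
}

#' @export
print.smaf <- function(x, ...) {
  cat(sprintf(paste0("smaf factorization: %d genes, %d cells, %d modules",
                     " (of %d initial; %d pruned)\n"),
              nrow(x$U), ncol(x$W), ncol(x$U), x$d, x$n_pruned))
  cat(sprintf("  k = %d, lambda_u = %g, objective %.6g -> %.6g (%s)\n",
              x$k, x$lambda_u, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) "converged" else "max_iter"))
  invisible(x)
}

#' Project cells onto a frozen module dictionary
#'
#' Sparse-codes new cells against a fitted dictionary: each cell's usage
#' profile is approximated by at most `k` non-negative module
#' activities, with `U` unchanged.  Used to score held-out cells.
#'
#' @param X_new genes x cells matrix over the same gene universe as the
#'   dictionary (`NA` allowed; imputed with the training gene means when
#'   `fit` is a `smaf` object).
#' @param fit a `smaf` object, or a dictionary matrix `U`.
#' @param k maximum active modules per cell (default: the fit's `k`).
#' @return activity matrix (modules x cells).
#' @export
project_cells <- function(X_new, fit, k = NULL) {
  if (inherits(fit, "smaf")) {
    U <- fit$U
    if (is.null(k)) k <- fit$k
    means <- fit$gene_means
  } else {
    U <- fit
    if (is.null(k)) stop("project_cells: k required with a bare dictionary")
    means <- NULL
  }
  if (!is.null(rownames(U)) && !is.null(rownames(X_new))) {
    if (!setequal(rownames(U), rownames(X_new)))
      stop("project_cells: gene universe of X_new does not match dictionary")
    X_new <- X_new[rownames(U), , drop = FALSE]
  } else if (nrow(X_new) != nrow(U)) {
    stop("project_cells: gene dimension mismatch")
  }
  miss <- is.na(X_new)
  if (any(miss)) {
    if (is.null(means)) means <- rowMeans(X_new, na.rm = TRUE)
    means[is.na(means)] <- 0
    X_new[miss] <- means[row(X_new)[miss]]
  }
  W <- smaf_sparse_code(X_new, U, k)
  rownames(W) <- colnames(U)
  colnames(W) <- colnames(X_new)
  W
}
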