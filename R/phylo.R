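# Phylogenetic machinery: Newick parsing (ape-backed, with validation),
# Brownian-motion covariance built from scratch by accumulating shared branch
# lengths over clades, and a GLS fitter using Cholesky whitening with t-based
# inference. This is the engine behind the ecology regressions and the
# allometry tests.

#' Parse a Newick tree with validation
#'
#' Wraps the standard Newick reader and enforces what the comparative engine
#' needs: unique tip labels, branch lengths present, finite and non-negative.
#'
#' @param text Newick string (or, if `file` given, ignored).
#' @param file Optional path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else {
      stopifnot(is.character(text), length(text) == 1)
      ape::read.tree(text = text)
    },
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: malformed tree text")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; PGLS needs them")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

#' Set every branch length to one
#'
#' The uniform branch-length configuration used as a sensitivity check
#' against the molecular (time-calibrated) configuration. Topology is
#' unchanged; tip depths become node counts from the root. Idempotent.
#'
#' @param tree An `ape::phylo` tree.
#' @return The tree with all `edge.length` equal to 1.
#' @export
set_uniform_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree$edge.length[] <- 1
  }
  tree
}

#' Brownian-motion covariance matrix of a rooted tree
#'
#' Under Brownian motion with unit rate, the covariance of tip values is the
#' shared path length from the root to the most recent common ancestor:
#' `C[i, j] = depth(MRCA(i, j))`, `C[i, i] = depth(tip i)`. Built by adding
#' each branch length to the block of tip pairs descending from that branch.
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param tip_order Optional character vector giving the row/column order;
#'   all names must be tips of the tree.
#' @return Symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
bm_covariance <- function(tree, tip_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  # tips below every node, accumulated in postorder
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (e in seq_len(nrow(post$edge))) {
    tips <- below[[post$edge[e, 2]]]
    C[tips, tips] <- C[tips, tips] + post$edge.length[e]
  }
  if (!is.null(tip_order)) {
    miss <- setdiff(tip_order, tree$tip.label)
    if (length(miss))
      stop("tips requested in tip_order but absent from tree: ",
           paste(miss, collapse = ", "))
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  C
}

# Cholesky factor of C, with the spec'd 1e-8 diagonal jitter fallback for
# singular matrices (e.g. zero-length branches from resolved polytomies)
chol_covariance <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    message("covariance matrix singular; adding 1e-8 diagonal jitter")
    U <- tryCatch(chol(C + diag(1e-8, nrow(C))), error = function(e) NULL)
    if (is.null(U)) stop("covariance matrix is singular even after 1e-8 jitter")
  }
  U
}

#' Phylogenetic generalized least squares fit
#'
#' Solves \eqn{\hat\beta = (X' C^{-1} X)^{-1} X' C^{-1} y} by whitening both
#' sides with the Cholesky factor of `C` (never an explicit inverse).
#' Residual variance uses `n - p` degrees of freedom; standard errors,
#' two-sided t-based P values, and the Gaussian log-likelihood are reported.
#'
#' @param y Response vector, one value per tip, aligned to the rows of `C`.
#' @param X Design matrix including the intercept column; column names are
#'   used in the coefficient table.
#' @param C Brownian covariance matrix from [bm_covariance()].
#' @return A `pgls_fit`: `coefficients` data frame (estimate, se, t, p),
#'   `df`, `sigma2`, `logLik`, `n`, `residuals` (response scale),
#'   `fitted`.
#' @export
pgls_fit <- function(y, X, C) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n)
    stop("dimension mismatch between y, X, and C")
  if (n < p + 1) stop("need at least p + 1 observations for PGLS")
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))[seq_len(p)]
  U <- chol_covariance(C)
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; offending predictor(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  df <- n - p
  sigma2 <- rss / df
  unpiv <- order(qrX$pivot)
  XtX_inv <- chol2inv(qr.R(qrX))[unpiv, unpiv, drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  fitted <- as.numeric(X %*% beta)
  structure(list(
    coefficients = data.frame(estimate = as.numeric(beta), se = se,
                              t = as.numeric(tval), p = as.numeric(pval),
                              row.names = colnames(X)),
    df = df, sigma2 = sigma2, logLik = ll, n = n,
    residuals = y - fitted, fitted = fitted),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, df = %d, sigma^2 = %.4g, logLik = %.4g)\n",
              x$n, x$df, x$sigma2, x$logLik))
  print(round(x$coefficients, 6))
  invisible(x)
}
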