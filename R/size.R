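# Size reintroduction: standardized (relative) measurements are multiplied
# back by a body-size measure ("size-included"), or reduced to phylogenetic
# residuals on size ("size-corrected").

#' Reintroduce body size into a relative measurement
#'
#' `size_include(trait, size) = trait * size`, e.g. Centroid Size x Relative
#' Fill Volume = Centroid Size Included Volume. Vectorized.
#'
#' @param trait Positive relative measurement(s).
#' @param size Positive size measure(s) (centroid size or body mass).
#' @return Element-wise product.
#' @export
size_include <- function(trait, size) {
  if (any(!is.finite(trait)) || any(trait <= 0))
    stop("trait values must be positive and finite")
  if (any(!is.finite(size)) || any(size <= 0))
    stop("size values must be positive and finite")
  trait * size
}

#' Phylogenetic size correction
#'
#' Residuals of the PGLS regression of `trait_ln` on `size_ln` (with
#' intercept) under Brownian covariance `C`. With `C = I` this reduces to
#' ordinary least-squares residuals.
#'
#' @param trait_ln,size_ln Aligned per-species ln-scale vectors.
#' @param C Brownian covariance matrix aligned to the same species order.
#' @return Residual vector (response scale), names preserved from
#'   `trait_ln`.
#' @export
size_correct <- function(trait_ln, size_ln, C) {
  if (length(trait_ln) != length(size_ln) || length(trait_ln) != nrow(C))
    stop("dimension mismatch between trait, size, and covariance")
  fit <- pgls_fit(trait_ln, cbind(`(Intercept)` = 1, ln_size = size_ln), C)
  stats::setNames(fit$residuals, names(trait_ln))
}

#' Natural-log transform selected table columns
#'
#' Applies `log()` to strictly positive columns, renaming them with an `ln_`
#' prefix to record provenance.
#'
#' @param table A data frame.
#' @param columns Character vector of column names to transform.
#' @return The table with transformed, renamed columns.
#' @export
ln_transform <- function(table, columns) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop("columns not in table: ", paste(miss, collapse = ", "))
  for (cl in columns) {
    x <- table[[cl]]
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad))
      stop("non-positive value in column '", cl, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; ln transform needs strictly positive data")
    table[[cl]] <- log(x)
    names(table)[names(table) == cl] <- paste0("ln_", cl)
  }
  table
}
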