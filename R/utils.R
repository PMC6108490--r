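#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call, so generators with explicit seeds never
#' disturb (or depend on) global random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Contact-face area of the standardized core cylinder
#'
#' Area of the 2.5 mm-radius circular face in contact with the compression
#' plate: \eqn{\pi r^2 = 19.63} mm^2 (printed to two decimals). The exact
#' value is used in all stress computations.
#'
#' @return Area in mm^2.
#' @examples
#' round(cylinder_contact_area(), 2) # 19.63
#' @export
cylinder_contact_area <- function() {
  pi * STD_CORE_RADIUS^2
}

# standardized core geometry (mm)
STD_CORE_HEIGHT <- 10
STD_CORE_DIAMETER <- 5
STD_CORE_RADIUS <- STD_CORE_DIAMETER / 2

`%||%` <- function(a, b) if (is.null(a)) b else a
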