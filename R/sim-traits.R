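# Synthetic phylogenies, Brownian traits with a specified ln-ln allometric
# slope, and tree-structured ecological covariates. These give the
# comparative engine inputs with known ground truth.

#' Simulate an ultrametric pure-birth tree
#'
#' Yule process (birth rate 1, no extinction), relabelled `sp01 ... spNN`.
#' Deterministic for a fixed seed; global RNG state is untouched.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A rooted, binary, ultrametric `ape::phylo` tree.
#' @export
generate_pure_birth_tree <- function(n_tips, seed = 1L) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Configuration for Brownian allometric trait simulation
#'
#' `ln trait = intercept + slope * ln size + resid`, where `ln size` is
#' Brownian motion with rate `sigma_size^2` from `root_ln_size` and `resid`
#' is an independent Brownian residual with rate `sigma_resid^2`.
#'
#' @param slope ln-ln allometric slope.
#' @param intercept ln-scale intercept.
#' @param sigma_size Brownian rate (sd per unit branch length) of ln size.
#' @param sigma_resid Brownian rate of the residual.
#' @param root_ln_size Root state of ln size (default 0).
#' @param seed Integer seed.
#' @return A `bm_trait_config`.
#' @export
bm_trait_config <- function(slope, intercept = 0, sigma_size = 0.3,
                            sigma_resid = 0.1, root_ln_size = 0, seed = 1L) {
  if (sigma_size < 0) stop("sigma_size must be >= 0")
  if (sigma_resid < 0) stop("sigma_resid must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 sigma_size = sigma_size, sigma_resid = sigma_resid,
                 root_ln_size = root_ln_size, seed = as.integer(seed)),
            class = "bm_trait_config")
}

# one multivariate-normal Brownian draw on the tree given the upper Cholesky
# factor of its covariance
bm_draw <- function(U, sigma) {
  if (sigma == 0) return(rep(0, ncol(U)))
  as.numeric(crossprod(U, stats::rnorm(ncol(U)))) * sigma
}

#' Simulate an allometrically related trait pair on a tree
#'
#' @param tree An `ape::phylo` tree (>= 3 tips).
#' @param cfg A `bm_trait_config`.
#' @return Data frame with columns `species`, `ln_size`, `ln_trait`, one row
#'   per tip in `tree$tip.label` order.
#' @export
simulate_allometric_traits <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "bm_trait_config"))
  if (length(tree$tip.label) < 3) stop("tree must have at least 3 tips")
  C <- bm_covariance(tree)
  U <- chol_covariance(C)
  with_seed(cfg$seed, {
    ln_size <- cfg$root_ln_size + bm_draw(U, cfg$sigma_size)
    resid <- bm_draw(U, cfg$sigma_resid)
    data.frame(species = tree$tip.label,
               ln_size = ln_size,
               ln_trait = cfg$intercept + cfg$slope * ln_size + resid)
  })
}

#' Simulate an ecological covariate table
#'
#' One row per tip with the eleven covariates used in the comparative
#' analyses: activity cycle, terrestriality, habitat breadth, dietary
#' breadth, trophic level (ordinal scores drawn from small integer ranges);
#' maximum longevity (months), sexual maturity age (days), mean monthly
#' precipitation (mm), temperature (deg C) (continuous, Brownian on the
#' tree); dietary mechanical demand (ordinal 1-5); and suborder (binary,
#' partitioned at the root split). All covariates are simulated with zero
#' true effect on any trait — the null world matching the reported absence of
#' ecological signal.
#'
#' @param tree An `ape::phylo` tree.
#' @param seed Integer seed.
#' @return Data frame with `species` plus 11 covariate columns.
#' @export
generate_ecology_table <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  C <- bm_covariance(tree)
  U <- chol_covariance(C)
  depth <- mean(diag(C))
  with_seed(seed, {
    bm <- function(mu, sd_total) mu + bm_draw(U, sd_total / sqrt(depth))
    root_node <- n + 1L
    first_child <- tree$edge[tree$edge[, 1] == root_node, 2][1]
    in_first <- clade_tips(tree, first_child)
    data.frame(
      species = tree$tip.label,
      activity_cycle = sample(1:3, n, replace = TRUE),
      terrestriality = sample(1:2, n, replace = TRUE),
      habitat_breadth = sample(1:4, n, replace = TRUE),
      dietary_breadth = sample(1:8, n, replace = TRUE),
      trophic_level = sample(1:3, n, replace = TRUE),
      maximum_longevity = pmax(12, bm(240, 80)),
      sexual_maturity_age = pmax(60, bm(600, 250)),
      mean_monthly_precipitation = pmax(0, bm(100, 40)),
      temperature = bm(15, 8),
      mechanical_demand = sample(1:5, n, replace = TRUE),
      suborder = as.integer(seq_len(n) %in% in_first)
    )
  })
}

# tip indices descending from a node (the node itself if a tip)
clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- ch[ch <= n]
    out <- c(out, tips)
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}
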