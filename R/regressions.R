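# The ecological-signal battery: single-predictor PGLS of every response
# variant against every covariate, laid out like the published tables
# (volume, structural complexity, strength: four size-variant column pairs;
# elastic modulus: one pair, with surface area and fill volume as extra
# predictors).

#' Run the ecological PGLS regression battery
#'
#' For volume, structural complexity, and maximum compressive strength, four
#' response variants are formed — size-included (`ln(trait * size)`) and
#' size-corrected (phylogenetic residuals of the included variant on ln
#' size), by centroid size and by body mass — and each is regressed on each
#' ecological covariate in its own single-predictor PGLS model. Strength
#' additionally runs against relative surface area and relative fill volume.
#' Elastic modulus, size-independent by definition, runs once (raw MPa)
#' against the eleven covariates plus surface area and volume.
#'
#' @param traits Data frame with columns `species`, `volume`, `complexity`,
#'   `modulus`, `strength`, `centroid_size`, `body_mass` (raw scales).
#' @param ecology Data frame with `species` plus covariate columns (see
#'   [generate_ecology_table()]).
#' @param tree An `ape::phylo` tree containing all species.
#' @param branch_lengths `"molecular"` (use the tree's lengths) or
#'   `"uniform"` (set all lengths to 1 first).
#' @param alpha Significance level used for flagging (default 0.05).
#' @return List of data frames: `volume`, `complexity`, `strength` (wide,
#'   one P/RC pair per response variant), `modulus` (13 predictors), and
#'   `long` (tidy: response, variant, variable, P, RC, significant).
#' @export
run_ecology_regressions <- function(traits, ecology, tree,
                                    branch_lengths = c("molecular", "uniform"),
                                    alpha = 0.05) {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(is.data.frame(traits), is.data.frame(ecology))
  need <- c("species", "volume", "complexity", "modulus", "strength",
            "centroid_size", "body_mass")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits table lacks columns: ", paste(miss, collapse = ", "))
  sp <- traits$species
  missing_tree <- setdiff(sp, tree$tip.label)
  if (length(missing_tree))
    stop("species missing from tree: ", paste(missing_tree, collapse = ", "))
  missing_eco <- setdiff(sp, ecology$species)
  if (length(missing_eco))
    stop("species missing from ecology table: ",
         paste(missing_eco, collapse = ", "))
  if (branch_lengths == "uniform") tree <- set_uniform_branch_lengths(tree)
  tree <- ape::keep.tip(tree, sp)
  C <- bm_covariance(tree, tip_order = sp)
  eco <- ecology[match(sp, ecology$species), , drop = FALSE]
  covars <- setdiff(names(eco), "species")

  ln_cs <- log(traits$centroid_size)
  ln_bm <- log(traits$body_mass)
  variants <- function(trait) {
    inc_cs <- log(size_include(trait, traits$centroid_size))
    inc_bm <- log(size_include(trait, traits$body_mass))
    list(cs_included = inc_cs,
         cs_corrected = size_correct(inc_cs, ln_cs, C),
         bm_included = inc_bm,
         bm_corrected = size_correct(inc_bm, ln_bm, C))
  }
  one_fit <- function(y, x, xname) {
    fit <- pgls_fit(y, cbind(`(Intercept)` = 1, stats::setNames(data.frame(x), xname)), C)
    c(P = fit$coefficients[xname, "p"], RC = fit$coefficients[xname, "estimate"])
  }
  long <- list()
  run_variants <- function(response_name, trait, extra_predictors = NULL) {
    vs <- variants(trait)
    preds <- c(as.list(eco[covars]), extra_predictors)
    wide <- data.frame(variable = names(preds))
    for (vn in names(vs)) {
      pr <- t(vapply(names(preds),
                     function(pn) one_fit(vs[[vn]], preds[[pn]], pn),
                     numeric(2)))
      wide[[paste0("P_", vn)]] <- pr[, "P"]
      wide[[paste0("RC_", vn)]] <- pr[, "RC"]
      long[[length(long) + 1L]] <<- data.frame(
        response = response_name, variant = vn, variable = names(preds),
        P = pr[, "P"], RC = pr[, "RC"],
        significant = pr[, "P"] < alpha, row.names = NULL)
    }
    wide
  }
  struct_preds <- list(surface_area = traits$complexity,
                       volume = traits$volume)
  out <- list(
    volume = run_variants("volume", traits$volume),
    complexity = run_variants("complexity", traits$complexity),
    strength = run_variants("strength", traits$strength,
                            extra_predictors = struct_preds)
  )
  # modulus: size-independent, raw MPa, 11 covariates + surface area + volume
  mod_preds <- c(as.list(eco[covars]), struct_preds)
  mp <- t(vapply(names(mod_preds),
                 function(pn) one_fit(traits$modulus, mod_preds[[pn]], pn),
                 numeric(2)))
  out$modulus <- data.frame(variable = names(mod_preds),
                            P = mp[, "P"], RC = mp[, "RC"],
                            significant = mp[, "P"] < alpha, row.names = NULL)
  long[[length(long) + 1L]] <- data.frame(
    response = "modulus", variant = "raw", variable = names(mod_preds),
    P = mp[, "P"], RC = mp[, "RC"], significant = mp[, "P"] < alpha,
    row.names = NULL)
  out$long <- do.call(rbind, long)
  rownames(out$long) <- NULL
  out
}
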