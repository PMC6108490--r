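# ln-ln allometry against dimensional expectations: volume and strength
# should scale isometrically with body size (slope 1), surface area as a
# 2D quantity against 3D size (slope 2/3), and elastic modulus — a material
# property — not at all (slope 0). A fitted slope whose confidence interval
# excludes the expectation is positively (expectation below the CI) or
# negatively (expectation above) allometric.

#' Expected isometric slope for a trait kind
#'
#' @param trait_kind One of `"volume"`, `"area"`, `"modulus"`, `"strength"`.
#' @return The dimensional expectation: volume 1, area 2/3, modulus 0,
#'   strength 1.
#' @examples
#' expected_isometry_slope("area") # 2/3
#' @export
expected_isometry_slope <- function(trait_kind) {
  trait_kind <- match.arg(trait_kind,
                          c("volume", "area", "modulus", "strength"))
  c(volume = 1, area = 2 / 3, modulus = 0, strength = 1)[[trait_kind]]
}

#' Fit a ln-ln PGLS allometry regression
#'
#' Regresses `trait_ln` on `size_ln` under Brownian covariance `C` and
#' builds Student-t confidence intervals for the slope at each requested
#' level with `df = n - 2`.
#'
#' @param trait_ln,size_ln Aligned ln-scale vectors (one value per tip).
#' @param C Brownian covariance matrix, same tip order.
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param trait_kind Optional trait kind for [expected_isometry_slope()];
#'   when given, classifications are attached per level.
#' @param trait,size_measure Optional labels carried into the result.
#' @return An `allometry_result`: `slope`, `se`, `p` (slope != 0), `df`,
#'   `ci` (named list of `c(lower, upper)` per level), `expected_slope`
#'   (or NA), `classification` (named per level, or NULL), labels.
#' @export
fit_allometry <- function(trait_ln, size_ln, C, levels = c(0.95, 0.99),
                          trait_kind = NULL, trait = trait_kind,
                          size_measure = "size") {
  n <- length(trait_ln)
  if (n < 4) stop("need at least 4 species for an allometry fit")
  stopifnot(all(levels > 0 & levels < 1))
  fit <- pgls_fit(trait_ln, cbind(`(Intercept)` = 1, ln_size = size_ln), C)
  slope <- fit$coefficients["ln_size", "estimate"]
  se <- fit$coefficients["ln_size", "se"]
  ci <- lapply(levels, function(lv) {
    tcrit <- stats::qt((1 + lv) / 2, df = fit$df)
    c(lower = slope - tcrit * se, upper = slope + tcrit * se)
  })
  names(ci) <- format_level(levels)
  res <- structure(list(
    trait = trait %||% "trait", size_measure = size_measure,
    slope = slope, se = se,
    p = fit$coefficients["ln_size", "p"], df = fit$df,
    ci = ci,
    expected_slope = NA_real_, classification = NULL, fit = fit),
    class = "allometry_result")
  if (!is.null(trait_kind)) {
    res$expected_slope <- expected_isometry_slope(trait_kind)
    res$classification <- vapply(format_level(levels), function(lv)
      classify_allometry(res, level = lv), character(1))
  }
  res
}

format_level <- function(levels) sprintf("%g", levels * 100)

#' Classify a fitted slope against the isometric expectation
#'
#' Expected slope inside the CI: isometric. Expected slope below the lower
#' limit (observed slope steeper than expected): positive allometry. Expected
#' slope above the upper limit: negative allometry.
#'
#' @param result An `allometry_result`.
#' @param level Confidence level, as fraction ("0.95") or percent ("95");
#'   must be one of the levels the result was fitted with.
#' @param expected_slope Override for the expectation (default the one stored
#'   in `result`).
#' @return `"isometric"`, `"positive"`, or `"negative"`.
#' @export
classify_allometry <- function(result, level = 0.95,
                               expected_slope = result$expected_slope) {
  stopifnot(inherits(result, "allometry_result"))
  key <- as.character(level)
  if (!key %in% names(result$ci)) {
    key <- format_level(as.numeric(level))
    if (!key %in% names(result$ci))
      stop("no CI at level ", level, " in this result (available: ",
           paste(names(result$ci), collapse = ", "), ")")
  }
  if (!is.finite(expected_slope))
    stop("no expected slope available; supply expected_slope or trait_kind")
  ci <- result$ci[[key]]
  # numerical guard: a degenerate zero-width CI (noiseless data) must not
  # flip the call on float error
  tol <- 1e-8 * max(1, abs(result$slope))
  if (expected_slope < ci[["lower"]] - tol) "positive"
  else if (expected_slope > ci[["upper"]] + tol) "negative"
  else "isometric"
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("allometry: %s vs %s\n  slope %.4g (SE %.4g, P = %.3g, df = %d)\n",
              x$trait, x$size_measure, x$slope, x$se, x$p, x$df))
  for (lv in names(x$ci)) {
    cl <- if (!is.null(x$classification)) paste0(" -> ", x$classification[[lv]]) else ""
    cat(sprintf("  CI%s%% [%.4g, %.4g]%s\n", lv, x$ci[[lv]]["lower"],
                x$ci[[lv]]["upper"], cl))
  }
  if (is.finite(x$expected_slope))
    cat(sprintf("  expected (isometry) %.2f\n", x$expected_slope))
  invisible(x)
}

#' Run the full allometry battery
#'
#' Fits every trait against every size measure and assembles a table in the
#' published layout: trait, size measure, P, RC (slope), SE, CI limits,
#' expected RC, classification. Classification uses the first level for the
#' CI columns; the last level's classification is also reported (the
#' stricter/wider interval used to confirm positive allometry).
#'
#' @param traits Named list of ln-scale trait vectors (per species).
#' @param trait_kinds Character vector, same names, giving each trait's kind.
#' @param sizes Named list of ln-scale size vectors (e.g. centroid size and
#'   body mass).
#' @param C Brownian covariance matrix aligned to all vectors.
#' @param levels Confidence levels (default 0.95, 0.99).
#' @return Data frame, one row per trait x size measure.
#' @export
run_allometry_battery <- function(traits, trait_kinds, sizes, C,
                                  levels = c(0.95, 0.99)) {
  stopifnot(length(traits) == length(trait_kinds),
            !is.null(names(traits)), !is.null(names(sizes)))
  lv1 <- format_level(levels[1])
  rows <- list()
  for (tn in names(traits)) {
    for (sn in names(sizes)) {
      r <- fit_allometry(traits[[tn]], sizes[[sn]], C, levels = levels,
                         trait_kind = trait_kinds[[tn]], trait = tn,
                         size_measure = sn)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tn, size_measure = sn,
        P = r$p, RC = r$slope, SE = r$se,
        ci_lower = r$ci[[lv1]][["lower"]],
        ci_upper = r$ci[[lv1]][["upper"]],
        expected_RC = r$expected_slope,
        classification = r$classification[[lv1]],
        classification_strict = r$classification[[length(r$classification)]]
      )
    }
  }
  do.call(rbind, rows)
}
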