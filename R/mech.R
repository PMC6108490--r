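# Reduction of compression-test records: stress-strain transform, elastic
# modulus from the maximal-R^2 linear window, peak strength, and replicate
# aggregation. Geometry is the standardized core: contact face pi * 2.5^2
# mm^2, gauge height 10 mm.

#' Force-displacement compression record
#'
#' @param time Seconds, strictly increasing.
#' @param force Newtons, non-negative; the first sample should sit at the
#'   preload (within 5%).
#' @param displacement Millimetres of vertical travel, re-zeroed at the first
#'   sample.
#' @param preload Initial standardizing load, N (default 10).
#' @param sample_rate Hz (default 4).
#' @return A `force_displacement_record`.
#' @export
force_displacement_record <- function(time, force, displacement,
                                      preload = 10, sample_rate = 4) {
  stopifnot(length(time) == length(force),
            length(force) == length(displacement))
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(force < 0)) stop("force must be non-negative")
  if (length(force) > 0 && preload > 0 &&
      abs(force[1] - preload) > 0.05 * preload)
    warning(sprintf("first recorded force %.3g N differs from preload %.3g N by more than 5%%",
                    force[1], preload))
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 displacement = as.numeric(displacement),
                 preload = preload, sample_rate = sample_rate),
            class = "force_displacement_record")
}

#' Convert a force-displacement record to a stress-strain curve
#'
#' Stress is force over the contact-face area of the standardized cylinder
#' (\eqn{\pi 2.5^2 = 19.63} mm^2); strain is displacement over the original
#' 10 mm height. Displacement is re-zeroed at the first sample.
#'
#' @param rec A `force_displacement_record`.
#' @return A `stress_strain_curve`: `stress` (MPa), `strain`
#'   (dimensionless), `area` (mm^2), `gauge_height` (mm).
#' @export
compute_stress_strain <- function(rec) {
  stopifnot(inherits(rec, "force_displacement_record"))
  d <- rec$displacement - rec$displacement[1]
  if (any(d < -1e-9)) stop("negative displacement after re-zeroing; record is not a monotone compression ramp")
  d[d < 0] <- 0
  structure(list(stress = rec$force / cylinder_contact_area(),
                 strain = d / STD_CORE_HEIGHT,
                 area = cylinder_contact_area(),
                 gauge_height = STD_CORE_HEIGHT),
            class = "stress_strain_curve")
}

#' Elastic modulus from the best-fitting linear strain window
#'
#' Slides a strain window of fixed width along the curve, fits ordinary least
#' squares in each window with at least `min_points` samples, and returns the
#' slope of the window maximizing R^2. Ties in R^2 (noiseless piecewise-linear
#' records are exactly linear in several windows) are broken toward the
#' steepest slope — the initial elastic region.
#'
#' @param curve A `stress_strain_curve`.
#' @param window_width Strain width of the sliding window (default 0.01).
#' @param min_points Minimum samples per window (default 5).
#' @return List: `E` (MPa), `window` (strain endpoints used), `r_squared`,
#'   `indices` (sample index range).
#' @export
estimate_elastic_modulus <- function(curve, window_width = 0.01,
                                     min_points = 5L) {
  stopifnot(inherits(curve, "stress_strain_curve"), window_width > 0)
  eps <- curve$strain
  sig <- curve$stress
  n <- length(eps)
  if (n < 10) stop("need at least 10 samples to locate the elastic region")
  ord <- order(eps)
  eps <- eps[ord]; sig <- sig[ord]
  cx <- cumsum(eps); cy <- cumsum(sig)
  cxx <- cumsum(eps^2); cxy <- cumsum(eps * sig); cyy <- cumsum(sig^2)
  ssum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  # window ending index for each start; only full-width windows compete,
  # otherwise a short noisy tail window can win on spurious R^2
  jend <- findInterval(eps + window_width + 1e-12, eps)
  full <- eps + window_width <= eps[n] + 1e-12
  starts <- which(full & jend - seq_len(n) + 1L >= min_points)
  if (length(starts) == 0)  # record shorter than one window: use all points
    starts <- if (n >= min_points) 1L else integer(0)
  if (length(starts) == 0)
    stop("fewer than ", min_points, " samples in every strain window of width ",
         window_width)
  m <- length(starts)
  slope <- r2 <- numeric(m)
  for (q in seq_len(m)) {
    i <- starts[q]; j <- jend[i]
    k <- j - i + 1
    sx <- ssum(cx, i, j); sy <- ssum(cy, i, j)
    sxx <- ssum(cxx, i, j); sxy <- ssum(cxy, i, j); syy <- ssum(cyy, i, j)
    vx <- sxx - sx^2 / k
    vy <- syy - sy^2 / k
    cv <- sxy - sx * sy / k
    if (vx <= 0) { slope[q] <- NA; r2[q] <- -Inf; next }
    b <- cv / vx
    rss <- max(0, vy - b * cv)  # cancellation can dip microscopically below 0
    slope[q] <- b
    r2[q] <- if (vy <= 1e-300) 1 else 1 - rss / vy
  }
  ok <- which(is.finite(slope))
  if (length(ok) == 0) stop("no usable strain window found")
  best_r2 <- max(r2[ok])
  cand <- ok[r2[ok] >= best_r2 - 1e-9]
  pick <- cand[which.max(slope[cand])]
  i <- starts[pick]; j <- jend[i]
  list(E = slope[pick],
       window = c(eps[i], eps[j]),
       r_squared = r2[pick],
       indices = c(i, j))
}

#' Maximum compressive strength of a stress-strain curve
#'
#' @param curve A `stress_strain_curve`.
#' @return List: `F_max` (N) and `sigma_max` (MPa), with
#'   `F_max = sigma_max * area` exactly.
#' @export
max_compressive_strength <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (length(curve$stress) == 0) stop("empty curve")
  smax <- max(curve$stress)
  list(F_max = smax * curve$area, sigma_max = smax)
}

#' Reduce one record to a mechanical summary
#'
#' @param rec A `force_displacement_record`.
#' @param window_width Passed to [estimate_elastic_modulus()].
#' @return A `mechanical_summary`: `elastic_modulus` (MPa),
#'   `max_strength_force` (N), `max_strength_stress` (MPa), `linear_window`,
#'   `replicate_n = 1`.
#' @export
summarize_record <- function(rec, window_width = 0.01) {
  curve <- compute_stress_strain(rec)
  em <- estimate_elastic_modulus(curve, window_width)
  st <- max_compressive_strength(curve)
  structure(list(elastic_modulus = em$E,
                 max_strength_force = st$F_max,
                 max_strength_stress = st$sigma_max,
                 linear_window = em$window,
                 replicate_n = 1L,
                 replicate_sd = c(elastic_modulus = 0,
                                  max_strength_force = 0,
                                  max_strength_stress = 0)),
            class = "mechanical_summary")
}

#' Aggregate replicate mechanical summaries
#'
#' Per-metric arithmetic mean with the standard deviation across replicates
#' (five replicate prints per species in the physical protocol).
#'
#' @param summaries Non-empty list of `mechanical_summary` objects.
#' @return A `mechanical_summary` with `replicate_n = length(summaries)`.
#' @export
aggregate_replicates <- function(summaries) {
  if (length(summaries) == 0) stop("no replicate summaries to aggregate")
  stopifnot(all(vapply(summaries, inherits, logical(1), "mechanical_summary")))
  g <- function(fld) vapply(summaries, `[[`, numeric(1), fld)
  E <- g("elastic_modulus")
  Fm <- g("max_strength_force")
  Sm <- g("max_strength_stress")
  sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(elastic_modulus = mean(E),
                 max_strength_force = mean(Fm),
                 max_strength_stress = mean(Sm),
                 linear_window = NULL,
                 replicate_n = length(summaries),
                 replicate_sd = c(elastic_modulus = sdv(E),
                                  max_strength_force = sdv(Fm),
                                  max_strength_stress = sdv(Sm))),
            class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("mechanical_summary (n = %d): E = %.4g MPa, F_max = %.4g N (%.4g MPa)\n",
              x$replicate_n, x$elastic_modulus, x$max_strength_force,
              x$max_strength_stress))
  invisible(x)
}

#' Read / write force-displacement records as CSV
#'
#' Columns `time_s, force_N, displacement_mm`; metadata lines prefixed `#`
#' carry `preload_N` and `sample_rate_hz`.
#'
#' @param rec A `force_displacement_record`.
#' @param path File path.
#' @return `write_record`: `path` invisibly; `read_record`: the record.
#' @export
write_record <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# preload_N: %.10g", rec$preload),
               sprintf("# sample_rate_hz: %.10g", rec$sample_rate)), con)
  utils::write.csv(data.frame(time_s = rec$time, force_N = rec$force,
                              displacement_mm = rec$displacement),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  ln <- readLines(path, warn = FALSE)
  meta <- ln[startsWith(ln, "#")]
  getm <- function(k, default) {
    hit <- grep(paste0("#\\s*", k, ":"), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*:", "", hit[1])) else default
  }
  df <- utils::read.csv(text = ln[!startsWith(ln, "#")])
  force_displacement_record(df$time_s, df$force_N, df$displacement_mm,
                            preload = getm("preload_N", 10),
                            sample_rate = getm("sample_rate_hz", 4))
}
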