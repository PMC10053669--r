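#' Force-response profile container
#'
#' A metric (occupancy, interaction energy, H-bond count, dissociation
#' probability, mass-center distance, cross-angle...) sampled over an ordered
#' tensile-force grid with replicate values per force level.
#'
#' @param metric metric name, e.g. \code{"fD"}, \code{"E"}, \code{"N_HB"}
#' @param force_grid strictly increasing forces, pN
#' @param replicates list (one element per force level) of numeric replicate
#'   values, or a matrix with one column per force level
#' @return object of class \code{force_profile} with per-force \code{mean}
#'   and standard error \code{se}.
#' @export
force_profile <- function(metric, force_grid, replicates) {
  if (any(diff(force_grid) <= 0))
    stop("force grid must be strictly increasing", call. = FALSE)
  if (is.matrix(replicates))
    replicates <- lapply(seq_len(ncol(replicates)),
                         function(j) replicates[, j])
  if (length(replicates) != length(force_grid))
    stop("one replicate set per force level required", call. = FALSE)
  if (any(lengths(replicates) < 1L))
    stop("every force level needs at least one replicate", call. = FALSE)
  means <- vapply(replicates, mean, numeric(1))
  se <- vapply(replicates, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0, numeric(1))
  structure(list(metric = metric, force_grid = force_grid,
                 replicates = replicates, mean = means, se = se),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat("force_profile '", x$metric, "':\n", sep = "")
  print(data.frame(force_pn = x$force_grid, mean = x$mean, se = x$se))
  invisible(x)
}

#' @export
as.data.frame.force_profile <- function(x, ...) {
  data.frame(metric = x$metric, force_pn = x$force_grid, mean = x$mean,
             se = x$se, n_rep = lengths(x$replicates))
}

#' Interface dissociation probability from bond occupancies
#'
#' Under the assumption that each interfacial hydrogen-bonding event is
#' independent and that these bonds are fully responsible for binding, the
#' probability that the interface is unbonded is the probability that every
#' bond is simultaneously absent: fD = prod(1 - o_i) over the per-bond
#' occupancies. Any permanently formed bond (o = 1) gives fD = 0; an empty
#' bond set gives fD = 1 (no bonds, certain dissociation) with a warning.
#'
#' @param occupancies numeric vector of per-bond occupancy fractions in [0,1]
#' @return dissociation probability in [0, 1].
#' @export
dissociation_probability <- function(occupancies) {
  if (length(occupancies) == 0L) {
    warning("no bonds: dissociation probability is 1", call. = FALSE)
    return(1)
  }
  if (any(!is.finite(occupancies)) || any(occupancies < 0 | occupancies > 1))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  prod(1 - occupancies)
}

#' Normalize a dissociation-probability profile
#'
#' Divides every replicate value by the mean at the reference condition (by
#' default the first force level), so the reference maps to 1 and the
#' profile reads as a mechano-regulation factor.
#'
#' @param profile a \code{\link{force_profile}} of fD values
#' @param reference index of the reference force level (default 1)
#' @return a normalized \code{force_profile}.
#' @export
normalize_fd <- function(profile, reference = 1L) {
  if (!inherits(profile, "force_profile")) stop("not a force_profile",
                                                call. = FALSE)
  ref <- profile$mean[reference]
  if (!is.finite(ref) || ref <= 0)
    stop("reference fD is zero; normalization undefined", call. = FALSE)
  force_profile(paste0(profile$metric, "_normalized"), profile$force_grid,
                lapply(profile$replicates, function(v) v / ref))
}

#' Biphasic force threshold of a profile
#'
#' Finds interior extrema of the mean curve on the force grid (no
#' interpolation: thresholds are reported as grid forces). A clean biphasic
#' profile has exactly one interior extremum -- its force and direction
#' (\code{"min"} for decrease-then-increase, \code{"max"} for the reverse)
#' are returned. Monotone profiles yield no threshold; profiles with several
#' interior extrema are flagged non-biphasic and all extrema are returned.
#'
#' @param profile a \code{\link{force_profile}} (at least 3 force levels)
#' @return list of class \code{biphasic_result}: \code{threshold} (pN or NA),
#'   \code{direction}, \code{biphasic} flag, and an \code{extrema}
#'   data.frame.
#' @export
biphasic_threshold <- function(profile) {
  if (!inherits(profile, "force_profile")) stop("not a force_profile",
                                                call. = FALSE)
  m <- profile$mean
  if (length(m) < 3L) stop("need at least 3 force levels", call. = FALSE)
  d <- diff(m)
  sgn <- sign(d)
  ext_i <- integer(0); ext_dir <- character(0)
  run <- sgn[sgn != 0]
  pos <- which(sgn != 0)
  if (length(run) >= 2L) {
    for (k in seq_len(length(run) - 1L)) {
      if (run[k] != run[k + 1L]) {
        i <- pos[k + 1L]  # interior grid point where the turn happens
        ext_i <- c(ext_i, i)
        ext_dir <- c(ext_dir, if (run[k] < 0) "min" else "max")
      }
    }
  }
  extrema <- data.frame(force_pn = profile$force_grid[ext_i],
                        direction = ext_dir, stringsAsFactors = FALSE)
  out <- if (length(ext_i) == 1L)
    list(threshold = profile$force_grid[ext_i], direction = ext_dir,
         biphasic = TRUE, extrema = extrema)
  else
    list(threshold = NA_real_, direction = NA_character_,
         biphasic = FALSE, extrema = extrema)
  class(out) <- "biphasic_result"
  out
}

#' @export
print.biphasic_result <- function(x, ...) {
  if (x$biphasic)
    cat(sprintf("biphasic threshold at %g pN (%s)\n", x$threshold,
                x$direction))
  else if (nrow(x$extrema) == 0L)
    cat("monotone profile: no force threshold\n")
  else {
    cat("non-biphasic profile;", nrow(x$extrema), "interior extrema:\n")
    print(x$extrema)
  }
  invisible(x)
}

#' Classify a bond's force-response mode
#'
#' Maps occupancy values over an ordered force grid to one of the five
#' force-response modes: steady, catch-slip, slip-catch, catch-slip-catch,
#' slip-catch-slip. Successive differences of the (replicate-mean) occupancy
#' are converted to signs with a dead band epsilon, zeros dropped and runs
#' collapsed; the resulting sign pattern determines the label. A pure
#' monotone rise/fall is reported as catch_slip / slip_catch with a
#' \code{pure_catch} / \code{pure_slip} flag; longer alternations are
#' labelled \code{"complex"} with the raw pattern preserved.
#'
#' @param occupancy_by_force occupancy values on the ordered force grid
#'   (replicate means), or a \code{\link{force_profile}}
#' @param epsilon dead band in occupancy units (default 0.05)
#' @return list of class \code{mode_label}: \code{mode}, \code{pattern},
#'   \code{flag}, \code{epsilon}.
#' @export
classify_mode <- function(occupancy_by_force, epsilon = 0.05) {
  if (inherits(occupancy_by_force, "force_profile"))
    occupancy_by_force <- occupancy_by_force$mean
  o <- as.numeric(occupancy_by_force)
  if (length(o) < 3L) stop("need at least 3 force levels", call. = FALSE)
  d <- diff(o)
  sgn <- ifelse(d > epsilon, 1L, ifelse(d < -epsilon, -1L, 0L))
  sgn <- sgn[sgn != 0L]
  if (length(sgn)) sgn <- sgn[c(TRUE, diff(sgn) != 0L)]  # collapse runs
  pat <- paste(ifelse(sgn > 0, "+", "-"), collapse = "")
  map <- stats::setNames(
    c("catch_slip", "catch_slip", "slip_catch", "slip_catch",
      "catch_slip_catch", "slip_catch_slip"),
    c("+", "+-", "-", "-+", "+-+", "-+-"))
  mode <- if (pat == "") "steady"
  else if (pat %in% names(map)) unname(map[pat]) else "complex"
  flag <- if (pat == "+") "pure_catch" else if (pat == "-") "pure_slip"
  else NA_character_
  structure(list(mode = mode, pattern = pat, flag = flag,
                 epsilon = epsilon),
            class = "mode_label")
}

#' @export
print.mode_label <- function(x, ...) {
  cat("mode:", x$mode,
      if (!is.na(x$flag)) paste0("(", x$flag, ")"),
      " pattern '", x$pattern, "' (epsilon ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Gaussian fit of an H-bond count frequency histogram
#'
#' Least-squares fit of a * exp(-(x - mu)^2 / (2 sigma^2)) to the frequency
#' of per-frame interfacial H-bond counts (unit-width integer bins). Starting
#' values come from the sample moments of the histogram; the fit uses
#' Levenberg-Marquardt. Used as a sanity check that the sampled H-bond-count
#' distribution is quasi-complete (approximately normal).
#'
#' @param counts integer bond-count bin centers, or a named table/vector of
#'   frequencies whose names are the counts
#' @param frequency bin frequencies (same length as \code{counts}); omit when
#'   \code{counts} is a table
#' @return list of class \code{gaussian_fit}: \code{mean}, \code{sigma},
#'   \code{amplitude}, \code{rss}.
#' @export
fit_gaussian <- function(counts, frequency = NULL) {
  if (is.null(frequency)) {
    tab <- if (is.table(counts)) counts else table(counts)
    frequency <- as.numeric(tab)
    counts <- as.numeric(names(tab))
  }
  keep <- frequency > 0
  x <- as.numeric(counts)[keep]; y <- as.numeric(frequency)[keep]
  if (length(x) < 4L)
    stop("need at least 4 distinct counts with nonzero frequency",
         call. = FALSE)
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- sqrt(max(sum(w * (x - mu0)^2), 0.25))
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(a = a0, mu = mu0, s = sd0),
                      lower = c(a = 0, mu = -Inf, s = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian fit did not converge (moment fallback: mean ",
           signif(mu0, 4), ", sigma ", signif(sd0, 4), "): ",
           conditionMessage(e), call. = FALSE))
  p <- stats::coef(fit)
  structure(list(mean = unname(p["mu"]), sigma = abs(unname(p["s"])),
                 amplitude = unname(p["a"]),
                 rss = sum(stats::residuals(fit)^2)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: mean %.3f, sigma %.3f, amplitude %.3f (rss %.3g)\n",
              x$mean, x$sigma, x$amplitude, x$rss))
  invisible(x)
}

#' Two-group replicate comparison
#'
#' Thin wrapper around the standard tests used for replicate comparisons:
#' an unpaired two-tailed equal-variance (Student's) t test, or Tukey's
#' honest significant difference from a one-way ANOVA of the two groups.
#' Two identical degenerate groups (zero variance, equal means) give p = 1.
#'
#' @param groupA,groupB numeric replicate values (each n >= 2)
#' @param method \code{"t"} or \code{"tukey"}
#' @return the two-sided p-value.
#' @export
compare_replicates <- function(groupA, groupB, method = c("t", "tukey")) {
  method <- match.arg(method)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    return(if (mean(groupA) == mean(groupB)) 1 else 0)
  }
  if (method == "t")
    return(stats::t.test(groupA, groupB, var.equal = TRUE)$p.value)
  g <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))
  fit <- stats::aov(c(groupA, groupB) ~ g)
  unname(stats::TukeyHSD(fit)$g[1, "p adj"])
}
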