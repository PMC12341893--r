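#' Mean nearest-neighbour Minkowski distance of a configuration
#'
#' The average, over points, of the distance to each point's nearest other
#' point. Duplicate points are allowed (distance 0).
#'
#' @param coords n x 2 coordinate matrix (n >= 2) or `latent_config`.
#' @param r Minkowski exponent (default 2).
#' @return Scalar mean nearest-neighbour distance.
#' @examples
#' nn_mean_distance(rbind(c(0, 0), c(1, 0)))  # 1
#' @export
nn_mean_distance <- function(coords, r = 2) {
  coords <- as_coords(coords)
  if (nrow(coords) < 2) stop("need at least 2 points", call. = FALSE)
  .nn_mean_cpp(coords, r)
}

#' Spatial-randomness ratio of a point configuration
#'
#' The ratio of the configuration's mean nearest-neighbour Minkowski distance
#' to the average of that quantity over `n_random` configurations of the same
#' number of points drawn uniformly on a reference support (by default the
#' axis-aligned bounding box of the configuration, making the statistic
#' translation- and scale-invariant). Values near 1 indicate complete spatial
#' randomness, below 1 clustering, above 1 a shift towards a regular grid.
#'
#' @param coords n x 2 matrix or `latent_config` (n >= 2).
#' @param n_random Number of null configurations (default 10000).
#' @param seed Integer seed for the null draws.
#' @param r Minkowski exponent.
#' @param support `"bbox"` (default) or a 2 x 2 matrix `rbind(xlim, ylim)`
#'   giving the null's support explicitly.
#' @return Scalar R; 0 (with a warning) for a degenerate all-identical
#'   configuration.
#' @examples
#' set.seed(1)
#' spatial_randomness(matrix(runif(64), 32, 2), n_random = 200, seed = 2)
#' @export
spatial_randomness <- function(coords, n_random = 10000, seed = NULL, r = 2,
                               support = "bbox") {
  coords <- as_coords(coords)
  if (nrow(coords) < 2) stop("need at least 2 points", call. = FALSE)
  if (identical(support, "bbox")) {
    lo <- apply(coords, 2, min)
    hi <- apply(coords, 2, max)
  } else {
    support <- as.matrix(support)
    lo <- support[, 1]; hi <- support[, 2]
  }
  if (all(hi == lo)) {
    warning("degenerate configuration: all points identical; R = 0",
            call. = FALSE)
    return(0)
  }
  obs <- .nn_mean_cpp(coords, r)
  null_mean <- with_seed(seed,
                         .null_nn_mean_cpp(nrow(coords), n_random, lo, hi, r))
  obs / null_mean
}

#' Spatial randomness across retained posterior samples
#'
#' One R value per retained posterior configuration, with mean and SD — the
#' posterior distribution of configuration randomness.
#'
#' @param fit A `bmds` fit (alignment does not affect R).
#' @param n_random Null configurations per sample (default 10000).
#' @param seed Integer seed.
#' @param r Minkowski exponent (defaults to the fit's).
#' @param support Passed to [spatial_randomness()].
#' @return A `randomness_result`: list with `R` (per-sample vector), `mean`,
#'   `sd` and the null settings.
#' @export
randomness_over_samples <- function(fit, n_random = 10000, seed = NULL,
                                    r = NULL, support = "bbox") {
  stopifnot(inherits(fit, "bmds"))
  r <- r %||% fit$config$minkowski_r
  ns <- dim(fit$samples)[1]
  # one shared null seed: identical samples then get identical R values
  R <- vapply(seq_len(ns), function(i) {
    spatial_randomness(fit$samples[i, , ], n_random = n_random,
                       seed = seed, r = r, support = support)
  }, numeric(1))
  structure(list(R = R, mean = mean(R), sd = sd(R),
                 settings = list(n_random = n_random, seed = seed, r = r,
                                 support = support)),
            class = "randomness_result")
}

#' @export
print.randomness_result <- function(x, ...) {
  cat("Spatial randomness over", length(x$R), "posterior samples:\n")
  cat("  mean R =", round(x$mean, 3), " SD =", round(x$sd, 3),
      " (", x$settings$n_random, "null configurations per sample )\n")
  invisible(x)
}

#' Compare two spatial-randomness distributions
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p) between the per-sample
#' R values of two fits, e.g. a control group versus a patient group.
#'
#' @param a,b `randomness_result` objects or numeric vectors.
#' @return List with the KS statistic `D` and `p`.
#' @export
compare_R_distributions <- function(a, b) {
  av <- if (inherits(a, "randomness_result")) a$R else as.numeric(a)
  bv <- if (inherits(b, "randomness_result")) b$R else as.numeric(b)
  if (length(av) == 0 || length(bv) == 0) {
    stop("both R distributions must be nonempty", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(av, bv, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
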