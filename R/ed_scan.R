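#' Fit a Euclidean-Distance genome scan to two-pool allele depths
#'
#' `ed_scan()` is the central fitting function.  For every retained site it
#' computes the ED statistic between the two pools (on allele frequencies by
#' default), raises it to `power_k`, then fits a distance-weighted profile
#' along each chromosome separately for the SNP and InDel marker classes,
#' and estimates a genome-wide association threshold per class.
#'
#' @param sites A site table as returned by [read_pooled_vcf()] or
#'   [simulate_pool_depths()]: a `data.frame` with columns `chrom`, `pos`,
#'   `class` (`"SNP"`/`"InDel"`), and list columns `depth_ms`, `depth_217`
#'   of per-allele depth vectors.
#' @param power_k Exponent of the background-suppressing power transform
#'   (default 5).
#' @param bandwidth Half-window of the profile fit in bp (default 1e6).
#' @param kernel Kernel of [fit_profile()].
#' @param multiplier Threshold spread multiplier (default 3).
#' @param robust Threshold center/spread estimator, see
#'   [association_threshold()].
#' @param on_frequencies Compute ED on allele frequencies (default) rather
#'   than on raw depths.  Raw depths preserve the literal depth-based
#'   formula but make ED scale with coverage.
#' @return An object of class `"ed_scan"`: list with
#'   \describe{
#'     \item{sites}{the input table with `ed`, `ed_powered`, `fitted` added,
#'       sorted by (class, chrom, pos);}
#'     \item{thresholds}{named list of [association_threshold()] results,
#'       one per variant class present;}
#'     \item{params}{the fitting parameters.}
#'   }
#' @seealso [call_regions()], [plot.ed_scan()]
#' @examples
#' cfg <- simulation_config(chromosomes = c(A09 = 2e6),
#'                          causal_regions = data.frame(chrom = "A09",
#'                            start = 5e5, end = 1e6),
#'                          n_genes = 50, n_degs = 5)
#' sites <- simulate_pool_depths(simulate_marker_map(cfg), cfg)
#' fit <- ed_scan(sites, bandwidth = 2e5)
#' fit
#' @export
ed_scan <- function(sites, power_k = 5, bandwidth = 1e6,
                    kernel = c("tricube", "triangular", "uniform"),
                    multiplier = 3, robust = TRUE, on_frequencies = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "class", "depth_ms", "depth_217")
                %in% names(sites)))
  if (nrow(sites) == 0L) stop("empty site table")

  ed <- vapply(seq_len(nrow(sites)), function(i) {
    dm <- sites$depth_ms[[i]]; ds <- sites$depth_217[[i]]
    if (on_frequencies) {
      ed_statistic(depth_frequencies(dm), depth_frequencies(ds))
    } else {
      ed_statistic(as.numeric(dm), as.numeric(ds))
    }
  }, numeric(1))
  sites$ed <- ed
  sites$ed_powered <- power_transform(ed, power_k)

  # per (class, chromosome) profile fit
  sites <- sites[order(sites$class, sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites$fitted <- NA_real_
  for (cl in unique(sites$class)) {
    for (ch in unique(sites$chrom[sites$class == cl])) {
      sel <- sites$class == cl & sites$chrom == ch
      sites$fitted[sel] <- fit_profile(sites$pos[sel],
                                       sites$ed_powered[sel],
                                       bandwidth = bandwidth,
                                       kernel = kernel)
    }
  }

  thresholds <- lapply(split(sites$fitted, sites$class),
                       association_threshold,
                       multiplier = multiplier, robust = robust)

  structure(
    list(sites = sites, thresholds = thresholds,
         params = list(power_k = power_k, bandwidth = bandwidth,
                       kernel = kernel, multiplier = multiplier,
                       robust = robust, on_frequencies = on_frequencies)),
    class = "ed_scan")
}

#' @export
print.ed_scan <- function(x, ...) {
  cat("Euclidean-Distance genome scan\n")
  cat(sprintf("  %d sites on %d chromosome(s); ED^%g, %s kernel, bandwidth %g bp\n",
              nrow(x$sites), length(unique(x$sites$chrom)),
              x$params$power_k, x$params$kernel, x$params$bandwidth))
  for (cl in names(x$thresholds)) {
    th <- x$thresholds[[cl]]
    cat(sprintf("  %-6s %6d sites, threshold %.6g\n",
                cl, sum(x$sites$class == cl), th$threshold))
  }
  invisible(x)
}

#' @export
summary.ed_scan <- function(object, ...) {
  s <- object$sites
  per_class <- lapply(split(s, s$class), function(d)
    c(n = nrow(d),
      ed_mean = mean(d$ed), ed_max = max(d$ed),
      fitted_median = stats::median(d$fitted),
      fitted_max = max(d$fitted)))
  structure(list(scan = object, per_class = per_class),
            class = "summary.ed_scan")
}

#' @export
print.summary.ed_scan <- function(x, ...) {
  print(x$scan)
  cat("\nPer-class profile summary:\n")
  print(do.call(rbind, lapply(x$per_class, round, 4)))
  n_above <- vapply(names(x$scan$thresholds), function(cl) {
    sel <- x$scan$sites$class == cl
    sum(x$scan$sites$fitted[sel] >= x$scan$thresholds[[cl]]$threshold)
  }, integer(1))
  cat("\nMarkers at/above threshold:\n")
  print(n_above)
  invisible(x)
}

#' @export
fitted.ed_scan <- function(object, class = NULL, ...) {
  s <- object$sites
  if (!is.null(class)) s <- s[s$class %in% class, , drop = FALSE]
  s$fitted
}

#' @export
residuals.ed_scan <- function(object, ...) {
  object$sites$ed_powered - object$sites$fitted
}

#' Scan plot of a fitted ED profile
#'
#' Plots the fitted powered-ED profile along one chromosome with the raw
#' powered values in grey and the association threshold as a dashed line,
#' in the style of the usual bulked-segregant scan figures.
#'
#' @param x An `ed_scan` object.
#' @param class Variant class to plot (default the first present).
#' @param chrom Chromosome (default the first present for that class).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ed_scan <- function(x, class = NULL, chrom = NULL, ...) {
  s <- x$sites
  if (is.null(class)) class <- s$class[1L]
  s <- s[s$class == class, , drop = FALSE]
  if (nrow(s) == 0L) stop("no sites of class ", class)
  if (is.null(chrom)) chrom <- s$chrom[1L]
  s <- s[s$chrom == chrom, , drop = FALSE]
  graphics::plot(s$pos / 1e6, s$ed_powered, pch = 16, cex = 0.3,
                 col = "grey70",
                 xlab = sprintf("%s position (Mb)", chrom),
                 ylab = sprintf("ED^%g", x$params$power_k),
                 main = sprintf("%s scan, %s", class, chrom), ...)
  graphics::lines(s$pos / 1e6, s$fitted, lwd = 2)
  graphics::abline(h = x$thresholds[[class]]$threshold,
                   lty = 2, col = "red")
  invisible(x)
}
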