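# Analytical machinery over the assembled dataset: pseudotorsion
# joint-density fields on the torus with mean + k*sigma contour levels,
# pucker/helix stratified nucleotide selection, and chain-length
# distributions by family.

#' Select nucleotide angle pairs by pucker/helix stratum
#'
#' Extracts `(x, y)` pseudotorsion pairs for density analysis from a
#' nucleotide record table. The `c3_endo_nonhelical` stratum keeps
#' C3'-endo nucleotides whose ingested helix form label is not A, B or Z
#' (nucleotides inside regular stems crowd the central region and are
#' removed); the `c2_endo` stratum filters on the pucker label only by
#' default. Pairs with any undefined member are dropped.
#'
#' @param records data.frame of nucleotide records (needs `pucker_label`,
#'   `form_label` and the two angle columns; `resolution` if filtering).
#' @param stratum `"c3_endo_nonhelical"` or `"c2_endo"`.
#' @param resolution_max Optional resolution cutoff (needs a
#'   `resolution` column).
#' @param angles Character pair naming the angle columns, e.g.
#'   `c("eta", "theta")` or `c("eta_prime", "theta_prime")`.
#' @param exclude_helical_c2 Also exclude A/B/Z forms from the C2'-endo
#'   stratum (off by default; exposed because published density panels
#'   are ambiguous on this point).
#' @return Two-column matrix of angle pairs in degrees.
#' @export
select_nucleotides <- function(records,
                               stratum = c("c3_endo_nonhelical", "c2_endo"),
                               resolution_max = NULL,
                               angles = c("eta", "theta"),
                               exclude_helical_c2 = FALSE) {
  stratum <- match.arg(stratum)
  keep <- if (stratum == "c3_endo_nonhelical") {
    records$pucker_label %in% "C3'-endo" &
      !(records$form_label %in% c("A", "B", "Z"))
  } else {
    k <- records$pucker_label %in% "C2'-endo"
    if (exclude_helical_c2) k <- k & !(records$form_label %in% c("A", "B", "Z"))
    k
  }
  if (!is.null(resolution_max)) {
    keep <- keep & !is.na(records$resolution) &
      records$resolution <= resolution_max
  }
  x <- records[[angles[[1]]]][keep]
  y <- records[[angles[[2]]]][keep]
  ok <- !is.na(x) & !is.na(y)
  cbind(x = x[ok], y = y[ok])
}

# circular standard deviation in degrees
.circ_sd_deg <- function(x) {
  r <- x / .DEG
  Rbar <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  Rbar <- min(max(Rbar, 1e-12), 1)
  sqrt(-2 * log(Rbar)) * .DEG
}

#' Periodic Gaussian kernel density estimate on the angle torus
#'
#' Product-Gaussian KDE of angle pairs on `[0, 360) x [0, 360)` with
#' wrap-around handling of both axes (each kernel is wrapped by summing
#' shifted copies at +/- k*360). The bandwidth defaults to Scott's rule
#' per axis (`sigma_circ * n^(-1/6)`, circular standard deviation of the
#' wrapped sample), floored at 1 degree. Contour levels are
#' `rho + {1, 2, 4} * sigma` where `rho` is the mean height of the
#' evaluated grid and `sigma` its standard deviation.
#'
#' @param points Two-column matrix of angle pairs in degrees.
#' @param gridsize Grid resolution per axis (default 256).
#' @param bandwidth Length-2 bandwidth in degrees, or `NULL` for Scott's
#'   rule.
#' @return Object of class `density_field`: list with `x`, `y` (cell
#'   centres), `grid` (density, integrates to 1 over the torus), `
#'   bandwidth`, `rho`, `sigma`, `contour_levels`, `n`.
#' @export
kde_torus <- function(points, gridsize = 256L, bandwidth = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("kernel density estimation needs at least 2 points")
  points <- points %% 360
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:2, function(k)
      max(.circ_sd_deg(points[, k]) * n^(-1 / 6), 1), numeric(1))
  }
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  centres <- (seq_len(gridsize) - 0.5) * 360 / gridsize
  shifts <- (-2:2) * 360
  wrapped_kernel <- function(grid_pos, data, h) {
    # gridsize x n matrix of wrapped 1-d normal kernel evaluations
    out <- matrix(0, length(grid_pos), length(data))
    for (s in shifts) {
      out <- out + outer(grid_pos, data + s,
                         function(g, d) stats::dnorm(g - d, sd = h))
    }
    out
  }
  kx <- wrapped_kernel(centres, points[, 1], bandwidth[[1]])
  ky <- wrapped_kernel(centres, points[, 2], bandwidth[[2]])
  grid <- (kx %*% t(ky)) / n
  rho <- mean(grid)
  sigma <- stats::sd(grid)
  structure(list(x = centres, y = centres, grid = grid,
                 bandwidth = bandwidth, rho = rho, sigma = sigma,
                 contour_levels = rho + c(1, 2, 4) * sigma, n = n),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(
    "<density_field: %dx%d torus grid, n = %d, bw = (%.2f, %.2f) deg>\n",
    length(x$x), length(x$y), x$n, x$bandwidth[1], x$bandwidth[2]))
  cat(sprintf(" rho = %.3g, sigma = %.3g, contours at rho + {1,2,4} sigma\n",
              x$rho, x$sigma))
  invisible(x)
}

#' Plot a pseudotorsion density field
#'
#' Scatter of the points (when supplied) with the density's
#' `rho + {1, 2, 4} sigma` line contours superposed, on 0-360 degree
#' axes.
#'
#' @param x A `density_field`.
#' @param points Optional two-column matrix of the underlying angle pairs.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.density_field <- function(x, points = NULL, xlab = "eta (degrees)",
                               ylab = "theta (degrees)", ...) {
  graphics::plot(NA, xlim = c(0, 360), ylim = c(0, 360),
                 xlab = xlab, ylab = ylab, ...)
  if (!is.null(points)) {
    graphics::points(points[, 1] %% 360, points[, 2] %% 360,
                     pch = 16, cex = 0.3,
                     col = grDevices::adjustcolor("grey40", 0.5))
  }
  graphics::contour(x$x, x$y, x$grid, levels = x$contour_levels,
                    add = TRUE, drawlabels = FALSE, col = "firebrick")
  invisible(x)
}

#' Chain-length distribution by family
#'
#' Bins chain lengths per family, pooling families with fewer chains
#' than `min_family_size` into an `Other` group. Counts conserve the
#' total number of chains.
#'
#' @param chains data.frame with columns `family` and `length`.
#' @param breaks Histogram breaks passed to [base::cut()]; by default
#'   logarithmic-friendly breaks covering the observed lengths.
#' @param min_family_size Families below this size pool into `Other`.
#' @return data.frame with columns `family`, `bin`, `count`. Empty input
#'   yields an empty data.frame.
#' @export
length_histogram <- function(chains, breaks = NULL, min_family_size = 3L) {
  if (!nrow(chains)) {
    return(data.frame(family = character(0), bin = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  fam <- as.character(chains$family)
  fam[is.na(fam)] <- "unmapped"
  sizes <- table(fam)
  fam[fam %in% names(sizes)[sizes < min_family_size]] <- "Other"
  if (is.null(breaks)) {
    breaks <- unique(round(exp(seq(log(max(min(chains$length), 1)),
                                   log(max(chains$length) + 1),
                                   length.out = 12L))))
    breaks <- c(breaks[-length(breaks)], max(chains$length) + 1)
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)
  }
  bin <- cut(chains$length, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  agg <- stats::aggregate(list(count = rep(1L, length(fam))),
                          by = list(family = fam, bin = as.character(bin)),
                          FUN = sum)
  agg[order(agg$family, agg$bin), , drop = FALSE]
}
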