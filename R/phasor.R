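#' Phasor transform of a decay stack
#'
#' Transforms each pixel's decay histogram into its first-harmonic Fourier
#' coordinates on the phasor plane: with `w = 2 pi f` (f the pulse frequency)
#' and bin centers `t_k`,
#' `G = sum(c_k cos(w t_k)) / sum(c_k)`, `S = sum(c_k sin(w t_k)) / sum(c_k)`.
#' Monoexponential decays fall on the universal semicircle
#' `(G - 1/2)^2 + S^2 = 1/4`; shorter lifetimes lie toward (1, 0).
#'
#' @param stack a `decay_stack`.
#' @param roi region name (from the stack's masks) or a logical matrix; `NULL`
#'   uses the whole image.
#' @param photon_floor minimum photons for a pixel to enter the result;
#'   pixels below the floor (including all-zero pixels) are dropped, not
#'   propagated as NaN.
#' @return an object of class `phasor_set`: data frame `pixels` (row, col, G,
#'   S, photons), photon-weighted `pooled` c(G, S), `omega` (rad/ns), and the
#'   ROI label.
#' @export
phasor_transform <- function(stack, roi = NULL, photon_floor = 20) {
  stopifnot(inherits(stack, "decay_stack"))
  d <- dim(stack$counts)
  roi_label <- "image"
  if (is.character(roi)) {
    roi_label <- roi
    if (is.null(stack$regions[[roi]])) stopf("unknown ROI '%s'", roi)
    roi <- stack$regions[[roi]]
  }
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (!any(roi)) stopf("empty ROI")

  omega <- 2 * pi * stack$rep_rate_mhz * 1e-3 # rad/ns
  cw <- cos(omega * stack$bin_centers_ns)
  sw <- sin(omega * stack$bin_centers_ns)

  idx <- which(roi, arr.ind = TRUE)
  mat <- matrix(stack$counts[cbind(rep(idx[, 1], d[3]), rep(idx[, 2], d[3]),
                                   rep(seq_len(d[3]), each = nrow(idx)))],
                nrow = nrow(idx))
  tot <- rowSums(mat)
  keep <- tot >= max(photon_floor, .Machine$double.eps)
  if (!any(keep)) stopf("no pixels above the photon floor in the ROI")
  g <- (mat[keep, , drop = FALSE] %*% cw) / tot[keep]
  s <- (mat[keep, , drop = FALSE] %*% sw) / tot[keep]
  pooled_tot <- colSums(mat[keep, , drop = FALSE])
  pooled <- c(G = sum(pooled_tot * cw) / sum(pooled_tot),
              S = sum(pooled_tot * sw) / sum(pooled_tot))
  structure(
    list(
      pixels = data.frame(row = idx[keep, 1], col = idx[keep, 2],
                          G = as.numeric(g), S = as.numeric(s),
                          photons = tot[keep]),
      pooled = pooled, omega = omega, roi = roi_label,
      rep_rate_mhz = stack$rep_rate_mhz
    ),
    class = "phasor_set"
  )
}

#' @export
print.phasor_set <- function(x, ...) {
  cat(sprintf(
    "Phasor set: %d pixels (ROI %s), pooled G = %.4f, S = %.4f\n",
    nrow(x$pixels), x$roi, x$pooled["G"], x$pooled["S"]
  ))
  invisible(x)
}

#' Predominant phasor cluster by Gaussian fitting
#'
#' Bins the (G, S) points into a 2D histogram at fixed bin width, locates the
#' mode, and fits a 2D Gaussian to the histogram within a window of +/- 5
#' moment-estimated sigmas around it; the fitted center is the cluster
#' centroid. On fit failure the photon-weighted centroid of the window is
#' returned and flagged.
#'
#' @param ps a `phasor_set` (or data frame with columns G, S and optionally
#'   photons) with at least `min_points` points.
#' @param bin_width histogram bin width in G and S.
#' @param min_points minimum number of points.
#' @param window_sigma half-width of the fit window in moment sigmas.
#' @return an object of class `phasor_cluster`: `centroid` (G0, S0), `sigma`
#'   (Gaussian widths), `n_pixels` (points in the fit window), `converged`,
#'   `roi`.
#' @export
cluster_fit <- function(ps, bin_width = 0.005, min_points = 50,
                        window_sigma = 5) {
  pts <- if (inherits(ps, "phasor_set")) ps$pixels else ps
  roi <- if (inherits(ps, "phasor_set")) ps$roi else "points"
  if (nrow(pts) < min_points) {
    stopf("need at least %d points for cluster fitting (got %d)", min_points,
          nrow(pts))
  }
  w <- pts$photons %||% rep(1, nrow(pts))

  gi <- floor(pts$G / bin_width)
  si <- floor(pts$S / bin_width)
  key <- paste(gi, si)
  cnt <- tapply(rep(1, length(key)), key, sum)
  mode_key <- names(cnt)[which.max(cnt)]
  mode_ctr <- (as.numeric(strsplit(mode_key, " ")[[1]]) + 0.5) * bin_width

  # moment estimate from points near the mode; degenerate clouds get a
  # one-bin-wide sigma so the window is never empty
  near <- abs(pts$G - mode_ctr[1]) < 6 * bin_width &
    abs(pts$S - mode_ctr[2]) < 6 * bin_width
  mu <- c(stats::weighted.mean(pts$G[near], w[near]),
          stats::weighted.mean(pts$S[near], w[near]))
  sig <- pmax(c(stats::sd(pts$G[near]), stats::sd(pts$S[near])),
              bin_width, na.rm = TRUE)

  win <- abs(pts$G - mu[1]) < window_sigma * sig[1] &
    abs(pts$S - mu[2]) < window_sigma * sig[2]
  gw <- pts$G[win]
  sw <- pts$S[win]
  ww <- w[win]

  # 2D histogram inside the window
  gb <- floor(gw / bin_width)
  sb <- floor(sw / bin_width)
  hk <- paste(gb, sb)
  hc <- tapply(rep(1, length(hk)), hk, sum)
  ctrs <- do.call(rbind, strsplit(names(hc), " "))
  hg <- (as.numeric(ctrs[, 1]) + 0.5) * bin_width
  hs <- (as.numeric(ctrs[, 2]) + 0.5) * bin_width
  hz <- as.numeric(hc)

  converged <- FALSE
  centroid <- c(stats::weighted.mean(gw, ww), stats::weighted.mean(sw, ww))
  sigma <- sig
  if (length(hz) >= 5) {
    obj <- function(par) {
      a <- par[1]
      m1 <- par[2]
      m2 <- par[3]
      s1 <- abs(par[4])
      s2 <- abs(par[5])
      mu_fit <- a * exp(-((hg - m1)^2 / (2 * s1^2) + (hs - m2)^2 / (2 * s2^2)))
      sum((hz - mu_fit)^2)
    }
    init <- c(max(hz), mu[1], mu[2], sig[1], sig[2])
    fit <- tryCatch(
      stats::optim(init, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$convergence == 0 && all(is.finite(fit$par))) {
      converged <- TRUE
      centroid <- fit$par[2:3]
      sigma <- abs(fit$par[4:5])
    }
  }
  if (centroid[1] < -0.1 || centroid[1] > 1.1 ||
      centroid[2] < -0.1 || centroid[2] > 0.7) {
    warning("cluster centroid outside the physical phasor region", call. = FALSE)
  }
  structure(
    list(centroid = c(G = centroid[1], S = centroid[2]),
         sigma = c(G = sigma[1], S = sigma[2]),
         n_pixels = sum(win), converged = converged, roi = roi),
    class = "phasor_cluster"
  )
}

#' @export
print.phasor_cluster <- function(x, ...) {
  cat(sprintf(
    "Phasor cluster (%s): centroid G = %.4f, S = %.4f; %d pixels%s\n",
    x$roi, x$centroid["G"], x$centroid["S"], x$n_pixels,
    if (x$converged) "" else " [moment fallback]"
  ))
  invisible(x)
}

#' Lifetime from phasor coordinates
#'
#' `tau = S / (2 pi f G)` with `f` the pulse frequency; exact for
#' monoexponential decays (for which the phasor lies on the universal
#' semicircle) and the standard single-frequency lifetime estimate otherwise.
#'
#' @param p a `phasor_cluster`, `phasor_set` (pooled coordinates), or numeric
#'   `c(G, S)`.
#' @param rep_rate_mhz pulse frequency, MHz.
#' @return lifetime in ns.
#' @export
lifetime_from_phasor <- function(p, rep_rate_mhz = 80) {
  gs <- if (inherits(p, "phasor_cluster")) {
    p$centroid
  } else if (inherits(p, "phasor_set")) {
    p$pooled
  } else {
    p
  }
  g <- unname(gs[1])
  s <- unname(gs[2])
  if (!is.finite(g) || g <= 0) stopf("lifetime undefined for G <= 0")
  f <- rep_rate_mhz * 1e-3 # cycles per ns
  s / (2 * pi * f * g)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, comparing the donor lifetime without acceptor
#' (`tau_d`) to that in its presence (`tau_da`). Negative efficiencies
#' (lifetime lengthening) are permitted but flagged.
#'
#' @param tau_d donor-only lifetime, ns (> 0).
#' @param tau_da donor lifetime in the presence of the acceptor, ns.
#' @return an object of class `fret_result`: `tau_d`, `tau_da`, `efficiency`,
#'   `flagged` (TRUE for negative efficiency).
#' @export
fret_efficiency <- function(tau_d, tau_da) {
  if (!is.finite(tau_d) || tau_d <= 0) stopf("tau_d must be positive")
  e <- 1 - tau_da / tau_d
  structure(
    list(tau_d = tau_d, tau_da = tau_da, efficiency = e, flagged = e < 0),
    class = "fret_result"
  )
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("FRET: tau_D = %.3f ns, tau_DA = %.3f ns, E = %.4f%s\n",
              x$tau_d, x$tau_da, x$efficiency,
              if (x$flagged) " [negative: lifetime lengthening]" else ""))
  invisible(x)
}
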