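#' Phase images of an oscillatory stack
#'
#' Computes a per-pixel phase in (-pi, pi] of the dominant oscillatory
#' component of the time series.  Bleaching is corrected globally by
#' dividing out a mono-exponential trend fitted to the per-frame median
#' intensities (a fitted trend, rather than frame-by-frame normalization,
#' so the correction cannot imprint the wave's own oscillation).  The
#' dominant oscillation frequency is located on the mean power spectrum and
#' refined by a matched-filter search; the time-resolved phase is then
#' obtained per pixel by local harmonic regression: a weighted least-squares
#' fit of `a + b cos(w s) + c sin(w s)` on a sliding window of about 1.5
#' oscillation periods, which jointly removes the local offset and the
#' conjugate-frequency leakage.  The sign convention makes the phase of a
#' wave `cos(k x - w t)` equal to `(k x - w t) mod 2pi`, so crests are the
#' zero-phase level set.  Pixels whose fitted oscillation power is below
#' `mask_frac` of their total variance are masked (`NA`), never fabricated.
#' Frames within half a fitting window of the stack ends carry edge bias;
#' the bias-free range is returned as `interior` and used as the default
#' frame range by [crest_displacements()].
#'
#' @param stack an `image_stack`; needs at least about one oscillation
#'   period of frames.
#' @param mask_frac masking threshold on the oscillation-power fraction.
#' @param window_periods length of the sliding fit window in oscillation
#'   periods.
#' @return list with `phase` (array `[H, W, T]`, `NA` where masked),
#'   `omega` (dominant angular frequency, rad/s), `mask` (H x W logical,
#'   TRUE = usable pixel) and `interior` (first, last edge-bias-free
#'   frame).
#' @export
phase_map <- function(stack, mask_frac = 0.2, window_periods = 1.5) {
  fr <- stack$frames
  H <- dim(fr)[1]; W <- dim(fr)[2]; T <- dim(fr)[3]
  if (T < 4) stop("stack too short for temporal phase estimation")
  dt <- stack$interval
  # bleach correction: divide out the fitted mono-exponential trend of the
  # per-frame medians
  med <- apply(fr, 3, stats::median)
  if (all(med > 0)) {
    idx <- seq_len(T)
    fit <- stats::lm(log(med) ~ idx)
    trend <- exp(stats::fitted(fit))
    for (t in idx) fr[, , t] <- fr[, , t] * (trend[1] / trend[t])
  }
  X <- matrix(fr, nrow = H * W, ncol = T)   # pixels x time
  X <- X - rowMeans(X)
  Xf <- t(stats::mvfft(t(X)))               # FFT along time, per pixel
  kmax <- floor(T / 2)
  pw <- colSums(abs(Xf[, 2:(kmax + 1), drop = FALSE])^2)
  if (sum(pw) <= .Machine$double.eps * max(sum(X^2), 1) + 1e-300)
    return(list(phase = array(NA_real_, dim(stack$frames)), omega = NA_real_,
                mask = matrix(FALSE, H, W), interior = c(1L, T)))
  k0 <- which.max(pw)                       # cycles per stack duration
  # matched-filter refinement of the carrier frequency
  tt <- (seq_len(T) - 1) * dt
  wh <- 0.5 * (1 - cos(2 * pi * (seq_len(T) - 0.5) / T))
  obj <- function(om) sum(abs(X %*% (wh * exp(1i * om * tt)))^2)
  om0 <- 2 * pi * k0 / (T * dt)
  omega <- stats::optimize(obj, interval = c(0.5 * om0, 1.5 * om0),
                           maximum = TRUE, tol = om0 * 1e-4)$maximum
  # sliding-window harmonic regression, shared Gram matrix per frame
  wlen <- min(T, max(5, round(window_periods * 2 * pi / omega / dt)))
  if (wlen %% 2 == 0) wlen <- wlen + 1
  half <- (wlen - 1) / 2
  ph <- array(NA_real_, c(H, W, T))
  amp2 <- NULL
  for (tc in seq_len(T)) {
    lo <- max(1, tc - half); hi <- min(T, tc + half)
    s <- (lo:hi - tc) * dt
    w <- 0.5 * (1 - cos(2 * pi * (seq_along(s) - 0.5) / length(s)))
    B <- cbind(1, cos(omega * s), sin(omega * s))
    G <- crossprod(B * w, B)
    beta <- X[, lo:hi, drop = FALSE] %*% (B * w) %*% t(solve(G))
    ph[, , tc] <- matrix(atan2(beta[, 3], beta[, 2]), H, W)
    if (tc == max(1, T %/% 2))
      amp2 <- beta[, 2]^2 + beta[, 3]^2
  }
  mask <- matrix(amp2 / (2 * rowMeans(X^2) + .Machine$double.eps) >=
                   mask_frac, H, W)
  ph[array(!mask, c(H, W, T))] <- NA
  interior <- c(min(half + 1, T), max(T - half, 1L))
  list(phase = ph, omega = omega, mask = mask,
       interior = as.integer(interior))
}

#' Detect wave crests in a phase frame
#'
#' Sub-pixel loci of the zero-phase level set (crest ridge), found as
#' wrap-aware zero crossings of the phase along the rows and columns.
#'
#' @param phase_frame H x W phase matrix (`NA` = masked).
#' @return data frame with sub-pixel columns `x` (column) and `y` (row),
#'   empty for an all-masked frame.
#' @export
detect_crests <- function(phase_frame) {
  pts_x <- .crossings(phase_frame, along = "x")
  pts_y <- .crossings(phase_frame, along = "y")
  out <- rbind(pts_x, pts_y)
  if (is.null(out)) data.frame(x = numeric(0), y = numeric(0)) else out
}

.crossings <- function(ph, along) {
  if (along == "y") ph <- t(ph)
  a <- ph[, -ncol(ph), drop = FALSE]
  b <- ph[, -1, drop = FALSE]
  hit <- which(!is.na(a) & !is.na(b) & (a <= 0) != (b <= 0) &
                 abs(b - a) < pi, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  fa <- a[hit]; fb <- b[hit]
  s <- fa / (fa - fb)
  if (along == "x") data.frame(x = hit[, 2] + s, y = hit[, 1])
  else data.frame(x = hit[, 1], y = hit[, 2] + s)
}

#' Frame-to-frame crest displacements
#'
#' For each crest point of frame `t`, estimates the displacement of the
#' crest to frame `t+1` by locating the zero-phase crossing of the next
#' frame along the local crest normal (the phase-gradient direction),
#' searching within a quarter wavelength on either side and refining to
#' sub-pixel by linear interpolation; among multiple crossings the one
#' closest to zero displacement is taken.  Velocities are reported in nm/s.
#'
#' @param stack the `image_stack` the phases came from.
#' @param pm result of [phase_map()].
#' @param frames which source frames to process; default: the edge-bias-free
#'   interior range reported by [phase_map()].
#' @return data frame (class `crest_velocity_record`) with columns `x`, `y`
#'   (pixels), `v_x`, `v_y` (nm/s), `frame`; dropped-point count in
#'   `attr(, "dropped")`.
#' @export
crest_displacements <- function(stack, pm, frames = NULL) {
  ph <- pm$phase
  T <- dim(ph)[3]
  if (is.null(frames)) {
    rng <- if (!is.null(pm$interior)) pm$interior else c(1L, T)
    frames <- seq(max(1L, rng[1]), min(rng[2], T - 1L))
  }
  px <- stack$pixel_size
  recs <- list()
  dropped <- 0L
  n_samp <- 41L
  for (t in frames) {
    f0 <- ph[, , t]; f1 <- ph[, , t + 1]
    cr <- detect_crests(f0)
    if (!nrow(cr)) next
    g <- .phase_gradient(f0)
    gx <- .bilin(g$gx, cr$x, cr$y)
    gy <- .bilin(g$gy, cr$x, cr$y)
    gn <- sqrt(gx^2 + gy^2)
    ok <- is.finite(gn) & gn > 1e-9
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    cr <- cr[ok, , drop = FALSE]
    nx <- (gx / gn)[ok]; ny <- (gy / gn)[ok]
    smax <- (2 * pi / gn[ok]) / 4              # quarter local wavelength
    # sample the next frame's phase along each normal
    su <- seq(-1, 1, length.out = n_samp)
    S <- outer(smax, su)                       # npts x n_samp offsets
    X <- cr$x + S * nx
    Y <- cr$y + S * ny
    c1 <- cos(f1); s1 <- sin(f1)
    pv <- atan2(.bilin(s1, X, Y), .bilin(c1, X, Y))
    s_star <- vapply(seq_len(nrow(S)), function(i)
      .nearest_zero(S[i, ], pv[i, ]), numeric(1))
    good <- is.finite(s_star)
    dropped <- dropped + sum(!good)
    if (!any(good)) next
    recs[[length(recs) + 1]] <- data.frame(
      x = cr$x[good], y = cr$y[good],
      v_x = s_star[good] * nx[good] * px / stack$interval * 1000,
      v_y = s_star[good] * ny[good] * px / stack$interval * 1000,
      frame = t)
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(x = numeric(0), y = numeric(0), v_x = numeric(0),
                         v_y = numeric(0), frame = integer(0))
  class(out) <- c("crest_velocity_record", class(out))
  attr(out, "dropped") <- dropped
  out
}

# wrap-aware phase gradient via the analytic representation
.phase_gradient <- function(ph) {
  z <- exp(1i * ph)
  H <- nrow(ph); W <- ncol(ph)
  gx <- matrix(NA_real_, H, W); gy <- gx
  dx <- Arg(z[, c(2:W, W)] / z[, c(1, 1:(W - 1))])
  gx <- dx / 2; gx[, 1] <- Arg(z[, 2] / z[, 1]); gx[, W] <- Arg(z[, W] / z[, W - 1])
  dy <- Arg(z[c(2:H, H), ] / z[c(1, 1:(H - 1)), ])
  gy <- dy / 2; gy[1, ] <- Arg(z[2, ] / z[1, ]); gy[H, ] <- Arg(z[H, ] / z[H - 1, ])
  list(gx = gx, gy = gy)
}

# vectorized bilinear interpolation; coordinates outside the frame give NA
.bilin <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 1 & x <= W & y >= 1 & y <= H
  if (any(ok)) {
    xi <- x[ok]; yi <- y[ok]
    x0 <- pmin(floor(xi), W - 1); y0 <- pmin(floor(yi), H - 1)
    fx <- xi - x0; fy <- yi - y0
    id <- function(r, c) (c - 1) * H + r
    out[ok] <- (1 - fx) * (1 - fy) * m[id(y0, x0)] +
      fx * (1 - fy) * m[id(y0, x0 + 1)] +
      (1 - fx) * fy * m[id(y0 + 1, x0)] +
      fx * fy * m[id(y0 + 1, x0 + 1)]
  }
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
  out
}

.nearest_zero <- function(s, p) {
  ok <- is.finite(p)
  s <- s[ok]; p <- p[ok]
  if (length(p) < 2) return(NA_real_)
  a <- p[-length(p)]; b <- p[-1]
  i <- which((a <= 0) != (b <= 0) & abs(b - a) < pi)
  if (!length(i)) return(NA_real_)
  cross <- s[i] + (s[i + 1] - s[i]) * (-p[i]) / (p[i + 1] - p[i])
  cross[which.min(abs(cross))]
}

#' Drop near-static velocity records
#'
#' Removes records whose speed is below 10% of the median speed, the rule
#' used to eliminate static bright objects (protein aggregates) from the
#' direction statistics.
#'
#' @param records a `crest_velocity_record` data frame.
#' @param frac threshold as a fraction of the median speed.
#' @return filtered records; number removed in `attr(, "removed")`.
#' @export
filter_velocities <- function(records, frac = 0.1) {
  if (!nrow(records)) {
    attr(records, "removed") <- 0L
    return(records)
  }
  sp <- sqrt(records$v_x^2 + records$v_y^2)
  keep <- sp >= frac * stats::median(sp)
  out <- records[keep, , drop = FALSE]
  class(out) <- class(records)
  attr(out, "removed") <- sum(!keep)
  attr(out, "dropped") <- attr(records, "dropped")
  out
}

#' Direction and speed statistics of crest velocities
#'
#' Builds the standard summaries of a crest-velocity record list: the 2D
#' velocity histogram with 25 nm/s bins, the normalized angular histogram in
#' 15-degree segments (half-open `(a-15, a]`, 0 deg = downstream = +x,
#' counter-clockwise), the downstream fraction (angles in `(-30, 30]`), the
#' upstream fraction (`(150, 210]`), and the peak speed with a FWHM/2
#' uncertainty from the 10 nm/s speed histogram.
#'
#' @param records filtered `crest_velocity_record`.
#' @param flow_angle orientation of the downstream direction (deg); angles
#'   are measured relative to it.
#' @param bin2d 2D histogram bin (nm/s).
#' @param bin_speed speed histogram bin (nm/s).
#' @return list of class `direction_summary` with elements `hist2d`,
#'   `angular` (data frame angle_hi, fraction), `downstream_fraction`,
#'   `upstream_fraction`, `peak_speed`, `fwhm`, `n`, `low_confidence`.
#' @export
direction_summary <- function(records, flow_angle = 0, bin2d = 25,
                              bin_speed = 10) {
  n <- nrow(records)
  th <- flow_angle * pi / 180
  vx <- cos(th) * records$v_x + sin(th) * records$v_y
  vy <- -sin(th) * records$v_x + cos(th) * records$v_y
  ang <- atan2(vy, vx) * 180 / pi            # (-180, 180]
  sp <- sqrt(vx^2 + vy^2)

  edges <- seq(-180, 180, by = 15)
  cnt <- if (n) table(cut(ang, edges, right = TRUE, include.lowest = TRUE))
         else table(cut(numeric(0), edges))
  angular <- data.frame(angle_lo = edges[-length(edges)],
                        angle_hi = edges[-1],
                        fraction = if (n) as.numeric(cnt) / n
                                   else rep(0, 24))
  down <- sum(angular$fraction[angular$angle_lo >= -30 &
                                 angular$angle_hi <= 30])
  up <- sum(angular$fraction[angular$angle_lo >= 150 |
                               angular$angle_hi <= -150])

  hist2d <- NULL
  if (n) {
    bx <- .bins_around(vx, bin2d); by <- .bins_around(vy, bin2d)
    hist2d <- table(cut(vx, bx), cut(vy, by))
  }

  peak <- NA_real_; fwhm <- NA_real_
  if (n) {
    sb <- seq(0, max(sp) + bin_speed, by = bin_speed)
    h <- graphics::hist(sp, breaks = sb, plot = FALSE)
    im <- which.max(h$counts)
    peak <- h$mids[im]
    half <- h$counts[im] / 2
    above <- which(h$counts >= half)
    lo <- min(above); hi <- max(above)
    fwhm <- h$breaks[hi + 1] - h$breaks[lo]
  }

  structure(list(hist2d = hist2d, angular = angular,
                 downstream_fraction = down, upstream_fraction = up,
                 peak_speed = peak, fwhm = fwhm, n = n,
                 low_confidence = n < 10),
            class = "direction_summary")
}

.bins_around <- function(v, w) {
  lo <- floor(min(v) / w) * w
  hi <- ceiling(max(v) / w) * w
  if (hi <= lo) hi <- lo + w
  seq(lo, hi, by = w)
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("Crest direction summary (n = %d%s)\n", x$n,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  cat(sprintf("  downstream fraction: %.3f   upstream fraction: %.3f\n",
              x$downstream_fraction, x$upstream_fraction))
  cat(sprintf("  peak speed: %.0f +/- %.0f nm/s (peak +/- FWHM/2)\n",
              x$peak_speed, x$fwhm / 2))
  invisible(x)
}

#' End-to-end crest velocimetry of a stack
#'
#' Convenience pipeline: [phase_map()] -> [crest_displacements()] ->
#' [filter_velocities()] -> [direction_summary()].
#'
#' @param stack an `image_stack`.
#' @param frames frames to process (default: all pairs).
#' @param ... passed to [direction_summary()].
#' @return list with `records` (filtered) and `summary`.
#' @export
analyze_crests <- function(stack, frames = NULL, ...) {
  pm <- phase_map(stack)
  rec <- crest_displacements(stack, pm, frames = frames)
  rec <- filter_velocities(rec)
  list(records = rec,
       summary = direction_summary(rec, flow_angle = stack$flow_angle, ...))
}

#' Render a 1D simulation as an image stack
#'
#' Extrudes the membrane MinD profile of a 1D trajectory along the
#' transverse axis (planar wave fronts perpendicular to the flow), giving a
#' synthetic single-channel stack on which the crest velocimetry can be run
#' against simulation ground truth.
#'
#' @param traj a `min_trajectory`.
#' @param H transverse height in pixels.
#' @param species field to render.
#' @return an `image_stack` with pixel size `grid$dx` and the trajectory's
#'   frame interval.
#' @export
trajectory_to_stack <- function(traj, H = 32L, species = "m_d") {
  m <- species_matrix(traj, species)            # frames x N
  T <- nrow(m); N <- ncol(m)
  fr <- array(0, c(H, N, T))
  for (t in seq_len(T)) fr[, , t] <- matrix(m[t, ], H, N, byrow = TRUE)
  interval <- diff(traj$times)[1]
  image_stack(fr, pixel_size = traj$grid$dx, interval = interval)
}
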