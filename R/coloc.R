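#' @title Object-based co-localization by half-maximum ellipse overlap
#' @description Scores spatial coincidence of detected objects between the
#'   two channels: the half-maximum ellipse of each basis-channel object is
#'   intersected with the opposite channel's ellipses, and an object
#'   covered over at least the threshold fraction (default 50%) of its own
#'   area counts as co-localized. The per-frame coefficient is the number
#'   of co-localized objects relative to the channel with fewer objects.
#' @name coloc
NULL

#' Polygonal approximation of a half-maximum ellipse
#'
#' @param x_um,y_um Center.
#' @param wx_um,wy_um Semi-axes (> 0).
#' @param orientation_rad Rotation of the `wx` axis.
#' @param n Number of vertices (default 64); vertices are returned
#'   counter-clockwise.
#' @return An `n x 2` matrix of vertex coordinates.
#' @export
ellipse_polygon <- function(x_um, y_um, wx_um, wy_um, orientation_rad = 0,
                            n = 64L) {
  if (wx_um <= 0 || wy_um <= 0)
    stop("degenerate ellipse: semi-axes must be > 0", call. = FALSE)
  t <- 2 * pi * (seq_len(n) - 1L) / n
  ex <- wx_um * cos(t); ey <- wy_um * sin(t)
  cp <- cos(orientation_rad); sp <- sin(orientation_rad)
  cbind(x_um + cp * ex - sp * ey, y_um + sp * ex + cp * ey)
}

polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clipping of a polygon by a convex CCW clip polygon;
# vectorized over subject vertices for each clip edge
clip_convex <- function(subj, clip) {
  nc <- nrow(clip)
  out <- subj
  for (e in seq_len(nc)) {
    if (is.null(nrow(out)) || nrow(out) < 3L) return(matrix(0, 0, 2))
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    n <- nrow(out)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >= 0: inside
    inside <- side >= 0
    nxt <- c(2:n, 1L)
    cross <- inside != inside[nxt]
    # intersection of each crossing edge with the clip line
    t <- side / (side - side[nxt])
    ix <- out[, 1] + t * (out[nxt, 1] - out[, 1])
    iy <- out[, 2] + t * (out[nxt, 2] - out[, 2])
    # per input edge k, emit: intersection (if crossing), then out[nxt] (if inside)
    stacked_x <- rbind(ix, out[nxt, 1])
    stacked_y <- rbind(iy, out[nxt, 2])
    take <- rbind(cross, inside[nxt])
    out <- cbind(stacked_x[take], stacked_y[take])
  }
  out
}

#' Fraction of one spot's half-max ellipse covered by another's
#'
#' Computes `area(A intersect B) / area(A)` for the half-maximum ellipses
#' of two spots (note the asymmetry: this is the fraction of `a`'s own
#' area). Both ellipses are approximated by convex polygons (`n` vertices)
#' and intersected by exact convex-polygon clipping; the approximation is
#' accurate to well under 1% relative for the default 64 vertices.
#'
#' @param a,b Spots: any list or one-row data frame with `x_um`, `y_um`,
#'   `wx_um`, `wy_um`, `orientation_rad`.
#' @param n Vertices per ellipse polygon.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, n = 64L) {
  if (a$wx_um <= 0 || a$wy_um <= 0 || b$wx_um <= 0 || b$wy_um <= 0)
    stop("degenerate ellipse: semi-axes must be > 0", call. = FALSE)
  d2 <- (a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2
  reach <- max(a$wx_um, a$wy_um) + max(b$wx_um, b$wy_um)
  if (d2 >= reach^2) return(0)
  pa <- ellipse_polygon(a$x_um, a$y_um, a$wx_um, a$wy_um, a$orientation_rad, n)
  pb <- ellipse_polygon(b$x_um, b$y_um, b$wx_um, b$wy_um, b$orientation_rad, n)
  inter <- polygon_area(clip_convex(pa, pb))
  min(1, inter / polygon_area(pa))
}

# pairwise intersection areas between two spot sets (um^2), with a
# center-distance prefilter; rows = first set, cols = second set
intersection_areas <- function(sa, sb, n = 64L) {
  na <- nrow(sa); nb <- nrow(sb)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  ra <- pmax(sa$wx_um, sa$wy_um); rb <- pmax(sb$wx_um, sb$wy_um)
  pa <- lapply(seq_len(na), function(i)
    ellipse_polygon(sa$x_um[i], sa$y_um[i], sa$wx_um[i], sa$wy_um[i],
                    sa$orientation_rad[i], n))
  pb <- lapply(seq_len(nb), function(j)
    ellipse_polygon(sb$x_um[j], sb$y_um[j], sb$wx_um[j], sb$wy_um[j],
                    sb$orientation_rad[j], n))
  for (i in seq_len(na)) {
    d2 <- (sa$x_um[i] - sb$x_um)^2 + (sa$y_um[i] - sb$y_um)^2
    for (j in which(d2 < (ra[i] + rb)^2)) {
      out[i, j] <- polygon_area(clip_convex(pa[[i]], pb[[j]]))
    }
  }
  out
}

#' Classify co-localization in one frame
#'
#' A basis-channel object is co-localized when the maximum, over
#' opposite-channel objects, of the fraction of its own half-max area
#' covered reaches `threshold`. Computed with both channels as basis. The
#' per-basis coefficient is `100 * n_coloc / min(n_green, n_red)`, with
#' `n_coloc` capped at `min(n_green, n_red)` so the coefficient cannot
#' exceed 100 when several basis objects overlap one opposite object. When
#' one channel is empty the coefficient is undefined (`NA`) and the frame
#' is excluded from summaries.
#'
#' @param green,red Spot tables for one frame.
#' @param threshold Area-overlap threshold in `(0, 1]` (default 0.5).
#' @param n Vertices per ellipse polygon.
#' @return One-row data frame: `n_green`, `n_red`,
#'   `n_coloc_basis_green`, `n_coloc_basis_red`,
#'   `coefficient_basis_green`, `coefficient_basis_red`,
#'   `coefficient_pct` (mean of the two bases) - coefficients in percent.
#' @export
classify_coloc_frame <- function(green, red, threshold = 0.5, n = 64L) {
  stopifnot(threshold > 0, threshold <= 1)
  ng <- nrow(green); nr <- nrow(red)
  mn <- min(ng, nr)
  if (mn == 0L) {
    return(data.frame(n_green = ng, n_red = nr,
                      n_coloc_basis_green = NA_integer_,
                      n_coloc_basis_red = NA_integer_,
                      coefficient_basis_green = NA_real_,
                      coefficient_basis_red = NA_real_,
                      coefficient_pct = NA_real_))
  }
  inter <- intersection_areas(green, red, n)
  area_g <- pi * green$wx_um * green$wy_um
  area_r <- pi * red$wx_um * red$wy_um
  frac_g <- inter / area_g                   # rows: green basis
  frac_r <- t(inter) / area_r                # rows: red basis
  ncg <- min(sum(apply(frac_g, 1, max) >= threshold), mn)
  ncr <- min(sum(apply(frac_r, 1, max) >= threshold), mn)
  data.frame(n_green = ng, n_red = nr,
             n_coloc_basis_green = ncg, n_coloc_basis_red = ncr,
             coefficient_basis_green = 100 * ncg / mn,
             coefficient_basis_red = 100 * ncr / mn,
             coefficient_pct = 100 * (ncg + ncr) / (2 * mn))
}

#' Per-frame co-localization over a whole movie's spot table
#'
#' @param spots A [detect_spots()] table covering both channels.
#' @param threshold Area-overlap threshold (default 0.5).
#' @param n Vertices per ellipse polygon.
#' @return Data frame with one row per frame (column `frame` first), as in
#'   [classify_coloc_frame()].
#' @export
coloc_frames <- function(spots, threshold = 0.5, n = 64L) {
  frames <- sort(unique(spots$frame))
  out <- do.call(rbind, lapply(frames, function(f) {
    g <- spots[spots$frame == f & spots$channel == "green", ]
    r <- spots[spots$frame == f & spots$channel == "red", ]
    cbind(data.frame(frame = f), classify_coloc_frame(g, r, threshold, n))
  }))
  if (is.null(out)) out <- cbind(data.frame(frame = integer()),
                                 classify_coloc_frame(empty_spot_table(),
                                                      empty_spot_table())[0, ])
  rownames(out) <- NULL
  out
}

#' Summarize per-frame co-localization coefficients
#'
#' Mean and standard deviation over frames of the per-frame coefficients,
#' reported for both basis channels side by side. Frames where one channel
#' is empty (undefined coefficient) are excluded and counted in
#' `n_excluded`.
#'
#' @param frames A [coloc_frames()] result (or any data frame with the
#'   per-frame coefficient columns).
#' @return One-row data frame: `n_frames`, `n_excluded`,
#'   `mean_basis_green`, `sd_basis_green`, `mean_basis_red`,
#'   `sd_basis_red`, `mean_coefficient_pct`, `sd_coefficient_pct`.
#' @export
summarize_coloc <- function(frames) {
  ok <- frames[!is.na(frames$coefficient_pct), ]
  if (nrow(ok) == 0L)
    stop("no frames with both channels populated; nothing to summarize",
         call. = FALSE)
  if (nrow(frames) > nrow(ok))
    message(nrow(frames) - nrow(ok),
            " frame(s) with an empty channel excluded from the summary")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(
    n_frames = nrow(ok),
    n_excluded = nrow(frames) - nrow(ok),
    mean_basis_green = mean(ok$coefficient_basis_green),
    sd_basis_green = sd0(ok$coefficient_basis_green),
    mean_basis_red = mean(ok$coefficient_basis_red),
    sd_basis_red = sd0(ok$coefficient_basis_red),
    mean_coefficient_pct = mean(ok$coefficient_pct),
    sd_coefficient_pct = sd0(ok$coefficient_pct))
}
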