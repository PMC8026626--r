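#' Segment retinal boundary surfaces
#'
#' Estimates the ILM, IPL/INL, ellipsoid-zone and RPE depth maps from a raw
#' OCT volume.  The segmenter is a transparent per-A-scan rule set designed
#' for layered macular volumes, not a clinical segmenter:
#'
#' * ILM: first voxel whose raw reflectivity exceeds `ilm_threshold`
#'   (vitreous is far darker than any tissue structure, including the
#'   hyporeflective troughs of traction folds, so the raw profile is
#'   robust even under speckle);
#' * RPE: start of the deepest high-reflectivity run (after 3x3 lateral and
#'   3-voxel axial box smoothing, threshold `bright_threshold`);
#' * ellipsoid zone: centre of the high-reflectivity run immediately above
#'   the RPE run; A-scans without a distinct run (true EZ loss) are flagged
#'   and interpolated from their neighbours;
#' * IPL/INL: first strong negative axial gradient below the ILM on the
#'   smoothed profile (the drop from the inner retinal complex into the
#'   inner nuclear layer).
#'
#' All maps are median-smoothed across A-scans (window
#' `median_window`) and the anatomical ordering `ilm < ipl_inl < ez < rpe`
#' is enforced.
#'
#' @param volume an [oct_volume()] with no missing voxels.
#' @param ilm_threshold raw reflectivity marking the vitreoretinal
#'   interface (default 0.045, between the vitreous and the darkest
#'   intraretinal structures).
#' @param bright_threshold smoothed reflectivity of the hyperreflective
#'   photoreceptor/RPE bands (default 0.65).
#' @param gradient_threshold negative axial gradient (per voxel, smoothed)
#'   marking the inner-retina to INL drop (default -0.06).
#' @param median_window cross-A-scan median smoothing window (default 7,
#'   wide enough that narrow fold streaks cannot dominate a window).
#' @return a [surface_set()] with maps `ilm`, `ipl_inl`, `ez`, `rpe`;
#'   attribute `n_interpolated` counts A-scans where a surface had to be
#'   interpolated from neighbours.
#' @export
segment_surfaces <- function(volume, ilm_threshold = 0.045,
                             bright_threshold = 0.65,
                             gradient_threshold = -0.06,
                             median_window = 7L) {
  stopifnot(inherits(volume, "oct_volume"))
  V <- volume$intensity
  if (anyNA(V)) stop("segment_surfaces requires a volume without missing voxels")
  geom <- volume$geometry
  nb <- geom$dims[1L]; na_ <- geom$dims[2L]; nz <- geom$dims[3L]
  nA <- nb * na_
  if (diff(range(V)) < 0.05) {
    stop("no detectable boundaries: volume intensity is near-constant")
  }
  M <- vol_as_matrix(V)

  # ILM from the raw profiles
  cond <- M > ilm_threshold
  ilm_idx <- first_true(cond)

  # smoothed channel: 3x3 lateral box + 3-voxel axial box
  Ms <- vol_as_matrix(lateral_box3(V))
  Ms <- axial_box3(Ms)

  # RPE / EZ from high-reflectivity runs
  bright <- Ms > bright_threshold
  starts <- bright & !cbind(FALSE, bright[, -nz, drop = FALSE])
  ends <- bright & !cbind(bright[, -1L, drop = FALSE], FALSE)
  rpe_idx <- last_true(starts)
  colm <- col(starts)
  ez_start <- last_true(starts & colm < rpe_idx - 1L)
  ez_end <- first_true(ends & colm >= ez_start)
  ez_idx <- (ez_start + ez_end) / 2

  # IPL/INL: per-A-scan candidates whose failure modes are disjoint; the
  # earliest falling edge below the ILM wins.
  # (a) first strong falling edge on the laterally smoothed channel
  # (robust under speckle);
  falling_edge <- function(channel, threshold) {
    D <- cbind(0, channel[, 3:nz, drop = FALSE] -
                  channel[, 1:(nz - 2L), drop = FALSE], 0)
    # the edge must land in a hyporeflective band (below the inner/nuclear
    # midpoint): the drop from an adherent membrane into the inner retina
    # is steep too, but its destination is bright and must not qualify
    dest <- channel[, pmin(seq_len(nz) + 2L, nz), drop = FALSE]
    z0 <- first_true(D < threshold & dest < 0.375 & colm > ilm_idx + 1L)
    # refine to the gradient minimum within the edge; the boundary is the
    # voxel after it
    zcand <- pmin(outer(z0, 0:4, `+`), nz)
    dvals <- matrix(D[cbind(rep(seq_len(nA), 5L), as.vector(zcand))], nA, 5L)
    dvals[is.na(dvals)] <- Inf
    z0 + (max.col(-dvals, ties.method = "first") - 1L) + 1L
  }
  ipl_grad <- falling_edge(Ms, gradient_threshold)
  # (b) first crossing below the inner-retina/INL midpoint on the axially
  # smoothed profile (sharp where pit, cysts and the inner band merge into
  # one composite ramp)
  Ms3 <- axial_box3(M)
  ipl_thr <- first_true(Ms3 < 0.375 & colm > ilm_idx + 1L)
  ipl_idx <- pmin(ipl_grad, ipl_thr, na.rm = TRUE)
  # (c) on low-noise volumes, the same falling edge on the sharp axial-only
  # channel additionally resolves the one-voxel INL notch at the foveal
  # pit, which lateral smoothing blurs away; the axial high-pass residual
  # estimates the speckle level
  sub <- seq_len(nA)
  if (nA > 2000L) sub <- as.integer(seq(1L, nA, length.out = 2000L))
  d1 <- abs(M[sub, 2:nz, drop = FALSE] - M[sub, 1:(nz - 1L), drop = FALSE])
  m1 <- (M[sub, 2:nz, drop = FALSE] + M[sub, 1:(nz - 1L), drop = FALSE]) / 2
  bright_sel <- m1 > 0.3
  noise_level <- if (any(bright_sel)) {
    stats::median(d1[bright_sel] / m1[bright_sel])
  } else 0
  if (noise_level < 0.05) {
    ipl_idx <- pmin(ipl_idx, falling_edge(Ms3, gradient_threshold),
                    na.rm = TRUE)
    # at the foveola the INL can pinch to a single voxel between brighter
    # bands; on the raw profile that voxel is a strict local minimum
    dip <- M < cbind(Inf, M[, -nz, drop = FALSE]) &
      M < cbind(M[, -1L, drop = FALSE], Inf) &
      M < 0.375 & colm > ilm_idx + 1L
    ipl_idx <- pmin(ipl_idx, first_true(dip), na.rm = TRUE)
  }

  # index -> depth (voxel centres); the reported boundary is the centre of
  # the first voxel of the deeper band
  sp <- geom$axial_spacing_um
  to_map <- function(idx) matrix((idx - 0.5) * sp, nb, na_)
  maps <- list(ilm = to_map(ilm_idx), ipl_inl = to_map(ipl_idx),
               ez = to_map(ez_idx), rpe = to_map(rpe_idx))

  n_bad <- sum(vapply(maps, function(m) sum(is.na(m)), numeric(1)))
  maps <- lapply(maps, fill_na_map)
  maps <- lapply(maps, median_smooth_map, window = median_window,
                 max_val = nz * sp)

  # the median map is robust but lags steeply bent boundaries (the foveal
  # pit); keep the per-A-scan estimate unless it disagrees with its
  # median-smoothed neighbourhood by more than a veto distance, in which
  # case the neighbourhood wins.  On low-noise volumes per-A-scan
  # estimates are trustworthy and the veto is loose; under speckle it
  # tightens to reject early-trigger outliers.
  veto_um <- if (noise_level < 0.05) 50 else 10
  for (nm in c("ilm", "ipl_inl")) {
    cand <- to_map(switch(nm, ilm = ilm_idx, ipl_inl = ipl_idx))
    cand[is.na(cand)] <- maps[[nm]][is.na(cand)]
    maps[[nm]] <- ifelse(abs(cand - maps[[nm]]) <= veto_um,
                         cand, maps[[nm]])
  }

  # narrow hyporeflective streaks under the ILM (traction-fold troughs)
  # can capture whole columns of IPL/INL estimates, and at the frame edge
  # their weight doubles under replicate padding; a wide-window
  # consistency pass removes them.  Genuine surface bends (the pit) vary
  # by well under 30 um across a 15-A-scan window.
  wide <- median_smooth_map(maps$ipl_inl, window = 15L, max_val = nz * sp)
  maps$ipl_inl <- ifelse(abs(maps$ipl_inl - wide) <= 30, maps$ipl_inl, wide)

  # enforce anatomical ordering
  maps$ipl_inl <- pmax(maps$ipl_inl, maps$ilm + sp / 2)
  maps$ez <- pmax(maps$ez, maps$ipl_inl + sp / 2)
  maps$rpe <- pmax(maps$rpe, maps$ez + sp / 2)

  out <- surface_set(maps, axial_extent_um = nz * sp)
  attr(out, "n_interpolated") <- n_bad
  out
}

# ---- vectorized profile helpers ------------------------------------------

# first / last TRUE per row; NA when a row has none
first_true <- function(cond) {
  cond[is.na(cond)] <- FALSE
  idx <- max.col(cond * 1, ties.method = "first")
  idx[rowSums(cond) == 0] <- NA_integer_
  idx
}

last_true <- function(cond) {
  cond[is.na(cond)] <- FALSE
  nzc <- ncol(cond)
  idx <- nzc + 1L - max.col(cond[, nzc:1, drop = FALSE] * 1,
                            ties.method = "first")
  idx[rowSums(cond) == 0] <- NA_integer_
  idx
}

# 3x3 lateral box mean with replicated edges
lateral_box3 <- function(V) {
  nb <- dim(V)[1L]; na_ <- dim(V)[2L]
  up <- c(1L, seq_len(nb - 1L)); dn <- c(seq_len(nb - 1L) + 1L, nb)
  S <- V[up, , , drop = FALSE] + V + V[dn, , , drop = FALSE]
  lf <- c(1L, seq_len(na_ - 1L)); rt <- c(seq_len(na_ - 1L) + 1L, na_)
  (S[, lf, , drop = FALSE] + S + S[, rt, , drop = FALSE]) / 9
}

# 3-voxel axial box mean on an (A-scan x depth) matrix, replicated edges
axial_box3 <- function(M) {
  nzc <- ncol(M)
  (M[, c(1L, seq_len(nzc - 1L)), drop = FALSE] + M +
     M[, c(seq_len(nzc - 1L) + 1L, nzc), drop = FALSE]) / 3
}

# iteratively fill NA cells with the mean of available 3x3 neighbours
fill_na_map <- function(map, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    nas <- is.na(map)
    if (!any(nas)) return(map)
    padded <- map
    padded[nas] <- 0
    w <- 1 - nas
    sums <- box3_sum(padded)
    cnts <- box3_sum(w)
    fill <- sums / pmax(cnts, 1)
    map[nas & cnts > 0] <- fill[nas & cnts > 0]
  }
  map[is.na(map)] <- stats::median(map, na.rm = TRUE)
  map
}

box3_sum <- function(m) {
  nb <- nrow(m); na_ <- ncol(m)
  up <- c(1L, seq_len(nb - 1L)); dn <- c(seq_len(nb - 1L) + 1L, nb)
  s <- m[up, , drop = FALSE] + m + m[dn, , drop = FALSE]
  lf <- c(1L, seq_len(na_ - 1L)); rt <- c(seq_len(na_ - 1L) + 1L, na_)
  s[, lf, drop = FALSE] + s + s[, rt, drop = FALSE]
}

# window x window median filter (EBImage constant-time median on the map
# normalized to [0, 1]; quantization is far below one voxel).  The map is
# replicate-padded first so borders are not dragged toward zero.
median_smooth_map <- function(map, window = 5L, max_val = NULL) {
  if (window <= 1L) return(map)
  if (is.null(max_val)) max_val <- max(map) + 1
  half <- window %/% 2L
  nb <- nrow(map); na_ <- ncol(map)
  ridx <- c(rep(1L, half), seq_len(nb), rep(nb, half))
  cidx <- c(rep(1L, half), seq_len(na_), rep(na_, half))
  m <- pmin(pmax(map[ridx, cidx] / max_val, 0), 1)
  out <- EBImage::medianFilter(m, size = half) * max_val
  out[half + seq_len(nb), half + seq_len(na_)]
}
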