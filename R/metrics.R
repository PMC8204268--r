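#' Mask overlap metrics
#'
#' Dice coefficient `2|A n B| / (|A| + |B|)` and Jaccard index
#' `|A n B| / |A u B|` between two voxel masks. The masks may be given as
#' logical arrays/vectors or as integer index sets; they must live on the
#' same grid. The two metrics satisfy `dice = 2 j / (1 + j)`.
#'
#' @param a,b masks: logical vectors/arrays of common length, or integer
#'   voxel index vectors.
#' @return scalar in `[0, 1]`.
#' @examples
#' dice(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'      c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))   # 0.6
#' @export
dice <- function(a, b) {
  s <- mask_sizes(a, b)
  if (s$na + s$nb == 0) stop("both masks are empty: Dice undefined")
  2 * s$ni / (s$na + s$nb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  s <- mask_sizes(a, b)
  if (s$na + s$nb == 0) stop("both masks are empty: Jaccard undefined")
  s$ni / (s$na + s$nb - s$ni)
}

mask_sizes <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    stopifnot(length(a) == length(b))
    list(na = sum(a), nb = sum(b), ni = sum(a & b))
  } else {
    a <- unique(as.integer(a)); b <- unique(as.integer(b))
    list(na = length(a), nb = length(b), ni = length(intersect(a, b)))
  }
}

#' Standardised uptake value ratio
#'
#' Ratio of mean uptake in the target region to mean uptake in the
#' reference region, both defined on the same grid as the PET image.
#' Invariant to global intensity scaling.
#'
#' @param pet quantitative PET [voxel_grid()].
#' @param labels parcellation [voxel_grid()] aligned to the PET grid.
#' @param target_id,reference_id label ids of the target (precuneus
#'   analogue) and reference (cerebellar grey matter analogue) regions.
#' @param pvc_applied flag carried into the result.
#' @return tibble with one row: target_roi, reference_roi, suvr,
#'   pvc_applied.
#' @export
suvr <- function(pet, labels, target_id, reference_id, pvc_applied = FALSE) {
  lv <- as.integer(labels$values)
  tm <- lv == target_id
  rm <- lv == reference_id
  if (!any(tm)) stop("target region ", target_id, " is empty")
  if (!any(rm)) stop("reference region ", reference_id, " is empty")
  tibble::tibble(
    target_roi = as.integer(target_id),
    reference_roi = as.integer(reference_id),
    suvr = mean(pet$values[tm]) / mean(pet$values[rm]),
    pvc_applied = isTRUE(pvc_applied)
  )
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, n >= 2, non-zero mean.
#' @return scalar CoV.
#' @export
coeff_var <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean: CoV undefined")
  stats::sd(values) / m
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA F test on the absolute deviations from the group medians
#' (median centring is what distinguishes Brown-Forsythe from the
#' mean-centred Levene variant); p-value from the F distribution with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 3.
#' @return tibble with columns statistic, p_value, df1, df2.
#' @export
brown_forsythe <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 3))
  z <- lapply(groups, function(x) abs(x - stats::median(x)))
  k <- length(z)
  n <- vapply(z, length, 1L)
  N <- sum(n)
  zbar <- vapply(z, mean, 1)
  zall <- sum(vapply(z, sum, 1)) / N
  ssb <- sum(n * (zbar - zall)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar[i])^2), 1))
  df1 <- k - 1; df2 <- N - k
  stat <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(stat)) 0 else stats::pf(stat, df1, df2, lower.tail = FALSE)
  tibble::tibble(statistic = stat, p_value = p, df1 = df1, df2 = df2)
}

#' Iterative-Yang partial volume correction
#'
#' At each iteration a piecewise-constant synthetic image is built from the
#' current regional means, the PET image is multiplied by the ratio of the
#' synthetic image to its PSF-smoothed version, and the regional means are
#' recomputed from the corrected image. Requires an already aligned
#' parcellation. Stops after `n_iter` iterations or when the regional means
#' change by less than `rel_tol` relative.
#'
#' @param pet [voxel_grid()], the quantitative PET.
#' @param labels parcellation [voxel_grid()] on the PET grid (0 =
#'   background).
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM in mm (default 4.5);
#'   0 returns the input unchanged.
#' @param n_iter maximum iterations (default 5).
#' @param rel_tol relative-change stopping tolerance on regional means.
#' @return corrected non-negative [voxel_grid()]; empty regions are skipped
#'   and recorded in attribute `"skipped_regions"`.
#' @export
yang_pvc <- function(pet, labels, psf_fwhm_mm = 4.5, n_iter = 5L,
                     rel_tol = 1e-4) {
  stopifnot(psf_fwhm_mm >= 0, n_iter >= 1)
  if (psf_fwhm_mm == 0) return(pet)
  stopifnot(all(dim(pet$values) == dim(labels$values)))
  lv <- as.integer(labels$values)
  ids <- sort(unique(lv))
  ids <- ids[ids > 0]
  skipped <- integer(0)
  sigma <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / pet$voxel_size_mm
  grp <- match(lv, ids)           # NA for background
  cur <- pet$values
  means <- vapply(ids, function(id) mean(cur[lv == id]), 1)
  for (it in seq_len(n_iter)) {
    synth <- array(0, dim(cur))
    ok <- !is.na(grp)
    synth[ok] <- means[grp[ok]]
    sm <- gauss_smooth3(synth, sigma)
    ratio <- array(1, dim(cur))
    nz <- sm > 0
    ratio[nz] <- synth[nz] / sm[nz]
    corrected <- pet$values * ratio
    new_means <- vapply(ids, function(id) {
      v <- corrected[lv == id]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 1)
    bad <- is.na(new_means)
    if (any(bad)) {
      skipped <- union(skipped, ids[bad])
      new_means[bad] <- means[bad]
    }
    delta <- max(abs(new_means - means) / pmax(abs(means), 1e-12))
    means <- new_means
    cur <- corrected
    if (delta < rel_tol) break
  }
  out <- voxel_grid(pmax(cur, 0), pet$voxel_size_mm, pet$affine)
  attr(out, "skipped_regions") <- skipped
  out
}
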