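# Orientation calling for 1-D AT-stain intensity profiles of stretched,
# partially ejected molecules anchored at a capsid: FIFO/LIFO decision by
# Pearson correlation against expected genome barcodes, plus the length
# arithmetic converting measured lengths to ejected fractions.

#' Construct an intensity profile object
#'
#' One-dimensional stain-intensity trace along a stretched molecule; pixel 1
#' is the capsid-proximal end.
#'
#' @param intensities non-negative numeric vector (length >= 2).
#' @param pixel_size_um physical pixel pitch in micrometres.
#' @param condition optional condition label.
#' @return an `intensity_profile`.
#' @export
intensity_profile <- function(intensities, pixel_size_um, condition = NA_character_) {
  stopifnot(is.numeric(intensities), length(intensities) >= 2,
            pixel_size_um > 0, all(is.finite(intensities)))
  structure(list(intensities = as.numeric(intensities),
                 pixel_size_um = pixel_size_um, condition = condition),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile>", length(x$intensities), "pixels at",
      x$pixel_size_um, "um/px\n")
  invisible(x)
}

#' Cumulative AT and N counts of a genome
#'
#' Base-resolution cumulative sums used for O(1) windowed AT fractions; a
#' shared cache for repeated barcode construction against one genome.
#'
#' @param genome a `genome_sequence`.
#' @return list with `at` and `n`, cumulative counts of length `length_bp + 1`.
#' @export
genome_cumulants <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  v <- utf8ToInt(genome$residues)
  list(at = c(0, cumsum(v == 65L | v == 84L)),   # A, T
       n  = c(0, cumsum(v == 78L)))              # N
}

#' Reverse an intensity profile in x
#' @param profile an `intensity_profile`.
#' @return the profile with its pixel order reversed.
#' @export
reverse_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  profile$intensities <- rev(profile$intensities)
  profile
}

#' Pearson product-moment correlation with validity checks
#'
#' @param a,b numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance input: constant profile is uninformative")
  cor(a, b)
}

#' DNA contour length in micrometres
#'
#' @param n_bp number of base pairs (`>= 0`).
#' @param rise_nm_per_bp helical rise per base pair in nm (default 0.34).
#' @return length in micrometres.
#' @export
#' @examples
#' contour_length_um(48502)  # 16.49 um, ~16.5
contour_length_um <- function(n_bp, rise_nm_per_bp = 0.34) {
  if (any(n_bp < 0)) stop("n_bp must be non-negative")
  n_bp * rise_nm_per_bp / 1000
}

#' Stain-corrected contour length
#'
#' Intercalating dyes lengthen DNA; the corrected length is the contour
#' length times an extension factor (150% for heavy intercalator staining).
#'
#' @param contour_um contour length in micrometres.
#' @param extension_factor multiplicative extension, `>= 1`.
#' @return corrected length in micrometres.
#' @export
#' @examples
#' stain_corrected_length(16.5, 1.5)  # 24.75, ~24.8
stain_corrected_length <- function(contour_um, extension_factor) {
  if (any(extension_factor < 1)) stop("extension_factor must be >= 1")
  contour_um * extension_factor
}

#' Measure a molecule's length from its intensity profile
#'
#' Background is estimated as the median of the 10% dimmest pixels and the
#' noise scale as their standard deviation; the molecule is the longest
#' contiguous run of pixels above `background + k_sd * noise`.
#'
#' @param profile an `intensity_profile`.
#' @param k_sd threshold multiplier on the noise scale (default 3).
#' @return list with `length_um`, `n_pixels`, `first_pixel`, `background`,
#'   `threshold`.
#' @export
measure_length <- function(profile, k_sd = 3) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$intensities
  nd <- max(2L, floor(0.1 * length(v)))
  dim_px <- sort(v)[seq_len(nd)]
  bg <- median(dim_px)
  noise <- sd(dim_px)
  if (!is.finite(noise)) noise <- 0
  thr <- bg + k_sd * noise
  above <- v > thr + 1e-12
  if (!any(above)) stop("no pixels above threshold: no molecule segment found")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  n_px <- r$lengths[best]
  list(length_um = n_px * profile$pixel_size_um, n_pixels = n_px,
       first_pixel = starts[best], background = bg, threshold = thr)
}

#' Ejected DNA fraction from a measured length
#'
#' @param length_um measured molecule length in micrometres.
#' @param control_um full-length control molecule length (default 17.25).
#' @return ejected fraction in percent.
#' @export
#' @examples
#' ejected_fraction(12.0)  # 69.6%
ejected_fraction <- function(length_um, control_um = 17.25) {
  if (any(length_um < 0) || control_um <= 0) stop("lengths must be positive")
  100 * length_um / control_um
}

#' Expected stain barcode of a genome segment on a pixel grid
#'
#' Models the AT-specific stain signal of a stretched DNA segment: windowed
#' AT fraction minus a binding baseline (clipped at zero), mapped to physical
#' coordinates via the helical rise and a stretch factor, blurred with a
#' Gaussian point-spread function, and resampled at pixel centres.  Pixel 1
#' is the capsid-proximal end of the segment; `orientation = "forward"` puts
#' the segment's first base proximal, `"reverse"` its last base.
#'
#' @param genome a `genome_sequence`.
#' @param start_bp,end_bp segment bounds (1-based, inclusive).
#' @param orientation `"forward"` or `"reverse"` (see above).
#' @param n_pixels number of output pixels.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param window_bp AT window width in bp (default 1000).
#' @param baseline_at AT-fraction binding baseline (default 0.30): signal is
#'   `max(AT - baseline, 0)`.
#' @param blur_um Gaussian blur standard deviation in micrometres (default
#'   0.3).
#' @param cum optional cached [genome_cumulants()] of `genome`.
#' @return numeric vector of expected signal at the `n_pixels` pixel centres.
#' @export
expected_stain_profile <- function(genome, start_bp, end_bp,
                                   orientation = c("forward", "reverse"),
                                   n_pixels, pixel_size_um = 0.16,
                                   window_bp = 1000, baseline_at = 0.30,
                                   blur_um = 0.3, cum = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(genome, "genome_sequence"),
            start_bp >= 1, end_bp <= genome$length_bp, end_bp > start_bp,
            n_pixels >= 3)
  if (is.null(cum)) cum <- genome_cumulants(genome)
  seg_len <- end_bp - start_bp + 1L
  win <- min(window_bp, seg_len)
  step <- max(1L, min(100L, seg_len %/% 20L))
  rel_starts <- seq.int(1L, seg_len - win + 1L, by = step)
  abs_starts <- start_bp + rel_starts - 1L
  at <- cum$at[abs_starts + win] - cum$at[abs_starts]
  nn <- cum$n[abs_starts + win] - cum$n[abs_starts]
  if (any(win - nn == 0)) stop("window of all-N content in segment")
  at_frac <- at / (win - nn)
  positions_bp <- rel_starts + (win - 1) / 2
  # fractional coordinate along the stretched molecule, capsid-proximal = 0;
  # the segment barcode is scaled onto the measured pixel span, so the
  # forward and reverse orientations are exact mirrors about its midpoint
  pos_frac <- (positions_bp - 0.5) / seg_len
  if (orientation == "reverse") pos_frac <- 1 - pos_frac
  signal <- pmax(at_frac - baseline_at, 0)
  len_um <- n_pixels * pixel_size_um
  x_um <- pos_frac * len_um
  # fine grid, Gaussian blur with edge renormalisation, pixel-centre sampling
  du <- pixel_size_um / 4
  grid <- seq(0, len_um, by = du)
  o <- order(x_um)
  fine <- approx(x_um[o], signal[o], xout = grid, rule = 2)$y
  if (blur_um > 0) {
    half <- ceiling(3 * blur_um / du)
    kern <- exp(-0.5 * ((-half:half) * du / blur_um)^2)
    m <- length(grid)
    pad <- rep(0, half)
    num <- stats::filter(c(pad, fine, pad), kern, method = "convolution",
                         sides = 2)
    den <- stats::filter(c(pad, rep(1, m), pad), kern, method = "convolution",
                         sides = 2)
    fine <- as.numeric(num[(half + 1):(half + m)] / den[(half + 1):(half + m)])
  }
  centres <- (seq_len(n_pixels) - 0.5) * pixel_size_um
  approx(grid, fine, xout = centres, rule = 2)$y
}

#' Call the ejection direction of a molecule profile
#'
#' Estimates the ejected fraction from the measured length, builds the two
#' candidate expected barcodes for that fraction -- FIFO (the genome's left,
#' first-packaged end ejected first and therefore distal) and LIFO (right end
#' distal) -- and returns the orientation with the larger Pearson correlation.
#' The call is `"ambiguous"` when the two coefficients are within
#' `tie_threshold` or the best coefficient is below `quality_threshold`.
#' Molecules within half a percent of full length are treated as complete
#' ejections (the two candidates are then exact mirror images).
#'
#' @param profile an `intensity_profile`.
#' @param genome the reference `genome_sequence`.
#' @param stretch_factor,window_bp,baseline_at,blur_um,rise_nm_per_bp barcode
#'   model parameters; see [expected_stain_profile()].
#' @param control_um full-length control for the reported ejected fraction.
#' @param tie_threshold minimum coefficient separation for a confident call.
#' @param quality_threshold minimum best coefficient for a confident call.
#' @param length_tolerance error if the measured length exceeds the stretched
#'   contour by more than this fraction.
#' @param min_callable_fraction molecules whose estimated ejected fraction is
#'   below this are returned as `ambiguous` without scoring.  In cohort
#'   estimation this should be set so that *both* candidate barcodes span the
#'   genome's composition boundary (for a boundary at 45% of the genome,
#'   `1 - 0.45 + margin`): below that point one pathway is systematically
#'   harder to score than the other and its exclusion biases cohort FIFO
#'   percentages, whereas a length cut is independent of the true pathway.
#'   Default 0 (score everything), appropriate for single-molecule use.
#' @param cache optional environment memoising candidate barcodes by pixel
#'   count (the estimated fraction is a function of the measured pixel count
#'   alone, so cohorts against one genome can share candidates).
#' @return an `orientation_call`: `call`, `pearson_r`, `r_forward` (FIFO),
#'   `r_reverse` (LIFO), `ejected_length_um`, `ejected_fraction_percent`.
#' @export
call_direction <- function(profile, genome, stretch_factor = 1.05,
                           window_bp = 1000, baseline_at = 0.30,
                           blur_um = 0.3, rise_nm_per_bp = 0.34,
                           control_um = 17.25, tie_threshold = 0.05,
                           quality_threshold = 0.3, length_tolerance = 0.1,
                           min_callable_fraction = 0, cache = NULL) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(genome, "genome_sequence"))
  m <- measure_length(profile)
  if (m$n_pixels < 3) stop("fewer than 3 informative pixels after segmentation")
  y <- profile$intensities[m$first_pixel:(m$first_pixel + m$n_pixels - 1)]
  # matched filter: smooth the measured trace at the optical blur scale
  # before correlating (suppresses pixel noise without moving the barcode;
  # symmetric, so reversal consistency is preserved exactly)
  if (blur_um > 0) {
    half <- ceiling(3 * blur_um / profile$pixel_size_um)
    kern <- exp(-0.5 * ((-half:half) * profile$pixel_size_um / blur_um)^2)
    pad <- rep(0, half)
    num <- stats::filter(c(pad, y, pad), kern, method = "convolution", sides = 2)
    den <- stats::filter(c(pad, rep(1, length(y)), pad), kern,
                         method = "convolution", sides = 2)
    y <- as.numeric(num[(half + 1):(half + length(y))] /
                      den[(half + 1):(half + length(y))])
  }
  L <- genome$length_bp
  full_um <- contour_length_um(L, rise_nm_per_bp) * stretch_factor
  f_est <- m$length_um / full_um
  if (f_est > 1 + length_tolerance)
    stop(sprintf("measured length %.2f um exceeds stretched contour %.2f um",
                 m$length_um, full_um))
  if (f_est > 0.995) f_est <- 1
  if (f_est < min_callable_fraction) {
    return(structure(list(
      call = "ambiguous", pearson_r = NA_real_,
      r_forward = NA_real_, r_reverse = NA_real_,
      ejected_length_um = m$length_um,
      ejected_fraction_percent = ejected_fraction(m$length_um, control_um),
      n_pixels = m$n_pixels
    ), class = "orientation_call"))
  }
  seg_bp <- max(3L, round(f_est * L))
  cum <- NULL
  if (!is.null(cache)) {
    if (is.null(cache$.cum)) cache$.cum <- genome_cumulants(genome)
    cum <- cache$.cum
  }
  cand <- function(start, end, orientation) {
    tryCatch(expected_stain_profile(
      genome, start, end, orientation, n_pixels = m$n_pixels,
      pixel_size_um = profile$pixel_size_um, window_bp = window_bp,
      baseline_at = baseline_at, blur_um = blur_um, cum = cum),
      error = function(e) NULL)
  }
  key <- as.character(m$n_pixels)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    fifo_exp <- cache[[key]]$fifo
    lifo_exp <- cache[[key]]$lifo
  } else {
    fifo_exp <- cand(1L, seg_bp, "reverse")            # left end distal
    lifo_exp <- cand(L - seg_bp + 1L, L, "forward")    # right end distal
    if (!is.null(cache)) cache[[key]] <- list(fifo = fifo_exp, lifo = lifo_exp)
  }
  safe_cor <- function(b) {
    if (is.null(b)) return(NA_real_)
    tryCatch(pearson_cor(y, b), error = function(e) NA_real_)
  }
  r_forward <- safe_cor(fifo_exp)
  r_reverse <- safe_cor(lifo_exp)
  rs <- c(r_forward, r_reverse)
  call <- if (all(is.na(rs))) "ambiguous" else {
    best <- max(rs, na.rm = TRUE)
    gap <- if (any(is.na(rs))) Inf else abs(r_forward - r_reverse)
    if (gap < tie_threshold || best < quality_threshold) "ambiguous"
    else if (which.max(replace(rs, is.na(rs), -Inf)) == 1L) "FIFO" else "LIFO"
  }
  structure(list(
    call = call,
    pearson_r = if (all(is.na(rs))) NA_real_ else max(rs, na.rm = TRUE),
    r_forward = r_forward, r_reverse = r_reverse,
    ejected_length_um = m$length_um,
    ejected_fraction_percent = ejected_fraction(m$length_um, control_um),
    n_pixels = m$n_pixels
  ), class = "orientation_call")
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf(
    "<orientation_call> %s (r = %.3f; FIFO %.3f vs LIFO %.3f), %.2f um (%.1f%%)\n",
    x$call, x$pearson_r, x$r_forward, x$r_reverse,
    x$ejected_length_um, x$ejected_fraction_percent))
  invisible(x)
}

#' Summarise a cohort of orientation calls
#'
#' @param calls list of `orientation_call` objects.
#' @param sets optional vector of set labels (one per call) for per-set FIFO
#'   percentages, as in replicate experimental sets.
#' @return list with `table` (one row per molecule), `percent_fifo` over
#'   unambiguous calls, `n_called`, `n_ambiguous`, and, when `sets` is given,
#'   `per_set` percentages with their `mean` and `sd`.
#' @export
cohort_summary <- function(calls, sets = NULL) {
  stopifnot(length(calls) >= 1)
  tab <- data.frame(
    call = vapply(calls, function(x) x$call, character(1)),
    pearson_r = vapply(calls, function(x) x$pearson_r, numeric(1)),
    length_um = vapply(calls, function(x) x$ejected_length_um, numeric(1)),
    fraction_percent = vapply(calls, function(x) x$ejected_fraction_percent,
                              numeric(1))
  )
  if (!is.null(sets)) tab$set <- sets
  called <- tab$call != "ambiguous"
  if (!any(called)) stop("all calls ambiguous: no callable molecules")
  pct <- 100 * mean(tab$call[called] == "FIFO")
  out <- list(table = tab, percent_fifo = pct,
              n_called = sum(called), n_ambiguous = sum(!called),
              mean_length_fifo = mean(tab$length_um[tab$call == "FIFO"]),
              mean_length_lifo = mean(tab$length_um[tab$call == "LIFO"]))
  if (!is.null(sets)) {
    per <- vapply(split(tab[called, ], tab$set[called]), function(d)
      100 * mean(d$call == "FIFO"), numeric(1))
    out$per_set <- per
    out$percent_fifo_mean <- mean(per)
    out$percent_fifo_sd <- sd(per)
  }
  out
}
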