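# Synthetic inputs with known ground truth: block-composition genomes, noisy
# molecule intensity profiles, and whole cohorts, mirroring the design of the
# single-molecule ejection experiments (three sets of 50 molecules per
# condition, ejected fractions in the 60-75% band).

#' Generate a two-block composition genome
#'
#' Independent per-position draws with a region-specific GC probability: a
#' GC-rich left block (the first-packaged region) and an AT-rich right block,
#' split at `boundary_fraction` of the length.
#'
#' @param length_bp genome length (default 48502, lambda-sized).
#' @param gc_left,gc_right GC fraction of the left/right block (defaults
#'   0.53 / 0.47).
#' @param boundary_fraction block boundary as a fraction of length (default
#'   0.45).
#' @param seed integer seed.
#' @return a `genome_sequence`.
#' @export
#' @examples
#' g <- synth_genome(10000, seed = 1)
synth_genome <- function(length_bp = 48502, gc_left = 0.53, gc_right = 0.47,
                         boundary_fraction = 0.45, seed = 1) {
  stopifnot(length_bp >= 1, gc_left >= 0, gc_left <= 1,
            gc_right >= 0, gc_right <= 1,
            boundary_fraction > 0, boundary_fraction < 1)
  b <- round(boundary_fraction * length_bp)
  local_seed(derive_seed(seed, "genome"), {
    draw <- function(n, gc) {
      if (n == 0) return(character(0))
      sample(c("G", "C", "A", "T"), n, replace = TRUE,
             prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
    }
    res <- paste(c(draw(b, gc_left), draw(length_bp - b, gc_right)),
                 collapse = "")
    genome_sequence(res, name = sprintf("synthetic_two_block_%dbp", length_bp))
  })
}

#' Specification of a synthetic molecule cohort
#'
#' Defaults mirror the experimental design: sets of 50 flow-stretched,
#' partially ejected molecules, ejected fractions centred in the 60-75% band,
#' lambda-sized two-block genomes, and additive Gaussian noise with a
#' constant background at 10% of the peak signal.
#'
#' @param n_molecules molecules per cohort (default 50).
#' @param true_p_fifo ground-truth FIFO probability (default 0.5).
#' @param ejected_mean,ejected_sd,ejected_bounds ejected-fraction
#'   distribution: normal with these moments, truncated to the bounds.
#' @param snr peak-signal-to-noise ratio (`Inf` = noiseless).
#' @param pixel_size_um pixel pitch (default 0.16).
#' @param stretch_factor stretched/contour length ratio (default 1.05).
#' @param length_bp,gc_left,gc_right,boundary_fraction genome block design.
#' @param window_bp,baseline_at,blur_um stain barcode model parameters (see
#'   [expected_stain_profile()]).
#' @param background_frac constant background as a fraction of peak signal.
#' @param seed integer master seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_molecules = 50, true_p_fifo = 0.5,
                        ejected_mean = 0.675, ejected_sd = 0.04,
                        ejected_bounds = c(0.55, 0.80), snr = 5,
                        pixel_size_um = 0.16, stretch_factor = 1.05,
                        length_bp = 48502, gc_left = 0.53, gc_right = 0.47,
                        boundary_fraction = 0.45, window_bp = 1000,
                        baseline_at = 0.30, blur_um = 0.3,
                        background_frac = 0.10, seed = 1) {
  stopifnot(n_molecules >= 1, true_p_fifo >= 0, true_p_fifo <= 1,
            ejected_bounds[1] > 0, ejected_bounds[2] <= 1,
            ejected_bounds[1] < ejected_bounds[2], snr > 0,
            boundary_fraction > 0, boundary_fraction < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Synthesise one molecule intensity profile
#'
#' Takes the ejected genome segment for the given pathway (FIFO: the left,
#' first-packaged end out first; LIFO: the right end), builds the expected
#' stain barcode oriented with the capsid-proximal pixel first and the
#' first-ejected end distal, maps it to pixels at the stretched length, and
#' adds constant background plus Gaussian noise at the requested SNR.
#' Background-only padding pixels are appended beyond the molecule's distal
#' end.
#'
#' @param genome a `genome_sequence`.
#' @param ejected_fraction fraction of the genome ejected, in `(0, 1]`.
#' @param first_out_end `"left"` (FIFO) or `"right"` (LIFO).
#' @param spec a [cohort_spec()] providing pixel size, SNR, barcode model.
#' @param seed integer seed for the noise draw.
#' @param cum optional cached [genome_cumulants()] of `genome`.
#' @return list with `profile` (an `intensity_profile`) and `truth` (list:
#'   `pathway`, `ejected_fraction`, `ejected_bp`, `length_um`, `n_pixels`).
#' @export
synth_molecule_profile <- function(genome, ejected_fraction,
                                   first_out_end = c("left", "right"),
                                   spec = cohort_spec(), seed = 1,
                                   cum = NULL) {
  first_out_end <- match.arg(first_out_end)
  stopifnot(inherits(genome, "genome_sequence"),
            ejected_fraction > 0, ejected_fraction <= 1)
  L <- genome$length_bp
  seg_bp <- max(3L, round(ejected_fraction * L))
  true_len_um <- contour_length_um(seg_bp) * spec$stretch_factor
  n_px <- floor(true_len_um / spec$pixel_size_um)
  if (n_px < 3) stop("ejected segment shorter than 3 pixels")
  sig <- if (first_out_end == "left") {
    expected_stain_profile(genome, 1L, seg_bp, "reverse", n_px,
                           spec$pixel_size_um, spec$window_bp,
                           spec$baseline_at, spec$blur_um, cum = cum)
  } else {
    expected_stain_profile(genome, L - seg_bp + 1L, L, "forward", n_px,
                           spec$pixel_size_um, spec$window_bp,
                           spec$baseline_at, spec$blur_um, cum = cum)
  }
  peak <- max(sig)
  if (peak <= 0) stop("segment produces no stain signal above baseline")
  pad <- max(10L, round(0.25 * n_px))
  noiseless <- c(sig, rep(0, pad)) + spec$background_frac * peak
  intens <- local_seed(derive_seed(seed, "noise"), {
    if (is.finite(spec$snr))
      noiseless + rnorm(length(noiseless), sd = peak / spec$snr)
    else noiseless
  })
  list(
    profile = intensity_profile(pmax(intens, 0), spec$pixel_size_um),
    truth = list(pathway = if (first_out_end == "left") "FIFO" else "LIFO",
                 ejected_fraction = ejected_fraction, ejected_bp = seg_bp,
                 length_um = n_px * spec$pixel_size_um, n_pixels = n_px)
  )
}

#' Synthesise a cohort of molecule profiles with ground truth
#'
#' Pathway labels are Bernoulli(`true_p_fifo`); ejected fractions are drawn
#' from the truncated normal in the spec; the genome is generated once per
#' cohort.  Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param genome optional pre-built `genome_sequence` (generated from the
#'   spec when `NULL`).
#' @return a `synthetic_cohort`: list with `profiles`, `truth` (data.frame),
#'   `genome`, `spec`.
#' @export
synth_cohort <- function(spec = cohort_spec(), genome = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(genome))
    genome <- synth_genome(spec$length_bp, spec$gc_left, spec$gc_right,
                           spec$boundary_fraction, seed = derive_seed(spec$seed, "g"))
  draws <- local_seed(derive_seed(spec$seed, "cohort"), {
    list(fifo = rbinom(spec$n_molecules, 1, spec$true_p_fifo) == 1,
         frac = pmin(spec$ejected_bounds[2], pmax(spec$ejected_bounds[1],
                 rnorm(spec$n_molecules, spec$ejected_mean, spec$ejected_sd))))
  })
  cum <- genome_cumulants(genome)
  out <- vector("list", spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    out[[i]] <- synth_molecule_profile(
      genome, draws$frac[i], if (draws$fifo[i]) "left" else "right",
      spec, seed = derive_seed(spec$seed, "molecule", i), cum = cum)
  }
  truth <- data.frame(
    molecule = seq_len(spec$n_molecules),
    pathway = vapply(out, function(m) m$truth$pathway, character(1)),
    ejected_fraction = draws$frac,
    length_um = vapply(out, function(m) m$truth$length_um, numeric(1)),
    n_pixels = vapply(out, function(m) m$truth$n_pixels, numeric(1))
  )
  structure(list(profiles = lapply(out, `[[`, "profile"), truth = truth,
                 genome = genome, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$truth), "molecules, true P_FIFO =",
      x$spec$true_p_fifo, "| SNR =", x$spec$snr, "\n")
  invisible(x)
}

#' Call every molecule in a cohort
#'
#' Runs [call_direction()] on each profile against the cohort's genome, using
#' the cohort's own barcode-model parameters.  Candidate barcodes are cached
#' by pixel count, since the estimated ejected fraction is a function of the
#' measured pixel count alone.
#'
#' @param cohort a `synthetic_cohort`, or a list of `intensity_profile`s.
#' @param genome reference genome (taken from the cohort when omitted).
#' @param ... further arguments passed to [call_direction()].
#' @return list of `orientation_call` objects.
#' @export
call_cohort <- function(cohort, genome = NULL, ...) {
  if (inherits(cohort, "synthetic_cohort")) {
    profiles <- cohort$profiles
    if (is.null(genome)) genome <- cohort$genome
    spec <- cohort$spec
    args <- list(stretch_factor = spec$stretch_factor,
                 window_bp = spec$window_bp, baseline_at = spec$baseline_at,
                 blur_um = spec$blur_um,
                 # call only molecules long enough that both candidate
                 # barcodes span the composition boundary (pathway-neutral cut)
                 min_callable_fraction = 1 - spec$boundary_fraction + 0.05)
  } else {
    profiles <- cohort
    args <- list()
  }
  stopifnot(!is.null(genome))
  dots <- list(...)
  args[names(dots)] <- dots
  if (is.null(args$cache)) args$cache <- new.env(parent = emptyenv())
  lapply(profiles, function(p) {
    do.call(call_direction, c(list(profile = p, genome = genome), args))
  })
}
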