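# run code with a private RNG stream so generators never touch global state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic paired labeled/un-labeled experiment
#'
#' Describes what the generator plants: a set of metabolite ions with known
#' un-labeled m/z, retention time and intensity; the label mass shift; the
#' chromatographic deuterium effect (the labeled ion elutes earlier by a
#' uniform draw within `rt_shift_range`); a multiplicative intensity drift;
#' matrix ions shared identically by both runs; per-run independent noise
#' ions; and a Gaussian m/z error emulating instrument resolution.
#'
#' Defaults emulate the published study conditions: a d4 label
#' (shift 4.0251 amu), retention-time shift within 0.1 min (labeled always
#' earlier), intensity drift within +/- 50 percent, a 20-min gradient with
#' analytes eluting between 1 and 15 min, scan range m/z 100-1000, and a
#' dominant shared matrix base peak.
#'
#' @param metabolites data.frame with columns `mz`, `rt`, `intensity`
#'   (un-labeled ion). Default: eight metabolite ions spread over the run.
#' @param label_shift Label mass shift in amu (> 0); default 4.025107
#'   (4 x (D - H)).
#' @param rt_shift_range Two-element range (minutes) of the one-sided
#'   earlier elution of the labeled ion; default c(0, 0.1).
#' @param drift_range Two-element multiplicative intensity-drift range;
#'   default c(0.5, 1.5) (+/- 50 percent).
#' @param n_matrix_ions Shared, un-shifted background ions present
#'   identically in both runs (default 50).
#' @param n_noise_ions Independent per-run noise ions (default 30).
#' @param mz_sigma Gaussian m/z error in amu applied per planted metabolite
#'   feature (resolution proxy); default 0 (high resolution).
#' @param mz_range,rt_range Sampling ranges for background ions.
#' @param matrix_base_intensity Intensity of the strongest shared matrix
#'   ion (the run base peak); default 1e6.
#' @param one_sided_rt If `FALSE`, the labeled rt shift is drawn
#'   symmetrically (stress-test option).
#' @param polarity Run polarity.
#' @param seed Integer seed; all randomness flows through it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(metabolites = NULL,
                           label_shift = 4 * (2.01410177785 - 1.00782503207),
                           rt_shift_range = c(0, 0.1),
                           drift_range = c(0.5, 1.5),
                           n_matrix_ions = 50L, n_noise_ions = 30L,
                           mz_sigma = 0,
                           mz_range = c(100, 1000), rt_range = c(1, 15),
                           matrix_base_intensity = 1e6,
                           one_sided_rt = TRUE,
                           polarity = c("positive", "negative"),
                           seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(metabolites)) {
    metabolites <- data.frame(
      mz = c(315.1701, 389.1157, 373.1211, 272.1273, 373.1212, 373.1211,
             332.1308, 355.1103),
      rt = c(6.78, 7.46, 8.09, 8.64, 9.89, 10.79, 11.66, 12.40),
      intensity = c(1.7e4, 1.1e5, 1.5e5, 2.0e4, 1.2e5, 5.1e4, 1.4e4,
                    6.3e4))
  }
  if (nrow(metabolites) > 0L) {
    stopifnot(all(c("mz", "rt", "intensity") %in% names(metabolites)))
  }
  if (label_shift <= 0) stop("label_shift must be > 0", call. = FALSE)
  if (mz_sigma < 0) stop("mz_sigma must be >= 0", call. = FALSE)
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop(nm, " must be an ordered two-element range", call. = FALSE)
  }
  chk_range(rt_shift_range, "rt_shift_range")
  chk_range(drift_range, "drift_range")
  chk_range(mz_range, "mz_range"); chk_range(rt_range, "rt_range")
  if (n_matrix_ions < 0 || n_noise_ions < 0)
    stop("ion counts must be >= 0", call. = FALSE)
  structure(list(metabolites = metabolites, label_shift = label_shift,
                 rt_shift_range = rt_shift_range, drift_range = drift_range,
                 n_matrix_ions = as.integer(n_matrix_ions),
                 n_noise_ions = as.integer(n_noise_ions),
                 mz_sigma = mz_sigma, mz_range = mz_range,
                 rt_range = rt_range,
                 matrix_base_intensity = matrix_base_intensity,
                 one_sided_rt = isTRUE(one_sided_rt), polarity = polarity,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# log-uniform intensities between lo and hi
.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a paired labeled/un-labeled run with known ground truth
#'
#' For each planted metabolite the un-labeled run receives a feature at
#' (rt, mz + e, I) and the labeled run a feature at
#' (rt - U(rt_shift_range), mz + label_shift + e', I * U(drift_range)),
#' where e, e' are independent N(0, mz_sigma) draws. Matrix ions are
#' duplicated exactly across runs (shared background, zero mass shift);
#' noise ions are drawn independently per run. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `unlabeled` and `labeled` (`feature_map`s) and
#'   `truth`, a data.frame with one row per planted metabolite
#'   (`id_unlabeled`, `id_labeled`, true deltas).
#' @export
generate_paired_runs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    met <- spec$metabolites
    nmet <- nrow(met)
    rt_shift <- if (nmet) stats::runif(nmet, spec$rt_shift_range[1],
                                       spec$rt_shift_range[2]) else numeric(0)
    if (!spec$one_sided_rt && nmet)
      rt_shift <- rt_shift * sample(c(-1, 1), nmet, replace = TRUE)
    drift <- if (nmet) stats::runif(nmet, spec$drift_range[1],
                                    spec$drift_range[2]) else numeric(0)
    mz_err_u <- if (nmet) stats::rnorm(nmet, 0, spec$mz_sigma) else numeric(0)
    mz_err_l <- if (nmet) stats::rnorm(nmet, 0, spec$mz_sigma) else numeric(0)

    u_met <- data.frame(
      id = sprintf("u_met%03d", seq_len(nmet)),
      rt = met$rt, mz = met$mz + mz_err_u, intensity = met$intensity,
      stringsAsFactors = FALSE)
    l_met <- data.frame(
      id = sprintf("l_met%03d", seq_len(nmet)),
      rt = met$rt - rt_shift,
      mz = met$mz + spec$label_shift + mz_err_l,
      intensity = met$intensity * drift,
      stringsAsFactors = FALSE)
    if (nmet == 0L) u_met <- l_met <- NULL

    nmat <- spec$n_matrix_ions
    if (nmat > 0L) {
      mat <- data.frame(
        id = sprintf("matrix%03d", seq_len(nmat)),
        rt = stats::runif(nmat, spec$rt_range[1], spec$rt_range[2]),
        mz = stats::runif(nmat, spec$mz_range[1], spec$mz_range[2]),
        intensity = .runif_log(nmat, 1e3, spec$matrix_base_intensity / 2),
        stringsAsFactors = FALSE)
      mat$intensity[1L] <- spec$matrix_base_intensity  # shared base peak
    } else mat <- NULL

    noise <- function(tag) {
      nn <- spec$n_noise_ions
      if (nn == 0L) return(NULL)
      data.frame(
        id = sprintf("%s_noise%03d", tag, seq_len(nn)),
        rt = stats::runif(nn, spec$rt_range[1], spec$rt_range[2]),
        mz = stats::runif(nn, spec$mz_range[1], spec$mz_range[2]),
        intensity = .runif_log(nn, 1e3, 1e6),
        stringsAsFactors = FALSE)
    }
    u_noise <- noise("u")
    l_noise <- noise("l")

    udf <- do.call(rbind, Filter(Negate(is.null),
                                 list(u_met, mat, u_noise)))
    ldf <- do.call(rbind, Filter(Negate(is.null),
                                 list(l_met, mat, l_noise)))
    unlabeled <- feature_map(udf, run_id = "sim_unlabeled",
                             polarity = spec$polarity,
                             label_status = "unlabeled")
    labeled <- feature_map(ldf, run_id = "sim_labeled",
                           polarity = spec$polarity,
                           label_status = "labeled")
    truth <- data.frame(
      id_unlabeled = if (nmet) u_met$id else character(0),
      id_labeled = if (nmet) l_met$id else character(0),
      mz_unlabeled = if (nmet) u_met$mz else numeric(0),
      rt_unlabeled = if (nmet) u_met$rt else numeric(0),
      delta_rt = if (nmet) -rt_shift else numeric(0),
      delta_mz = if (nmet) l_met$mz - u_met$mz else numeric(0),
      drift = if (nmet) drift else numeric(0),
      stringsAsFactors = FALSE)
    list(unlabeled = unlabeled, labeled = labeled, truth = truth)
  })
}

#' Generate centroided scan lists for a paired experiment
#'
#' Expands each feature of [generate_paired_runs()] into a Gaussian elution
#' profile sampled at regular scan times; each scan's centroid m/z is
#' jittered independently by `spec$mz_sigma`. Exercises feature detection
#' end to end.
#'
#' @param spec A [synthetic_spec()].
#' @param gradient_length Run length in minutes; default 20.
#' @param scan_interval Scan spacing in minutes (> 0); default 0.02.
#' @param peak_width_sigma Gaussian elution peak sigma in minutes;
#'   default 0.05.
#' @param min_signal Centroids below this intensity are not written;
#'   default 1.
#' @return List with `unlabeled` and `labeled` scan lists (of
#'   `centroid_scan`) and the same `truth` table as
#'   [generate_paired_runs()].
#' @export
generate_scans <- function(spec, gradient_length = 20, scan_interval = 0.02,
                           peak_width_sigma = 0.05, min_signal = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (scan_interval <= 0) stop("scan_interval must be > 0", call. = FALSE)
  runs <- generate_paired_runs(spec)
  times <- seq(0, gradient_length, by = scan_interval)
  profile <- function(map, seed_offset) {
    f <- map$features
    .with_seed(spec$seed + seed_offset, {
      lapply(times, function(t) {
        h <- f$intensity * exp(-(t - f$rt)^2 / (2 * peak_width_sigma^2))
        keep <- which(h >= min_signal)
        if (length(keep) == 0L) return(centroid_scan(t))
        mz <- f$mz[keep]
        if (spec$mz_sigma > 0)
          mz <- mz + stats::rnorm(length(keep), 0, spec$mz_sigma)
        centroid_scan(t, mz, h[keep])
      })
    })
  }
  list(unlabeled = profile(runs$unlabeled, 1L),
       labeled = profile(runs$labeled, 2L),
       truth = runs$truth)
}
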