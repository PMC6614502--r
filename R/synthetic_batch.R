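#' Configuration for the synthetic batch generator
#'
#' Describes a single UPLC-MS batch that interleaves extraction blanks with
#' replicate sample injections: a leading block of conditioning QCs, then
#' repeated "intense" deconditioning cycles (3 consecutive blanks + 8
#' samples) and "mild" cycles (1 blank + 8 samples). Feature classes are
#' planted so every downstream stage has ground truth:
#'
#' * `informative_stable` — biological features with no response to blanks;
#' * `informative_cluster1` — features with a small, immediate post-blank
#'   deviation that decays back to baseline within a few injections;
#' * `informative_cluster2` — late-eluting lipophilic-like features whose
#'   intensity rises gradually after a blank, peaks at `p_max` injections
#'   post blank, and returns to baseline by the `k`-th conditioning sample;
#' * `contaminant` — background signals (plasticizers, solvent impurities)
#'   present in blanks at sample-comparable intensity;
#' * `carryover1/2/3` — column carry-over eluting over the first 1, 2 or 3
#'   blanks and missing from the first 1, 2 or 3 post-blank samples.
#'
#' Defaults mirror a desk-scale version of the plasma-style study design:
#' 10 leading QCs, 8 intense and 8 mild cycles (170 injections), 5% analytical
#' noise, 10% smooth within-batch drift, a cluster-2 response peaking 3
#' injections after the blank and recovering by the 7th conditioning sample,
#' and a post-blank retention-time shift of 0.04 min for cluster-2 features.
#'
#' @param n_features named integer vector with entries `informative_stable`,
#'   `informative_cluster1`, `informative_cluster2`, `contaminant`,
#'   `carryover1`, `carryover2`, `carryover3`.
#' @param n_cycles_intense,n_cycles_mild number of 3-blank and 1-blank
#'   cycles.
#' @param n_leading_qc length of the leading QC block.
#' @param drift_amplitude peak relative amplitude of the smooth multiplicative
#'   within-batch drift (fraction of baseline, in `[0, 1)`).
#' @param noise_rsd relative standard deviation of the multiplicative
#'   log-normal measurement noise (fraction).
#' @param decondition per-cluster response parameters: a list with elements
#'   `cluster1` and `cluster2`, each `list(p_max, k, max_dev)` where `p_max`
#'   is the position (1..8) of the maximal deviation, `k` the recovery
#'   position (factor is 1 from `k` on) and `max_dev` the maximal relative
#'   deviation.
#' @param mild_attenuation factor applied to the deviation in mild (1-blank)
#'   cycles; 1-blank deconditioning is weaker than 3-blank deconditioning.
#' @param rt_shift_minutes post-blank retention-time perturbation of
#'   cluster-2 features (min), decaying linearly to 0 at position `k`.
#' @param width_shift_minutes analogous peak-width perturbation (min).
#' @param contaminant_blank_level blank intensity of contaminants as a
#'   fraction of their sample intensity.
#' @param carryover_blank_level blank intensity of carry-over features as a
#'   fraction of their sample intensity.
#' @param rt_range chromatographic run span (min) over which feature RTs are
#'   drawn; cluster-2 and carry-over features are planted late
#'   (`rt_late_split` onward), mirroring the lipophilic tail of the gradient.
#' @param rt_late_split RT (min) separating early from late-eluting features.
#' @param seed integer seed; every draw flows from it deterministically.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    n_features = c(informative_stable = 10, informative_cluster1 = 45,
                   informative_cluster2 = 40, contaminant = 60,
                   carryover1 = 4, carryover2 = 3, carryover3 = 11),
    n_cycles_intense = 8, n_cycles_mild = 8, n_leading_qc = 10,
    drift_amplitude = 0.10, noise_rsd = 0.05,
    decondition = list(cluster1 = list(p_max = 1, k = 5, max_dev = 0.15),
                       cluster2 = list(p_max = 3, k = 7, max_dev = 0.5)),
    mild_attenuation = 0.5,
    rt_shift_minutes = 0.04, width_shift_minutes = 0.02,
    contaminant_blank_level = 1.0, carryover_blank_level = 0.5,
    rt_range = c(0.5, 7.0), rt_late_split = 4.5,
    seed = 1L) {
  need <- c("informative_stable", "informative_cluster1",
            "informative_cluster2", "contaminant", "carryover1", "carryover2",
            "carryover3")
  stopifnot(all(need %in% names(n_features)), all(n_features >= 0),
            drift_amplitude >= 0, drift_amplitude < 1, noise_rsd >= 0,
            n_leading_qc >= 0, n_cycles_intense >= 0, n_cycles_mild >= 0)
  for (cl in c("cluster1", "cluster2")) {
    p <- decondition[[cl]]
    stopifnot(p$p_max >= 1, p$p_max <= 8, p$k >= p$p_max, p$k <= 8,
              p$max_dev >= 0)
  }
  structure(list(
    n_features = n_features[need], n_cycles_intense = n_cycles_intense,
    n_cycles_mild = n_cycles_mild, n_leading_qc = n_leading_qc,
    drift_amplitude = drift_amplitude, noise_rsd = noise_rsd,
    decondition = decondition, mild_attenuation = mild_attenuation,
    rt_shift_minutes = rt_shift_minutes,
    width_shift_minutes = width_shift_minutes,
    contaminant_blank_level = contaminant_blank_level,
    carryover_blank_level = carryover_blank_level,
    rt_range = rt_range, rt_late_split = rt_late_split,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Multiplicative deconditioning response at a conditioning position
#'
#' Piecewise-linear response of a feature's intensity to the preceding blank
#' injection, as a function of the position 1..8 of the sample after the
#' blank. Cluster 1: an immediate relative deviation `max_dev` at position 1
#' decaying linearly to 1 at the recovery position `k`. Cluster 2: a linear
#' rise from baseline to `1 + max_dev` at `p_max`, then a linear decay to 1
#' at `k`; 1 for all positions at or beyond `k`.
#'
#' @param position integer (vector) in 1..8, position after the blank group.
#' @param cluster 1 or 2.
#' @param params `list(p_max, k, max_dev)`; `p_max` is ignored for cluster 1.
#' @return multiplicative factor(s) > 0; exactly 1 for `position >= k`.
#' @export
decondition_response <- function(position, cluster, params) {
  stopifnot(all(position >= 1), all(position <= 8), cluster %in% c(1, 2))
  p_max <- params$p_max
  k <- params$k
  dev <- params$max_dev
  f <- function(p) {
    if (p >= k) return(1)
    if (cluster == 1) {
      # immediate deviation at position 1 decaying to 1 at k
      return(1 + dev * (k - p) / (k - 1))
    }
    if (p <= p_max) return(1 + dev * p / p_max)
    1 + dev * (k - p) / (k - p_max)
  }
  vapply(position, f, numeric(1))
}

# smooth random multiplicative drift over run order: spline through a few
# uniform control points, rescaled to peak amplitude `amp`
.drift_curve <- function(n, amp, n_knots = 5) {
  if (amp == 0 || n < 2) return(rep(1, n))
  kx <- seq(1, n, length.out = n_knots)
  ky <- stats::runif(n_knots, -1, 1)
  s <- stats::spline(kx, ky, xout = seq_len(n))$y
  m <- max(abs(s))
  if (m == 0) return(rep(1, n))
  1 + amp * s / m
}

# mean-one multiplicative log-normal noise at a given RSD
.noise <- function(n, rsd) {
  if (rsd == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

#' Generate a synthetic batch with planted ground truth
#'
#' Builds a full `peak_table` following the cyclic blank/sample design in
#' `config`, plus the planted truth needed to score every downstream stage.
#' Construction, per feature: a baseline area drawn log-uniformly over four
#' decades; a smooth multiplicative within-batch drift; mean-one
#' multiplicative log-normal noise; for deconditioned (cluster 1/2) features
#' a position-dependent multiplicative response after each blank group
#' ([decondition_response()], attenuated in mild cycles); retention-time and
#' peak-width columns perturbed post blank for cluster-2 features with the
#' same linear recovery. Informative features have zero area and
#' `detected = FALSE` in blanks (the extraction blank carries no sample
#' matrix), so the blank-ratio clean-up condition holds by construction.
#' Contaminants are detected everywhere at sample-comparable blank intensity.
#' Carry-over `+k` features are detected in blanks `1..k` and samples
#' `(k+1)..8` of every cycle and absent elsewhere in the cycle.
#'
#' @param config a [simulation_config()].
#' @return `list(table = peak_table, truth = list(...))`. `truth` has
#'   `classes` (data.frame: feature_id, class, cluster, recovery_position)
#'   and `drift` (features x injections multiplicative trend matrix).
#' @export
generate_batch <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  nf <- config$n_features
  n_feat <- sum(nf)
  n_inform <- sum(nf[c("informative_stable", "informative_cluster1",
                       "informative_cluster2")])
  n_cycles <- config$n_cycles_intense + config$n_cycles_mild
  if (n_inform == 0 && n_cycles > 0) {
    stop("at least one informative feature is required when cycles are ",
         "requested: downstream conditioning statistics are undefined")
  }
  # injection sequence: leading QCs, intense cycles, mild cycles
  classes <- c(rep("QC", config$n_leading_qc),
               rep(c(rep("blank", 3), rep("sample", 8)),
                   config$n_cycles_intense),
               rep(c("blank", rep("sample", 8)), config$n_cycles_mild))
  inj <- annotate_sequence(classes)
  n_inj <- nrow(inj)
  is_blank <- inj$sample_class == "blank"
  is_sample <- inj$sample_class == "sample"
  pos <- inj$position_after_blank
  gs <- inj$blank_group_size

  cls_lab <- c(informative_stable = "informative",
               informative_cluster1 = "informative",
               informative_cluster2 = "informative",
               contaminant = "contaminant", carryover1 = "carryover+1",
               carryover2 = "carryover+2", carryover3 = "carryover+3")
  kind <- rep(names(nf), nf)  # generator class per feature
  label <- unname(cls_lab[kind])
  cluster <- ifelse(kind == "informative_cluster1", 1L,
                    ifelse(kind == "informative_cluster2", 2L, NA_integer_))

  set.seed(config$seed)
  # per-feature sub-seeds so each feature's draws are self-contained
  sub_seed <- sample.int(.Machine$integer.max - 1L, n_feat)

  area <- matrix(0, n_feat, n_inj)
  rt <- matrix(0, n_feat, n_inj)
  width <- matrix(0, n_feat, n_inj)
  detected <- matrix(FALSE, n_feat, n_inj)
  drift_m <- matrix(1, n_feat, n_inj)
  mz <- numeric(n_feat)
  rt_med <- numeric(n_feat)
  recovery <- rep(NA_integer_, n_feat)

  late <- kind %in% c("informative_cluster2", "carryover1", "carryover2",
                      "carryover3")
  for (f in seq_len(n_feat)) {
    set.seed(sub_seed[f])
    baseline <- 10^stats::runif(1, 3, 7)
    mz[f] <- stats::runif(1, 100, 1100)
    rt_med[f] <- if (late[f]) {
      stats::runif(1, config$rt_late_split, config$rt_range[2])
    } else {
      stats::runif(1, config$rt_range[1], config$rt_late_split)
    }
    w0 <- stats::runif(1, 0.08, 0.2)
    drift <- .drift_curve(n_inj, config$drift_amplitude)
    drift_m[f, ] <- drift
    noise <- .noise(n_inj, config$noise_rsd)
    rt_noise <- stats::rnorm(n_inj, 0, 0.002)
    w_noise <- stats::rnorm(n_inj, 0, 0.002)

    # deconditioning factor per injection (samples in cycles only)
    dfac <- rep(1, n_inj)
    shift_frac <- rep(0, n_inj)  # 1 at position 1, 0 from recovery on
    if (!is.na(cluster[f])) {
      par <- config$decondition[[paste0("cluster", cluster[f])]]
      recovery[f] <- as.integer(par$k)
      at_pos <- is_sample & !is.na(pos)
      fac <- decondition_response(pos[at_pos], cluster[f], par)
      att <- ifelse(gs[at_pos] == 1, config$mild_attenuation, 1)
      dfac[at_pos] <- 1 + att * (fac - 1)
      sf <- pmax(0, (par$k - pos[at_pos]) / (par$k - 1))
      shift_frac[at_pos] <- att * sf
    }

    samp_like <- is_sample | inj$sample_class == "QC"
    base_area <- baseline * drift * dfac * noise
    rt[f, ] <- rt_med[f] + rt_noise
    width[f, ] <- pmax(0, w0 + w_noise)
    if (cluster[f] %in% 2L && !all(shift_frac == 0)) {
      rt[f, ] <- rt[f, ] + config$rt_shift_minutes * shift_frac
      width[f, ] <- width[f, ] + config$width_shift_minutes * shift_frac
    }

    if (label[f] == "informative") {
      area[f, samp_like] <- base_area[samp_like]
      detected[f, samp_like] <- TRUE
      # extraction blanks carry no sample matrix: area 0, not detected
      area[f, is_blank] <- 0
      rt[f, is_blank] <- rt_med[f]
      width[f, is_blank] <- w0
    } else if (label[f] == "contaminant") {
      area[f, samp_like] <- base_area[samp_like]
      area[f, is_blank] <- config$contaminant_blank_level * baseline *
        drift[is_blank] * noise[is_blank]
      detected[f, ] <- TRUE
    } else {  # carry-over +k
      kk <- as.integer(sub("carryover", "", kind[f]))
      in_cycle <- inj$cycle_id > 0L
      det_blank <- is_blank & !is.na(pos) & pos <= kk
      det_samp <- is_sample & in_cycle & !is.na(pos) & pos > kk
      det_qc <- inj$sample_class == "QC"
      detected[f, det_blank | det_samp | det_qc] <- TRUE
      area[f, det_samp | det_qc] <- base_area[det_samp | det_qc]
      # carry-over elutes progressively weaker over consecutive blanks
      bsel <- which(det_blank)
      area[f, bsel] <- config$carryover_blank_level * baseline *
        0.6^(pos[bsel] - 1) * noise[bsel]
      rt[f, !detected[f, ]] <- rt_med[f]
      width[f, !detected[f, ]] <- w0
      area[f, !detected[f, ] & !samp_like] <- 0
      area[f, !detected[f, ] & samp_like] <- 0
    }
  }

  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(n_feat)),
    mz = round(mz, 4), rt_median = round(rt_med, 3),
    stringsAsFactors = FALSE)
  pt <- peak_table(features, inj, area, rt, width, detected = detected)
  truth <- list(
    classes = data.frame(feature_id = features$feature_id,
                         class = label,
                         generator_class = kind,
                         cluster = cluster,
                         recovery_position = recovery,
                         stringsAsFactors = FALSE),
    drift = `dimnames<-`(drift_m, dimnames(pt$area)))
  list(table = pt, truth = truth)
}
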