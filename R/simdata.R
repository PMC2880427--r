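#' Simulation configuration for batched microarray data
#'
#' Describes a synthetic whole-blood microarray study: arrays are
#' processed in batches, each batch holding an equal number of case and
#' healthy-control study samples plus a fixed number of technical
#' controls (aliquots of one reference RNA hybridised in every batch).
#' A subset of probes carries a planted case-vs-control shift; per-probe
#' per-batch additive shifts emulate batch effects; a fraction of
#' measurements is generated low-quality (sub-threshold signal-to-noise
#' or a high scanner flag) to exercise the masking rules.
#'
#' Defaults mirror the batched study design this package targets:
#' 13 batches of 10 study samples plus 2 technical controls (156 arrays,
#' 130 study samples), and 3 subjects contributing two biological
#' replicate arrays each, so that replicate averaging leaves 127
#' independent subjects.
#'
#' @param n_batches number of processing batches.
#' @param samples_per_batch study samples per batch (must be even, so
#'   cases and controls balance within each batch).
#' @param controls_per_batch technical-control arrays per batch.
#' @param n_probes number of probes on the array.
#' @param n_signal_probes number of probes carrying a planted class
#'   effect.
#' @param effect_size standardized case-minus-control shift on signal
#'   probes, in units of the within-group sd (log2 scale).
#' @param batch_sd sd of the zero-mean per-probe per-batch additive
#'   shift (log2 units).
#' @param noise_sd within-group sd of a single measurement (log2 units);
#'   split evenly between a between-subject and a technical component.
#' @param baseline_mean,baseline_sd parameters of the normal baseline
#'   probe mean distribution on the log2 scale.
#' @param missing_snr_threshold SNR below which a measurement counts as
#'   low-quality.
#' @param p_low_snr probability that a measurement is generated with
#'   sub-threshold SNR.
#' @param p_high_flag probability that a measurement is generated with a
#'   flag value of 9000 (above the 8191 masking threshold).
#' @param n_replicate_subjects number of subjects measured on two arrays.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#'
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_batches = 13, samples_per_batch = 10,
                       controls_per_batch = 2, n_probes = 1000,
                       n_signal_probes = 50, effect_size = 0.5,
                       batch_sd = 0.5, noise_sd = 1,
                       baseline_mean = 8, baseline_sd = 1.5,
                       missing_snr_threshold = 3, p_low_snr = 0.02,
                       p_high_flag = 0.005,
                       n_replicate_subjects = 3, seed = 1L) {
  cfg <- list(n_batches = n_batches, samples_per_batch = samples_per_batch,
              controls_per_batch = controls_per_batch, n_probes = n_probes,
              n_signal_probes = n_signal_probes, effect_size = effect_size,
              batch_sd = batch_sd, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              missing_snr_threshold = missing_snr_threshold,
              p_low_snr = p_low_snr, p_high_flag = p_high_flag,
              n_replicate_subjects = n_replicate_subjects,
              seed = as.integer(seed))
  counts <- c("n_batches", "samples_per_batch", "controls_per_batch",
              "n_probes", "n_signal_probes", "n_replicate_subjects")
  for (nm in counts)
    if (cfg[[nm]] < 0) stop(nm, " must be nonnegative")
  if (cfg$n_signal_probes > cfg$n_probes)
    stop("n_signal_probes must not exceed n_probes")
  for (nm in c("effect_size", "batch_sd", "noise_sd", "p_low_snr",
               "p_high_flag"))
    if (cfg[[nm]] < 0) stop(nm, " must be nonnegative")
  if (cfg$samples_per_batch %% 2 != 0)
    stop("unbalanced batch: samples_per_batch must be even so each ",
         "batch holds equal numbers of cases and controls")
  n_study <- cfg$n_batches * cfg$samples_per_batch
  if (cfg$n_replicate_subjects > n_study %/% 2)
    stop("too many replicate subjects for the number of study arrays")
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a synthetic batched microarray dataset
#'
#' Simulates log2 intensities under an additive model
#' \deqn{x_{ps} = \mu_p + \delta_p c_s + u_{ps} + b_{p,B(s)} + e_{psa}}
#' with probe baselines \eqn{\mu_p \sim N(baseline\_mean, baseline\_sd)},
#' planted signed effects \eqn{\delta_p = \pm effect\_size \cdot noise\_sd}
#' on the signal probes (\eqn{c_s} = 1 for cases, 0 otherwise),
#' between-subject and technical noise components \eqn{u, e} each with
#' variance \eqn{noise\_sd^2 / 2}, and zero-mean batch shifts
#' \eqn{b \sim N(0, batch\_sd)} shared by every array of a batch.
#' Technical controls are noisy copies of a single fixed reference
#' profile (the probe baselines) plus the batch shift. Cases and healthy
#' controls are balanced within every batch; replicate subjects
#' contribute two arrays (same subject term, fresh technical noise),
#' possibly in different batches.
#'
#' Quality grids: entries are low-quality (SNR below
#' `missing_snr_threshold`) with probability `p_low_snr`, and carry flag
#' 9000 with probability `p_high_flag` (flag 0 otherwise). Low-quality
#' entries keep a numeric value; masking is the preprocessor's job.
#'
#' @param config a [sim_config()].
#' @return List with elements `em` (`ExpressionMatrix`), `annot`
#'   (annotation data.frame) and `truth` (list with `signal_probe_ids`
#'   and named `signed_effects`, the planted case-minus-control shifts).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  p <- config$n_probes
  nb <- config$n_batches
  spb <- config$samples_per_batch
  cpb <- config$controls_per_batch
  n_study <- nb * spb
  n_arrays <- nb * (spb + cpb)

  probe_ids <- sprintf("P%05d", seq_len(p))
  baseline <- config$baseline_mean + config$baseline_sd * stats::rnorm(p)

  sig_idx <- if (config$n_signal_probes > 0)
    sort(sample.int(p, config$n_signal_probes)) else integer(0)
  signs <- if (length(sig_idx))
    sample(c(-1, 1), length(sig_idx), replace = TRUE) else numeric(0)
  delta <- numeric(p)
  delta[sig_idx] <- signs * config$effect_size * config$noise_sd

  # subjects: replicate subjects contribute two study arrays of one class
  n_case_arrays <- n_study %/% 2
  n_ctrl_arrays <- n_study - n_case_arrays
  r_case <- ceiling(config$n_replicate_subjects / 2)
  r_ctrl <- config$n_replicate_subjects - r_case
  if (2 * r_case > n_case_arrays || 2 * r_ctrl > n_ctrl_arrays)
    stop("replicate subjects exceed per-class array counts")
  n_case_subj <- n_case_arrays - r_case
  n_ctrl_subj <- n_ctrl_arrays - r_ctrl
  subj_class <- c(rep("case", n_case_subj), rep("control_healthy", n_ctrl_subj))
  subj_ids <- sprintf("S%04d", seq_along(subj_class))
  rep_subj <- c(subj_ids[seq_len(r_case)],
                subj_ids[n_case_subj + seq_len(r_ctrl)])

  # one array per subject plus a second for replicate subjects
  arr_subj <- c(subj_ids, rep_subj)
  arr_class <- subj_class[match(arr_subj, subj_ids)]
  # assign study arrays to batch slots, balancing classes within batches
  case_arr <- sample(which(arr_class == "case"))
  ctrl_arr <- sample(which(arr_class == "control_healthy"))
  slot_subj <- integer(n_study)
  half <- spb %/% 2
  for (b in seq_len(nb)) {
    s0 <- (b - 1) * spb
    slot_subj[s0 + seq_len(half)] <- case_arr[(b - 1) * half + seq_len(half)]
    slot_subj[s0 + half + seq_len(half)] <- ctrl_arr[(b - 1) * half + seq_len(half)]
  }

  # subject effects: planted shift + between-subject deviation
  subj_sd <- config$noise_sd / sqrt(2)
  tech_sd <- config$noise_sd / sqrt(2)
  subj_dev <- subj_sd * matrix(stats::rnorm(p * length(subj_ids)), nrow = p)
  batch_shift <- config$batch_sd * matrix(stats::rnorm(p * nb), nrow = p)
  if (nb > 1)  # exactly zero-mean across batches: shifts redistribute, never
    batch_shift <- batch_shift - rowMeans(batch_shift)  # move a probe's level


  values <- matrix(NA_real_, p, n_arrays)
  array_ids <- character(n_arrays)
  annot <- data.frame(array_id = character(n_arrays),
                      subject_id = character(n_arrays),
                      batch_id = character(n_arrays),
                      class_label = character(n_arrays),
                      replicate_group = NA_character_,
                      stringsAsFactors = FALSE)
  k <- 0L
  for (b in seq_len(nb)) {
    bid <- sprintf("B%02d", b)
    for (j in seq_len(spb)) {
      k <- k + 1L
      ai <- slot_subj[(b - 1) * spb + j]
      sid <- arr_subj[ai]
      si <- match(sid, subj_ids)
      mu <- baseline + subj_dev[, si] +
        if (arr_class[ai] == "case") delta else 0
      values[, k] <- mu + batch_shift[, b] + tech_sd * stats::rnorm(p)
      array_ids[k] <- sprintf("%s_S%02d", bid, j)
      annot[k, c("array_id", "subject_id", "batch_id", "class_label")] <-
        c(array_ids[k], sid, bid, arr_class[ai])
      if (sid %in% rep_subj) annot$replicate_group[k] <- sid
    }
    for (j in seq_len(cpb)) {
      k <- k + 1L
      values[, k] <- baseline + batch_shift[, b] + tech_sd * stats::rnorm(p)
      array_ids[k] <- sprintf("%s_TC%d", bid, j)
      annot[k, c("array_id", "subject_id", "batch_id", "class_label")] <-
        c(array_ids[k], "REF", bid, "technical_control")
    }
  }
  rownames(values) <- probe_ids
  colnames(values) <- array_ids

  low <- matrix(stats::runif(p * n_arrays) < config$p_low_snr, p, n_arrays)
  snr <- matrix(stats::runif(p * n_arrays, config$missing_snr_threshold, 40),
                p, n_arrays)
  snr[low] <- stats::runif(sum(low), 0, config$missing_snr_threshold * 0.999)
  flag <- matrix(0, p, n_arrays)
  flag[stats::runif(p * n_arrays) < config$p_high_flag] <- 9000

  em <- expression_matrix(values, snr = snr, flag = flag)
  truth <- list(signal_probe_ids = probe_ids[sig_idx],
                signed_effects = stats::setNames(delta[sig_idx],
                                                 probe_ids[sig_idx]))
  list(em = em, annot = validate_annotation(annot, em), truth = truth)
}
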