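#' Cohort design for the chronic kidney disease study structure
#'
#' Describes the multigroup, multiblock design the generator emulates:
#' five cohorts — 56 healthy controls (CTRL), 69 intermediate-stage CKD
#' patients (ICKD), 35 hemodialysis patients (HD, sampled pre/post
#' session), 42 kidney-graft recipients (KG, sampled before and 1 week /
#' 1 month after) and 24 living kidney donors (DV, before and 1 week /
#' 1 year after donation) — giving 10 observation sets (row classes) and
#' 393 profiles, each measured on four LC-MS variable blocks (RPLC+ 88,
#' RPLC- 38, aHILIC+ 27, ZICpHILIC- 65; 218 variables in total), hence 40
#' data matrices.
#'
#' Two latent axes are planted. A dominant *severity* axis orders the row
#' classes by renal impairment (CTRL and preDV lowest; ICKD intermediate;
#' preHD and preKG highest; post-treatment classes pulled back toward
#' intermediate/healthy levels). A smaller *dialysis* axis shifts postHD
#' only, emulating a treatment-specific signature. Both act as rank-one
#' mean shifts shared across the four blocks, on configurable variable
#' supports, plus independent Gaussian noise.
#'
#' @param severity_levels named numeric vector of per-row-class severity
#'   means (defaults encode the ordering above).
#' @param secondary_levels named numeric vector of per-row-class levels of
#'   the dialysis axis (default: -1 for postHD, 0 elsewhere).
#' @param severity_frac fraction of each block's variables carrying the
#'   severity axis (default 0.5).
#' @param n_secondary_vars number of variables carrying the dialysis axis
#'   (default 30, drawn across blocks).
#' @param severity_sd within-row-class spread of individual severity
#'   values (default 0.25).
#' @param secondary_sd within-row-class spread of the dialysis covariate
#'   (default 0.1).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 1).
#' @param subject_sd standard deviation of an optional subject-level
#'   random effect shared across a subject's timepoints (default 0 =
#'   independent timepoints).
#' @return an object of class `"cohort_design"`.
#' @seealso [generate_cohort()]
#' @export
ckd_design <- function(severity_levels = c(
                         CTRL = 0, ICKD = 1, preHD = 2, postHD = 1.1,
                         preKG = 2, postKG1 = 0.9, postKG2 = 0.6,
                         preDV = 0, postDV1 = 0.15, postDV2 = 0.1),
                       secondary_levels = c(postHD = -1),
                       severity_frac = 0.5,
                       n_secondary_vars = 30L,
                       severity_sd = 0.25,
                       secondary_sd = 0.1,
                       noise_sd = 1,
                       subject_sd = 0) {
  row_classes <- data.frame(
    row_class = c("CTRL", "ICKD", "preHD", "postHD", "preKG", "postKG1",
                  "postKG2", "preDV", "postDV1", "postDV2"),
    group = c("CTRL", "ICKD", "HD", "HD", "KG", "KG", "KG",
              "DV", "DV", "DV"),
    n = c(56L, 69L, 35L, 35L, 42L, 42L, 42L, 24L, 24L, 24L),
    stringsAsFactors = FALSE)
  blocks <- c("RPLC+" = 88L, "RPLC-" = 38L, "aHILIC+" = 27L,
              "ZICpHILIC-" = 65L)
  sev <- stats::setNames(rep(0, nrow(row_classes)), row_classes$row_class)
  sev[names(severity_levels)] <- severity_levels
  sec <- stats::setNames(rep(0, nrow(row_classes)), row_classes$row_class)
  sec[names(secondary_levels)] <- secondary_levels
  if (any(row_classes$n < 1L)) stop("all cohort sizes must be >= 1")
  structure(list(row_classes = row_classes, blocks = blocks,
                 severity_levels = sev, secondary_levels = sec,
                 severity_frac = severity_frac,
                 n_secondary_vars = as.integer(n_secondary_vars),
                 severity_sd = severity_sd, secondary_sd = secondary_sd,
                 noise_sd = noise_sd, subject_sd = subject_sd),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d row classes x %d blocks = %d matrices; %d profiles, %d variables\n",
              nrow(x$row_classes), length(x$blocks),
              nrow(x$row_classes) * length(x$blocks),
              sum(x$row_classes$n), sum(x$blocks)))
  invisible(x)
}

#' Generate a synthetic multigroup/multiblock cohort
#'
#' Simulates the data network described by a [ckd_design()]: every matrix
#' is baseline + severity x severity-loadings + dialysis x
#' dialysis-loadings + independent Gaussian noise, fully reproducible from
#' the seed. The planted per-observation covariates and per-variable
#' supports are returned so that downstream recovery (score correlation,
#' block influence, marker selection, enrichment) can be checked against
#' ground truth.
#'
#' @param design a [ckd_design()] (or compatible `cohort_design`).
#' @param seed integer seed.
#' @return list with elements:
#' \describe{
#'   \item{network}{a [data_network()] of one matrix per (row class,
#'     block).}
#'   \item{truth}{list with `severity` and `secondary` (named lists, row
#'     class -> per-observation covariate), `severity_vars`,
#'     `secondary_vars` (variable ids of the planted supports),
#'     `severity_amplitude`, `secondary_amplitude` (named loading
#'     amplitudes).}
#' }
#' @export
generate_cohort <- function(design = ckd_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  blocks <- design$blocks
  n_var_total <- sum(blocks)
  var_ids <- sprintf("met%03d", seq_len(n_var_total))
  block_of <- rep(names(blocks), blocks)

  # planted variable supports and amplitudes
  n_sev <- round(design$severity_frac * n_var_total)
  severity_vars <- sort(sample(var_ids, n_sev))
  sev_amp <- stats::setNames(rep(0, n_var_total), var_ids)
  sev_amp[severity_vars] <- stats::runif(n_sev, 0.5, 1.5)
  n_sec <- min(design$n_secondary_vars, n_var_total)
  secondary_vars <- sort(sample(var_ids, n_sec))
  sec_amp <- stats::setNames(rep(0, n_var_total), var_ids)
  sec_amp[secondary_vars] <- stats::runif(n_sec, 0.8, 1.5)
  baseline <- stats::setNames(stats::rnorm(n_var_total, 10, 2), var_ids)

  rcs <- design$row_classes
  # per-observation covariates; subjects are shared across timepoints of a
  # group, so the optional subject effect is drawn once per subject
  subj_eff <- lapply(unique(rcs$group), function(grp) {
    n <- rcs$n[rcs$group == grp][1L]
    stats::rnorm(n, 0, design$subject_sd)
  })
  names(subj_eff) <- unique(rcs$group)

  severity <- list(); secondary <- list()
  for (i in seq_len(nrow(rcs))) {
    g <- rcs$row_class[i]; n <- rcs$n[i]
    severity[[g]] <- design$severity_levels[[g]] +
      stats::rnorm(n, 0, design$severity_sd)
    secondary[[g]] <- design$secondary_levels[[g]] +
      stats::rnorm(n, 0, design$secondary_sd)
  }

  mats <- list()
  for (i in seq_len(nrow(rcs))) {
    g <- rcs$row_class[i]; grp <- rcs$group[i]; n <- rcs$n[i]
    obs_ids <- sprintf("%s_%02d", g, seq_len(n))
    for (b in names(blocks)) {
      vid <- var_ids[block_of == b]
      X <- matrix(rep(baseline[vid], each = n), n, length(vid)) +
        outer(severity[[g]], sev_amp[vid]) +
        outer(secondary[[g]], sec_amp[vid]) +
        outer(subj_eff[[grp]], rep(1, length(vid))) +
        matrix(stats::rnorm(n * length(vid), 0, design$noise_sd),
               n, length(vid))
      dimnames(X) <- list(obs_ids, vid)
      mats[[paste(g, b, sep = ".")]] <- data_matrix(X, g, b)
    }
  }
  list(network = data_network(unname(mats)),
       truth = list(severity = severity, secondary = secondary,
                    severity_vars = severity_vars,
                    secondary_vars = secondary_vars,
                    severity_amplitude = sev_amp,
                    secondary_amplitude = sec_amp))
}

#' Generate a synthetic LC-MS feature run with planted drift
#'
#' Emulates one acquisition sequence for testing the QC machinery:
#' batches of injections where every sixth injection is a pooled QC
#' immediately followed by its dilution (dQC), a multiplicative linear
#' intensity drift across each batch, per-batch global scale factors, and
#' log-normal feature baselines with proportional measurement noise.
#'
#' @param n_features number of features.
#' @param n_batches number of batches.
#' @param samples_per_batch study samples per batch.
#' @param qc_every a QC (followed by a dQC) is injected after every this
#'   many study samples (default 6).
#' @param drift_fold multiplicative drift across a batch: intensities are
#'   scaled linearly from 1 at the first injection to `drift_fold` at the
#'   last (default 1 = no drift).
#' @param dqc_factor expected dQC/QC intensity ratio (default 0.5).
#' @param noise_cv proportional measurement noise (default 0.02).
#' @param batch_scales optional numeric vector of per-batch scale factors
#'   (default all 1).
#' @param seed integer seed.
#' @return a [feature_run()].
#' @export
generate_feature_run <- function(n_features = 40L, n_batches = 2L,
                                 samples_per_batch = 48L, qc_every = 6L,
                                 drift_fold = 1, dqc_factor = 0.5,
                                 noise_cv = 0.02, batch_scales = NULL,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(batch_scales)) batch_scales <- rep(1, n_batches)
  base <- exp(stats::rnorm(n_features, log(1000), 0.5))
  meta <- list(); rows <- list()
  ord <- 0L
  for (b in seq_len(n_batches)) {
    roles <- character(0)
    ns <- 0L
    while (ns < samples_per_batch) {
      take <- min(qc_every, samples_per_batch - ns)
      roles <- c(roles, rep("sample", take), "QC", "dQC")
      ns <- ns + take
    }
    nb <- length(roles)
    for (j in seq_len(nb)) {
      ord <- ord + 1L
      drift <- 1 + (drift_fold - 1) * (j - 1) / max(nb - 1, 1)
      lvl <- switch(roles[j],
                    sample = base * exp(stats::rnorm(n_features, 0, 0.3)),
                    QC = base,
                    dQC = base * dqc_factor)
      y <- lvl * drift * batch_scales[b] *
        (1 + stats::rnorm(n_features, 0, noise_cv))
      meta[[ord]] <- data.frame(
        sample_id = sprintf("B%d_I%03d_%s", b, j, roles[j]),
        role = roles[j], batch = b, order = ord,
        stringsAsFactors = FALSE)
      rows[[ord]] <- y
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- sprintf("F%03d", seq_len(n_features))
  feature_run(do.call(rbind, meta), X)
}
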