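#' Configuration for the synthetic longitudinal two-compartment cohort
#'
#' Defines the planted structure of a simulated progressor / non-progressor
#' cohort: a cross-compartment discriminative signature, progressor subgroup
#' blocks, group-specific correlation structure, a progressor-only temporal
#' drift, and limit-of-detection censoring of BAL values. Defaults mirror
#' the dimensions of a multi-centre IPF progression cohort: 34 progressors
#' and 25 non-progressors, 1,129 blood proteins measured at weeks 0/48/80,
#' 29 BAL cytokines at week 0, and a 54-protein planted signature.
#'
#' @param n_prog,n_nonprog subject counts per group.
#' @param p_blood,p_bal analyte counts per compartment.
#' @param k_signature size of the planted cross-compartment signature.
#' @param effect_size between-group mean shift of each signature analyte, in
#'   autoscaled (latent SD) units.
#' @param n_subgroups number of progressor subgroups (heterogeneity blocks).
#' @param subgroup_block_size analytes uniquely elevated in each subgroup.
#' @param subgroup_effect elevation of a subgroup block within its subgroup,
#'   autoscaled units.
#' @param n_drift number of blood analytes carrying temporal drift.
#' @param temporal_drift per-time-step shift of drift analytes in
#'   progressors only, autoscaled units.
#' @param corr_strong target |r| of the sparse, strong non-progressor
#'   correlation blocks over the signature analytes.
#' @param corr_weak target |r| of the dense, weak progressor correlation
#'   structure over the signature analytes.
#' @param nonprog_factor_size analytes per latent factor in the
#'   non-progressor group (small blocks -> few strong correlations).
#' @param lod_quantile fraction of each BAL analyte's values censored at the
#'   limit of detection.
#' @param seed integer random seed; the full cohort is a deterministic
#'   function of the configuration.
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_prog = 34, n_nonprog = 25,
                          p_blood = 1129, p_bal = 29,
                          k_signature = 54, effect_size = 1.5,
                          n_subgroups = 3, subgroup_block_size = 5,
                          subgroup_effect = 2,
                          n_drift = 15, temporal_drift = 1,
                          corr_strong = 0.6, corr_weak = 0.2,
                          nonprog_factor_size = 4,
                          lod_quantile = 0.1, seed = 1) {
  cfg <- list(n_prog = n_prog, n_nonprog = n_nonprog, p_blood = p_blood,
              p_bal = p_bal, k_signature = k_signature,
              effect_size = effect_size, n_subgroups = n_subgroups,
              subgroup_block_size = subgroup_block_size,
              subgroup_effect = subgroup_effect, n_drift = n_drift,
              temporal_drift = temporal_drift, corr_strong = corr_strong,
              corr_weak = corr_weak,
              nonprog_factor_size = nonprog_factor_size,
              lod_quantile = lod_quantile, seed = seed)
  counts <- c("n_prog", "n_nonprog", "p_blood", "p_bal", "k_signature",
              "n_subgroups", "subgroup_block_size")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("invalid `", nm, "`: must be an integer count >= 1")
  }
  if (cfg$k_signature > cfg$p_blood + cfg$p_bal)
    stop("invalid `k_signature`: exceeds total analyte count")
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1)
    stop("invalid `lod_quantile`: must be in [0, 1)")
  if (cfg$corr_weak < 0 || cfg$corr_weak >= cfg$corr_strong ||
      cfg$corr_strong > 1)
    stop("invalid `corr_weak`/`corr_strong`: need 0 <= corr_weak < corr_strong <= 1")
  if (cfg$n_drift < 0) stop("invalid `n_drift`: must be >= 0")
  structure(cfg, class = "cohort_config")
}

# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a two-group, two-compartment, three-visit cohort from a latent
#' factor model. Concentrations are positive and right-skewed (a per-analyte
#' log-normal baseline with multiplicative noise); all planted effects act
#' on the latent standardised scale:
#'
#' * signature analytes are shifted by +/- `effect_size` between groups
#'   (sign drawn per analyte);
#' * each progressor subgroup has its own disjoint block of elevated
#'   analytes;
#' * non-progressor signature analytes share small latent factors with high
#'   loadings (few, strong correlations), progressor signature analytes
#'   share one broad factor with low loadings (many, weak correlations);
#' * drift analytes move by `temporal_drift` per visit in progressors only;
#' * BAL values below each analyte's empirical `lod_quantile` are censored
#'   and flagged, with the censoring threshold recorded as the analyte's
#'   minimum detectable concentration.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort`: list with `blood_tables` (named list of
#'   [analyte_table()] at weeks 0/48/80), `bal_table` (week 0, with
#'   per-sample `total_protein`), and `truth` (planted signature analytes
#'   and directions, subgroup labels and blocks, drift analytes and
#'   directions).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_prog + cfg$n_nonprog
  subjects <- sprintf("subj_%03d", seq_len(n))
  group <- c(rep("progressor", cfg$n_prog), rep("non_progressor", cfg$n_nonprog))
  blood_ids <- sprintf("blood_%04d", seq_len(cfg$p_blood))
  bal_ids <- sprintf("bal_%02d", seq_len(cfg$p_bal))
  all_ids <- c(blood_ids, bal_ids)
  p <- length(all_ids)

  # planted signature spans both compartments (proportional allocation,
  # at least one BAL analyte whenever the signature has room for it)
  k_bal <- 0L
  if (cfg$p_bal >= 1 && cfg$k_signature >= 2) {
    k_bal <- round(cfg$k_signature * cfg$p_bal / p)
    k_bal <- max(1L, min(k_bal, cfg$p_bal, cfg$k_signature - 1L))
  }
  k_blood <- cfg$k_signature - k_bal
  if (k_blood > cfg$p_blood)
    stop("invalid `k_signature`: too many blood analytes requested")
  sig_blood <- sample(blood_ids, k_blood)
  sig_bal <- if (k_bal > 0) sample(bal_ids, k_bal) else character()
  signature <- c(sig_blood, sig_bal)
  sig_dir <- setNames(sample(c(-1, 1), cfg$k_signature, replace = TRUE),
                      signature)

  # subgroup blocks and drift analytes: blood analytes disjoint from the
  # signature (and from each other), so each planted structure can be
  # validated independently
  pool <- setdiff(blood_ids, sig_blood)
  need <- cfg$n_subgroups * cfg$subgroup_block_size + cfg$n_drift
  if (length(pool) < need)
    stop("invalid `p_blood`: too small for subgroup blocks and drift analytes")
  picked <- sample(pool, need)
  subgroup_analytes <- split(
    picked[seq_len(cfg$n_subgroups * cfg$subgroup_block_size)],
    rep(seq_len(cfg$n_subgroups), each = cfg$subgroup_block_size)
  )
  names(subgroup_analytes) <- paste0("subgroup_", seq_len(cfg$n_subgroups))
  drift_analytes <- picked[seq_len(cfg$n_drift) +
                             cfg$n_subgroups * cfg$subgroup_block_size]
  drift_dir <- setNames(sample(c(-1, 1), cfg$n_drift, replace = TRUE),
                        drift_analytes)
  subgroup_labels <- setNames(
    rep_len(seq_len(cfg$n_subgroups), cfg$n_prog),
    subjects[group == "progressor"]
  )

  # per-analyte concentration scale: wide positive baselines with
  # multiplicative (log-normal) noise of 15-35% CV, typical of multiplexed
  # immunoassays
  baseline <- setNames(rlnorm(p, meanlog = log(100), sdlog = 1.5), all_ids)
  noise_sd <- setNames(runif(p, 0.15, 0.35), all_ids)

  is_prog <- group == "progressor"
  sig_idx <- match(signature, all_ids)
  # non-progressor factor blocks over the signature
  np_block <- split(seq_len(cfg$k_signature),
                    ceiling(seq_len(cfg$k_signature) / cfg$nonprog_factor_size))

  # latent factor values are drawn once per subject and persist across
  # visits: protein co-regulation is a property of the subject, so a
  # factor's chance sample mean cannot masquerade as a temporal shift
  g_prog <- rnorm(sum(is_prog))                    # one broad weak factor
  f_nonprog <- lapply(np_block, function(blk) rnorm(sum(!is_prog)))

  latent_z <- function(t_index) {
    z <- matrix(rnorm(n * p), n, p, dimnames = list(subjects, all_ids))
    # group-specific correlation structure on the signature analytes
    if (cfg$k_signature >= 2) {
      for (j in sig_idx) {
        z[is_prog, j] <- sqrt(cfg$corr_weak) * g_prog +
          sqrt(1 - cfg$corr_weak) * z[is_prog, j]
      }
      for (b in seq_along(np_block)) {             # small strong factors
        for (j in sig_idx[np_block[[b]]]) {
          z[!is_prog, j] <- sqrt(cfg$corr_strong) * f_nonprog[[b]] +
            sqrt(1 - cfg$corr_strong) * z[!is_prog, j]
        }
      }
    }
    # planted group separation (constant across visits)
    half <- cfg$effect_size / 2
    for (a in signature) {
      z[, a] <- z[, a] + ifelse(is_prog, half, -half) * sig_dir[a]
    }
    # progressor subgroup blocks
    for (s in seq_along(subgroup_analytes)) {
      in_s <- subjects %in% names(subgroup_labels)[subgroup_labels == s]
      z[in_s, subgroup_analytes[[s]]] <-
        z[in_s, subgroup_analytes[[s]], drop = FALSE] + cfg$subgroup_effect
    }
    # temporal drift, progressors only, linear in visit index
    if (cfg$n_drift > 0 && t_index > 0) {
      for (a in drift_analytes) {
        z[is_prog, a] <- z[is_prog, a] +
          cfg$temporal_drift * t_index * drift_dir[a]
      }
    }
    z
  }

  to_conc <- function(z, ids) {
    conc <- sweep(exp(sweep(z[, ids, drop = FALSE], 2, noise_sd[ids], "*")),
                  2, baseline[ids], "*")
    conc
  }

  weeks <- c(0, 48, 80)
  blood_tables <- list()
  bal_table <- NULL
  for (ti in seq_along(weeks)) {
    z <- latent_z(ti - 1)
    wk <- weeks[ti]
    conc <- to_conc(z, blood_ids)
    sid <- paste0(subjects, "_w", wk)
    rownames(conc) <- sid
    meta <- data.frame(sample_id = sid, subject_id = subjects, group = group,
                       time_week = wk, compartment = "blood",
                       stringsAsFactors = FALSE)
    blood_tables[[as.character(wk)]] <- analyte_table(
      conc, meta,
      data.frame(analyte_id = blood_ids, compartment = "blood",
                 stringsAsFactors = FALSE)
    )
    if (wk == 0) {
      total_protein <- rlnorm(n, meanlog = log(150), sdlog = 0.3)
      conc_bal <- to_conc(z, bal_ids)
      raw <- conc_bal * total_protein
      mask <- matrix(FALSE, n, cfg$p_bal)
      min_det <- rep(NA_real_, cfg$p_bal)
      for (j in seq_len(cfg$p_bal)) {
        thr <- quantile(raw[, j], cfg$lod_quantile, names = FALSE)
        min_det[j] <- thr
        if (cfg$lod_quantile > 0) mask[, j] <- raw[, j] < thr
      }
      raw[mask] <- NA_real_
      sid_bal <- paste0(subjects, "_w0_bal")
      rownames(raw) <- sid_bal
      dimnames(mask) <- dimnames(raw)
      meta_bal <- data.frame(sample_id = sid_bal, subject_id = subjects,
                             group = group, time_week = 0,
                             compartment = "bal",
                             total_protein = total_protein,
                             stringsAsFactors = FALSE)
      bal_table <- analyte_table(
        raw, meta_bal,
        data.frame(analyte_id = bal_ids, compartment = "bal",
                   min_detectable = min_det, stringsAsFactors = FALSE),
        mask
      )
    }
  }

  truth <- list(
    signature_analytes = signature,
    signature_direction = sig_dir,
    subgroup_labels = subgroup_labels,
    subgroup_analytes = subgroup_analytes,
    drift_analytes = drift_analytes,
    drift_direction = drift_dir
  )
  structure(list(blood_tables = blood_tables, bal_table = bal_table,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic_cohort: %d progressors + %d non-progressors\n",
              cfg$n_prog, cfg$n_nonprog))
  cat(sprintf("  blood: %d analytes at weeks %s; BAL: %d analytes at week 0\n",
              cfg$p_blood, paste(names(x$blood_tables), collapse = "/"),
              cfg$p_bal))
  cat(sprintf("  planted: %d-analyte signature (effect %.2g), %d subgroups, %d drift analytes (%.2g/step)\n",
              cfg$k_signature, cfg$effect_size, cfg$n_subgroups,
              cfg$n_drift, cfg$temporal_drift))
  invisible(x)
}

#' Export a synthetic cohort to delimited text files
#'
#' Writes one tab-delimited concentration table per compartment/time point
#' (`blood_week0.tsv`, `blood_week48.tsv`, `blood_week80.tsv`,
#' `bal_week0.tsv`), a sample metadata table per concentration table
#' (`*.meta.tsv`, including subgroup labels and BAL total protein), a shared
#' analyte metadata table (`analyte_meta.tsv`, with compartments and BAL
#' detection limits) and a ground-truth table (`ground_truth.tsv`).
#' Censored BAL cells are written as the sentinel token `"<LOD"`. The files
#' round-trip through [read_analyte_table()] without loss.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @param overwrite overwrite existing files? Default `FALSE`.
#' @return Invisibly, the vector of files written.
#' @export
export_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  tables <- c(
    setNames(cohort$blood_tables,
             paste0("blood_week", names(cohort$blood_tables))),
    list(bal_week0 = cohort$bal_table)
  )
  files <- character()
  analyte_all <- list()
  sg <- cohort$truth$subgroup_labels
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    path <- file.path(directory, paste0(nm, ".tsv"))
    meta_path <- file.path(directory, paste0(nm, ".meta.tsv"))
    for (pth in c(path, meta_path)) {
      if (file.exists(pth) && !overwrite)
        stop("file already exists: ", pth)
    }
    cells <- format(tab$values, trim = TRUE, digits = 17)
    cells[tab$lod_mask] <- LOD_SENTINEL
    df <- data.frame(sample_id = rownames(tab$values), cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    m <- tab$sample_meta
    m$subgroup <- ifelse(m$subject_id %in% names(sg),
                         unname(sg[m$subject_id]), NA_integer_)
    write.table(m, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path, meta_path)
    analyte_all[[nm]] <- tab$analyte_meta
  }

  am <- unique(do.call(rbind, lapply(analyte_all, function(a) {
    if (!"min_detectable" %in% names(a)) a$min_detectable <- NA_real_
    a
  })))
  rownames(am) <- NULL
  am_path <- file.path(directory, "analyte_meta.tsv")
  if (file.exists(am_path) && !overwrite)
    stop("file already exists: ", am_path)
  write.table(am, am_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- cohort$truth
  gt <- rbind(
    data.frame(analyte_id = truth$signature_analytes, role = "signature",
               direction = unname(truth$signature_direction),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(truth$subgroup_analytes), function(s) {
      data.frame(analyte_id = truth$subgroup_analytes[[s]], role = s,
                 direction = 1, stringsAsFactors = FALSE)
    })),
    if (length(truth$drift_analytes))
      data.frame(analyte_id = truth$drift_analytes, role = "drift",
                 direction = unname(truth$drift_direction),
                 stringsAsFactors = FALSE)
  )
  gt_path <- file.path(directory, "ground_truth.tsv")
  if (file.exists(gt_path) && !overwrite)
    stop("file already exists: ", gt_path)
  write.table(gt, gt_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(files, meta_path, am_path, gt_path))
}
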