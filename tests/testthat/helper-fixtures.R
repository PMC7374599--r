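# Small in-code fixtures shared across test files.

make_table <- function(values, group = NULL, compartment = "blood",
                       time_week = 0, subject = NULL, lod_mask = NULL,
                       total_protein = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%02d", 1:n)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("a%02d", seq_len(ncol(values)))
  if (is.null(group)) group <- rep("progressor", n)
  if (is.null(subject)) subject <- rownames(values)
  meta <- data.frame(sample_id = rownames(values), subject_id = subject,
                     group = group, time_week = time_week,
                     compartment = compartment, stringsAsFactors = FALSE)
  if (!is.null(total_protein)) meta$total_protein <- total_protein
  analyte_table(values, meta, lod_mask = lod_mask)
}

# A small two-group matrix with a known mean shift on the first k columns.
make_shifted_matrix <- function(n_per_group = 15, p = 20, k = 5, delta = 2,
                                seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p)
  grp <- rep(c("progressor", "non_progressor"), each = n_per_group)
  x[grp == "progressor", seq_len(k)] <- x[grp == "progressor", seq_len(k)] + delta
  colnames(x) <- sprintf("a%02d", seq_len(p))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per_group))
  list(x = x, group = grp)
}

quick_config <- function(...) {
  defaults <- list(n_prog = 15, n_nonprog = 12, p_blood = 40, p_bal = 8,
                   k_signature = 10, effect_size = 2, n_subgroups = 3,
                   subgroup_block_size = 3, n_drift = 6, temporal_drift = 1,
                   seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}
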