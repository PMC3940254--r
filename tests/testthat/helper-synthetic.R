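# Shared fixture builders; everything is generated in code under fixed seeds.

# pure-noise feature table: no association between columns and line labels
make_noise_table <- function(n_lines = 14, n_per_line = 5, p = 9,
                             prefix = "q", seed = 1) {
  line <- factor(rep(sprintf("L%02d", seq_len(n_lines)), each = n_per_line))
  n <- length(line)
  tab <- data.frame(sample_id = sprintf("s%03d", seq_len(n)), line = line,
                    stringsAsFactors = FALSE)
  set.seed(seed)
  for (j in seq_len(p)) tab[[paste0(prefix, j)]] <- rnorm(n)
  tab
}

# strongly line-separated cohort: between-line SD = 5x within-line SD
make_separable_cohort <- function(n_lines = 14, n_per_line = 5, p = 8,
                                  seed = 1, var_between = 25, var_within = 1) {
  specs <- lapply(seq_len(p), function(j)
    parameter_spec(paste0("p", j), var_between = var_between,
                   var_within = var_within))
  generate_cohort(cohort_spec(n_lines, n_per_line, specs, seed = seed))
}

param_cols <- function(tab) setdiff(names(tab), c("sample_id", "line"))
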