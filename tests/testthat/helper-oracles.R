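# Independent oracles and fixture builders used across the suite.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (summing probabilities at or below
# the observed one, with the customary relative tolerance).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- dhyper(k, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Closed-form Welch two-sample t-test (statistic, Satterthwaite df,
# two-sided p), written independently of stats::t.test.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Build a complete probe table around the columns a test cares about.
toy_probes <- function(probe_id,
                       gene_id = "g1",
                       chromosome = "chr1",
                       start = seq(100, by = 300, length.out = length(probe_id)),
                       probe_type = "Inside",
                       signal_WT = 1,
                       signal_TG = 1,
                       pvalue_WT = 0.5,
                       pvalue_TG = 0.5) {
  data.frame(
    probe_id = probe_id,
    gene_id = gene_id,
    chromosome = chromosome,
    start = as.integer(start),
    end = as.integer(start + 60L),
    probe_type = probe_type,
    signal_WT_1 = signal_WT,
    signal_WT_2 = signal_WT,
    signal_TG_1 = signal_TG,
    signal_TG_2 = signal_TG,
    pvalue_WT = pvalue_WT,
    pvalue_TG = pvalue_TG,
    stringsAsFactors = FALSE
  )
}

# One-row binding profile, as produced by call_bound_genes().
toy_profile <- function(gene_id, condition = "WT", n_bound = 0L,
                        bound_signal_sum = 0) {
  data.frame(gene_id = gene_id, condition = condition,
             n_bound = as.integer(n_bound),
             bound_signal_sum = bound_signal_sum,
             signature = ifelse(n_bound > 0, "Inside", "NONE"),
             bound_probe_ids = "", stringsAsFactors = FALSE)
}

# A small simulated study shared by io/cross-check tests.
small_study <- function(seed = 11, n_genes = 120) {
  simulate_study(sim_params(n_genes = n_genes, seed = seed))
}
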