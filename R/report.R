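#' Run the full binding/expression analysis
#'
#' Orchestrates the whole pipeline on in-memory tables: bound-probe and
#' bound-gene calling per condition, descriptive binding statistics,
#' composite differential-acetylation scoring and categorisation,
#' expression and differential-expression calls, and the
#' binding-by-expression association statistics.
#'
#' @param probes Probe table with signals and p-values.
#' @param annotation Gene annotation table.
#' @param expression Long expression table.
#' @param config An `acechip_config` with the decision thresholds.
#' @return A list of class `acechip_results` with components
#'   `bound_probes`, `profiles`, `histograms`, `chromosome_table`,
#'   `occupancy`, `signatures`, `diffacet`, `diffacet_census`,
#'   `top_decreased`, `top_increased`, `expression_calls`, `de_calls`,
#'   `contingency`, `fractions`, `signature_by_expression`,
#'   `de_by_diffacet`, `config`.
#' @export
run_pipeline <- function(probes, annotation, expression,
                         config = run_config()) {
  stopifnot(inherits(config, "acechip_config"))
  bound <- lapply(setNames(CONDITIONS, CONDITIONS), function(cc) {
    call_bound_probes(probes, cc, config$probe_p_threshold)
  })
  profiles <- lapply(setNames(CONDITIONS, CONDITIONS), function(cc) {
    call_bound_genes(probes, bound[[cc]], cc, annotation)
  })
  histograms <- lapply(profiles, probes_per_gene_distribution)
  chrom_tab <- chromosome_binding_table(profiles$WT, annotation, profiles$TG)
  occupancy <- lapply(setNames(CONDITIONS, CONDITIONS), function(cc) {
    probe_type_occupancy(probes, bound[[cc]])
  })
  signatures <- lapply(profiles, signature_census)
  diffacet <- differential_acetylation_table(profiles$WT, profiles$TG,
                                             annotation)
  expr_calls <- expression_call_table(expression, config$expression_threshold)
  de_calls <- de_call_table(expression, config$fc_threshold,
                            config$de_p_threshold)
  contingency <- lapply(setNames(CONDITIONS, CONDITIONS), function(cc) {
    odds_ratio_ci(bound_by_expressed_table(profiles[[cc]], expr_calls, cc),
                  config$ci_level)
  })
  structure(list(
    bound_probes = bound,
    profiles = profiles,
    histograms = histograms,
    chromosome_table = chrom_tab,
    occupancy = occupancy,
    signatures = signatures,
    diffacet = diffacet,
    diffacet_census = category_census(diffacet),
    top_decreased = rank_genes(diffacet, "decreased", 30L),
    top_increased = rank_genes(diffacet, "increased", 30L),
    expression_calls = expr_calls,
    de_calls = de_calls,
    contingency = contingency,
    fractions = lapply(contingency, fraction_bound_expressed),
    signature_by_expression = lapply(
      setNames(CONDITIONS, CONDITIONS),
      function(cc) signature_by_expression(profiles[[cc]], expr_calls, cc)),
    de_by_diffacet = de_by_diffacet(de_calls, diffacet),
    config = config
  ), class = "acechip_results")
}

md_table <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Write a human-readable analysis report
#'
#' Renders the results of [run_pipeline()] as a Markdown document
#' covering binding summaries, per-chromosome and probe-type breakdowns,
#' binding signatures, the differential-acetylation categories and top
#' ranked genes, expression calls and the binding-by-expression
#' association statistics.
#'
#' @param results An `acechip_results` from [run_pipeline()].
#' @param path Output Markdown file.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "acechip_results"))
  cfg <- results$config
  n_bound <- vapply(results$profiles, function(p) sum(p$n_bound >= 1L),
                    integer(1))
  n_probes <- vapply(results$bound_probes, length, integer(1))
  or_line <- function(cc) {
    x <- results$contingency[[cc]]
    p_disp <- if (x$p_exact < 2.2e-16) "< 2.2e-16" else sprintf("= %.3g", x$p_exact)
    sprintf(
      "- %s: a=%d, b=%d, c=%d, d=%d; odds ratio = %.1f, %d%% CI = (%.1f, %.1f), p %s; %d%% of bound genes expressed",
      cc, x$a, x$b, x$c, x$d, x$odds_ratio, round(100 * x$ci_level),
      x$ci_low, x$ci_high, p_disp, results$fractions[[cc]]$display)
  }
  lines <- c(
    "# AcH3 binding and expression report",
    "",
    sprintf("Thresholds: probe p <= %g; expressed > %g; DE >= %g-fold, p <= %g; CI %g%%; seed %d.",
            cfg$probe_p_threshold, cfg$expression_threshold,
            cfg$fc_threshold, cfg$de_p_threshold, 100 * cfg$ci_level,
            cfg$seed),
    "",
    "## Binding summary",
    "",
    sprintf("- WT: %d bound probes across %d bound genes (max %d probes/gene)",
            n_probes["WT"], n_bound["WT"], results$histograms$WT$max),
    sprintf("- TG: %d bound probes across %d bound genes (max %d probes/gene)",
            n_probes["TG"], n_bound["TG"], results$histograms$TG$max),
    sprintf("- TG/WT bound-probe ratio: %.1f%%; bound-gene ratio: %.1f%%",
            ratio_percent(n_probes["TG"], max(n_probes["WT"], 1))$display,
            ratio_percent(n_bound["TG"], max(n_bound["WT"], 1))$display),
    "",
    "## Probes bound per gene (WT)",
    "",
    md_table(results$histograms$WT$histogram),
    "",
    "## Per-chromosome binding",
    "",
    md_table(results$chromosome_table),
    "",
    "## Probe-type occupancy (WT)",
    "",
    md_table(results$occupancy$WT),
    "",
    "## Binding signatures (WT)",
    "",
    md_table(results$signatures$WT),
    "",
    "## Differential acetylation categories",
    "",
    md_table(results$diffacet_census),
    "",
    "## Top genes with decreased acetylation in TG",
    "",
    md_table(results$top_decreased[, c("rank", "gene_id", "n_wt_bound",
                                       "n_tg_bound", "score")]),
    "",
    "## Top genes with increased acetylation in TG",
    "",
    md_table(results$top_increased[, c("rank", "gene_id", "n_wt_bound",
                                       "n_tg_bound", "score")]),
    "",
    "## Binding by expression",
    "",
    or_line("WT"),
    or_line("TG"),
    "",
    "## Signature by expression (WT)",
    "",
    md_table(results$signature_by_expression$WT),
    "",
    "## Differential expression by differential acetylation",
    "",
    if (nrow(results$de_by_diffacet) > 0) md_table(results$de_by_diffacet)
    else "No differentially expressed genes.",
    ""
  )
  writeLines(lines, path)
  invisible(path)
}
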