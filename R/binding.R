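# Canonical display order of probe types in signatures and tables.
SIGNATURE_ORDER <- c("Promoter", "Inside", "Downstream", "DivergentPromoter",
                     "Unknown")

#' Call bound probes
#'
#' A probe is bound in a condition when its enrichment p-value is at or
#' below the threshold (inclusive, matching the stated p <= 0.005 rule).
#' Probes with a missing p-value in the condition are treated as unbound,
#' with a message reporting how many were skipped.
#'
#' @param probes Probe table ([read_probe_table()] / [simulate_probes()]).
#' @param condition `"WT"` or `"TG"`.
#' @param threshold P-value cutoff in (0,1); default 0.005.
#' @return Character vector of bound probe ids.
#' @export
#' @examples
#' df <- data.frame(probe_id = c("a", "b"), pvalue_WT = c(0.005, 0.0051))
#' call_bound_probes(df, "WT") # "a"
call_bound_probes <- function(probes, condition, threshold = 0.005) {
  condition <- match_condition(condition)
  stopifnot(threshold > 0, threshold < 1)
  p <- probes[[pvalue_col(condition)]]
  if (is.null(p)) stop("no p-value column for condition ", condition)
  n_missing <- sum(is.na(p))
  if (n_missing > 0L) {
    message(n_missing, " probe(s) with missing ", condition,
            " p-value treated as unbound")
  }
  probes$probe_id[!is.na(p) & p <= threshold]
}

#' Aggregate bound probes to gene binding profiles
#'
#' A gene is bound when at least one of its probes is bound. Each profile
#' carries the bound probe count, the summed replicate-mean log2(IP/WCE)
#' signal over bound probes, and the binding signature: the set of probe
#' location types among the gene's bound probes (pipe-joined in canonical
#' order), `"NONE"` for unbound genes.
#'
#' @param probes Probe table.
#' @param bound_probe_ids From [call_bound_probes()].
#' @param condition `"WT"` or `"TG"`.
#' @param annotation Optional annotation table; when given, every
#'   annotated gene gets a profile (unbound genes included) and probes
#'   referencing unknown genes are dropped with a warning.
#' @return Profile `data.frame`: gene_id, condition, n_bound,
#'   bound_signal_sum, signature, bound_probe_ids (comma-joined).
#' @export
call_bound_genes <- function(probes, bound_probe_ids, condition,
                             annotation = NULL) {
  condition <- match_condition(condition)
  probes <- probes[!is.na(probes$gene_id), , drop = FALSE]
  if (!is.null(annotation)) {
    unknown <- setdiff(unique(probes$gene_id), annotation$gene_id)
    if (length(unknown) > 0L) {
      warning(length(unknown), " probe gene_id(s) absent from annotation; ",
              "their probes are ignored for gene-level statistics")
      probes <- probes[probes$gene_id %in% annotation$gene_id, , drop = FALSE]
    }
    genes <- annotation$gene_id
  } else {
    genes <- sort(unique(probes$gene_id))
  }
  bound <- probes[probes$probe_id %in% bound_probe_ids, , drop = FALSE]
  sig_mean <- if (nrow(bound) > 0L) probe_signal_mean(bound, condition) else numeric(0)
  f <- factor(bound$gene_id, levels = genes)
  n_bound <- as.integer(table(f))
  signal_sum <- as.numeric(tapply(sig_mean, f, sum, default = 0))
  signature <- vapply(split(bound$probe_type, f), function(tt) {
    if (length(tt) == 0L) return("NONE")
    paste(SIGNATURE_ORDER[SIGNATURE_ORDER %in% tt], collapse = "|")
  }, character(1))
  ids <- vapply(split(bound$probe_id, f), paste, character(1), collapse = ",")
  data.frame(
    gene_id = genes, condition = condition, n_bound = n_bound,
    bound_signal_sum = signal_sum, signature = unname(signature),
    bound_probe_ids = unname(ids), stringsAsFactors = FALSE
  )
}

#' Distribution of bound probes per gene
#'
#' Histogram of the number of binding events per bound gene (n_bound >= 1)
#' and its maximum, the per-gene saturation statistic of the array.
#'
#' @param profiles From [call_bound_genes()].
#' @return List with `histogram` (data.frame n_bound, n_genes) and `max`.
#' @export
probes_per_gene_distribution <- function(profiles) {
  nb <- profiles$n_bound[profiles$n_bound >= 1L]
  if (length(nb) == 0L) {
    return(list(histogram = data.frame(n_bound = integer(0),
                                       n_genes = integer(0)),
                max = 0L))
  }
  tab <- table(nb)
  list(
    histogram = data.frame(n_bound = as.integer(names(tab)),
                           n_genes = as.integer(tab)),
    max = max(nb)
  )
}

#' Per-chromosome binding summary
#'
#' For each chromosome: total genes, bound genes and percent bound.
#' When a second condition's profiles are supplied, the per-chromosome
#' TG/WT ratio of percent bound is added.
#'
#' @param profiles Profiles of the reference condition (WT).
#' @param annotation Gene annotation (chromosome per gene).
#' @param profiles2 Optional profiles of the comparison condition (TG).
#' @return Data frame with one row per chromosome carrying genes.
#' @export
chromosome_binding_table <- function(profiles, annotation, profiles2 = NULL) {
  chr <- annotation$chromosome[match(profiles$gene_id, annotation$gene_id)]
  if (anyNA(chr)) stop("profiles contain genes absent from annotation")
  empty <- setdiff(unique(annotation$chromosome), unique(chr))
  if (length(empty) > 0L) {
    warning("chromosome(s) without genes excluded: ",
            paste(empty, collapse = ", "))
  }
  agg <- function(p) {
    cc <- annotation$chromosome[match(p$gene_id, annotation$gene_id)]
    tab <- tapply(p$n_bound >= 1L, cc, sum)
    tot <- tapply(rep(1L, nrow(p)), cc, sum)
    data.frame(chromosome = names(tab), n_genes = as.integer(tot),
               n_bound = as.integer(tab),
               percent_bound = 100 * as.integer(tab) / as.integer(tot),
               stringsAsFactors = FALSE)
  }
  out <- agg(profiles)
  if (!is.null(profiles2)) {
    t2 <- agg(profiles2)
    m <- match(out$chromosome, t2$chromosome)
    out$n_bound_2 <- t2$n_bound[m]
    out$percent_bound_2 <- t2$percent_bound[m]
    out$ratio <- ifelse(out$percent_bound > 0,
                        out$percent_bound_2 / out$percent_bound, NA_real_)
  }
  ord <- order(match(out$chromosome, names(MOUSE_CHROM_LENGTHS)),
               out$chromosome)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probe-type occupancy
#'
#' Percent of probes bound within each probe location type, with per-type
#' array totals as denominators. Types absent from the array are omitted.
#'
#' @param probes Probe table.
#' @param bound_probe_ids From [call_bound_probes()].
#' @return Data frame: probe_type, n_total, n_bound, percent_bound.
#' @export
probe_type_occupancy <- function(probes, bound_probe_ids) {
  tt <- factor(probes$probe_type, levels = SIGNATURE_ORDER)
  n_total <- as.integer(table(tt))
  n_bound <- as.integer(table(tt[probes$probe_id %in% bound_probe_ids]))
  out <- data.frame(
    probe_type = SIGNATURE_ORDER, n_total = n_total, n_bound = n_bound,
    percent_bound = ifelse(n_total > 0, 100 * n_bound / n_total, NA_real_),
    stringsAsFactors = FALSE
  )
  out[out$n_total > 0L, , drop = FALSE]
}

#' Render a binding signature as its display label
#'
#' Single-type signatures become `"<Type> Only"` (e.g. `"Inside Only"`,
#' `"Divergent Promoter Only"`), multi-type signatures are joined with
#' `" & "` in canonical order.
#'
#' @param signature Pipe-joined signature strings from
#'   [call_bound_genes()].
#' @return Character vector of labels (`"NONE"` passes through).
#' @export
signature_label <- function(signature) {
  display <- c(Promoter = "Promoter", Inside = "Inside",
               Downstream = "Downstream",
               DivergentPromoter = "Divergent Promoter",
               Unknown = "Unknown")
  vapply(signature, function(s) {
    if (is.na(s) || s == "NONE") return("NONE")
    parts <- display[strsplit(s, "|", fixed = TRUE)[[1]]]
    if (length(parts) == 1L) paste(parts, "Only") else paste(parts, collapse = " & ")
  }, character(1), USE.NAMES = FALSE)
}

#' Census of binding signatures
#'
#' Counts bound genes per binding-signature label; counts sum to the
#' number of bound genes (signatures partition them).
#'
#' @param profiles From [call_bound_genes()].
#' @return Data frame: signature (label), n_genes, sorted by count.
#' @export
signature_census <- function(profiles) {
  bound <- profiles[profiles$n_bound >= 1L, , drop = FALSE]
  lab <- signature_label(bound$signature)
  tab <- sort(table(lab), decreasing = TRUE)
  data.frame(signature = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Single-gene ChIP qPCR enrichment
#'
#' Converts qPCR threshold cycles of IP and input reactions into the
#' study's printed enrichment statistic `log2(Ct_IP / Ct_input)`. The
#' conventional percent-of-input form `2^(Ct_input - Ct_IP)` is available
#' as an alternate mode.
#'
#' @param ct_ip,ct_input Threshold cycle numbers, > 0.
#' @param mode `"log2_ct_ratio"` (default, as printed) or
#'   `"percent_input"`.
#' @return Numeric enrichment value(s).
#' @export
#' @examples
#' qpcr_enrichment(30, 15) # 1
qpcr_enrichment <- function(ct_ip, ct_input,
                            mode = c("log2_ct_ratio", "percent_input")) {
  mode <- match.arg(mode)
  if (any(ct_ip <= 0) || any(ct_input <= 0)) {
    stop("threshold cycles must be positive")
  }
  switch(mode,
         log2_ct_ratio = log2(ct_ip / ct_input),
         percent_input = 2^(ct_input - ct_ip))
}
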