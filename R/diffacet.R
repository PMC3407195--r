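# Five-way differential-acetylation vocabulary (plus the explicit
# zero-difference tie label).
DIFFACET_CATEGORIES <- c("NOT_ACETYLATED_IN_TG", "HYPOACETYLATED_IN_TG",
                         "HYPERACETYLATED_IN_TG", "ECTOPICALLY_ACETYLATED_IN_TG",
                         "NOT_ACETYLATED", "UNCHANGED")

DIFFERENTIAL_CATEGORIES <- DIFFACET_CATEGORIES[1:4]

category_display <- c(
  NOT_ACETYLATED_IN_TG = "Not acetylated in TG",
  HYPOACETYLATED_IN_TG = "Hypoacetylated in TG",
  HYPERACETYLATED_IN_TG = "Hyperacetylated in TG",
  ECTOPICALLY_ACETYLATED_IN_TG = "Ectopically acetylated in TG",
  NOT_ACETYLATED = "Not acetylated",
  UNCHANGED = "Unchanged"
)

#' Composite differential-acetylation score for one gene
#'
#' The composite score is the summed bound-probe signal in TG minus that
#' in WT: `bound_signal_sum(TG) - bound_signal_sum(WT)`. Negative scores
#' mean less acetylation in the transgenic condition. Genes with no bound
#' probes on either side score 0.
#'
#' @param profile_wt,profile_tg Single-gene rows of profile tables from
#'   [call_bound_genes()], same gene.
#' @return The score (numeric scalar).
#' @export
#' @examples
#' wt <- data.frame(gene_id = "g", n_bound = 2L, bound_signal_sum = 3.5)
#' tg <- data.frame(gene_id = "g", n_bound = 1L, bound_signal_sum = 1.2)
#' composite_score(wt, tg) # -2.3
composite_score <- function(profile_wt, profile_tg) {
  stopifnot(nrow(profile_wt) == 1L, nrow(profile_tg) == 1L)
  if (profile_wt$gene_id != profile_tg$gene_id) {
    stop("profiles refer to different genes: ", profile_wt$gene_id,
         " vs ", profile_tg$gene_id)
  }
  profile_tg$bound_signal_sum - profile_wt$bound_signal_sum
}

classify_one <- function(bound_wt, bound_tg, score, epsilon) {
  if (bound_wt && !bound_tg) return("NOT_ACETYLATED_IN_TG")
  if (!bound_wt && bound_tg) return("ECTOPICALLY_ACETYLATED_IN_TG")
  if (!bound_wt && !bound_tg) return("NOT_ACETYLATED")
  if (score < -epsilon) return("HYPOACETYLATED_IN_TG")
  if (score > epsilon) return("HYPERACETYLATED_IN_TG")
  "UNCHANGED"
}

#' Classify a gene's differential-acetylation category
#'
#' Bound in WT only: not acetylated in TG; bound in TG only: ectopically
#' acetylated in TG; bound in both with score below `-epsilon` / above
#' `+epsilon`: hypo-/hyper-acetylated in TG; bound in neither: not
#' acetylated; otherwise unchanged. `epsilon = 0` (default) is the strict
#' sign rule.
#'
#' @inheritParams composite_score
#' @param score From [composite_score()].
#' @param epsilon Dead-band half-width, >= 0.
#' @return One of the category strings.
#' @export
classify_differential_acetylation <- function(profile_wt, profile_tg, score,
                                              epsilon = 0) {
  stopifnot(epsilon >= 0)
  if (profile_wt$gene_id != profile_tg$gene_id) stop("gene mismatch")
  classify_one(profile_wt$n_bound >= 1L, profile_tg$n_bound >= 1L,
               score, epsilon)
}

#' Score and classify all genes
#'
#' Joins WT and TG binding profiles by gene and computes the composite
#' score and category per gene; genes missing from one condition's table
#' count as unbound there.
#'
#' @param profiles_wt,profiles_tg Profile tables from
#'   [call_bound_genes()].
#' @param annotation Optional annotation; adds a chromosome column.
#' @param epsilon Dead-band for the both-bound tie rule (default 0).
#' @return Data frame: gene_id, n_wt_bound, n_tg_bound, score, category.
#' @export
differential_acetylation_table <- function(profiles_wt, profiles_tg,
                                           annotation = NULL, epsilon = 0) {
  genes <- union(profiles_wt$gene_id, profiles_tg$gene_id)
  iw <- match(genes, profiles_wt$gene_id)
  it <- match(genes, profiles_tg$gene_id)
  n_wt <- ifelse(is.na(iw), 0L, profiles_wt$n_bound[iw])
  n_tg <- ifelse(is.na(it), 0L, profiles_tg$n_bound[it])
  s_wt <- ifelse(is.na(iw), 0, profiles_wt$bound_signal_sum[iw])
  s_tg <- ifelse(is.na(it), 0, profiles_tg$bound_signal_sum[it])
  score <- s_tg - s_wt
  category <- mapply(classify_one, n_wt >= 1L, n_tg >= 1L, score,
                     MoreArgs = list(epsilon = epsilon))
  out <- data.frame(
    gene_id = genes, n_wt_bound = as.integer(n_wt),
    n_tg_bound = as.integer(n_tg), score = score,
    category = unname(category), stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    out$chromosome <- annotation$chromosome[match(genes, annotation$gene_id)]
  }
  out
}

#' Rank genes by composite score
#'
#' `direction = "decreased"` ranks ascending (most negative scores, i.e.
#' the greatest acetylation losses, first); `"increased"` descending.
#' Ties break by larger `|n_wt_bound - n_tg_bound|`, then gene id, for a
#' deterministic order.
#'
#' @param records From [differential_acetylation_table()].
#' @param direction `"decreased"` or `"increased"`.
#' @param k Number of genes to return; if larger than the table, all are
#'   returned with a message.
#' @return The top-`k` rows with a `rank` column prepended.
#' @export
rank_genes <- function(records, direction = c("decreased", "increased"),
                       k = 30L) {
  direction <- match.arg(direction)
  if (k > nrow(records)) {
    message("k = ", k, " exceeds ", nrow(records), " genes; returning all")
    k <- nrow(records)
  }
  key <- if (direction == "decreased") records$score else -records$score
  ord <- order(key, -abs(records$n_wt_bound - records$n_tg_bound),
               records$gene_id)
  out <- records[ord[seq_len(k)], , drop = FALSE]
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}

#' Census of differential-acetylation categories
#'
#' Counts per category over all genes (a partition: counts sum to the
#' gene total) and each differential category's share of the four
#' differential categories (excluding not-acetylated and unchanged).
#' With no differential genes, shares are reported as 0 and flagged.
#'
#' @param records From [differential_acetylation_table()].
#' @return Data frame: category, label, n_genes, percent_of_differential;
#'   attribute `no_differential` flags the degenerate case.
#' @export
category_census <- function(records) {
  f <- factor(records$category, levels = DIFFACET_CATEGORIES)
  counts <- as.integer(table(f))
  n_diff <- sum(counts[DIFFACET_CATEGORIES %in% DIFFERENTIAL_CATEGORIES])
  pct <- ifelse(DIFFACET_CATEGORIES %in% DIFFERENTIAL_CATEGORIES,
                if (n_diff > 0) 100 * counts / n_diff else 0,
                NA_real_)
  out <- data.frame(
    category = DIFFACET_CATEGORIES,
    label = unname(category_display[DIFFACET_CATEGORIES]),
    n_genes = counts,
    percent_of_differential = pct,
    stringsAsFactors = FALSE
  )
  attr(out, "no_differential") <- n_diff == 0L
  out
}
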