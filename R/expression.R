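#' @importFrom stats t.test
NULL

#' Gene-level expression value
#'
#' A gene represented by several probesets gets the arithmetic mean of
#' its probeset values as its expression value.
#'
#' @param probeset_values Numeric vector, length >= 1.
#' @return The mean.
#' @export
#' @examples
#' gene_expression_value(c(50, 250)) # 150
gene_expression_value <- function(probeset_values) {
  if (length(probeset_values) == 0L) {
    stop("at least one probeset value is required")
  }
  if (!is.numeric(probeset_values) || anyNA(probeset_values)) {
    stop("probeset values must be numeric and non-missing")
  }
  mean(probeset_values)
}

#' Expressed-gene call
#'
#' A gene is expressed when its average expression value is strictly
#' greater than the threshold (default 100).
#'
#' @param mean_expression Numeric vector of gene means.
#' @param threshold Positive threshold.
#' @return Logical vector.
#' @export
#' @examples
#' call_expressed(c(100, 100.1)) # FALSE TRUE
call_expressed <- function(mean_expression, threshold = 100) {
  stopifnot(threshold > 0)
  mean_expression > threshold
}

#' Differential expression between conditions for one gene
#'
#' Fold change is `mean(TG)/mean(WT)` reported as the larger of the ratio
#' and its reciprocal together with the direction; the p-value comes from
#' a two-sided Welch (unequal-variance) t-test. The gene is `UP` when TG
#' exceeds WT with fold change at or above `fc_threshold` and p at or
#' below `p_threshold` (both boundaries inclusive), `DOWN` analogously,
#' otherwise `UNCHANGED`. Two constant groups with equal means give p = 1;
#' constant groups with different means give p = 0 (the test degenerates)
#' and the fold gate decides.
#'
#' @param values_wt,values_tg Sample values per group, >= 2 each, positive
#'   means.
#' @param fc_threshold Minimum fold change (default 1.5).
#' @param p_threshold Maximum p-value (default 0.05).
#' @return List: `fold_change` (>= 1), `direction` (+1 TG higher, -1 TG
#'   lower, 0 equal), `p_value`, `status` in {UP, DOWN, UNCHANGED}.
#' @export
differential_expression <- function(values_wt, values_tg,
                                    fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(length(values_wt) >= 2L, length(values_tg) >= 2L,
            fc_threshold > 0, p_threshold > 0, p_threshold <= 1)
  m_wt <- mean(values_wt); m_tg <- mean(values_tg)
  if (m_wt <= 0 || m_tg <= 0) stop("group means must be positive")
  ratio <- m_tg / m_wt
  direction <- sign(m_tg - m_wt)
  fold <- max(ratio, 1 / ratio)
  v_wt <- stats::var(values_wt); v_tg <- stats::var(values_tg)
  if (v_wt == 0 && v_tg == 0) {
    p <- if (m_wt == m_tg) 1 else 0
  } else {
    p <- t.test(values_tg, values_wt, var.equal = FALSE)$p.value
  }
  status <- "UNCHANGED"
  if (fold >= fc_threshold && p <= p_threshold && direction != 0) {
    status <- if (direction > 0) "UP" else "DOWN"
  }
  list(fold_change = fold, direction = direction, p_value = p,
       status = status)
}

expression_value_columns <- function(expression) {
  grep("^value_[0-9]+$", names(expression), value = TRUE)
}

#' Per-gene, per-condition expression calls
#'
#' Computes the mean expression over the sample columns of a long
#' expression table and applies the expressed-gene rule.
#'
#' @param expression Long expression table ([read_expression_table()]).
#' @param threshold Expression threshold (default 100).
#' @return Data frame: gene_id, condition, mean_expression, expressed.
#' @export
expression_call_table <- function(expression, threshold = 100) {
  vals <- expression_value_columns(expression)
  if (length(vals) == 0L) stop("no value_<sample> columns")
  m <- rowMeans(as.matrix(expression[, vals, drop = FALSE]))
  data.frame(
    gene_id = expression$gene_id, condition = expression$condition,
    mean_expression = m, expressed = call_expressed(m, threshold),
    stringsAsFactors = FALSE
  )
}

#' Genome-wide differential-expression calls
#'
#' Applies [differential_expression()] to each gene of a long expression
#' table containing both conditions.
#'
#' @param expression Long expression table.
#' @param fc_threshold,p_threshold Gates of the call (defaults 1.5, 0.05).
#' @return Data frame: gene_id, fold_change, direction, p_value,
#'   de_status.
#' @export
de_call_table <- function(expression, fc_threshold = 1.5, p_threshold = 0.05) {
  vals <- expression_value_columns(expression)
  wt <- expression[expression$condition == "WT", , drop = FALSE]
  tg <- expression[expression$condition == "TG", , drop = FALSE]
  genes <- intersect(wt$gene_id, tg$gene_id)
  if (length(genes) == 0L) stop("no genes present in both conditions")
  mw <- as.matrix(wt[match(genes, wt$gene_id), vals, drop = FALSE])
  mt <- as.matrix(tg[match(genes, tg$gene_id), vals, drop = FALSE])
  res <- lapply(seq_along(genes), function(i) {
    differential_expression(mw[i, ], mt[i, ], fc_threshold, p_threshold)
  })
  data.frame(
    gene_id = genes,
    fold_change = vapply(res, `[[`, numeric(1), "fold_change"),
    direction = vapply(res, `[[`, numeric(1), "direction"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    de_status = vapply(res, `[[`, character(1), "status"),
    stringsAsFactors = FALSE
  )
}
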