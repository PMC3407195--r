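#' @importFrom stats fisher.test chisq.test qnorm var
NULL

#' Common gene set of two platforms
#'
#' The genes present on both the ChIP-chip and the expression platform,
#' canonically sorted; association statistics are computed over this set.
#'
#' @param binding_genes,expression_genes Character vectors of gene ids.
#' @return Sorted character vector; empty intersection is an error.
#' @export
common_gene_set <- function(binding_genes, expression_genes) {
  stopifnot(length(binding_genes) > 0L, length(expression_genes) > 0L)
  common <- sort(intersect(binding_genes, expression_genes))
  if (length(common) == 0L) {
    stop("binding and expression gene sets do not intersect")
  }
  common
}

new_contingency <- function(a, b, c, d, condition = NA_character_) {
  structure(
    list(a = a, b = b, c = c, d = d, n = a + b + c + d,
         condition = condition,
         margins = list(bound = a + b, not_bound = c + d,
                        expressed = a + c, not_expressed = b + d)),
    class = "acechip_contingency"
  )
}

#' 2x2 table of gene binding by transcript presence
#'
#' Cross-tabulates bound/not-bound (>= 1 bound probe) against
#' expressed/not-expressed over the common gene set of the two inputs:
#' `a` = bound & expressed, `b` = bound & not expressed, `c` = not bound
#' & expressed, `d` = neither. Cells sum to the common-set size.
#'
#' @param profiles Binding profiles ([call_bound_genes()]) for the
#'   condition.
#' @param expression_calls From [expression_call_table()].
#' @param condition `"WT"` or `"TG"`.
#' @return An `acechip_contingency` (counts and margins; complete with
#'   [odds_ratio_ci()]).
#' @export
bound_by_expressed_table <- function(profiles, expression_calls, condition) {
  condition <- match_condition(condition)
  ec <- expression_calls[expression_calls$condition == condition, , drop = FALSE]
  common <- common_gene_set(profiles$gene_id, ec$gene_id)
  bound <- profiles$n_bound[match(common, profiles$gene_id)] >= 1L
  expressed <- ec$expressed[match(common, ec$gene_id)]
  if (anyNA(bound) || anyNA(expressed)) {
    bad <- common[is.na(bound) | is.na(expressed)]
    stop("genes missing a call: ", paste(head(bad, 5), collapse = ", "))
  }
  new_contingency(
    a = sum(bound & expressed), b = sum(bound & !expressed),
    c = sum(!bound & expressed), d = sum(!bound & !expressed),
    condition = condition
  )
}

as_contingency <- function(x) {
  if (inherits(x, "acechip_contingency")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(new_contingency(x[1], x[2], x[3], x[4]))
  }
  stop("expected an acechip_contingency or a numeric vector c(a, b, c, d)")
}

#' Odds ratio with Wald confidence interval and exact test
#'
#' Completes a 2x2 binding-by-expression table with the cross-product
#' odds ratio `ad/bc`, the Wald interval on the log odds ratio
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, and a two-sided
#' exact p-value (Fisher; a chi-square test is available behind
#' `method`). With any zero cell the Haldane +0.5 correction is applied
#' to all four cells for the OR and CI only, and the result is flagged;
#' the exact p is computed on the uncorrected counts.
#'
#' @param table An `acechip_contingency` or numeric `c(a, b, c, d)`.
#' @param ci_level Confidence level in (0,1), default 0.99.
#' @param method `"fisher"` (default) or `"chisq"` for the p-value.
#' @return The completed `acechip_contingency` with `odds_ratio`,
#'   `ci_level`, `ci_low`, `ci_high`, `p_exact`, `haldane`.
#' @export
#' @examples
#' res <- odds_ratio_ci(c(4171, 304, 4484, 3860))
#' round(res$odds_ratio, 1) # 11.8
#' round(c(res$ci_low, res$ci_high), 1) # 10.0 13.9
odds_ratio_ci <- function(table, ci_level = 0.99,
                          method = c("fisher", "chisq")) {
  method <- match.arg(method)
  tab <- as_contingency(table)
  stopifnot(ci_level > 0, ci_level < 1,
            tab$a >= 0, tab$b >= 0, tab$c >= 0, tab$d >= 0)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  haldane <- any(cells == 0)
  w <- if (haldane) cells + 0.5 else cells
  or <- (w[1] * w[4]) / (w[2] * w[3])
  se <- sqrt(sum(1 / w))
  z <- qnorm((1 + ci_level) / 2)
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- if (method == "fisher") {
    fisher.test(m)$p.value
  } else {
    chisq.test(m, correct = FALSE)$p.value
  }
  tab$odds_ratio <- or
  tab$ci_level <- ci_level
  tab$ci_low <- or * exp(-z * se)
  tab$ci_high <- or * exp(z * se)
  tab$p_exact <- p
  tab$haldane <- haldane
  tab
}

#' @export
print.acechip_contingency <- function(x, ...) {
  cond <- if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")
  cat("bound-by-expressed 2x2 table", cond, "\n", sep = "")
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("bound", "not bound"),
                              c("expressed", "not expressed")))
  print(m)
  if (!is.null(x$odds_ratio)) {
    # display convention mirrors the usual p-value floor
    p_disp <- if (x$p_exact < 2.2e-16) "< 2.2e-16" else format(x$p_exact)
    cat(sprintf("odds ratio = %.1f, %d%% CI = %.1f, %.1f, p %s%s\n",
                x$odds_ratio, round(100 * x$ci_level), x$ci_low, x$ci_high,
                p_disp, if (isTRUE(x$haldane)) " [Haldane-corrected]" else ""))
  }
  invisible(x)
}

#' Fraction of bound genes that are expressed
#'
#' `100 * a / (a + b)`: the percentage of acetylation-marked genes whose
#' transcript is present. The raw value is retained; the display value is
#' rounded to the nearest integer.
#'
#' @param table An `acechip_contingency` or numeric `c(a, b, c, d)`.
#' @return List: `raw` percent, `display` (rounded), `defined` (FALSE
#'   when no gene is bound).
#' @export
#' @examples
#' fraction_bound_expressed(c(4171, 304, 4484, 3860))$display # 93
fraction_bound_expressed <- function(table) {
  tab <- as_contingency(table)
  if (tab$a + tab$b == 0) {
    return(list(raw = NA_real_, display = NA_real_, defined = FALSE))
  }
  raw <- 100 * tab$a / (tab$a + tab$b)
  list(raw = raw, display = round(raw), defined = TRUE)
}

#' Binding signature by expression status
#'
#' Cross-tabulates the binding-signature labels of bound genes against
#' expressed/not-expressed; marginals agree with [signature_census()] and
#' the expression totals over bound genes.
#'
#' @inheritParams bound_by_expressed_table
#' @return Data frame: signature, expressed, not_expressed.
#' @export
signature_by_expression <- function(profiles, expression_calls, condition) {
  condition <- match_condition(condition)
  ec <- expression_calls[expression_calls$condition == condition, , drop = FALSE]
  common <- common_gene_set(profiles$gene_id, ec$gene_id)
  prof <- profiles[match(common, profiles$gene_id), , drop = FALSE]
  expressed <- ec$expressed[match(common, ec$gene_id)]
  bound <- prof$n_bound >= 1L
  lab <- signature_label(prof$signature[bound])
  ex <- expressed[bound]
  labs <- unique(lab)
  out <- data.frame(
    signature = labs,
    expressed = vapply(labs, function(l) sum(lab == l & ex), integer(1)),
    not_expressed = vapply(labs, function(l) sum(lab == l & !ex), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-(out$expressed + out$not_expressed)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression by differential acetylation
#'
#' For each differential-expression direction (UP, DOWN), counts genes
#' per differential-acetylation category with percentages, plus the
#' convenience aggregate "decreased acetylation" = hypoacetylated +
#' not-acetylated-in-TG.
#'
#' @param de_records From [de_call_table()].
#' @param records From [differential_acetylation_table()].
#' @return Data frame: de_status, category, n_genes, percent;
#'   attribute `decreased_acetylation_share` gives the aggregate percent
#'   per direction. Empty when there are no DE genes (with a warning).
#' @export
de_by_diffacet <- function(de_records, records) {
  common <- intersect(de_records$gene_id, records$gene_id)
  de <- de_records[match(common, de_records$gene_id), , drop = FALSE]
  cat_ <- records$category[match(common, records$gene_id)]
  out <- list(); shares <- c()
  for (dir in c("UP", "DOWN")) {
    sel <- de$de_status == dir
    n_dir <- sum(sel)
    if (n_dir == 0L) next
    f <- factor(cat_[sel], levels = DIFFACET_CATEGORIES)
    counts <- as.integer(table(f))
    out[[dir]] <- data.frame(
      de_status = dir, category = DIFFACET_CATEGORIES, n_genes = counts,
      percent = 100 * counts / n_dir, stringsAsFactors = FALSE
    )
    dec <- sum(counts[DIFFACET_CATEGORIES %in%
                        c("HYPOACETYLATED_IN_TG", "NOT_ACETYLATED_IN_TG")])
    shares[dir] <- 100 * dec / n_dir
  }
  if (length(out) == 0L) {
    warning("no differentially expressed genes")
    res <- data.frame(de_status = character(0), category = character(0),
                      n_genes = integer(0), percent = numeric(0))
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  attr(res, "decreased_acetylation_share") <- shares
  res
}
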