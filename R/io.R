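#' @importFrom utils read.delim write.table head
NULL

# The two study conditions used throughout: wild-type and transgenic.
CONDITIONS <- c("WT", "TG")

# Probe location classes as annotated on the promoter array.
PROBE_TYPES <- c("Promoter", "Inside", "Downstream", "DivergentPromoter",
                 "Unknown")

match_condition <- function(condition) {
  match.arg(toupper(condition), CONDITIONS)
}

signal_cols <- function(df, condition) {
  grep(sprintf("^signal_%s_[0-9]+$", condition), names(df), value = TRUE)
}

pvalue_col <- function(condition) sprintf("pvalue_%s", condition)

#' Replicate-mean probe signal
#'
#' The working signal for a probe in a condition is the arithmetic mean of
#' its replicate log2(IP/WCE) ratios.
#'
#' @param probes Probe table (see [read_probe_table()]).
#' @param condition `"WT"` or `"TG"`.
#' @return Numeric vector, one value per probe.
#' @export
probe_signal_mean <- function(probes, condition) {
  condition <- match_condition(condition)
  cols <- signal_cols(probes, condition)
  if (length(cols) == 0L) {
    stop("no signal columns found for condition ", condition)
  }
  rowMeans(as.matrix(probes[, cols, drop = FALSE]))
}

# ---- low-level table writing/reading -------------------------------------
# Numeric columns are serialised with %.17g so that a write/read cycle
# reproduces doubles exactly; missing values are ".".

format_field <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- sprintf("%.17g", x)
  } else if (is.logical(x)) {
    out <- ifelse(x, "TRUE", "FALSE")
  } else {
    out <- as.character(x)
  }
  out[is.na(x) | out == ""] <- "."
  out
}

write_tsv_header <- function(df, path, header_lines) {
  cols <- lapply(df, format_field)
  body <- if (nrow(df) == 0L) character(0) else do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header_lines, paste(names(df), collapse = "\t"), body), path)
}

read_tsv_header <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  n_skip <- match(FALSE, is_comment) - 1L
  if (is.na(n_skip) || n_skip >= length(lines)) {
    stop("no table found in ", path)
  }
  header <- strsplit(lines[n_skip + 1L], "\t", fixed = TRUE)[[1]]
  data_lines <- lines[-seq_len(n_skip + 1L)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)), header),
                        check.names = FALSE)
    return(list(table = df, line_numbers = integer(0)))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("line %d of %s has %d fields, expected %d",
                 bad + n_skip + 1L, path, nf[bad], length(header)))
  }
  mat <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[df == "."] <- NA
  list(table = df, line_numbers = seq_along(data_lines) + n_skip + 1L)
}

# Convert character columns to numeric, reporting the file line of the
# first unparseable value.
coerce_numeric <- function(df, cols, line_numbers, path) {
  for (col in cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   raw[bad[1]], col, line_numbers[bad[1]], path))
    }
    df[[col]] <- val
  }
  df
}

require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
}

# ---- probe table ---------------------------------------------------------

#' Read a probe-level ChIP-chip results table
#'
#' Tab-delimited with a header row and optional `#` provenance comments.
#' Required columns: `probe_id`, `gene_id`, `chromosome`, `start`, `end`,
#' `probe_type`, per-condition replicate signal columns
#' (`signal_WT_1`, `signal_WT_2`, ..., `signal_TG_1`, ...) and per-condition
#' p-value columns (`pvalue_WT`, `pvalue_TG`). Coordinates are 0-based
#' half-open. Missing values are ".".
#'
#' @param path TSV file.
#' @return A validated probe `data.frame`.
#' @details Duplicate probe ids are an error. Probe-type strings outside
#'   the known vocabulary are mapped to `"Unknown"` with a warning.
#'   P-values outside `[0, 1]` and non-numeric signals are parse errors
#'   reporting the offending line.
#' @export
read_probe_table <- function(path) {
  parsed <- read_tsv_header(path)
  df <- parsed$table
  ln <- parsed$line_numbers
  required <- c("probe_id", "gene_id", "chromosome", "start", "end",
                "probe_type", "pvalue_WT", "pvalue_TG")
  require_columns(df, required, path)
  sig <- unlist(lapply(CONDITIONS, function(cc) signal_cols(df, cc)))
  if (length(sig) == 0L) {
    stop("missing required column(s) in ", path,
         ": signal_<condition>_<replicate>")
  }
  num_cols <- c("start", "end", sig, pvalue_col("WT"), pvalue_col("TG"))
  df <- coerce_numeric(df, num_cols, ln, path)
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0L) {
    stop("duplicate probe_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  for (cc in CONDITIONS) {
    p <- df[[pvalue_col(cc)]]
    bad <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad) > 0L) {
      stop(sprintf("p-value %g outside [0,1] in column '%s' at line %d of %s",
                   p[bad[1]], pvalue_col(cc), ln[bad[1]], path))
    }
  }
  unknown <- !(df$probe_type %in% PROBE_TYPES)
  if (any(unknown)) {
    warning(sum(unknown), " probe(s) with unrecognised probe_type mapped ",
            "to Unknown")
    df$probe_type[unknown] <- "Unknown"
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write a probe table
#'
#' Inverse of [read_probe_table()]; prepends provenance header comments
#' recording the thresholds and seed of `config`.
#'
#' @param probes Probe `data.frame`.
#' @param path Output TSV path.
#' @param config An `acechip_config` ([run_config()]).
#' @export
write_probe_table <- function(probes, path, config = run_config()) {
  write_tsv_header(probes, path, config_header(config, "probe table"))
  invisible(path)
}

# ---- gene annotation -----------------------------------------------------

#' Read gene annotation (chromosome, strand, TSS, TES)
#'
#' Coordinates are transcription-oriented: `tss` is the transcriptional
#' start (+1) and `tes` the end, so `tss > tes` on the minus strand.
#'
#' @param path TSV with columns `gene_id`, `chromosome`, `strand`,
#'   `tss`, `tes`.
#' @return Annotation `data.frame`.
#' @export
read_annotation_table <- function(path) {
  parsed <- read_tsv_header(path)
  df <- parsed$table
  require_columns(df, c("gene_id", "chromosome", "strand", "tss", "tes"), path)
  df <- coerce_numeric(df, c("tss", "tes"), parsed$line_numbers, path)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' in ", path)
  }
  if (any(df$tss == df$tes)) stop("tss == tes for some gene in ", path)
  # normalise to transcription orientation if supplied as plain intervals
  flip <- (df$strand == "-" & df$tss < df$tes) |
    (df$strand == "+" & df$tss > df$tes)
  if (any(flip)) {
    tmp <- df$tss[flip]
    df$tss[flip] <- df$tes[flip]
    df$tes[flip] <- tmp
  }
  df$tss <- as.integer(df$tss)
  df$tes <- as.integer(df$tes)
  df
}

#' @rdname read_annotation_table
#' @param annotation Annotation `data.frame`.
#' @param config An `acechip_config`.
#' @export
write_annotation_table <- function(annotation, path, config = run_config()) {
  write_tsv_header(annotation, path, config_header(config, "gene annotation"))
  invisible(path)
}

# ---- expression table ----------------------------------------------------

#' Read a gene-level expression table
#'
#' Long format: one row per gene and condition with columns `gene_id`,
#' `condition` and per-sample expression values `value_1 ... value_k`
#' (already normalised; probeset-level inputs should be averaged with
#' [gene_expression_value()] upstream).
#'
#' @param path TSV file.
#' @return Expression `data.frame`.
#' @export
read_expression_table <- function(path) {
  parsed <- read_tsv_header(path)
  df <- parsed$table
  require_columns(df, c("gene_id", "condition"), path)
  vals <- grep("^value_[0-9]+$", names(df), value = TRUE)
  if (length(vals) == 0L) {
    stop("missing required column(s) in ", path, ": value_<sample>")
  }
  df <- coerce_numeric(df, vals, parsed$line_numbers, path)
  if (!all(df$condition %in% CONDITIONS)) {
    stop("condition must be one of ", paste(CONDITIONS, collapse = "/"),
         " in ", path)
  }
  df
}

#' @rdname read_expression_table
#' @param expression Expression `data.frame`.
#' @param config An `acechip_config`.
#' @export
write_expression_table <- function(expression, path, config = run_config()) {
  write_tsv_header(expression, path, config_header(config, "expression table"))
  invisible(path)
}

# ---- truth table ---------------------------------------------------------

#' Read/write the simulation ground-truth table
#'
#' One row per gene and condition: `truly_bound`, `truly_expressed`,
#' comma-joined `bound_probe_ids`, and the pairwise `true_de` direction.
#'
#' @param path TSV file.
#' @return Truth `data.frame`.
#' @export
read_truth_table <- function(path) {
  parsed <- read_tsv_header(path)
  df <- parsed$table
  require_columns(df, c("gene_id", "condition", "truly_bound",
                        "truly_expressed", "bound_probe_ids", "true_de"), path)
  df$truly_bound <- df$truly_bound == "TRUE"
  df$truly_expressed <- df$truly_expressed == "TRUE"
  df$bound_probe_ids[is.na(df$bound_probe_ids)] <- ""
  df
}

#' @rdname read_truth_table
#' @param truth Truth `data.frame`.
#' @param config An `acechip_config`.
#' @export
write_truth_table <- function(truth, path, config = run_config()) {
  truth$bound_probe_ids[truth$bound_probe_ids == ""] <- NA
  write_tsv_header(truth, path, config_header(config, "truth table"))
  invisible(path)
}

# ---- BED export ----------------------------------------------------------

#' Export bound probes as a BED6 track
#'
#' Writes one BED6 line per bound probe (0-based half-open coordinates),
#' name = probe id, score = `round(1000 * min(1, mean_log2_ratio / 3))`
#' clamped to `[0, 1000]`, strand ".". A `track` header line is always
#' written, so a condition with zero bound probes yields a header-only
#' file.
#'
#' @param probes Probe table.
#' @param condition `"WT"` or `"TG"`.
#' @param path Output BED path.
#' @param bound_probe_ids Ids of bound probes, e.g. from
#'   [call_bound_probes()].
#' @export
write_bed <- function(probes, condition, path, bound_probe_ids) {
  condition <- match_condition(condition)
  ok <- grepl("^chr([0-9]+|[XYM])$", unique(probes$chromosome))
  if (!all(ok)) {
    stop("unsortable chromosome names: ",
         paste(unique(probes$chromosome)[!ok], collapse = ", "))
  }
  sel <- probes[probes$probe_id %in% bound_probe_ids, , drop = FALSE]
  header <- sprintf(
    'track name="AcH3_bound_%s" description="AcH3-bound probes (%s)"',
    condition, condition)
  if (nrow(sel) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- round(1000 * pmin(1, pmax(0, probe_signal_mean(sel, condition) / 3)))
  chr_rank <- function(chr) {
    key <- sub("^chr", "", chr)
    num <- suppressWarnings(as.integer(key))
    num[key == "X"] <- 100L
    num[key == "Y"] <- 101L
    num[key == "M"] <- 102L
    num
  }
  ord <- order(chr_rank(sel$chromosome), sel$start)
  sel <- sel[ord, , drop = FALSE]
  score <- score[ord]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   sel$chromosome, sel$start, sel$end, sel$probe_id, score)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Percentage ratio of two counts
#'
#' Small reporting helper for printed count ratios such as
#' bound-probe and bound-gene totals between conditions.
#'
#' @param numerator,denominator Non-negative counts, `denominator > 0`.
#' @param digits Decimal places for the rounded display value.
#' @return List with `raw` (percent) and `display` (rounded percent).
#' @export
#' @examples
#' ratio_percent(5542, 10187)$display # 54.4
ratio_percent <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0, numerator >= 0)
  raw <- 100 * numerator / denominator
  list(raw = raw, display = round(raw, digits))
}
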