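# Delimited-table I/O. All score inputs/outputs are plain CSV/TSV with a
# header row; the dialect is auto-detected from the header line (tab wins if
# present, comma otherwise). Drug names are canonicalized on read.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, required, sep = NULL, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a table of raw connectivity/inhibition scores
#'
#' One row per (drug, tool, method, dataset, stage) observation, `score` in
#' \[-1, 1\] where negative means the drug reverses the disease signature.
#' Row order is preserved; drug names are canonicalized; duplicate keys after
#' canonicalization are an error (they would double-count in aggregation).
#'
#' @param path CSV or TSV file with columns `drug, tool, method, dataset,
#'   stage, score`.
#' @return data.frame with those six columns, scores numeric.
#' @seealso [filter_qualifying()], [aggregate_inhibition()]
#' @export
read_drug_scores <- function(path) {
  df <- read_delim_checked(path,
    c("drug", "tool", "method", "dataset", "stage", "score"))
  df$score <- as.numeric(df$score)
  bad <- which(is.na(df$score) | df$score < -1 | df$score > 1)
  if (length(bad) > 0L) {
    stop("score out of [-1, 1] at row ", bad[1L], " of ", path, call. = FALSE)
  }
  df$drug <- canonicalize_drug_name(df$drug)
  key <- paste(df$drug, df$tool, df$method, df$dataset, df$stage, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (drug, tool, method, dataset, stage) key at row ",
         dup[1L], " of ", path, call. = FALSE)
  }
  df[, c("drug", "tool", "method", "dataset", "stage", "score")]
}

# round half up at `digits` decimals (tables print 3 d.p. half-up)
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a score table with fixed rendered precision
#'
#' Real-valued columns are rendered at 3 decimal places (half-up, the
#' precision of the published tables) and each is accompanied by a
#' `<name>_full` column carrying full machine precision, so rounding never
#' propagates through a round-trip. Integer and character columns pass
#' through unchanged.
#'
#' @param records nonempty data.frame (e.g. component scores or a ranked
#'   table from [score_stage()]).
#' @param path output file; extension `.tsv` selects tabs, anything else
#'   commas.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a nonempty data.frame", call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- list()
  for (nm in names(records)) {
    col <- records[[nm]]
    if (is.double(col)) {
      out[[nm]] <- formatC(round_half_up(col, 3L), format = "f", digits = 3L)
      out[[paste0(nm, "_full")]] <- formatC(col, format = "g", digits = 17L)
    } else {
      out[[nm]] <- col
    }
  }
  utils::write.table(as.data.frame(out, stringsAsFactors = FALSE), path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_score_table()]
#'
#' Restores full machine precision from the `*_full` columns and drops the
#' rendered 3-decimal ones.
#'
#' @param path file produced by [write_score_table()].
#' @return data.frame with the original columns.
#' @export
read_score_table <- function(path) {
  df <- read_delim_checked(path, character())
  full <- grep("_full$", names(df), value = TRUE)
  for (nm in full) {
    base <- sub("_full$", "", nm)
    df[[base]] <- as.numeric(df[[nm]])
    df[[nm]] <- NULL
  }
  for (nm in names(df)) {
    if (is.integer(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
  }
  df
}

#' Read a differential-expression table
#'
#' Expects columns `gene`, `p_value` and either `logFC` (signed, log scale)
#' or `FC` plus `scale = "ratio"` declared by the caller, in which case the
#' ratio is converted to log2 (values must be positive). Positive fold change
#' means up-regulated.
#'
#' @param path CSV/TSV file.
#' @param scale `"log"` (default) if the fold-change column is already
#'   signed log-scale, `"ratio"` to log2-transform an `FC` ratio column.
#' @return data.frame with columns `gene`, `fold_change`, `p_value`.
#' @export
read_deg_table <- function(path, scale = c("log", "ratio")) {
  scale <- match.arg(scale)
  df <- read_delim_checked(path, c("gene", "p_value"))
  fc_col <- intersect(c("logFC", "FC", "fold_change"), names(df))
  if (length(fc_col) == 0L) {
    stop("no fold-change column (logFC/FC/fold_change) in ", path,
         call. = FALSE)
  }
  fc <- as.numeric(df[[fc_col[1L]]])
  if (scale == "ratio") {
    if (any(fc <= 0, na.rm = TRUE)) {
      stop("ratio-scale fold changes must be positive", call. = FALSE)
    }
    fc <- log2(fc)
  }
  p <- as.numeric(df$p_value)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("p_value outside [0, 1] in ", path, call. = FALSE)
  }
  data.frame(gene = as.character(df$gene), fold_change = fc, p_value = p,
             stringsAsFactors = FALSE)
}

#' Read druglikeness rule-violation counts
#'
#' @param path CSV/TSV with columns `drug, violations` (non-negative
#'   integers, as reported by a property-prediction tool).
#' @return data.frame with canonical `drug` and integer `violations`.
#' @export
read_violations <- function(path) {
  df <- read_delim_checked(path, c("drug", "violations"))
  v <- as.numeric(df$violations)
  bad <- which(is.na(v) | v < 0 | v != floor(v))
  if (length(bad) > 0L) {
    stop("violations must be non-negative integers (row ", bad[1L], ")",
         call. = FALSE)
  }
  data.frame(drug = canonicalize_drug_name(df$drug),
             violations = as.integer(v), stringsAsFactors = FALSE)
}

#' Read per-drug functional (gene-target enrichment) evidence
#'
#' Long format: one row per (drug, gene) with an enrichment `score` in
#' \[0, 1\]. A drug absent from the file, or present with no rows, has an
#' empty score list and a functional mean of 0 downstream.
#'
#' @param path CSV/TSV with columns `drug, gene, score`.
#' @return named list mapping canonical drug to its numeric score vector.
#' @export
read_functional <- function(path) {
  df <- read_delim_checked(path, c("drug", "score"))
  s <- as.numeric(df$score)
  bad <- which(is.na(s) | s < 0 | s > 1)
  if (length(bad) > 0L) {
    stop("functional scores must lie in [0, 1] (row ", bad[1L], ")",
         call. = FALSE)
  }
  split(s, canonicalize_drug_name(df$drug))
}

#' Read side-effect severity profiles
#'
#' @param path CSV/TSV with columns `drug, c1..c8, unknown` where `c<i>` is
#'   the count of side effects in severity class i (class weight = i) and
#'   `unknown` is TRUE/1 when no side-effect information exists for the drug.
#' @return data.frame with canonical `drug`, integer columns `c1..c8`,
#'   logical `unknown`.
#' @export
read_side_effects <- function(path) {
  classes <- paste0("c", 1:8)
  df <- read_delim_checked(path, c("drug", classes, "unknown"))
  out <- data.frame(drug = canonicalize_drug_name(df$drug),
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    v <- as.numeric(df[[cl]])
    if (any(is.na(v) | v < 0 | v != floor(v))) {
      stop("side-effect counts must be non-negative integers (column ", cl,
           ")", call. = FALSE)
    }
    out[[cl]] <- as.integer(v)
  }
  out$unknown <- as.logical(df$unknown)
  if (any(is.na(out$unknown))) stop("unknown flag must be logical",
                                    call. = FALSE)
  out
}

#' Read binary molecular fingerprints
#'
#' @param path CSV/TSV with columns `drug, bits`, `bits` a 0/1 string; all
#'   rows must share one length.
#' @return named list of integer 0/1 vectors keyed by canonical drug name.
#' @export
read_fingerprints <- function(path) {
  df <- read_delim_checked(path, c("drug", "bits"), colClasses = "character")
  bits <- lapply(strsplit(as.character(df$bits), ""), function(ch) {
    v <- match(ch, c("0", "1")) - 1L
    if (any(is.na(v))) stop("fingerprint bits must be 0/1", call. = FALSE)
    v
  })
  if (length(unique(lengths(bits))) > 1L) {
    stop("all fingerprints must share one bit length", call. = FALSE)
  }
  names(bits) <- canonicalize_drug_name(df$drug)
  bits
}

#' Read a pathway list (one pathway name per line)
#'
#' Names are normalized to lowercase and trimmed; duplicates collapse (set
#' semantics).
#'
#' @param path plain-text file, one pathway per line.
#' @return character vector of normalized pathway names.
#' @export
read_pathway_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x <- gsub("[[:space:]]+", " ", tolower(trimws(x)))
  unique(x[x != ""])
}

#' Read entity-to-gene target sets
#'
#' Long format linking drugs and microRNAs to their target genes, used by the
#' common-target analysis.
#'
#' @param path CSV/TSV with columns `entity, entity_kind, gene` and optional
#'   `direction` (miRNA rows: `inhibits_disease`, `induces_disease` or
#'   `unknown`).
#' @return data.frame with those columns (direction `"unknown"` if absent).
#' @export
read_target_sets <- function(path) {
  df <- read_delim_checked(path, c("entity", "entity_kind", "gene"))
  kind <- as.character(df$entity_kind)
  if (!all(kind %in% c("drug", "mirna"))) {
    stop("entity_kind must be 'drug' or 'mirna'", call. = FALSE)
  }
  direction <- if ("direction" %in% names(df)) {
    as.character(df$direction)
  } else {
    rep("unknown", nrow(df))
  }
  out <- data.frame(entity = as.character(df$entity), entity_kind = kind,
                    gene = as.character(df$gene), direction = direction,
                    stringsAsFactors = FALSE)
  unique(out)
}
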