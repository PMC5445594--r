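#' Construct an expression matrix object
#'
#' The central container of the pipeline: a dense genes x samples matrix of
#' expression values with per-sample tissue labels and a scale flag recording
#' whether values are raw intensities or log2.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   row and column names set to gene and sample identifiers.
#' @param tissue named character vector mapping every sample id to a tissue
#'   label, or a single unnamed label shared by all samples.
#' @param scale one of `"raw"` or `"log2"`.
#' @param allow_missing if `FALSE` (default) any non-finite value is an error.
#' @return An object of class `expr_matrix` with elements `values`, `tissue`
#'   and `scale`.
#' @export
expression_matrix <- function(values, tissue = "unspecified",
                              scale = c("raw", "log2"),
                              allow_missing = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!allow_missing && !all(is.finite(values)))
    stop("expression matrix contains non-finite values ",
         "(set allow_missing = TRUE to permit)")
  if (length(tissue) == 1L && is.null(names(tissue)))
    tissue <- stats::setNames(rep(tissue, ncol(values)), colnames(values))
  missing_lab <- setdiff(colnames(values), names(tissue))
  if (length(missing_lab))
    stop("samples without a tissue label: ",
         paste(utils::head(missing_lab, 5), collapse = ", "))
  structure(
    list(values = values,
         tissue = tissue[colnames(values)],
         scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale], %d tissue(s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$tissue))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param m an `expr_matrix`.
#' @param genes,samples character vectors of identifiers (default: keep all).
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  if (!is.null(samples)) v <- v[, intersect(samples, colnames(v)), drop = FALSE]
  expression_matrix(v, m$tissue[colnames(v)], scale = m$scale,
                    allow_missing = TRUE)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: first column gene ids, header row sample ids. GCT 1.2: a
#' `#1.2` version line, a dimensions line, then a header with `Name`,
#' `Description` and sample columns. Duplicate gene ids are collapsed by the
#' mean of their rows, with a warning.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"gct"`; guessed from the extension when missing.
#' @param tissue_map_path optional two-column TSV (sample_id, tissue).
#' @param scale scale flag to record, `"raw"` by default.
#' @param allow_missing permit NA cells.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            tissue_map_path = NULL,
                            scale = c("raw", "log2"),
                            allow_missing = FALSE) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"

  if (format == "gct") {
    lines <- readLines(path, n = 2L)
    if (length(lines) < 2L || !grepl("^#1\\.2", lines[1]))
      stop("malformed GCT header: expected '#1.2' version line in ", path)
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    df <- df[, -(1:2), drop = FALSE] # drop Name, Description
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("malformed header in ", path,
           ": need a gene-id column plus at least one sample column")
    gene_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }

  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                     bad[1], colnames(df)[j], path))
      df[[j]] <- num
    }
  }
  values <- as.matrix(df)
  rownames(values) <- gene_ids

  if (anyDuplicated(gene_ids)) {
    ndup <- sum(duplicated(gene_ids))
    warning(ndup, " duplicate gene id(s) collapsed by mean")
    values <- rowsum(values, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }

  tissue <- "unspecified"
  if (!is.null(tissue_map_path)) {
    tm <- utils::read.delim(tissue_map_path, stringsAsFactors = FALSE)
    tissue <- stats::setNames(as.character(tm[[2]]), as.character(tm[[1]]))
  }
  expression_matrix(values, tissue, scale = scale,
                    allow_missing = allow_missing)
}

#' Write an expression matrix as TSV
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a drug response table
#'
#' Long-format sensitivity records: one row per (sample, drug) pair carrying
#' the sensitivity value (IC50 in micromolar or a dose-response AUC) and the
#' metric name.
#'
#' @param sample_id,drug_id character vectors.
#' @param value numeric sensitivity values; must be finite.
#' @param metric per-record metric flag, `"IC50"` or `"AUC"`.
#' @return A `data.frame` of class `drug_response`.
#' @export
drug_response_table <- function(sample_id, drug_id, value,
                                metric = "IC50") {
  if (!all(is.finite(value))) stop("sensitivity values must be finite")
  d <- data.frame(sample_id = as.character(sample_id),
                  drug_id = as.character(drug_id),
                  value = as.numeric(value),
                  metric = as.character(metric),
                  stringsAsFactors = FALSE)
  spread <- tapply(d$value, d$drug_id, function(v) length(unique(v)))
  flat <- names(spread)[spread < 2L]
  if (length(flat))
    stop("drug(s) with fewer than 2 distinct sensitivity values: ",
         paste(flat, collapse = ", "))
  class(d) <- c("drug_response", "data.frame")
  d
}

#' Read a long-format drug response TSV
#'
#' Expected columns: `sample_id`, `drug_id`, `value` and optionally `metric`.
#'
#' @param path path to the TSV.
#' @return A [drug_response_table()].
#' @export
read_drug_response <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "drug_id", "value")
  if (!all(need %in% colnames(df)))
    stop("drug response TSV must have columns: ",
         paste(need, collapse = ", "))
  drug_response_table(df$sample_id, df$drug_id, df$value,
                      metric = if ("metric" %in% colnames(df)) df$metric
                               else "IC50")
}

#' Construct a gene signature
#'
#' A signature is a sparse set of signed gene weights (mean log2 fold change,
#' responder minus non-responder) together with the thresholds that produced
#' it and its training ROC AUC.
#'
#' @param weights named numeric vector of nonzero gene weights.
#' @param thresholds list with elements `p`, `fc` (ratio scale, >= 1) and
#'   `conservation` (in (0, 1]).
#' @param training_auc training ROC AUC in \[0.5, 1\], or `NA` if not yet
#'   evaluated.
#' @param provenance free-form list of metadata (drugs, tissues, seed, ...).
#' @return An object of class `signature`.
#' @export
signature <- function(weights, thresholds = list(p = NA_real_, fc = NA_real_,
                                                 conservation = NA_real_),
                      training_auc = NA_real_, provenance = list()) {
  if (length(weights) == 0L) stop("signature must contain at least one gene")
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("weights must be uniquely named by gene id")
  if (any(weights == 0)) stop("signature weights must be nonzero")
  if (!is.na(training_auc) &&
      (training_auc < 0.5 || training_auc > 1))
    stop("training_auc of a selected signature must lie in [0.5, 1]")
  structure(list(weights = weights,
                 thresholds = thresholds,
                 training_auc = training_auc,
                 provenance = provenance),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d genes (%d up, %d down), training AUC %s\n",
              length(x$weights), sum(x$weights > 0), sum(x$weights < 0),
              ifelse(is.na(x$training_auc), "NA",
                     sprintf("%.3f", x$training_auc))))
  cat(sprintf("  thresholds: p < %s, fold change > %s, conservation >= %s\n",
              format(x$thresholds$p), format(x$thresholds$fc),
              format(x$thresholds$conservation)))
  invisible(x)
}

#' Write / read a signature
#'
#' The canonical serialization is JSON (weights at full precision, thresholds,
#' training AUC, provenance). `write_signature` also drops a two-column
#' gene/weight TSV next to the JSON for interoperability.
#'
#' @param sig a [signature()].
#' @param path output JSON path; the TSV export replaces the extension with
#'   `.tsv` (or appends it).
#' @param tsv whether to also write the TSV export (default `TRUE`).
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the reconstructed `signature`.
#' @export
write_signature <- function(sig, path, tsv = TRUE) {
  stopifnot(inherits(sig, "signature"))
  payload <- list(
    weights = as.list(sig$weights),
    thresholds = sig$thresholds,
    training_auc = sig$training_auc,
    provenance = sig$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (tsv) {
    tsv_path <- sub("\\.json$", ".tsv", path)
    if (tsv_path == path) tsv_path <- paste0(path, ".tsv")
    utils::write.table(
      data.frame(gene_id = names(sig$weights), weight = unname(sig$weights)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("weights", "thresholds"))
    if (is.null(obj[[field]]))
      stop("invalid signature file: missing field '", field, "'")
  w <- unlist(obj$weights)
  thr <- lapply(obj$thresholds, function(v) if (is.null(v)) NA_real_ else v)
  signature(w, thresholds = thr,
            training_auc = if (is.null(obj$training_auc)) NA_real_
                           else obj$training_auc,
            provenance = if (is.null(obj$provenance)) list()
                         else as.list(obj$provenance))
}

#' Read a patient survival table
#'
#' Expected TSV columns: `id`, `time`, `event` and optionally `score`,
#' `stage`, `grade`. Times must be positive; events coded 0 (censored) or 1.
#'
#' @param path path to the TSV.
#' @return A validated `data.frame` of class `survival_table`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  survival_table(df)
}

#' @rdname read_survival_table
#' @param df a data frame with the columns described above.
#' @export
survival_table <- function(df) {
  need <- c("id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write / read a resampling archive as long TSV
#'
#' The archive is flattened to (iteration, gene, p, log2_fc) rows; the
#' per-iteration group sizes and metadata travel in a comment header.
#'
#' @param archive a `resampling_archive` from [run_resampling()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `write_archive` returns `path` invisibly; `read_archive` rebuilds
#'   the archive object.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "resampling_archive"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# seed=", archive$seed),
    paste0("# fraction=", archive$fraction),
    paste0("# skipped=", archive$skipped),
    paste0("# n_resp=", paste(archive$n_resp, collapse = ",")),
    paste0("# n_nonresp=", paste(archive$n_nonresp, collapse = ","))
  ), con)
  it <- ncol(archive$p)
  df <- data.frame(
    iteration = rep(seq_len(it), each = nrow(archive$p)),
    gene = rep(rownames(archive$p), times = it),
    p = as.vector(archive$p),
    log2_fc = as.vector(archive$log2_fc)
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) {
      pushBack(line, con)
      break
    }
    hdr <- c(hdr, line)
  }
  meta <- function(key, split = FALSE) {
    m <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                               hdr, value = TRUE))
    if (!length(m)) return(NULL)
    if (split) as.numeric(strsplit(m, ",")[[1]]) else as.numeric(m)
  }
  df <- utils::read.delim(con, stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  it <- max(df$iteration)
  p <- matrix(df$p, nrow = length(genes), ncol = it,
              dimnames = list(genes, NULL))
  fc <- matrix(df$log2_fc, nrow = length(genes), ncol = it,
               dimnames = list(genes, NULL))
  structure(list(p = p, log2_fc = fc,
                 n_resp = meta("n_resp", split = TRUE),
                 n_nonresp = meta("n_nonresp", split = TRUE),
                 genes = genes,
                 seed = meta("seed"), fraction = meta("fraction"),
                 skipped = meta("skipped")),
            class = "resampling_archive")
}
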