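#' Survival cohort container
#'
#' Bundles the classic survival-analysis triplet for a transcriptomic cohort:
#' an expression matrix `X` (samples x genes, log2 scale after normalization),
#' observed follow-up times in days, and 0/1 event indicators (1 = deceased,
#' 0 = right-censored at last follow-up).
#'
#' @param X numeric matrix, n samples x p genes.
#' @param time numeric vector of n positive durations (days).
#' @param event integer/numeric vector of n indicators in \{0, 1\}.
#' @param subject_ids character vector of n unique identifiers.
#' @param genes character vector of p unique gene symbols.
#' @param cohort_label free-text label, e.g. `"OV"`.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(X, time, event, subject_ids = NULL, genes = NULL,
                            cohort_label = "cohort") {
  X <- as.matrix(X)
  n <- nrow(X)
  subject_ids <- subject_ids %||% rownames(X) %||% sprintf("S%04d", seq_len(n))
  genes <- genes %||% colnames(X) %||% sprintf("G%04d", seq_len(ncol(X)))
  if (length(time) != n || length(event) != n)
    stopf("time/event length (%d/%d) does not match nrow(X) = %d",
          length(time), length(event), n)
  if (anyNA(X)) stopf("expression matrix contains missing values")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0 or 1")
  if (any(time <= 0)) stopf("all follow-up times must be positive")
  if (anyDuplicated(genes)) stopf("gene list contains duplicates")
  if (anyDuplicated(subject_ids)) stopf("subject ids contain duplicates")
  rownames(X) <- subject_ids
  colnames(X) <- genes
  structure(
    list(X = X, time = as.numeric(time), event = as.integer(event),
         subject_ids = as.character(subject_ids), genes = as.character(genes),
         cohort_label = cohort_label),
    class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort '%s'> %d subjects x %d genes, %d events (%.1f%% censored)\n",
              x$cohort_label, nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' @export
`[.survival_cohort` <- function(x, i, ...) {
  survival_cohort(x$X[i, , drop = FALSE], x$time[i], x$event[i],
                  x$subject_ids[i], x$genes, x$cohort_label)
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression table and returns it oriented samples x genes.
#' The first column holds row identifiers and the header the column
#' identifiers. Duplicate gene symbols are collapsed by their mean (with a
#' message); duplicate subject ids are an error.
#'
#' @param path delimited text file (delimiter sniffed by [data.table::fread]).
#' @param orientation `"samples_rows"` if rows are samples, `"genes_rows"` if
#'   rows are genes. Required: silent transposition is the classic bug.
#' @return list with `X` (samples x genes), `subject_ids`, `genes`.
#' @export
load_expression <- function(path, orientation = c("samples_rows", "genes_rows")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2L) stopf("expression file needs an id column plus data: %s", path)
  ids <- as.character(dt[[1L]])
  nms <- colnames(dt)[-1L]  # duplicate headers preserved (no make.names)
  body <- as.list(dt)[-1L]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      nonnum <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))
      row <- if (length(nonnum)) nonnum[1L] else 1L
      stopf("non-numeric value in column '%s', row id '%s'", nms[j], ids[row])
    }
    if (anyNA(body[[j]])) {
      row <- which(is.na(body[[j]]))[1L]
      stopf("missing value in column '%s', row id '%s'", nms[j], ids[row])
    }
  }
  M <- do.call(cbind, body)
  dimnames(M) <- list(ids, nms)
  if (orientation == "genes_rows") M <- t(M)
  # rows now samples, columns genes
  if (anyDuplicated(rownames(M))) stopf("duplicate subject ids in %s", path)
  if (anyDuplicated(colnames(M))) {
    dup <- unique(colnames(M)[duplicated(colnames(M))])
    message(sprintf("collapsing %d duplicated gene symbol(s) by mean: %s",
                    length(dup), paste(head(dup, 5L), collapse = ", ")))
    M <- t(rowsum(t(M), group = colnames(M), reorder = FALSE) /
             as.vector(table(colnames(M))[unique(colnames(M))]))
  }
  list(X = M, subject_ids = rownames(M), genes = colnames(M))
}

#' Read a two-column survival annotation table
#'
#' Expects columns subject id, time (days), event (0/1); extra columns ignored.
#' @param path delimited text file.
#' @return data.frame with `subject_id`, `time`, `event`.
#' @export
load_survival <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L) stopf("survival table needs id, time, event columns")
  out <- data.frame(subject_id = as.character(dt[[1L]]),
                    time = as.numeric(dt[[2L]]),
                    event = as.integer(dt[[3L]]))
  if (anyNA(out$time) || anyNA(out$event)) stopf("missing survival values in %s", path)
  out
}

#' log2(x + 1) transform
#'
#' The standard variance-stabilizing transform applied to normalized
#' expression values before modeling.
#' @param X nonnegative numeric matrix or vector.
#' @export
log2p1 <- function(X) {
  if (any(X < 0)) stopf("log2p1 requires nonnegative entries")
  log2(X + 1)
}

#' Zero-mean / unit-variance standardization with train-only statistics
#'
#' Per-gene centering and scaling statistics are computed on `train_X` ONLY
#' and applied to `apply_X` (which may be the training matrix itself, a test
#' fold, or an external cohort). Zero-variance genes are kept and mapped to
#' all-zero columns so gene indices stay aligned with attribution outputs.
#'
#' @param train_X matrix whose columns define the statistics.
#' @param apply_X matrix to transform; defaults to `train_X`.
#' @return list with `X` (standardized `apply_X`), `center`, `scale`.
#' @export
standardize <- function(train_X, apply_X = train_X) {
  if (ncol(train_X) != ncol(apply_X))
    stopf("column mismatch: train has %d genes, apply has %d",
          ncol(train_X), ncol(apply_X))
  if (!is.null(colnames(train_X)) && !is.null(colnames(apply_X)) &&
      !identical(colnames(train_X), colnames(apply_X)))
    stopf("column names of train and apply matrices differ")
  center <- colMeans(train_X)
  # population (1/n) standard deviation: a two-point column (1, 3) maps to
  # exactly (-1, 1)
  scale <- sqrt(colMeans(sweep(train_X, 2L, center, "-")^2))
  scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  X <- sweep(sweep(apply_X, 2L, center, "-"), 2L, scale, "/")
  list(X = X, center = center, scale = scale)
}

apply_standardization <- function(X, center, scale) {
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

#' Survival-stratified k-fold split
#'
#' Folds are stratified on the cross-tabulation of the event indicator with
#' quantile bins of the observed time, so each fold sees a similar censoring
#' rate and follow-up distribution. Cells smaller than `k` trigger a merge of
#' adjacent time bins (with a warning).
#'
#' @param cohort a [survival_cohort] (or any list with `time` and `event`).
#' @param k number of folds (>= 2).
#' @param n_time_bins number of quantile bins on observed time (default 4).
#' @param seed integer seed; identical seeds give identical folds.
#' @return list of k elements, each `list(train_idx, test_idx)`.
#' @export
stratified_kfold <- function(cohort, k, n_time_bins = 4L, seed = 1L) {
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  if (k < 2L) stopf("k must be >= 2")
  if (n < k) stopf("n = %d is smaller than k = %d", n, k)
  bins <- n_time_bins
  repeat {
    qs <- unique(quantile(time, probs = seq(0, 1, length.out = bins + 1L),
                          type = 1L))
    tb <- if (length(qs) < 2L) rep(1L, n) else
      cut(time, breaks = qs, include.lowest = TRUE, labels = FALSE)
    if (bins == 1L || all(table(event, tb) >= k)) break
    bins <- bins - 1L
  }
  if (bins < n_time_bins)
    warnf("stratification cells smaller than k; merged time bins %d -> %d",
          n_time_bins, bins)
  # shuffle within event x time-bin cells, concatenate event-major: a
  # continuous round-robin then keeps per-fold event counts within +/- 1
  key <- event * (max(tb) + 1L) + tb
  ord <- with_seed(seed, order(key, sample.int(n)))
  assign <- integer(n)
  assign[ord] <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f)
    list(train_idx = which(assign != f), test_idx = which(assign == f)))
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (gene symbols).
#' @param source provenance string (file path or `"synthetic"`).
#' @export
gene_set_collection <- function(sets, source = "synthetic") {
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stopf("all gene sets must be named")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) stopf("gene sets must be non-empty")
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %s) from %s\n",
              length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-",
              x$source))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' The description field is ignored; symbols are uppercased and deduplicated.
#' @param path GMT file.
#' @return a [gene_set_collection].
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("GMT file %s is empty", path)
    return(gene_set_collection(list(), source = path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stopf("GMT line %d has fewer than 3 tab-separated fields", short[1L])
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, source = path)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection].
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort as the TSV pair this package reads back
#'
#' Emits `<prefix>_expression.tsv` (samples x genes, id column first) and
#' `<prefix>_survival.tsv` (subject_id, time, event).
#' @param cohort a [survival_cohort].
#' @param prefix output path prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  expr_path <- paste0(prefix, "_expression.tsv")
  surv_path <- paste0(prefix, "_survival.tsv")
  df <- data.frame(subject_id = cohort$subject_ids,
                   cohort$X, check.names = FALSE)
  data.table::fwrite(df, expr_path, sep = "\t")
  data.table::fwrite(data.frame(subject_id = cohort$subject_ids,
                                time = cohort$time, event = cohort$event),
                     surv_path, sep = "\t")
  invisible(c(expression = expr_path, survival = surv_path))
}

#' Read a cohort from the TSV pair written by [write_cohort]
#' @param expr_path expression TSV (samples x genes unless stated otherwise).
#' @param surv_path survival TSV.
#' @inheritParams load_expression
#' @param cohort_label label for the assembled cohort.
#' @export
read_cohort <- function(expr_path, surv_path,
                        orientation = "samples_rows", cohort_label = "cohort") {
  ex <- load_expression(expr_path, orientation)
  sv <- load_survival(surv_path)
  idx <- match(ex$subject_ids, sv$subject_id)
  if (anyNA(idx)) stopf("subjects in expression file missing from survival table")
  survival_cohort(ex$X, sv$time[idx], sv$event[idx],
                  subject_ids = ex$subject_ids, genes = ex$genes,
                  cohort_label = cohort_label)
}
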