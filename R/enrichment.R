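# Enrichment score from the positions of the set members in a ranked list.
# w_abs: |score|^weight of every gene in rank order; pos: sorted hit
# positions. The weighted KS running sum attains its extremes only at hit
# boundaries, so only 2*s candidates need to be examined.
es_from_positions <- function(pos, w_abs, N) {
  s <- length(pos)
  sw <- w_abs[pos]
  NR <- sum(sw)
  Nm <- N - s
  if (NR <= 0) {
    # all-zero hit scores: hits contribute equal steps (uniform fallback)
    sw <- rep(1, s)
    NR <- s
  }
  ch <- cumsum(sw) / NR
  js <- seq_len(s)
  dev_after <- ch - (pos - js) / Nm
  dev_before <- c(0, ch[-s]) - (pos - js) / Nm
  cand <- c(dev_after, dev_before)
  pick <- which.max(abs(cand))
  es <- unname(cand[pick])
  leading <- if (es >= 0) ((pick - 1L) %% s) + 1L else s - ((pick - 1L) %% s)
  list(es = es, leading_edge_size = as.integer(leading))
}

#' Preranked gene-set enrichment (weighted KS statistic)
#'
#' Walks the ranked gene list accumulating `|score|^weight / NR` at set
#' members ("hits") and `-1/(N - N_hit)` elsewhere; the enrichment score ES
#' is the maximal deviation of this running sum, with its sign. The p-value
#' comes from gene-label permutations (random hit positions), one-sided on
#' the side matching the observed sign, floored at `1/(n_perm + 1)`.
#'
#' @param scores named numeric vector of per-gene scores (e.g. attributions);
#'   ranked internally in decreasing order.
#' @param gene_set character vector of member symbols; must overlap the
#'   ranked genes and be a strict subset of them.
#' @param n_perm number of permutations (default 1000).
#' @param seed permutation seed.
#' @param weight exponent on |score| for hit increments (default 1).
#' @param null_es optional pre-computed permutation ES vector (shared across
#'   sets of equal size for one ranking).
#' @return list with `ES`, `p_value`, `leading_edge_size`, `n_hits`.
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 1000L, seed = 1L,
                           weight = 1, null_es = NULL) {
  if (is.null(names(scores))) stopf("scores must be a named vector")
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  N <- length(ranked)
  hits <- which(ranked %in% toupper(gene_set))
  if (!length(hits)) stopf("gene set does not overlap the ranked genes")
  if (length(hits) == N)
    stopf("gene set covers all ranked genes; miss decrement undefined")
  w_abs <- abs(scores[ord])^weight
  obs <- es_from_positions(hits, w_abs, N)
  if (is.null(null_es))
    null_es <- gsea_null(w_abs, N, length(hits), n_perm, seed)
  p <- if (obs$es >= 0) {
    (1 + sum(null_es >= obs$es)) / (length(null_es) + 1)
  } else {
    (1 + sum(null_es <= obs$es)) / (length(null_es) + 1)
  }
  list(ES = obs$es, p_value = p,
       leading_edge_size = obs$leading_edge_size, n_hits = length(hits))
}

# Permutation null: ES of random position sets of size s in a ranking with
# hit weights w_abs.
gsea_null <- function(w_abs, N, s, n_perm, seed) {
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    es_from_positions(sort.int(sample.int(N, s)), w_abs, N)$es
  }, 0))
}

#' Per-patient enrichment of gene sets on attribution rankings
#'
#' For every patient, genes are ranked by their attribution (signed,
#' decreasing, by default; `rank_by = "absolute"` ranks by |attribution|),
#' each gene set is scored with [gsea_preranked], and p-values are
#' Benjamini-Hochberg adjusted across sets within the patient. The
#' cohort-level summary reports, per set, the percentage of patients in
#' which it is significantly enriched (adjusted p < `alpha`; restrict to
#' positive ES with `positive_only = TRUE`).
#'
#' Permutation nulls are shared across sets of equal size within a patient
#' (the gene-label null depends only on the ranking and the set size).
#'
#' @param attributions n x p matrix (e.g. an [attribute] result), rows
#'   patients, columns genes.
#' @param sets a [gene_set_collection].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param n_perm permutations per (patient, set size).
#' @param seed base seed.
#' @param rank_by `"signed"` or `"absolute"` attribution ranking.
#' @param positive_only count only positive-ES enrichments in the summary.
#' @return list of class `enrichment_result`: `results` (one row per
#'   patient x set) and `frequency` (set, pct_patients).
#' @export
enrich_cohort <- function(attributions, sets, alpha = 0.05, n_perm = 1000L,
                          seed = 1L, rank_by = c("signed", "absolute"),
                          positive_only = FALSE) {
  rank_by <- match.arg(rank_by)
  A <- unclass(as.matrix(attributions))
  genes <- toupper(colnames(A))
  if (is.null(genes)) stopf("attribution matrix needs gene column names")
  usable <- list()
  for (nm in names(sets$sets)) {
    ov <- intersect(sets$sets[[nm]], genes)
    if (!length(ov) || length(ov) == length(genes)) {
      warnf("set '%s' skipped (overlap %d of %d genes)", nm, length(ov),
            length(genes))
    } else usable[[nm]] <- ov
  }
  if (!length(usable)) stopf("no usable gene sets")
  pats <- rownames(A) %||% sprintf("S%04d", seq_len(nrow(A)))
  res <- vector("list", nrow(A))
  for (i in seq_len(nrow(A))) {
    sc <- A[i, ]
    if (rank_by == "absolute") sc <- abs(sc)
    names(sc) <- genes
    ord <- order(sc, decreasing = TRUE)
    w_abs <- abs(sc[ord])
    N <- length(sc)
    ranked <- genes[ord]
    null_cache <- new.env(parent = emptyenv())
    rows <- lapply(names(usable), function(nm) {
      s <- length(usable[[nm]])
      key <- as.character(s)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- gsea_null(w_abs, N, s, n_perm,
                                       child_seed(seed, i * 131L + s))
      hits <- sort.int(match(usable[[nm]], ranked))
      obs <- es_from_positions(hits, w_abs, N)
      null_es <- null_cache[[key]]
      p <- if (obs$es >= 0) (1 + sum(null_es >= obs$es)) / (n_perm + 1)
           else (1 + sum(null_es <= obs$es)) / (n_perm + 1)
      data.frame(patient = pats[i], set = nm, ES = obs$es, p_value = p,
                 leading_edge_size = obs$leading_edge_size)
    })
    df <- do.call(rbind, rows)
    df$p_adjusted <- p.adjust(df$p_value, method = "BH")
    res[[i]] <- df
  }
  results <- do.call(rbind, res)
  sig <- results$p_adjusted < alpha
  if (positive_only) sig <- sig & results$ES > 0
  freq <- tapply(sig, results$set, mean)[names(usable)]
  frequency <- data.frame(set = names(usable),
                          pct_patients = 100 * as.numeric(freq),
                          row.names = NULL)
  frequency <- frequency[order(-frequency$pct_patients), ]
  structure(list(results = results, frequency = frequency,
                 alpha = alpha, rank_by = rank_by,
                 positive_only = positive_only),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d patients x %d sets (alpha = %s)\n",
              length(unique(x$results$patient)),
              length(unique(x$results$set)), x$alpha))
  print(head(x$frequency, 10L))
  invisible(x)
}

#' Combine gene sets into one aggregate set
#'
#' Selects sets either by name or by a frequency threshold on an
#' [enrich_cohort] summary (sets enriched in more than `min_frequency` of
#' patients) and returns the deduplicated union of their member genes.
#'
#' @param sets a [gene_set_collection].
#' @param names explicit set names to combine.
#' @param min_frequency fraction threshold (e.g. 0.05) applied to
#'   `freq_table`.
#' @param freq_table the `frequency` data.frame from [enrich_cohort]
#'   (`pct_patients` on the 0-100 scale).
#' @return character vector of member genes with attribute `sets` listing
#'   the selected set names.
#' @export
combine_sets <- function(sets, names = NULL, min_frequency = NULL,
                         freq_table = NULL) {
  if (is.null(names)) {
    if (is.null(min_frequency) || is.null(freq_table))
      stopf("supply either `names` or both `min_frequency` and `freq_table`")
    names <- freq_table$set[freq_table$pct_patients > 100 * min_frequency]
  }
  names <- intersect(names, base::names(sets$sets))
  if (!length(names)) stopf("empty selection: no sets to combine")
  message(sprintf("combining %d set(s): %s", length(names),
                  paste(names, collapse = ", ")))
  genes <- unique(unlist(sets$sets[names], use.names = FALSE))
  structure(genes, sets = names)
}

#' GSVA-style single-sample activity score
#'
#' Rank-based per-sample activity of one gene set, following the gene-set
#' variation analysis recipe for continuous (log-scale) expression:
#' \enumerate{
#'   \item per gene, a Gaussian-kernel smoothed ECDF across samples
#'     (bandwidth sd/4) gives each sample an expression-level statistic;
#'   \item per sample, genes are ranked by that statistic (decreasing) and
#'     weighted by the symmetric rank statistic `|p/2 - rank|`;
#'   \item a KS-like random walk over the ranked list (hits = set members)
#'     yields the score as the maximum positive deviation minus the
#'     magnitude of the maximum negative deviation.
#' }
#' The score is invariant to sample order, gene order and per-gene positive
#' rescaling. The expression matrix should be the scoring cohort's own
#' log-scale values (not standardized to a training set).
#'
#' @param X samples x genes matrix, log scale.
#' @param combined_set character vector of member genes (>= 1 measured).
#' @param tau weighting exponent on the rank statistic (default 1).
#' @return named numeric vector of per-sample scores (class
#'   `activity_score`, attribute `gene_set`).
#' @export
gsva_score <- function(X, combined_set, tau = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stopf("GSVA needs at least 2 samples (ECDF across samples)")
  genes <- toupper(colnames(X) %||% stopf("X needs gene column names"))
  members <- genes %in% toupper(combined_set)
  if (!any(members)) stopf("combined set does not overlap measured genes")
  if (all(members)) stopf("combined set covers all measured genes")
  Z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    xj <- X[, j]
    h <- sd(xj) / 4
    if (!is.finite(h) || h <= 0) h <- 1
    Z[, j] <- colMeans(pnorm(outer(xj, xj, "-") / -h))  # P(Xj <= x_ij), smoothed
  }
  s <- sum(members)
  scores <- vapply(seq_len(n), function(i) {
    ord <- order(Z[i, ], decreasing = TRUE)
    w <- abs(p / 2 - seq_len(p))^tau
    hit <- members[ord]
    inc <- w * hit
    v <- cumsum(ifelse(hit, inc / sum(inc), -1 / (p - s)))
    max(0, max(v)) + min(0, min(v))
  }, 0)
  names(scores) <- rownames(X) %||% sprintf("S%04d", seq_len(n))
  structure(scores, class = "activity_score", gene_set = attr(combined_set, "sets"))
}
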