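# Term enrichment of a test protein set against a background, from a
# user-supplied annotation table (no web services, no ontology closure).

#' Read an annotation table
#'
#' Tab-delimited `accession  term_id  [term_label]`; `#` lines ignored.
#'
#' @param path Path to the TSV.
#' @return Tibble: `accession`, `term_id`, `term_label` (`NA` if absent).
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("accession", "term_id") %in% names(raw))) {
    stop("annotation TSV needs columns `accession` and `term_id`")
  }
  if (!"term_label" %in% names(raw)) raw$term_label <- NA_character_
  raw[, c("accession", "term_id", "term_label")]
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For each term: `k` = annotated proteins in the test set, `K` = annotated
#' in the background, `n` = test-set size, `N` = background size;
#' `p_raw = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`;
#' `p_bonferroni = min(1, p_raw * #terms tested)`. Terms annotating no
#' background protein are skipped and excluded from the Bonferroni
#' denominator. Fold enrichment is the ratio of proportions
#' `(k/n) / (K/N)`; set `fold = "ratio_of_counts"` for the literal `k / K`
#' variant (not scale-free; kept for comparability with legend-style
#' definitions).
#'
#' @param test Character vector of test-set accessions (subset of
#'   `background`).
#' @param background Character vector of background accessions.
#' @param annotations Annotation tibble ([read_annotations()]) or named
#'   list of accession vectors (term -> accessions).
#' @param fold `"ratio_of_proportions"` (default) or `"ratio_of_counts"`.
#' @return Tibble sorted by `p_raw` (ties by `term_id`): `term_id`,
#'   `term_label`, `k`, `K`, `n`, `N`, `fold`, `p_raw`, `p_bonferroni`.
#' @export
hypergeom_enrichment <- function(test, background, annotations,
                                 fold = c("ratio_of_proportions",
                                          "ratio_of_counts")) {
  fold <- match.arg(fold)
  test <- unique(test)
  background <- unique(background)
  if (length(test) < 1) stop("empty test set")
  if (!all(test %in% background)) {
    stop("test set is not a subset of the background")
  }
  if (is.data.frame(annotations)) {
    ann <- split(annotations$accession, annotations$term_id)
    labels <- annotations$term_label[!duplicated(annotations$term_id)]
    names(labels) <- annotations$term_id[!duplicated(annotations$term_id)]
  } else {
    ann <- annotations
    labels <- stats::setNames(rep(NA_character_, length(ann)), names(ann))
  }
  N <- length(background)
  n <- length(test)
  rows <- lapply(names(ann), function(tid) {
    members <- intersect(unique(ann[[tid]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- sum(test %in% members)
    p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    f <- if (fold == "ratio_of_proportions") (k / n) / (K / N) else k / K
    tibble::tibble(term_id = tid, term_label = unname(labels[tid]),
                   k = k, K = K, n = n, N = N, fold = f, p_raw = p_raw)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw, out$term_id), , drop = FALSE]
}
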