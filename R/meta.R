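#' Construct a raw expression dataset
#'
#' One microarray/RNA-seq dataset: a genes x samples matrix plus sample
#' metadata marking control samples, treatment labels and replicate ids.
#' `scale` declares how the values are stored: `"linear"` (intensities),
#' `"log2"` (log2 intensities) or `"log2_change"` (already log2 ratios
#' versus control, in which case normalisation is a pass-through).
#'
#' @param expr numeric matrix, rownames = gene symbols, colnames = sample
#'   ids.
#' @param metadata data.frame with columns `sample`, `treatment`,
#'   `replicate`, `is_control` covering every column of `expr`.
#' @param id dataset identifier.
#' @param scale one of `"linear"`, `"log2"`, `"log2_change"`.
#' @return a `raw_dataset`.
#' @export
raw_dataset <- function(expr, metadata, id,
                        scale = c("linear", "log2", "log2_change")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)),
            all(c("sample", "treatment", "is_control") %in% names(metadata)),
            all(colnames(expr) %in% metadata$sample))
  metadata <- metadata[match(colnames(expr), metadata$sample), , drop = FALSE]
  if (scale != "log2_change" && !any(metadata$is_control))
    stop("dataset ", id, " has no control sample")
  if (!any(!metadata$is_control))
    stop("dataset ", id, " has no treatment sample")
  structure(list(expr = expr, metadata = metadata, id = id, scale = scale),
            class = "raw_dataset")
}

#' Normalise a dataset to per-treatment log2 changes versus control
#'
#' Biological replicates of the same treatment are averaged on the linear
#' scale and divided by the mean of the control samples (all treatments of
#' a dataset share the single control mean), then log2-transformed. One
#' output column per non-control treatment. A dataset declared as
#' `"log2_change"` is already normalised: replicates are averaged on that
#' scale and nothing else is done (idempotence).
#'
#' @param raw a [raw_dataset()].
#' @return numeric matrix genes x treatments of log2 changes.
#' @export
normalize_dataset <- function(raw) {
  stopifnot(inherits(raw, "raw_dataset"))
  expr <- raw$expr
  md <- raw$metadata
  if (raw$scale == "log2") expr <- 2^expr
  treatments <- unique(md$treatment[!md$is_control])
  if (raw$scale == "log2_change") {
    out <- sapply(treatments, function(tr) {
      cols <- md$sample[md$treatment == tr & !md$is_control]
      rowMeans(expr[, cols, drop = FALSE])
    })
    out <- matrix(out, nrow = nrow(expr),
                  dimnames = list(rownames(expr), treatments))
    return(out)
  }
  ctrl <- rowMeans(expr[, md$sample[md$is_control], drop = FALSE])
  bad <- ctrl <= 0
  if (any(bad))
    stop("non-positive control mean for gene(s): ",
         paste(head(rownames(expr)[bad], 5L), collapse = ", "))
  out <- sapply(treatments, function(tr) {
    cols <- md$sample[md$treatment == tr & !md$is_control]
    log2(rowMeans(expr[, cols, drop = FALSE]) / ctrl)
  })
  matrix(out, nrow = nrow(expr),
         dimnames = list(rownames(expr), treatments))
}

#' Merge normalised datasets into a compendium by official gene symbol
#'
#' Symbols are case-normalised and optionally replaced by their official
#' symbols through an alias table before an outer merge. Genes absent from
#' a dataset stay missing (`NA`), never zero. Duplicate symbols within one
#' dataset are collapsed by their mean with a warning. Column names are
#' `<dataset>.<treatment>`.
#'
#' @param normalized named list of matrices from [normalize_dataset()]
#'   (names = dataset ids).
#' @param alias_table optional data.frame `alias` -> `official`.
#' @return a `merged_compendium`: list with `matrix` (genes x columns of
#'   log2 changes) and `provenance` (data.frame `column`, `dataset`,
#'   `treatment`).
#' @export
merge_by_symbol <- function(normalized, alias_table = NULL) {
  if (length(normalized) == 0L) stop("no datasets to merge")
  if (is.null(names(normalized)))
    names(normalized) <- paste0("ds", seq_along(normalized))
  cleaned <- lapply(names(normalized), function(id) {
    m <- normalized[[id]]
    sym <- apply_aliases(rownames(m), alias_table)
    sym <- toupper(sym)
    if (anyDuplicated(sym)) {
      warning("dataset ", id, ": duplicate symbols collapsed by mean: ",
              paste(unique(sym[duplicated(sym)]), collapse = ", "))
      m <- apply(m, 2L, function(col) tapply(col, sym, mean))
      m <- matrix(m, ncol = ncol(normalized[[id]]),
                  dimnames = list(sort(unique(sym)),
                                  colnames(normalized[[id]])))
    } else {
      rownames(m) <- sym
    }
    m
  })
  all_genes <- sort(unique(unlist(lapply(cleaned, rownames))))
  cols <- list(); prov <- list()
  for (k in seq_along(cleaned)) {
    m <- cleaned[[k]]
    id <- names(normalized)[k]
    for (j in seq_len(ncol(m))) {
      v <- setNames(rep(NA_real_, length(all_genes)), all_genes)
      v[rownames(m)] <- m[, j]
      cname <- paste(id, colnames(m)[j], sep = ".")
      cols[[cname]] <- v
      prov[[cname]] <- data.frame(column = cname, dataset = id,
                                  treatment = colnames(m)[j])
    }
  }
  structure(list(matrix = do.call(cbind, cols),
                 provenance = do.call(rbind, c(prov,
                                               make.row.names = FALSE))),
            class = "merged_compendium")
}

#' Fraction of compendium columns in which a gene is up-regulated
#'
#' The percentage of columns whose log2 change for `gene` exceeds
#' `log2(threshold)`, computed over the columns in which the gene is
#' non-missing (the basis count is reported alongside).
#'
#' @param comp a [merge_by_symbol()] compendium.
#' @param gene gene symbol (case-insensitive).
#' @param threshold fold-change threshold (default 1.5, i.e. log2 change >
#'   0.585).
#' @return list `percent`, `n_up`, `basis`, `n_columns`.
#' @export
upregulation_fraction <- function(comp, gene, threshold = 1.5) {
  stopifnot(inherits(comp, "merged_compendium"), threshold > 0)
  i <- match(toupper(gene), rownames(comp$matrix))
  if (is.na(i)) stop("gene ", gene, " absent from the compendium")
  v <- comp$matrix[i, ]
  basis <- sum(!is.na(v))
  if (basis == 0L) stop("gene ", gene, " is missing in every column")
  n_up <- sum(v > log2(threshold), na.rm = TRUE)
  list(percent = 100 * n_up / basis, n_up = n_up, basis = basis,
       n_columns = ncol(comp$matrix))
}

#' Stratify compendium columns by EMT-score strength
#'
#' Scores every column with [signature_score()] and splits columns at the
#' given quantile of the score ("strongly induced EMT" = top group). For
#' each query gene the up-regulation fraction is reported in the strong and
#' weak groups together with their difference.
#'
#' @param comp a [merge_by_symbol()] compendium.
#' @param sig a [signature_set()] to score EMT strength.
#' @param strong_quantile quantile defining the strong group (default 0.75:
#'   top quartile).
#' @param genes query genes (default the Sox2/neuron-projection/Stat3
#'   panel).
#' @param threshold fold threshold passed to [upregulation_fraction()].
#' @return list with `scores` (per column), `strong_columns`,
#'   `weak_columns`, and `enrichment` (data.frame per gene: fractions in
#'   both groups, basis counts, difference).
#' @export
stratify_by_emt <- function(comp, sig, strong_quantile = 0.75,
                            genes = c("Sox2", "Map1b", "Reln", "Robo1",
                                      "Tubb3", "Stat3"),
                            threshold = 1.5) {
  stopifnot(inherits(comp, "merged_compendium"))
  if (ncol(comp$matrix) < 4L)
    stop("need at least 4 columns to stratify by EMT strength")
  scores <- vapply(seq_len(ncol(comp$matrix)), function(j) {
    v <- comp$matrix[, j]
    v <- v[!is.na(v)]
    signature_score(v, sig)$score
  }, numeric(1L))
  names(scores) <- colnames(comp$matrix)
  cut <- stats::quantile(scores, strong_quantile, names = FALSE)
  strong <- scores > cut
  if (!any(strong)) strong <- scores >= cut  # all-identical tie-break
  frac <- function(gene, cols) {
    i <- match(toupper(gene), rownames(comp$matrix))
    if (is.na(i)) return(c(NA_real_, 0))
    v <- comp$matrix[i, cols]
    basis <- sum(!is.na(v))
    if (basis == 0L) return(c(NA_real_, 0))
    c(100 * sum(v > log2(threshold), na.rm = TRUE) / basis, basis)
  }
  enr <- do.call(rbind, lapply(genes, function(g) {
    s <- frac(g, strong); w <- frac(g, !strong)
    data.frame(gene = g, strong_percent = s[1L], strong_basis = s[2L],
               weak_percent = w[1L], weak_basis = w[2L],
               difference = s[1L] - w[1L])
  }))
  list(scores = scores, strong_columns = names(scores)[strong],
       weak_columns = names(scores)[!strong], enrichment = enr)
}
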