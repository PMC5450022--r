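#' Construct a signature gene set
#'
#' @param name signature name.
#' @param up,down character vectors of up- and down-regulated member genes;
#'   must be disjoint and both non-empty.
#' @return a `signature_set`.
#' @export
signature_set <- function(name, up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) == 0L || length(down) == 0L)
    stop("both up and down gene lists must be non-empty")
  if (length(intersect(toupper(up), toupper(down))) > 0L)
    stop("up and down lists overlap: ",
         paste(intersect(toupper(up), toupper(down)), collapse = ", "))
  structure(list(name = name, up = up, down = down), class = "signature_set")
}

#' Signed signature score on log2 expression changes
#'
#' `score = (sum of log2 changes of up-regulated signature genes - sum of
#' log2 changes of down-regulated signature genes) / number of signature
#' genes used`. By default genes absent from `changes` are excluded from
#' both numerator and denominator ("genes used for calculation");
#' `denominator = "all"` divides by the full signature size instead.
#'
#' Gene matching is case-insensitive.
#'
#' @param changes named numeric vector of log2 fold changes (gene symbol ->
#'   log2 change versus control).
#' @param sig a [signature_set()].
#' @param denominator `"used"` (default) or `"all"`.
#' @return list with `score`, `n_used`, `n_signature`, and the `missing`
#'   symbols.
#' @export
signature_score <- function(changes, sig, denominator = c("used", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(sig, "signature_set"), is.numeric(changes))
  if (any(!is.finite(changes))) stop("changes must be finite")
  nm <- toupper(names(changes))
  if (anyDuplicated(nm)) stop("duplicate gene symbols in changes")
  up_idx <- match(toupper(sig$up), nm)
  dn_idx <- match(toupper(sig$down), nm)
  missing <- c(sig$up[is.na(up_idx)], sig$down[is.na(dn_idx)])
  n_used <- sum(!is.na(up_idx)) + sum(!is.na(dn_idx))
  if (n_used == 0L)
    stop("no signature genes present in changes; missing: ",
         paste(missing, collapse = ", "))
  num <- sum(changes[up_idx[!is.na(up_idx)]]) -
    sum(changes[dn_idx[!is.na(dn_idx)]])
  denom <- if (denominator == "used") n_used
  else length(sig$up) + length(sig$down)
  list(score = num / denom, n_used = n_used,
       n_signature = length(sig$up) + length(sig$down), missing = missing)
}

#' The six-gene qPCR EMT signature
#'
#' Up-regulated during EMT: Cdh2, Fn1, Slug, Zeb1; down-regulated: Epcam,
#' Ocln.
#'
#' @return a [signature_set()].
#' @export
qpcr_emt_signature <- function() {
  signature_set("EMT-qPCR", up = c("Cdh2", "Fn1", "Slug", "Zeb1"),
                down = c("Epcam", "Ocln"))
}

#' EMT score from the six-gene qPCR panel
#'
#' [signature_score()] with the fixed qPCR signature. Gene aliases in the
#' supplied table are resolved first (notably Snai2, the official symbol of
#' Slug).
#'
#' @param changes named numeric vector of log2 fold changes.
#' @param alias_table data.frame with columns `alias` and `official`
#'   (default: the alias table shipped with the package).
#' @inheritParams signature_score
#' @return as [signature_score()].
#' @export
emt_score_qpcr <- function(changes, alias_table = default_alias_table(),
                           denominator = c("used", "all")) {
  names(changes) <- apply_aliases(names(changes), alias_table)
  signature_score(changes, qpcr_emt_signature(), denominator)
}

#' Metabolism score (oxidative phosphorylation versus glycolysis)
#'
#' [signature_score()] with up := oxidative-phosphorylation pathway members
#' (KEGG00190) and down := glycolysis members (KEGG00010); a positive score
#' means expression shifted towards oxidative phosphorylation.
#'
#' @param changes named numeric vector of log2 fold changes.
#' @param ox_set,gly_set character vectors of pathway member symbols; by
#'   default read from the GMT fixture shipped with the package.
#' @inheritParams signature_score
#' @return as [signature_score()].
#' @export
metabolism_score <- function(changes, ox_set = NULL, gly_set = NULL,
                             denominator = c("used", "all")) {
  if (is.null(ox_set) || is.null(gly_set)) {
    gmt <- read_gmt(system.file("extdata", "kegg_metabolism_subset.gmt",
                                package = "morphotrace"))
    ox_set <- ox_set %||% gmt[["KEGG00190_OXIDATIVE_PHOSPHORYLATION"]]
    gly_set <- gly_set %||% gmt[["KEGG00010_GLYCOLYSIS"]]
  }
  sig <- signature_set("metabolism", up = ox_set, down = gly_set)
  signature_score(changes, sig, denominator)
}

#' Convert raw expression values to log2 changes versus control
#'
#' `log2((x + pseudocount) / (control + pseudocount))`.
#'
#' @param x named numeric vector of raw values.
#' @param control matching control values (vector or single sample).
#' @param pseudocount added to both (default 1).
#' @return named numeric vector of log2 changes.
#' @export
log2_changes <- function(x, control, pseudocount = 1) {
  stopifnot(length(control) %in% c(1L, length(x)))
  log2((x + pseudocount) / (control + pseudocount))
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[parts[1L]]] <- parts[-(1:2)]
  }
  out
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Default gene-alias table
#'
#' Two-column table mapping aliases to the symbols used by the package's
#' signatures (e.g. Snai2 -> Slug for the qPCR panel).
#'
#' @return data.frame with columns `alias`, `official`.
#' @export
default_alias_table <- function() {
  read_tsv(system.file("extdata", "gene_aliases.tsv",
                       package = "morphotrace"))
}

apply_aliases <- function(symbols, alias_table) {
  if (is.null(alias_table) || nrow(alias_table) == 0L) return(symbols)
  m <- match(toupper(symbols), toupper(alias_table$alias))
  out <- symbols
  out[!is.na(m)] <- alias_table$official[m[!is.na(m)]]
  out
}

#' Map gene symbols across species through a homolog table
#'
#' Case-normalised lookup in a two-column table (e.g. human symbol ->
#' mouse symbol). Unmapped symbols are returned separately, never silently
#' dropped. Conflicting duplicate rows (one source symbol mapping to two
#' targets) are an error.
#'
#' @param symbols character vector to map.
#' @param table data.frame whose first two columns are source and target
#'   symbols.
#' @return list with `mapped` (data.frame `from`, `to`) and `unmapped`
#'   (character vector).
#' @export
homolog_map <- function(symbols, table) {
  stopifnot(ncol(table) >= 2L)
  src <- toupper(table[[1L]])
  dup <- duplicated(table[, 1:2]) | duplicated(table[, 1:2], fromLast = TRUE)
  conflict <- (duplicated(src) | duplicated(src, fromLast = TRUE)) & !dup
  if (any(conflict))
    stop("conflicting duplicate mapping rows for: ",
         paste(unique(table[[1L]][conflict]), collapse = ", "))
  m <- match(toupper(symbols), src)
  mapped <- data.frame(from = symbols[!is.na(m)],
                       to = table[[2L]][m[!is.na(m)]])
  list(mapped = mapped, unmapped = symbols[is.na(m)])
}
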