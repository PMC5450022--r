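#' Write a synthetic movie to disk
#'
#' Label frames and nucleus labels go to 16-bit multi-page TIFF (or
#' per-frame PNG); truth tables are written as TSV with a reproducibility
#' header. Column schemas: `truth_cells.tsv` has `frame, cell, lineage,
#' parent, archetype, row, col, displacement` (0-based pixel coordinates,
#' frame 1 = hour 0); `truth_divisions.tsv` `frame, parent, child_a,
#' child_b`; `truth_deaths.tsv` `frame, cell`; `truth_conversions.tsv`
#' `frame, cell, lineage, mode, from, to`; `truth_tuj.tsv` `cell, tuj`.
#'
#' @param movie a [generate_movie()] result.
#' @param dir output directory (created if needed).
#' @param format `"tiff"` (multi-page) or `"png"` (per frame).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(movie, "synthetic_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(config_hash = config_hash(movie$config),
           seed = movie$config$seed)
  if (format == "tiff") {
    tiff::writeTIFF(lapply(movie$frames, function(f) f / 65535),
                    file.path(dir, "frames.tif"), bits.per.sample = 16L)
    tiff::writeTIFF(lapply(movie$nuclei, function(f) f / 65535),
                    file.path(dir, "nuclei.tif"), bits.per.sample = 16L)
  } else {
    for (t in seq_along(movie$frames)) {
      png::writePNG(movie$frames[[t]] / 65535,
                    file.path(dir, sprintf("frame_%03d.png", t)))
      png::writePNG(movie$nuclei[[t]] / 65535,
                    file.path(dir, sprintf("nucleus_%03d.png", t)))
    }
  }
  for (nm in names(movie$truth)) {
    write_tsv(movie$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
              header = hdr)
  }
  invisible(dir)
}

#' Read movie frames back from disk
#'
#' Reads the 16-bit label TIFFs written by [write_movie()] (or any
#' multi-page label TIFF) back into integer label matrices.
#'
#' @param path TIFF file path.
#' @return list of integer matrices.
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    matrix(as.integer(round(p * 65535)), nrow(p))
  })
}

#' Write per-frame observation tables
#'
#' @param obs observation table with a `frame` column.
#' @param path output TSV path.
#' @param header optional named header values.
#' @return the path, invisibly.
#' @export
write_observations <- function(obs, path, header = NULL) {
  invisible(write_tsv(obs, path, header = header))
}

#' Write expression tables of a synthetic compendium
#'
#' Each dataset gets `<id>_expr.tsv` (genes x samples, header row = sample
#' ids) and a `<id>_samples.tsv` metadata sidecar marking
#' control/treatment/replicate.
#'
#' @param compendium a [generate_compendium()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_compendium <- function(compendium, dir) {
  stopifnot(inherits(compendium, "synthetic_compendium"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(config_hash = config_hash(compendium$config),
           seed = compendium$config$seed)
  for (ds in compendium$datasets) {
    df <- data.frame(gene = rownames(ds$expr), ds$expr, check.names = FALSE)
    write_tsv(df, file.path(dir, paste0(ds$id, "_expr.tsv")), header = hdr)
    write_tsv(ds$metadata, file.path(dir, paste0(ds$id, "_samples.tsv")),
              header = hdr)
  }
  write_tsv(compendium$truth, file.path(dir, "truth_strength.tsv"),
            header = hdr)
  invisible(dir)
}

#' Read an expression dataset from TSV files
#'
#' @param expr_path genes x samples TSV (first column = gene symbols).
#' @param samples_path sample metadata TSV (`sample`, `treatment`,
#'   `replicate`, `is_control`).
#' @param id dataset id.
#' @param scale value scale, see [raw_dataset()].
#' @return a [raw_dataset()].
#' @export
read_dataset <- function(expr_path, samples_path, id,
                         scale = c("linear", "log2", "log2_change")) {
  df <- read_tsv(expr_path)
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df[[1L]]
  md <- read_tsv(samples_path)
  md$is_control <- as.logical(md$is_control)
  raw_dataset(expr, md, id = id, scale = match.arg(scale))
}
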