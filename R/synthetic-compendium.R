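#' Default gene universe of the synthetic expression compendium
#'
#' The qPCR EMT panel, Stat3/Sox2 and the neuron projection markers, the
#' synthetic EMT signature members, the metabolism pathway fixture members
#' (null effect, so metabolism scores centre on zero), and unaffected
#' filler genes.
#'
#' @param sig the EMT [signature_set()] whose members respond to EMT
#'   strength.
#' @param n_filler number of null (unaffected) genes.
#' @return character vector of gene symbols.
#' @export
default_compendium_genes <- function(sig = synthetic_emt_signature(),
                                     n_filler = 60L) {
  kegg <- read_gmt(system.file("extdata", "kegg_metabolism_subset.gmt",
                               package = "morphotrace"))
  unique(c("Stat3", "Sox2", "Map1b", "Reln", "Robo1", "Tubb3",
           "Cdh2", "Fn1", "Slug", "Zeb1", "Epcam", "Ocln",
           sig$up, sig$down, unlist(kegg, use.names = FALSE),
           sprintf("Filler%03d", seq_len(n_filler))))
}

#' The synthetic EMT signature shipped with the package
#'
#' The real 130-gene EMT signature is external; this stand-in (clearly
#' marked synthetic in the fixture file name) has the same structure: named
#' up- and down-regulated member lists in GMT form.
#'
#' @return a [signature_set()].
#' @export
synthetic_emt_signature <- function() {
  gmt <- read_gmt(system.file("extdata", "emt_signature_synthetic.gmt",
                              package = "morphotrace"))
  signature_set("EMT-synthetic", up = gmt[["EMT_UP_SYNTHETIC"]],
                down = gmt[["EMT_DOWN_SYNTHETIC"]])
}

#' Configuration of a synthetic expression compendium
#'
#' Each dataset carries an EMT strength `s >= 0` drawn from an exponential
#' distribution. Up-signature genes respond with log2 changes
#' `Normal(+a s, sigma)`, down-signature genes `Normal(-a s, sigma)`.
#' Stat3 is up-regulated universally and modestly, independent of `s`
#' (`Normal(b, sigma_b)`); Sox2 and the neuron projection markers respond
#' only above the strength threshold `s0`
#' (`Normal(c * max(0, s - s0), sigma_c)`). Replicate-level measurement
#' noise `sigma_rep` is added on the log2 scale; values are emitted as raw
#' linear intensities with control columns, so the meta-analysis module
#' must do the replicate averaging and control normalisation itself.
#'
#' @param n_datasets number of datasets (>= 1).
#' @param genes gene universe; must contain each special gene exactly once.
#' @param signature the EMT [signature_set()] embedded in the data.
#' @param emt_strength_mean mean of the exponential EMT-strength
#'   distribution.
#' @param a,sigma effect slope and gene-level sd for signature genes.
#' @param b,sigma_b Stat3 effect mean and sd.
#' @param c_sox2,sigma_c,s0 Sox2/neuron-marker coupling slope, sd and
#'   strength threshold.
#' @param sigma_rep replicate noise sd (log2 scale).
#' @param replicates replicates per treatment and per control.
#' @param treatments_per_dataset treatments sharing one control per
#'   dataset.
#' @param baseline_log2_mean,baseline_log2_sd per-gene control baseline
#'   distribution (log2 intensities).
#' @param seed integer seed.
#' @return a `compendium_config`.
#' @export
compendium_config <- function(n_datasets = 30L,
                              genes = default_compendium_genes(),
                              signature = synthetic_emt_signature(),
                              emt_strength_mean = 1,
                              a = 1, sigma = 0.3,
                              b = 0.8, sigma_b = 0.2,
                              c_sox2 = 1.2, sigma_c = 0.3, s0 = 1.5,
                              sigma_rep = 0.05,
                              replicates = 3L,
                              treatments_per_dataset = 1L,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1,
                              seed = 20260102L) {
  if (!is_count(n_datasets) || n_datasets < 1)
    stop("n_datasets must be a positive count")
  stopifnot(sigma > 0, sigma_b > 0, sigma_c > 0, sigma_rep >= 0,
            is_count(replicates), replicates >= 1,
            emt_strength_mean > 0, s0 >= 0)
  special <- c("Stat3", "Sox2", "Map1b", "Reln", "Robo1", "Tubb3")
  for (g in special) {
    if (sum(toupper(genes) == toupper(g)) != 1L)
      stop("gene list must contain ", g, " exactly once")
  }
  structure(list(n_datasets = as.integer(n_datasets), genes = genes,
                 signature = signature,
                 emt_strength_mean = emt_strength_mean, a = a, sigma = sigma,
                 b = b, sigma_b = sigma_b, c_sox2 = c_sox2,
                 sigma_c = sigma_c, s0 = s0, sigma_rep = sigma_rep,
                 replicates = as.integer(replicates),
                 treatments_per_dataset = as.integer(treatments_per_dataset),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 seed = as.integer(seed)),
            class = "compendium_config")
}

#' Generate a synthetic expression compendium with ground truth
#'
#' @param config a [compendium_config()].
#' @return list of class `synthetic_compendium`: `datasets` (list of
#'   [raw_dataset()] objects, linear scale, replicate and control columns),
#'   `truth` (data.frame `dataset`, `treatment`, `s`), and `config`.
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "compendium_config"))
  set.seed(config$seed)
  genes <- config$genes
  up <- toupper(config$signature$up); dn <- toupper(config$signature$down)
  gu <- toupper(genes)
  neuron_markers <- toupper(c("Sox2", "Map1b", "Reln", "Robo1", "Tubb3"))
  datasets <- vector("list", config$n_datasets)
  truth <- list()
  for (d in seq_len(config$n_datasets)) {
    mu <- rnorm(length(genes), config$baseline_log2_mean,
                config$baseline_log2_sd)
    n_tr <- config$treatments_per_dataset
    n_rep <- config$replicates
    cols <- list(); md <- list()
    # control replicates
    for (r in seq_len(n_rep)) {
      nm <- sprintf("ctrl_r%d", r)
      cols[[nm]] <- 2^(mu + rnorm(length(genes), 0, config$sigma_rep))
      md[[nm]] <- data.frame(sample = nm, treatment = "control",
                             replicate = r, is_control = TRUE)
    }
    for (tr in seq_len(n_tr)) {
      s <- stats::rexp(1, rate = 1 / config$emt_strength_mean)
      delta <- numeric(length(genes))
      delta[gu %in% up] <- rnorm(sum(gu %in% up), config$a * s, config$sigma)
      delta[gu %in% dn] <- rnorm(sum(gu %in% dn), -config$a * s, config$sigma)
      delta[gu == "STAT3"] <- rnorm(1, config$b, config$sigma_b)
      boost <- config$c_sox2 * max(0, s - config$s0)
      delta[gu %in% neuron_markers] <-
        rnorm(length(neuron_markers), boost, config$sigma_c)
      trname <- sprintf("emt%d", tr)
      for (r in seq_len(n_rep)) {
        nm <- sprintf("%s_r%d", trname, r)
        cols[[nm]] <- 2^(mu + delta +
                           rnorm(length(genes), 0, config$sigma_rep))
        md[[nm]] <- data.frame(sample = nm, treatment = trname,
                               replicate = r, is_control = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        dataset = sprintf("ds%02d", d), treatment = trname, s = s)
    }
    expr <- do.call(cbind, cols)
    rownames(expr) <- genes
    datasets[[d]] <- raw_dataset(expr,
                                 do.call(rbind, c(md,
                                                  make.row.names = FALSE)),
                                 id = sprintf("ds%02d", d),
                                 scale = "linear")
  }
  names(datasets) <- vapply(datasets, function(x) x$id, character(1L))
  structure(list(datasets = datasets,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 config = config),
            class = "synthetic_compendium")
}
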