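#' Build a validated run configuration
#'
#' One configuration object drives both pipelines; every stage threshold
#' lives here, all randomness flows from the single `seed` (stage seeds are
#' derived with [derive_seed()]: stream 1 for the movie generator, stream 2
#' for the compendium generator), and unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param seed master integer seed.
#' @param movie named list of [movie_config()] arguments (or `NULL` when
#'   analysing an existing movie).
#' @param input optional named list with `frames` and `nuclei` TIFF paths
#'   for a pre-rendered movie.
#' @param thresholds named list of [class_thresholds()] arguments.
#' @param tracking named list: `gate` (NULL = 5 x the largest motion step
#'   sd when a generator config is available, else 50) and
#'   `division_radius` (NULL = automatic).
#' @param kinetics named list: `persistence`, `mitosis_threshold`,
#'   `frames_per_day`, `grid_k`.
#' @param compendium named list of [compendium_config()] arguments.
#' @param scoring named list: `up_threshold`, `strong_quantile`.
#' @param schema_version config schema version string.
#' @return a `run_config` object.
#' @export
run_config <- function(seed = 20260101L, movie = list(), input = NULL,
                       thresholds = list(), tracking = list(),
                       kinetics = list(), compendium = list(),
                       scoring = list(), schema_version = "1.0") {
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(movie, setdiff(names(formals(movie_config)), "shape_params"),
             "movie")
  check_keys(input, c("frames", "nuclei"), "input")
  check_keys(thresholds, names(formals(class_thresholds)), "thresholds")
  check_keys(tracking, c("gate", "division_radius"), "tracking")
  check_keys(kinetics, c("persistence", "mitosis_threshold",
                         "frames_per_day", "grid_k"), "kinetics")
  check_keys(compendium,
             setdiff(names(formals(compendium_config)), "signature"),
             "compendium")
  check_keys(scoring, c("up_threshold", "strong_quantile"), "scoring")
  structure(list(seed = as.integer(seed), movie = movie, input = input,
                 thresholds = thresholds, tracking = tracking,
                 kinetics = kinetics, compendium = compendium,
                 scoring = scoring, schema_version = schema_version),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML round-trips losslessly through [run_config()]; the movie
#' section's `conversion_schedule` is a list of row maps.
#'
#' @param path YAML file path.
#' @return a `run_config` ([read_run_config()]) or the path
#'   ([write_run_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## materialize section configs
build_movie_config <- function(config) {
  args <- config$movie
  if (!is.null(args$conversion_schedule) &&
      !is.data.frame(args$conversion_schedule)) {
    args$conversion_schedule <-
      do.call(rbind, lapply(args$conversion_schedule, as.data.frame))
  }
  if (!is.null(args$field_size)) args$field_size <- unlist(args$field_size)
  for (nm in c("archetype_mix", "motion_step_sd", "division_prob",
               "apoptosis_prob")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (is.null(args$seed)) args$seed <- derive_seed(config$seed, 1L)
  do.call(movie_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Accuracy of reconstructed links against generator truth
#'
#' Fraction of true consecutive-frame identity pairs and true divisions
#' that the frame links recover exactly.
#'
#' @param links list of [link_frames()] results.
#' @param truth the `truth` element of a [generate_movie()] result.
#' @return list `identity_accuracy`, `division_recall`, `n_pairs`,
#'   `n_divisions`.
#' @export
tracking_accuracy <- function(links, truth) {
  cells <- truth$cells
  n_pairs <- 0L; hit_pairs <- 0L
  for (t in seq_along(links)) {
    ids_t <- cells$cell[cells$frame == t]
    ids_t1 <- cells$cell[cells$frame == t + 1L]
    both <- intersect(ids_t, ids_t1)
    n_pairs <- n_pairs + length(both)
    l <- links[[t]]$links
    hit_pairs <- hit_pairs + sum(l$from %in% both & l$from == l$to)
  }
  dv <- truth$divisions
  hit_div <- 0L
  for (k in seq_len(nrow(dv))) {
    l <- links[[dv$frame[k] - 1L]]$divisions
    m <- l[l$parent == dv$parent[k], , drop = FALSE]
    if (nrow(m) == 1L &&
        setequal(c(m$child_a, m$child_b), c(dv$child_a[k], dv$child_b[k])))
      hit_div <- hit_div + 1L
  }
  list(identity_accuracy = if (n_pairs) hit_pairs / n_pairs else NA_real_,
       division_recall = if (nrow(dv)) hit_div / nrow(dv) else NA_real_,
       n_pairs = n_pairs, n_divisions = nrow(dv))
}

#' Run the full movie pipeline
#'
#' Simulate (or load) a movie, then detect, classify, link, reconstruct
#' lineages and compute the kinetics summaries. When ground truth is
#' available the summary additionally reports the morphology-versus-marker
#' overlap and tracking accuracy. With an `out_dir`, every intermediate
#' table is written as TSV and the summary as JSON, all stamped with the
#' config hash and seed; identical config and seed give identical outputs.
#'
#' @param config a [run_config()] (or path to its YAML).
#' @param out_dir optional output directory.
#' @param movie optional pre-generated [generate_movie()] result (skips
#'   simulation; used to reuse one movie across analyses).
#' @return a result bundle (list) with the movie, observations, links,
#'   forest, kinetics tables and `summary`.
#' @export
run_movie_pipeline <- function(config, out_dir = NULL, movie = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  thr <- do.call(class_thresholds, config$thresholds)
  kin <- config$kinetics
  persistence <- kin$persistence %||% 3L
  mitosis_threshold <- kin$mitosis_threshold %||% 1L
  frames_per_day <- kin$frames_per_day %||% 24L
  grid_k <- kin$grid_k %||% 5L

  truth <- NULL; mcfg <- NULL
  if (is.null(movie)) {
    if (!is.null(config$input)) {
      if (!file.exists(config$input$frames))
        stop("input frames not found: ", config$input$frames)
      frames <- read_label_stack(config$input$frames)
      nuclei <- if (!is.null(config$input$nuclei)) {
        if (!file.exists(config$input$nuclei))
          stop("input nuclei not found: ", config$input$nuclei)
        read_label_stack(config$input$nuclei)
      }
    } else {
      mcfg <- build_movie_config(config)
      movie <- run_stage("simulate", generate_movie(mcfg))
      frames <- movie$frames; nuclei <- movie$nuclei; truth <- movie$truth
    }
  } else {
    frames <- movie$frames; nuclei <- movie$nuclei; truth <- movie$truth
    mcfg <- movie$config
  }

  obs_list <- run_stage("detect", lapply(seq_along(frames), function(t) {
    o <- detect_cells(frames[[t]], if (!is.null(nuclei)) nuclei[[t]],
                      min_neurite_len = thr$min_neurite_len)
    o <- classify_cells(o, thr)
    cbind(data.frame(frame = t), o)
  }))
  obs_all <- do.call(rbind, obs_list)

  gate <- config$tracking$gate %||%
    if (!is.null(mcfg)) 5 * max(mcfg$motion_step_sd) else 50
  links <- run_stage("link", lapply(seq_len(length(frames) - 1L), function(t)
    link_frames(obs_list[[t]], obs_list[[t + 1L]], gate = gate,
                division_radius = config$tracking$division_radius)))
  forest <- run_stage("lineages", build_lineages(links, obs_list))

  migration <- do.call(rbind, lapply(seq_along(links), function(t) {
    m <- migration_distance(obs_list[[t]], obs_list[[t + 1L]], links[[t]])
    cbind(data.frame(frame = t), m)
  }))

  counts <- vapply(obs_list, nrow, integer(1L))
  growth <- doubling_time_course(counts, frames_per_day)
  ctc <- class_time_course(obs_all, frames_per_day)
  conv <- run_stage("conversions", detect_conversions(
    forest, obs_all, target = "neuron-like", persistence = persistence,
    mitosis_threshold = mitosis_threshold, frames_per_day = frames_per_day))
  conv_summary <- mitosis_contribution_summary(conv, forest, obs_all)
  grid_sel <- grid_sample(obs_list[[1L]], dim(frames[[1L]]), k = grid_k)

  final <- obs_list[[length(obs_list)]]
  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_frames = length(frames), gate = gate,
    final_cells = nrow(final),
    final_class_counts = as.list(table(final$class)),
    percent_classified = if (nrow(final))
      100 * mean(final$class != "unclassified") else NA_real_,
    per_day_percent = ctc,
    doubling_time_final = growth$td[nrow(growth)],
    conversion_summary = conv_summary,
    grid_sample_frame1 = grid_sel)
  if (!is.null(truth)) {
    pred <- final$label[final$class == "neuron-like"]
    ov <- marker_overlap(pred, truth$tuj$cell[truth$tuj$tuj])
    acc <- tracking_accuracy(links, truth)
    summary$marker_overlap <- ov
    summary$tracking_accuracy <- acc
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(config_hash = summary$config_hash, seed = config$seed)
    write_tsv(obs_all, file.path(out_dir, "observations.tsv"), hdr)
    write_tsv(forest$tracks, file.path(out_dir, "lineage_tracks.tsv"), hdr)
    write_tsv(forest$map, file.path(out_dir, "lineage_map.tsv"), hdr)
    write_tsv(migration, file.path(out_dir, "migration.tsv"), hdr)
    write_tsv(growth, file.path(out_dir, "growth.tsv"), hdr)
    write_tsv(ctc, file.path(out_dir, "class_time_course.tsv"), hdr)
    write_tsv(conv, file.path(out_dir, "conversion_events.tsv"), hdr)
    write_tsv(conv_summary, file.path(out_dir, "conversion_summary.tsv"), hdr)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(list(movie = movie, observations = obs_all, obs_list = obs_list,
                 links = links, forest = forest, migration = migration,
                 growth = growth, class_time_course = ctc,
                 conversions = conv, conversion_summary = conv_summary,
                 summary = summary, thresholds = thr))
}

#' Run the expression pipeline
#'
#' Simulate a compendium (stream 2 of the master seed), normalise every
#' dataset, merge by official symbol, score every column with the EMT
#' signature and the metabolism gene sets, compute up-regulation fractions
#' for the Stat3/Sox2 panel and the strong-EMT stratification, and write
#' the report.
#'
#' @param config a [run_config()] (or path to its YAML).
#' @param out_dir optional output directory.
#' @return a result bundle (list) with the compendium, merged matrix,
#'   per-column scores, fractions, stratification and `report`.
#' @export
run_expression_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  args <- config$compendium
  if (is.null(args$seed)) args$seed <- derive_seed(config$seed, 2L)
  ccfg <- do.call(compendium_config, args)
  comp <- run_stage("simulate-compendium", generate_compendium(ccfg))
  normalized <- run_stage("normalize",
                          lapply(comp$datasets, normalize_dataset))
  merged <- run_stage("merge",
                      merge_by_symbol(normalized, default_alias_table()))
  sig <- ccfg$signature
  up_threshold <- config$scoring$up_threshold %||% 1.5
  strong_quantile <- config$scoring$strong_quantile %||% 0.75
  strat <- run_stage("stratify",
                     stratify_by_emt(merged, sig,
                                     strong_quantile = strong_quantile,
                                     threshold = up_threshold))
  met <- vapply(seq_len(ncol(merged$matrix)), function(j) {
    v <- merged$matrix[, j]
    metabolism_score(v[!is.na(v)])$score
  }, numeric(1L))
  scores <- data.frame(column = colnames(merged$matrix),
                       emt_score = as.numeric(strat$scores),
                       metabolism_score = met)
  fractions <- do.call(rbind, lapply(
    c("Stat3", "Sox2", "Map1b", "Reln", "Robo1", "Tubb3"), function(g) {
      f <- upregulation_fraction(merged, g, threshold = up_threshold)
      data.frame(gene = g, percent = f$percent, n_up = f$n_up,
                 basis = f$basis)
    }))
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 n_datasets = ccfg$n_datasets,
                 n_columns = ncol(merged$matrix),
                 up_threshold = up_threshold,
                 strong_quantile = strong_quantile,
                 fractions = fractions,
                 enrichment = strat$enrichment)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(config_hash = report$config_hash, seed = config$seed)
    write_tsv(data.frame(gene = rownames(merged$matrix), merged$matrix,
                         check.names = FALSE),
              file.path(out_dir, "merged_compendium.tsv"), hdr)
    write_tsv(scores, file.path(out_dir, "column_scores.tsv"), hdr)
    write_tsv(fractions, file.path(out_dir, "upregulation_fractions.tsv"),
              hdr)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(list(compendium = comp, merged = merged, scores = scores,
                 fractions = fractions, stratification = strat,
                 report = report))
}
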