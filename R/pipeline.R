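# End-to-end orchestration: screen -> insertion matrix -> IACFs -> per
# replicate clusters -> CACFs -> hierarchical annotation -> summary.

#' Default pipeline configuration
#'
#' @param seed integer seed driving every random stage.
#' @param sim a [screen_sim_config()] (synthetic mode) or `NULL` when event
#'   files are supplied.
#' @param control_beds,treated_beds per-replicate raw-event BED paths (one
#'   record per read), used when `sim` is `NULL`.
#' @param genome_lengths named contig lengths (required in file mode;
#'   derived from `sim` otherwise).
#' @param iacf an [iacf_params()].
#' @param islands an [island_params()].
#' @param min_support CACF replicate support; default 2.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = screen_sim_config(),
                            control_beds = NULL, treated_beds = NULL,
                            genome_lengths = NULL,
                            iacf = iacf_params(),
                            islands = island_params(),
                            min_support = 2) {
  if (is.null(sim)) {
    if (length(control_beds) != length(treated_beds) ||
        length(control_beds) < 3)
      stopf("file mode needs 3 control and 3 treated replicate BEDs")
    if (is.null(genome_lengths)) stopf("file mode needs genome_lengths")
  }
  structure(list(seed = seed, sim = sim, control_beds = control_beds,
                 treated_beds = treated_beds,
                 genome_lengths = genome_lengths, iacf = iacf,
                 islands = islands, min_support = min_support),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `sim` (synthetic-screen fields),
#' `control_beds`, `treated_beds`, `genome_lengths`, `iacf`, `islands`,
#' `min_support`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$control_beds)) NULL
         else do.call(screen_sim_config, c(
           if (!is.null(y$sim$genome_lengths))
             list(genome_lengths = unlist(y$sim$genome_lengths)),
           y$sim[setdiff(names(y$sim), "genome_lengths")]))
  pipeline_config(
    seed = y$seed %||% 1,
    sim = sim,
    control_beds = y$control_beds, treated_beds = y$treated_beds,
    genome_lengths = if (!is.null(y$genome_lengths))
      unlist(y$genome_lengths),
    iacf = do.call(iacf_params, y$iacf %||% list()),
    islands = do.call(island_params, y$islands %||% list()),
    min_support = y$min_support %||% 2)
}

#' Run the analysis pipeline
#'
#' Executes screen acquisition (synthetic simulation or event-file
#' loading), depth normalization, IACF calling, per-replicate cluster
#' calling in both directions, CACF consensus, coordinate merging,
#' hierarchical annotation (synthetic mode), and the summary report. With
#' `outdir` set, stage outputs (BED/TSV), `summary.json` and
#' `pipeline.log` are written; reruns with the same configuration and seed
#' reproduce them byte-for-byte.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param outdir output directory, or `NULL` for in-memory results only.
#' @return list: `matrix`, `iacfs`, `clusters`, `cacfs`, `merged`,
#'   `categories` (synthetic mode), `summary`, `annotations` (synthetic
#'   mode), `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[inset] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  note("config: seed=%d mode=%s", config$seed,
       if (is.null(config$sim)) "files" else "synthetic")
  annotations <- NULL
  if (!is.null(config$sim)) {
    genome_lengths <- config$sim$genome_lengths
    annotations <- stage("annotations",
                         generate_annotations(config$sim))
    screen <- stage("screen",
                    simulate_screen(config$sim, annotations,
                                    seed = config$seed))
    mat <- screen$matrix
    nrep <- config$sim$replicates
    control_ids <- paste0("ctrl_", seq_len(nrep))
    treated_ids <- paste0("trt_", seq_len(nrep))
    events_c <- screen$events[control_ids]
    events_t <- screen$events[treated_ids]
  } else {
    genome_lengths <- config$genome_lengths
    load_events <- function(path) {
      b <- read_bed(path)
      data.frame(chrom = b$chrom, pos = b$start, stringsAsFactors = FALSE)
    }
    events_c <- lapply(config$control_beds, load_events)
    events_t <- lapply(config$treated_beds, load_events)
    names(events_c) <- control_ids <- paste0("ctrl_",
                                             seq_along(events_c))
    names(events_t) <- treated_ids <- paste0("trt_", seq_along(events_t))
    mat <- NULL
    for (s in c(control_ids, treated_ids)) {
      ev <- c(events_c, events_t)[[s]]
      mat <- aggregate_counts(ev, s, existing = mat)
    }
    mat <- normalize_depth(mat)
  }
  note("matrix: %d sites x %d samples", nrow(mat$sites), ncol(mat$counts))

  iacfs <- stage("iacf",
                 call_iacfs(mat, control_ids, treated_ids, config$iacf))
  note("iacf: %d calls (fdr <= %.2f)", nrow(iacfs),
       config$iacf$fdr_threshold)

  clusters <- stage("clusters", {
    cl <- lapply(seq_along(events_t), function(i)
      call_fitness_clusters(events_t[[i]], events_c[[i]],
                            genome_lengths, config$islands))
    names(cl) <- paste0("rep", seq_along(cl))
    cl
  })
  note("clusters: %s",
       paste(names(clusters), vapply(clusters, nrow, integer(1)),
             sep = "=", collapse = " "))

  cacfs <- stage("cacf", consensus_cacfs(clusters, config$min_support))
  merged <- stage("merge", merge_unique(cacfs))
  note("cacf: %d consensus, %d unique merged", nrow(cacfs),
       merged$n_unique)

  categories <- NULL
  if (!is.null(annotations) && nrow(cacfs) > 0) {
    mid <- data.frame(chrom = cacfs$chrom,
                      pos = floor((cacfs$start + cacfs$end) / 2))
    categories <- stage("annotate",
                        assign_category(mid, annotations$hierarchy))
  }

  summary <- stage("summary",
                   overlap_summary(iacfs, cacfs, nrow(mat$sites)))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_insertion_matrix(mat, file.path(outdir, "insertion_matrix.tsv"))
    if (nrow(iacfs))
      write_bed(gintervals(iacfs$chrom, iacfs$pos, iacfs$pos + 1,
                           iacfs$strand, name = iacfs$direction,
                           score = signif(iacfs$q, 6)),
                file.path(outdir, "iacfs.bed"))
    if (nrow(cacfs))
      write_bed(gintervals(cacfs$chrom, cacfs$start, cacfs$end,
                           name = paste0(cacfs$direction, ";",
                                         cacfs$support)),
                file.path(outdir, "cacfs.bed"))
    jsonlite::write_json(list(counts = summary$counts,
                              percentages = summary$percentages),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log, file.path(outdir, "pipeline.log"))
  }
  list(matrix = mat, iacfs = iacfs, clusters = clusters, cacfs = cacfs,
       merged = merged, categories = categories, summary = summary,
       annotations = annotations, log = log)
}
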