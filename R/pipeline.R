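#' Pipeline configuration
#'
#' Assembles a validated configuration for [run_pipeline()]. All
#' randomness in a run is funnelled through `seed`, which is recorded in
#' the manifest.
#'
#' @param output_dir directory receiving all stage outputs.
#' @param seed integer seed for every stochastic step.
#' @param stages character vector, subset of
#'   `c("simulate", "hic", "annotation", "conservation")`, executed in
#'   dependency order.
#' @param params named list of parameter overrides, with elements `hic`,
#'   `annot`, `coupling` passed to the corresponding generators.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            stages = c("simulate", "hic", "annotation",
                                       "conservation"),
                            params = list()) {
  known <- c("simulate", "hic", "annotation", "conservation")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ","))
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = known[known %in% stages], params = params),
            class = "PipelineConfig")
}

#' Read a plain key-value pipeline configuration file
#'
#' Lines of the form `key = value`; `stages` is comma-separated; keys of
#' the form `section.name` populate the params list (numeric values are
#' converted).
#'
#' @param path configuration file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  cfg <- list(output_dir = ".", seed = 1L,
              stages = c("simulate", "hic", "annotation", "conservation"),
              params = list())
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    if (k == "output_dir") cfg$output_dir <- v
    else if (k == "seed") cfg$seed <- as.integer(num)
    else if (k == "stages") cfg$stages <- trimws(strsplit(v, ",")[[1L]])
    else if (grepl(".", k, fixed = TRUE)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
      cfg$params[[parts[1L]]][[parts[2L]]] <-
        if (is.na(num)) v else num
    } else stop("unknown config key: ", k)
  }
  pipeline_config(cfg$output_dir, cfg$seed, cfg$stages, cfg$params)
}

#' Generate a synthetic fixture directory
#'
#' Calls the synthetic-data generators and writes every format the
#' analysis stages read: a binned contact map (bins BED + pair counts)
#' with planted-structure truth files, per-species GTF annotations with
#' an orthology table and the planted syntenic triplets, and a coupled
#' peak/expression dataset.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param hic,annot,coupling named lists of generator parameter
#'   overrides.
#' @return invisible character vector of the files written.
#' @export
simulate_fixtures <- function(out_dir, seed = 1L, hic = list(),
                              annot = list(), coupling = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output dir not writable: ", out_dir)
  files <- character(0)
  w <- function(path) {
    files <<- c(files, path)
    path
  }
  tsv <- function(df, path) {
    utils::write.table(df, w(path), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  sim <- do.call(simulate_contact_map, c(list(seed = seed), hic))
  dir.create(file.path(out_dir, "hic"), showWarnings = FALSE)
  write_contact_map(sim$map, w(file.path(out_dir, "hic", "bins.bed")),
                    w(file.path(out_dir, "hic", "pairs.tsv")))
  tsv(data.frame(bin = seq_along(sim$truth$labels) - 1L,
                 label = sim$truth$labels),
      file.path(out_dir, "hic", "truth_labels.tsv"))
  tsv(sim$truth$tads, file.path(out_dir, "hic", "truth_tads.tsv"))

  ms <- do.call(simulate_multispecies_annotation,
                c(list(seed = seed), annot))
  dir.create(file.path(out_dir, "annot"), showWarnings = FALSE)
  for (sp in names(ms$annotations)) {
    write_gtf(ms$annotations[[sp]],
              w(file.path(out_dir, "annot", paste0(sp, ".gtf"))))
  }
  tsv(ms$orthology, file.path(out_dir, "annot", "orthology.tsv"))
  tsv(ms$planted, file.path(out_dir, "annot", "planted_triplets.tsv"))

  cp <- do.call(simulate_coupled_peaks_expression,
                c(list(ann = ms$annotations[[1L]], seed = seed), coupling))
  dir.create(file.path(out_dir, "coupling"), showWarnings = FALSE)
  write_bed(data.frame(cp$peaks$peaks[, c("chrom", "start", "end")],
                       name = cp$peaks$peaks$peak_id),
            w(file.path(out_dir, "coupling", "peaks.bed")))
  tsv(data.frame(peak_id = rownames(cp$peaks$counts), cp$peaks$counts,
                 check.names = FALSE),
      file.path(out_dir, "coupling", "peak_counts.tsv"))
  write_expression(cp$expression,
                   w(file.path(out_dir, "coupling", "expression.tsv")))
  tsv(data.frame(gene_id = names(cp$truth), coupling = unname(cp$truth)),
      file.path(out_dir, "coupling", "truth_coupling.tsv"))
  invisible(files)
}

#' Run the analysis pipeline on a fixture directory
#'
#' Executes the requested stages in dependency order (simulate -> hic ->
#' annotation -> conservation), writing every stage output to files under
#' the configured directory plus a JSON manifest recording the package
#' version, seed, parameters and output checksums. A rerun with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fixdir <- file.path(out, "fixtures")
  resdir <- file.path(out, "results")
  dir.create(resdir, showWarnings = FALSE)
  need <- function(stage, ...) {
    paths <- c(...)
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      stop(sprintf("stage '%s': missing input %s (run the 'simulate' stage)",
                   stage, miss[1L]))
    }
    paths
  }
  outputs <- character(0)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
  }

  if ("simulate" %in% config$stages) {
    outputs <- c(outputs, simulate_fixtures(
      fixdir, seed = config$seed,
      hic = config$params$hic %||% list(),
      annot = config$params$annot %||% list(),
      coupling = config$params$coupling %||% list()))
  }

  if ("hic" %in% config$stages) {
    need("hic", file.path(fixdir, "hic", "bins.bed"),
         file.path(fixdir, "hic", "pairs.tsv"))
    cm <- read_contact_map(file.path(fixdir, "hic", "bins.bed"),
                           file.path(fixdir, "hic", "pairs.tsv"))
    track <- call_compartments(cm)
    write_compartments_bed(track, file.path(resdir, "compartments.bed"))
    outputs <- c(outputs, file.path(resdir, "compartments.bed"))
    prof <- insulation_profile(cm)
    tsv(data.frame(chrom = prof$chrom, position = prof$positions,
                   score = signif(prof$scores, 6)),
        file.path(resdir, "insulation.tsv"))
    di <- directionality_index(cm, window_bp = 20L * cm$bin_size)
    tsv(data.frame(chrom = cm$chrom, di[, c("bin", "DI", "edge")]),
        file.path(resdir, "directionality.tsv"))
    tads <- utils::read.table(file.path(fixdir, "hic", "truth_tads.tsv"),
                              header = TRUE)
    bsc <- boundary_scores(
      data.frame(start = tads$start_bin * cm$bin_size,
                 end = tads$end_bin * cm$bin_size), prof)
    tsv(bsc, file.path(resdir, "boundary_scores.tsv"))
  }

  if ("annotation" %in% config$stages) {
    need("annotation", file.path(fixdir, "annot", "sp1.gtf"),
         file.path(fixdir, "coupling", "peak_counts.tsv"),
         file.path(fixdir, "coupling", "peaks.bed"),
         file.path(fixdir, "coupling", "expression.tsv"))
    ann <- read_gtf(file.path(fixdir, "annot", "sp1.gtf"))
    bed <- read_bed(file.path(fixdir, "coupling", "peaks.bed"))
    cnt <- utils::read.table(file.path(fixdir, "coupling", "peak_counts.tsv"),
                             header = TRUE, check.names = FALSE,
                             row.names = 1L)
    pk <- peak_set(data.frame(peak_id = bed$name, chrom = bed$chrom,
                              start = bed$start, end = bed$end),
                   as.matrix(cnt))
    dom <- classify_peaks(pk, ann)
    tsv(data.frame(peak_id = rownames(dom), dom, check.names = FALSE),
        file.path(resdir, "peak_domains.tsv"))
    expr <- read_expression(file.path(fixdir, "coupling", "expression.tsv"))
    acc <- promoter_accessibility(pk, ann)
    corr <- expression_accessibility_correlation(expr, acc)
    corr$r <- signif(corr$r, 6)
    tsv(corr, file.path(resdir, "gene_correlation.tsv"))
    cl <- cluster_samples(expr)
    write_dendrogram_newick(cl$hclust,
                            file.path(resdir, "sample_dendrogram.nwk"))
    outputs <- c(outputs, file.path(resdir, "sample_dendrogram.nwk"))
  }

  if ("conservation" %in% config$stages) {
    ortho_path <- file.path(fixdir, "annot", "orthology.tsv")
    need("conservation", ortho_path, file.path(fixdir, "annot", "sp1.gtf"))
    ortho <- utils::read.table(ortho_path, header = TRUE,
                               stringsAsFactors = FALSE)
    gtfs <- list.files(file.path(fixdir, "annot"), pattern = "^sp\\d+\\.gtf$",
                       full.names = TRUE)
    anns <- lapply(gtfs, read_gtf)
    names(anns) <- sub("\\.gtf$", "", basename(gtfs))
    tri <- detect_syntenic_lncrnas(anns, ortho)
    tsv(tri, file.path(resdir, "syntenic_triplets.tsv"))
    # peaks vs promoter windows on the first species
    ann <- anns[[1L]]
    bed <- read_bed(file.path(fixdir, "coupling", "peaks.bed"))
    tt <- derive_tss_tts(ann)$by_transcript
    win <- data.frame(chrom = tt$chrom, start = pmax(0L, tt$tss - 1000L),
                      end = tt$tss + 1001L)
    span <- max(c(bed$end, win$end))
    sizes <- stats::setNames(span + 10000, unique(c(bed$chrom, win$chrom)))
    pt <- permutation_overlap_test(
      bed[, c("chrom", "start", "end")], win, sizes,
      n_perm = 200L, seed = config$seed)
    json_path <- file.path(resdir, "overlap_test.json")
    jsonlite::write_json(
      list(observed_count = pt$observed_count,
           observed_fraction = pt$observed_fraction,
           p_value = pt$p_value),
      json_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, json_path)
  }

  outputs <- unique(outputs)
  manifest <- list(
    package = "epicross",
    version = as.character(utils::packageVersion("epicross")),
    seed = config$seed,
    stages = config$stages,
    params = config$params,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)),
      sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out), "/?"),
          "", outputs)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
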