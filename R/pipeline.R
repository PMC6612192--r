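#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis. The defaults are
#' the reference study conditions for the OASIS-style corpus: keywords with
#' fewer than 10 occurrences ignored, network nodes at frequency >= 100 and
#' edges at similarity >= 0.57, MCL with expansion 2 / inflation 2.0 /
#' pruning 0.02, and the six-phase preset as the segmentation.
#'
#' @param corpus Path to the corpus file (CSV or JSON-lines).
#' @param synonyms Optional path to a synonym-map TSV.
#' @param corpus_format Passed to [read_corpus()].
#' @param years Optional inclusive study year range.
#' @param min_freq Keyword frequency filter (default 10).
#' @param phases `"preset"` (use `preset_phases`), `"drop"` or `"fixed"`
#'   (run [segment_phases()] with the parameters below).
#' @param preset_phases A [phase_set()] used when `phases = "preset"`;
#'   default [oasis_phases()].
#' @param delta,zero_eps,min_phase_len,fixed_width Segmentation parameters
#'   (see [segment_phases()]).
#' @param network_min_freq,network_min_sim Network thresholds (defaults
#'   100, 0.57).
#' @param mcl An [mcl_params()] object.
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the corpus is generated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = NULL, synonyms = NULL,
                            corpus_format = "auto", years = NULL,
                            min_freq = 10,
                            phases = c("preset", "drop", "fixed"),
                            preset_phases = oasis_phases(),
                            delta = 0.1, zero_eps = 0, min_phase_len = 3,
                            fixed_width = 10,
                            network_min_freq = 100, network_min_sim = 0.57,
                            mcl = mcl_params(),
                            out_dir = "kwtrends_out", seed = 1L) {
  phases <- match.arg(phases)
  structure(list(
    corpus = corpus, synonyms = synonyms, corpus_format = corpus_format,
    years = years, min_freq = min_freq, phases = phases,
    preset_phases = preset_phases, delta = delta, zero_eps = zero_eps,
    min_phase_len = min_phase_len, fixed_width = fixed_width,
    network_min_freq = network_min_freq, network_min_sim = network_min_sim,
    mcl = mcl, out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Serialize / read a pipeline configuration as YAML
#'
#' Round-trip safe: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x$preset_phases <- list(start = cfg$preset_phases$start,
                          end = cfg$preset_phases$end)
  x$mcl <- unclass(cfg$mcl)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    corpus = x$corpus, synonyms = x$synonyms,
    corpus_format = x$corpus_format,
    years = if (is.null(x$years)) NULL else as.integer(unlist(x$years)),
    min_freq = x$min_freq, phases = x$phases,
    preset_phases = phase_set(as.integer(unlist(x$preset_phases$start)),
                              as.integer(unlist(x$preset_phases$end))),
    delta = x$delta, zero_eps = x$zero_eps,
    min_phase_len = x$min_phase_len, fixed_width = x$fixed_width,
    network_min_freq = x$network_min_freq,
    network_min_sim = x$network_min_sim,
    mcl = mcl_params(x$mcl$expansion, x$mcl$inflation, x$mcl$pruning,
                     x$mcl$max_iterations, x$mcl$convergence_tol,
                     x$mcl$self_loops),
    out_dir = x$out_dir, seed = x$seed
  )
}

#' Run the full trend-analysis pipeline
#'
#' Reads the corpus (and synonym map if configured), builds the annual
#' frequency matrix, computes the year-over-year similarity series and
#' phase segmentation, aggregates the phase table, builds and clusters the
#' co-trend network, and writes every artifact into `cfg$out_dir`:
#' `matrix.tsv` (+ `.meta.yaml` sidecar), `similarity.tsv`,
#' `phase_table.tsv`, `network.graphml`, `network.gexf`, `clusters.tsv`,
#' `report.txt` and `manifest.yaml` (parameters plus md5 checksums of all
#' inputs and outputs). Outputs are staged in a temporary directory and
#' moved into place only on success, so a failing stage leaves no partial
#' bundle; re-running with identical inputs and configuration is
#' byte-identical.
#'
#' @param cfg A [pipeline_config()] with `corpus` set, or `articles`
#'   supplied directly.
#' @param articles Optional corpus data frame, overriding `cfg$corpus`.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage results (`matrix`,
#'   `series`, `phases`, `phase_table`, `network`, `clustering`,
#'   `out_dir`).
#' @export
run_pipeline <- function(cfg, articles = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[kwtrends] ", ...)

  # validate inputs up front so failure leaves nothing behind
  input_files <- character(0)
  if (is.null(articles)) {
    if (is.null(cfg$corpus)) {
      stop("pipeline stage 'input': no corpus path configured and no ",
           "articles supplied", call. = FALSE)
    }
    if (!file.exists(cfg$corpus)) {
      stop("pipeline stage 'input': corpus file not found: ", cfg$corpus,
           call. = FALSE)
    }
    input_files <- c(input_files, corpus = cfg$corpus)
  }
  if (!is.null(cfg$synonyms)) {
    if (!file.exists(cfg$synonyms)) {
      stop("pipeline stage 'input': synonym map not found: ", cfg$synonyms,
           call. = FALSE)
    }
    input_files <- c(input_files, synonyms = cfg$synonyms)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(articles)) {
    articles <- stage("input",
      read_corpus(cfg$corpus, cfg$corpus_format, quiet = quiet))
  }
  map <- if (!is.null(cfg$synonyms)) {
    stage("input", load_synonym_map(cfg$synonyms))
  } else NULL
  say("corpus: ", nrow(articles), " articles")
  if (!is.null(map)) say("synonym map: ", length(map), " variants")

  m <- stage("matrix",
    build_annual_matrix(articles, map, min_freq = cfg$min_freq,
                        years = cfg$years))
  say("matrix: ", nrow(m$counts), " keywords x ", length(m$years),
      " years (min_freq ", cfg$min_freq, ")")

  series <- stage("temporal", similarity_series(m))
  phases <- stage("temporal", switch(cfg$phases,
    preset = {
      check_phase_cover(cfg$preset_phases, m$years)
      cfg$preset_phases
    },
    drop = segment_phases(series, delta = cfg$delta,
                          zero_eps = cfg$zero_eps,
                          min_len = cfg$min_phase_len),
    fixed = segment_phases(series, method = "fixed",
                           width = cfg$fixed_width)
  ))
  say("phases: ", nrow(phases))
  pt <- stage("temporal", phase_aggregate(m, phases))

  g <- stage("network",
    build_cotrend_network(m, min_freq = cfg$network_min_freq,
                          min_sim = cfg$network_min_sim))
  say("network: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
      " edges")
  cl <- stage("mcl", mcl_cluster(g, cfg$mcl))
  say("clusters: ", length(cl$clusters))

  # write everything to a staging area, then move into place
  staging <- tempfile("kwtrends_stage_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  stage("output", {
    write_annual_matrix(m, file.path(staging, "matrix.tsv"))
    utils::write.table(series, file.path(staging, "similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ptdf <- data.frame(keyword = rownames(pt$counts), pt$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(ptdf, file.path(staging, "phase_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_network(g, file.path(staging, "network.graphml"), "graphml")
    export_network(g, file.path(staging, "network.gexf"), "gexf")
    utils::write.table(
      data.frame(keyword = names(cl$labels), cluster = unname(cl$labels)),
      file.path(staging, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(pipeline_report(cfg, articles, m, series, phases, pt, g, cl),
               file.path(staging, "report.txt"))
    manifest <- list(
      parameters = yaml::yaml.load(yaml::as.yaml(
        read_write_roundtrip(cfg))),
      inputs = as.list(tools::md5sum(input_files)),
      n_articles = nrow(articles),
      outputs = as.list(tools::md5sum(
        list.files(staging, full.names = TRUE)))
    )
    names(manifest$outputs) <- basename(names(manifest$outputs))
    yaml::write_yaml(manifest, file.path(staging, "manifest.yaml"))
  })

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(staging, full.names = TRUE)) {
    file.copy(f, file.path(cfg$out_dir, basename(f)), overwrite = TRUE)
  }
  say("wrote ", length(list.files(cfg$out_dir)), " files to ", cfg$out_dir)

  invisible(list(matrix = m, series = series, phases = phases,
                 phase_table = pt, network = g, clustering = cl,
                 out_dir = cfg$out_dir))
}

read_write_roundtrip <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_pipeline_config(cfg, f)
  yaml::read_yaml(f)
}

pipeline_report <- function(cfg, articles, m, series, phases, pt, g, cl) {
  top <- top_keywords(m, 10)
  c(
    "Keyword trend analysis report",
    "=============================",
    "",
    sprintf("Corpus: %d articles, %d-%d", nrow(articles), m$years[1],
            m$years[length(m$years)]),
    sprintf("Keywords kept (frequency >= %d): %d", cfg$min_freq,
            nrow(m$counts)),
    "",
    "Top keywords:",
    sprintf("  %2d. %-30s %d", top$rank, top$keyword, top$frequency),
    "",
    sprintf("Phases (%d):", nrow(phases)),
    sprintf("  %d-%d (%d articles)", phases$start, phases$end,
            pt$article_totals),
    "",
    sprintf("Co-trend network: %d nodes (freq >= %g), %d edges (J >= %g)",
            igraph::vcount(g), cfg$network_min_freq, igraph::ecount(g),
            cfg$network_min_sim),
    sprintf("MCL clusters (expansion %d, inflation %g, pruning %g): %d",
            cfg$mcl$expansion, cfg$mcl$inflation, cfg$mcl$pruning,
            length(cl$clusters)),
    vapply(seq_along(cl$clusters), function(k) {
      sprintf("  cluster %d (n=%d): %s", k, length(cl$clusters[[k]]),
              paste(cl$clusters[[k]], collapse = ", "))
    }, character(1))
  )
}
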