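# End-to-end orchestration: similarity -> graph -> sweep -> families ->
# motifs -> annotation -> optional elements -> host network, with all
# intermediates written to an output directory and a checksum manifest.

#' Run the whole family-inference pipeline
#'
#' Executes the stages in order: all-vs-all similarity search (skipped when
#' a precomputed hit table is supplied), similarity-graph construction,
#' MCL inflation sweep with ICCC selection, per-family alignment and motif
#' detection, family annotation and report, optional element detection on a
#' feature table, and the host-sharing network.  The run is deterministic:
#' identical inputs and options give identical outputs.
#'
#' @param proteins Tibble with `id`, `sequence`, `mge_type`, `host`,
#'   `replicon` (e.g. from [generate_protein_set()], or join
#'   [read_fasta()] + [read_metadata_tsv()]).
#' @param fasta,metadata Alternatively, paths to a protein FASTA and its
#'   metadata sidecar TSV.
#' @param hits Optional precomputed hit tibble; `hits_file` reads one in
#'   BLAST tabular format.  Either skips the alignment stage.
#' @param features Optional gene-feature tibble (or `gff` path) for element
#'   detection.
#' @param out_dir Optional output directory; when given, every stage result
#'   is written there and a `manifest.json` with md5 checksums is produced.
#' @param scoring [scoring_scheme()].
#' @param e_cutoff,weight_cap Hit filtering and graph construction options.
#' @param mcl_opts,grid [mcl_options()] and inflation grid.
#' @param motif_opts [motif_options()].
#' @param ann_rules [annotation_rules()].
#' @param elem_rules [element_rules()].
#' @param bim_partner_famint Partner family for BIM detection (skipped when
#'   `NULL`).
#' @param min_shared_family_size Family-size floor for the host network.
#' @return An object of class `famint_run`: list with `proteins`, `hits`,
#'   `graph`, `sweep`, `partition`, `motifs`, `profiles`, `report`,
#'   `elements`, `host_graph`, `components`, `manifest`.
#' @export
run_pipeline <- function(proteins = NULL, fasta = NULL, metadata = NULL,
                         hits = NULL, hits_file = NULL,
                         features = NULL, gff = NULL, out_dir = NULL,
                         scoring = scoring_scheme(), e_cutoff = 0.01,
                         weight_cap = 200, mcl_opts = mcl_options(),
                         grid = sweep_grid(), motif_opts = motif_options(),
                         ann_rules = annotation_rules(),
                         elem_rules = element_rules(),
                         bim_partner_famint = NULL,
                         min_shared_family_size = 2L) {
  warnings <- character(0)
  stages <- character(0)
  if (is.null(proteins)) {
    if (is.null(fasta) || is.null(metadata)) {
      abort("supply `proteins` or both `fasta` and `metadata`")
    }
    proteins <- read_fasta(fasta) |>
      left_join(read_metadata_tsv(metadata), by = c(id = "protein_id"))
  }
  stages <- c(stages, "input")

  if (is.null(hits)) {
    if (!is.null(hits_file)) {
      hits <- read_hits_blasttab(hits_file)
      stages <- c(stages, "hits:precomputed")
    } else {
      hits <- all_vs_all(proteins, scoring, e_cutoff)
      stages <- c(stages, "hits:aligned")
    }
  } else {
    stages <- c(stages, "hits:supplied")
  }

  graph <- build_graph(hits, weight_cap = weight_cap, nodes = proteins$id,
                       e_cutoff = e_cutoff)
  stages <- c(stages, "graph")

  sweep <- withCallingHandlers(
    inflation_sweep(graph, grid, mcl_opts),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  partition <- selected_partition(sweep)
  stages <- c(stages, "sweep")

  motifs <- family_motifs(partition, proteins, graph, scoring, motif_opts)
  stages <- c(stages, "motifs")

  profiles <- annotate_families(partition, proteins, motifs, ann_rules)
  report <- family_report(profiles, partition, ann_rules)
  stages <- c(stages, "annotation")

  elements <- NULL
  if (!is.null(gff) && is.null(features)) features <- read_gff3(gff)
  if (!is.null(features)) {
    elements <- detect_elements(features, elem_rules, bim_partner_famint)
    stages <- c(stages, "elements")
  }

  host_nodes <- group_hosts(proteins)
  host_graph <- shared_family_graph(partition, proteins, host_nodes,
                                    min_shared_family_size)
  components <- host_components(host_graph)
  stages <- c(stages, "network")

  run <- structure(list(
    proteins = proteins, hits = hits, graph = graph, sweep = sweep,
    partition = partition, motifs = motifs, profiles = profiles,
    report = report, elements = elements, host_graph = host_graph,
    components = components, manifest = NULL), class = "famint_run")

  run$manifest <- if (!is.null(out_dir)) {
    write_run_outputs(run, out_dir, stages, warnings)
  } else {
    list(stages = stages, warnings = warnings)
  }
  run
}

write_run_outputs <- function(run, out_dir, stages, warnings) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msa_dir <- file.path(out_dir, "msa")
  dir.create(msa_dir, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  write_fasta(run$proteins, p("proteins.fasta"))
  write_metadata_tsv(run$proteins, p("metadata.tsv"))
  write_hits_blasttab(run$hits, p("hits.blasttab.tsv"))
  write_abc(run$graph, p("graph.abc"))
  write_sweep_tsv(run$sweep, p("sweep.tsv"))
  write_mcl_clusters(run$partition, p("clusters.mcl"))
  write_partition_tsv(run$partition, p("partition.tsv"))
  run$motifs |>
    select("famint", "size", "found", "label", "y_column", "r_column",
           "median_spacing", "y_conservation", "r_conservation") |>
    readr::write_tsv(p("motifs.tsv"))
  for (k in seq_len(nrow(run$motifs))) {
    aln <- run$motifs$msa[[k]]
    write_fasta(aln$rows,
                file.path(msa_dir, sprintf("famint%03d.fasta",
                                           run$motifs$famint[k])))
  }
  run$report$families |> readr::write_tsv(p("family_report.tsv"))
  per_protein <- run$partition$assignment |>
    left_join(run$profiles |>
                select("famint", family_size = "size", "specificity",
                       "motif_label"), by = "famint") |>
    left_join(run$proteins |> select(protein_id = "id", "length"),
              by = "protein_id") |>
    mutate(defective = .data$length < 200L)
  readr::write_tsv(per_protein, p("protein_annotation.tsv"))
  if (!is.null(run$elements)) {
    write_element_calls(run$elements, p("elements.gff3"), p("elements.tsv"))
  }
  readr::write_tsv(run$host_graph$edges, p("host_edges.tsv"))
  comp_tbl <- tibble(
    component = rep(seq_along(run$components), lengths(run$components)),
    label = unlist(run$components))
  readr::write_tsv(comp_tbl, p("host_components.tsv"))

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    stages = stages,
    warnings = warnings,
    timestamp = format(Sys.time(), tz = "UTC"),
    version = as.character(utils::packageVersion("famintr")),
    parameters = list(
      e_cutoff = run$graph$e_cutoff, weight_cap = run$graph$weight_cap,
      selected_inflation = attr(run$sweep, "selected_inflation"),
      min_shared_family_size = run$host_graph$min_family_size),
    files = as.list(tools::md5sum(file.path(out_dir, files))) |>
      setNames(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.famint_run <- function(x, ...) {
  cat("<famint_run>\n  proteins: ", nrow(x$proteins),
      "\n  families: ", length(x$partition$family_sizes),
      " (selected inflation ", attr(x$sweep, "selected_inflation"), ")\n",
      "  host components: ", length(x$components), "\n", sep = "")
  invisible(x)
}

#' Pipeline configuration as a plain list, with YAML round trip
#'
#' Collects the tunable options of [run_pipeline()] into one list that can
#' be written to and re-read from a YAML file losslessly.
#'
#' @param fasta,metadata,hits_file,gff Input paths (may be `NULL`).
#' @param out_dir Output directory.
#' @param e_cutoff,weight_cap Similarity-stage options.
#' @param scoring,mcl_opts,grid,motif_opts,ann_rules,elem_rules Stage
#'   option objects/values; the substitution matrix itself is not
#'   serialised (the default is implied).
#' @param bim_partner_famint,min_shared_family_size Remaining options.
#' @param seed Seed recorded for synthetic inputs.
#' @export
pipeline_config <- function(fasta = NULL, metadata = NULL, hits_file = NULL,
                            gff = NULL, out_dir = NULL, e_cutoff = 0.01,
                            weight_cap = 200, mcl_opts = mcl_options(),
                            grid = sweep_grid(),
                            motif_opts = motif_options(),
                            ann_rules = annotation_rules(),
                            elem_rules = element_rules(),
                            bim_partner_famint = NULL,
                            min_shared_family_size = 2L, seed = 1L) {
  list(paths = list(fasta = fasta, metadata = metadata,
                    hits_file = hits_file, gff = gff, out_dir = out_dir),
       e_cutoff = e_cutoff, weight_cap = weight_cap,
       mcl_opts = mcl_opts, grid = grid, motif_opts = motif_opts,
       ann_rules = ann_rules, elem_rules = elem_rules,
       bim_partner_famint = bim_partner_famint,
       min_shared_family_size = as.integer(min_shared_family_size),
       seed = as.integer(seed))
}

#' @rdname pipeline_config
#' @param config A [pipeline_config()] list.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # restore types yaml cannot distinguish
  cfg$mcl_opts$max_iterations <- as.integer(cfg$mcl_opts$max_iterations)
  cfg$motif_opts$spacing_range <- as.integer(cfg$motif_opts$spacing_range)
  cfg$motif_opts$min_rows <- as.integer(cfg$motif_opts$min_rows)
  for (f in grep("_range$", names(cfg$elem_rules), value = TRUE)) {
    cfg$elem_rules[[f]] <- as.integer(cfg$elem_rules[[f]])
  }
  for (f in c("tn554_max_gap", "long_next_extension_min",
              "bim_partner_max_gap")) {
    cfg$elem_rules[[f]] <- as.integer(cfg$elem_rules[[f]])
  }
  cfg$ann_rules$min_family_size <- as.integer(cfg$ann_rules$min_family_size)
  cfg$ann_rules$defective_max_len <-
    as.integer(cfg$ann_rules$defective_max_len)
  cfg$min_shared_family_size <- as.integer(cfg$min_shared_family_size)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the pipeline from a configuration list
#'
#' @param config A [pipeline_config()] list (or the path of a YAML file
#'   written by [write_config()]).
#' @param proteins Optional in-memory protein tibble overriding the
#'   configured FASTA/metadata paths.
#' @export
run_pipeline_config <- function(config, proteins = NULL) {
  if (is.character(config)) config <- read_config(config)
  run_pipeline(proteins = proteins,
               fasta = config$paths$fasta, metadata = config$paths$metadata,
               hits_file = config$paths$hits_file, gff = config$paths$gff,
               out_dir = config$paths$out_dir, e_cutoff = config$e_cutoff,
               weight_cap = config$weight_cap, mcl_opts = config$mcl_opts,
               grid = config$grid, motif_opts = config$motif_opts,
               ann_rules = config$ann_rules, elem_rules = config$elem_rules,
               bim_partner_famint = config$bim_partner_famint,
               min_shared_family_size = config$min_shared_family_size)
}
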