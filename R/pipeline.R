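#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one input source must be supplied: either paths to an existing
#' matrix TSV (plus optional groups TSV and GMT pathway library), or a
#' [study_config()] describing a synthetic study to simulate.
#'
#' @param matrix_path path to a metabolite-abundance matrix TSV.
#' @param groups_path optional path to the sample-to-group sidecar TSV.
#' @param gmt_path optional path to a GMT pathway library.
#' @param synthetic a [study_config()] for simulated input.
#' @param k_candidates candidate ranks for [select_rank()].
#' @param n_runs consensus restarts per candidate rank.
#' @param base_seed seed base for consensus restarts and the final fit.
#' @param objective NMF objective.
#' @param top_rule,top_threshold top-metabolite rule for signature lists and
#'   enrichment hits.
#' @param test two-group test for the differential table.
#' @param out_dir output directory.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, groups_path = NULL,
                            gmt_path = NULL, synthetic = NULL,
                            k_candidates = 2:7, n_runs = 50L, base_seed = 0L,
                            objective = "frobenius",
                            top_rule = "cumulative_mass", top_threshold = NULL,
                            test = "student_t", out_dir = "metabosig_out") {
  if (is.null(matrix_path) == is.null(synthetic))
    msig_stop("supply exactly one of `matrix_path` or `synthetic`", "config_error")
  if (!is.null(synthetic) && !inherits(synthetic, "study_config"))
    msig_stop("`synthetic` must be a study_config", "config_error")
  structure(list(matrix_path = matrix_path, groups_path = groups_path,
                 gmt_path = gmt_path, synthetic = synthetic,
                 k_candidates = as.integer(k_candidates),
                 n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
                 objective = objective, top_rule = top_rule,
                 top_threshold = top_threshold, test = test,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Field names mirror the arguments of [pipeline_config()]; a `synthetic`
#' block holds [study_config()] fields.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    if (!is.null(syn$n_per_group)) syn$n_per_group <- unlist(syn$n_per_group)
    if (!is.null(syn$group_signature_map))
      syn$group_signature_map <- unlist(syn$group_signature_map)
    if (!is.null(syn$planted_fold_changes))
      syn$planted_fold_changes <- as.data.frame(syn$planted_fold_changes)
    raw$synthetic <- do.call(study_config, syn)
  }
  do.call(pipeline_config, raw)
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  dump <- rapply(unclass(config), function(x)
    if (is.function(x)) NULL else x, how = "replace")
  jsonlite::write_json(dump, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full signature-extraction pipeline
#'
#' Chains all stages on one input: simulate (or load) the metabolite
#' matrix, select the number of signatures by consensus stability,
#' factorize at the chosen rank, normalize, cluster samples by signature
#' make-up, run pathway overrepresentation per signature (when a library is
#' available), and build the two-group differential table.  Every stage
#' writes its outputs as TSV/Newick under `out_dir`, and a run manifest
#' (JSON) records the package version, configuration hash, seeds, chosen
#' rank, per-stage outputs and wall times.  Re-running with an identical
#' configuration reproduces byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    msig_stop("`config` must be a pipeline_config", "config_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, msg) {
    if (!quiet) pipeline_log(log_con, stage, msg)
    else writeLines(sprintf("[%s] %s: %s",
                            format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg),
                    log_con)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("metabosig")),
                   config_hash = config_hash(config),
                   base_seed = config$base_seed,
                   stages = list(), partial = FALSE)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$partial <<- TRUE
      write_manifest(manifest, config$out_dir)
      msig_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "pipeline_stage_error")
    })
    manifest$stages[[name]] <<- list(
      outputs = attr(res, "outputs"),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  out <- function(...) file.path(config$out_dir, ...)

  # 1. input: simulate or load
  input <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      say("input", sprintf("simulating study (seed %d)", config$synthetic$seed))
      st <- generate_study(config$synthetic)
      write_metabolite_matrix(st$matrix, out("matrix.tsv"), out("groups.tsv"))
      write_study_truth(st$truth, out("truth"))
      structure(list(matrix = st$matrix, truth = st$truth),
                outputs = c("matrix.tsv", "groups.tsv", "truth/truth.json"))
    } else {
      say("input", sprintf("reading %s", config$matrix_path))
      mm <- read_metabolite_matrix(config$matrix_path, config$groups_path)
      structure(list(matrix = mm, truth = NULL), outputs = character(0))
    }
  })
  dat <- input$matrix
  truth <- input$truth

  # 2. rank selection
  sel <- run_stage("rank_selection", {
    say("rank_selection", sprintf("candidates %s, %d restarts",
                                  paste(range(config$k_candidates), collapse = "-"),
                                  config$n_runs))
    sel <- select_rank(dat, config$k_candidates, n_runs = config$n_runs,
                       base_seed = config$base_seed, objective = config$objective)
    write_rank_curve(sel, out("cophenetic_by_k.tsv"))
    write_consensus(sel$results[[as.character(sel$chosen_k)]],
                    out("consensus.tsv"))
    say("rank_selection", sprintf("chosen rank %d (cophenetic %.4f)",
                                  sel$chosen_k,
                                  sel$cophenetic_by_k[[as.character(sel$chosen_k)]]))
    structure(sel, outputs = c("cophenetic_by_k.tsv", "consensus.tsv"))
  })
  manifest$chosen_k <- sel$chosen_k

  # 3. factorization at the chosen rank
  fit <- run_stage("factorization", {
    fit <- nmf_factorize(dat, sel$chosen_k, objective = config$objective,
                         seed = config$base_seed + 1L, n_starts = 10L)
    write_named_table(unclass(fit$signatures), "metabolite", out("signatures.tsv"))
    write_named_table(unclass(fit$loadings), "signature", out("loadings.tsv"))
    structure(fit, outputs = c("signatures.tsv", "loadings.tsv"))
  })

  # 4. signature interpretation
  run_stage("signature_analysis", {
    dom <- dominant_signature(fit$loadings)
    utils::write.table(dom, out("dominant_signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    groups <- attr(dat, "groups")
    cl <- cluster_samples(fit$loadings,
                          cut_k = if (!is.null(groups)) length(unique(groups)) else 2L,
                          groups = groups)
    write_newick(cl, out("dendrogram.nwk"))
    utils::write.table(data.frame(sample = names(cl$flat_labels),
                                  cluster = unname(cl$flat_labels)),
                       out("cluster_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tops <- write_top_metabolites(fit$signatures, out("top_metabolites"),
                                  rule = config$top_rule,
                                  threshold = config$top_threshold)
    structure(cl, outputs = c("dominant_signature.tsv", "dendrogram.nwk",
                              "cluster_labels.tsv",
                              file.path("top_metabolites", basename(tops))))
  })

  # 5. enrichment (when a pathway library is available)
  lib <- if (!is.null(config$gmt_path)) {
    read_gmt(config$gmt_path)
  } else if (!is.null(truth)) {
    generate_pathway_library(
      n_pathways = 10L, size_range = c(10L, 30L), truth = truth,
      planted = lapply(seq_along(truth$dominant_map),
                       function(i) c(i, truth$dominant_map[[i]])),
      seed = config$base_seed + 2L)
  } else NULL
  if (!is.null(lib)) {
    run_stage("enrichment", {
      files <- vapply(colnames(fit$signatures), function(s) {
        tab <- enrich_signature(fit$signatures, s, lib,
                                rule = config$top_rule,
                                threshold = config$top_threshold)
        f <- sprintf("enrichment_%s.tsv", s)
        write_enrichment(tab, out(f))
        f
      }, character(1))
      if (is.null(config$gmt_path)) write_gmt(lib, out("library.gmt"))
      structure(lib, outputs = c(unname(files),
                                 if (is.null(config$gmt_path)) "library.gmt"))
    })
  }

  # 6. differential table (when groups are available)
  if (!is.null(attr(dat, "groups"))) {
    run_stage("differential", {
      tab <- fold_change(dat, test = config$test)
      write_differential(tab, out("differential.tsv"))
      structure(tab, outputs = "differential.tsv")
    })
  }

  run_stage("manifest", {
    structure(TRUE, outputs = "manifest.json")
  })
  write_manifest(manifest, config$out_dir)
  say("done", sprintf("outputs in %s", config$out_dir))
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
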