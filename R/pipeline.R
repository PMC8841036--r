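# End-to-end orchestration: simulate-or-load -> rarefy -> partition ->
# alpha/beta -> fertility/RF -> networks -> functions, from one config,
# with per-stage timing, sub-seeds and a JSON run report.

STAGE_NAMES <- c("data", "rarefy", "abundance", "alpha", "beta",
                 "fertility", "networks", "functions")

#' Analysis configuration
#'
#' Houses every fixed constant of the pipeline.  Defaults: rare taxa below
#' 0.01% and abundant above 0.1% of total reads; network candidates above
#' 0.5% relative abundance present in more than half the communities;
#' edges at |rho| >= 0.8 with BH-adjusted p <= 0.001; 999 permutations for
#' PERMANOVA/Mantel; Zi/Pi role cutoffs 2.5 / 0.62.
#'
#' @param rarefaction_depth Reads per sample after rarefaction; NA skips
#'   the rarefaction stage.
#' @param rare_threshold,abundant_threshold Dataset-fraction class cuts.
#' @param network_abundance_threshold,network_occurrence_threshold Network
#'   candidate filters.
#' @param rho_min,q_max Edge gates.
#' @param n_permutations Permutations for PERMANOVA and Mantel.
#' @param rf_trees,rf_permutations Random-forest size and response
#'   permutations.
#' @param zi_threshold,pi_threshold Node-role cutoffs.
#' @param enrichment_q Kruskal-Wallis BH cutoff for layer enrichment.
#' @param seed Global seed; stages derive sub-seeds from it.
#' @return Validated list of class "analysis_config".
#' @export
analysis_config <- function(rarefaction_depth = NA, rare_threshold = 1e-4,
                            abundant_threshold = 1e-3,
                            network_abundance_threshold = 5e-3,
                            network_occurrence_threshold = 0.5,
                            rho_min = 0.8, q_max = 0.001,
                            n_permutations = 999,
                            rf_trees = 500, rf_permutations = 99,
                            zi_threshold = 2.5, pi_threshold = 0.62,
                            enrichment_q = 0.05, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    if (!(rare_threshold > 0 && rare_threshold < abundant_threshold &&
          abundant_threshold < 1)) {
      stop_("need 0 < rare_threshold < abundant_threshold < 1")
    }
    if (rho_min <= 0 || rho_min > 1) stop_("rho_min must be in (0, 1]")
    if (q_max <= 0 || network_abundance_threshold <= 0 ||
        network_occurrence_threshold <= 0 || n_permutations < 1 ||
        rf_trees < 1 || rf_permutations < 1) {
      stop_("thresholds and counts must be strictly positive")
    }
    if (!is.na(rarefaction_depth) && rarefaction_depth < 1) {
      stop_("rarefaction_depth must be >= 1")
    }
  })
  class(cfg) <- "analysis_config"
  cfg
}

# Fixed documented derivation: sub-seed = global seed + stage index.
stage_seed <- function(config, stage) {
  as.integer(config$seed) + match(stage, STAGE_NAMES)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a loaded
#' dataset (`input_paths`) or a simulated one (`sim_params`), writing
#' result TSVs and a JSON run report to `out_dir`.  Identical config + seed
#' gives identical outputs.  A failing stage stops the run; the report
#' (already on disk) lists the stages completed up to that point.
#'
#' @param config [analysis_config()].
#' @param out_dir Output directory.
#' @param sim_params [simulation_params()] for simulated input, or NULL.
#' @param input_paths Named list (counts, metadata, taxonomy, soil) of TSV
#'   paths, or NULL.
#' @param stages Character vector of stages to run (default all).
#' @param rules_path Functional-rules TSV; defaults to the packaged
#'   miniature rules file.
#' @param verbose Log stage progress to stderr.
#' @return The run report (list), invisibly; also written as report.json.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir,
                         sim_params = NULL, input_paths = NULL,
                         stages = STAGE_NAMES,
                         rules_path = system.file("extdata",
                                                  "function_rules.tsv",
                                                  package = "microdepth"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  bad <- setdiff(stages, STAGE_NAMES)
  if (length(bad)) stop_("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.null(sim_params) && is.null(input_paths)) {
    stop_("supply either sim_params or input_paths")
  }
  if (!"data" %in% stages) stop_("the 'data' stage is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(config = unclass(config), stages = list(), warnings = list(),
                 status = "running")
  say <- function(...) if (verbose) message("[microdepth] ", ...)
  report_path <- file.path(out_dir, "report.json")
  flush_report <- function() {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        report$status <<- paste0("failed at stage '", name, "'")
        report$error <<- conditionMessage(e)
        flush_report()
        stop_("pipeline failed at stage '%s': %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- list(
      outputs = res %||% character(0),
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      seed = stage_seed(config, name))
    if (length(warns)) report$warnings[[name]] <<- warns
    flush_report()
    invisible(res)
  }

  env <- new.env()
  run_stage("data", function() {
    if (!is.null(sim_params)) {
      ds <- simulate_dataset(sim_params)
      write_dataset(ds, out_dir)
      env$ds <- ds
      return(file.path(out_dir, c("counts.tsv", "metadata.tsv")))
    }
    env$ds <- load_dataset(input_paths$counts, input_paths$metadata,
                           input_paths$taxonomy, input_paths$soil)
    unlist(input_paths)
  })

  run_stage("rarefy", function() {
    if (is.na(config$rarefaction_depth)) return(character(0))
    env$ds$counts <- rarefy(env$ds$counts, config$rarefaction_depth,
                            seed = stage_seed(config, "rarefy"))
    keep <- env$ds$metadata$sample_id %in% rownames(env$ds$counts)
    env$ds$metadata <- env$ds$metadata[keep, ]
    write_count_table(env$ds$counts, file.path(out_dir, "counts_rarefied.tsv"))
    file.path(out_dir, "counts_rarefied.tsv")
  })

  run_stage("abundance", function() {
    cls <- classify_abundance(env$ds$counts, config$rare_threshold,
                              config$abundant_threshold)
    env$classes <- cls
    rp <- rare_proportions(env$ds$counts, cls, env$ds$metadata)
    env$rare_props <- rp
    enr <- enrichment_classify(env$ds$counts, env$ds$metadata,
                               q_cutoff = config$enrichment_q)
    c(write_tsv(cls, file.path(out_dir, "abundance_classes.tsv")),
      write_tsv(rp, file.path(out_dir, "rare_proportions.tsv")),
      write_tsv(enr, file.path(out_dir, "enrichment.tsv")))
  })

  run_stage("alpha", function() {
    div <- alpha_diversity(env$ds$counts)
    env$alpha <- div
    outs <- write_tsv(div, file.path(out_dir, "alpha_diversity.tsv"))
    for (resp in c("S", "J")) {
      fit <- try(two_way_anova(div[[resp]], env$ds$metadata,
                               sample_id = div$sample_id), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        outs <- c(outs, write_tsv(as.data.frame(fit),
                                  file.path(out_dir, paste0("anova_", resp, ".tsv"))))
        tk <- tukey_posthoc(div[[resp]], env$ds$metadata, "layer",
                            sample_id = div$sample_id)
        outs <- c(outs, write_tsv(tk,
                                  file.path(out_dir, paste0("tukey_", resp, "_layer.tsv"))))
      }
    }
    outs
  })

  run_stage("beta", function() {
    d <- bray_curtis(env$ds$counts)
    env$bray <- d
    pc <- pcoa(d)
    pm <- permanova(d, env$ds$metadata,
                    n_permutations = config$n_permutations,
                    seed = stage_seed(config, "beta"))
    env$permanova <- pm
    coords <- data.frame(sample_id = rownames(pc$coordinates),
                         pc$coordinates[, seq_len(min(4, ncol(pc$coordinates))),
                                        drop = FALSE])
    c(write_distance(d, file.path(out_dir, "bray_curtis.tsv")),
      write_tsv(coords, file.path(out_dir, "pcoa_coordinates.tsv")),
      write_tsv(as.data.frame(pm), file.path(out_dir, "permanova.tsv")))
  })

  run_stage("fertility", function() {
    if (is.null(env$ds$soil)) stop_("fertility stage requires a soil table")
    fi <- fertility_index(env$ds$soil)
    env$fertility <- fi
    preds <- env$ds$soil[, intersect(SOIL_VARIABLES, names(env$ds$soil))]
    rf <- rf_importance(preds,
                        fi$fertility_index[match(env$ds$soil$sample_id,
                                                 fi$sample_id)],
                        n_trees = config$rf_trees,
                        n_response_permutations = config$rf_permutations,
                        seed = stage_seed(config, "fertility"))
    env$rf <- rf
    c(write_tsv(fi, file.path(out_dir, "fertility_index.tsv")),
      write_tsv(rf, file.path(out_dir, "rf_soil_drivers.tsv")))
  })

  run_stage("networks", function() {
    md <- env$ds$metadata
    outs <- character(0)
    env$networks <- list()
    for (lay in intersect(c("S", "M", "D"), unique(as.character(md$layer)))) {
      samp <- md$sample_id[md$layer == lay]
      filt <- try(filter_for_network(env$ds$counts,
                                     config$network_abundance_threshold,
                                     config$network_occurrence_threshold,
                                     samples = samp), silent = TRUE)
      if (inherits(filt, "try-error")) {
        warn_("layer %s: %s", lay, attr(filt, "condition")$message)
        next
      }
      sp <- spearman_matrix(filt)
      net <- build_network(sp$rho, sp$p, config$rho_min, config$q_max,
                           abundances = relative_abundance(env$ds$counts,
                                                           "dataset_total"))
      if (nrow(net$edges) == 0) {
        warn_("layer %s: no edges pass the gates", lay)
        next
      }
      mods <- detect_modules(net, seed = stage_seed(config, "networks"))
      topo <- zi_pi(net, mods, config$zi_threshold, config$pi_threshold)
      met <- network_metrics(net, mods)
      env$networks[[lay]] <- list(net = net, topology = topo, metrics = met)
      outs <- c(outs,
        write_tsv(net$edges, file.path(out_dir, paste0("network_", lay, "_edges.tsv"))),
        write_tsv(topo, file.path(out_dir, paste0("network_", lay, "_nodes.tsv"))))
      jsonlite::write_json(met, file.path(out_dir, paste0("network_", lay, "_metrics.json")),
                           auto_unbox = TRUE, digits = NA)
      outs <- c(outs, file.path(out_dir, paste0("network_", lay, "_metrics.json")))
    }
    if (length(env$networks) >= 2) {
      shared <- compare_networks(lapply(env$networks, `[[`, "net"))
      outs <- c(outs, write_tsv(shared, file.path(out_dir, "network_shared_nodes.tsv")))
    }
    outs
  })

  run_stage("functions", function() {
    if (is.null(env$ds$taxonomy)) stop_("functions stage requires taxonomy")
    rules <- read_function_rules(rules_path)
    mp <- map_functions(env$ds$counts, env$ds$taxonomy, rules)
    env$functions <- mp
    attrib <- function_attribution(env$ds$counts, mp, env$ds$taxonomy, "phylum")
    prof <- data.frame(sample_id = rownames(mp$group_profile),
                       mp$group_profile, check.names = FALSE)
    c(write_tsv(prof, file.path(out_dir, "function_groups.tsv")),
      write_tsv(attrib, file.path(out_dir, "function_attribution.tsv")))
  })

  report$status <- "completed"
  flush_report()
  res <- as.list(env)
  res$report <- report
  invisible(res)
}
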