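# Synthetic dataset generator.
#
# Emulates a plots x times x depths soil 16S survey: a heavy-tailed
# (log-normal) species-abundance distribution with many rare ASVs,
# multiplicative layer/time fold-changes on latent abundances, planted
# correlated ASV blocks (network modules) driven by per-sample latent
# factors, plot random intercepts, soil variables with depth gradients, and
# a latent fertility factor linking designated ASVs to the nutrient pool.
# Counts are drawn multinomially per sample, so compositional closure holds
# by construction and fold-change is the single effect-size unit.

PHYLUM_POOL <- list(
  dominant = list(
    Proteobacteria    = c("Sphingomonas", "Pseudomonas", "Bradyrhizobium"),
    Actinobacteriota  = c("Streptomyces", "Mycobacterium", "Arthrobacter"),
    Acidobacteriota   = c("Bryobacter", "Vicinamibacter"),
    Chloroflexi       = c("Ktedonobacter", "Roseiflexus"),
    Bacteroidota      = c("Flavobacterium", "Chitinophaga"),
    Gemmatimonadota   = c("Gemmatimonas"),
    Verrucomicrobiota = c("Chthoniobacter"),
    Crenarchaeota     = c("Nitrososphaera")
  ),
  rare = list(
    Latescibacterota  = character(0),
    Zixibacteria      = character(0),
    Dadabacteria      = character(0),
    Dependentiae      = c("Vermiphilus"),
    Calditrichota     = c("Caldithrix"),
    Micrarchaeota     = character(0),
    Desulfobacterota  = c("Desulfovibrio", "Desulfobacca"),
    Cyanobacteria     = c("Nostoc", "Microcoleus"),
    Halanaerobiaeota  = c("Halanaerobium"),
    Euryarchaeota     = c("Methanobacterium"),
    Halobacterota     = c("Methanosarcina"),
    Firmicutes        = c("Bacillus", "Clostridium")
  )
)

ARCHAEAL_PHYLA <- c("Crenarchaeota", "Micrarchaeota", "Euryarchaeota", "Halobacterota")

#' Simulation parameters
#'
#' Full parameterization of the synthetic dataset.  Defaults emulate the
#' 6 plots x 4 sampling times x 3 soil layers design at a desk-scale library
#' size, with a strong depth effect and no temporal effect — the regime the
#' analysis stages are built for.  A fold-change of 0 (or 1) disables the
#' corresponding effect.
#'
#' @param n_plots,n_times Number of field plots and sampling occasions.
#' @param n_asvs Number of ASVs.
#' @param library_size Reads per sample (multinomial total).
#' @param sad_sigma Log-normal shape of the species-abundance distribution;
#'   >= 2 gives the strong rare-taxa skew of real soil surveys.
#' @param depth_effect Multiplicative fold-change applied, in one preferred
#'   layer, to a `depth_affected_frac` fraction of ASVs (0 disables).
#' @param depth_affected_frac Fraction of ASVs receiving a layer preference.
#' @param time_effect,time_affected_frac Analogous temporal fold-change
#'   (default 0 = null, matching the motivating study's finding).
#' @param n_modules,module_size Planted correlation blocks: count and size.
#' @param module_strength Planted-module cohesion in \[0, 1): the target
#'   correlation of member ASVs' latent log-abundances (members load on a
#'   shared per-sample factor with loading sqrt(module_strength)).
#' @param plot_sd SD of the per-plot random intercept on latent log-abundance.
#' @param latent_noise_sd SD of per-sample idiosyncratic latent log noise.
#' @param n_fertility_linked Number of ASVs whose latent abundance co-varies
#'   with the nutrient variables via a shared per-sample fertility factor.
#' @param fertility_strength Loading of linked ASVs on the fertility factor.
#' @param soil_depth_gradient Named additive mean shift per layer step
#'   (S -> M -> D) for soil variables.
#' @param soil_noise_sd Multiplier on each soil variable's natural noise SD.
#' @param seed Integer RNG seed.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_plots = 6, n_times = 4, n_asvs = 2000,
                              library_size = 50000, sad_sigma = 2,
                              depth_effect = 4, depth_affected_frac = 0.1,
                              time_effect = 0, time_affected_frac = 0.1,
                              n_modules = 3, module_size = 10,
                              module_strength = 0.9,
                              plot_sd = 0.1, latent_noise_sd = 0.5,
                              n_fertility_linked = 20, fertility_strength = 1,
                              soil_depth_gradient = NULL, soil_noise_sd = 1,
                              seed = 1) {
  p <- list(n_plots = n_plots, n_times = n_times, n_layers = 3L,
            n_asvs = n_asvs, library_size = library_size,
            sad_sigma = sad_sigma,
            depth_effect = depth_effect,
            depth_affected_frac = depth_affected_frac,
            time_effect = time_effect, time_affected_frac = time_affected_frac,
            n_modules = n_modules, module_size = module_size,
            module_strength = module_strength,
            plot_sd = plot_sd, latent_noise_sd = latent_noise_sd,
            n_fertility_linked = n_fertility_linked,
            fertility_strength = fertility_strength,
            soil_depth_gradient = soil_depth_gradient %||% list(
              TC = -4, TN = -0.4, DOC = -40, DON = -4, NO3 = -2.5, NH4 = -1,
              moisture = 3, pH = 0.2),
            soil_noise_sd = soil_noise_sd, seed = seed)
  class(p) <- "simulation_params"
  validate_simulation_params(p)
}

validate_simulation_params <- function(p) {
  with(p, {
    if (n_plots < 1 || n_times < 1 || n_asvs < 1 || library_size < 1) {
      stop_("design sizes and library_size must be positive")
    }
    if (n_modules * module_size > n_asvs) {
      stop_("n_modules * module_size (%d) exceeds n_asvs (%d)",
            n_modules * module_size, n_asvs)
    }
    if (module_strength < 0 || module_strength >= 1) {
      stop_("module_strength must be in [0, 1)")
    }
    if (sad_sigma <= 0) stop_("sad_sigma must be positive")
    if (depth_effect < 0 || time_effect < 0) stop_("fold-changes must be >= 0")
  })
  p
}

# Synthesize silva-style lineage strings.  Module and other high-abundance
# ASVs get dominant phyla; a slice of the rare tail is assigned to the
# designated rare-phylum pool so phylum summaries and function mapping see
# realistic structure.  ~3% of ASVs are left out of the table entirely
# (fully unclassified) and some lineages stop above genus.
synth_taxonomy <- function(asv_ids, base_frac) {
  n <- length(asv_ids)
  dom <- names(PHYLUM_POOL$dominant)
  rar <- names(PHYLUM_POOL$rare)
  phy <- character(n)
  is_rare <- base_frac < stats::quantile(base_frac, 0.6)
  phy[!is_rare] <- sample(dom, sum(!is_rare), replace = TRUE,
                          prob = c(5, 4, 3, 2, 2, 1, 1, 1))
  phy[is_rare] <- sample(c(dom, rar), sum(is_rare), replace = TRUE,
                         prob = c(rep(2, length(dom)), rep(1, length(rar))))
  genera <- c(PHYLUM_POOL$dominant, PHYLUM_POOL$rare)
  lineage <- vapply(seq_len(n), function(i) {
    p <- phy[i]
    domn <- if (p %in% ARCHAEAL_PHYLA) "Archaea" else "Bacteria"
    gpool <- genera[[p]]
    g <- if (length(gpool) && stats::runif(1) > 0.25) sample(gpool, 1) else ""
    depth_stop <- sample(3:6, 1, prob = c(1, 1, 2, 4))  # how far the lineage resolves
    ranks <- c(domn, p, paste0(p, "_c"), paste0(p, "_o"), paste0(p, "_f"), g)
    ranks[seq_along(ranks) > depth_stop] <- ""
    if (nzchar(g)) ranks[6] <- g
    paste(ranks, collapse = ";")
  }, character(1))
  keep <- stats::runif(n) > 0.03
  data.frame(asv_id = asv_ids[keep], lineage = lineage[keep],
             stringsAsFactors = FALSE)
}

synth_soil <- function(metadata, g_factor, p) {
  n <- nrow(metadata)
  lay <- as.integer(factor(metadata$layer, levels = c("S", "M", "D"))) - 1L
  base <- c(TC = 18, TN = 1.8, DOC = 180, DON = 18, NO3 = 8, NH4 = 4,
            moisture = 22, pH = 6.8)
  nat_sd <- base * 0.1
  grad <- p$soil_depth_gradient
  soil <- data.frame(sample_id = metadata$sample_id, stringsAsFactors = FALSE)
  for (v in names(base)) {
    mu <- base[[v]] + (grad[[v]] %||% 0) * lay
    load <- if (v %in% SOIL_NUTRIENTS) 0.7 else 0
    x <- mu + load * nat_sd[[v]] * g_factor +
      stats::rnorm(n, 0, p$soil_noise_sd * nat_sd[[v]] * sqrt(1 - load^2))
    soil[[v]] <- pmax(x, 0.01)
  }
  # texture: sand rises with depth; closure to 100 via softmax
  logit <- cbind(clay = 1.0 - 0.15 * lay, silt = 1.4 - 0.1 * lay,
                 sand = 1.2 + 0.25 * lay) +
    matrix(stats::rnorm(3 * n, 0, 0.1 * p$soil_noise_sd), n, 3)
  tex <- exp(logit) / rowSums(exp(logit)) * 100
  soil$clay <- tex[, "clay"]; soil$silt <- tex[, "silt"]; soil$sand <- tex[, "sand"]
  soil
}

#' Simulate a depth- and time-structured community dataset
#'
#' Deterministic for a fixed seed.  Latent per-sample ASV abundances are
#' log-normal with multiplicative layer/time effects, plot random
#' intercepts, planted module factors and a fertility factor; counts are a
#' multinomial draw of `library_size` reads per sample.  Effects are planted
#' only on ASVs whose expected per-sample count is at least ~10 reads, so
#' every planted signal is realizable in counts.
#'
#' @param params A [simulation_params()] object.
#' @return List: counts (samples x ASVs), metadata, taxonomy, soil, and
#'   ground_truth (depth/time-affected ASVs with their preferred level,
#'   module membership, fertility-linked ASVs).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  p <- validate_simulation_params(params)
  with_seed(p$seed, {
    n_samp <- p$n_plots * p$n_times * p$n_layers
    asv_ids <- sprintf("ASV%04d", seq_len(p$n_asvs))
    layers <- c("S", "M", "D")

    design <- expand.grid(plot = seq_len(p$n_plots), layer = layers,
                          time = paste0("T", seq_len(p$n_times)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    metadata <- data.frame(
      sample_id = sprintf("P%d_%s_%s", design$plot, design$time, design$layer),
      plot = design$plot, layer = design$layer, time = design$time,
      stringsAsFactors = FALSE)

    # species-abundance distribution
    base_log <- stats::rnorm(p$n_asvs, 0, p$sad_sigma)
    a <- exp(base_log)

    # planted modules: boost members into the network-filter abundance range
    n_mod_asv <- p$n_modules * p$module_size
    module_of <- integer(p$n_asvs)
    if (n_mod_asv > 0 && p$n_modules > 0) {
      mod_idx <- sample.int(p$n_asvs, n_mod_asv)
      module_of[mod_idx] <- rep(seq_len(p$n_modules), each = p$module_size)
      a[mod_idx] <- 0.015 * sum(a) * exp(stats::rnorm(n_mod_asv, 0, 0.1))
    }
    base_frac <- a / sum(a)

    # effect eligibility: expected >= 10 reads per sample, outside modules
    eligible <- which(base_frac >= 10 / p$library_size & module_of == 0)
    pick_affected <- function(frac, levels_) {
      n_aff <- min(round(frac * p$n_asvs), length(eligible))
      idx <- sample(eligible, n_aff)
      eligible <<- setdiff(eligible, idx)
      data.frame(asv_id = asv_ids[idx],
                 level = rep_len(levels_, n_aff),
                 idx = idx, stringsAsFactors = FALSE)
    }
    depth_aff <- if (p$depth_effect > 0 && p$depth_effect != 1) {
      pick_affected(p$depth_affected_frac, layers)
    } else data.frame(asv_id = character(0), level = character(0), idx = integer(0))
    time_aff <- if (p$time_effect > 0 && p$time_effect != 1) {
      pick_affected(p$time_affected_frac, paste0("T", seq_len(p$n_times)))
    } else data.frame(asv_id = character(0), level = character(0), idx = integer(0))

    fert_pool <- setdiff(which(base_frac >= 5 / p$library_size), which(module_of > 0))
    fert_idx <- sample(fert_pool, min(p$n_fertility_linked, length(fert_pool)))

    plot_eff <- matrix(stats::rnorm(p$n_plots * p$n_asvs, 0, p$plot_sd),
                       p$n_plots, p$n_asvs)
    g_factor <- stats::rnorm(n_samp)                       # fertility factor
    mod_factor <- matrix(stats::rnorm(n_samp * max(p$n_modules, 1)),
                         n_samp, max(p$n_modules, 1))

    counts <- matrix(0L, n_samp, p$n_asvs,
                     dimnames = list(metadata$sample_id, asv_ids))
    log_depth <- if (nrow(depth_aff)) log(p$depth_effect) else 0
    log_time <- if (nrow(time_aff)) log(p$time_effect) else 0
    ms <- p$module_strength
    for (s in seq_len(n_samp)) {
      ll <- base_log
      ll[module_of > 0] <- log(a[module_of > 0])
      ll <- ll + plot_eff[metadata$plot[s], ]
      if (nrow(depth_aff)) {
        hit <- depth_aff$idx[depth_aff$level == metadata$layer[s]]
        ll[hit] <- ll[hit] + log_depth
      }
      if (nrow(time_aff)) {
        hit <- time_aff$idx[time_aff$level == metadata$time[s]]
        ll[hit] <- ll[hit] + log_time
      }
      z <- stats::rnorm(p$n_asvs)
      e <- p$latent_noise_sd * z
      if (ms > 0 && any(module_of > 0)) {
        im <- module_of > 0
        e[im] <- p$latent_noise_sd *
          (sqrt(ms) * mod_factor[s, module_of[im]] + sqrt(1 - ms) * z[im])
      }
      ll <- ll + e
      ll[fert_idx] <- ll[fert_idx] + p$fertility_strength * g_factor[s]
      lam <- exp(ll - max(ll))
      counts[s, ] <- stats::rmultinom(1, p$library_size, lam / sum(lam))
    }

    taxonomy <- synth_taxonomy(asv_ids, base_frac)
    soil <- synth_soil(metadata, g_factor, p)

    ground_truth <- list(
      depth_affected = depth_aff[c("asv_id", "level")],
      time_affected = time_aff[c("asv_id", "level")],
      modules = stats::setNames(module_of[module_of > 0],
                                asv_ids[module_of > 0]),
      fertility_linked = asv_ids[fert_idx],
      base_fraction = stats::setNames(base_frac, asv_ids))

    list(counts = validate_count_table(counts),
         metadata = validate_metadata(metadata, counts),
         taxonomy = taxonomy, soil = validate_soil(soil),
         ground_truth = ground_truth)
  })
}

#' Write a simulated dataset to a directory as TSV + JSON
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$soil, file.path(dir, "soil.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth
    gt$modules <- as.list(gt$modules)
    gt$base_fraction <- NULL
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
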