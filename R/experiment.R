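#' Experiment configuration
#'
#' Bundles everything the factorial runner needs: the synthetic world, the
#' species roster, the predictor construction, the partition sweep and the
#' algorithm list. The defaults describe the demo world: a 150 x 150 cell
#' window at 0.6 degrees (longitude -120 to -30, latitude 35 southward),
#' 6 climate-like and 8 edaphic-like layers, and 24 virtual species with
#' mixed niches.
#'
#' @param world list from [world_config()].
#' @param n_species number of virtual species.
#' @param niche `"mixed"`, `"climate"` or `"edaphic"` species niches.
#' @param n_responses response layers per species.
#' @param breadth_range,n_records_range roster knobs
#'   (see [make_species_roster()]).
#' @param predictors subset of `c("C", "E", "CE")`.
#' @param algorithms subset of `c("GAM", "MElq", "RF", "SVM")`.
#' @param pca_threshold cumulative-variance cutoff.
#' @param thin_factor thinning resolution in multiples of the model cell
#'   size (2 mirrors thinning a 5 arc-minute grid at 10 arc-minutes).
#' @param r_min,r_max,step checkerboard resolution sweep, degrees.
#' @param pa_method pseudo-absence bin allocation (see
#'   [allocate_pa_to_bins()]).
#' @param connectivity patch adjacency for the shape index.
#' @param year_range collection window for cleaning.
#' @param seed global seed; every stage derives its own from it.
#' @param out_dir optional output directory.
#' @return a named list of class `experiment_config`.
#' @export
experiment_config <- function(world = world_config(),
                              n_species = 24, niche = "mixed",
                              n_responses = 2,
                              breadth_range = c(0.5, 1.25),
                              n_records_range = c(20, 1227),
                              predictors = c("C", "E", "CE"),
                              algorithms = c("GAM", "MElq", "RF", "SVM"),
                              pca_threshold = 0.95, thin_factor = 2,
                              r_min = 0.5, r_max = 15, step = 0.5,
                              pa_method = "spatial", connectivity = 4,
                              year_range = c(1979, 2013),
                              seed = 1, out_dir = NULL) {
  stopifnot(all(predictors %in% c("C", "E", "CE")),
            all(algorithms %in% c("GAM", "MElq", "RF", "SVM")),
            length(predictors) >= 1, length(algorithms) >= 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; a `world`
#' mapping mirrors [world_config()].
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  wc <- do.call(world_config, raw$world %||% list())
  raw$world <- NULL
  do.call(experiment_config, c(list(world = wc), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit seed derived from the global seed and a key string,
# so every treatment is reproducible in isolation
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h %% 2147483647)
}

#' Enumerate the factorial design
#'
#' The full cross of species x predictor set x algorithm, in deterministic
#' order (species outermost, algorithm innermost). One species under the
#' default three predictors and four algorithms gives 12 treatments; 125
#' species give 1500.
#'
#' @param config an `experiment_config` (or anything with `n_species`,
#'   `predictors`, `algorithms`).
#' @return data.frame `species, predictor, algorithm`.
#' @export
build_design <- function(config) {
  if (config$n_species < 1 || length(config$predictors) < 1 ||
      length(config$algorithms) < 1)
    stop("empty design factor")
  species <- sprintf("vsp%02d", seq_len(config$n_species))
  d <- expand.grid(algorithm = config$algorithms,
                   predictor = config$predictors,
                   species = species,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[c("species", "predictor", "algorithm")]
  rownames(d) <- NULL
  d
}

#' Study conditions for the edaphic-niche direction-of-effect experiment
#'
#' The configuration used to test the headline qualitative ordering on
#' ground truth: species whose niches load only on short-range edaphic
#' fields should be better recovered by the E and CE predictor sets than by
#' C (higher TSS), and their binary maps should rank SI(E) > SI(CE) > SI(C).
#' The world covers the same 90 x 90 degree window as the demo at a coarser
#' 1.5-degree cell (60 x 60 cells) with the same physical autocorrelation
#' ranges (24 degrees climate = 16 cells, 2.4 degrees edaphic = 1.6 cells),
#' so a replicate set of 20 edaphic-niche species runs in about a minute.
#'
#' @param seed replicate seed.
#' @param n_species species per replicate.
#' @return an `experiment_config`.
#' @export
edaphic_study_config <- function(seed, n_species = 20) {
  experiment_config(
    world = world_config(nrow = 60, ncol = 60, cell_size = 1.5,
                         origin_x = -120, origin_y = 35,
                         n_climate = 6, n_edaphic = 8,
                         range_climate = 16, range_edaphic = 1.6,
                         seed = seed),
    n_species = n_species, niche = "edaphic", seed = seed)
}

#' Run the factorial experiment end to end
#'
#' Generates (or accepts) the synthetic world, builds the C/E/CE
#' principal-component predictor sets, and then, per species: samples and
#' cleans occurrences, thins them systematically, selects the checkerboard
#' partition, samples prevalence-1 pseudo-absences, and evaluates every
#' predictor x algorithm treatment by 2-fold spatial cross-validation.
#' Whole-map Kendall tau is computed for every predictor pair within each
#' algorithm and every algorithm pair within each predictor set. The run
#' closes with per-species geographic profiles and repeated-measures
#' ANOVAs (TSS arcsine-transformed; TPR, AUC and SI raw) over the complete
#' species. Individual treatment failures yield NA records rather than
#' aborting; the run stops only if more than half the treatments fail.
#'
#' @param config an `experiment_config`.
#' @param env optional pre-generated world (list with `climate`, `edaphic`)
#'   to reuse across runs.
#' @return list of class `experiment_result`: `eval` (one row per
#'   treatment), `taus`, `profiles`, `profile_cor`, `anova` (named list per
#'   index), `manifest`. When `config$out_dir` is set, tables, the ANOVA
#'   report and the manifest are also written there.
#' @export
run_experiment <- function(config, env = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  w <- config$world
  if (is.null(env)) env <- gen_environment(w)
  combined <- grid_stack(c(env$climate$layers, env$edaphic$layers))
  mask_layer <- env$edaphic$layers[[1L]]      # one soil layer as raster mask
  sets <- build_predictor_sets(env$climate, env$edaphic,
                               threshold = config$pca_threshold)
  sets <- sets[config$predictors]
  g <- stack_geometry(combined)
  bbox <- c(g$origin_x, g$origin_x + g$ncol * g$cell_size,
            g$origin_y - g$nrow * g$cell_size, g$origin_y)
  anchor <- c(g$origin_x, g$origin_y)
  roster <- make_species_roster(
    combined, config$n_species, niche = config$niche,
    climate_layers = names(env$climate$layers),
    edaphic_layers = names(env$edaphic$layers),
    n_responses = config$n_responses,
    breadth_range = config$breadth_range,
    n_records_range = config$n_records_range,
    seed = derive_seed(config$seed, "roster"))

  design <- build_design(config)
  eval_rows <- vector("list", nrow(design))
  tau_rows <- list()
  prof_rows <- list()
  failures <- character(0)

  for (vs in roster) {
    sid <- vs$species_id
    occ <- sample_occurrences(vs, attr(vs, "n_records"),
                              seed = derive_seed(config$seed, sid, "occ"))
    occ <- clean_records(occ, bbox, year_range = config$year_range)
    occ <- thin_systematic(occ, resolution = config$thin_factor * g$cell_size,
                           seed = derive_seed(config$seed, sid, "thin"),
                           anchor = anchor)
    suits <- list()   # per-treatment mean suitability maps for tau
    for (pl in config$predictors) {
      scores <- sets[[pl]]$scores
      ts <- tryCatch(
        build_training_set(sid, occ[c("lon", "lat")], scores, mask_layer,
                           seed = derive_seed(config$seed, sid, pl, "design"),
                           r_min = config$r_min, r_max = config$r_max,
                           step = config$step, anchor = anchor,
                           pa_method = config$pa_method),
        error = function(e) e)
      bg <- if ("MElq" %in% config$algorithms)
        sample_background(scores, derive_seed(config$seed, sid, pl, "bg"))
      for (al in config$algorithms) {
        row_id <- which(design$species == sid & design$predictor == pl &
                          design$algorithm == al)
        res <- if (inherits(ts, "error")) ts else tryCatch(
          evaluate_treatment(ts, al, scores,
                             seed = derive_seed(config$seed, sid, pl, al),
                             background = bg,
                             connectivity = config$connectivity),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, sprintf("%s/%s/%s: %s", sid, pl, al,
                                          conditionMessage(res)))
          eval_rows[[row_id]] <- data.frame(
            species = sid, predictor = pl, algorithm = al,
            TSS = NA_real_, TPR = NA_real_, AUC = NA_real_, SI = NA_real_,
            threshold = NA_real_, n_train = NA_integer_, n_test = NA_integer_,
            chosen_resolution = NA_real_)
        } else {
          r <- res$record
          eval_rows[[row_id]] <- data.frame(
            species = sid, predictor = pl, algorithm = al,
            TSS = r$TSS, TPR = r$TPR, AUC = r$AUC, SI = r$SI,
            threshold = r$threshold, n_train = r$n_train, n_test = r$n_test,
            chosen_resolution = r$chosen_resolution)
          suits[[paste(pl, al, sep = ".")]] <- res$suitability
        }
      }
    }
    tau_rows[[sid]] <- species_taus(sid, suits, config)
    prof_rows[[sid]] <- tryCatch(
      geo_profile(occ, sets, g),
      error = function(e) NULL)
  }

  eval_tab <- do.call(rbind, eval_rows)
  if (length(failures) > nrow(design) / 2)
    stop("more than half the treatments failed:\n",
         paste(utils::head(failures, 10), collapse = "\n"))
  if (length(failures))
    message(length(failures), " treatment(s) failed and were recorded as NA")

  taus <- do.call(rbind, tau_rows)
  profiles <- do.call(rbind, prof_rows)
  rownames(eval_tab) <- rownames(profiles) <- NULL
  profile_cor <- if (!is.null(profiles) && nrow(profiles) >= 3)
    correlate_profiles(profiles) else NULL

  keep_sp <- names(which(tapply(!is.na(eval_tab$TSS), eval_tab$species, all)))
  anv <- NULL
  if (length(keep_sp) >= 3) {
    sub <- eval_tab[eval_tab$species %in% keep_sp, ]
    sub$TSS_t <- arcsine_tss(sub$TSS)
    anv <- list(TSS = rm_anova(sub, "TSS_t"),
                TPR = rm_anova(sub, "TPR"),
                AUC = rm_anova(sub, "AUC"),
                SI = rm_anova(sub, "SI"))
  }

  manifest <- list(
    config = unclass(config[setdiff(names(config), "world")]),
    world = config$world,
    design_size = nrow(design),
    n_failures = length(failures), failures = failures,
    retained_components = vapply(sets, `[[`, integer(1), "k"),
    timestamp_free = TRUE)

  out <- structure(list(eval = eval_tab, taus = taus, profiles = profiles,
                        profile_cor = profile_cor, anova = anv,
                        manifest = manifest, predictor_sets = sets),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

# whole-map tau for predictor pairs within algorithm and algorithm pairs
# within predictor, for one species
species_taus <- function(sid, suits, config) {
  if (length(suits) < 2L) return(NULL)
  rows <- list()
  pair_tau <- function(k1, k2) {
    tryCatch(kendall_map_tau(suits[[k1]], suits[[k2]]),
             error = function(e) NA_real_)
  }
  for (al in config$algorithms) {
    pls <- config$predictors
    for (x in seq_along(pls)) for (y in seq_along(pls)) if (x < y) {
      k1 <- paste(pls[x], al, sep = "."); k2 <- paste(pls[y], al, sep = ".")
      if (!is.null(suits[[k1]]) && !is.null(suits[[k2]]))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sid, type = "predictor_pair", group = al,
          pair = paste(pls[x], pls[y], sep = "-"), tau = pair_tau(k1, k2))
    }
  }
  for (pl in config$predictors) {
    als <- config$algorithms
    for (x in seq_along(als)) for (y in seq_along(als)) if (x < y) {
      k1 <- paste(pl, als[x], sep = "."); k2 <- paste(pl, als[y], sep = ".")
      if (!is.null(suits[[k1]]) && !is.null(suits[[k2]]))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sid, type = "algorithm_pair", group = pl,
          pair = paste(als[x], als[y], sep = "-"), tau = pair_tau(k1, k2))
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Write an experiment's tables, report and manifest
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$eval, "evaluation.csv")
  if (!is.null(result$taus)) {
    wr(result$taus, "tau_pairs.csv")
    wr(summarize_pairwise_tau(result$taus), "tau_summary.csv")
  }
  if (!is.null(result$profiles)) wr(result$profiles, "geo_profiles.csv")
  if (!is.null(result$anova)) {
    p <- file.path(dir, "anova_report.txt")
    sink(p); on.exit(sink(), add = TRUE)
    for (nm in names(result$anova)) {
      cat("==", nm, "==\n"); print(result$anova[[nm]]); cat("\n")
    }
    sink(); on.exit()
    paths <- c(paths, p)
    tab <- do.call(rbind, lapply(names(result$anova), function(nm) {
      e <- result$anova[[nm]]$effects
      cbind(index = nm, e)
    }))
    wr(tab, "anova_table.csv")
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mp))
}

#' @export
print.experiment_result <- function(x, ...) {
  ok <- sum(!is.na(x$eval$TSS))
  cat(sprintf("<experiment_result> %d treatments (%d ok), %d species\n",
              nrow(x$eval), ok, length(unique(x$eval$species))))
  agg <- stats::aggregate(cbind(TSS, AUC, SI) ~ predictor, x$eval, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
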