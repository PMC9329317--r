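#' Build a pipeline run configuration
#'
#' Declarative configuration for [runPipeline()]. Values can come from a
#' YAML file (`readRunConfig()`), with arguments overriding file values.
#' Stage toggles: `allometry`, `binned`, `ancova`, `simmap`, `regime_models`,
#' `asr`, `cov`. `regime_models` depends on `simmap`.
#'
#' @param tree path to a Newick tree (dated, or a topology when
#'   `occurrences` is supplied)
#' @param occurrences optional path to an occurrence CSV (taxon, fad, lad);
#'   when present the tree is (re)dated with [dateTreeEqual()]
#' @param segments path to a segment-table CSV
#' @param ecology optional path to a tip-state CSV (taxon, state)
#' @param out_dir output directory
#' @param stages character vector of enabled stages
#' @param metrics linear/volumetric columns to regress against WBCHV
#' @param thresholds size-bin thresholds in kg (see [wbchvThreshold()])
#' @param density_coefficient kg per unit WBCHV for threshold conversion
#' @param n_maps stochastic maps to simulate (default 1000)
#' @param n_sampled_maps maps retained for regime fitting (default 100)
#' @param regime_trait column (or "WBCHV") used as the regime-model trait
#' @param root_extension root extension for dating (Myr)
#' @param seed integer seed governing all stochastic stages
#' @return a `runConfig` list
#' @export
runConfig <- function(tree, segments, occurrences = NULL, ecology = NULL,
                      out_dir = "skelevol_run",
                      stages = c("allometry", "binned", "ancova", "simmap",
                                 "regime_models", "asr", "cov"),
                      metrics = c("FL", "HL", "forelimb_length",
                                  "hindlimb_length", "trunk"),
                      thresholds = c(25, 100, 500),
                      density_coefficient = 1000,
                      n_maps = 1000, n_sampled_maps = 100,
                      regime_trait = "WBCHV", root_extension = 10,
                      seed = 1) {
  if (n_sampled_maps > n_maps) stop("n_sampled_maps must be <= n_maps")
  cfg <- list(tree = tree, segments = segments, occurrences = occurrences,
              ecology = ecology, out_dir = out_dir, stages = stages,
              metrics = metrics, thresholds = thresholds,
              density_coefficient = density_coefficient, n_maps = n_maps,
              n_sampled_maps = n_sampled_maps, regime_trait = regime_trait,
              root_extension = root_extension, seed = seed)
  for (f in c("tree", "segments", "occurrences", "ecology")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input file does not exist: ", cfg[[f]])
    }
  }
  structure(cfg, class = "runConfig")
}

#' @rdname runConfig
#' @param file YAML config file
#' @param ... overrides of file values
#' @export
readRunConfig <- function(file, ...) {
  vals <- yaml::read_yaml(file)
  over <- list(...)
  vals[names(over)] <- over
  do.call(runConfig, vals)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order: dating, table assembly
#' and normalisation, per-metric PGLS allometry (linear and quadratic with
#' AICc comparison), size-binned slopes, phylogenetic ANCOVA by ecology
#' group, Mk model selection and stochastic mapping, per-map regime-model
#' fitting with an across-map summary, BM ancestral state reconstruction and
#' per-group CoV profiles. Every stage writes a CSV into `out_dir`, and a
#' manifest records input hashes, seeds and package version, so a rerun with
#' an identical config reproduces all stochastic stages bit-identically.
#'
#' @param config a [runConfig()] (or path to a YAML file)
#' @return the manifest, invisibly; stage tables are in `config$out_dir`
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  manifest <- list(package = "skelevol",
                   version = as.character(utils::packageVersion("skelevol")),
                   seed = cfg$seed, stages = stages,
                   inputs = list(), outputs = list())
  for (f in c("tree", "segments", "occurrences", "ecology")) {
    if (!is.null(cfg[[f]])) {
      manifest$inputs[[f]] <- list(path = cfg[[f]],
                                   md5 = unname(tools::md5sum(cfg[[f]])))
    }
  }
  note <- function(...) message("[skelevol] ", ...)
  emit <- function(obj, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".csv"))
    write.csv(obj, path, row.names = FALSE)
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
    path
  }

  # --- date ---
  tree <- readNewickTree(file = cfg$tree)
  if (!is.null(cfg$occurrences)) {
    occ <- readOccurrences(cfg$occurrences)
    tree <- dateTreeEqual(tree, occ, root_extension = cfg$root_extension)
    note("dated tree: root age ", signif(rootAge(tree), 6), " Ma")
  } else {
    .assertDated(tree)
  }

  # --- tables ---
  seg <- readSegmentTable(cfg$segments)
  seg <- seg[seg$taxon %in% tree$tip.label, ]
  tree <- timeTree(ape::keep.tip(tree, seg$taxon), root_age = NULL)
  norm <- sizeNormalise(seg)
  emit(as.data.frame(norm), "normalised_segments")
  logw <- setNames(log10(seg$WBCHV), seg$taxon)
  ecology <- if (!is.null(cfg$ecology)) readTipStates(cfg$ecology) else NULL

  metric_vec <- function(m) {
    v <- seg[[m]]
    if (is.null(v)) stop("unknown metric column: ", m)
    setNames(log10(v), seg$taxon)
  }

  # --- allometry ---
  if ("allometry" %in% stages) {
    rows <- lapply(cfg$metrics, function(m) {
      y <- metric_vec(m)
      f1 <- pglsFit(logw, y, tree, degree = 1)
      f2 <- pglsFit(logw, y, tree, degree = 2)
      cmp <- akaikeWeights(c(linear = f1$AICc, quadratic = f2$AICc),
                           k = c(f1$k, f2$k))
      data.frame(metric = m, slope = f1$coefficients["b1"],
                 slope_lo = f1$ci["b1", 1], slope_hi = f1$ci["b1", 2],
                 intercept = f1$coefficients["b0"], lambda = f1$lambda,
                 AICc_linear = f1$AICc, AICc_quadratic = f2$AICc,
                 b2 = f2$coefficients["b2"], preferred = preferredModel(cmp),
                 row.names = NULL)
    })
    emit(do.call(rbind, rows), "allometry")
    note("allometry: ", length(cfg$metrics), " metrics")
  }

  # --- binned slopes ---
  if ("binned" %in% stages) {
    thr <- wbchvThreshold(cfg$thresholds, cfg$density_coefficient)
    thr <- thr[thr > min(logw) & thr < max(logw)]
    if (length(thr)) {
      rows <- lapply(cfg$metrics, function(m) {
        y <- metric_vec(m)
        bs <- tryCatch(binnedSlopes(logw, y, tree, thr),
                       error = function(e) NULL)
        if (is.null(bs)) return(NULL)
        do.call(rbind, lapply(bs, function(b) {
          data.frame(metric = m, threshold_logw = b$threshold,
                     slope_below = b$below$coefficients["b1"],
                     slope_above = b$above$coefficients["b1"],
                     diff = b$contrast["slope_diff"], p = b$contrast["p"],
                     row.names = NULL)
        }))
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) emit(do.call(rbind, rows), "binned_slopes")
    }
  }

  # --- phylANCOVA ---
  if ("ancova" %in% stages && !is.null(ecology)) {
    grp <- ecology[seg$taxon]
    big <- names(table(grp))[table(grp) >= 4]
    if (length(big) >= 2) {
      keep <- names(grp)[grp %in% big]
      sub <- timeTree(ape::keep.tip(tree, keep))
      rows <- lapply(cfg$metrics, function(m) {
        y <- metric_vec(m)
        an <- phylAncova(logw[keep], y[keep], grp[keep], sub)
        cbind(metric = m, as.data.frame(an))
      })
      emit(do.call(rbind, rows), "phylancova")
      note("phylANCOVA across ", length(big), " groups")
    }
  }

  maps <- NULL
  # --- simmap ---
  if ("simmap" %in% stages && !is.null(ecology)) {
    cmp <- selectMkModel(tree, ecology[seg$taxon])
    emit(as.data.frame(cmp), "mk_model_selection")
    bestfit <- attr(cmp, "fits")[[preferredModel(cmp)]]
    maps <- simulateStochasticMaps(tree, bestfit, ecology[seg$taxon],
                                   n_maps = cfg$n_maps, seed = cfg$seed)
    maps <- sampleMaps(maps, cfg$n_sampled_maps, seed = cfg$seed + 1)
    emit(paintingToTable(maps[[1]]), "example_map_segments")
    note("simmap: ", cfg$n_maps, " maps simulated under ",
         preferredModel(cmp), ", ", length(maps), " sampled")
  }

  # --- regime models ---
  if ("regime_models" %in% stages) {
    if (is.null(maps)) {
      if (!"simmap" %in% stages) {
        note("regime_models skipped: depends on the simmap stage, ",
             "which is disabled")
      } else note("regime_models skipped: no ecology input")
    } else {
      trait <- if (identical(cfg$regime_trait, "WBCHV")) logw
               else metric_vec(cfg$regime_trait)
      fits <- lapply(seq_along(maps), function(i) {
        all <- fitAllRegimeModels(tree, maps[[i]], trait,
                                  seed = cfg$seed + i)
        all$fits[[all$best]]
      })
      per_map <- do.call(rbind, lapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        data.frame(map = i, model = f$model, logL = f$logL, k = f$k,
                   AICc = f$AICc,
                   t(setNames(as.numeric(f$params$sigma2),
                              paste0("sigma2_", names(f$params$sigma2)))),
                   row.names = NULL)
      }))
      emit(per_map, "regime_fits")
      summ <- acrossMapSummary(fits)
      emit(summ$patterns, "regime_patterns")
      emit(summ$pairwise, "regime_pairwise_differences")
      note("regime models fitted on ", length(maps), " maps")
    }
  }

  # --- ASR ---
  if ("asr" %in% stages) {
    a <- asrBM(tree, logw)
    emit(a$nodes, "asr_log10_wbchv")
  }

  # --- CoV ---
  if ("cov" %in% stages && !is.null(ecology)) {
    grp <- ecology[seg$taxon]
    rows <- lapply(intersect(cfg$metrics, names(norm)), function(m) {
      v <- setNames(norm[[m]], norm$taxon)
      tryCatch(groupCoV(v, grp, metric = m), error = function(e) NULL)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) emit(do.call(rbind, rows), "cov_profiles")
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}
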