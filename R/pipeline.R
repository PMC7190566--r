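#' Configuration for the end-to-end candidate pipeline
#'
#' Aggregates every numeric constant of the pipeline with the study's
#' defaults: 0.24 um pixels, the 25-5000 um^2 area filter, the 1000 um^2
#' stratum boundary, 1900 + 300 stratified samples split into two groups of
#' 1500, 256 um review patches with a 0.03 mm^2 marker, and the
#' 70%-majority voting rule. Simulation-scale parameters (tile count and
#' size, object classes, sample sizes) are configurable so the pipeline can
#' be exercised at any scale.
#'
#' @param pixel_size_um Physical pixel size.
#' @param stain A [stain_model()].
#' @param dab_threshold DAB concentration threshold.
#' @param od_epsilon OD offset used when reading 8-bit tiles from disk.
#' @param closing_radius_um Morphological closing radius (0 = off).
#' @param min_area_um2,max_area_um2 Area-filter bounds.
#' @param stratum_boundary_um2 Small/large stratum boundary.
#' @param n_small,n_large Stratified sample sizes.
#' @param group_sizes Review-group sizes (must sum to `n_small + n_large`).
#' @param patch_side_um Review-patch side length.
#' @param marker_area_mm2 Marker square area.
#' @param vote_fraction Consensus voting fraction in (0.5, 1].
#' @param n_tiles Number of synthetic tiles to simulate.
#' @param tile_size_px Tile dimensions (height, width).
#' @param object_classes Planted object classes per tile.
#' @param background_hematoxylin Background hematoxylin concentration.
#' @param noise_sd Intensity noise sd.
#' @param n_raters Simulated panel size.
#' @param rater_confusions Confusion matrix (or list per rater) for the
#'   simulated raters; identity = perfectly reliable raters.
#' @param seeds Named list of integer seeds per stochastic stage:
#'   `scene`, `sample`, `split`, `panel`.
#'
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.24,
                            stain = stain_model(),
                            dab_threshold = 0.15,
                            od_epsilon = 1,
                            closing_radius_um = 0,
                            min_area_um2 = 25, max_area_um2 = 5000,
                            stratum_boundary_um2 = 1000,
                            n_small = 1900, n_large = 300,
                            group_sizes = c(1500, 1500),
                            patch_side_um = 256,
                            marker_area_mm2 = 0.03,
                            vote_fraction = 0.7,
                            n_tiles = 10L,
                            tile_size_px = c(1024L, 1024L),
                            object_classes = default_object_classes(),
                            background_hematoxylin = 0.3,
                            noise_sd = 0,
                            n_raters = 7L,
                            rater_confusions = diag(3),
                            seeds = list(scene = 100L, sample = 200L,
                                         split = 300L, panel = 400L)) {
  stopifnot(pixel_size_um > 0, min_area_um2 < max_area_um2,
            stratum_boundary_um2 > 0, patch_side_um > 0,
            vote_fraction > 0.5, vote_fraction <= 1,
            sum(group_sizes) == n_small + n_large,
            n_tiles >= 1, n_raters >= 1,
            all(c("scene", "sample", "split", "panel") %in% names(seeds)))
  structure(as.list(environment()), class = "pipeline_config")
}

# Run one stage with stderr logging; on error, leave a failure marker in
# the output directory and rethrow with the stage name.
run_stage <- function(name, out_dir, code) {
  t0 <- proc.time()[["elapsed"]]
  message("[", name, "] started")
  res <- tryCatch(code, error = function(e) {
    writeLines(paste0("failed at stage: ", name, "\n",
                      conditionMessage(e)),
               file.path(out_dir, "FAILURE"))
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[%s] done in %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline into an artifact directory
#'
#' Executes simulate -> detect -> area filter -> stratified sample -> group
#' split -> patch extraction -> (ratings in) -> consensus -> agreement, and
#' writes every stage product (tiles, ground truth, candidate tables, patch
#' PNGs, consensus and agreement CSVs) plus a run manifest. The run is
#' deterministic given the configuration: repeating it yields byte-identical
#' tabular outputs. Stage failures leave a `FAILURE` marker naming the
#' stage; earlier outputs are retained.
#'
#' Ratings are taken from `ratings` when given (a panel CSV path or a
#' [rating_panel()] over the sampled objects); otherwise a panel is
#' simulated with `config$rater_confusions`, with each sampled candidate's
#' latent class set by its stratum (small = TB, large = PDC).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param ratings Optional ratings source (path or [rating_panel()]).
#'
#' @return Invisibly, a list with the key stage products: `candidates`,
#'   `sampled`, `panel`, `truth`, `consensus`, `summary`, `agreement`,
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir, ratings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tiles"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "patches"), showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILURE"))

  tile_ids <- sprintf("tile%02d", seq_len(config$n_tiles))

  truth_tabs <- run_stage("simulate", out_dir, {
    lapply(seq_len(config$n_tiles), function(t) {
      spec <- scene_spec(tile_size_px = config$tile_size_px,
                         pixel_size_um = config$pixel_size_um,
                         object_classes = config$object_classes,
                         background_hematoxylin =
                           config$background_hematoxylin,
                         noise_sd = config$noise_sd,
                         seed = config$seeds$scene + t - 1L)
      gen <- generate_tile(spec, config$stain)
      write_tile(gen$tile,
                 file.path(out_dir, "tiles", paste0(tile_ids[t], ".png")))
      write_label_mask(gen$ground_truth$label_mask,
                       file.path(out_dir, "tiles",
                                 paste0(tile_ids[t], "_labels.tiff")))
      gt <- gen$ground_truth$objects
      gt$tile_id <- tile_ids[t]
      write.csv(gt, file.path(out_dir, "tiles",
                              paste0(tile_ids[t], "_truth.csv")),
                row.names = FALSE)
      gt
    })
  })

  candidates <- run_stage("detect", out_dir, {
    pool <- do.call(rbind, lapply(seq_len(config$n_tiles), function(t) {
      tile <- read_tile(file.path(out_dir, "tiles",
                                  paste0(tile_ids[t], ".png")))
      detect_candidates(tile, config$stain,
                        pixel_size_um = config$pixel_size_um,
                        dab_threshold = config$dab_threshold,
                        closing_radius_um = config$closing_radius_um,
                        min_um2 = config$min_area_um2,
                        max_um2 = config$max_area_um2,
                        epsilon = config$od_epsilon,
                        tile_id = tile_ids[t])
    }))
    write_candidates(pool, file.path(out_dir, "candidates.csv"))
    pool
  })

  sampled <- run_stage("sample", out_dir, {
    s <- stratify_sample(candidates, config$n_small, config$n_large,
                         config$stratum_boundary_um2, config$seeds$sample)
    split_groups(s, config$group_sizes, config$seeds$split)
  })
  sampled$uid <- paste0(sampled$tile_id, "_obj", sampled$object_id)
  run_stage("write-sample", out_dir, {
    out <- sampled
    out$object_id <- seq_len(nrow(out)) # unique ids across tiles
    write_candidates(out, file.path(out_dir, "sampled_candidates.csv"))
  })

  manifest_tab <- run_stage("patches", out_dir, {
    tiles_cache <- new.env()
    rows <- lapply(seq_len(nrow(sampled)), function(i) {
      tid <- sampled$tile_id[i]
      if (is.null(tiles_cache[[tid]])) {
        tiles_cache[[tid]] <- read_tile(file.path(out_dir, "tiles",
                                                  paste0(tid, ".png")))
      }
      p <- extract_patch(tiles_cache[[tid]], sampled[i, ],
                         pixel_size_um = config$pixel_size_um,
                         side_um = config$patch_side_um,
                         marker_area_mm2 = config$marker_area_mm2,
                         background_intensity =
                           config$stain$background_intensity)
      path <- file.path("patches", paste0(sampled$uid[i], ".png"))
      write_tile(p$image, file.path(out_dir, path))
      data.frame(object_id = sampled$uid[i], group = sampled$group[i],
                 stratum = sampled$stratum[i], patch_path = path,
                 com_x_um = sampled$centroid_x_um[i],
                 com_y_um = sampled$centroid_y_um[i])
    })
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out_dir, "patch_manifest.csv"),
              row.names = FALSE)
    tab
  })

  panel_truth <- run_stage("ratings", out_dir, {
    if (is.null(ratings)) {
      latent <- ifelse(sampled$stratum == "small", "TB", "PDC")
      cms <- config$rater_confusions
      if (is.matrix(cms)) cms <- rep(list(cms), config$n_raters)
      pr <- with_seed(config$seeds$panel, {
        m <- matrix(NA_character_, nrow(sampled), config$n_raters,
                    dimnames = list(sampled$uid,
                                    sprintf("rater%02d",
                                            seq_len(config$n_raters))))
        li <- match(latent, RATING_CLASSES)
        for (r in seq_len(config$n_raters)) {
          for (k in 1:3) {
            sel <- li == k
            if (any(sel)) {
              m[sel, r] <- sample(RATING_CLASSES, sum(sel),
                                  replace = TRUE, prob = cms[[r]][k, ])
            }
          }
        }
        m
      })
      panel <- rating_panel(pr)
      truth_csv <- data.frame(object_id = sampled$uid, latent_class = latent)
      write.csv(truth_csv, file.path(out_dir, "panel_truth.csv"),
                row.names = FALSE)
      write_panel(panel, file.path(out_dir, "panel.csv"))
      list(panel = panel, truth = setNames(latent, sampled$uid))
    } else {
      panel <- if (inherits(ratings, "rating_panel")) ratings else {
        if (!file.exists(ratings)) {
          stop("ratings file not found: ", ratings)
        }
        read_panel(ratings, allow_incomplete = TRUE)
      }
      if (!setequal(panel$object_ids, sampled$uid)) {
        stop("rating panel objects do not match the sampled candidates")
      }
      list(panel = panel, truth = NULL)
    }
  })
  panel <- panel_truth$panel

  consensus_out <- run_stage("consensus", out_dir, {
    res <- consensus_labels(panel, config$vote_fraction)
    write.csv(as.data.frame(res), file.path(out_dir, "consensus.csv"),
              row.names = FALSE)
    smry <- summarize_consensus(res)
    write.csv(smry$table, file.path(out_dir, "consensus_summary.csv"),
              row.names = FALSE)
    list(labels = res, summary = smry)
  })

  agreement_out <- run_stage("agreement", out_dir, {
    obj_group <- setNames(manifest_tab$group, manifest_tab$object_id)
    fl <- do.call(rbind, lapply(sort(unique(obj_group)), function(g) {
      sub <- panel$ratings[panel$object_ids %in%
                             names(obj_group)[obj_group == g], ,
                           drop = FALSE]
      kp <- fleiss_kappa(rating_panel(sub, allow_incomplete = TRUE))
      data.frame(statistic = "fleiss_kappa", group = as.character(g),
                 value = kp, band = interpret_kappa(kp))
    }))
    cm <- pairwise_kappa_matrix(panel)
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    co <- data.frame(
      statistic = "cohen_kappa",
      group = paste(rownames(cm)[pairs[, 1]], colnames(cm)[pairs[, 2]],
                    sep = ":"),
      value = cm[pairs],
      band = ifelse(is.na(cm[pairs]), NA, interpret_kappa(cm[pairs][
        !is.na(cm[pairs])])[cumsum(!is.na(cm[pairs]))]))
    rep_tab <- rbind(fl, co)
    write.csv(rep_tab, file.path(out_dir, "agreement.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(cm), file.path(out_dir, "cohen_matrix.csv"),
              row.names = TRUE)
    list(table = rep_tab, cohen_matrix = cm)
  })

  run_stage("manifest", out_dir, {
    cfg_echo <- unclass(config)
    cfg_echo$stain <- NULL
    cfg_echo$object_classes <- NULL
    lines <- c(
      jsonlite::toJSON(list(record = "config", config = cfg_echo,
                            stain = list(
                              od_hematoxylin = config$stain$od_hematoxylin,
                              od_dab = config$stain$od_dab,
                              background =
                                config$stain$background_intensity)),
                       auto_unbox = TRUE, digits = NA),
      jsonlite::toJSON(list(record = "run", n_candidates = nrow(candidates),
                            n_sampled = nrow(sampled),
                            package_version =
                              as.character(utils::packageVersion(
                                "budconsensus"))),
                       auto_unbox = TRUE))
    writeLines(lines, file.path(out_dir, "manifest.jsonl"))
  })

  invisible(list(candidates = candidates, sampled = sampled,
                 panel = panel, truth = panel_truth$truth,
                 consensus = consensus_out$labels,
                 summary = consensus_out$summary,
                 agreement = agreement_out,
                 paths = list(out_dir = out_dir)))
}
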