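#' Read and validate a specimen metadata table
#'
#' @param path CSV file with header columns \code{image_id, species_id,
#'   genus_id, family_id, elevation_m, temperature_c, precip_mm} (extra
#'   columns are preserved).
#' @return A data.frame of typed records.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("image_id", "species_id", "genus_id", "family_id",
                "elevation_m", "temperature_c", "precip_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing metadata column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$image_id)) {
    stop("duplicate image_id in metadata: ",
         paste(unique(df$image_id[duplicated(df$image_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$elevation_m)) || any(df$elevation_m < 0)) {
    stop("elevation_m must be finite and nonnegative")
  }
  df
}

#' Run the full colour-diversity analysis pipeline
#'
#' End to end: synthetic dataset generation (or a pre-built
#' \code{moth_dataset}), foreground masks (ground truth or two-cluster
#' segmentation), feature embedding, representative-image selection,
#' species cosine distances, 100-m assemblage binning, diversity trend
#' with pairwise and family bootstraps, melanism colour indices and
#' their climate trends, 1-D MDS + T-statistic variance partitioning
#' with climate trends, the temperature -> brightness -> log T_IC/IR
#' path model with the saturation side-check, and (optionally) the
#' ridge elevation-prediction model with per-image prediction averaging.
#'
#' All randomness derives from \code{config$seed} (bootstrap and
#' train/validation streams use fixed small offsets of it), so reruns
#' with the same config are identical.
#'
#' @param config A \code{\link{sim_config}} or a prebuilt
#'   \code{moth_dataset}.
#' @param variant Embedding variant ("colour", "greyscale", "silhouette").
#' @param D Embedding length.
#' @param bin_width Assemblage bin width (m).
#' @param boot_pairwise_reps Pairwise-bootstrap repeats (0 skips).
#' @param boot_family_reps Family-bootstrap repeats (0 skips).
#' @param boot_m Pairwise resample size; NULL = pair count of the
#'   smallest assemblage.
#' @param segment "truth" uses the generator's ground-truth masks;
#'   "cluster" runs \code{\link{cluster_segment}} + \code{\link{repair_mask}}
#'   and reports segmentation quality.
#' @param fit_elevation Also fit the elevation model (80/20 image split).
#' @return A \code{moth_report} list of records and fitted statistics.
#' @export
run_pipeline <- function(config, variant = "colour", D = 256, bin_width = 100,
                         boot_pairwise_reps = 5000, boot_family_reps = 1000,
                         boot_m = NULL, segment = c("truth", "cluster"),
                         fit_elevation = FALSE) {
  segment <- match.arg(segment)
  ds <- if (inherits(config, "moth_dataset")) config else generate_dataset(config)
  cfg <- ds$config
  meta <- ds$metadata

  seg_masks <- NULL
  seg_report <- NULL
  if (segment == "cluster") {
    seg <- segment_dataset(ds$images, ds$masks)
    seg_masks <- seg$masks
    seg_report <- seg$report
  }
  X <- embed_dataset(ds, variant = variant, D = D, masks = seg_masks)

  # species-level table: mean elevation (over images), climate, family
  reps_df <- select_representatives(meta)
  sp_split <- split(meta, meta$species_id)
  reps_df$temperature <- vapply(sp_split[reps_df$species_id],
                                function(d) mean(d$temperature_c), numeric(1))
  reps_df$precip <- vapply(sp_split[reps_df$species_id],
                           function(d) mean(d$precip_mm), numeric(1))
  reps_df$family_id <- vapply(sp_split[reps_df$species_id],
                              function(d) d$family_id[1], character(1))
  spX <- X[reps_df$rep_image, , drop = FALSE]
  rownames(spX) <- reps_df$species_id

  assemblages <- build_assemblages(reps_df$species_id, reps_df$mean_elev, spX,
                                   family_id = reps_df$family_id,
                                   width = bin_width)
  div <- assemblage_diversity(assemblages)
  div_trend <- fit_trend(div$diversity, div$midpoint)
  boot_pw <- if (boot_pairwise_reps > 0) {
    bootstrap_pairwise(assemblages, m = boot_m, reps = boot_pairwise_reps,
                       seed = cfg$seed + 1)
  }
  boot_fam <- if (boot_family_reps > 0) {
    bootstrap_family(assemblages, reps = boot_family_reps, seed = cfg$seed + 2)
  }

  # assemblage climate = mean over member species
  bins <- bin_species(reps_df$mean_elev, bin_width)
  reps_df$assemblage <- bins$label
  atab <- do.call(rbind, lapply(split(reps_df, reps_df$assemblage), function(d) {
    data.frame(label = d$assemblage[1],
               midpoint = floor(d$mean_elev[1] / bin_width) * bin_width + bin_width / 2,
               n_species = nrow(d),
               temperature = mean(d$temperature),
               precip = mean(d$precip),
               stringsAsFactors = FALSE)
  }))
  rownames(atab) <- NULL

  # melanism indices on representative images (ground-truth part masks)
  idx_rows <- lapply(seq_len(nrow(reps_df)), function(i) {
    id <- reps_df$rep_image[i]
    cbind(species_id = reps_df$species_id[i],
          specimen_indices(ds$images[[id]], ds$masks[[id]]))
  })
  sp_indices <- do.call(rbind, idx_rows)
  sp_indices$assemblage <- reps_df$assemblage
  col_by_asm <- do.call(rbind, lapply(split(sp_indices, sp_indices$assemblage),
                                      function(d) {
    ai <- assemblage_indices(d)
    data.frame(label = d$assemblage[1], mean_B = ai[["mean_B"]],
               mean_S = ai[["mean_S"]], stringsAsFactors = FALSE)
  }))
  atab <- merge(atab, col_by_asm, by = "label", sort = FALSE)

  # 1-D trait axis over the whole regional pool of individuals
  axis1 <- mds_project(cosine_dist_matrix(X), dims = 1,
                       orient_by = meta$elevation_m)[, 1]
  ind_assemblage <- reps_df$assemblage[match(meta$species_id, reps_df$species_id)]
  ts <- t_stats(axis1, meta$species_id, ind_assemblage)
  atab <- merge(atab, ts[, c("label", "t_ip_ic", "t_ic_ir")],
                by = "label", sort = FALSE)
  atab <- atab[order(atab$midpoint), ]
  rownames(atab) <- NULL

  trend_on <- function(y, x) tryCatch(fit_trend(y, x), error = function(e) NULL)
  tst_trends <- list(
    ticir_elevation = trend_on(atab$t_ic_ir, atab$midpoint),
    ticir_temperature = trend_on(atab$t_ic_ir, atab$temperature),
    ticir_precipitation = trend_on(atab$t_ic_ir, atab$precip),
    tipic_elevation = trend_on(atab$t_ip_ic, atab$midpoint),
    tipic_temperature = trend_on(atab$t_ip_ic, atab$temperature),
    tipic_precipitation = trend_on(atab$t_ip_ic, atab$precip)
  )
  colour_trends <- list(
    b_elevation = trend_on(atab$mean_B, atab$midpoint),
    b_temperature = trend_on(atab$mean_B, atab$temperature),
    s_elevation = trend_on(atab$mean_S, atab$midpoint),
    s_temperature = trend_on(atab$mean_S, atab$temperature)
  )

  ok_path <- is.finite(atab$t_ic_ir) & atab$t_ic_ir > 0
  path <- if (sum(ok_path) >= 4) {
    fit_path(atab$temperature[ok_path], atab$mean_B[ok_path],
             atab$t_ic_ir[ok_path])
  }
  sat_check <- if (sum(ok_path) >= 4) {
    fit_saturation_check(atab$mean_S[ok_path], atab$t_ic_ir[ok_path])
  }

  elev_model <- if (fit_elevation) {
    eval_elevation_model(X, meta, reps_df, seed = cfg$seed + 3)
  }

  structure(list(
    seed = cfg$seed, variant = variant, bin_width = bin_width,
    n_images = nrow(meta), n_species = nrow(reps_df),
    assemblage_table = atab,
    diversity = list(records = div, trend = div_trend,
                     boot_pairwise = boot_pw, boot_family = boot_fam),
    colour_trends = colour_trends,
    tstat_trends = tst_trends,
    path = path,
    saturation_check = sat_check,
    elevation_model = elev_model,
    segmentation = seg_report
  ), class = "moth_report")
}

# 80/20 image split (every species keeps >= 1 training image), ridge fit,
# species-level validation R^2 with per-image prediction averaging.
eval_elevation_model <- function(X, meta, reps_df, lambda = 1, seed = 1) {
  n <- nrow(meta)
  val <- with_seed(seed, {
    v <- sample.int(n, max(1, round(0.2 * n)))
    for (sp in unique(meta$species_id[v])) {
      rows <- which(meta$species_id == sp)
      if (all(rows %in% v)) v <- setdiff(v, rows[1])
    }
    v
  })
  train <- setdiff(seq_len(n), val)
  model <- fit_elevation_model(X[train, , drop = FALSE],
                               meta$elevation_m[train], lambda = lambda)
  val_meta <- meta[val, ]
  val_sp <- unique(val_meta$species_id)
  pred <- vapply(val_sp, function(sp) {
    rows <- val_meta$image_id[val_meta$species_id == sp]
    predict_species_elevation(model, X[rows, , drop = FALSE])
  }, numeric(1))
  actual <- reps_df$mean_elev[match(val_sp, reps_df$species_id)]
  list(r2_species = stats::cor(pred, actual)^2,
       mse_train = model$mse, r2_train = model$r2,
       n_val_species = length(val_sp), lambda = lambda)
}

#' Write a pipeline report as JSON
#'
#' @param report A \code{moth_report} (or any list of records/statistics).
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    class(x) <- NULL
  } else if (inherits(x, "trend_fit") || inherits(x, "path_fit")) {
    class(x) <- NULL
  }
  x
}
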