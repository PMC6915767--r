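#' Run the full quantification pipeline from a single configuration
#'
#' Orchestrates simulate -> register -> segment -> reconstruct ->
#' plaque -> colocalization -> statistics, writing one CSV per stage
#' table plus a JSON manifest. A rerun with the same configuration and
#' seed is bit-identical at the CSV level.
#'
#' Configuration schema (YAML or nested list):
#' \preformatted{
#' seed: 1
#' run: all            # or "simulate" for stacks + truth only
#' calibration: {pixel_size_xy: 0.1, section_thickness: 0.07}
#' channels:
#'   synaptic: [synaptophysin, PSD95]
#'   markers:  [tau, abeta]
#'   plaque_core: thios
#' simulate:
#'   base_params: {field_size_px: [96, 96], n_sections: 10}
#'   groups:
#'     - name: vehicle
#'       n_animals: 4
#'       params: {marker_positive_fraction: {tau: 0.05, abeta: 0.05}}
#'     - name: dox
#'       n_animals: 4
#'       params: {marker_positive_fraction: {tau: 0.01, abeta: 0.05}}
#' segmentation: {methods: [otsu, triangle], min_object_px: 2}
#' coloc: {threshold: 0.5}
#' plaque: {cutoff_um: 20, min_plaque_area_um2: 20}
#' stats: {alternative: two.sided}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return invisibly, `list(tables, manifest)`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  cal <- config$calibration
  if (is.null(cal) || is.null(cal$pixel_size_xy) ||
      is.null(cal$section_thickness)) {
    stop("config error: calibration (pixel_size_xy, section_thickness) is required")
  }
  if (is.null(config$simulate)) {
    stop("config error: this build runs from a `simulate` block (no raw-data loader configured)")
  }
  seed <- as.integer(if (!is.null(seed)) seed else
                       if (!is.null(config$seed)) config$seed else 1L)
  run_mode <- if (!is.null(config$run)) config$run else "all"
  seg <- config$segmentation
  methods <- if (!is.null(seg$methods)) unlist(seg$methods) else c("otsu", "triangle")
  min_obj <- if (!is.null(seg$min_object_px)) seg$min_object_px else 2L
  coloc_thr <- if (!is.null(config$coloc$threshold)) config$coloc$threshold else 0.5
  cutoff_um <- if (!is.null(config$plaque$cutoff_um)) config$plaque$cutoff_um else 20
  min_plaque <- if (!is.null(config$plaque$min_plaque_area_um2))
    config$plaque$min_plaque_area_um2 else 20
  alternative <- if (!is.null(config$stats$alternative))
    config$stats$alternative else "two.sided"
  # integer mode by default: ribbon misalignments are whole-pixel and
  # integer corrections are lossless; set registration$upsample > 1 for
  # subpixel refinement
  reg_upsample <- if (!is.null(config$registration$upsample))
    config$registration$upsample else 1

  syn_channels <- unlist(config$channels$synaptic)
  markers <- unlist(config$channels$markers)
  core_channel <- config$channels$plaque_core

  groups <- config$simulate$groups
  if (is.null(groups)) stop("config error: simulate$groups is required")
  base_par <- config$simulate$base_params

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  densities <- list(); coloc_tab <- list()
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(g$n_animals)) {
      idx <- idx + 1L
      animal <- sprintf("%s_%02d", g$name, i)
      aseed <- (seed + 7919L * idx) %% 2147483647L
      par_args <- list(pixel_size_xy = cal$pixel_size_xy,
                       section_thickness = cal$section_thickness,
                       seed = aseed)
      for (src in list(base_par, g$params)) {
        for (nm in names(src)) {
          v <- src[[nm]]
          if (is.list(v)) v <- unlist(v)
          par_args[[nm]] <- v
        }
      }
      params <- .stage("simulate", animal, do.call(synth_params, par_args))
      gen <- .stage("simulate", animal,
                    generate_stack(params, keep_aligned = FALSE,
                                   keep_masks = FALSE))
      if (run_mode == "simulate") {
        sdir <- file.path(out_dir, "stacks", animal)
        .stage("simulate", animal, write_stack(gen$stack, sdir))
        jsonlite::write_json(
          list(animal_id = animal, group = g$name, seed = aseed,
               true_densities = as.list(gen$truth$true_densities),
               true_shifts = gen$truth$true_shifts,
               n_puncta = nrow(gen$truth$puncta)),
          file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
        next
      }
      est <- .stage("register", animal,
                    estimate_shifts(gen$stack, upsample = reg_upsample))
      reg <- .stage("register", animal,
                    apply_transforms(gen$stack, est))$stack
      vol <- stack_volume_um3(reg)

      pm <- NULL
      if (!is.null(core_channel) && core_channel %in% names(reg$channels)) {
        plaque_methods <- if (!is.null(config$plaque$methods))
          unlist(config$plaque$methods) else "otsu"
        pm <- .stage("plaque", animal,
                     detect_plaques(reg, core_channel = core_channel,
                                    min_plaque_area_um2 = min_plaque,
                                    methods = plaque_methods))
      }
      marker_masks <- list()
      for (m in intersect(markers, names(reg$channels))) {
        mm <- .stage("segment", animal,
                     binarize_stack(reg, m, methods = methods,
                                    min_object_px = min_obj))
        # denoised marker mask: single-section marker objects removed
        marker_masks[[m]] <- .stage("segment", animal,
                                    mask_from_puncta(filter_single_section(link_3d(mm))))
      }
      for (ch in syn_channels) {
        ps <- .stage("segment", animal,
                     binarize_stack(reg, ch, methods = methods,
                                    min_object_px = min_obj))
        ps <- .stage("reconstruct", animal, filter_single_section(link_3d(ps)))
        densities[[length(densities) + 1L]] <- data.frame(
          animal_id = animal, group = g$name, channel = ch,
          n_puncta = length(ps), volume_um3 = vol,
          density_per_um3 = punctum_density(ps, vol),
          stringsAsFactors = FALSE)
        if (length(marker_masks)) {
          strata <- if (!is.null(pm)) {
            data.frame(near_far = annotate_near_far(ps, pm,
                                                    cutoff_um)$near_far)
          } else NULL
          cr <- .stage("coloc", animal,
                       coloc_rates(ps, marker_masks, strata = strata,
                                   threshold = coloc_thr))
          cr <- cbind(data.frame(animal_id = animal, group = g$name,
                                 channel = ch, stringsAsFactors = FALSE),
                      as.data.frame(cr))
          coloc_tab[[length(coloc_tab) + 1L]] <- cr
        }
      }
    }
  }

  if (run_mode == "simulate") {
    manifest <- write_results(list(), out_dir, config = config, seed = seed)
    return(invisible(list(tables = list(), manifest = manifest)))
  }

  tables <- list(density = do.call(rbind, densities))
  if (length(coloc_tab)) tables$coloc <- do.call(rbind, coloc_tab)

  # group statistics on per-animal values (animal = experimental unit)
  stats_rows <- list()
  gnames <- vapply(groups, `[[`, character(1), "name")
  if (length(gnames) >= 2L) {
    cmp <- function(df, metric, label, channel, marker = NA_character_) {
      a <- df$value[df$group == gnames[1]]
      b <- df$value[df$group == gnames[2]]
      if (length(a) && length(b)) {
        mw <- mann_whitney_u(a, b, alternative = alternative)
        data.frame(metric = label, channel = channel, marker = marker,
                   group_a = gnames[1], group_b = gnames[2],
                   n_a = mw$n_a, n_b = mw$n_b, U = mw$U, p = mw$p,
                   method = mw$method, stringsAsFactors = FALSE)
      }
    }
    for (ch in unique(tables$density$channel)) {
      sub <- tables$density[tables$density$channel == ch, ]
      sub$value <- sub$density_per_um3
      stats_rows[[length(stats_rows) + 1L]] <-
        cmp(sub, "density", "density_per_um3", ch)
    }
    if (!is.null(tables$coloc)) {
      for (ch in unique(tables$coloc$channel)) {
        for (m in unique(tables$coloc$marker)) {
          sub <- tables$coloc[tables$coloc$channel == ch &
                                tables$coloc$marker == m &
                                !is.na(tables$coloc$fraction), ]
          if (!nrow(sub)) next
          # per-animal value: pool strata by animal (median)
          agg <- aggregate_per_animal(sub, "fraction", "median",
                                      group_cols = "group")
          agg$value <- agg$value
          stats_rows[[length(stats_rows) + 1L]] <-
            cmp(agg, "coloc_fraction", "coloc_fraction", ch, m)
        }
      }
    }
  }
  stats_rows <- Filter(Negate(is.null), stats_rows)
  if (length(stats_rows)) tables$stats <- do.call(rbind, stats_rows)

  manifest <- write_results(tables, out_dir, config = config, seed = seed)
  invisible(list(tables = tables, manifest = manifest))
}

# run one stage, aborting with the stage name on failure
.stage <- function(stage, unit, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for '%s': %s", stage, unit,
                 conditionMessage(e)), call. = FALSE)
  })
}
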