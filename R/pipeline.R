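#' Measure one fiber image end to end
#'
#' Runs segmentation, Z-line localization, autophagosome and lysosome
#' detection and contact analysis on a single fiber image and returns a
#' one-row data.frame of per-fiber measurements.
#'
#' @param image a [fiber_image()].
#' @param params named list overriding detection parameters:
#'   `threshold_factor` (1.1), `min_area_px` (4),
#'   `zline_band_halfwidth_um` (0.15), `max_gap_um` (0.4),
#'   `lyso_threshold_factor` (defaults to `threshold_factor`),
#'   `high_threshold` (100), `segment_channel` ("mito"),
#'   `profile_bin_um` (pixel size).
#' @return one-row data.frame: mask area, axis angle, Z-line count and
#'   period, LC3 alignment offset, puncta count, area_ratio (all puncta)
#'   and area_ratio_off_zline, lysosome count, is_high, contact_fraction.
#' @export
measure_fiber <- function(image, params = list()) {
  p <- utils::modifyList(list(threshold_factor = 1.1, min_area_px = 4,
                              zline_band_halfwidth_um = 0.15,
                              max_gap_um = 0.4,
                              lyso_threshold_factor = NULL,
                              high_threshold = 100,
                              segment_channel = "mito",
                              profile_bin_um = image$pixel_size_um),
                         params)
  if (is.null(p$lyso_threshold_factor)) p$lyso_threshold_factor <- p$threshold_factor
  mask <- segment_fiber(image, channel = p$segment_channel)
  mito_prof <- axis_profile(image, mask, channel = "mito",
                            bin_width_um = p$profile_bin_um)
  pairs <- detect_mito_pairs(mito_prof)
  zmap <- if (nrow(pairs) > 0) infer_zlines(pairs) else NULL
  lc3_prof <- axis_profile(image, mask, channel = "lc3",
                           bin_width_um = p$profile_bin_um)
  align <- tryCatch(
    if (!is.null(zmap)) lc3_alignment_offset(lc3_prof, zmap) else NA_real_,
    fiberflux_no_peaks = function(e) NA_real_)
  puncta <- segment_autophagosomes(image, mask, zmap,
                                   threshold_factor = p$threshold_factor,
                                   min_area_px = p$min_area_px,
                                   zline_band_halfwidth_um = p$zline_band_halfwidth_um)
  lyso <- segment_lysosomes(image, mask,
                            threshold_factor = p$lyso_threshold_factor,
                            min_area_px = p$min_area_px)
  lres <- count_and_classify(lyso, high_threshold = p$high_threshold)
  cf <- contact_fraction(puncta, lyso, max_gap_um = p$max_gap_um)
  data.frame(area_px = mask$area_px, area_um2 = mask$area_um2,
             axis_angle = mask$axis_angle,
             n_zlines = if (is.null(zmap)) 0L else length(zmap$zline_positions_um),
             period_um = if (is.null(zmap)) NA_real_ else zmap$period_um,
             lc3_alignment_um = align,
             n_puncta = nrow(puncta$records),
             area_ratio = area_ratio(puncta, mask),
             area_ratio_off_zline = area_ratio(puncta, mask, off_zline_only = TRUE),
             lyso_count = lres$count,
             is_high = lres$is_high,
             contact_fraction = as.numeric(cf))
}

#' @keywords internal
condition_string <- function(genotype, age_group, treatment)
  paste(genotype, age_group, treatment, sep = "_")

#' Run the full quantification pipeline over a cohort
#'
#' The cohort is either simulated in place (config element `simulate`) or
#' read from a directory of multi-page TIFFs with a manifest CSV (config
#' element `images`). Each fiber is measured with [measure_fiber()],
#' per-condition summaries (mean, SEM, percent high-lysosome) are built,
#' and declared pairwise comparisons are tested with the pooled t-test.
#'
#' @param config a named list or path to a YAML file with elements:
#'   \describe{
#'     \item{simulate}{list: `conditions` (data.frame or list of lists
#'       with genotype/age_group/treatment), `n_fibers`, `seed`, optional
#'       `image` overrides passed to [sim_config()].}
#'     \item{images}{list: `dir` and `manifest` (CSV with columns file,
#'       genotype, age_group, treatment, pixel_size_um).}
#'     \item{params}{detection parameter overrides, see [measure_fiber()].}
#'     \item{comparisons}{list of lists with `a`, `b` (condition strings
#'       "genotype_age_treatment") and optional `metric` (default
#'       "area_ratio").}
#'     \item{out_dir}{optional output directory for CSVs and a JSON run
#'       log.}
#'   }
#' @return list with `per_fiber`, `groups`, `comparisons` data.frames and
#'   `log` (run metadata).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- if (is.null(config$params)) list() else config$params
  per <- list()

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    conds <- sim$conditions
    if (is.data.frame(conds))
      conds <- lapply(seq_len(nrow(conds)), function(i) as.list(conds[i, ]))
    cfg_args <- if (is.null(sim$image)) list() else sim$image
    if (!is.null(sim$seed)) cfg_args$master_seed <- sim$seed
    scfg <- do.call(sim_config, cfg_args)
    for (ci in seq_along(conds)) {
      cn <- conds[[ci]]
      preset <- build_preset(cn$genotype, cn$age_group, cn$treatment)
      for (fi in seq_len(sim$n_fibers)) {
        img <- simulate_fiber(preset, scfg,
                              fiber_seed(scfg$master_seed, ci, fi))$image
        row <- measure_fiber(img, params)
        row <- cbind(data.frame(fiber_id = sprintf("%s_f%03d",
                                                   condition_string(cn$genotype, cn$age_group, cn$treatment), fi),
                                genotype = cn$genotype, age_group = cn$age_group,
                                treatment = cn$treatment), row)
        per[[length(per) + 1L]] <- row
      }
    }
  } else if (!is.null(config$images)) {
    man <- utils::read.csv(config$images$manifest, stringsAsFactors = FALSE)
    missing <- !file.exists(file.path(config$images$dir, man$file))
    if (any(missing))
      stop_fiberflux("fiberflux_missing_files", "missing image files: %s",
                     paste(man$file[missing], collapse = ", "))
    for (i in seq_len(nrow(man))) {
      img <- read_fiber_tiff(file.path(config$images$dir, man$file[i]),
                             pixel_size_um = man$pixel_size_um[i])
      row <- measure_fiber(img, params)
      row <- cbind(data.frame(fiber_id = man$file[i], genotype = man$genotype[i],
                              age_group = man$age_group[i],
                              treatment = man$treatment[i]), row)
      per[[length(per) + 1L]] <- row
    }
  } else {
    stop("config must contain either a 'simulate' or an 'images' block")
  }
  per_fiber <- do.call(rbind, per)
  per_fiber$condition <- condition_string(per_fiber$genotype,
                                          per_fiber$age_group,
                                          per_fiber$treatment)

  metrics <- c("area_ratio", "area_ratio_off_zline", "lyso_count",
               "contact_fraction")
  groups <- do.call(rbind, lapply(split(per_fiber, per_fiber$condition), function(g) {
    rows <- do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]][!is.na(g[[m]])]
      if (!length(v)) return(NULL)
      group_summary(v, condition = g$condition[1], metric = m)
    }))
    ph <- data.frame(condition = g$condition[1], metric = "percent_high",
                     n = nrow(g), mean = percent_high(g$is_high), sem = NA_real_)
    rbind(rows, ph)
  }))
  rownames(groups) <- NULL

  comparisons <- NULL
  if (!is.null(config$comparisons)) {
    comparisons <- do.call(rbind, lapply(config$comparisons, function(cmp) {
      metric <- if (is.null(cmp$metric)) "area_ratio" else cmp$metric
      va <- per_fiber[[metric]][per_fiber$condition == cmp$a]
      vb <- per_fiber[[metric]][per_fiber$condition == cmp$b]
      if (sum(!is.na(va)) < 2 || sum(!is.na(vb)) < 2) return(NULL)
      out <- two_sample_ttest(va, vb, label_a = cmp$a, label_b = cmp$b)
      cbind(data.frame(metric = metric), out)
    }))
    rownames(comparisons) <- NULL
  }

  log <- list(package = "fiberflux",
              version = as.character(utils::packageVersion("fiberflux")),
              schema = 1L,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              n_fibers = nrow(per_fiber),
              params = params,
              seed = if (!is.null(config$simulate)) config$simulate$seed else NULL)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_fiber, file.path(config$out_dir, "per_fiber.csv"),
                     row.names = FALSE)
    utils::write.csv(groups, file.path(config$out_dir, "groups.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                       row.names = FALSE)
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(per_fiber = per_fiber, groups = groups, comparisons = comparisons,
       log = log)
}
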