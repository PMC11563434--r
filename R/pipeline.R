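#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' with every tunable switch at its default. Fields:
#' \describe{
#'   \item{input_dir/out_dir}{paths to a study bundle (see
#'     [simulate_study()]) and the output directory.}
#'   \item{erg}{`normalization` ("per_wavelength"/"per_animal"),
#'     `bwave_mode` ("trough_to_peak"/"baseline_to_peak"),
#'     `reject_factor` (artifact rejection multiple).}
#'   \item{spectra}{`auc_baseline` ("zero"/"min").}
#'   \item{stats}{`alpha` in (0,1), `normality`
#'     ("lilliefors"/"ks_naive").}
#'   \item{seed}{integer recorded in the manifest.}
#' }
#' @param ... named overrides, e.g. `stats = list(alpha = 0.01)`.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input_dir = NULL, out_dir = NULL,
    erg = list(normalization = "per_wavelength",
               bwave_mode = "trough_to_peak", reject_factor = 5),
    spectra = list(auc_baseline = "zero"),
    stats = list(alpha = 0.05, normality = "lilliefors"),
    seed = 1L)
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    else cfg[[nm]] <- mods[[nm]]
  }
  cfg
}

validate_config <- function(cfg) {
  a <- cfg$stats$alpha
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a >= 1)
    stop("config: alpha must lie strictly between 0 and 1", call. = FALSE)
  if (!cfg$erg$normalization %in% c("per_wavelength", "per_animal"))
    stop("config: unknown normalization mode '", cfg$erg$normalization, "'",
         call. = FALSE)
  if (!cfg$erg$bwave_mode %in% c("trough_to_peak", "baseline_to_peak"))
    stop("config: unknown b-wave mode '", cfg$erg$bwave_mode, "'",
         call. = FALSE)
  if (!cfg$spectra$auc_baseline %in% c("zero", "min"))
    stop("config: unknown AUC baseline '", cfg$spectra$auc_baseline, "'",
         call. = FALSE)
  if (!cfg$stats$normality %in% c("lilliefors", "ks_naive"))
    stop("config: unknown normality method '", cfg$stats$normality, "'",
         call. = FALSE)
  if (!is.numeric(cfg$erg$reject_factor) || cfg$erg$reject_factor <= 1)
    stop("config: reject_factor must exceed 1", call. = FALSE)
  invisible(cfg)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tf)
  unname(tools::md5sum(tf))
}

write_output_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a pipeline output table
#'
#' Reads a CSV written by [run_pipeline()], skipping the config-hash
#' comment line (returned as attribute `config_hash`).
#' @param path file path.
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- sub("^# config_hash: ", "", first)
  df
}

#' Write a synthetic study bundle to disk
#'
#' Generates and writes a complete synthetic study mirroring the
#' morph-level comparison at the heart of the analysis: two aposematic
#' morph groups ("Popa"-like and "Cemetery"-like, 11 animals each, the
#' field cohort sizes), six stimulus wavelengths (400-650 nm), a true
#' sensitivity advantage of the Popa-like group at 450 and 550 nm, and
#' per-group dorsal reflectance spectra peaking at 560 nm (Popa-like)
#' and 642 nm (Cemetery-like). The bundle holds everything
#' [run_pipeline()] consumes: per-specimen reflectance spectra with a
#' manifest, photographic marking and surface tables, a pre-extracted
#' ERG amplitude table, and the generating ground truth as JSON.
#'
#' @param out_dir directory to create.
#' @param seed integer seed; all randomness derives from it.
#' @param groups cohort design data frame (`group`, `n_female`,
#'   `n_male`).
#' @param wavelengths_nm stimulus set.
#' @param effect_map per-group per-wavelength true `flash0` shifts.
#' @param noise_sd_rel amplitude noise SD on relative b-wave amplitude.
#' @param reflectance_peaks named vector of dorsal reflectance peak
#'   centers (nm) per group.
#' @return Invisibly, the paths written.
#' @export
simulate_study <- function(out_dir, seed = 1L,
                           groups = data.frame(
                             group = c("Popa", "Cemetery"),
                             n_female = c(6, 7), n_male = c(5, 4)),
                           wavelengths_nm = c(400, 450, 500, 550, 600, 650),
                           effect_map = data.frame(
                             group = "Popa",
                             wavelength_nm = c(450, 550),
                             shift = c(-0.5, -0.5)),
                           noise_sd_rel = 0.05,
                           reflectance_peaks = c(Popa = 560, Cemetery = 642)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
  set.seed(seed)

  truth <- generate_cohort(groups, wavelengths_nm = wavelengths_nm,
                           effect_map = effect_map,
                           seed = sample.int(2^31 - 1, 1))
  amps <- simulate_cohort_amplitudes(truth, noise_sd_rel = noise_sd_rel,
                                     seed = sample.int(2^31 - 1, 1))
  utils::write.csv(amps, file.path(out_dir, "erg_amplitudes.csv"),
                   row.names = FALSE)

  # per-specimen dorsal reflectance spectra: 6 specimens per group,
  # Gaussian peak at the group's dorsal color with mild jitter
  manifest <- list()
  animals <- unique(truth[, c("animal_id", "group")])
  for (g in names(reflectance_peaks)) {
    ids <- utils::head(animals$animal_id[animals$group == g], 6)
    for (sid in ids) {
      cv <- generate_spectrum(
        baseline_pct = 5,
        peaks = data.frame(center_nm = reflectance_peaks[[g]] + stats::rnorm(1, 0, 3),
                           amplitude_pct = 55 + stats::rnorm(1, 0, 5),
                           sigma_nm = 45 + stats::rnorm(1, 0, 4)),
        noise_sd_pct = 1, grid = c(300, 700, 1),
        seed = sample.int(2^31 - 1, 1))
      fn <- sprintf("spectra/%s_dorsal.csv", sid)
      utils::write.csv(data.frame(wavelength_nm = cv$wavelength_nm,
                                  reflectance_pct = cv$reflectance_pct),
                       file.path(out_dir, fn), row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = fn, specimen_id = sid, group = g, region = "dorsal",
        subregion = "")
    }
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(out_dir, "spectra_manifest.csv"),
                   row.names = FALSE)

  # photographic marking tables: bright dorsal marking on most of the
  # surface for both aposematic morphs, darker flanks
  mk_all <- list(); sf_all <- list()
  for (i in seq_len(nrow(animals))) {
    g <- animals$group[i]
    bright <- if (g == "Popa") c(90, 200, 40) else c(220, 60, 30)
    tabs <- generate_marking_table(
      markings = data.frame(
        surface = c("dorsal", "dorsal", "lateral"),
        marking_label = c("ground_color", "spots", "flank"),
        r = pmin(255, pmax(0, c(bright[1], 20, 60) + stats::rnorm(3, 0, 4))),
        g = pmin(255, pmax(0, c(bright[2], 20, 50) + stats::rnorm(3, 0, 4))),
        b = pmin(255, pmax(0, c(bright[3], 20, 45) + stats::rnorm(3, 0, 4))),
        fraction = c(0.8, 0.15, 0.6)),
      total_areas = c(dorsal = stats::rlnorm(1, log(300), 0.1),
                      lateral = stats::rlnorm(1, log(200), 0.1)),
      frog_id = animals$animal_id[i])
    tabs$markings$group <- g
    tabs$surfaces$group <- g
    mk_all[[i]] <- tabs$markings; sf_all[[i]] <- tabs$surfaces
  }
  utils::write.csv(do.call(rbind, mk_all),
                   file.path(out_dir, "markings.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, sf_all),
                   file.path(out_dir, "surfaces.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed,
         truth = truth,
         design = list(groups = groups, wavelengths_nm = wavelengths_nm,
                       effect_map = effect_map,
                       noise_sd_rel = noise_sd_rel,
                       reflectance_peaks = as.list(reflectance_peaks))),
    file.path(out_dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  invisible(list.files(out_dir, recursive = TRUE, full.names = TRUE))
}

#' Run the full analysis pipeline on a study bundle
#'
#' Chains the analysis stages on the files of an input directory (the
#' layout written by [simulate_study()]): reflectance spectra are read
#' and summarized into curve metrics, PCA and per-group dorsal summary
#' curves; photographic marking tables are scored and compared across
#' groups by one-way ANOVA with Tukey HSD; the ERG amplitude table is
#' fitted per animal and wavelength, thresholds extracted, group tuning
#' curves built and compared by two-way ANOVA (wavelength x group) with
#' Bonferroni contrasts, after an assumption screen; finally the
#' matched-filter report juxtaposes each group's tuning-curve minimum
#' with its dorsal reflectance peak. All tables are written as CSV
#' stamped with the config hash, together with a JSON run manifest and
#' a log file.
#'
#' @param config a [default_config()] list (or path to a YAML file with
#'   the same structure); `input_dir` and `out_dir` are required.
#' @return Invisibly, a list with the principal results (`metrics`,
#'   `pca`, `scores`, `photo_anova`, `erg`, `tuning`, `erg_anova`,
#'   `assumptions`, `match_report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  cfg <- validate_config(utils::modifyList(default_config(), config))
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stop("config must set input_dir and out_dir", call. = FALSE)
  ind <- cfg$input_dir
  if (!dir.exists(ind)) stop("input directory not found: ", ind, call. = FALSE)
  outd <- cfg$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  # hash only the analysis-relevant configuration, not filesystem paths
  hash <- config_hash(cfg[setdiff(names(cfg), c("input_dir", "out_dir"))])
  logf <- file.path(outd, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  alpha <- cfg$stats$alpha

  # --- spectra ---
  say("reading reflectance spectra")
  man <- utils::read.csv(file.path(ind, "spectra_manifest.csv"))
  curves <- lapply(seq_len(nrow(man)), function(i)
    read_spectrum(file.path(ind, man$file[i]),
                  meta = as.list(man[i, setdiff(names(man), "file")])))
  metrics <- do.call(rbind, lapply(seq_along(curves), function(i)
    cbind(man[i, setdiff(names(man), "file"), drop = FALSE],
          as.data.frame(compute_metrics(
            curves[[i]], auc_baseline = cfg$spectra$auc_baseline)))))
  rownames(metrics) <- NULL
  write_output_csv(metrics, file.path(outd, "spectrum_metrics.csv"), hash)

  pca <- NULL
  if (nrow(metrics) >= 3L &&
      all(apply(metrics[, c("peak_nm", "fwhm_nm", "auc_pct_nm", "avg_pct")],
                2, stats::var) > 0)) {
    pca <- pca_metrics(metrics, group = "group")
    write_output_csv(data.frame(component = seq_along(pca$variance_pct),
                                variance_pct = pca$variance_pct),
                     file.path(outd, "pca_variance.csv"), hash)
    write_output_csv(cbind(metrics[, c("specimen_id", "group")],
                           as.data.frame(pca$scores)),
                     file.path(outd, "pca_scores.csv"), hash)
    say("PCA: PC1 ", round(pca$variance_pct[1], 1), "%, PC2 ",
        round(pca$variance_pct[2], 1), "%")
  } else say("PCA skipped: too few or degenerate metric rows")

  dorsal <- curves[vapply(curves, function(cv)
    identical(cv$meta$region, "dorsal"), logical(1))]
  dorsal_summary <- summarize_group(dorsal, group_key = "group")
  write_output_csv(dorsal_summary, file.path(outd, "dorsal_summary.csv"), hash)

  # --- photometry ---
  say("scoring photographic marking tables")
  mk <- utils::read.csv(file.path(ind, "markings.csv"))
  sf <- utils::read.csv(file.path(ind, "surfaces.csv"))
  scores <- scaled_reflectance(mk, sf)
  surf_scores <- scores$surfaces
  surf_scores$group <- sf$group[match(
    paste(surf_scores$frog_id, surf_scores$surface),
    paste(sf$frog_id, sf$surface))]
  write_output_csv(surf_scores, file.path(outd, "surface_scores.csv"), hash)
  photo_anova <- lapply(split(surf_scores, surf_scores$surface), function(d) {
    if (length(unique(d$group)) < 2L) return(NULL)
    one_way_anova(d$scaled_reflectance_au, d$group, alpha = alpha)
  })
  pa_tab <- do.call(rbind, lapply(names(photo_anova), function(s) {
    if (is.null(photo_anova[[s]])) return(NULL)
    cbind(surface = s, photo_anova[[s]]$table)
  }))
  if (!is.null(pa_tab))
    write_output_csv(pa_tab, file.path(outd, "photometry_anova.csv"), hash)

  # --- erg ---
  say("fitting V-log(I) curves")
  amps <- utils::read.csv(file.path(ind, "erg_amplitudes.csv"))
  erg <- erg_thresholds(amps, normalization = cfg$erg$normalization)
  write_output_csv(erg$fits, file.path(outd, "erg_fits.csv"), hash)
  thr <- erg$thresholds
  thr$group <- amps$group[match(thr$animal_id, amps$animal_id)]
  write_output_csv(thr, file.path(outd, "erg_thresholds.csv"), hash)
  tuning <- build_tuning_curve(thr, groups = "group")
  write_output_csv(as.data.frame(tuning),
                   file.path(outd, "tuning_curve.csv"), hash)

  say("assumption checks and two-way ANOVA on thresholds")
  checks <- assumption_checks(thr$threshold_log_intensity, thr$group,
                              normality = cfg$stats$normality)
  write_output_csv(checks$normality, file.path(outd, "assumptions.csv"), hash)
  erg_anova <- NULL
  if (length(unique(thr$group)) >= 2L) {
    erg_anova <- two_way_anova(thr$threshold_log_intensity,
                               thr$wavelength_nm, thr$group, alpha = alpha)
    write_output_csv(erg_anova$table, file.path(outd, "erg_anova.csv"), hash)
    write_output_csv(erg_anova$pairwise,
                     file.path(outd, "erg_pairwise.csv"), hash)
  }

  # --- matched filter ---
  match_report <- tryCatch(
    matched_filter_report(tuning, dorsal_summary),
    error = function(e) {
      say("matched-filter report skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(match_report))
    write_output_csv(match_report, file.path(outd, "match_report.csv"), hash)

  manifest <- list(
    package = "ergtune",
    version = as.character(utils::packageVersion("ergtune")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = hash,
    outputs = list.files(outd, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, logf)
  say("pipeline complete: ", outd)

  invisible(list(metrics = metrics, pca = pca, scores = scores,
                 photo_anova = photo_anova, erg = erg, tuning = tuning,
                 erg_anova = erg_anova, assumptions = checks,
                 match_report = match_report, manifest = manifest))
}
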