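#' Simulate a dataset to disk
#'
#' Generates a cohort under the configuration and writes the tracker-style
#' angle table, the clip metadata table, the per-clip generative ground
#' truth, and a run manifest (seed, config hash, file digests, clip counts
#' per task).
#'
#' @param config a [load_config()] result (default: all documented defaults)
#' @param out_dir output directory
#' @param force overwrite a non-empty output directory
#' @return the manifest list, invisibly
#' @export
run_simulate <- function(config = load_config(quiet = TRUE), out_dir,
                         force = FALSE) {
  prepare_dir(out_dir, force)
  cohort <- simulate_cohort(config$cohort, config$simulation, config$arena,
                            seed = config$seed)
  paths <- file.path(out_dir, c("angles.csv", "metadata.csv", "truth.csv"))
  write_angle_table(cohort, paths[1])
  write_clip_metadata(cohort$metadata, paths[2])
  data.table::fwrite(cohort$truth, paths[3])
  manifest <- make_manifest(
    config, paths,
    counts = list(clips_total = length(cohort$clips),
                  clips_by_task = as.list(table(cohort$metadata$task)),
                  mice = nrow(cohort$mice)))
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Analyse a simulated or imported dataset
#'
#' Full analysis pass over a dataset directory written by [run_simulate()]
#' (or assembled by hand in the same CSV dialect): clip QC, per-clip
#' metrics, PC/DC sectioning and differencing for object clips, per-metric
#' mixed models with Kenward-Roger F-tests, MANOVA with effect sizes,
#' session post hoc contrasts, and a chi-squared test on genotype-by-zone
#' occupancy percentages. Writes tidy CSV tables plus a JSON summary and
#' manifest.
#'
#' @param dataset_dir directory containing `angles.csv` and `metadata.csv`
#' @param config a [load_config()] result
#' @param out_dir results directory
#' @param force overwrite a non-empty output directory
#' @return invisible list with the main result tables
#' @export
run_analyze <- function(dataset_dir, config = load_config(quiet = TRUE),
                        out_dir, force = FALSE) {
  prepare_dir(out_dir, force)
  md <- read_clip_metadata(file.path(dataset_dir, "metadata.csv"))
  clips <- read_angle_table(file.path(dataset_dir, "angles.csv"),
                            metadata = md, fps = config$simulation$fps)

  # --- QC ---------------------------------------------------------------
  qc <- lapply(clips, qc_clip, thresholds = config$qc)
  qc_report <- data.frame(
    clip_id = names(clips),
    pass = vapply(qc, `[[`, TRUE, "pass"),
    reasons = vapply(qc, function(q) paste(q$reasons, collapse = "; "), ""),
    stringsAsFactors = FALSE)
  passed <- names(clips)[qc_report$pass]
  if (length(passed) == 0L) stop("zero clips passed QC; nothing to analyse")

  # --- metrics ----------------------------------------------------------
  rows <- list(); pcdc_rows <- list()
  for (id in passed) {
    cl <- clips[[id]]
    m <- md[md$clip_id == id, , drop = FALSE]
    if (identical(m$task, "object")) {
      dd <- pc_dc_delta(cl, config$qc)
      if (!dd$accepted) {
        qc_report$pass[qc_report$clip_id == id] <- FALSE
        qc_report$reasons[qc_report$clip_id == id] <- dd$reason
        next
      }
      pcdc_rows[[id]] <- cbind(
        m[c("clip_id", "mouse_id", "genotype", "sex", "age_group", "line")],
        setNames(as.data.frame(dd$pc)[metric_names()],
                 paste0("pc_", metric_names())),
        setNames(as.data.frame(dd$dc)[metric_names()],
                 paste0("dc_", metric_names())),
        setNames(as.list(dd$delta), paste0("delta_", metric_names())),
        nose_object_mm = min_nose_object_distance(cl, config$arena))
    } else {
      rows[[id]] <- cbind(
        m[c("clip_id", "mouse_id", "genotype", "sex", "age_group", "line",
            "task", "session")],
        as.data.frame(clip_metrics(cl)))
    }
  }
  metrics <- do.call(rbind, rows)
  pcdc <- if (length(pcdc_rows)) do.call(rbind, pcdc_rows)
  if (is.null(metrics) && is.null(pcdc))
    stop("no clip survived QC and PC/DC sectioning; nothing to analyse")
  if (!is.null(metrics))
    write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
  data.table::fwrite(qc_report, file.path(out_dir, "qc_report.csv"))
  if (!is.null(pcdc))
    write_metrics_table(pcdc, file.path(out_dir, "pcdc.csv"))

  # --- inference --------------------------------------------------------
  if (!is.null(metrics))
    metrics$session <- factor(metrics$session,
                              levels = config$cohort$sessions)
  responses <- intersect(config$analysis$responses, names(metrics))
  lmm_rows <- list(); post_rows <- list()
  for (resp in responses) {
    fit <- try(fit_lmm(metrics, resp, fixed = "genotype * session"),
               silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit$f_table)) next
    lmm_rows[[resp]] <- cbind(response = resp, fit$f_table)
    if (nlevels(metrics$session) > 1L && !is.null(fit$model)) {
      ph <- try(posthoc_pairwise(fit, "session",
                                 adjust = config$analysis$posthoc_adjust),
                silent = TRUE)
      if (!inherits(ph, "try-error"))
        post_rows[[resp]] <- cbind(response = resp, ph$contrasts)
    }
  }
  lmm_table <- do.call(rbind, lmm_rows)
  posthoc_table <- do.call(rbind, post_rows)

  mv <- try(fit_manova(metrics, responses,
                       factors = c("genotype", "session"),
                       aggregate = config$analysis$manova_aggregate),
            silent = TRUE)
  manova_table <- if (!inherits(mv, "try-error"))
    do.call(rbind, lapply(names(mv), function(f)
      data.frame(factor = f, pillai = mv[[f]]$pillai, F = mv[[f]]$F,
                 df1 = mv[[f]]$df1, df2 = mv[[f]]$df2, p = mv[[f]]$p,
                 eta_sq_p = mv[[f]]$eta_sq_p,
                 size_class = mv[[f]]$size_class)))

  # --- zone occupancy ---------------------------------------------------
  of_ids <- intersect(passed, md$clip_id[md$task == "open_field"])
  zone_tab <- chisq <- NULL
  if (length(of_ids) >= 2L) {
    zs <- t(vapply(of_ids, function(id)
      unlist(zone_occupancy(clips[[id]]$centroid, config$arena,
                            px_per_mm = clips[[id]]$px_per_mm,
                            include_object = FALSE)[
                              c("pct_middle", "pct_edge")]),
      numeric(2)))
    geno <- md$genotype[match(of_ids, md$clip_id)]
    if (length(unique(geno)) == 2L) {
      zone_tab <- rowsum(zs, geno) / as.vector(table(geno))
      chisq <- chi_square_zones(zone_tab)
    }
  }

  for (nm in c("lmm_table", "posthoc_table", "manova_table"))
    if (!is.null(get(nm)))
      data.table::fwrite(get(nm), file.path(out_dir, paste0(nm, ".csv")))

  summary <- list(
    seed = config$seed,
    n_clips = length(clips), n_passed_qc = sum(qc_report$pass),
    n_analysed = list(open_field_habituation = nrow(metrics),
                      object = if (is.null(pcdc)) 0L else nrow(pcdc)),
    chi_square_zones = if (!is.null(chisq))
      chisq[c("statistic", "df", "p_value")])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- make_manifest(
    config, list.files(out_dir, full.names = TRUE),
    counts = list(clips_read = length(clips),
                  clips_passed_qc = sum(qc_report$pass),
                  clips_analysed = summary$n_analysed))
  write_manifest(manifest, out_dir)
  invisible(list(metrics = metrics, pcdc = pcdc, qc_report = qc_report,
                 lmm_table = lmm_table, posthoc_table = posthoc_table,
                 manova_table = manova_table, zone_table = zone_tab,
                 chi_square = chisq, summary = summary))
}

#' Simulate, analyse, and compare against generative truth
#'
#' The parameter-recovery harness: simulates a cohort, extracts the
#' metrics, and checks each against its closed-form expectation under the
#' generative model (setpoint; amplitude including the asymmetry and
#' whisker-offset contributions; spread shrunk by the c4 bias factor;
#' whisk-frequency band; contact-effect directions; habituation session
#' ordering).
#'
#' @param config a [load_config()] result
#' @param amplitude_tol,spread_tol relative tolerances for the closed-form
#'   comparisons
#' @return data.frame with one row per property: `observed`, `expected`,
#'   `pass`
#' @export
run_recovery <- function(config = load_config(quiet = TRUE),
                         amplitude_tol = 0.05, spread_tol = 0.1) {
  sim <- config$simulation
  cohort <- simulate_cohort(config$cohort, sim, config$arena,
                            seed = config$seed)
  md <- cohort$metadata
  res <- list()
  add <- function(property, observed, expected, pass)
    res[[length(res) + 1L]] <<- data.frame(property = property,
                                           observed = observed,
                                           expected = expected, pass = pass)

  plain <- md$clip_id[md$task != "object"]
  mets <- lapply(cohort$clips[plain], clip_metrics)
  tr <- cohort$truth[match(plain, cohort$truth$clip_id), ]

  dev_pos <- mean(vapply(mets, `[[`, 0, "mean_angular_position") -
                    tr$setpoint)
  add("setpoint_bias_deg", dev_pos, 0, abs(dev_pos) < 0.5)

  # pooled-SD amplitude picks up the asymmetry offset and the averaged
  # frame noise (whisker offsets are centred within a side)
  nw <- sim$n_whiskers_per_side
  exp_amp <- sqrt(tr$amplitude^2 + 2 * tr$asymmetry^2 +
                    (8 / nw) * sim$angle_noise_sd^2)
  obs_amp <- mean(vapply(mets, `[[`, 0, "amplitude"))
  add("amplitude_deg", obs_amp, mean(exp_amp),
      abs(obs_amp - mean(exp_amp)) < amplitude_tol * mean(exp_amp))

  exp_spr <- c4_factor(nw) *
    sqrt(tr$whisker_spread^2 + sim$angle_noise_sd^2)
  obs_spr <- mean(vapply(mets, `[[`, 0, "spread"))
  add("spread_deg", obs_spr, mean(exp_spr),
      abs(obs_spr - mean(exp_spr)) < spread_tol * mean(exp_spr))

  fhat <- vapply(cohort$clips[plain], function(cl)
    estimate_whisk_frequency(frame_mean_angles(cl)$left,
                             cl$fps)$frequency, 0)
  frac_f <- mean(abs(fhat - tr$frequency) < 1)
  add("frequency_within_1hz_frac", frac_f, 1, frac_f >= 0.9)

  obj <- md$clip_id[md$task == "object"]
  if (length(obj)) {
    ok <- vapply(cohort$clips[obj], function(cl) {
      dd <- pc_dc_delta(cl, config$qc)
      if (!dd$accepted) return(NA)
      all(dd$delta[c("amplitude", "asymmetry")] < 0) &&
        all(dd$delta[c("spread", "protraction_speed",
                       "retraction_speed")] > 0)
    }, NA)
    frac_dir <- mean(ok, na.rm = TRUE)
    add("contact_direction_frac", frac_dir, 1, frac_dir >= 0.9)
  }

  pos <- vapply(mets, `[[`, 0, "mean_angular_position")
  ses <- md$session[match(plain, md$clip_id)]
  msn <- tapply(pos, ses, mean)
  hb <- sim$habituation$setpoint
  if (all(c("OF", "H1", "H5") %in% names(msn)) &&
      all(c("H1", "H5") %in% names(hb)) && hb["H1"] < 0 &&
      hb["H5"] < hb["H1"]) {
    ord_ok <- msn["OF"] > msn["H1"] && msn["H1"] > msn["H5"]
    add("habituation_ordering", as.numeric(ord_ok), 1, ord_ok)
  }
  do.call(rbind, res)
}

prepare_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

make_manifest <- function(config, files, counts) {
  cfgfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config_as_list(config), cfgfile)
  on.exit(unlink(cfgfile))
  files <- unlist(files)
  list(package_version = as.character(utils::packageVersion("whiskerkin")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(cfgfile)),
       files = as.list(setNames(unname(tools::md5sum(files)),
                                basename(files))),
       counts = counts,
       timestamp_utc = format(Sys.time(), tz = "UTC"))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
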