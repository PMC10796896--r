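# End-to-end analysis: exposure QC -> per-image channel statistics ->
# per-source/channel calibration fits -> cross-source comparison and report.

#' Configure an analysis run
#'
#' Exactly one input mode must be active: a measured-run manifest CSV
#' (columns `file`, `source`, `concentration_mgdl`) pointing at photographs
#' on disk, or a list of [scene_config()] objects to simulate in memory.
#'
#' @param manifest Path to a manifest CSV, or a data frame.
#' @param scenes Named list of [scene_config()] objects (simulation mode).
#' @param concentrations Concentration series for simulation mode.
#' @param roi ROI spec used for measured images; `NULL` = [roi_default()].
#' @param sigma_method `"blank_sd"` (blank replicates; simulated scenes
#'   generate `n_blanks` of them, measured runs use rows with zero
#'   concentration) or `"residual_se"`. When `blank_sd` is requested but no
#'   blanks exist, the fit falls back to `residual_se` with a log note.
#' @param n_blanks Blank replicates to simulate per source.
#' @param qc Exposure thresholds, see [qc_params()].
#' @param channels Channels fitted per source.
#' @param seed Master seed for simulation mode.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(manifest = NULL, scenes = NULL,
                       concentrations = default_concentrations(),
                       roi = NULL, sigma_method = c("blank_sd", "residual_se"),
                       n_blanks = 8, qc = qc_params(),
                       channels = c("R", "G", "B", "Y"),
                       seed = 1, log_level = c("info", "quiet")) {
  sigma_method <- match.arg(sigma_method)
  log_level <- match.arg(log_level)
  if (is.null(manifest) == is.null(scenes))
    stop("exactly one input mode must be active: 'manifest' or 'scenes'")
  if (!is.null(scenes)) {
    if (inherits(scenes, "scene_config")) scenes <- list(scenes)
    names(scenes) <- vapply(scenes, function(s) s$source$name, character(1))
  }
  structure(list(manifest = manifest, scenes = scenes,
                 concentrations = concentrations, roi = roi,
                 sigma_method = sigma_method, n_blanks = n_blanks, qc = qc,
                 channels = match.arg(channels, several.ok = TRUE),
                 seed = seed, log_level = log_level),
            class = "run_config")
}

read_manifest <- function(x) {
  d <- if (is.data.frame(x)) x else utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("file", "source", "concentration_mgdl")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!file.exists(d$file))
  if (length(bad))
    stop("manifest rows with missing image files: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  d
}

log_line <- function(config, log, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (config$log_level == "info") message(msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' For each light source: exposure QC on the lowest-concentration image
#' (an overexposure failure aborts that source only, since exposure is
#' calibrated per source), channel statistics for every image, an OLS
#' calibration fit per colour channel with detection limits, and finally a
#' cross-source ranking selecting the best (source, channel) pair.
#' Deterministic given the configuration and seed.
#'
#' @param config A [run_config()].
#' @return An object of class `"analysis_report"`: `curves` (data frame,
#'   one row per source x channel), `curve_objects` (list of `"calib"`),
#'   `ranking`, `best`, `qc` (per-source status), `stats` (per-image),
#'   `log`, and `provenance` (config hash, seed, package version).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  per_source <- list()
  if (!is.null(config$scenes)) {
    for (nm in names(config$scenes)) {
      scene <- config$scenes[[nm]]
      src_seed <- config$seed + 1000L * (match(nm, names(config$scenes)) - 1L)
      mask <- build_roi(c(scene$height, scene$width), scene$roi)
      conc <- sort(config$concentrations)
      stats <- vector("list", length(conc))
      for (i in seq_along(conc)) {
        img <- render_strip(scene, conc[i], seed = src_seed + i - 1L)
        stats[[i]] <- channel_means(img, mask)
        log <- log_line(config, log, "%s c=%.3f mg/dL: ROI %d px, G mean %.3f",
                        nm, conc[i], stats[[i]]$n_pixels, stats[[i]]$mean_g)
      }
      blanks <- NULL
      if (config$sigma_method == "blank_sd")
        blanks <- generate_blanks(scene, config$n_blanks,
                                  base_seed = src_seed + 100000L)
      per_source[[nm]] <- list(concentration = conc, stats = stats,
                               blanks = blanks, source = scene$source)
    }
  } else {
    man <- read_manifest(config$manifest)
    roi <- config$roi %||% roi_default()
    for (nm in unique(man$source)) {
      rows <- man[man$source == nm, , drop = FALSE]
      rows <- rows[order(rows$concentration_mgdl), , drop = FALSE]
      is_blank <- rows$concentration_mgdl == 0
      stats <- lapply(rows$file, function(f) {
        img <- read_strip_image(f)
        s <- channel_means(img, build_roi(img, roi, image = img))
        s
      })
      for (i in seq_along(stats))
        log <- log_line(config, log, "%s %s: ROI %d px, G mean %.3f", nm,
                        basename(rows$file[i]), stats[[i]]$n_pixels,
                        stats[[i]]$mean_g)
      blanks <- if (any(is_blank)) stats[is_blank] else NULL
      per_source[[nm]] <- list(concentration = rows$concentration_mgdl[!is_blank],
                               stats = stats[!is_blank], blanks = blanks,
                               source = led_sources()[[nm]] %||%
                                 led_source(nm, 550, 30))
    }
  }

  curves <- list()
  qc_rows <- list()
  all_stats <- list()
  for (nm in names(per_source)) {
    ps <- per_source[[nm]]
    pref <- pref_channel(nm)
    qc_status <- exposure_qc(ps$stats[[which.min(ps$concentration)]],
                             channel = pref, params = config$qc)
    qc_rows[[nm]] <- data.frame(source = nm, status = qc_status)
    log <- log_line(config, log, "%s exposure QC: %s", nm, qc_status)
    tab <- cbind(concentration = ps$concentration, stats_table(ps$stats))
    all_stats[[nm]] <- cbind(source = nm, tab)
    if (qc_status == "fail_overexposed") {
      log <- log_line(config, log, "%s aborted (overexposed)", nm)
      next
    }
    for (ch in config$channels) {
      col <- c(R = "mean_r", G = "mean_g", B = "mean_b", Y = "mean_y")[[ch]]
      blank_means <- if (!is.null(ps$blanks))
        vapply(ps$blanks, `[[`, numeric(1), col) else NULL
      cv <- tryCatch({
        if (!is.null(blank_means) && config$sigma_method == "blank_sd")
          fit_line(tab, ch, blanks = blank_means, sigma_method = "blank_sd",
                   source = nm)
        else
          fit_line(tab, ch, sigma_method = "residual_se", source = nm)
      }, error = function(e) e)
      if (inherits(cv, "error")) {
        log <- log_line(config, log, "%s/%s fit error: %s", nm, ch,
                        conditionMessage(cv))
        next
      }
      curves[[paste(nm, ch, sep = "_")]] <- cv
    }
  }
  if (!length(curves)) {
    ranking <- NULL; best <- NULL
    curve_tab <- data.frame()
  } else {
    ranking <- select_best(curves)
    best <- ranking$best
    curve_tab <- ranking$ranking
    peak <- vapply(curve_tab$source, function(s) {
      ls <- led_sources()[[s]]
      if (is.null(ls)) NA_real_ else ls$peak_wavelength_nm
    }, numeric(1))
    npix <- vapply(curve_tab$source, function(s)
      all_stats[[s]]$n_pixels[1L], numeric(1))
    curve_tab <- cbind(curve_tab[, c("source", "channel")],
                       peak_nm = peak,
                       curve_tab[, c("slope", "intercept", "r_squared",
                                     "sigma", "lod", "loq", "n")],
                       n_pixels = npix)
    rownames(curve_tab) <- NULL
  }
  report <- structure(list(curves = curve_tab, curve_objects = curves,
                           ranking = ranking, best = best,
                           qc = do.call(rbind, qc_rows),
                           stats = do.call(rbind, c(all_stats,
                                                    make.row.names = FALSE)),
                           log = log,
                           provenance = list(seed = config$seed,
                                             version = as.character(
                                               utils::packageVersion("bilistrip")))),
                      class = "analysis_report")
  report$provenance$hash <- report_hash(report)
  if (!is.null(best))
    report$log <- log_line(config, report$log, "best combination: %s/%s",
                           best$source, best$channel)
  report
}

pref_channel <- function(source_name) {
  ch <- toupper(substr(source_name, 1L, 1L))
  if (ch %in% c("R", "G", "B")) ch else "G"
}

# md5 of the numeric content of the report (curves + per-image stats)
report_hash <- function(report) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  utils::write.csv(format(report$curves, digits = 12), con, row.names = FALSE)
  utils::write.csv(format(report$stats, digits = 12), con, row.names = FALSE)
  close(con)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  if (nrow(x$qc %||% data.frame())) {
    cat("QC: ", paste(sprintf("%s=%s", x$qc$source, x$qc$status),
                      collapse = ", "), "\n")
  }
  if (nrow(x$curves)) print(x$curves, digits = 4)
  if (!is.null(x$best))
    cat(sprintf("Best combination: %s / %s (R-squared %.4f, LOD %.3f mg/dL)\n",
                x$best$source, x$best$channel, x$best$r_squared, x$best$lod))
  invisible(x)
}

#' Write report files
#'
#' Writes `report.csv` (one row per curve, numbers rendered at configurable
#' precision), `report.json` (full precision, reloadable), and `run.log`.
#'
#' @param report An [run_analysis()] result.
#' @param outdir Output directory (created if missing).
#' @param precision List with `conc` (decimals for mg/dL quantities,
#'   default 3) and `coef` (slopes, intercepts, R-squared; default 4).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir,
                         precision = list(conc = 3, coef = 4)) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  csv <- file.path(outdir, "report.csv")
  js <- file.path(outdir, "report.json")
  lg <- file.path(outdir, "run.log")
  tab <- report$curves
  if (nrow(tab)) {
    fmt_c <- function(v) sprintf(paste0("%.", precision$conc, "f"), v)
    fmt_k <- function(v) sprintf(paste0("%.", precision$coef, "f"), v)
    tab$slope <- fmt_k(tab$slope); tab$intercept <- fmt_k(tab$intercept)
    tab$r_squared <- fmt_k(tab$r_squared)
    tab$sigma <- fmt_c(tab$sigma)
    tab$lod <- fmt_c(tab$lod); tab$loq <- fmt_c(tab$loq)
  }
  utils::write.csv(tab, csv, row.names = FALSE)
  payload <- list(curves = report$curves, qc = report$qc,
                  stats = report$stats,
                  best = if (!is.null(report$best))
                    list(source = report$best$source,
                         channel = report$best$channel),
                  provenance = report$provenance)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(report$log, lg)
  invisible(c(csv, js, lg))
}

#' Command-line entry point
#'
#' Thin dispatcher behind the installed `bilistrip` script
#' (`system.file("cli", "bilistrip", package = "bilistrip")`). Subcommands:
#' `simulate` (render a calibration run from a scene YAML), `analyze`
#' (run the pipeline on a manifest), `report` (re-export report files from
#' a report JSON), `limits` (print LOD/LOQ for a sigma/slope pair).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 1 validation error, 2 usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bilistrip <simulate|analyze|report|limits> [options]",
    "  simulate --config scene.yaml --out DIR [--seed N]",
    "  analyze  --manifest run/manifest.csv --out DIR",
    "           [--roi rect:H,W|full] [--sigma-method blank_sd|residual_se]",
    "           [--log-level info|quiet] [--seed N]",
    "  report   --json report.json --out DIR",
    "  limits   --sigma S --slope M", sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1L]
  opts <- tryCatch(parse_cli_opts(argv[-1L]), error = function(e) e)
  if (inherits(opts, "error") ||
      !cmd %in% c("simulate", "analyze", "report", "limits")) {
    message(if (inherits(opts, "error")) conditionMessage(opts)
            else paste0("unknown subcommand: ", cmd))
    message(usage)
    return(2L)
  }
  required <- switch(cmd, simulate = c("config", "out"),
                     analyze = c("manifest", "out"),
                     report = c("json", "out"),
                     limits = c("sigma", "slope"))
  miss <- setdiff(required, names(opts))
  if (length(miss)) {
    message("missing required option(s): --", paste(miss, collapse = ", --"))
    message(usage)
    return(2L)
  }
  res <- tryCatch({
    switch(cmd,
      simulate = {
        scene <- scene_from_yaml(opts$config)
        if (!is.null(opts$seed)) scene$seed <- as.integer(opts$seed)
        man <- generate_calibration_run(scene, outdir = opts$out)
        message(sprintf("wrote %d images + manifest to %s", nrow(man),
                        opts$out))
      },
      analyze = {
        roi <- if (!is.null(opts$roi)) parse_roi_opt(opts$roi) else NULL
        cfg <- run_config(manifest = opts$manifest, roi = roi,
                          sigma_method = opts[["sigma-method"]] %||% "blank_sd",
                          seed = as.integer(opts$seed %||% 1),
                          log_level = opts[["log-level"]] %||% "info")
        rep <- run_analysis(cfg)
        write_report(rep, opts$out)
        print(rep)
      },
      report = {
        payload <- jsonlite::read_json(opts$json, simplifyVector = TRUE)
        rep <- structure(list(curves = payload$curves, qc = payload$qc,
                              stats = payload$stats, best = NULL,
                              log = character(),
                              provenance = payload$provenance),
                         class = "analysis_report")
        write_report(rep, opts$out)
        message("report files written to ", opts$out)
      },
      limits = {
        lim <- detection_limits(as.numeric(opts$sigma),
                                as.numeric(opts$slope))
        cat(sprintf("LOD = %.3f mg/dL\nLOQ = %.3f mg/dL\n",
                    lim[["lod"]], lim[["loq"]]))
      })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  res
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  known <- c("config", "out", "seed", "manifest", "roi", "sigma-method",
             "log-level", "json", "sigma", "slope")
  bad <- setdiff(names(opts), known)
  if (length(bad)) stop("unknown flag(s): --", paste(bad, collapse = ", --"))
  opts
}

parse_roi_opt <- function(s) {
  if (s == "full") return(roi_full())
  if (startsWith(s, "rect:")) {
    hw <- as.integer(strsplit(substring(s, 6L), ",")[[1L]])
    return(roi_rect(hw[1L], hw[2L]))
  }
  stop("cannot parse ROI spec: ", s)
}
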