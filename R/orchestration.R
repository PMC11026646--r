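#' Run one analysis stage from a config
#'
#' Config-driven driver for the full experiment layout. The config (a
#' YAML file or an equivalent named list) carries a `seed`, an
#' `output_dir`, and one block per stage; `run_stage()` executes a
#' single stage over its inputs, writes CSV tables plus a summary JSON
#' and a plain-text log into `output_dir`, and returns the results
#' bundle. Runs are deterministic given config + seed; numeric table
#' fields are rounded to 6 significant digits at write time so repeated
#' runs produce byte-identical tables.
#'
#' Stages:
#' * `simulate` — generate a tunnel time-lapse, a neurite field, a
#'   synapse pair, a z-stack and an MEA recording with ground truth
#'   (files under `output_dir/sim`).
#' * `mito` — mitochondria counts per tunnel for listed series TIFFs.
#' * `kymo` — kymograph + track table per tunnel for listed series.
#' * `morpho` — bouton counts / neurite area for listed images.
#' * `ephys` — spikes, rates and connectivity for listed recordings.
#'
#' @param stage one of `"simulate"`, `"mito"`, `"kymo"`, `"morpho"`,
#'   `"ephys"`.
#' @param config path to a YAML config, or a named list.
#' @return list of class `results_bundle`: `tables` (named list of
#'   data.frames), `summary`, `files` written, `log`.
#' @export
run_stage <- function(stage = c("simulate", "mito", "kymo", "morpho",
                                "ephys"), config) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$output_dir)) stop("config must name an output_dir")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("stage=%s seed=%s", stage, format(cfg$seed %||% NA))
  tables <- list()
  summary <- list(stage = stage, seed = cfg$seed)

  if (stage == "simulate") {
    sp <- do.call(sim_params, cfg$sim %||% list())
    simdir <- file.path(cfg$output_dir, "sim")
    dir.create(simdir, showWarnings = FALSE)
    ms <- gen_mito_series(sp)
    write_tiff(ms$series, file.path(simdir, "tunnels.tif"))
    write_rois(ms$rois, file.path(simdir, "tunnels.rois.json"))
    write.csv(ms$truth$objects, file.path(simdir, "tunnels.truth.csv"),
              row.names = FALSE)
    ne <- gen_neurite_image(sp)
    write_tiff(ne$image, file.path(simdir, "neurites.tif"))
    write.csv(ne$truth$objects, file.path(simdir, "neurites.truth.csv"),
              row.names = FALSE)
    sy <- gen_synapse_channels(sp)
    write_tiff(sy$channel_a, file.path(simdir, "synapse_pre.tif"))
    write_tiff(sy$channel_b, file.path(simdir, "synapse_post.tif"))
    zs <- gen_zstack(sp)
    write_tiff(zs$stack, file.path(simdir, "zstack.tif"))
    me <- gen_mea_recording(sp)
    write_recording(me$recording, file.path(simdir, "mea.raw"))
    write.csv(me$truth$objects, file.path(simdir, "mea.truth.csv"),
              row.names = FALSE)
    tables$truth_counts <- data.frame(
      asset = c("tunnels", "neurites", "synapses", "mea_spikes"),
      records = c(nrow(ms$truth$objects), nrow(ne$truth$objects),
                  nrow(sy$truth$objects), nrow(me$truth$objects)))
    note("simulated assets under %s", simdir)
  } else if (stage == "mito") {
    rows <- list()
    for (item in cfg$mito$series) {
      series <- read_tiff(item$path)
      rois <- read_rois(item$rois)
      mc <- do.call(mito_cfg, cfg$mito$params %||% list())
      for (i in seq_len(nrow(rois))) {
        det <- detect_mitochondria(get_frame(series, 1L), mc, rois[i, ])
        rows[[length(rows) + 1L]] <- data.frame(
          path = item$path, tunnel = rois$tunnel[i], count = det$count,
          mean_size_um2 = if (det$count) mean(det$sizes_um2) else NA_real_)
      }
      note("mito: %s (%d tunnels)", item$path, nrow(rois))
    }
    tables$mito_counts <- do.call(rbind, rows)
  } else if (stage == "kymo") {
    kc <- do.call(kymo_cfg, cfg$kymo$params %||% list())
    trows <- list(); srows <- list()
    for (item in cfg$kymo$series) {
      series <- read_tiff(item$path)
      rois <- read_rois(item$rois)
      for (i in seq_len(nrow(rois))) {
        km <- build_kymograph(series, rois[i, ])
        sup <- suppress_stationary(km)
        tr <- detect_tracks(sup$filtered, kc)
        ms <- motility_summary(tr, sup$n_stationary)
        if (nrow(tr)) {
          tr$path <- item$path
          trows[[length(trows) + 1L]] <- tr
        }
        srows[[length(srows) + 1L]] <- data.frame(
          path = item$path, tunnel = rois$tunnel[i],
          n_motile = ms$n_motile, n_stationary = ms$n_stationary,
          motile_ratio = ms$motile_ratio,
          mean_speed_um_s = ms$mean_speed_um_s,
          anterograde_fraction = ms$anterograde_fraction)
      }
      note("kymo: %s (%d tunnels)", item$path, nrow(rois))
    }
    tables$tracks <- if (length(trows)) do.call(rbind, trows) else
      data.frame()
    tables$motility <- do.call(rbind, srows)
  } else if (stage == "morpho") {
    mc <- do.call(morpho_cfg, cfg$morpho$params %||% list())
    rows <- list()
    for (item in cfg$morpho$images) {
      img <- read_tiff(item$path)
      manual <- if (!is.null(item$manual) && file.exists(item$manual))
        read.csv(item$manual) else NULL
      br <- count_boutons(img, mc, manual)
      rows[[length(rows) + 1L]] <- data.frame(
        path = item$path, n_boutons = br$n_boutons,
        n_manual = br$n_manual_added,
        neurite_area_um2 = br$neurite_area_um2,
        density_per_um2 = br$density_per_um2)
      note("morpho: %s -> %d boutons", item$path, br$n_total)
    }
    tables$boutons <- do.call(rbind, rows)
  } else if (stage == "ephys") {
    ec <- do.call(ephys_cfg, cfg$ephys$params %||% list())
    srow <- list(); prow <- list()
    for (item in cfg$ephys$recordings) {
      rec <- read_recording(item$path)
      st <- detect_spikes(bandpass(rec, ec), ec)
      mfr <- mean_firing_rate(st, rec$duration_s)
      conn <- network_correlation(st, cfg = ec)
      srow[[length(srow) + 1L]] <- data.frame(
        path = item$path, n_spikes = sum(lengths(st$times)),
        network_mfr = mfr$network_mfr, mfr_sd = mfr$network_sd,
        n_active = conn$n_active,
        total_r = conn$total_network_correlation)
      if (nrow(conn$pairs)) {
        conn$pairs$path <- item$path
        prow[[length(prow) + 1L]] <- conn$pairs
      }
      note("ephys: %s (%d active)", item$path, conn$n_active)
    }
    tables$ephys_summary <- do.call(rbind, srow)
    tables$connectivity <- if (length(prow)) do.call(rbind, prow) else
      data.frame()
  }

  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(cfg$output_dir, paste0(stage, "_", nm, ".csv"))
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  logfile <- file.path(cfg$output_dir, paste0(stage, ".log"))
  writeLines(log, logfile)
  jsonlite::write_json(summary,
                       file.path(cfg$output_dir, paste0(stage,
                                                        "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  structure(list(tables = tables, summary = summary, files = files,
                 log = log), class = "results_bundle")
}

#' Normality-routed two-group comparison table
#'
#' For each response named in `design`, checks normality per group
#' (Shapiro-Wilk at 0.05) and routes to the parametric test (Welch t,
#' or paired t) when both groups look normal, otherwise to the
#' non-parametric alternative (Mann-Whitney, or Wilcoxon signed-rank).
#' Groups with fewer than 2 (unpaired) or 2 pairs (paired) observations
#' are flagged and skipped. Tests themselves are delegated to the
#' standard routines.
#'
#' @param data data.frame with a `group` column (2 levels) and numeric
#'   response columns.
#' @param responses response column names to compare.
#' @param paired use paired tests (rows must align within group).
#' @return data.frame: response, test, statistic, p, n per group, flag.
#' @export
compare_groups <- function(data, responses, paired = FALSE) {
  g <- factor(data$group)
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  rows <- lapply(responses, function(resp) {
    x <- data[[resp]][g == lv[1]]
    y <- data[[resp]][g == lv[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2 || (paired &&
                                           length(x) != length(y)))
      return(data.frame(response = resp, test = NA_character_,
                        statistic = NA_real_, p = NA_real_,
                        n1 = length(x), n2 = length(y),
                        flag = "degenerate group"))
    normal <- function(v) length(unique(v)) > 2 &&
      length(v) >= 3 && shapiro.test(v)$p.value > 0.05
    if (paired) {
      d <- x - y
      if (all(d == 0))
        return(data.frame(response = resp, test = "paired t",
                          statistic = 0, p = 1, n1 = length(x),
                          n2 = length(y), flag = ""))
      use_param <- normal(d)
      ht <- if (use_param) t.test(x, y, paired = TRUE)
      else wilcox.test(x, y, paired = TRUE, exact = FALSE)
      tname <- if (use_param) "paired t" else "wilcoxon signed-rank"
    } else {
      use_param <- normal(x) && normal(y)
      ht <- if (use_param) t.test(x, y)
      else wilcox.test(x, y, exact = FALSE)
      tname <- if (use_param) "welch t" else "mann-whitney"
    }
    data.frame(response = resp, test = tname,
               statistic = unname(ht$statistic), p = ht$p.value,
               n1 = length(x), n2 = length(y), flag = "")
  })
  do.call(rbind, rows)
}
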