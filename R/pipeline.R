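#' Default pipeline configuration
#'
#' Nested list capturing every generator and analysis parameter; write it to
#' YAML, edit, and feed to [runPipeline()]. Defaults reproduce the canonical
#' screen structure: 384-well plates, 3 oligos per gene in separate wells,
#' negative/lethal/LMNA controls on every plate, 2 biological replicates,
#' ~300 cells seeded per well (so analyzed nuclei typically exceed 250), and
#' additive row/column plate gradients.
#'
#' @param n_genes library size.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
defaultScreenConfig <- function(n_genes = 100L, seed = 1L) {
  list(
    seed = seed,
    layout = list(n_genes = n_genes, oligos_per_gene = 3L,
                  n_rows = 16L, n_cols = 24L,
                  controls_per_plate = list(neg_ctrl = 8L, lethal_ctrl = 4L,
                                            lmna_ctrl = 4L),
                  control_placement = "columns"),
    truth = list(hit_spec = list(), cytotoxic = list(n = 0L,
                                                     range = c(0.1, 0.5)),
                 plate_effects = list(row_amp = 0.5, col_amp = 0.5,
                                      edge = 0.25)),
    cells = list(mean = 300, dispersion = 20, replicates = 2L),
    images = list(render = FALSE, size = c(512L, 512L),
                  cells_per_field = 12L, background = 400, noise_sd = 50),
    segmentation = list(threshold = "otsu", min_area = 50L),
    scoring = list(mad_constant = 1.4826, min_count = 50L),
    hits = list(threshold = 1.5, viability_threshold = -2,
                two_sided_shape = FALSE)
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

.loadConfig <- function(config) {
  user <- if (is.character(config)) {
    .checkTrue(file.exists(config), "config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a path or a list", call. = FALSE)
  .mergeConfig(defaultScreenConfig(
    n_genes = user$layout$n_genes %||% 100L,
    seed = user$seed %||% 1L), user)
}

.md5 <- function(paths) {
  v <- tools::md5sum(paths)
  stats::setNames(unname(v), basename(paths))
}

.needFile <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' expects '", path,
         "'; run the '", producer, "' stage first", call. = FALSE)
  }
  path
}

#' Run the screen analysis pipeline
#'
#' Chains the analysis end-to-end, each stage runnable independently on the
#' previous stage's files in `out_dir`:
#' \describe{
#'   \item{simulate}{build layout + ground truth, simulate per-nucleus tables,
#'     aggregate to per-well summaries (and optionally render field images).}
#'   \item{segment}{segment and measure rendered field images (listed in
#'     `fields.csv`) and aggregate to per-well summaries.}
#'   \item{score}{B-score / robust-Z / replicate-mean chain on the well table.}
#'   \item{call-hits}{gene medians, directional hit flags, viability
#'     exclusion; writes gene table and per-class hit lists.}
#'   \item{report}{markdown summary of the run.}
#' }
#' Every run writes the resolved configuration and a manifest (config hash,
#' master seed, per-file MD5 checksums, stage timings and counts): re-running
#' with identical config and seed reproduces identical checksums for all
#' deterministic stages.
#'
#' @param config configuration list or YAML path (see
#'   [defaultScreenConfig()]).
#' @param out_dir output directory (created if needed).
#' @param stages stages to run, in order.
#' @param seed optional master-seed override.
#' @param quiet suppress progress logging (stderr).
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config = defaultScreenConfig(),
                        out_dir = "nucscreen_out",
                        stages = c("simulate", "score", "call-hits",
                                   "report"),
                        seed = NULL, quiet = FALSE) {
  cfg <- .loadConfig(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[nucscreen] ", ...)
  resolved <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, resolved)
  manifest <- list(package_version = as.character(utils::packageVersion("nucscreen")),
                   config_md5 = unname(tools::md5sum(resolved)),
                   seed = cfg$seed, stages = list(), files = list())
  t_all <- Sys.time()
  paths <- list(layout = file.path(out_dir, "layout.csv"),
                truth = file.path(out_dir, "truth.json"),
                cells = file.path(out_dir, "cells.csv"),
                wells = file.path(out_dir, "wells.csv"),
                fields = file.path(out_dir, "fields.csv"),
                oligo = file.path(out_dir, "oligo_scores.csv"),
                genes = file.path(out_dir, "gene_calls.csv"),
                report = file.path(out_dir, "report.md"))

  for (stage in stages) {
    t0 <- Sys.time()
    counts <- list()
    if (stage == "simulate") {
      lcfg <- cfg$layout
      lay <- buildLibraryLayout(
        n_genes = lcfg$n_genes, oligos_per_gene = lcfg$oligos_per_gene,
        n_rows = lcfg$n_rows, n_cols = lcfg$n_cols,
        controls_per_plate = unlist(lcfg$controls_per_plate),
        control_placement = lcfg$control_placement, seed = cfg$seed)
      tcfg <- cfg$truth
      truth <- sampleGroundTruth(
        lay, hit_spec = tcfg$hit_spec,
        cytotoxic_spec = list(n = tcfg$cytotoxic$n,
                              range = tcfg$cytotoxic$range),
        plate_effect_spec = tcfg$plate_effects,
        cells_mean = cfg$cells$mean,
        cells_dispersion = cfg$cells$dispersion, seed = cfg$seed)
      cells <- simulateCells(lay, truth,
                             replicates = seq_len(cfg$cells$replicates))
      wellsum <- aggregateWells(cells, lay,
                                min_count = cfg$scoring$min_count)
      writeLayout(lay, paths$layout)
      writeGroundTruth(truth, paths$truth)
      writeCellTable(cells, paths$cells)
      writeWellTable(wellsum, paths$wells)
      counts <- list(plates = length(plateIds(lay)),
                     library_wells = nrow(libraryTable(lay)),
                     nuclei = nrow(cells))
      log("simulate: ", counts$nuclei, " nuclei over ",
          counts$library_wells, " library wells")
      if (isTRUE(cfg$images$render)) {
        counts$fields <- .renderStage(cfg, cells, out_dir, paths)
        log("simulate: rendered ", counts$fields, " fields")
      }
    } else if (stage == "segment") {
      idx <- utils::read.csv(.needFile(paths$fields, "segment", "simulate"),
                             stringsAsFactors = FALSE)
      recs <- list()
      for (i in seq_len(nrow(idx))) {
        dapi <- readImageGray(.needFile(
          file.path(out_dir, idx$dapi[i]), "segment", "simulate"))
        chans <- list(
          laminAC = readImageGray(file.path(out_dir, idx$laminAC[i])),
          laminB1 = readImageGray(file.path(out_dir, idx$laminB1[i])))
        mask <- segmentNuclei(dapi, threshold = cfg$segmentation$threshold,
                              min_area = cfg$segmentation$min_area)
        m <- measureNuclei(mask, chans, plate_id = idx$plate_id[i],
                           well = idx$well[i], field = idx$field[i])
        if (nrow(m)) {
          m$replicate <- idx$replicate[i]
          recs[[length(recs) + 1L]] <- m
        }
      }
      cells <- do.call(rbind, recs)
      lay <- readLayout(.needFile(paths$layout, "segment", "simulate"))
      w <- layoutWells(lay)
      j <- match(paste(cells$plate_id, cells$well),
                 paste(w$plate_id, w$well))
      cells <- cbind(cells, w[j, c("row", "col", "role", "gene_id",
                                   "oligo_id")])
      wellsum <- aggregateWells(cells, lay,
                                min_count = cfg$scoring$min_count)
      writeCellTable(cells, file.path(out_dir, "cells_measured.csv"))
      writeWellTable(wellsum, paths$wells)
      counts <- list(fields = nrow(idx), nuclei = nrow(cells))
      log("segment: ", counts$nuclei, " nuclei from ", counts$fields,
          " fields")
    } else if (stage == "score") {
      wellsum <- readWellTable(.needFile(paths$wells, "score",
                                         "simulate or segment"))
      sc <- scoreScreen(wellsum, mad_constant = cfg$scoring$mad_constant)
      utils::write.csv(oligoScores(sc), paths$oligo, row.names = FALSE)
      counts <- list(wells_scored = sum(wellsum$role == "library"),
                     oligo_rows = nrow(oligoScores(sc)))
      log("score: ", counts$oligo_rows, " oligo x feature scores")
    } else if (stage == "call-hits") {
      ol <- utils::read.csv(.needFile(paths$oligo, "call-hits", "score"),
                            stringsAsFactors = FALSE)
      calls <- callHits(ol, threshold = cfg$hits$threshold,
                        viability_threshold = cfg$hits$viability_threshold,
                        two_sided_shape = cfg$hits$two_sided_shape)
      utils::write.csv(geneCalls(calls), paths$genes, row.names = FALSE)
      for (cls in .HIT_CLASSES$class) {
        writeLines(hitList(calls, cls),
                   file.path(out_dir, paste0("hits_", cls, ".txt")))
      }
      counts <- list(genes = nrow(geneCalls(calls)),
                     shape_hits = length(hitList(calls, "shape_hit")),
                     excluded = sum(geneCalls(calls)$excluded_cytotoxic))
      log("call-hits: ", counts$shape_hits, " shape hits of ",
          counts$genes, " genes (", counts$excluded, " excluded)")
    } else if (stage == "report") {
      gen <- utils::read.csv(.needFile(paths$genes, "report", "call-hits"),
                             stringsAsFactors = FALSE)
      .writeReport(gen, cfg, paths$report)
      counts <- list(genes = nrow(gen))
      log("report: written to ", paths$report)
    } else {
      stop("unknown stage: ", stage, call. = FALSE)
    }
    manifest$stages[[stage]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      counts = counts)
  }
  outfiles <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  outfiles <- outfiles[!grepl("manifest\\.json$", outfiles)]
  manifest$files <- as.list(.md5(outfiles))
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## render fields for every well of the simulated cell table; returns the
## number of fields written and writes fields.csv index
.renderStage <- function(cfg, cells, out_dir, paths) {
  idx <- list()
  key <- paste(cells$replicate, cells$plate_id, cells$well)
  n_fields <- 0L
  for (k in unique(key)) {
    sub <- cells[key == k, , drop = FALSE]
    fields <- shapesFromRecords(sub, image_size = unlist(cfg$images$size),
                                cells_per_field = cfg$images$cells_per_field,
                                seed = childSeed(cfg$seed, "render", k))
    for (fi in seq_along(fields)) {
      fld <- renderField(fields[[fi]],
                         image_size = unlist(cfg$images$size),
                         background = cfg$images$background,
                         noise_sd = cfg$images$noise_sd,
                         seed = childSeed(cfg$seed, "noise", k, fi))
      base <- sprintf("%s_%s_%d", sub$plate_id[1], sub$well[1], fi)
      files <- c(dapi = paste0(base, "_dapi.tif"),
                 laminAC = paste0(base, "_laminAC.tif"),
                 laminB1 = paste0(base, "_laminB1.tif"))
      for (ch in names(files)) {
        writeImageGray(fld$images[[ch]], file.path(out_dir, files[[ch]]))
      }
      n_fields <- n_fields + 1L
      idx[[n_fields]] <- data.frame(
        replicate = sub$replicate[1], plate_id = sub$plate_id[1],
        well = sub$well[1], field = fi, dapi = files[["dapi"]],
        laminAC = files[["laminAC"]], laminB1 = files[["laminB1"]],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, idx), paths$fields, row.names = FALSE)
  n_fields
}

.writeReport <- function(genes, cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# Nuclear morphology screen report")
  w("")
  w("Genes scored: ", nrow(genes), "; hit threshold |median Z| >= ",
    cfg$hits$threshold, "; viability exclusion at cell-number Z <= ",
    cfg$hits$viability_threshold, ".")
  w("")
  for (i in seq_len(nrow(.HIT_CLASSES))) {
    cls <- .HIT_CLASSES$class[i]
    f <- .HIT_CLASSES$feature[i]
    side <- .HIT_CLASSES$side[i]
    col <- paste0("median_", f)
    sel <- genes[[cls]] %in% TRUE & !genes$excluded_cytotoxic %in% TRUE
    w("## ", cls, " (", sum(sel), " genes)")
    w("")
    if (any(sel)) {
      g <- genes[sel, c("gene_id", col, paste0("sd_", f))]
      g <- g[order(side * g[[col]], decreasing = TRUE), ]
      w("| gene | median Z (", f, ") | SD over oligos |")
      w("|------|------------------:|---------------:|")
      for (j in seq_len(nrow(g))) {
        w("| ", g$gene_id[j], " | ", sprintf("%.2f", g[[col]][j]), " | ",
          sprintf("%.2f", g[[3]][j]), " |")
      }
    }
    w("")
  }
  excl <- genes$gene_id[genes$excluded_cytotoxic %in% TRUE]
  w("## Viability exclusions (", length(excl), " genes)")
  w("")
  if (length(excl)) w(paste(excl, collapse = ", "))
  invisible(path)
}
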